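#' @title Paired comparisons of prediction accuracy
#'
#' @description
#' Two-group comparisons of per-gene accuracy (continental groups; or the
#' same genes predicted from two different weight databases) use a paired
#' t-test with the pairing on the gene: each gene contributes one
#' difference in correlation coefficients, so between-gene variation
#' cancels.
#' @name comparison
NULL

#' Paired t-test on per-gene accuracy values
#'
#' Pairs are matched by name when both vectors are named, otherwise by
#' position. Incomplete pairs (either value missing) are dropped and
#' counted.
#'
#' @param x,y numeric vectors of per-gene values (e.g. Pearson r for two
#'   groups), paired by gene.
#' @return Object of class `paired_t_result`: `mean_diff` (mean of x - y),
#'   `t`, `df` (= pairs - 1), `p` (two-sided), `n_pairs`, `n_dropped`.
#' @export
paired_t_test <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    shared <- intersect(names(x), names(y))
    n_dropped <- (length(x) - length(shared)) + (length(y) - length(shared))
    x <- x[shared]
    y <- y[shared]
  } else {
    if (length(x) != length(y)) {
      stop("unnamed vectors must have equal length", call. = FALSE)
    }
    n_dropped <- 0L
  }
  d <- x - y
  incomplete <- is.na(d)
  n_dropped <- n_dropped + sum(incomplete)
  d <- d[!incomplete]
  n <- length(d)
  if (n < 2L) stop("fewer than 2 complete pairs", call. = FALSE)
  s <- stats::sd(d)
  if (s < 1e-300) {
    stop("degenerate paired differences: zero variance", call. = FALSE)
  }
  tstat <- mean(d) / (s / sqrt(n))
  structure(list(mean_diff = mean(d), t = tstat, df = n - 1L,
                 p = 2 * stats::pt(-abs(tstat), df = n - 1L),
                 n_pairs = n, n_dropped = n_dropped),
            class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat("Paired t-test (pairing by gene)\n  mean difference = ",
      format(x$mean_diff, digits = 6), "\n  t(", x$df, ") = ",
      format(x$t, digits = 6), ", p = ", format.pval(x$p, digits = 4),
      "\n  pairs: ", x$n_pairs,
      if (x$n_dropped > 0L) paste0(" (", x$n_dropped, " dropped)") else "",
      "\n", sep = "")
  invisible(x)
}

#' Compare two weight databases' accuracy on shared genes
#'
#' Both correlation tables must use the pooled all-samples grouping (a
#' single group column). Genes are intersected and the per-gene r values
#' compared with [paired_t_test()] — a positive mean difference means
#' database A predicts better.
#'
#' @param tableA,tableB single-group [correlation_table()]s from the same
#'   expression data scored against two databases.
#' @return A `paired_t_result` (see [paired_t_test()]) plus `n_shared`.
#' @export
compare_databases <- function(tableA, tableB) {
  stopifnot(inherits(tableA, "correlation_table"),
            inherits(tableB, "correlation_table"))
  if (ncol(tableA$r) != 1L || ncol(tableB$r) != 1L) {
    stop("compare_databases expects pooled (single-group) tables",
         call. = FALSE)
  }
  shared <- intersect(tableA$genes, tableB$genes)
  if (length(shared) == 0L) {
    stop("no genes shared between the two tables", call. = FALSE)
  }
  res <- paired_t_test(stats::setNames(tableA$r[shared, 1L], shared),
                       stats::setNames(tableB$r[shared, 1L], shared))
  res$n_shared <- length(shared)
  res
}

#' Write mixed-model and ANOVA results as a TSV block
#'
#' One row per contrast (estimate, SE, 95% CI, p) followed by an `anova`
#' row (F, df1, df2, p), mirroring a per-population results table.
#'
#' @param fit an `lmm_fit`.
#' @param anova an `anova_result`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_lmm_tsv <- function(fit, anova, path) {
  contrasts <- names(fit$beta)[-1L]
  rows <- data.frame(
    term = c(contrasts, "anova_F"),
    estimate = c(fit$beta[contrasts], anova$F),
    se = c(fit$se[contrasts], NA_real_),
    ci_lower = c(fit$ci95[contrasts, "lower"], NA_real_),
    ci_upper = c(fit$ci95[contrasts, "upper"], NA_real_),
    df1 = c(rep(NA_integer_, length(contrasts)), anova$df1),
    df2 = c(rep(NA_integer_, length(contrasts)), anova$df2),
    p = c(vapply(contrasts, function(g) wald_test(fit, g)$p, numeric(1)),
          anova$p),
    row.names = NULL
  )
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
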