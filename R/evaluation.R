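#' @title Scoring prediction accuracy
#'
#' @description
#' Accuracy is scored per gene and per sample group (typically population)
#' as the Pearson correlation r between observed and predicted expression.
#' r is used rather than r^2 so that directionality counts: genes whose
#' predictions correlate negatively with observation are genuinely badly
#' predicted, which r^2 would mask. Genes with a constant vector in a group
#' have no defined correlation and the cell is recorded as missing.
#' @name evaluation
NULL

.VAR_TOL <- 1e-12

#' Pearson correlation with explicit constant-vector handling
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return The Pearson correlation estimate, or `NA` with attribute
#'   `reason = "constant_input"` when either vector's sample variance is
#'   below `1e-12` (correlation undefined).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(x) < .VAR_TOL || stats::var(y) < .VAR_TOL) {
    return(structure(NA_real_, reason = "constant_input"))
  }
  stats::cor(x, y)
}

#' Construct a correlation table
#'
#' @param r genes x groups matrix of Pearson correlations (NA = missing).
#' @param n genes x groups matrix of per-cell sample counts.
#' @return Object of class `correlation_table` with elements `r`, `n`,
#'   `groups`, `genes`.
#' @export
correlation_table <- function(r, n) {
  stopifnot(is.matrix(r), identical(dim(r), dim(n)))
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE)) {
    stop("|r| > 1 in correlation table", call. = FALSE)
  }
  structure(list(r = r, n = n, groups = colnames(r), genes = rownames(r)),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, ...) {
  cat("correlation_table: ", nrow(x$r), " genes x ", ncol(x$r),
      " groups (", sum(is.na(x$r)), " missing cells)\n", sep = "")
  invisible(x)
}

#' Per-gene, per-group correlations between observed and predicted expression
#'
#' For every gene and every sample group, computes [pearson_r()] between
#' the observed and predicted expression vectors restricted to the group's
#' samples. Groups must be disjoint; pooled groupings (all samples, or a
#' continental pool) are expressed as their own single-group call.
#'
#' @param observed,predicted genes x samples matrices sharing gene and
#'   sample names (order may differ).
#' @param grouping named character vector mapping sample id -> group, or a
#'   data.frame with columns `sample_id`, `population`.
#' @return A [correlation_table()], genes x groups; cells are missing when
#'   either vector was constant within the group.
#' @export
compute_correlations <- function(observed, predicted, grouping) {
  if (is.data.frame(grouping)) {
    grouping <- stats::setNames(as.character(grouping$population),
                                grouping$sample_id)
  }
  samples <- intersect(colnames(observed), colnames(predicted))
  samples <- samples[samples %in% names(grouping)]
  genes <- intersect(rownames(observed), rownames(predicted))
  if (length(genes) == 0L) stop("no shared genes", call. = FALSE)
  obs <- observed[genes, samples, drop = FALSE]
  pre <- predicted[genes, samples, drop = FALSE]
  grp <- grouping[samples]
  groups <- unique(unname(grp))
  sizes <- table(grp)
  if (any(sizes < 3L)) {
    stop("group(s) with fewer than 3 samples: ",
         paste(names(sizes)[sizes < 3L], collapse = ", "), call. = FALSE)
  }
  r <- matrix(NA_real_, length(genes), length(groups),
              dimnames = list(genes, groups))
  n <- matrix(0L, length(genes), length(groups),
              dimnames = list(genes, groups))
  for (g in groups) {
    idx <- which(grp == g)
    m <- length(idx)
    a <- obs[, idx, drop = FALSE]
    b <- pre[, idx, drop = FALSE]
    a <- a - rowMeans(a)
    b <- b - rowMeans(b)
    ssa <- rowSums(a * a)
    ssb <- rowSums(b * b)
    ok <- ssa / (m - 1) >= .VAR_TOL & ssb / (m - 1) >= .VAR_TOL
    rg <- rep(NA_real_, length(genes))
    rg[ok] <- rowSums(a * b)[ok] / sqrt(ssa[ok] * ssb[ok])
    r[, g] <- rg
    n[, g] <- m
  }
  correlation_table(r, n)
}

#' Filter genes whose predictions carry no signal
#'
#' For each gene a simple linear regression of observed on predicted
#' expression is fit over the pooled samples (all populations together) and
#' the slope is tested with a two-sided Wald test. Genes with p above
#' `alpha` are labeled `poorly_predicted`; genes whose predicted vector is
#' constant (no slope estimable) are `excluded_constant`; the rest are
#' `kept`. The test is two-sided, so genes with a significantly negative
#' slope are kept.
#'
#' With `grouping` supplied the regression is instead run within each group
#' (sensitivity mode) and a gene is kept when its slope is significant in
#' at least one group; the pooled regression is the primary definition.
#'
#' @param observed,predicted genes x samples matrices sharing names.
#' @param alpha significance level for the slope Wald test (default 0.05).
#' @param grouping optional sample -> group map enabling per-group mode.
#' @return data.frame with columns `gene_id`,
#'   `status` (kept / poorly_predicted / excluded_constant), `p_value`.
#' @export
filter_poorly_predicted <- function(observed, predicted, alpha = 0.05,
                                    grouping = NULL) {
  samples <- intersect(colnames(observed), colnames(predicted))
  genes <- intersect(rownames(observed), rownames(predicted))
  n <- length(samples)
  if (n <= 2L) stop("need more than 2 samples", call. = FALSE)
  if (!is.null(grouping)) {
    if (is.data.frame(grouping)) {
      grouping <- stats::setNames(as.character(grouping$population),
                                  grouping$sample_id)
    }
    groups <- unique(unname(grouping[samples]))
    per_group <- lapply(groups, function(g) {
      s <- samples[grouping[samples] == g]
      .slope_test(observed[genes, s, drop = FALSE],
                  predicted[genes, s, drop = FALSE])
    })
    p <- do.call(pmin, c(lapply(per_group, `[[`, "p"), na.rm = TRUE))
    const <- Reduce(`&`, lapply(per_group, `[[`, "constant"))
  } else {
    st <- .slope_test(observed[genes, samples, drop = FALSE],
                      predicted[genes, samples, drop = FALSE])
    p <- st$p
    const <- st$constant
  }
  status <- ifelse(const, "excluded_constant",
                   ifelse(!is.na(p) & p <= alpha, "kept", "poorly_predicted"))
  data.frame(gene_id = genes, status = status, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Row-wise slope Wald test of observed ~ predicted (equivalent to the lm
# t-test on the slope): t = r * sqrt((n-2) / (1-r^2)), df = n - 2.
.slope_test <- function(obs, pre, tol = .VAR_TOL) {
  n <- ncol(obs)
  a <- obs - rowMeans(obs)
  b <- pre - rowMeans(pre)
  ssa <- rowSums(a * a)
  ssb <- rowSums(b * b)
  constant <- ssb / (n - 1) < tol
  r <- rowSums(a * b) / sqrt(ssa * ssb)
  r[constant] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[!is.finite(p) & !constant] <- 1
  list(p = p, constant = constant)
}

.BIN_LABELS <- c("r<0", "[0,0.2)", "[0.2,0.4)", "[0.4,0.6)", "[0.6,0.8)",
                 "[0.8,1]")

#' Bin correlation coefficients into six accuracy categories
#'
#' Categories: r < 0, then five left-closed intervals [0,0.2), [0.2,0.4),
#' [0.4,0.6), [0.6,0.8), [0.8,1]. The left-closed convention is declared
#' explicitly (r = 0 falls in [0,0.2)) because interval notation for such
#' tables is often ambiguous at the boundaries. Missing cells are not
#' counted, so each group's counts sum to its non-missing cell count.
#'
#' @param table a [correlation_table()].
#' @return Integer matrix, 6 categories x groups.
#' @export
bin_correlations <- function(table) {
  stopifnot(inherits(table, "correlation_table"))
  breaks <- c(-Inf, 0, 0.2, 0.4, 0.6, 0.8, Inf)
  out <- sapply(table$groups, function(g) {
    r <- table$r[, g]
    r <- r[!is.na(r)]
    tabulate(findInterval(r, breaks, left.open = FALSE), nbins = 6L)
  })
  out <- matrix(as.integer(out), nrow = 6L,
                dimnames = list(.BIN_LABELS, table$groups))
  out
}

#' Write a correlation table as TSV
#' @param table a [correlation_table()].
#' @param path output path; columns `gene_id`, one per group.
#' @return `path`, invisibly.
#' @export
write_correlation_tsv <- function(table, path) {
  df <- data.frame(gene_id = table$genes, table$r, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
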