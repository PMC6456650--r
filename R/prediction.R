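#' @title Genotype-based expression prediction
#'
#' @description
#' Predicted expression for a sample is the weighted linear combination of
#' effect-allele dosages over the SNPs of a gene's model:
#' \deqn{\hat y_s = \sum_k w_k d_{sk}.}
#' No intercept is added: the downstream accuracy metric is the Pearson
#' correlation between observed and predicted expression, which is
#' invariant to location and scale, so an intercept would be irrelevant.
#' Model SNPs absent from the dosage data contribute nothing; per-gene
#' coverage (usable / total model SNPs) is reported so users can filter.
#' @name prediction
NULL

#' Predict one gene's expression from dosages
#'
#' Each model SNP is looked up in the dosage matrix by rsid and oriented to
#' its effect allele via [harmonize()]; SNPs that are absent, mismatched or
#' strand-ambiguous (when `drop_ambiguous` is set) are dropped and counted.
#'
#' @param model a gene model from [gene_model()] (or any list with
#'   `gene_id` and a `weights` data.frame).
#' @param dosages a [dosage_matrix()].
#' @param drop_ambiguous passed to [harmonize()].
#' @return list with `gene_id`, `yhat` (named per-sample predictions),
#'   `coverage` (usable / total model SNPs), `constant` (TRUE when no SNP
#'   was usable, giving an all-zero prediction), and `decisions` (named
#'   counts of harmonization outcomes, including `absent`).
#' @export
predict_gene <- function(model, dosages, drop_ambiguous = FALSE) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  w <- model$weights
  n_samp <- nrow(dosages$dosages)
  yhat <- numeric(n_samp)
  names(yhat) <- rownames(dosages$dosages)
  decisions <- c(use_alt_dosage = 0L, flip = 0L,
                 use_complemented_orientation = 0L, flip_complemented = 0L,
                 drop_ambiguous = 0L, drop_mismatch = 0L, absent = 0L)
  col <- match(w$rsid, dosages$variants$rsid)
  n_used <- 0L
  for (k in seq_len(nrow(w))) {
    j <- col[k]
    if (is.na(j)) {
      decisions[["absent"]] <- decisions[["absent"]] + 1L
      next
    }
    dec <- harmonize(w$ref_allele[k], w$eff_allele[k],
                     dosages$variants$ref[j], dosages$variants$alt[j],
                     drop_ambiguous = drop_ambiguous)
    decisions[[dec]] <- decisions[[dec]] + 1L
    if (dec %in% c("use_alt_dosage", "use_complemented_orientation")) {
      yhat <- yhat + w$weight[k] * dosages$dosages[, j]
      n_used <- n_used + 1L
    } else if (dec %in% c("flip", "flip_complemented")) {
      yhat <- yhat + w$weight[k] * (2 - dosages$dosages[, j])
      n_used <- n_used + 1L
    }
  }
  list(gene_id = model$gene_id, yhat = yhat,
       coverage = if (nrow(w) > 0L) n_used / nrow(w) else 0,
       constant = n_used == 0L, decisions = decisions)
}

#' Predict expression for every gene model in a weight database
#'
#' @param db a [weight_db()].
#' @param dosages a [dosage_matrix()].
#' @param drop_ambiguous passed to [harmonize()].
#' @return An object of class `prediction_result`: list with
#'   `predicted` (genes x samples matrix), `coverage` (named per-gene
#'   fraction of model SNPs used), `constant` (named logical; TRUE genes
#'   had no usable SNP and carry an all-zero prediction), and `decisions`
#'   (genes x decision-category count matrix).
#' @export
predict_all <- function(db, dosages, drop_ambiguous = FALSE) {
  stopifnot(inherits(db, "weight_db"), inherits(dosages, "dosage_matrix"))
  if (nrow(dosages$dosages) == 0L) {
    stop("dosage matrix has no samples", call. = FALSE)
  }
  genes <- model_genes(db)
  pred <- matrix(0, nrow = length(genes), ncol = nrow(dosages$dosages),
                 dimnames = list(genes, rownames(dosages$dosages)))
  coverage <- numeric(length(genes))
  constant <- logical(length(genes))
  names(coverage) <- names(constant) <- genes
  dec_mat <- NULL
  wsplit <- split(seq_len(nrow(db$weights)), db$weights$gene)
  for (g in genes) {
    model <- list(gene_id = g,
                  weights = db$weights[wsplit[[g]], , drop = FALSE])
    res <- predict_gene(model, dosages, drop_ambiguous = drop_ambiguous)
    pred[g, ] <- res$yhat
    coverage[g] <- res$coverage
    constant[g] <- res$constant
    if (is.null(dec_mat)) {
      dec_mat <- matrix(0L, nrow = length(genes),
                        ncol = length(res$decisions),
                        dimnames = list(genes, names(res$decisions)))
    }
    dec_mat[g, ] <- res$decisions
  }
  structure(list(predicted = pred, coverage = coverage, constant = constant,
                 decisions = dec_mat),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat("prediction_result: ", nrow(x$predicted), " genes x ",
      ncol(x$predicted), " samples\n  mean coverage: ",
      format(mean(x$coverage), digits = 3), "\n  constant genes: ",
      sum(x$constant), "\n", sep = "")
  invisible(x)
}

#' Write predicted expression and coverage as TSV
#'
#' @param result a `prediction_result`.
#' @param path output TSV for the genes x samples matrix (first column
#'   `gene_id`); a sidecar `<path>.coverage.tsv` carries per-gene coverage
#'   and the constant flag.
#' @return `path`, invisibly.
#' @export
write_prediction_tsv <- function(result, path) {
  stopifnot(inherits(result, "prediction_result"))
  write_expression_tsv(result$predicted, path)
  cov <- data.frame(gene_id = names(result$coverage),
                    coverage = result$coverage,
                    constant = result$constant)
  utils::write.table(cov, paste0(path, ".coverage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genes x samples expression matrix as TSV
#' @param mat numeric matrix, gene ids in rownames, sample ids in colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes x samples expression matrix from TSV
#' @param path TSV with a `gene_id` first column and one column per sample.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
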