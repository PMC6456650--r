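#' @title PredictDB-format weight databases
#'
#' @description
#' A weight database stores, per gene, the SNP weights of a linear
#' expression-prediction model: predicted expression is the weighted sum of
#' effect-allele dosages over the model's SNPs. The on-disk format is the
#' PredictDB SQLite layout (a `weights` table with columns
#' `rsid, gene, weight, ref_allele, eff_allele`, and an optional `extra`
#' table with training metadata), as distributed for transcriptome
#' imputation tools.
#'
#' In memory a `weight_db` is a list with elements
#' \describe{
#'   \item{weights}{data.frame with columns `rsid`, `gene`, `weight`,
#'     `ref_allele`, `eff_allele`, one row per (gene, SNP) pair.}
#'   \item{extra}{data.frame of per-gene metadata (`gene`, `genename`,
#'     `n.snps.in.model`, `pred.perf.R2`), or NULL.}
#'   \item{label}{free-text tag, e.g. the tissue or source of the models.}
#' }
#' @name weight_db
NULL

#' Construct a weight database object
#'
#' @param weights data.frame with columns `rsid`, `gene`, `weight`,
#'   `ref_allele`, `eff_allele`.
#' @param extra optional per-gene metadata data.frame with a `gene` column.
#' @param label free-text tag for the database (e.g. tissue).
#' @return An object of class `weight_db`.
#' @export
weight_db <- function(weights, extra = NULL, label = "") {
  required <- c("rsid", "gene", "weight", "ref_allele", "eff_allele")
  missing_cols <- setdiff(required, names(weights))
  if (length(missing_cols) > 0L) {
    stop("weights table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  weights <- as.data.frame(weights)[required]
  weights$rsid <- as.character(weights$rsid)
  weights$gene <- as.character(weights$gene)
  weights$weight <- as.numeric(weights$weight)
  weights$ref_allele <- as.character(weights$ref_allele)
  weights$eff_allele <- as.character(weights$eff_allele)
  if (nrow(weights) > 0L) {
    if (any(!is.finite(weights$weight))) {
      stop("non-finite weight(s) in weights table", call. = FALSE)
    }
    key <- paste(weights$gene, weights$rsid, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- weights[duplicated(key), , drop = FALSE]
      stop("duplicate (gene, rsid) pair(s) in weights table, e.g. (",
           dup$gene[1L], ", ", dup$rsid[1L], ")", call. = FALSE)
    }
    same <- weights$ref_allele == weights$eff_allele
    if (any(same)) {
      stop("ref_allele equals eff_allele for rsid ",
           weights$rsid[which(same)[1L]], call. = FALSE)
    }
  }
  if (!is.null(extra)) {
    extra <- as.data.frame(extra)
    if (!"gene" %in% names(extra)) {
      stop("extra table lacks required column: gene", call. = FALSE)
    }
    extra$gene <- as.character(extra$gene)
  }
  structure(list(weights = weights, extra = extra, label = label),
            class = "weight_db")
}

#' Number of gene models in a weight database
#' @param db a `weight_db`.
#' @return Integer count of distinct genes.
#' @export
n_models <- function(db) {
  stopifnot(inherits(db, "weight_db"))
  length(unique(db$weights$gene))
}

#' Total number of SNP weights in a weight database
#'
#' SNPs used by several gene models are counted with multiplicity, matching
#' the row count of the `weights` table.
#' @param db a `weight_db`.
#' @return Integer count.
#' @export
n_snps_total <- function(db) {
  stopifnot(inherits(db, "weight_db"))
  nrow(db$weights)
}

#' Gene identifiers present in a weight database
#' @param db a `weight_db`.
#' @return Character vector of gene ids, in first-appearance order.
#' @export
model_genes <- function(db) {
  stopifnot(inherits(db, "weight_db"))
  unique(db$weights$gene)
}

#' Extract one gene's prediction model
#'
#' @param db a `weight_db`.
#' @param gene_id gene identifier as stored in the database.
#' @return A list with `gene_id`, `weights` (the rows of the weights table
#'   for this gene, in table order), `n_snps`, and `extra` (the gene's
#'   metadata row or NULL).
#' @export
gene_model <- function(db, gene_id) {
  stopifnot(inherits(db, "weight_db"))
  w <- db$weights[db$weights$gene == gene_id, , drop = FALSE]
  if (nrow(w) == 0L) stop("no model for gene ", gene_id, call. = FALSE)
  extra <- NULL
  if (!is.null(db$extra)) {
    ex <- db$extra[db$extra$gene == gene_id, , drop = FALSE]
    if (nrow(ex) > 0L) extra <- ex[1L, , drop = FALSE]
  }
  list(gene_id = gene_id, weights = w, n_snps = nrow(w), extra = extra)
}

#' @export
print.weight_db <- function(x, ...) {
  cat("weight_db", if (nzchar(x$label)) paste0("[", x$label, "]") else "",
      "\n  models:    ", n_models(x),
      "\n  snp rows:  ", n_snps_total(x), "\n", sep = "")
  invisible(x)
}

#' Strip Ensembl-style version suffixes from gene identifiers
#'
#' Expression matrices and weight databases frequently disagree only in the
#' `.NN` version suffix of Ensembl gene ids; matching is done on the
#' unversioned id.
#' @param ids character vector of gene identifiers.
#' @return Character vector with any trailing `.number` removed.
#' @export
strip_gene_version <- function(ids) {
  sub("\\.[0-9]+$", "", ids)
}

#' Read a PredictDB-format SQLite weight database
#'
#' Expects a `weights` table with columns
#' `rsid, gene, weight, ref_allele, eff_allele` (an additional `varID`
#' column, present in some database revisions, is ignored). An `extra`
#' table is read when present. Duplicate (gene, rsid) rows are an error:
#' silent last-wins merging would hide corrupt databases.
#'
#' @param path path to a SQLite file.
#' @param label optional tag stored on the returned object; defaults to the
#'   file name.
#' @return A [weight_db()] object. Weight rows keep the table's row order.
#' @export
read_weight_db <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  tabs <- DBI::dbListTables(con)
  if (!"weights" %in% tabs) {
    stop("not a weight database (missing `weights` table): ", path,
         call. = FALSE)
  }
  w <- DBI::dbReadTable(con, "weights")
  required <- c("rsid", "gene", "weight", "ref_allele", "eff_allele")
  missing_cols <- setdiff(required, names(w))
  if (length(missing_cols) > 0L) {
    stop("`weights` table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- if ("extra" %in% tabs) DBI::dbReadTable(con, "extra") else NULL
  if (is.null(label)) label <- basename(path)
  weight_db(w[required], extra = extra, label = label)
}

#' Write a weight database as a PredictDB-format SQLite file
#'
#' Emits `weights` and `extra` tables laid out so the file is readable both
#' by [read_weight_db()] and by standard transcriptome-imputation tools.
#' An empty `extra` table with per-gene SNP counts is synthesized when the
#' object carries no metadata.
#'
#' @param db a `weight_db`.
#' @param path output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_weight_db <- function(db, path) {
  stopifnot(inherits(db, "weight_db"))
  if (file.exists(path)) file.remove(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  DBI::dbWriteTable(con, "weights", db$weights)
  extra <- db$extra
  if (is.null(extra)) {
    genes <- model_genes(db)
    if (length(genes) == 0L) {
      extra <- data.frame(gene = character(), genename = character(),
                          n.snps.in.model = integer(),
                          pred.perf.R2 = numeric(), check.names = FALSE)
    } else {
      extra <- data.frame(
        gene = genes,
        genename = genes,
        n.snps.in.model = as.integer(table(db$weights$gene)[genes]),
        pred.perf.R2 = NA_real_,
        check.names = FALSE,
        stringsAsFactors = FALSE
      )
    }
  }
  DBI::dbWriteTable(con, "extra", extra)
  invisible(path)
}
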