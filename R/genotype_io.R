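#' @title Dosage matrices and allele harmonization
#'
#' @description
#' Prediction weights are expressed per copy of a designated effect allele,
#' while VCF genotypes count ALT alleles; before prediction every model SNP
#' must be oriented to its effect allele. A `dosage_matrix` holds ALT-allele
#' dosages (samples x variants, values in [0, 2]) together with the variant
#' records needed for harmonization.
#' @name dosage_matrix
NULL

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.is_snv <- function(a) {
  !is.na(a) & nchar(a) == 1L & a %in% names(.COMPLEMENT)
}

#' Decide how to orient a model SNP against a VCF variant record
#'
#' Compares the model's (ref_allele, eff_allele) pair against the variant's
#' (REF, ALT) pair and returns one of six decisions:
#' \describe{
#'   \item{use_alt_dosage}{effect allele is ALT; use the ALT dosage as-is.}
#'   \item{flip}{effect allele is REF; effect dosage = 2 - ALT dosage.}
#'   \item{use_complemented_orientation}{as `use_alt_dosage` after
#'     strand-complementing the model alleles.}
#'   \item{flip_complemented}{as `flip` after strand-complementing.}
#'   \item{drop_ambiguous}{A/T or C/G model alleles with
#'     `drop_ambiguous = TRUE`: strand cannot be resolved.}
#'   \item{drop_mismatch}{no allele correspondence, or non-SNV alleles.}
#' }
#' A/T and C/G (strand-ambiguous) pairs are treated as plain direct matches
#' unless `drop_ambiguous` is set; within-study data has no strand
#' uncertainty, so the flag defaults to off at the call sites.
#'
#' @param w_ref,w_eff model reference and effect alleles (single bases).
#' @param v_ref,v_alt variant REF and ALT alleles.
#' @param drop_ambiguous drop strand-ambiguous (A/T, C/G) model SNPs?
#' @return One decision string.
#' @export
harmonize <- function(w_ref, w_eff, v_ref, v_alt, drop_ambiguous = FALSE) {
  if (!all(.is_snv(c(w_ref, w_eff, v_ref, v_alt)))) return("drop_mismatch")
  ambiguous <- .COMPLEMENT[[w_ref]] == w_eff
  if (ambiguous && drop_ambiguous) return("drop_ambiguous")
  if (w_ref == v_ref && w_eff == v_alt) return("use_alt_dosage")
  if (w_ref == v_alt && w_eff == v_ref) return("flip")
  if (!ambiguous) {
    cr <- .COMPLEMENT[[w_ref]]
    ce <- .COMPLEMENT[[w_eff]]
    if (cr == v_ref && ce == v_alt) return("use_complemented_orientation")
    if (cr == v_alt && ce == v_ref) return("flip_complemented")
  }
  "drop_mismatch"
}

#' Construct a dosage matrix
#'
#' @param dosages numeric matrix, samples in rows (rownames = sample ids),
#'   variants in columns (colnames = variant ids), ALT-allele orientation,
#'   values in [0, 2].
#' @param variants data.frame with one row per column of `dosages`:
#'   `rsid`, `chrom`, `pos`, `ref`, `alt`, `n_imputed` (missing genotypes
#'   mean-imputed for that variant).
#' @param skipped named integer vector of record counts skipped during
#'   parsing (e.g. multiallelic, non-SNV).
#' @return An object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(dosages, variants,
                          skipped = c(multiallelic = 0L, non_snv = 0L)) {
  stopifnot(is.matrix(dosages), nrow(variants) == ncol(dosages))
  if (length(dosages) > 0L) {
    rng <- range(dosages)
    if (rng[1L] < 0 || rng[2L] > 2) {
      stop("dosages outside [0, 2]", call. = FALSE)
    }
  }
  structure(list(dosages = dosages, variants = as.data.frame(variants),
                 skipped = skipped),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat("dosage_matrix: ", nrow(x$dosages), " samples x ",
      ncol(x$dosages), " variants\n", sep = "")
  if (sum(x$skipped) > 0L) {
    cat("  skipped records:",
        paste(names(x$skipped), x$skipped, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Sample identifiers of a dosage matrix
#' @param x a `dosage_matrix`.
#' @return Character vector.
#' @export
dosage_samples <- function(x) rownames(x$dosages)

#' Read effect-allele dosages from a VCF file
#'
#' Parses a VCF (v4.x, plain or bgzipped) and returns ALT-allele dosages for
#' biallelic SNVs. Dosage comes from the `DS` FORMAT field when present,
#' otherwise from `GT` allele counts. Multiallelic and non-SNV records are
#' skipped and counted. Missing genotypes are imputed as the variant's mean
#' ALT dosage over the non-missing samples in the file (computed before any
#' sample subsetting), so downstream sample sizes are preserved; the
#' per-variant count of imputed calls is reported in the `variants` table.
#'
#' Variants are keyed by rsid when the ID column is set, falling back to a
#' `chrom:pos:ref:alt` key when it is `.`.
#'
#' @param path VCF file path.
#' @param variant_ids optional character vector restricting the returned
#'   variants (warning if none are found).
#' @param samples optional ordered character vector of sample ids to keep.
#' @return A [dosage_matrix()] in ALT-dosage orientation.
#' @export
read_vcf_dosages <- function(path, variant_ids = NULL, samples = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(dosage_matrix(matrix(numeric(), 0L, 0L),
                         data.frame(rsid = character(), chrom = character(),
                                    pos = integer(), ref = character(),
                                    alt = character(), n_imputed = integer())))
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  snv <- .is_snv(fix$REF) & .is_snv(fix$ALT) & !multi
  skipped <- c(multiallelic = sum(multi, na.rm = TRUE),
               non_snv = sum(!snv & !multi, na.rm = TRUE))
  keep <- which(snv)
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"),
                fix$ID)

  fmt <- rownames(v@gt)
  have_ds <- "DS" %in% unlist(strsplit(unique(v@gt[, "FORMAT"]), ":"))
  if (have_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    alt_count <- function(g) {
      alleles <- strsplit(g, "[/|]")
      vapply(alleles, function(a) {
        if (any(is.na(a)) || any(a == ".")) return(NA_real_)
        sum(a == "1")
      }, numeric(1))
    }
    ds <- apply(gt, 2L, alt_count)
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(gt),
                                       dimnames = dimnames(gt))
  }
  ds <- ds[keep, , drop = FALSE]
  ids <- ids[keep]
  fix <- fix[keep, , drop = FALSE]

  n_imputed <- integer(nrow(ds))
  for (i in seq_len(nrow(ds))) {
    miss <- is.na(ds[i, ])
    if (any(miss)) {
      n_imputed[i] <- sum(miss)
      m <- mean(ds[i, !miss])
      if (is.nan(m)) m <- 0
      ds[i, miss] <- m
    }
  }

  if (!is.null(variant_ids)) {
    sel <- ids %in% variant_ids
    if (!any(sel)) {
      warning("none of the requested variants found in ", path)
    }
    ds <- ds[sel, , drop = FALSE]
    ids <- ids[sel]
    fix <- fix[sel, , drop = FALSE]
    n_imputed <- n_imputed[sel]
  }

  dm <- t(ds)
  colnames(dm) <- ids
  if (!is.null(samples)) {
    absent <- setdiff(samples, rownames(dm))
    if (length(absent) > 0L) {
      stop("sample(s) not in VCF: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    dm <- dm[samples, , drop = FALSE]
  }
  variants <- data.frame(rsid = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, n_imputed = n_imputed,
                         stringsAsFactors = FALSE)
  dosage_matrix(dm, variants, skipped = skipped)
}

#' Read a sample-to-population map
#'
#' @param path 2-column TSV `sample_id<TAB>population`, no header required;
#'   a header line is detected (and skipped) when its first field is
#'   `sample_id`.
#' @return data.frame with columns `sample_id`, `population`.
#' @export
read_population_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("sample_id", "population"))
  if (nrow(tab) > 0L && tab$sample_id[1L] == "sample_id") {
    tab <- tab[-1L, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}
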