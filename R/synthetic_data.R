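#' @title Synthetic multi-population study generator
#'
#' @description
#' Generates genotype, expression and weight-database fixtures with
#' controlled population divergence, linkage disequilibrium (LD) and
#' cis-heritability, emulating the structure of a cross-population
#' prediction-accuracy study: several closely related populations plus one
#' diverged population, with prediction models trained in a single
#' reference population. Allele-frequency drift follows the
#' Balding-Nichols model; LD comes from a first-order Markov chain along
#' each gene's SNPs. All draws are reproducible from a master seed, with
#' one derived stream per (component, gene) so adding genes does not
#' perturb earlier genes' draws.
#' @name synthetic_data
NULL

# deterministic 31-bit stream seed from a master seed and tags
derive_seed <- function(seed, ...) {
  tags <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (code in utf8ToInt(tags)) h <- (h * 31 + code) %% 2147483629
  as.integer(h)
}

#' Draw drifted per-population allele frequencies (Balding-Nichols)
#'
#' Given ancestral frequency p and divergence F, the population frequency
#' is Beta(p(1-F)/F, (1-p)(1-F)/F), whose mean is p and variance
#' F p (1-p). F = 0 returns p unchanged. Draws are clamped to
#' [0.01, 0.99], keeping every variant polymorphic and "common" in the
#' sense prediction models assume.
#'
#' @param p_ancestral vector of ancestral allele frequencies in (0, 1).
#' @param fst divergence F in [0, 1).
#' @param seed optional integer seed.
#' @return Vector of drifted frequencies, same length as `p_ancestral`.
#' @export
draw_population_freqs <- function(p_ancestral, fst, seed = NULL) {
  if (any(p_ancestral <= 0 | p_ancestral >= 1)) {
    stop("ancestral frequencies must lie in (0, 1)", call. = FALSE)
  }
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (fst == 0) return(p_ancestral)
  a <- p_ancestral * (1 - fst) / fst
  b <- (1 - p_ancestral) * (1 - fst) / fst
  pmin(pmax(stats::rbeta(length(p_ancestral), a, b), 0.01), 0.99)
}

# one haplotype matrix (n_hap x m) from a first-order Markov chain with
# stationary frequencies `freqs` and adjacent-allele correlation `ld_rho`;
# conditional probabilities are clamped to [0, 1], which attenuates the
# realized correlation when adjacent frequencies are very different
.simulate_haplotypes <- function(freqs, ld_rho, n_hap) {
  m <- length(freqs)
  H <- matrix(0L, n_hap, m)
  H[, 1L] <- stats::rbinom(n_hap, 1L, freqs[1L])
  if (m > 1L) {
    q <- 1 - freqs
    for (j in 2:m) {
      slope <- ld_rho * sqrt(freqs[j] * q[j] / (freqs[j - 1L] * q[j - 1L]))
      pr <- freqs[j] + slope * (H[, j - 1L] - freqs[j - 1L])
      H[, j] <- stats::rbinom(n_hap, 1L, pmin(pmax(pr, 0), 1))
    }
  }
  H
}

#' Simulate diploid genotypes with Markov-chain LD
#'
#' Two independent haplotypes per sample are generated along the SNPs by a
#' first-order Markov chain whose stationary allele frequencies equal
#' `freqs` and whose adjacent-haplotype allele correlation is `ld_rho`;
#' the genotype is their sum (ALT-allele count in 0..2).
#'
#' @param freqs per-SNP ALT allele frequencies for this population.
#' @param ld_rho adjacent-SNP haplotype correlation in [0, 1).
#' @param n_samples number of diploid samples.
#' @param seed optional integer seed.
#' @return Integer matrix, samples x SNPs.
#' @export
simulate_genotypes <- function(freqs, ld_rho, n_samples, seed = NULL) {
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)",
                                      call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  .simulate_haplotypes(freqs, ld_rho, n_samples) +
    .simulate_haplotypes(freqs, ld_rho, n_samples)
}

#' Simulate expression with a controlled cis-genetic component
#'
#' y = g + e with g the weighted sum of causal dosages and
#' e ~ N(0, Var(g) (1 - h2) / h2), so the genetic fraction of variance is
#' h2. Var(g) is computed empirically over the supplied samples unless a
#' pre-computed `noise_var` is given (used to hold the noise level fixed
#' across populations while Var(g) drifts). h2 = 0 gives pure N(0, 1)
#' noise.
#'
#' @param genotypes samples x SNPs dosage matrix with column names.
#' @param causal_effects named numeric vector of effects on a subset of
#'   the SNP columns.
#' @param h2 cis-heritability in [0, 1].
#' @param seed optional integer seed.
#' @param noise_var optional fixed noise variance overriding the
#'   h2-derived one.
#' @return list with `y` (expression), `g` (genetic component),
#'   `noise_var`.
#' @export
simulate_expression <- function(genotypes, causal_effects, h2, seed = NULL,
                                noise_var = NULL) {
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes)
  if (h2 == 0) {
    return(list(y = stats::rnorm(n), g = numeric(n), noise_var = 1))
  }
  snps <- names(causal_effects)
  if (!all(snps %in% colnames(genotypes))) {
    stop("causal effect on SNP absent from genotypes", call. = FALSE)
  }
  g <- as.numeric(genotypes[, snps, drop = FALSE] %*% causal_effects)
  if (is.null(noise_var)) {
    vg <- stats::var(g)
    if (vg < 1e-12) {
      stop("genetic component has zero variance but h2 > 0", call. = FALSE)
    }
    noise_var <- vg * (1 - h2) / h2
  }
  e <- if (noise_var > 0) stats::rnorm(n, 0, sqrt(noise_var)) else numeric(n)
  list(y = g + e, g = g, noise_var = noise_var)
}

#' Train a simplified per-gene weight model
#'
#' A deliberately simple stand-in for the penalized-regression training of
#' published databases, run in the training population only:
#' `marginal_ols` fits one univariate regression per SNP and keeps SNPs
#' whose slope is significant at `alpha`; `multiple_ols` fits a joint
#' least-squares model on all SNPs.
#'
#' @param train_genotypes samples x SNPs dosages (column names = rsids).
#' @param train_expression numeric expression vector for the same samples.
#' @param variants data.frame with `rsid`, `ref`, `alt` for the SNP
#'   columns (alt is the counted, hence effect, allele).
#' @param gene_id gene identifier for the resulting model.
#' @param method `"marginal_ols"` or `"multiple_ols"`.
#' @param alpha marginal-OLS retention threshold on the slope p-value.
#' @return A gene-model list (as [gene_model()]) whose `weights`
#'   data.frame is serializable by [write_weight_db()]; a marginal model
#'   with no significant SNP has zero rows.
#' @export
train_weight_model <- function(train_genotypes, train_expression, variants,
                               gene_id, method = c("marginal_ols",
                                                   "multiple_ols"),
                               alpha = 0.05) {
  method <- match.arg(method)
  n <- nrow(train_genotypes)
  m <- ncol(train_genotypes)
  y <- train_expression - mean(train_expression)
  if (method == "multiple_ols") {
    if (n <= m) {
      stop("fewer samples than SNPs under multiple_ols; use marginal_ols",
           call. = FALSE)
    }
    X <- scale(train_genotypes, center = TRUE, scale = FALSE)
    beta <- as.numeric(stats::lm.fit(cbind(1, X), train_expression)$coefficients[-1L])
    keep <- !is.na(beta)
    beta[!keep] <- 0
    w <- beta
    sel <- seq_len(m)
  } else {
    xc <- scale(train_genotypes, center = TRUE, scale = FALSE)
    sxx <- colSums(xc^2)
    ok <- sxx / (n - 1) >= 1e-12
    slope <- rep(NA_real_, m)
    pval <- rep(NA_real_, m)
    slope[ok] <- colSums(xc[, ok, drop = FALSE] * y) / sxx[ok]
    # per-SNP residual variance and slope t-test
    for (j in which(ok)) {
      resid <- y - slope[j] * xc[, j]
      se <- sqrt(sum(resid^2) / (n - 2) / sxx[j])
      tstat <- slope[j] / se
      pval[j] <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    sel <- which(ok & pval < alpha)
    w <- slope[sel]
  }
  rsids <- colnames(train_genotypes)[sel]
  vi <- match(rsids, variants$rsid)
  weights <- data.frame(rsid = rsids,
                        gene = rep(gene_id, length(sel)),
                        weight = as.numeric(w),
                        ref_allele = variants$ref[vi],
                        eff_allele = variants$alt[vi],
                        stringsAsFactors = FALSE)
  list(gene_id = gene_id, weights = weights, n_snps = nrow(weights),
       extra = NULL)
}

#' Write genotypes as a VCF v4.2 file
#'
#' @param genotypes integer samples x variants matrix of ALT-allele counts
#'   (0, 1, 2), sample ids in rownames.
#' @param variants data.frame with `rsid`, `chrom`, `pos`, `ref`, `alt`,
#'   one row per genotype column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, variants, path) {
  stopifnot(nrow(variants) == ncol(genotypes))
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(variants$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c(variants$chrom[i], variants$pos[i], variants$rsid[i],
            variants$ref[i], variants$alt[i], ".", "PASS", ".", "GT",
            gt_code[genotypes[, i] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Configuration for a synthetic cross-population study
#'
#' Defaults describe the study structure the generator emulates: five
#' populations — a reference/training population, three close relatives
#' (F = 0.01-0.02) and one strongly diverged population (F = 0.15) — with
#' moderate LD and a cis-heritability typical of well-predicted genes.
#'
#' @param n_populations number of populations; the first is the training
#'   reference.
#' @param samples_per_population diploid samples per population.
#' @param n_genes number of genes.
#' @param snps_per_gene SNPs in each gene's cis-window.
#' @param causal_snps_per_gene causal SNPs per gene.
#' @param ancestral_maf_range range the ancestral allele frequencies are
#'   drawn from (uniform).
#' @param fst_per_population Balding-Nichols F of each population relative
#'   to the shared ancestry (length `n_populations`; reference usually 0).
#' @param ld_rho adjacent-SNP haplotype correlation.
#' @param h2 cis-heritability of expression in the reference population.
#' @param tissue_mismatch_noise relative sd of weight perturbation used to
#'   build the optional "wrong tissue" database.
#' @param tagging_only if TRUE (default), causal SNPs are excluded from the
#'   trainable SNP set, so models rely on LD tagging — the mechanism by
#'   which cross-population transfer degrades.
#' @param train_method weight-training method, see [train_weight_model()].
#' @param seed master seed; every stream is derived from it.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_populations = 5L,
                              samples_per_population = 60L,
                              n_genes = 80L,
                              snps_per_gene = 6L,
                              causal_snps_per_gene = 1L,
                              ancestral_maf_range = c(0.1, 0.5),
                              fst_per_population = c(0, 0.01, 0.01, 0.02,
                                                     0.15),
                              ld_rho = 0.7,
                              h2 = 0.3,
                              tissue_mismatch_noise = 0.5,
                              tagging_only = TRUE,
                              train_method = "marginal_ols",
                              seed = 1L) {
  cfg <- list(n_populations = as.integer(n_populations),
              samples_per_population = as.integer(samples_per_population),
              n_genes = as.integer(n_genes),
              snps_per_gene = as.integer(snps_per_gene),
              causal_snps_per_gene = as.integer(causal_snps_per_gene),
              ancestral_maf_range = ancestral_maf_range,
              fst_per_population = fst_per_population,
              ld_rho = ld_rho, h2 = h2,
              tissue_mismatch_noise = tissue_mismatch_noise,
              tagging_only = isTRUE(tagging_only),
              train_method = train_method,
              seed = as.integer(seed))
  if (length(cfg$fst_per_population) != cfg$n_populations) {
    stop("fst_per_population must have one entry per population",
         call. = FALSE)
  }
  if (any(cfg$fst_per_population < 0 | cfg$fst_per_population >= 1)) {
    stop("fst_per_population values must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) {
    stop("ld_rho must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$h2 < 0 || cfg$h2 > 1) stop("h2 must lie in [0, 1]", call. = FALSE)
  if (cfg$causal_snps_per_gene >= cfg$snps_per_gene && cfg$tagging_only) {
    stop("tagging_only requires snps_per_gene > causal_snps_per_gene",
         call. = FALSE)
  }
  if (any(c(cfg$n_populations, cfg$samples_per_population, cfg$n_genes,
            cfg$snps_per_gene, cfg$causal_snps_per_gene) < 1L)) {
    stop("counts must be positive", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# non-strand-ambiguous REF/ALT letter pairs, cycled across variants
.ALLELE_PAIRS <- matrix(c("A", "G", "A", "C", "T", "C", "T", "G",
                          "G", "A", "C", "T"), ncol = 2L, byrow = TRUE)

#' Generate a complete synthetic study on disk
#'
#' Writes a VCF of all populations' genotypes, an observed-expression TSV,
#' a sample-to-population TSV, a "matched" PredictDB SQLite database
#' trained in the reference population, a "mismatched-tissue" database
#' with perturbed weights, and a ground-truth JSON (causal effects, drifted
#' frequencies, noise variances). Gene windows are laid out disjointly at
#' 1 Mb spacing on one chromosome. Every draw derives from `config$seed`.
#'
#' Expression noise variance is fixed per gene at the level implied by h2
#' in the reference population, so target-population heritability moves
#' with the drifted genetic variance, as it would in real data.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @return A `synthetic_study` list: file `paths`, the `config`, `truth`
#'   (per-gene causal effects and noise variances), and `populations`.
#' @export
generate_study <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  pops <- paste0("POP", seq_len(cfg$n_populations))
  n_per <- cfg$samples_per_population
  sample_ids <- unlist(lapply(pops, function(p) {
    sprintf("%s_S%03d", p, seq_len(n_per))
  }))
  pop_of <- rep(pops, each = n_per)

  S <- cfg$snps_per_gene
  G <- cfg$n_genes
  all_variants <- NULL
  geno <- matrix(0L, length(sample_ids), G * S)
  rownames(geno) <- sample_ids
  expr <- matrix(0, G, length(sample_ids))
  genes <- sprintf("GENE%04d", seq_len(G))
  rownames(expr) <- genes
  colnames(expr) <- sample_ids
  truth <- vector("list", G)
  model_list <- vector("list", G)
  mism_list <- vector("list", G)

  for (g in seq_len(G)) {
    idx <- (g - 1L) * S + seq_len(S)
    pair <- .ALLELE_PAIRS[(idx - 1L) %% nrow(.ALLELE_PAIRS) + 1L, ,
                          drop = FALSE]
    variants <- data.frame(
      rsid = paste0("rs", idx),
      chrom = "1",
      pos = (g - 1L) * 1000000L + (seq_len(S) - 1L) * 1000L + 1L,
      ref = pair[, 1L], alt = pair[, 2L],
      stringsAsFactors = FALSE)
    all_variants <- rbind(all_variants, variants)

    set.seed(derive_seed(cfg$seed, "anc", g))
    p_anc <- stats::runif(S, cfg$ancestral_maf_range[1L],
                          cfg$ancestral_maf_range[2L])
    # causal SNPs in the middle of the window
    mid <- ceiling(S / 2)
    causal <- ((mid + seq_len(cfg$causal_snps_per_gene) - 2L) %% S) + 1L
    set.seed(derive_seed(cfg$seed, "beta", g))
    beta <- stats::rnorm(cfg$causal_snps_per_gene)
    names(beta) <- variants$rsid[causal]

    gene_geno <- matrix(0L, length(sample_ids), S)
    for (p in seq_along(pops)) {
      freqs <- draw_population_freqs(p_anc, cfg$fst_per_population[p],
                                     seed = derive_seed(cfg$seed, "freq",
                                                        g, pops[p]))
      rows <- which(pop_of == pops[p])
      gene_geno[rows, ] <- simulate_genotypes(
        freqs, cfg$ld_rho, length(rows),
        seed = derive_seed(cfg$seed, "hap", g, pops[p]))
    }
    colnames(gene_geno) <- variants$rsid
    geno[, idx] <- gene_geno

    ref_rows <- which(pop_of == pops[1L])
    g_ref <- as.numeric(gene_geno[ref_rows, names(beta), drop = FALSE] %*%
                          beta)
    vg_ref <- stats::var(g_ref)
    if (cfg$h2 > 0 && vg_ref < 1e-12) {
      # drifted causal variant lost all variation in the reference; treat
      # the gene as non-genetic rather than aborting the whole study
      noise_var <- 1
      sim <- simulate_expression(gene_geno, beta, 0,
                                 seed = derive_seed(cfg$seed, "expr", g))
    } else {
      noise_var <- if (cfg$h2 > 0) {
        vg_ref * (1 - cfg$h2) / cfg$h2
      } else 1
      sim <- simulate_expression(gene_geno, beta, cfg$h2,
                                 seed = derive_seed(cfg$seed, "expr", g),
                                 noise_var = noise_var)
    }
    expr[g, ] <- sim$y

    trainable <- if (cfg$tagging_only) setdiff(seq_len(S), causal) else
      seq_len(S)
    model <- train_weight_model(
      gene_geno[ref_rows, trainable, drop = FALSE],
      sim$y[ref_rows], variants, genes[g], method = cfg$train_method)
    model_list[[g]] <- model$weights

    mism <- model$weights
    if (nrow(mism) > 0L && cfg$tissue_mismatch_noise > 0) {
      set.seed(derive_seed(cfg$seed, "mismatch", g))
      scale_sd <- stats::sd(mism$weight)
      if (!is.finite(scale_sd) || scale_sd < 1e-12) {
        scale_sd <- mean(abs(mism$weight))
      }
      mism$weight <- mism$weight +
        stats::rnorm(nrow(mism), 0, cfg$tissue_mismatch_noise * scale_sd)
    }
    mism_list[[g]] <- mism

    truth[[g]] <- list(gene = genes[g], causal = as.list(beta),
                       noise_var = noise_var)
  }

  paths <- list(
    vcf = file.path(out_dir, "genotypes.vcf"),
    expression = file.path(out_dir, "expression.tsv"),
    population = file.path(out_dir, "population.tsv"),
    weights = file.path(out_dir, "weights_matched.db"),
    weights_mismatched = file.path(out_dir, "weights_mismatched.db"),
    truth = file.path(out_dir, "ground_truth.json")
  )
  write_vcf(geno, all_variants, paths$vcf)
  write_expression_tsv(expr, paths$expression)
  utils::write.table(data.frame(sample_id = sample_ids,
                                population = pop_of),
                     paths$population, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  matched <- do.call(rbind, model_list)
  write_weight_db(weight_db(matched, label = "matched"), paths$weights)
  write_weight_db(weight_db(do.call(rbind, mism_list),
                            label = "mismatched"),
                  paths$weights_mismatched)
  jsonlite::write_json(
    list(config = unclass(cfg), genes = truth),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(paths = paths, config = cfg, truth = truth,
                 populations = pops, sample_ids = sample_ids),
            class = "synthetic_study")
}
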