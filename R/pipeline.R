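#' @title End-to-end pipeline and reporting
#'
#' @description
#' Orchestrates the full evaluation: read a weight database, extract and
#' harmonize VCF dosages, predict expression, score per-population Pearson
#' correlations, filter poorly predicted genes, bin correlations, and run
#' the inferential layer (continental paired t-test, random-intercept
#' mixed models with repeated-measures ANOVA, optional between-database
#' comparison). All tabular outputs are TSV; the run log records every
#' setting in effect and all stage counts, and contains no timestamps, so
#' a rerun with identical inputs is bit-identical.
#' @name pipeline
NULL

#' Parse a key = value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' @param path config file path.
#' @return Named list of character values.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed config line: ", lines[which(bad)[1L]], call. = FALSE)
  }
  vals <- lapply(kv, function(m) trimws(m[3L]))
  names(vals) <- vapply(kv, function(m) trimws(m[2L]), character(1))
  vals
}

#' Assemble a pipeline configuration
#'
#' @param vcf,expression,population,weights input file paths (VCF,
#'   genes x samples TSV, sample-population TSV, PredictDB SQLite).
#' @param weights_b optional second weight database for a between-database
#'   paired comparison on shared genes.
#' @param alpha significance level of the poorly-predicted filter.
#' @param reference reference population for the mixed-model contrasts;
#'   default the first population in the map.
#' @param diverged population treated as the diverged (other-continent)
#'   group for the pooled paired t-test and the within-continent model;
#'   default the last population in the map.
#' @param lmm_missing missing-cell handling for [fit_lmm()].
#' @param drop_ambiguous drop strand-ambiguous model SNPs, see
#'   [harmonize()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(vcf, expression, population, weights,
                            weights_b = NULL, alpha = 0.05,
                            reference = NULL, diverged = NULL,
                            lmm_missing = "likelihood",
                            drop_ambiguous = FALSE) {
  alpha <- as.numeric(alpha)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  structure(list(vcf = vcf, expression = expression,
                 population = population, weights = weights,
                 weights_b = weights_b, alpha = alpha,
                 reference = reference, diverged = diverged,
                 lmm_missing = lmm_missing,
                 drop_ambiguous = isTRUE(drop_ambiguous) ||
                   identical(drop_ambiguous, "true")),
            class = "pipeline_config")
}

#' Run the full evaluation pipeline
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory for report TSVs and the run log
#'   (created if needed); NULL skips writing and returns results only.
#' @return Invisible list with all stage results: `prediction`,
#'   `filter`, `correlations` (per-population), `correlations_filtered`,
#'   `bins`, `bins_filtered`, `continental_t`, `lmm` (models
#'   `all_populations`, `drop_reference`, `within_continent`, each with
#'   `fit` and `anova`), `db_comparison` (or NULL), `log` (character).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  say <- function(...) log <<- c(log, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("predxpop pipeline run")
  say("settings: alpha=", config$alpha,
      " lmm_missing=", config$lmm_missing,
      " drop_ambiguous=", config$drop_ambiguous)

  db <- stage("read_weights", read_weight_db(config$weights))
  say("weight db: ", n_models(db), " models, ", n_snps_total(db),
      " SNP rows")
  popmap <- stage("read_population", read_population_map(config$population))
  observed <- stage("read_expression", read_expression_tsv(config$expression))

  pops <- unique(popmap$population)
  reference <- if (is.null(config$reference)) pops[1L] else config$reference
  diverged <- if (is.null(config$diverged)) pops[length(pops)] else
    config$diverged
  say("populations: ", paste(pops, collapse = ", "),
      " (reference=", reference, ", diverged=", diverged, ")")

  dos_all <- stage("read_vcf", read_vcf_dosages(
    config$vcf, variant_ids = unique(db$weights$rsid)))
  vcf_samples <- dosage_samples(dos_all)
  samples <- intersect(intersect(vcf_samples, colnames(observed)),
                       popmap$sample_id)
  say("samples: vcf=", length(vcf_samples), " expression=",
      ncol(observed), " population_map=", nrow(popmap),
      " used(intersection)=", length(samples))
  if (length(samples) < length(vcf_samples) ||
      length(samples) < ncol(observed)) {
    warning("sample sets differ between inputs; using their intersection (",
            length(samples), " samples)")
  }
  if (length(samples) == 0L) stop("no shared samples across inputs",
                                  call. = FALSE)
  dos <- dosage_matrix(dos_all$dosages[samples, , drop = FALSE],
                       dos_all$variants, skipped = dos_all$skipped)
  popmap <- popmap[popmap$sample_id %in% samples, , drop = FALSE]
  grouping <- stats::setNames(popmap$population, popmap$sample_id)

  pred <- stage("predict", predict_all(db, dos,
                                       drop_ambiguous = config$drop_ambiguous))
  say("predicted genes: ", nrow(pred$predicted),
      " (constant: ", sum(pred$constant), ")")

  # align gene ids between database and expression (version-insensitive)
  predicted <- pred$predicted[!pred$constant, , drop = FALSE]
  rn <- strip_gene_version(rownames(predicted))
  obs_map <- match(rn, strip_gene_version(rownames(observed)))
  keep <- !is.na(obs_map) & !duplicated(obs_map)
  predicted <- predicted[keep, , drop = FALSE]
  observed2 <- observed[obs_map[keep], samples, drop = FALSE]
  rownames(observed2) <- rownames(predicted)
  say("genes with observed and predicted expression: ", nrow(predicted))

  filt <- stage("filter", filter_poorly_predicted(observed2, predicted,
                                                  alpha = config$alpha))
  kept_genes <- filt$gene_id[filt$status == "kept"]
  say("filter: kept=", sum(filt$status == "kept"),
      " poorly_predicted=", sum(filt$status == "poorly_predicted"),
      " excluded_constant=", sum(filt$status == "excluded_constant"))

  corr <- stage("correlate", compute_correlations(observed2, predicted,
                                                  grouping))
  corr_f <- correlation_table(corr$r[kept_genes, , drop = FALSE],
                              corr$n[kept_genes, , drop = FALSE])
  bins <- bin_correlations(corr)
  bins_f <- bin_correlations(corr_f)

  # continental comparison: pooled non-diverged populations vs diverged
  home_samples <- names(grouping)[grouping != diverged]
  div_samples <- names(grouping)[grouping == diverged]
  cont <- NULL
  if (length(div_samples) >= 3L && length(home_samples) >= 3L) {
    pooled_grouping <- stats::setNames(
      ifelse(grouping == diverged, "diverged_pool", "home_pool"),
      names(grouping))
    corr_cont <- compute_correlations(observed2, predicted, pooled_grouping)
    cont <- stage("continental_t", paired_t_test(
      stats::setNames(corr_cont$r[, "home_pool"], corr_cont$genes),
      stats::setNames(corr_cont$r[, "diverged_pool"], corr_cont$genes)))
    say("continental paired t: mean_diff=",
        format(cont$mean_diff, digits = 6), " p=",
        format(cont$p, digits = 4), " pairs=", cont$n_pairs)
  }

  fit_block <- function(tab, groups, ref) {
    fit <- fit_lmm(tab, groups = groups, reference = ref,
                   missing = config$lmm_missing)
    list(fit = fit, anova = rm_anova(tab, groups = groups,
                                     missing = config$lmm_missing))
  }
  lmm <- list()
  lmm$all_populations <- stage("lmm_all",
                               fit_block(corr_f, pops, reference))
  if (length(pops) > 2L) {
    rest <- setdiff(pops, reference)
    lmm$drop_reference <- stage("lmm_drop_reference",
                                fit_block(corr_f, rest, rest[1L]))
    home <- setdiff(pops, diverged)
    if (length(home) >= 2L) {
      lmm$within_continent <- stage("lmm_within_continent",
                                    fit_block(corr_f, home,
                                              if (reference %in% home)
                                                reference else home[1L]))
    }
  }
  for (nm in names(lmm)) {
    b <- lmm[[nm]]
    say("lmm[", nm, "]: ref=", b$fit$reference, " contrasts=",
        paste(sprintf("%s=%.4f", names(b$fit$beta)[-1L],
                      b$fit$beta[-1L]), collapse = " "),
        " anova_F=", format(b$anova$F, digits = 6),
        " p=", format(b$anova$p, digits = 4))
  }

  db_comparison <- NULL
  if (!is.null(config$weights_b)) {
    db_b <- stage("read_weights_b", read_weight_db(config$weights_b))
    dos_b <- stage("read_vcf_b", read_vcf_dosages(
      config$vcf, variant_ids = unique(db_b$weights$rsid),
      samples = samples))
    pred_b <- stage("predict_b",
                    predict_all(db_b, dos_b,
                                drop_ambiguous = config$drop_ambiguous))
    pooled_all <- stats::setNames(rep("all", length(samples)), samples)
    pb <- pred_b$predicted[!pred_b$constant, , drop = FALSE]
    rn_b <- strip_gene_version(rownames(pb))
    map_b <- match(rn_b, strip_gene_version(rownames(observed)))
    keep_b <- !is.na(map_b) & !duplicated(map_b)
    pb <- pb[keep_b, , drop = FALSE]
    ob <- observed[map_b[keep_b], samples, drop = FALSE]
    rownames(ob) <- rownames(pb)
    tabA <- compute_correlations(observed2, predicted, pooled_all)
    tabB <- compute_correlations(ob, pb, pooled_all)
    db_comparison <- stage("compare_databases",
                           compare_databases(tabA, tabB))
    say("database comparison (A - B): mean_diff=",
        format(db_comparison$mean_diff, digits = 6), " p=",
        format(db_comparison$p, digits = 4), " shared genes=",
        db_comparison$n_shared)
  }

  results <- list(prediction = pred, filter = filt, correlations = corr,
                  correlations_filtered = corr_f, bins = bins,
                  bins_filtered = bins_f, continental_t = cont, lmm = lmm,
                  db_comparison = db_comparison, log = log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_prediction_tsv(pred, file.path(out_dir, "predicted.tsv"))
    utils::write.table(filt, file.path(out_dir, "filter.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_correlation_tsv(corr, file.path(out_dir, "correlations.tsv"))
    write_correlation_tsv(corr_f,
                          file.path(out_dir, "correlations_filtered.tsv"))
    write_bins <- function(b, path) {
      utils::write.table(data.frame(category = rownames(b), b,
                                    check.names = FALSE),
                         path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    write_bins(bins, file.path(out_dir, "bins.tsv"))
    write_bins(bins_f, file.path(out_dir, "bins_filtered.tsv"))
    if (!is.null(cont)) {
      utils::write.table(
        data.frame(comparison = "pooled_home_vs_diverged",
                   mean_diff = cont$mean_diff, t = cont$t, df = cont$df,
                   p = cont$p, n_pairs = cont$n_pairs),
        file.path(out_dir, "continental_t.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    }
    for (nm in names(lmm)) {
      write_lmm_tsv(lmm[[nm]]$fit, lmm[[nm]]$anova,
                    file.path(out_dir, paste0("lmm_", nm, ".tsv")))
    }
    if (!is.null(db_comparison)) {
      utils::write.table(
        data.frame(comparison = "database_A_vs_B",
                   mean_diff = db_comparison$mean_diff,
                   t = db_comparison$t, df = db_comparison$df,
                   p = db_comparison$p, n_pairs = db_comparison$n_pairs),
        file.path(out_dir, "db_comparison.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    }
    writeLines(log, file.path(out_dir, "run.log"))
  }
  invisible(results)
}

#' Simulate a study from a config file (CLI backend)
#'
#' Config keys mirror [simulation_config()] arguments
#' (`n_populations`, `samples_per_population`, `n_genes`, `snps_per_gene`,
#' `causal_snps_per_gene`, `fst_per_population` as comma-separated values,
#' `ld_rho`, `h2`, `tissue_mismatch_noise`, `tagging_only`,
#' `train_method`). Unknown keys are an error naming the key.
#'
#' @param config_file optional key = value file; defaults used when NULL.
#' @param out output directory.
#' @param seed master seed (overrides any `seed` key).
#' @return The `synthetic_study`, invisibly.
#' @export
cmd_simulate <- function(config_file = NULL, out, seed = 1L) {
  args <- list()
  if (!is.null(config_file)) {
    raw <- parse_config(config_file)
    known <- names(formals(simulation_config))
    unknown <- setdiff(names(raw), known)
    if (length(unknown) > 0L) {
      stop("unknown simulation config key(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    numeric_keys <- c("n_populations", "samples_per_population", "n_genes",
                      "snps_per_gene", "causal_snps_per_gene", "ld_rho",
                      "h2", "tissue_mismatch_noise", "seed")
    for (k in names(raw)) {
      args[[k]] <- if (k %in% numeric_keys) {
        as.numeric(raw[[k]])
      } else if (k %in% c("fst_per_population", "ancestral_maf_range")) {
        as.numeric(strsplit(raw[[k]], ",")[[1L]])
      } else if (k == "tagging_only") {
        tolower(raw[[k]]) %in% c("true", "1", "yes")
      } else raw[[k]]
    }
  }
  args$seed <- as.integer(seed)
  cfg <- do.call(simulation_config, args)
  invisible(generate_study(cfg, out))
}

#' Run the pipeline from a config file (CLI backend)
#'
#' Config keys mirror [pipeline_config()] arguments; `vcf`, `expression`,
#' `population` and `weights` are required paths.
#'
#' @param config_file key = value file.
#' @param out output directory for the report.
#' @return The pipeline results, invisibly.
#' @export
cmd_run <- function(config_file, out) {
  raw <- parse_config(config_file)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown pipeline config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- do.call(pipeline_config, raw)
  invisible(run_pipeline(cfg, out))
}
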