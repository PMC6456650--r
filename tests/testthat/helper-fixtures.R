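# Shared fixture builders; everything is generated in code at test time.

# small weight database with deterministic fields
make_test_db <- function(n_genes = 2L, snps_per_gene = c(3L, 2L),
                         seed = 101L) {
  set.seed(seed)
  if (length(snps_per_gene) == 1L) {
    snps_per_gene <- rep(snps_per_gene, n_genes)
  }
  rows <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
    s <- snps_per_gene[g]
    data.frame(rsid = sprintf("rs%d_%d", g, seq_len(s)),
               gene = sprintf("ENSG%08d.%d", g, g %% 7 + 1L),
               weight = round(stats::rnorm(s), 6),
               ref_allele = rep(c("A", "T", "G"), length.out = s),
               eff_allele = rep(c("G", "C", "A"), length.out = s),
               stringsAsFactors = FALSE)
  }))
  weight_db(rows, label = "test")
}

# hand-tabulated 5-variant x 8-sample VCF; expected ALT dosages below were
# written out by hand from the genotype strings before being asserted
write_fixture_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("S", 1:8)), collapse = "\t"),
    # rs1: 0/0 0/1 1/1 0/0 0/1 1/1 0/0 0/1
    paste(c("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1", "0/0", "0/1", "1/1", "0/0", "0/1"),
          collapse = "\t"),
    # rs2 (phased): 0|0 0|1 1|0 1|1 0|0 0|1 1|0 1|1
    paste(c("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
            "0|0", "0|1", "1|0", "1|1", "0|0", "0|1", "1|0", "1|1"),
          collapse = "\t"),
    # rs3: one missing genotype (S4), non-missing dosages 0,1,2,0,1,2,0
    paste(c("1", "300", "rs3", "G", "A", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1", "./.", "0/0", "0/1", "1/1", "0/0"),
          collapse = "\t"),
    # rs4: multiallelic, must be skipped
    paste(c("1", "400", "rs4", "A", "G,T", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1", "0/0", "0/1", "1/1", "0/0", "0/1"),
          collapse = "\t"),
    # rs5: indel ALT, must be skipped
    paste(c("1", "500", "rs5", "A", "AT", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1", "0/0", "0/1", "1/1", "0/0", "0/1"),
          collapse = "\t"),
    # rs6: all ALT
    paste(c("1", "600", "rs6", "T", "C", ".", "PASS", ".", "GT",
            "1/1", "1/1", "1/1", "1/1", "1/1", "1/1", "1/1", "1/1"),
          collapse = "\t")
  )
  writeLines(lines, path)
  path
}

# the hand-tabulated expected dosages of the usable fixture variants
fixture_expected_dosages <- function() {
  m <- cbind(
    rs1 = c(0, 1, 2, 0, 1, 2, 0, 1),
    rs2 = c(0, 1, 1, 2, 0, 1, 1, 2),
    rs3 = c(0, 1, 2, 6 / 7, 0, 1, 2, 0),  # S4 imputed: mean(0,1,2,0,1,2,0)
    rs6 = c(2, 2, 2, 2, 2, 2, 2, 2)
  )
  rownames(m) <- paste0("S", 1:8)
  m
}

# random correlation table drawn from the random-intercept model
make_random_table <- function(n_genes, k, miss = 0, s2g = 0.02,
                              s2e = 0.01, beta = NULL, groups = NULL) {
  if (is.null(groups)) groups <- paste0("G", seq_len(k))
  if (is.null(beta)) beta <- c(0.2, stats::rnorm(k - 1, 0, 0.05))
  mu <- c(beta[1], beta[1] + beta[-1])
  gam <- stats::rnorm(n_genes, 0, sqrt(s2g))
  r <- outer(gam, mu, `+`) +
    matrix(stats::rnorm(n_genes * k, 0, sqrt(s2e)), n_genes)
  r <- pmin(pmax(r, -1), 1)  # rare tail values: r is bounded by definition
  if (miss > 0) {
    r[matrix(stats::runif(n_genes * k) < miss, n_genes)] <- NA
  }
  dimnames(r) <- list(paste0("g", seq_len(n_genes)), groups)
  correlation_table(r, matrix(50L, n_genes, k, dimnames = dimnames(r)))
}

# independent REML oracle via lme4 with tight convergence control
lmer_oracle <- function(tab, groups = NULL, reference = NULL) {
  if (is.null(groups)) groups <- tab$groups
  if (is.null(reference)) reference <- groups[1L]
  groups <- c(reference, setdiff(groups, reference))
  d <- data.frame(y = as.vector(tab$r[, groups]),
                  gene = rep(tab$genes, times = length(groups)),
                  grp = factor(rep(groups, each = nrow(tab$r)),
                               levels = groups))
  d <- d[!is.na(d$y), ]
  ctrl <- lme4::lmerControl(
    optimizer = "nloptwrap",
    optCtrl = list(xtol_abs = 1e-14, ftol_abs = 1e-14),
    check.conv.singular = "ignore")
  m <- lme4::lmer(y ~ grp + (1 | gene), data = d, REML = TRUE,
                  control = ctrl)
  vc <- as.data.frame(lme4::VarCorr(m))
  list(beta = unname(lme4::fixef(m)),
       se = unname(sqrt(diag(as.matrix(vcov(m))))),
       sigma2_gene = vc$vcov[1L], sigma2_resid = vc$vcov[2L])
}
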