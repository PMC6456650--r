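test_that("Balding-Nichols drift has the right mean and variance", {
  expect_equal(draw_population_freqs(c(0.2, 0.5), 0), c(0.2, 0.5))
  set.seed(51)
  draws <- draw_population_freqs(rep(0.3, 10000), 0.1)
  expect_equal(mean(draws), 0.3, tolerance = 0.01)
  expect_equal(var(draws), 0.1 * 0.3 * 0.7, tolerance = 0.1)
  expect_true(all(draws >= 0.01 & draws <= 0.99))
  expect_error(draw_population_freqs(0.3, 1), "fst")
  expect_error(draw_population_freqs(1.2, 0.1), "frequencies")
})

test_that("Markov-chain haplotypes hit the target LD and frequencies", {
  set.seed(52)
  # independence limit
  g0 <- simulate_genotypes(rep(0.5, 2), ld_rho = 0, n_samples = 2000)
  expect_lt(abs(cor(g0[, 1], g0[, 2])), 0.05)
  # genotype correlation equals haplotype allele correlation (sum of two
  # independent haplotypes), so it estimates ld_rho directly
  g8 <- simulate_genotypes(rep(0.5, 5), ld_rho = 0.8, n_samples = 5000)
  adj <- sapply(1:4, function(j) cor(g8[, j], g8[, j + 1]))
  expect_equal(mean(adj), 0.80, tolerance = 0.03)
  # stationary frequencies preserved along the chain
  expect_equal(unname(colMeans(g8) / 2), rep(0.5, 5), tolerance = 0.03)
  expect_error(simulate_genotypes(0.5, 1, 10), "ld_rho")
})

test_that("emitted VCF re-read by the dosage reader is exact", {
  set.seed(53)
  n <- 40L
  geno <- simulate_genotypes(c(0.3, 0.5, 0.7), 0.5, n)
  rownames(geno) <- sprintf("S%02d", seq_len(n))
  variants <- data.frame(rsid = paste0("rs", 1:3), chrom = "1",
                         pos = c(101L, 201L, 301L),
                         ref = c("A", "T", "G"), alt = c("G", "C", "A"))
  colnames(geno) <- variants$rsid
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(geno, variants, path)
  dm <- read_vcf_dosages(path)
  expect_equal(dm$dosages[rownames(geno), variants$rsid],
               `storage.mode<-`(geno, "double"))
  expect_equal(dm$variants$pos, variants$pos)
})

test_that("expression heritability is controlled by construction", {
  set.seed(54)
  n <- 5000L
  geno <- simulate_genotypes(c(0.4, 0.3), 0.3, n)
  colnames(geno) <- c("rs1", "rs2")
  eff <- c(rs1 = 0.8)
  # noiseless limit
  s1 <- simulate_expression(geno, eff, h2 = 1)
  expect_equal(s1$y, s1$g)
  # target variance fraction
  s <- simulate_expression(geno, eff, h2 = 0.4)
  r2 <- summary(lm(s$y ~ s$g))$r.squared
  expect_equal(r2, 0.40, tolerance = 0.03)
  # no genetic component: unit-variance noise
  s0 <- simulate_expression(geno, eff, h2 = 0)
  expect_equal(var(s0$y), 1, tolerance = 0.1)
  expect_equal(s0$g, numeric(n))
  # degenerate genetic variance
  mono <- matrix(2L, n, 1, dimnames = list(NULL, "rs1"))
  expect_error(simulate_expression(mono, eff, h2 = 0.4), "zero variance")
})

test_that("weight training recovers effects and calibrates its retention", {
  set.seed(55)
  n <- 300L
  geno <- simulate_genotypes(c(0.4, 0.3, 0.5), 0.4, n)
  colnames(geno) <- paste0("rs", 1:3)
  variants <- data.frame(rsid = paste0("rs", 1:3), ref = "A", alt = "G")
  eff <- c(rs2 = 0.7)
  s <- simulate_expression(geno, eff, h2 = 1)
  model <- train_weight_model(geno, s$y, variants, "G1",
                              method = "multiple_ols")
  w <- setNames(model$weights$weight, model$weights$rsid)
  expect_equal(unname(w["rs2"]), 0.7, tolerance = 1e-6)
  expect_equal(unname(abs(w[c("rs1", "rs3")])), c(0, 0), tolerance = 1e-6)

  # marginal training on pure-noise genes keeps ~alpha of SNPs
  set.seed(56)
  n_tests <- 0L; n_kept <- 0L
  for (g in 1:200) {
    gg <- simulate_genotypes(rep(0.5, 5), 0, 100)
    colnames(gg) <- paste0("n", 1:5)
    vv <- data.frame(rsid = colnames(gg), ref = "A", alt = "G")
    y <- rnorm(100)
    m <- train_weight_model(gg, y, vv, "null", method = "marginal_ols")
    n_tests <- n_tests + 5L
    n_kept <- n_kept + nrow(m$weights)
  }
  expect_equal(n_kept / n_tests, 0.05, tolerance = 0.4)
  expect_error(train_weight_model(geno[1:2, ], s$y[1:2], variants, "G1",
                                  method = "multiple_ols"),
               "marginal_ols")
})

test_that("generated studies are deterministic and well shaped", {
  cfg <- simulation_config(n_genes = 100L, samples_per_population = 50L,
                           n_populations = 5L, seed = 99L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- generate_study(cfg, d1)
  s2 <- generate_study(cfg, d2)
  for (nm in names(s1$paths)) {
    expect_identical(unname(tools::md5sum(s1$paths[[nm]])),
                     unname(tools::md5sum(s2$paths[[nm]])),
                     label = paste("md5 of", nm))
  }
  expr <- read_expression_tsv(s1$paths$expression)
  expect_equal(dim(expr), c(100L, 250L))
  pm <- read_population_map(s1$paths$population)
  expect_equal(nrow(pm), 250L)
  expect_equal(length(unique(pm$population)), 5L)
  db <- read_weight_db(s1$paths$weights)
  expect_gt(n_models(db), 0L)
  expect_lte(n_models(db), 100L)
})

test_that("config validation names the offending field", {
  expect_error(simulation_config(fst_per_population = c(0, 1.2),
                                 n_populations = 2), "fst_per_population")
  expect_error(simulation_config(h2 = 1.5), "h2")
  expect_error(simulation_config(ld_rho = 1), "ld_rho")
  expect_error(simulation_config(n_genes = 0), "positive")
  expect_error(simulation_config(snps_per_gene = 1,
                                 causal_snps_per_gene = 1), "tagging_only")
})
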