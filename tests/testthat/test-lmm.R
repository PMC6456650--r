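test_that("a constant table yields zero variances and exact means", {
  r <- matrix(0.3, 10, 3, dimnames = list(paste0("g", 1:10),
                                          c("A", "B", "C")))
  tab <- correlation_table(r, matrix(20L, 10, 3, dimnames = dimnames(r)))
  fit <- fit_lmm(tab)
  expect_equal(unname(fit$beta), c(0.3, 0, 0))
  expect_equal(fit$sigma2_gene, 0)
  expect_equal(fit$sigma2_resid, 0)
})

test_that("balanced two-by-two fixed effects are group-mean contrasts", {
  r <- matrix(c(0.1, 0.3, 0.0, 0.1), 2, 2,
              dimnames = list(c("g1", "g2"), c("ref", "other")))
  tab <- correlation_table(r, matrix(10L, 2, 2, dimnames = dimnames(r)))
  fit <- fit_lmm(tab, reference = "ref")
  expect_equal(unname(fit$beta["(Intercept)"]), 0.2, tolerance = 1e-10)
  expect_equal(unname(fit$beta["other"]), -0.15, tolerance = 1e-10)
})

test_that("balanced complete tables reproduce group-mean contrasts exactly", {
  set.seed(31)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    tab <- make_random_table(sample(5:40, 1), k)
    fit <- fit_lmm(tab)
    means <- colMeans(tab$r)
    expect_equal(unname(fit$beta),
                 unname(c(means[1], means[-1] - means[1])),
                 tolerance = 1e-12)
  }
})

test_that("REML estimates agree with an independent mixed-model oracle", {
  skip_if_not_installed("lme4")
  set.seed(32)
  for (i in 1:8) {
    tab <- make_random_table(sample(10:40, 1), sample(3:5, 1),
                             miss = runif(1, 0, 0.1))
    fit <- fit_lmm(tab)
    oracle <- lmer_oracle(tab)
    expect_equal(unname(fit$beta), oracle$beta, tolerance = 1e-6)
    expect_equal(unname(fit$se), oracle$se, tolerance = 1e-6)
    expect_equal(fit$sigma2_gene, oracle$sigma2_gene, tolerance = 1e-6)
    expect_equal(fit$sigma2_resid, oracle$sigma2_resid, tolerance = 1e-6)
  }
})

test_that("missing cells are handled by likelihood or listwise deletion", {
  set.seed(33)
  tab <- make_random_table(40, 4, miss = 0.15)
  f1 <- fit_lmm(tab, missing = "likelihood")
  f2 <- fit_lmm(tab, missing = "complete_cases")
  expect_equal(f1$n_genes, 40L)
  expect_lt(f2$n_genes, 40L)
  expect_equal(f2$n_obs, f2$n_genes * 4L)
})

test_that("relabeling the reference maps contrasts linearly, F unchanged", {
  set.seed(34)
  tab <- make_random_table(30, 4)
  f1 <- fit_lmm(tab, reference = "G1")
  f2 <- fit_lmm(tab, reference = "G3")
  # new contrast of group g = old contrast of g minus old contrast of G3
  expect_equal(unname(f2$beta["G2"]),
               unname(f1$beta["G2"] - f1$beta["G3"]), tolerance = 1e-9)
  expect_equal(unname(f2$beta["G1"]),
               unname(-f1$beta["G3"]), tolerance = 1e-9)
  a1 <- rm_anova(tab)
  expect_equal(rm_anova(tab)$F, a1$F)
})

test_that("variance components are recovered and clamped at zero", {
  set.seed(35)
  tab <- make_random_table(500, 5, s2g = 0.02, s2e = 0.01)
  fit <- fit_lmm(tab)
  expect_equal(fit$sigma2_gene, 0.02, tolerance = 0.3)
  expect_equal(fit$sigma2_resid, 0.01, tolerance = 0.1)
  expect_false(fit$boundary)

  # no gene variance at all: estimate pinned at the boundary
  tab0 <- make_random_table(100, 3, s2g = 0, s2e = 0.01)
  fit0 <- fit_lmm(tab0)
  expect_gte(fit0$sigma2_gene, 0)
  expect_lt(fit0$sigma2_gene, 0.002)
})

test_that("degenerate or underspecified tables raise errors", {
  r <- matrix(0.1, 2, 1, dimnames = list(c("g1", "g2"), "A"))
  tab <- correlation_table(r, matrix(5L, 2, 1, dimnames = dimnames(r)))
  expect_error(fit_lmm(tab), "at least 2 groups")
  r2 <- matrix(c(0.2, NA, NA, NA), 2, 2, dimnames = list(c("g1", "g2"),
                                                         c("A", "B")))
  tab2 <- correlation_table(r2, matrix(5L, 2, 2, dimnames = dimnames(r2)))
  expect_error(fit_lmm(tab2), "at least 2 genes")
  set.seed(36)
  tab3 <- make_random_table(10, 3)
  expect_error(fit_lmm(tab3, reference = "nope"), "reference")
})

test_that("Wald tests use normal quantiles and model-based SEs", {
  set.seed(37)
  tab <- make_random_table(50, 3)
  fit <- fit_lmm(tab)
  w <- wald_test(fit, "G2")
  expect_equal(w$p, 2 * pnorm(-abs(fit$beta[["G2"]] / fit$se[["G2"]])))
  expect_equal(unname(w$ci95),
               unname(c(fit$beta[["G2"]] - 1.96 * fit$se[["G2"]],
                        fit$beta[["G2"]] + 1.96 * fit$se[["G2"]])))
  expect_error(wald_test(fit, "G9"), "unknown contrast")

  # beta at exactly 1.96 SE has p ~= 0.05; beta 0 has p = 1
  fake <- fit
  fake$beta["G2"] <- 1.96 * fake$se[["G2"]]
  expect_equal(wald_test(fake, "G2")$p, 0.05, tolerance = 1e-3)
  fake$beta["G2"] <- 0
  expect_equal(wald_test(fake, "G2")$p, 1)
})

test_that("balanced ANOVA agrees with the aov error-stratum oracle", {
  set.seed(38)
  for (i in 1:5) {
    n <- sample(5:25, 1); k <- sample(3:5, 1)
    tab <- make_random_table(n, k)
    a <- rm_anova(tab)
    d <- data.frame(y = as.vector(tab$r),
                    gene = factor(rep(tab$genes, k)),
                    grp = factor(rep(tab$groups, each = n)))
    ref <- summary(aov(y ~ grp + Error(gene), data = d))
    Fref <- ref[["Error: Within"]][[1]]["grp", "F value"]
    expect_equal(a$F, Fref, tolerance = 1e-10)
    expect_equal(a$df1, k - 1L)
    expect_equal(a$df2, (k - 1L) * (n - 1L))
    expect_false(a$approximate)
  }
})

test_that("ANOVA F is zero when groups do not differ within genes", {
  r <- matrix(rep(c(0.1, 0.5, -0.2, 0.3), 3), 4, 3,
              dimnames = list(paste0("g", 1:4), c("A", "B", "C")))
  tab <- correlation_table(r, matrix(10L, 4, 3, dimnames = dimnames(r)))
  expect_equal(rm_anova(tab)$F, 0)
})

test_that("ANOVA degrees of freedom scale to thousands of genes", {
  set.seed(39)
  tab <- make_random_table(3493, 5)
  a <- rm_anova(tab)
  expect_equal(a$df1, 4L)
  expect_equal(a$df2, 4L * 3492L)
})

test_that("the unbalanced ANOVA path approximates the balanced F", {
  set.seed(40)
  tab <- make_random_table(200, 4, beta = c(0.2, 0.05, -0.03, 0.02))
  bal <- rm_anova(tab)
  r <- tab$r
  r[1, 2] <- NA  # a single missing cell switches to the LMM Wald F
  tab2 <- correlation_table(r, tab$n)
  unb <- rm_anova(tab2)
  expect_true(unb$approximate)
  expect_equal(unb$method, "lmm_wald_f")
  expect_equal(unb$F, bal$F, tolerance = 0.05)
  expect_error(rm_anova(tab, groups = "G1"), "at least 2 groups")
})
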