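test_that("pearson_r handles identity, negation and constant input", {
  set.seed(11)
  x <- rnorm(20)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  r <- pearson_r(x, rep(3, 20))
  expect_true(is.na(r))
  expect_equal(attr(r, "reason"), "constant_input")
  expect_error(pearson_r(x, x[-1]), "equal length")
  expect_error(pearson_r(1:2, 2:1), "at least 3")
})

test_that("pearson_r is affine-invariant and odd under negation", {
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    r <- pearson_r(x, y)
    a <- runif(1, -5, 5); b <- runif(1, 0.1, 5)
    expect_equal(pearson_r(a + b * x, y), r, tolerance = 1e-12)
    expect_equal(pearson_r(x, -y), -r, tolerance = 1e-12)
  }
})

test_that("compute_correlations matches direct per-group recomputation", {
  set.seed(13)
  n_genes <- 25L; samples <- paste0("S", 1:30)
  grouping <- setNames(rep(c("A", "B", "C"), each = 10), samples)
  obs <- matrix(rnorm(n_genes * 30), n_genes,
                dimnames = list(paste0("g", 1:n_genes), samples))
  pre <- 0.5 * obs + matrix(rnorm(n_genes * 30), n_genes)
  dimnames(pre) <- dimnames(obs)
  tab <- compute_correlations(obs, pre, grouping)
  for (g in c("A", "B", "C")) {
    s <- names(grouping)[grouping == g]
    for (gene in rownames(obs)) {
      expect_equal(tab$r[gene, g],
                   as.numeric(pearson_r(obs[gene, s], pre[gene, s])),
                   tolerance = 1e-12)
    }
  }
  expect_true(all(tab$n == 10L))
})

test_that("constant vectors yield missing cells, small groups an error", {
  samples <- paste0("S", 1:12)
  grouping <- setNames(rep(c("A", "B"), each = 6), samples)
  obs <- matrix(rnorm(24), 2, dimnames = list(c("g1", "g2"), samples))
  pre <- obs
  pre["g2", grouping == "B"] <- 7  # constant prediction in group B only
  tab <- compute_correlations(obs, pre, grouping)
  expect_equal(tab$r["g1", ], c(A = 1, B = 1))
  expect_equal(unname(tab$r["g2", "A"]), 1)
  expect_true(is.na(tab$r["g2", "B"]))
  bad <- setNames(c(rep("A", 10), "B", "B"), samples)
  expect_error(compute_correlations(obs, pre, bad), "fewer than 3")
})

test_that("the poorly-predicted filter keeps signal and drops noise", {
  set.seed(14)
  n <- 100L
  samples <- paste0("S", seq_len(n))
  obs <- matrix(rnorm(3 * n), 3, dimnames = list(c("sig", "null", "const"),
                                                 samples))
  pre <- obs
  pre["null", ] <- rnorm(n)
  pre["const", ] <- 2
  res <- filter_poorly_predicted(obs, pre, alpha = 0.05)
  expect_equal(res$status[res$gene_id == "sig"], "kept")
  expect_equal(res$status[res$gene_id == "const"], "excluded_constant")
  expect_lt(res$p_value[res$gene_id == "sig"], 1e-10)
  expect_error(filter_poorly_predicted(obs[, 1:2], pre[, 1:2]),
               "more than 2")
})

test_that("filter slope p-values agree with lm Wald tests", {
  set.seed(15)
  n <- 40L
  samples <- paste0("S", seq_len(n))
  obs <- matrix(rnorm(5 * n), 5, dimnames = list(paste0("g", 1:5), samples))
  pre <- 0.3 * obs + matrix(rnorm(5 * n), 5)
  dimnames(pre) <- dimnames(obs)
  res <- filter_poorly_predicted(obs, pre)
  for (g in rownames(obs)) {
    fit <- summary(lm(obs[g, ] ~ pre[g, ]))
    expect_equal(res$p_value[res$gene_id == g],
                 fit$coefficients[2L, 4L], tolerance = 1e-10)
  }
})

test_that("null genes are labeled poorly predicted at close to 1 - alpha", {
  set.seed(16)
  n_genes <- 1000L; n <- 100L
  samples <- paste0("S", seq_len(n))
  obs <- matrix(rnorm(n_genes * n), n_genes,
                dimnames = list(paste0("g", seq_len(n_genes)), samples))
  pre <- matrix(rnorm(n_genes * n), n_genes, dimnames = dimnames(obs))
  res <- filter_poorly_predicted(obs, pre, alpha = 0.05)
  frac <- mean(res$status == "poorly_predicted")
  # binomial 99.9% band around 0.95 at 1000 genes: ~0.95 +/- 0.023
  expect_gt(frac, 0.925)
  expect_lt(frac, 0.975)
})

test_that("two-sided filtering keeps significantly negative slopes", {
  set.seed(17)
  n <- 60L
  obs <- matrix(rnorm(n), 1, dimnames = list("g1", paste0("S", 1:n)))
  pre <- -obs + 0.1 * matrix(rnorm(n), 1)
  dimnames(pre) <- dimnames(obs)
  res <- filter_poorly_predicted(obs, pre)
  expect_equal(res$status, "kept")
})

test_that("binning uses left-closed intervals and conserves counts", {
  r <- matrix(c(-0.1, 0.05, 0.25, 0.45, 0.65, 0.85), 6, 1,
              dimnames = list(paste0("g", 1:6), "A"))
  tab <- correlation_table(r, matrix(10L, 6, 1,
                                     dimnames = dimnames(r)))
  b <- bin_correlations(tab)
  expect_equal(unname(b[, "A"]), rep(1L, 6))

  r0 <- matrix(c(0, -1e-9, 0.2, 0.8, 1), 5, 1,
               dimnames = list(paste0("g", 1:5), "A"))
  t0 <- correlation_table(r0, matrix(10L, 5, 1, dimnames = dimnames(r0)))
  b0 <- bin_correlations(t0)
  expect_equal(unname(b0["[0,0.2)", "A"]), 1L)   # r = 0 exactly
  expect_equal(unname(b0["r<0", "A"]), 1L)
  expect_equal(unname(b0["[0.2,0.4)", "A"]), 1L) # boundary 0.2
  expect_equal(unname(b0["[0.8,1]", "A"]), 2L)   # 0.8 and 1

  set.seed(18)
  rr <- matrix(runif(1000, -1, 1), 500, 2,
               dimnames = list(paste0("g", 1:500), c("A", "B")))
  rr[sample(1000, 50)] <- NA
  tt <- correlation_table(rr, matrix(10L, 500, 2, dimnames = dimnames(rr)))
  bb <- bin_correlations(tt)
  expect_equal(colSums(bb), colSums(!is.na(rr)))
})
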