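#' @title Random-intercept mixed model for per-gene correlations
#'
#' @description
#' Population differences in prediction accuracy are assessed with the
#' linear mixed model
#' \deqn{r_{ij} = \beta_0 + \gamma_i + \sum_{g \ne ref} \beta_g
#'   \mathbb{I}[j = g] + \epsilon_{ij},}
#' where \eqn{r_{ij}} is gene i's observed-vs-predicted Pearson correlation
#' in population j, \eqn{\gamma_i \sim N(0, \sigma_\gamma^2)} is a per-gene
#' random intercept absorbing between-gene variation, and
#' \eqn{\epsilon_{ij} \sim N(0, \sigma^2)}. The shared random intercept
#' induces compound symmetry within genes. Estimation is restricted maximum
#' likelihood (REML) via Fisher scoring on the two variance components with
#' the fixed effects profiled out analytically at each step; the per-gene
#' block structure keeps every trace and quadratic form O(groups^2), so
#' fits scale linearly in the number of genes. Missing cells are handled by
#' the likelihood (genes contribute whatever cells they have); no
#' imputation is done.
#' @name lmm
NULL

# Per-pattern ingredients for the scoring equations. For a gene observed in
# m groups, V = sigma2_e * I + sigma2_g * J and
# W = V^{-1} = (1/sigma2_e) (I - phi/(1+m phi) J), phi = sigma2_g/sigma2_e.
.block_terms <- function(X, sigma2_g, sigma2_e) {
  m <- nrow(X)
  phi <- sigma2_g / sigma2_e
  W <- (diag(m) - (phi / (1 + m * phi)) * matrix(1, m, m)) / sigma2_e
  w1 <- rowSums(W)
  W2 <- W %*% W
  list(
    m = m, W = W, w1 = w1,
    s1 = sum(w1),                      # 1' W 1
    trW = sum(diag(W)),
    trWW = sum(W * W),
    trWJW = sum(w1^2),                 # 1' W W 1
    W21 = rowSums(W2),                 # W^2 1
    XtW = crossprod(X, W),
    XtWX = crossprod(X, W %*% X),
    Xw1 = crossprod(X, w1),
    XtW2X = crossprod(X, W2 %*% X),
    XtW3X = crossprod(X, W2 %*% W %*% X),
    logdetV = m * log(sigma2_e) + log(1 + m * phi)
  )
}

# REML log-likelihood (up to a constant), score vector and expected
# information for theta = (sigma2_g, sigma2_e), computed per missingness
# pattern. `pat` is a list of lists with X (m x k design), Y (g x m values).
.reml_pieces <- function(pat, theta) {
  k <- ncol(pat[[1L]]$X)
  A <- matrix(0, k, k)
  bvec <- numeric(k)
  terms <- vector("list", length(pat))
  for (s in seq_along(pat)) {
    tt <- .block_terms(pat[[s]]$X, theta[1L], theta[2L])
    terms[[s]] <- tt
    g <- nrow(pat[[s]]$Y)
    A <- A + g * tt$XtWX
    bvec <- bvec + tt$XtW %*% colSums(pat[[s]]$Y)
  }
  beta <- solve(A, bvec)
  ypy <- 0; logdetV <- 0
  tr_Vg <- 0; tr_Ve <- 0
  q_g <- 0; q_e <- 0
  T1 <- matrix(0, 2L, 2L)
  Bg <- matrix(0, k, k); Be <- matrix(0, k, k)
  Cgg <- matrix(0, k, k); Cge <- matrix(0, k, k); Cee <- matrix(0, k, k)
  for (s in seq_along(pat)) {
    tt <- terms[[s]]
    g <- nrow(pat[[s]]$Y)
    mu <- as.numeric(pat[[s]]$X %*% beta)
    E <- sweep(pat[[s]]$Y, 2L, mu)
    U <- E %*% tt$W
    ypy <- ypy + sum(E * U)
    logdetV <- logdetV + g * tt$logdetV
    tr_Vg <- tr_Vg + g * tt$s1
    tr_Ve <- tr_Ve + g * tt$trW
    q_g <- q_g + sum(rowSums(U)^2)
    q_e <- q_e + sum(U * U)
    T1[1L, 1L] <- T1[1L, 1L] + g * tt$s1^2
    T1[1L, 2L] <- T1[1L, 2L] + g * tt$trWJW
    T1[2L, 2L] <- T1[2L, 2L] + g * tt$trWW
    XtW21 <- crossprod(pat[[s]]$X, tt$W21)
    Bg <- Bg + g * tcrossprod(tt$Xw1)
    Be <- Be + g * tt$XtW2X
    Cgg <- Cgg + g * tt$s1 * tcrossprod(tt$Xw1)
    Cge <- Cge + g * tcrossprod(tt$Xw1, XtW21)
    Cee <- Cee + g * tt$XtW3X
  }
  T1[2L, 1L] <- T1[1L, 2L]
  Ainv <- solve(A)
  trA <- function(M) sum(Ainv * t(M))
  # tr(P Z_k)
  trP <- c(tr_Vg - trA(Bg), tr_Ve - trA(Be))
  score <- -0.5 * trP + 0.5 * c(q_g, q_e)
  # tr(P Z_k P Z_l) = T1 - tr(Ainv (C_kl + C_lk)) + tr(Ainv B_k Ainv B_l)
  info <- matrix(0, 2L, 2L)
  info[1L, 1L] <- T1[1L, 1L] - 2 * trA(Cgg) + sum((Ainv %*% Bg) * t(Ainv %*% Bg))
  info[1L, 2L] <- T1[1L, 2L] - trA(Cge + t(Cge)) +
    sum((Ainv %*% Bg) * t(Ainv %*% Be))
  info[2L, 1L] <- info[1L, 2L]
  info[2L, 2L] <- T1[2L, 2L] - 2 * trA(Cee) + sum((Ainv %*% Be) * t(Ainv %*% Be))
  info <- 0.5 * info
  loglik <- -0.5 * (logdetV + determinant(A, logarithm = TRUE)$modulus + ypy)
  list(loglik = as.numeric(loglik), score = score, info = info,
       beta = as.numeric(beta), A = A, Ainv = Ainv)
}

#' Fit the random-intercept mixed model to a correlation table
#'
#' REML estimation of the compound-symmetry model described in
#' \link{lmm}. For balanced complete tables the profiled (GLS) fixed
#' effects coincide with ordinary group-mean contrasts. A variance
#' component driven to zero is clamped at the boundary and flagged.
#'
#' @param table a [correlation_table()].
#' @param groups groups (populations) to include; default all columns.
#' @param reference reference group for the contrasts; default the first
#'   included group.
#' @param missing `"likelihood"` (default; each gene contributes its
#'   non-missing cells) or `"complete_cases"` (genes missing any included
#'   cell are dropped).
#' @param max_iter,tol Fisher-scoring iteration cap and relative
#'   log-REML-change convergence tolerance.
#' @return Object of class `lmm_fit`: `beta` (named: `(Intercept)` then one
#'   contrast per non-reference group), `se`, `ci95` (estimate +/- 1.96 SE),
#'   `sigma2_gene`, `sigma2_resid`, `vcov`, `n_genes`, `n_obs`, `groups`,
#'   `reference`, `reml_loglik`, `iterations`, `converged`, `boundary`.
#' @export
fit_lmm <- function(table, groups = NULL, reference = NULL,
                    missing = c("likelihood", "complete_cases"),
                    max_iter = 100L, tol = 1e-10) {
  stopifnot(inherits(table, "correlation_table"))
  missing <- match.arg(missing)
  if (is.null(groups)) groups <- table$groups
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (is.null(reference)) reference <- groups[1L]
  if (!reference %in% groups) {
    stop("reference group not among included groups", call. = FALSE)
  }
  groups <- c(reference, setdiff(groups, reference))
  R <- table$r[, groups, drop = FALSE]
  obs <- !is.na(R)
  if (missing == "complete_cases") {
    keep <- rowSums(obs) == length(groups)
    R <- R[keep, , drop = FALSE]
    obs <- obs[keep, , drop = FALSE]
  }
  keep <- rowSums(obs) > 0L
  R <- R[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  n_genes <- nrow(R)
  if (n_genes < 2L) stop("need at least 2 genes with data", call. = FALSE)
  k <- length(groups)
  Xfull <- cbind(1, stats::model.matrix(~ 0 + g,
    data = data.frame(g = factor(groups, levels = groups)))[, -1L, drop = FALSE])
  colnames(Xfull) <- c("(Intercept)", groups[-1L])

  # group genes by missingness pattern; identical patterns share a design
  pat_key <- apply(obs, 1L, function(z) paste(which(z), collapse = ","))
  pat <- lapply(split(seq_len(n_genes), pat_key), function(idx) {
    cols <- which(obs[idx[1L], ])
    Y <- matrix(R[idx, cols], nrow = length(idx))
    list(X = Xfull[cols, , drop = FALSE], Y = Y)
  })

  y_all <- R[obs]

  # degenerate input: if OLS already fits exactly, both variance
  # components are zero and the scoring iteration has nothing to estimate
  Xlong <- do.call(rbind, lapply(pat, function(p) {
    p$X[rep(seq_len(nrow(p$X)), each = nrow(p$Y)), , drop = FALSE]
  }))
  ylong <- unlist(lapply(pat, function(p) as.vector(p$Y)), use.names = FALSE)
  ols <- stats::lm.fit(Xlong, ylong)
  if (mean(ols$residuals^2) < 1e-20) {
    beta <- ols$coefficients
    names(beta) <- colnames(Xfull)
    se <- stats::setNames(rep(0, k), colnames(Xfull))
    ci <- cbind(lower = beta, upper = beta)
    return(structure(list(beta = beta, se = se, ci95 = ci,
                          vcov = matrix(0, k, k), sigma2_gene = 0,
                          sigma2_resid = 0, n_genes = n_genes,
                          n_obs = length(y_all), groups = groups,
                          reference = reference, reml_loglik = NA_real_,
                          iterations = 0L, converged = TRUE,
                          boundary = TRUE, missing = missing),
                     class = "lmm_fit"))
  }

  v0 <- stats::var(y_all)
  if (!is.finite(v0) || v0 <= 0) v0 <- 1e-6
  theta <- c(v0 / 2, v0 / 2)
  boundary <- FALSE
  converged <- FALSE
  pieces <- .reml_pieces(pat, theta)
  iter <- 0L
  rel <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    at_boundary <- theta[1L] == 0 && pieces$score[1L] <= 0
    if (at_boundary) {
      # sigma2_gene pinned at 0: scalar scoring on sigma2_resid only
      step <- c(0, pieces$score[2L] / pieces$info[2L, 2L])
    } else {
      step <- tryCatch(solve(pieces$info, pieces$score),
                       error = function(e) pieces$score / diag(pieces$info))
    }
    new_theta <- theta + step
    if (new_theta[1L] < 0) {
      # project onto the boundary and take the 1-D step for sigma2_resid
      new_theta[1L] <- 0
      new_theta[2L] <- theta[2L] + pieces$score[2L] / pieces$info[2L, 2L]
      step <- new_theta - theta
    }
    halvings <- 0L
    while (new_theta[2L] <= 0 && halvings < 30L) {
      step <- step / 2
      new_theta <- theta + step
      halvings <- halvings + 1L
    }
    new_pieces <- .reml_pieces(pat, new_theta)
    # fall back to halving if the scoring step decreased the objective
    halvings <- 0L
    while (new_pieces$loglik < pieces$loglik - 1e-12 && halvings < 30L) {
      step <- step / 2
      new_theta <- theta + step
      if (new_theta[1L] < 0) new_theta[1L] <- 0
      new_pieces <- .reml_pieces(pat, new_theta)
      halvings <- halvings + 1L
    }
    rel <- abs(new_pieces$loglik - pieces$loglik) /
      (abs(pieces$loglik) + 1)
    rel_par <- max(abs(new_theta - theta) / pmax(abs(new_theta), 1e-12))
    theta <- new_theta
    pieces <- new_pieces
    if (theta[1L] == 0) boundary <- TRUE
    if (rel < tol && rel_par < 1e-8 &&
        (theta[1L] > 0 || pieces$score[1L] <= 0)) {
      converged <- TRUE
      break
    }
  }
  if (!converged && iter >= max_iter) {
    stop("REML Fisher scoring did not converge after ", max_iter,
         " iterations (last rel change ", format(rel), ")", call. = FALSE)
  }
  if (theta[1L] <= 0) { theta[1L] <- 0; boundary <- TRUE }
  vc <- pieces$Ainv
  se <- sqrt(diag(vc))
  beta <- pieces$beta
  names(beta) <- names(se) <- colnames(Xfull)
  ci <- cbind(lower = beta - 1.96 * se, upper = beta + 1.96 * se)
  structure(list(beta = beta, se = se, ci95 = ci, vcov = vc,
                 sigma2_gene = theta[1L], sigma2_resid = theta[2L],
                 n_genes = n_genes, n_obs = length(y_all),
                 groups = groups, reference = reference,
                 reml_loglik = pieces$loglik, iterations = iter,
                 converged = converged, boundary = boundary,
                 missing = missing),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept LMM (REML), reference = ", x$reference, "\n",
      "  genes: ", x$n_genes, "  observations: ", x$n_obs, "\n",
      "  sigma2_gene = ", format(x$sigma2_gene, digits = 6),
      "  sigma2_resid = ", format(x$sigma2_resid, digits = 6),
      if (x$boundary) "  [variance at boundary]" else "", "\n", sep = "")
  est <- cbind(estimate = x$beta, se = x$se, x$ci95)
  print(round(est, 6))
  invisible(x)
}

#' Wald test for one group contrast of a mixed-model fit
#'
#' Two-sided z-test of the contrast against zero with model-based standard
#' errors; the normal reference is used (gene counts are large in the
#' intended applications).
#'
#' @param fit an `lmm_fit`.
#' @param contrast name of a non-reference group in the fit.
#' @return list with `contrast`, `estimate`, `se`, `z`, `p`, `ci95`.
#' @export
wald_test <- function(fit, contrast) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!contrast %in% names(fit$beta)[-1L]) {
    stop("unknown contrast: ", contrast, call. = FALSE)
  }
  est <- fit$beta[[contrast]]
  se <- fit$se[[contrast]]
  z <- est / se
  list(contrast = contrast, estimate = est, se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)),
       ci95 = c(lower = est - 1.96 * se, upper = est + 1.96 * se))
}

#' Repeated-measures ANOVA for group differences in prediction accuracy
#'
#' Tests the null that all group contrasts are zero (no difference in mean
#' correlation among populations). For a balanced complete table the
#' classical two-way ANOVA without replication is used: genes are blocks,
#' F = MS_group / MS_error with df (k-1, (k-1)(n-1)). For unbalanced
#' tables the statistic is the Wald F on the k-1 contrasts of the REML fit
#' with the same denominator df (n = genes with any data), flagged
#' approximate in the result.
#'
#' @param table a [correlation_table()].
#' @param groups groups to include; default all.
#' @param missing passed to [fit_lmm()] on the unbalanced path.
#' @return Object of class `anova_result`: `F`, `df1`, `df2`, `p`,
#'   `method` ("balanced_ss" or "lmm_wald_f"), `approximate`.
#' @export
rm_anova <- function(table, groups = NULL,
                     missing = c("likelihood", "complete_cases")) {
  stopifnot(inherits(table, "correlation_table"))
  if (is.null(groups)) groups <- table$groups
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  R <- table$r[, groups, drop = FALSE]
  R <- R[rowSums(!is.na(R)) > 0L, , drop = FALSE]
  k <- length(groups)
  n <- nrow(R)
  balanced <- !anyNA(R)
  if (balanced) {
    grand <- mean(R)
    ss_group <- n * sum((colMeans(R) - grand)^2)
    ss_gene <- k * sum((rowMeans(R) - grand)^2)
    ss_tot <- sum((R - grand)^2)
    ss_err <- ss_tot - ss_group - ss_gene
    df1 <- k - 1L
    df2 <- (k - 1L) * (n - 1L)
    Fstat <- if (ss_group <= 1e-30) 0 else (ss_group / df1) / (ss_err / df2)
    method <- "balanced_ss"
    approximate <- FALSE
  } else {
    fit <- fit_lmm(table, groups = groups, missing = match.arg(missing))
    idx <- seq_along(fit$beta)[-1L]
    b <- fit$beta[idx]
    Vb <- fit$vcov[idx, idx, drop = FALSE]
    df1 <- k - 1L
    df2 <- (k - 1L) * (fit$n_genes - 1L)
    Fstat <- as.numeric(crossprod(b, solve(Vb, b))) / df1
    method <- "lmm_wald_f"
    approximate <- TRUE
  }
  structure(list(F = Fstat, df1 = df1, df2 = df2,
                 p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
                 method = method, approximate = approximate),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Repeated-measures ANOVA (", x$method, ")\n  F(", x$df1, ", ",
      x$df2, ") = ", format(x$F, digits = 6), ", p = ",
      format.pval(x$p, digits = 4),
      if (x$approximate) "  [approximate]" else "", "\n", sep = "")
  invisible(x)
}
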