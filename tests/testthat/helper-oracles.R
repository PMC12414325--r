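# Independent oracles used across the suite. These deliberately take
# different computational routes from the package implementation.

# Weighted least squares through lm(): oracle for IVW (no intercept) and
# Egger (with intercept) point estimates and standard errors under
# multiplicative overdispersion floored at 1.
wls_oracle <- function(ivs, intercept = FALSE) {
  w <- 1 / ivs$se_out^2
  if (intercept) {
    flip <- ifelse(ivs$beta_exp < 0, -1, 1)
    fit <- lm(I(ivs$beta_out * flip) ~ I(ivs$beta_exp * flip), weights = w)
    k <- 2
  } else {
    fit <- lm(ivs$beta_out ~ 0 + ivs$beta_exp, weights = w)
    k <- 1
  }
  s <- summary(fit)
  # lm reports SEs scaled by the residual dispersion; refit the floor-at-1
  # convention from the unscaled (fixed-effect) covariance
  sigma2 <- sum(w * resid(fit)^2) / (nrow(ivs) - k)
  infl <- sqrt(max(1, sigma2))
  se_unscaled <- sqrt(diag(s$cov.unscaled))
  list(coef = coef(fit), se = se_unscaled * infl)
}

# Exhaustive-subset constrained-ML oracle at small J: for every invalid set
# of size K, minimize the profiled objective over theta by grid search plus
# golden-section polish, and return the best subset.
cml_brute_oracle <- function(ivs, K) {
  bx <- ivs$beta_exp; by <- ivs$beta_out
  sx2 <- ivs$se_exp^2; sy2 <- ivs$se_out^2
  J <- length(bx)
  pobj <- function(theta, valid) {
    b <- (bx[valid] / sx2[valid] + theta * by[valid] / sy2[valid]) /
      (1 / sx2[valid] + theta^2 / sy2[valid])
    0.5 * sum((bx[valid] - b)^2 / sx2[valid] +
                (by[valid] - theta * b)^2 / sy2[valid])
  }
  subs <- if (K == 0) list(integer(0)) else
    utils::combn(J, K, simplify = FALSE)
  best <- NULL
  for (sub in subs) {
    valid <- setdiff(seq_len(J), sub)
    grid <- seq(-3, 3, length.out = 601)
    vals <- vapply(grid, pobj, numeric(1), valid = valid)
    g0 <- grid[which.min(vals)]
    o <- optimize(pobj, c(g0 - 0.05, g0 + 0.05), valid = valid, tol = 1e-12)
    if (is.null(best) || o$objective < best$objective)
      best <- list(objective = o$objective, invalid = sort(sub),
                   theta = o$minimum)
  }
  best
}

# Direct multivariate-normal log-density sum (mvtnorm route) for complete
# twin data: oracle for the sufficient-statistic FIML fast path.
dmvnorm_oracle <- function(data, params, include_prs = TRUE) {
  vars <- if (include_prs) c("prs1", "x1", "y1", "prs2", "x2", "y2")
    else c("x1", "y1", "x2", "y2")
  ll <- 0
  for (z in c("MZ", "DZ")) {
    d <- data[data$zyg == z, , drop = FALSE]
    if (!nrow(d)) next
    S <- mrdoc_implied_moments(params, z, include_prs = include_prs)$cov
    use <- vars
    if (z == "MZ" && include_prs) use <- setdiff(vars, "prs2")
    ll <- ll + sum(mvtnorm::dmvnorm(as.matrix(d[use]),
                                    sigma = S[use, use], log = TRUE))
  }
  ll
}

# Harmonized instrument table drawn directly (not via the generator), for
# estimator unit tests.
random_iv_table <- function(J, theta = 0.2, seed = 1, pleio_sd = 0) {
  withr::with_seed(seed, {
    bx <- runif(J, 0.05, 0.3) * sample(c(-1, 1), J, TRUE)
    sex <- runif(J, 0.005, 0.02)
    sey <- runif(J, 0.005, 0.02)
    by <- theta * bx + rnorm(J, 0, pleio_sd) + rnorm(J, 0, sey)
    data.frame(snp_id = sprintf("rs%03d", seq_len(J)),
               beta_exp = bx + rnorm(J, 0, sex), se_exp = sex,
               beta_out = by, se_out = sey,
               n_exp = 30000, n_out = 50000,
               stringsAsFactors = FALSE)
  })
}

g1_row <- function(fit) {
  i <- match("g1", fit$estimates$param)
  c(estimate = fit$estimates$estimate[i], se = fit$estimates$se[i],
    pval = fit$estimates$pval[i])
}
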