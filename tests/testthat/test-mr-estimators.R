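test_that("Wald ratio follows the delta method and rejects a zero exposure effect", {
  iv <- data.frame(snp_id = "rs1", beta_exp = 0.2, se_exp = 0.02,
                   beta_out = 0.04, se_out = 0.01)
  r <- mr_wald_ratio(iv)
  expect_equal(r$estimate, 0.2)
  expect_equal(r$se, 0.05)
  iv0 <- transform(iv, beta_out = 0)
  expect_equal(mr_wald_ratio(iv0)$estimate, 0)
  expect_error(mr_wald_ratio(transform(iv, beta_exp = 0)), "undefined")
})

test_that("IVW matches the closed-form WLS oracle and handles zero heterogeneity", {
  two <- data.frame(snp_id = c("a", "b"), beta_exp = c(0.1, 0.2),
                    se_exp = 0.01, beta_out = c(0.02, 0.04),
                    se_out = c(0.01, 0.02))
  r <- mr_ivw(two)
  expect_equal(r$estimate, 0.2)
  expect_equal(r$q_stat, 0)
  # zero heterogeneity: random-effects SE equals the fixed-effect SE
  w <- 1 / two$se_out^2
  expect_equal(r$se, sqrt(1 / sum(w * two$beta_exp^2)))

  for (seed in 1:5) {
    ivs <- random_iv_table(8, theta = -0.3, seed = seed, pleio_sd = 0.02)
    r <- mr_ivw(ivs)
    o <- wls_oracle(ivs)
    expect_equal(r$estimate, unname(o$coef), tolerance = 1e-10)
    expect_equal(r$se, unname(o$se), tolerance = 1e-10)
  }
  expect_error(mr_ivw(two[1, ]), "insufficient")
})

test_that("weighted median returns mass-based quantiles with the stated conventions", {
  mk <- function(ratios, weights) {
    # encode desired ratios/weights into an instrument table:
    # beta_exp = w^(1/2) * se_out constant trick
    se_out <- 0.01
    bx <- sqrt(weights) * se_out
    data.frame(snp_id = paste0("rs", seq_along(ratios)), beta_exp = bx,
               se_exp = 1e-6, beta_out = ratios * bx, se_out = se_out)
  }
  # plain median with equal weights
  r <- mr_weighted_median(mk(c(0.1, 0.2, 0.9), c(1, 1, 1)), n_boot = 10)
  expect_equal(r$estimate, 0.2)
  # an instrument with the weight majority dictates the estimate
  r2 <- mr_weighted_median(mk(c(0.9, 0.1, 0.5), c(6, 2, 2)), n_boot = 10)
  expect_equal(r2$estimate, 0.9)
  # duplication invariance: splitting an instrument's weight in half
  r3 <- mr_weighted_median(mk(c(0.1, 0.2, 0.9, 0.9), c(1, 1, 0.5, 0.5)),
                           n_boot = 10)
  r4 <- mr_weighted_median(mk(c(0.1, 0.2, 0.9), c(1, 1, 1)), n_boot = 10)
  expect_equal(r3$estimate, r4$estimate)
  # fixed seed gives a bit-identical bootstrap SE
  ivs <- random_iv_table(9, seed = 4)
  a <- mr_weighted_median(ivs, n_boot = 200, seed = 42)
  b <- mr_weighted_median(ivs, n_boot = 200, seed = 42)
  expect_identical(a$se, b$se)
})

test_that("Egger matches the WLS-with-intercept oracle and reproduces exact linear data", {
  bx <- c(0.1, 0.15, 0.2, 0.3)
  exact <- data.frame(snp_id = letters[1:4], beta_exp = bx, se_exp = 0.01,
                      beta_out = 0.05 + 0.3 * bx, se_out = 0.01)
  r <- mr_egger(exact)
  expect_equal(r$estimate, 0.3, tolerance = 1e-10)
  expect_equal(r$intercept, 0.05, tolerance = 1e-10)
  expect_equal(r$q_stat, 0, tolerance = 1e-16)

  for (seed in 1:5) {
    ivs <- random_iv_table(10, theta = 0.25, seed = 10 + seed,
                           pleio_sd = 0.03)
    ivs$beta_exp <- abs(ivs$beta_exp)   # oracle orientation
    r <- mr_egger(ivs)
    o <- wls_oracle(ivs, intercept = TRUE)
    expect_equal(r$estimate, unname(o$coef[2]), tolerance = 1e-10)
    expect_equal(r$intercept, unname(o$coef[1]), tolerance = 1e-10)
    expect_equal(r$se, unname(o$se[2]), tolerance = 1e-10)
    expect_equal(r$intercept_se, unname(o$se[1]), tolerance = 1e-10)
  }
  flat <- data.frame(snp_id = letters[1:4], beta_exp = 0.2, se_exp = 0.01,
                     beta_out = rnorm(4, 0, 0.01), se_out = 0.01)
  expect_error(mr_egger(flat), "singular")
  expect_error(mr_egger(exact[1:2, ]), "insufficient")
})

test_that("Egger orients exposure effects positive before fitting", {
  ivs <- random_iv_table(10, theta = 0.25, seed = 3, pleio_sd = 0.02)
  flipped <- ivs
  flipped$beta_exp <- -flipped$beta_exp
  flipped$beta_out <- -flipped$beta_out
  expect_equal(mr_egger(flipped)$estimate, mr_egger(ivs)$estimate,
               tolerance = 1e-12)
})

test_that("estimators are equivariant under outcome negation and exposure scaling", {
  ivs <- random_iv_table(9, theta = 0.2, seed = 6, pleio_sd = 0.02)
  neg <- transform(ivs, beta_out = -beta_out)
  scl <- transform(ivs, beta_exp = 2.5 * beta_exp, se_exp = 2.5 * se_exp)
  for (est in list(mr_ivw,
                   function(d) mr_weighted_median(d, n_boot = 10, seed = 1),
                   mr_egger)) {
    expect_equal(est(neg)$estimate, -est(ivs)$estimate, tolerance = 1e-9)
    expect_equal(est(scl)$estimate, est(ivs)$estimate / 2.5,
                 tolerance = 1e-9)
  }
})

test_that("a single effective instrument direction makes every estimator return that ratio", {
  bx <- c(0.1, 0.15, 0.2, 0.25, 0.3)
  ivs <- data.frame(snp_id = letters[1:5], beta_exp = bx, se_exp = 0.01,
                    beta_out = 0.4 * bx, se_out = 0.01)
  expect_equal(mr_ivw(ivs)$estimate, 0.4, tolerance = 1e-12)
  expect_equal(mr_weighted_median(ivs, n_boot = 10)$estimate, 0.4,
               tolerance = 1e-12)
  expect_equal(mr_egger(ivs)$estimate, 0.4, tolerance = 1e-10)
  cm <- mr_cml_ma(ivs, n_effective = 30000, seed = 1)
  expect_equal(cm$aic$estimate, 0.4, tolerance = 1e-6)
  expect_equal(cm$bic$estimate, 0.4, tolerance = 1e-6)
  expect_length(cm$bic$invalid_ivs, 0)
})

test_that("leave-one-out returns one result per omitted instrument plus the full fit", {
  ivs <- random_iv_table(7, seed = 9)
  loo <- mr_leave_one_out(ivs)
  expect_equal(nrow(loo), 8L)
  expect_equal(loo$omitted, c(ivs$snp_id, "(all)"))
  # exchangeable instruments: all leave-one-out estimates equal the full one
  bx <- c(0.1, 0.2, 0.3, 0.4)
  same <- data.frame(snp_id = letters[1:4], beta_exp = bx, se_exp = 0.01,
                     beta_out = 0.5 * bx, se_out = 0.01)
  loo2 <- mr_leave_one_out(same)
  expect_true(all(abs(loo2$estimate - 0.5) < 1e-12))
})

test_that("omitting a planted outlier moves the estimate most", {
  bx <- seq(0.1, 0.3, length.out = 10)
  ivs <- data.frame(snp_id = sprintf("rs%02d", 1:10), beta_exp = bx,
                    se_exp = 0.005, beta_out = 0.2 * bx, se_out = 0.01)
  ivs$beta_out[4] <- ivs$beta_out[4] + 10 * 0.2 * ivs$beta_exp[4]
  loo <- mr_leave_one_out(ivs)
  full <- loo$estimate[loo$omitted == "(all)"]
  shift <- abs(loo$estimate[loo$omitted != "(all)"] - full)
  expect_equal(which.max(shift), 4L)
  # and its omission lands nearest the truth
  err <- abs(loo$estimate[loo$omitted != "(all)"] - 0.2)
  expect_equal(which.min(err), 4L)
})
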