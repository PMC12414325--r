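test_that("independence parameter point gives identity within-twin covariance", {
  p <- list(e_x = 1, e_y = 1, a_x = 0, c_x = 0, a_y = 0, c_y = 0)
  for (z in c("MZ", "DZ")) {
    S <- mrdoc_implied_moments(p, z)$cov
    expect_equal(S[c("x1", "y1"), c("x1", "y1")], diag(2),
                 ignore_attr = TRUE)
    expect_equal(S["x1", "x2"], 0)
    expect_equal(S["y1", "y2"], 0)
  }
})

test_that("no PRS-to-outcome path means zero implied PRS-outcome covariance", {
  p <- list(g1 = 0, b2 = 0, b1 = 0.4, a_x = 0.5, c_x = 0.4, e_x = 0.5,
            a_y = 0.6, c_y = 0.3, e_y = 0.6)
  for (z in c("MZ", "DZ")) {
    S <- mrdoc_implied_moments(p, z)$cov
    expect_equal(S["prs1", "y1"], 0)
    expect_equal(S["prs1", "y2"], 0)
  }
})

test_that("implied moments match brute-force simulation of the path equations", {
  # moderate n here; the large-n version runs in the acceptance suite
  sc <- twin_scenario(n_mz = 40000, n_dz = 40000, g1 = 0.3, b1 = 0.3,
                      b2 = 0.15, covE = 0.1, ra_xy = 0.2, rc_xy = -0.1)
  sim <- simulate_twins(sc, seed = 19)
  vars <- c("prs1", "x1", "y1", "prs2", "x2", "y2")
  for (z in c("MZ", "DZ")) {
    emp <- cov(as.matrix(sim$data[sim$data$zyg == z, vars]))
    imp <- mrdoc_implied_moments(sc$params, z)$cov
    n <- sum(sim$data$zyg == z)
    mc_se <- sqrt((outer(diag(imp), diag(imp)) + imp^2) / n)
    expect_true(all(abs(emp - imp) < 4.5 * mc_se))
  }
})

test_that("vectorized bivariate normal CDF agrees with mvtnorm and handles infinities", {
  h <- c(-2.5, -1, 0, 0.7, 1.8, 3)
  for (rho in c(-0.85, -0.3, 0, 0.45, 0.9)) {
    grid <- expand.grid(h = h, k = h)
    got <- pbvnorm(grid$h, grid$k, rho)
    want <- mapply(function(a, b)
      mvtnorm::pmvnorm(upper = c(a, b),
                       corr = matrix(c(1, rho, rho, 1), 2))[1],
      grid$h, grid$k)
    expect_equal(got, unname(want), tolerance = 1e-12)
  }
  expect_equal(pbvnorm(Inf, 1.2, 0.5), pnorm(1.2))
  expect_equal(pbvnorm(-Inf, 1.2, 0.5), 0)
  expect_equal(pbvnorm(Inf, Inf, 0.5), 1)
  expect_equal(pbvnorm(c(1, -1), c(0.5, 2), 0.97),
               mapply(function(a, b)
                 mvtnorm::pmvnorm(upper = c(a, b),
                                  corr = matrix(c(1, 0.97, 0.97, 1), 2))[1],
                 c(1, -1), c(0.5, 2)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("continuous FIML equals the direct multivariate-normal density sum", {
  sc <- twin_scenario(n_mz = 120, n_dz = 150, g1 = 0.25, b1 = 0.35,
                      b2 = 0.1)
  sim <- simulate_twins(sc, seed = 8)
  ll <- mrdoc_loglik(sc$params, sim$data)
  expect_equal(ll, dmvnorm_oracle(sim$data, sc$params), tolerance = 1e-8)
  # also for the PRS-free model over (x1, y1, x2, y2)
  ll4 <- mrdoc_loglik(sc$params, sim$data, include_prs = FALSE)
  expect_equal(ll4, dmvnorm_oracle(sim$data, sc$params, include_prs = FALSE),
               tolerance = 1e-8)
})

test_that("FIML handles missing values pattern-wise", {
  sc <- twin_scenario(n_mz = 80, n_dz = 90)
  sim <- simulate_twins(sc, seed = 12)
  d <- sim$data
  d$x2[1:10] <- NA; d$y1[5:20] <- NA
  ll <- mrdoc_loglik(sc$params, d)
  expect_true(is.finite(ll))
  # dropping a variable cannot raise the joint density contribution pattern
  # count; oracle: sum pattern-wise mvtnorm densities
  vars <- c("prs1", "x1", "y1", "prs2", "x2", "y2")
  oracle <- 0
  for (z in c("MZ", "DZ")) {
    dz <- d[d$zyg == z, vars]
    if (z == "MZ") dz$prs2 <- NA  # MZ likelihood uses the single shared PRS
    S <- mrdoc_implied_moments(sc$params, z)$cov
    for (i in seq_len(nrow(dz))) {
      obs <- which(!is.na(dz[i, ]))
      oracle <- oracle + mvtnorm::dmvnorm(as.numeric(dz[i, obs]),
                                          sigma = S[obs, obs, drop = FALSE],
                                          log = TRUE)
    }
  }
  expect_equal(ll, oracle, tolerance = 1e-8)
})

test_that("likelihood is invariant to family order and twin relabeling", {
  sc <- twin_scenario(n_mz = 60, n_dz = 70, g1 = 0.2, b1 = 0.3, covE = 0.05)
  sim <- simulate_twins(sc, seed = 3)
  d <- sim$data
  ll <- mrdoc_loglik(sc$params, d)
  perm <- d[sample(nrow(d)), ]
  expect_equal(mrdoc_loglik(sc$params, perm), ll, tolerance = 1e-12)
  swapped <- transform(d, prs1 = prs2, prs2 = prs1, x1 = x2, x2 = x1,
                       y1 = y2, y2 = y1)
  expect_equal(mrdoc_loglik(sc$params, swapped), ll, tolerance = 1e-8)
})

test_that("degenerate thresholds make the categorical part contribute probability one", {
  sc <- twin_scenario(n_mz = 50, n_dz = 60, outcome_type = "ordinal3")
  sim <- simulate_twins(sc, seed = 4)
  d <- sim$data
  d$y1 <- 1L; d$y2 <- 1L     # single observed category
  ll <- mrdoc_loglik(sc$params, d, outcome_type = "ordinal3",
                     thresholds = c(-1e6, 1e6))
  # equals the continuous-margins-only likelihood over (prs, x)
  d2 <- d; d2$y1 <- NA_real_; d2$y2 <- NA_real_
  ll_marg <- mrdoc_loglik(sc$params, d2, outcome_type = "ordinal3",
                          thresholds = c(-1e6, 1e6))
  expect_equal(ll, ll_marg, tolerance = 1e-10)
})

test_that("the unit-liability constraint pins implied outcome variance at 1", {
  p <- list(g1 = 0.4, b1 = 0.3, b2 = 0.2, a_x = 0.5, c_x = 0.4, e_x = 0.6,
            a_y = 0.4, c_y = 0.3, covE = 0)
  ey <- mrtwin:::solve_unit_liability_ey(p)
  p$e_y <- ey
  for (z in c("MZ", "DZ"))
    expect_equal(mrdoc_implied_moments(p, z)$cov["y1", "y1"], 1,
                 tolerance = 1e-12)
  # paths already exceeding unit variance are inadmissible
  too_big <- utils::modifyList(p, list(g1 = 1.2, b2 = 0.9))
  expect_true(is.na(mrtwin:::solve_unit_liability_ey(too_big)))
})
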