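# Constrained-maximum-likelihood MR with data-driven invalid-instrument
# selection and AIC/BIC model averaging.
#
# Model: observed effects (beta_exp_i, beta_out_i) are independent normals
# around latent (b_i, theta * b_i + r_i) with known SEs; r_i is a free
# horizontal-pleiotropy parameter for at most K instruments (the "invalid"
# set), zero for the rest. For each K the profiled likelihood is maximized by
# coordinate iteration; models are combined across K by information-criterion
# weights.

# One constrained fit at fixed invalid-set size K. The latent exposure
# effects b_i have a closed form given theta, so for a fixed invalid set the
# negative log-likelihood profiles to a smooth 1-D function of theta which is
# minimized exactly; the invalid set (K largest profiled outcome residuals)
# is re-selected around that inner solve until stable. Returns theta, se,
# objective (negative profile log-likelihood up to a constant), invalid
# indices, convergence flag.
cml_fit_k <- function(bx, by, sx2, sy2, K, theta_start, maxit = 100) {
  J <- length(bx)
  profile_obj <- function(theta, valid) {
    b <- (bx[valid] / sx2[valid] + theta * by[valid] / sy2[valid]) /
      (1 / sx2[valid] + theta^2 / sy2[valid])
    0.5 * sum((bx[valid] - b)^2 / sx2[valid] +
                (by[valid] - theta * b)^2 / sy2[valid])
  }
  theta <- theta_start
  invalid <- NULL
  converged <- FALSE
  for (it in seq_len(maxit)) {
    b0 <- (bx / sx2 + theta * by / sy2) / (1 / sx2 + theta^2 / sy2)
    # the K instruments whose outcome residuals resist the shared slope most
    score <- (by - theta * b0)^2 / sy2
    invalid_new <- if (K > 0) sort(order(score, decreasing = TRUE)[1:K])
      else integer(0)
    valid <- if (K > 0) seq_len(J)[-invalid_new] else seq_len(J)
    inner <- tryCatch(
      nlminb(theta, profile_obj, valid = valid,
             control = list(rel.tol = 1e-14, iter.max = 500)),
      error = function(e) NULL)
    if (is.null(inner) || !is.finite(inner$objective)) break
    done <- abs(inner$par - theta) < 1e-10 * (1 + abs(inner$par)) &&
      identical(invalid_new, invalid)
    theta <- inner$par
    invalid <- invalid_new
    if (done) { converged <- TRUE; break }
  }
  if (is.null(invalid)) invalid <- integer(0)
  b0 <- (bx / sx2 + theta * by / sy2) / (1 / sx2 + theta^2 / sy2)
  b <- b0
  if (K > 0) b[invalid] <- bx[invalid]
  valid <- setdiff(seq_len(J), invalid)
  obj <- profile_obj(theta, valid)
  # observed-information SE: invert the (theta, b_valid) Hessian by its
  # Schur complement; invalid instruments carry no information on theta
  h_tt <- sum(b[valid]^2 / sy2[valid])
  h_tb <- (2 * theta * b[valid] - by[valid]) / sy2[valid]
  h_bb <- 1 / sx2[valid] + theta^2 / sy2[valid]
  info <- h_tt - sum(h_tb^2 / h_bb)
  se <- if (is.finite(info) && info > 0) sqrt(1 / info) else NA_real_
  list(theta = theta, se = se, objective = obj, invalid = invalid,
       converged = converged && length(valid) > 0)
}

#' Constrained-ML MR with AIC/BIC model averaging
#'
#' For each candidate number of invalid instruments `K` in `k_range`, the
#' constrained Gaussian likelihood is maximized allowing exactly `K`
#' instruments a free pleiotropy parameter (selected iteratively by largest
#' profiled residual contribution). Fits are combined across `K` by AIC and
#' BIC model-averaging weights `exp(-delta/2)`: the AIC combination is more
#' powerful but less stringent in instrument selection, the BIC combination
#' (penalty `log(n) * K`) more conservative. The model-averaged variance adds
#' between-model spread to within-model variance. The invalid-instrument set
#' reported under each criterion is that of the single best model.
#'
#' @param ivs Harmonized instrument table with at least 3 rows.
#' @param n_effective Sample size entering the BIC penalty; defaults to the
#'   smallest exposure/outcome sample size on the instrument table
#'   (`min(n_exp, n_out)`).
#' @param k_range Candidate invalid-set sizes; default `0:(J-2)`.
#' @param seed RNG seed for the randomized extra starts.
#' @param n_starts Number of starting values per `K` (IVW, zero, and
#'   seeded jitters); default 5.
#' @return A list of class `mr_cml`: `aic` and `bic` (`mr_result`s with the
#'   best-model invalid-IV sets), and `per_k` (a data frame with one row per
#'   converged `K`: estimate, se, objective, aic, bic, invalid ids).
#' @export
mr_cml_ma <- function(ivs, n_effective = NULL, k_range = NULL, seed = 1,
                      n_starts = 5) {
  check_ivs(ivs, 3L, "cml")
  J <- nrow(ivs)
  if (is.null(k_range)) k_range <- 0:(J - 2)
  if (any(k_range < 0 | k_range > J - 2))
    stopf("cml: k_range must lie in 0..J-2")
  if (is.null(n_effective)) {
    ns <- c(ivs$n_exp, ivs$n_out)
    ns <- ns[is.finite(ns)]
    if (!length(ns))
      stopf("cml: n_effective not supplied and instrument table has no sample sizes")
    n_effective <- min(ns)
  }
  bx <- ivs$beta_exp; by <- ivs$beta_out
  sx2 <- ivs$se_exp^2; sy2 <- ivs$se_out^2
  theta_ivw <- sum(by * bx / sy2) / sum(bx^2 / sy2)
  # the coordinate iteration is non-convex in the invalid set; start from the
  # IVW slope, zero, and individual Wald ratios (each being the slope
  # consistent with one instrument's validity) to cover the selection modes
  ratios <- by / bx
  ratio_starts <- if (J <= 10) ratios else
    with_seed(seed + 1, sample(ratios, 8))
  starts <- unique(c(theta_ivw, 0, median(ratios), ratio_starts,
                     with_seed(seed, rnorm(max(0, n_starts - 2), theta_ivw,
                                           abs(theta_ivw) + 0.1))))

  fits <- lapply(k_range, function(K) {
    best <- NULL
    for (s in starts) {
      f <- cml_fit_k(bx, by, sx2, sy2, K, s)
      if (!f$converged) next
      if (is.null(best) || f$objective < best$objective - 1e-12) best <- f
    }
    if (is.null(best)) warnf("cml: no converged fit at K = %d; dropped", K)
    best
  })
  keep <- !vapply(fits, is.null, logical(1))
  if (!any(keep)) stopf("cml: no invalid-set size reached convergence")
  fits <- fits[keep]
  ks <- k_range[keep]

  obj <- vapply(fits, `[[`, numeric(1), "objective")
  aic <- 2 * obj + 2 * ks
  bic <- 2 * obj + log(n_effective) * ks
  per_k <- data.frame(
    k = ks,
    estimate = vapply(fits, `[[`, numeric(1), "theta"),
    se = vapply(fits, `[[`, numeric(1), "se"),
    objective = obj, aic = aic, bic = bic,
    invalid = vapply(fits, function(f)
      paste(ivs$snp_id[f$invalid], collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )

  average <- function(crit, label) {
    w <- exp(-(crit - min(crit)) / 2)
    w <- w / sum(w)
    est <- sum(w * per_k$estimate)
    se <- sqrt(sum(w * (per_k$se^2 + (per_k$estimate - est)^2)))
    best <- which.min(crit)
    r <- mr_result(label, est, se, n_iv = J,
                   invalid_ivs = ivs$snp_id[fits[[best]]$invalid])
    r$k_best <- ks[best]
    r$weights <- setNames(w, ks)
    r
  }
  structure(list(aic = average(aic, "MR-cML (MA-AIC)"),
                 bic = average(bic, "MR-cML (MA-BIC)"),
                 per_k = per_k, n_effective = n_effective),
            class = "mr_cml")
}

#' @export
print.mr_cml <- function(x, ...) {
  print(x$aic); print(x$bic)
  invisible(x)
}
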