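# Core two-sample MR estimators operating on a harmonized instrument table
# (columns beta_exp, se_exp, beta_out, se_out, ...; see harmonize()).

mr_result <- function(method, estimate, se, pval = NULL, n_iv, q_stat = NA,
                      intercept = NA, intercept_se = NA, invalid_ivs = NULL,
                      notes = NULL) {
  ci <- estimate + c(-1, 1) * qnorm(0.975) * se
  structure(list(
    method = method, estimate = estimate, se = se,
    ci_low = ci[1], ci_high = ci[2],
    pval = pval %||% 2 * pnorm(-abs(estimate / se)),
    n_iv = n_iv, q_stat = q_stat,
    intercept = intercept, intercept_se = intercept_se,
    invalid_ivs = invalid_ivs %||% character(0),
    notes = notes %||% character(0)
  ), class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: estimate %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g, %d IVs\n",
              x$method, x$estimate, x$se, x$ci_low, x$ci_high, x$pval, x$n_iv))
  if (is.finite(x$intercept))
    cat(sprintf("  intercept %.4f (SE %.4f)\n", x$intercept, x$intercept_se))
  if (length(x$invalid_ivs))
    cat("  invalid IVs:", paste(x$invalid_ivs, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, estimate = x$estimate, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             n_iv = x$n_iv, q_stat = x$q_stat, intercept = x$intercept,
             intercept_se = x$intercept_se,
             invalid_ivs = paste(x$invalid_ivs, collapse = ";"),
             stringsAsFactors = FALSE)
}

check_ivs <- function(ivs, min_n, method) {
  if (!is.data.frame(ivs) || !all(c("beta_exp", "se_exp", "beta_out",
                                    "se_out") %in% names(ivs)))
    stopf("%s: ivs must be a harmonized instrument table", method)
  if (nrow(ivs) < min_n)
    stopf("%s: insufficient instruments (%d supplied, %d required)",
          method, nrow(ivs), min_n)
  invisible(TRUE)
}

#' Wald ratio for a single instrument
#'
#' Per-instrument causal estimate `beta_out / beta_exp` with first-order
#' delta-method standard error `|se_out / beta_exp|` (exposure estimation
#' error ignored, the convention underlying IVW and the weighted median).
#'
#' @param iv One-row harmonized instrument table.
#' @return An `mr_result`.
#' @export
mr_wald_ratio <- function(iv) {
  check_ivs(iv, 1L, "wald_ratio")
  iv <- iv[1L, ]
  if (iv$beta_exp == 0) stopf("wald_ratio: beta_exp is zero; ratio undefined")
  mr_result("Wald ratio", iv$beta_out / iv$beta_exp,
            abs(iv$se_out / iv$beta_exp), n_iv = 1L)
}

#' Inverse-variance-weighted estimator (multiplicative random effects)
#'
#' Weighted least squares of outcome effects on exposure effects through the
#' origin with weights `1/se_out^2`. Heterogeneity is measured by Cochran's
#' `Q = sum w_j (beta_out_j - theta * beta_exp_j)^2`; the random-effects
#' standard error inflates the fixed-effect one by `max(1, sqrt(Q/(J-1)))`
#' (multiplicative overdispersion floored at 1). CI and p are normal-based.
#'
#' @param ivs Harmonized instrument table with at least 2 rows.
#' @return An `mr_result` with `q_stat` filled.
#' @export
mr_ivw <- function(ivs) {
  check_ivs(ivs, 2L, "ivw")
  w <- 1 / ivs$se_out^2
  sxx <- sum(w * ivs$beta_exp^2)
  theta <- sum(w * ivs$beta_exp * ivs$beta_out) / sxx
  se_fixed <- sqrt(1 / sxx)
  q <- sum(w * (ivs$beta_out - theta * ivs$beta_exp)^2)
  phi <- max(1, q / (nrow(ivs) - 1))
  mr_result("IVW (random effects)", theta, se_fixed * sqrt(phi),
            n_iv = nrow(ivs), q_stat = q)
}

# Weighted quantile at cumulative mass 0.5 of the Wald ratios. The estimate is
# the smallest ratio whose normalized cumulative weight reaches 0.5; when the
# cumulative weight hits 0.5 exactly at a boundary between two instruments the
# two adjacent ratios are interpolated midway. An instrument carrying more
# than half the total weight therefore returns its own ratio, and splitting
# any instrument's weight across duplicates leaves the estimate unchanged.
weighted_median_point <- function(ratios, weights) {
  o <- order(ratios)
  r <- ratios[o]
  cw <- cumsum(weights[o]) / sum(weights)
  k <- which(cw >= 0.5 - 1e-12)[1]
  if (abs(cw[k] - 0.5) < 1e-12 && k < length(r)) (r[k] + r[k + 1]) / 2
  else r[k]
}

#' Weighted-median estimator
#'
#' Median of the per-instrument Wald ratios under inverse-variance weights
#' `(beta_exp/se_out)^2`; consistent when instruments carrying at least half
#' the weight are valid. The standard error comes from a parametric bootstrap
#' that redraws `beta_exp` and `beta_out` from their reported standard errors
#' with a fixed seed (bit-reproducible).
#'
#' @param ivs Harmonized instrument table with at least 2 rows.
#' @param n_boot Bootstrap replicates for the SE; default 10000.
#' @param seed RNG seed for the bootstrap.
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(ivs, n_boot = 10000, seed = 1) {
  check_ivs(ivs, 2L, "weighted_median")
  if (any(ivs$beta_exp == 0))
    stopf("weighted_median: beta_exp contains zero; ratio undefined")
  wm <- function(bx, by) weighted_median_point(by / bx, (bx / ivs$se_out)^2)
  est <- wm(ivs$beta_exp, ivs$beta_out)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      wm(rnorm(nrow(ivs), ivs$beta_exp, ivs$se_exp),
         rnorm(nrow(ivs), ivs$beta_out, ivs$se_out))
    }, numeric(1))
  })
  mr_result("Weighted median", est, sd(boot), n_iv = nrow(ivs))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with a
#' free intercept (weights `1/se_out^2`), after orienting every instrument so
#' its exposure effect is positive (both betas flipped together, the
#' convention required for interpreting the intercept as average directional
#' pleiotropy under InSIDE). The slope is the causal estimate; standard
#' errors use multiplicative overdispersion, residual-based and floored at 1.
#'
#' @param ivs Harmonized instrument table with at least 3 rows.
#' @return An `mr_result` with `intercept` and `intercept_se`.
#' @export
mr_egger <- function(ivs) {
  check_ivs(ivs, 3L, "egger")
  flip <- sign(ivs$beta_exp)
  flip[flip == 0] <- 1
  bx <- ivs$beta_exp * flip
  by <- ivs$beta_out * flip
  w <- 1 / ivs$se_out^2
  # weighted normal equations for (intercept, slope)
  sw <- sum(w); swx <- sum(w * bx); swxx <- sum(w * bx^2)
  det <- sw * swxx - swx^2
  if (!is.finite(det) || abs(det) < 1e-12 * sw * swxx ||
      var(bx) < .Machine$double.eps)
    stopf("egger: singular design (exposure effects collinear with intercept)")
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  slope <- (sw * swxy - swx * swy) / det
  inter <- (swxx * swy - swx * swxy) / det
  resid2 <- w * (by - inter - slope * bx)^2
  phi <- max(1, sum(resid2) / (nrow(ivs) - 2))
  se_slope <- sqrt(phi * sw / det)
  se_inter <- sqrt(phi * swxx / det)
  q <- sum(resid2)
  res <- mr_result("MR-Egger", slope, se_slope, n_iv = nrow(ivs), q_stat = q,
                   intercept = inter, intercept_se = se_inter)
  res$intercept_pval <- 2 * pnorm(-abs(inter / se_inter))
  res
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the causal effect with each instrument omitted in turn,
#' flagging instruments whose omission changes the estimate's sign or its
#' nominal significance at the 5% level.
#'
#' @param ivs Harmonized instrument table with at least 3 rows.
#' @param estimator Function mapping an instrument table to an `mr_result`;
#'   default [mr_ivw()].
#' @return A `data.frame` with one row per omitted SNP plus an `(all)` row,
#'   columns `omitted`, `estimate`, `se`, `ci_low`, `ci_high`, `pval`,
#'   `sign_change`, `significance_change`.
#' @export
mr_leave_one_out <- function(ivs, estimator = mr_ivw) {
  check_ivs(ivs, 3L, "leave_one_out")
  full <- estimator(ivs)
  one <- function(i, label) {
    r <- if (is.na(i)) full else estimator(ivs[-i, , drop = FALSE])
    data.frame(omitted = label, estimate = r$estimate, se = r$se,
               ci_low = r$ci_low, ci_high = r$ci_high, pval = r$pval,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(ivs)), function(i) one(i, ivs$snp_id[i]))
  out <- rbind(do.call(rbind, rows), one(NA, "(all)"))
  out$sign_change <- sign(out$estimate) != sign(full$estimate)
  out$significance_change <- (out$pval < 0.05) != (full$pval < 0.05)
  rownames(out) <- NULL
  out
}
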