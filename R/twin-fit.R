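# Maximum-likelihood fitting of the MR-DoC and hybrid DoC twin models.

BIG_PENALTY <- 1e10

# Free-parameter template for each model variant. Ordinal outcomes drop e_y
# (derived from the unit-liability constraint).
twin_free_params <- function(model, outcome_type, estimate_rarc, free_g2) {
  free <- c(if (model == "mrdoc") c("g1", "b1", "b2")
            else c("g1", if (free_g2) "g2"),
            "a_x", "c_x", "e_x", "a_y", "c_y",
            if (outcome_type != "ordinal3") "e_y",
            if (estimate_rarc) c("ra_xy", "rc_xy"))
  free
}

twin_start_values <- function(free) {
  defaults <- c(g1 = 0.1, g2 = 0.1, b1 = 0.2, b2 = 0,
                a_x = 0.55, c_x = 0.45, e_x = 0.55,
                a_y = 0.5, c_y = 0.4, e_y = 0.55,
                ra_xy = 0, rc_xy = 0)
  defaults[free]
}

twin_objective <- function(prep, spec) {
  base <- utils::modifyList(
    mrdoc_default_params(),
    list(g2 = 0, b1 = 0, b2 = 0, ra_xy = 0, rc_xy = 0, covE = spec$covE))
  ifree <- match(spec$free, names(base))
  ordinal <- spec$outcome_type == "ordinal3"
  function(par) {
    params <- base
    params[ifree] <- par
    if (ordinal) {
      ey <- solve_ey_full(params)
      if (is.na(ey)) return(BIG_PENALTY)
      params$e_y <- ey
    }
    ll <- twin_loglik_prepared(params, prep, spec$thresholds)
    if (!is.finite(ll)) return(BIG_PENALTY)
    -ll
  }
}

# Multi-start quasi-Newton maximization with numerically derived SEs.
fit_twin_model <- function(prep, spec, starts, seed, control = list()) {
  obj <- twin_objective(prep, spec)
  start0 <- twin_start_values(spec$free)
  ctrl <- utils::modifyList(
    list(iter.max = 1000, eval.max = 2000, rel.tol = 1e-10), control)
  start_list <- with_seed(seed, {
    c(list(start0),
      lapply(seq_len(max(0, starts - 1)), function(i)
        start0 + rnorm(length(start0), 0, 0.15)))
  })
  best <- NULL
  for (s in start_list) {
    fit <- tryCatch(nlminb(s, obj, control = ctrl), error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective) ||
        fit$objective >= BIG_PENALTY / 2) next
    fit$conv_ok <- fit$convergence == 0
    if (is.null(best) || fit$objective < best$objective - 1e-9 ||
        (fit$conv_ok && !best$conv_ok &&
           fit$objective < best$objective + 1e-9))
      best <- fit
  }
  if (is.null(best))
    stopf("twin model: no start reached an admissible optimum")
  par <- setNames(best$par, spec$free)

  H <- tryCatch(optimHess(par, obj), error = function(e) NULL)
  vcov <- NULL; se <- rep(NA_real_, length(par)); se_ok <- FALSE
  if (!is.null(H)) {
    ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) -1)
    if (all(ev > 0)) {
      vcov <- solve(H)
      se <- sqrt(pmax(diag(vcov), 0))
      se_ok <- TRUE
    }
  }
  names(se) <- spec$free
  if (!se_ok)
    warnf("twin model: observed-information matrix not positive definite; SEs flagged unreliable")

  params <- utils::modifyList(mrdoc_default_params(),
                              list(g2 = 0, b1 = 0, b2 = 0, covE = spec$covE))
  params[spec$free] <- as.list(par)
  if (spec$outcome_type == "ordinal3")
    params$e_y <- solve_unit_liability_ey(params)

  list(params = params, free = spec$free, par = par, se = se, vcov = vcov,
       se_ok = se_ok, loglik = -best$objective, converged = best$conv_ok,
       n_starts_used = length(start_list))
}

# Shared post-processing into an mrdoc_fit object.
build_fit_object <- function(core, spec, n_mz, n_dz, model) {
  est <- data.frame(param = core$free, estimate = core$par, se = core$se,
                    stringsAsFactors = FALSE, row.names = NULL)
  est$z <- est$estimate / est$se
  est$pval <- 2 * pnorm(-abs(est$z))
  structure(list(
    model = model, outcome_type = spec$outcome_type,
    params = core$params, free = core$free, estimates = est,
    se_ok = core$se_ok, vcov = core$vcov,
    loglik = core$loglik, converged = core$converged,
    covE = spec$covE, thresholds = spec$thresholds,
    n_mz = n_mz, n_dz = n_dz
  ), class = "mrdoc_fit")
}

#' Fit the MR-DoC twin structural equation model
#'
#' Maximizes the FIML likelihood of the MR-DoC model — polygenic score as
#' instrument (`b1`), causal path `g1` from exposure to outcome, explicit
#' horizontal-pleiotropy path `b2`, ACE decompositions for both traits — with
#' the unique-environment exposure-outcome covariance `covE` *fixed* (not
#' estimated; fixing it, typically at 0, is what identifies `g1` and `b2`
#' simultaneously). A 3-level ordinal outcome is handled under the liability
#' threshold model with thresholds fixed from the observed category counts
#' and residual liability variance constrained to 1.
#'
#' Continuous variables are standardized (pooled over twins and zygosity)
#' before fitting, so estimates are on the standardized scale. Standard
#' errors come from the numerically evaluated observed information; when that
#' matrix is not positive definite the fit is returned with `se_ok = FALSE`
#' rather than dropped.
#'
#' @param data Wide twin table: columns `zyg` ("MZ"/"DZ"), `prs1`, `prs2`,
#'   `x1`, `x2`, `y1`, `y2` (`y` ordinal levels 0..2 for
#'   `outcome_type = "ordinal3"`). One row per pair; missing values allowed.
#' @param outcome_type `"continuous"` or `"ordinal3"`.
#' @param covE Fixed unique-environment covariance between exposure and
#'   outcome; default 0 (the identification assumption).
#' @param estimate_rarc Also free the A/C cross-trait correlations (default
#'   `FALSE`, the identified MR-DoC configuration).
#' @param starts Number of optimizer starts (first from defaults, the rest
#'   jittered); default 10.
#' @param seed Seed for the start jitter.
#' @param standardize Standardize continuous columns before fitting.
#' @param thresholds Optional fixed thresholds for the ordinal outcome;
#'   default estimated from pooled category counts via
#'   [estimate_thresholds()].
#' @param control Passed to [stats::nlminb()] control.
#' @return An object of class `mrdoc_fit`: parameter estimates with SEs/z/p
#'   (`$estimates`), full parameter list (`$params`), log-likelihood,
#'   convergence flag, zygosity group sizes, fixed `covE` and thresholds.
#' @seealso [fit_hybrid_doc()], [cov_e_sensitivity()], [mrdoc_loglik()]
#' @export
fit_mrdoc <- function(data, outcome_type = c("continuous", "ordinal3"),
                      covE = 0, estimate_rarc = FALSE, starts = 10, seed = 1,
                      standardize = TRUE, thresholds = NULL,
                      control = list()) {
  outcome_type <- match.arg(outcome_type)
  n_mz <- sum(data$zyg == "MZ"); n_dz <- sum(data$zyg == "DZ")
  if (n_mz == 0 || n_dz == 0)
    stopf("fit_mrdoc: both MZ and DZ pairs are required (have %d MZ, %d DZ)",
          n_mz, n_dz)
  prs <- c(data$prs1, data$prs2)
  if (!is.numeric(prs) || var(prs, na.rm = TRUE) <= 0 || all(is.na(prs)))
    stopf("fit_mrdoc: degenerate instrument (PRS has zero variance)")

  if (standardize) {
    data <- standardize_pairs(data, c("prs", "x",
                                      if (outcome_type == "continuous") "y"))
  }
  if (outcome_type == "ordinal3" && is.null(thresholds)) {
    counts <- tabulate(factor(c(data$y1, data$y2), levels = 0:2), 3L)
    thresholds <- estimate_thresholds(counts)
  }
  spec <- list(model = "mrdoc", outcome_type = outcome_type, covE = covE,
               thresholds = thresholds,
               free = twin_free_params("mrdoc", outcome_type, estimate_rarc,
                                       free_g2 = FALSE))
  prep <- prepare_twin_data(data, outcome_type, include_prs = TRUE)
  core <- fit_twin_model(prep, spec, starts, seed, control)
  build_fit_object(core, spec, n_mz, n_dz, "mrdoc")
}

# Pooled (twin-1 + twin-2) centering and unit-variance scaling per measure.
standardize_pairs <- function(data, stems) {
  for (stem in stems) {
    cols <- paste0(stem, 1:2)
    v <- unlist(data[cols])
    mu <- mean(v, na.rm = TRUE); sdv <- sd(v, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) next
    for (cn in cols) data[[cn]] <- (data[[cn]] - mu) / sdv
  }
  data
}

#' Fit the PRS-free hybrid direction-of-causation model
#'
#' Bivariate ACE twin model with reciprocal causal paths `g1` (X to Y) and
#' `g2` (Y to X), identified by the differing MZ/DZ cross-twin cross-trait
#' covariance signatures — no polygenic-score instrument required, so it can
#' be fitted to the full twin sample regardless of PRS availability.
#' By default the A/C cross-trait correlations are fixed at 0 (freeing them
#' together with both causal paths is structurally under-identified). When
#' the likelihood surface is empirically flat (observed information not
#' positive definite) the fit carries an identification warning rather than
#' failing.
#'
#' @inheritParams fit_mrdoc
#' @param free_g2 Estimate the reverse causal path `g2` (default `TRUE`;
#'   set `FALSE` for a single-direction DoC fit, e.g. when comparing against
#'   [fit_mrdoc()] in the weak-instrument limit).
#' @param estimate_rarc Free `ra_xy`/`rc_xy` instead of a second causal path
#'   (identification requires `free_g2 = FALSE`; combining both triggers a
#'   warning).
#' @return An object of class `mrdoc_fit` with `model = "doc"`.
#' @export
fit_hybrid_doc <- function(data, outcome_type = c("continuous", "ordinal3"),
                           free_g2 = TRUE, estimate_rarc = FALSE,
                           starts = 10, seed = 1, standardize = TRUE,
                           thresholds = NULL, control = list()) {
  outcome_type <- match.arg(outcome_type)
  n_mz <- sum(data$zyg == "MZ"); n_dz <- sum(data$zyg == "DZ")
  if (n_mz == 0 || n_dz == 0)
    stopf("fit_hybrid_doc: direction of causation is identified by the MZ/DZ contrast; both groups are required (have %d MZ, %d DZ)",
          n_mz, n_dz)
  if (free_g2 && estimate_rarc)
    warnf("fit_hybrid_doc: reciprocal paths plus free A/C cross-correlations are not jointly identified; expect a flat likelihood")
  if (standardize)
    data <- standardize_pairs(data, c("x",
                                      if (outcome_type == "continuous") "y"))
  if (outcome_type == "ordinal3" && is.null(thresholds)) {
    counts <- tabulate(factor(c(data$y1, data$y2), levels = 0:2), 3L)
    thresholds <- estimate_thresholds(counts)
  }
  spec <- list(model = "doc", outcome_type = outcome_type, covE = 0,
               thresholds = thresholds,
               free = twin_free_params("doc", outcome_type, estimate_rarc,
                                       free_g2 = free_g2))
  prep <- prepare_twin_data(data, outcome_type, include_prs = FALSE)
  core <- fit_twin_model(prep, spec, starts, seed, control)
  fit <- build_fit_object(core, spec, n_mz, n_dz, "doc")
  if (!core$se_ok) {
    fit$identification_warning <-
      "observed information not positive definite; likelihood may be flat (similar ACE profiles for the two traits)"
    warning(fit$identification_warning, call. = FALSE)
  }
  fit
}

#' Sensitivity of the causal estimate to fixed unique-environment confounding
#'
#' Refits the MR-DoC model over a grid of fixed `covE` values (the
#' unique-environment exposure-outcome covariance that the primary analysis
#' assumes to be 0). The grid must be strictly increasing and contain 0; the
#' curve's `covE = 0` entry is the primary fit. Per-point non-convergence is
#' recorded in the curve rather than aborting it.
#'
#' @inheritParams fit_mrdoc
#' @param grid Strictly increasing numeric vector of covE values containing 0.
#' @return Object of class `mrdoc_sensitivity`: a `data.frame` with columns
#'   `covE`, `estimate` (g1), `se`, `loglik`, `converged`; the per-point fits
#'   are attached as attribute `"fits"`.
#' @export
cov_e_sensitivity <- function(data, outcome_type = "continuous", grid,
                              estimate_rarc = FALSE, starts = 10, seed = 1,
                              standardize = TRUE, thresholds = NULL,
                              control = list()) {
  if (!length(grid) || is.unsorted(grid, strictly = TRUE))
    stopf("cov_e_sensitivity: grid must be strictly increasing")
  if (!any(grid == 0))
    stopf("cov_e_sensitivity: grid must contain 0 (the primary fit)")
  fits <- lapply(grid, function(ce) {
    tryCatch(
      fit_mrdoc(data, outcome_type, covE = ce,
                estimate_rarc = estimate_rarc, starts = starts, seed = seed,
                standardize = standardize, thresholds = thresholds,
                control = control),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "mrdoc_fit_failure"))
  })
  row1 <- function(f, ce) {
    if (inherits(f, "mrdoc_fit_failure"))
      return(data.frame(covE = ce, estimate = NA_real_, se = NA_real_,
                        loglik = NA_real_, converged = FALSE))
    i <- match("g1", f$estimates$param)
    data.frame(covE = ce, estimate = f$estimates$estimate[i],
               se = f$estimates$se[i], loglik = f$loglik,
               converged = f$converged)
  }
  curve <- do.call(rbind, Map(row1, fits, grid))
  rownames(curve) <- NULL
  structure(curve, fits = fits, class = c("mrdoc_sensitivity", "data.frame"))
}

#' Fixed liability thresholds from ordinal category counts
#'
#' Under the liability-threshold model the two thresholds of a 3-level
#' ordinal measure are fixed at the standard-normal quantiles of the
#' cumulative category proportions: `tau1 = qnorm(n0/N)`,
#' `tau2 = qnorm((n0+n1)/N)`. They are then held constant during model
#' fitting.
#'
#' @param counts Integer vector `(n0, n1, n2)` of category counts (levels in
#'   increasing severity). `n0` and `n1` must be positive; an empty top
#'   category makes `tau2` infinite and is an error instructing category
#'   collapse.
#' @return Numeric `c(tau1, tau2)`, strictly increasing.
#' @examples
#' estimate_thresholds(c(470, 34, 7))
#' @export
estimate_thresholds <- function(counts) {
  if (length(counts) != 3L || any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stopf("estimate_thresholds: counts must be three non-negative integers")
  if (counts[1] == 0 || counts[2] == 0)
    stopf("estimate_thresholds: empty lower/middle category; thresholds undefined")
  if (counts[3] == 0)
    stopf("estimate_thresholds: empty top category makes tau2 infinite; collapse categories before fitting")
  n <- sum(counts)
  c(tau1 = qnorm(counts[1] / n), tau2 = qnorm((counts[1] + counts[2]) / n))
}

#' Instrument-strength F statistic for a polygenic score
#'
#' Univariate regression F statistic of the exposure on its polygenic score,
#' `F = (n - 2) r^2 / (1 - r^2)`; instruments with `F > 10` are conventionally
#' called strong.
#'
#' @param exposure,prs Numeric vectors (pairwise-complete observations used).
#' @return List with `f_stat`, `pval`, `strong` (`F > 10`), `r`, `n`.
#' @export
instrument_f_stat <- function(exposure, prs) {
  ok <- is.finite(exposure) & is.finite(prs)
  x <- exposure[ok]; p <- prs[ok]
  n <- length(x)
  if (n <= 2) stopf("instrument_f_stat: need more than 2 complete pairs")
  if (var(x) == 0 || var(p) == 0)
    stopf("instrument_f_stat: zero variance in exposure or PRS")
  r <- cor(x, p)
  f <- (n - 2) * r^2 / (1 - r^2)
  list(f_stat = f, pval = pf(f, 1, n - 2, lower.tail = FALSE),
       strong = f > 10, r = r, n = n)
}

#' @export
print.mrdoc_fit <- function(x, ...) {
  cat(sprintf("%s model (%s outcome), covE fixed at %g\n",
              if (x$model == "mrdoc") "MR-DoC" else "Hybrid DoC",
              x$outcome_type, x$covE))
  cat(sprintf("  %d MZ / %d DZ pairs, loglik %.3f, %s\n", x$n_mz, x$n_dz,
              x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$thresholds))
    cat(sprintf("  thresholds: %.4f, %.4f (fixed)\n",
                x$thresholds[1], x$thresholds[2]))
  est <- x$estimates
  est[2:5] <- lapply(est[2:5], function(z) signif(z, 4))
  print(est, row.names = FALSE)
  if (!x$se_ok) cat("  [SEs unreliable: information matrix not positive definite]\n")
  invisible(x)
}

#' @export
coef.mrdoc_fit <- function(object, ...) {
  setNames(object$estimates$estimate, object$estimates$param)
}

#' @export
logLik.mrdoc_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$free), class = "logLik")
}

#' @export
vcov.mrdoc_fit <- function(object, ...) object$vcov
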