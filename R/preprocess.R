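#' log10(x + 1) transform for zero-inflated checklist scores
#'
#' Child Behavior Checklist scores are zero-inflated counts; adding 1 keeps
#' zeros at zero and the base-10 log reduces right skew. Strictly monotone.
#'
#' @param scores Numeric vector of non-negative scores (NA passed through).
#' @return `log10(scores + 1)`.
#' @examples
#' log_transform_cbcl(c(0, 9, 99))  # 0 1 2
#' @export
log_transform_cbcl <- function(scores) {
  if (any(scores < 0, na.rm = TRUE))
    stopf("log_transform_cbcl: scores must be non-negative")
  log10(scores + 1)
}

#' Residualize a measure on fixed covariates and a grouped random effect
#'
#' Fits `value ~ covariates + (1 | group)` by REML and returns the response
#' minus both the fixed-effect predictions and the predicted (BLUP) group
#' intercepts — the covariate-adjustment step applied to every phenotype and
#' polygenic score before twin modeling (genetic PCs, sex and age as fixed
#' effects; acquisition site as a random intercept). With fewer than three
#' group levels (or `group = NULL`) the random effect is dropped with a
#' warning and plain least-squares residuals are returned; these are exactly
#' orthogonal to the fixed covariates and idempotent under re-residualization.
#'
#' Rows with missing covariates or group labels are dropped (their residuals
#' are `NA`, and the dropped indices are attached as attribute
#' `"dropped_rows"`). Constant covariate columns are dropped with a warning;
#' a singular fixed-effect design is an error.
#'
#' @param values Numeric response vector.
#' @param covariates Data frame or matrix of fixed covariates (numeric or
#'   factor columns), one row per element of `values`.
#' @param group Optional grouping labels (e.g. study site) for the random
#'   intercept.
#' @return Numeric vector of residuals, aligned with `values` (NA where
#'   dropped), mean approximately zero.
#' @export
residualize <- function(values, covariates, group = NULL) {
  covariates <- as.data.frame(covariates)
  n <- length(values)
  if (nrow(covariates) != n)
    stopf("residualize: covariates have %d rows for %d values",
          nrow(covariates), n)
  constant <- vapply(covariates, function(z)
    length(unique(z[!is.na(z)])) < 2L, logical(1))
  if (any(constant)) {
    warnf("residualize: dropping constant covariate column(s): %s",
          paste(names(covariates)[constant], collapse = ", "))
    covariates <- covariates[, !constant, drop = FALSE]
  }
  complete <- stats::complete.cases(covariates) & !is.na(values)
  if (!is.null(group)) complete <- complete & !is.na(group)
  dropped <- which(!complete)
  dat <- covariates[complete, , drop = FALSE]
  dat$.y <- values[complete]

  use_random <- !is.null(group) &&
    length(unique(group[complete])) >= 3L
  if (!is.null(group) && !use_random)
    warnf("residualize: %d group level(s) < 3; falling back to fixed-effects-only residualization",
          length(unique(group[complete])))

  rhs <- if (ncol(covariates)) paste(names(covariates), collapse = " + ")
    else "1"
  res <- rep(NA_real_, n)
  if (use_random) {
    dat$.g <- factor(group[complete])
    fml <- stats::as.formula(paste(".y ~", rhs, "+ (1 | .g)"))
    fit <- lme4::lmer(fml, data = dat, REML = TRUE)
    res[complete] <- resid(fit)
  } else {
    fml <- stats::as.formula(paste(".y ~", rhs))
    fit <- lm(fml, data = dat)
    if (fit$rank < ncol(stats::model.matrix(fit)))
      stopf("residualize: singular fixed-effect design")
    res[complete] <- resid(fit)
  }
  if (length(dropped))
    message("residualize: dropped ", length(dropped),
            " row(s) with missing covariates")
  attr(res, "dropped_rows") <- dropped
  res
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values `q_(i) = min_(j >= i) p_(j) * m / j`, capped at
#' 1 and returned in input order (delegates to [stats::p.adjust()] with
#' `method = "BH"` after validating the inputs). Applied across the family of
#' causal-effect tests within one analysis direction.
#'
#' @param pvals Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same order as input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1))
    stopf("bh_fdr: p-values must lie in (0, 1]")
  p.adjust(pvals, method = "BH")
}
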