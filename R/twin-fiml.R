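# Full-information maximum likelihood for twin-pair data.
#
# Families are independent; within a zygosity group all pairs share the
# model-implied covariance, so complete continuous data reduce to sufficient
# statistics (one crossproduct matrix per missingness pattern) and each
# likelihood evaluation is O(1) in the number of families. Ordinal outcomes
# are integrated per family over the threshold rectangle of the conditional
# bivariate liability distribution.

twin_var_names <- function(include_prs, n_twin = 2) {
  if (include_prs) c("prs1", "x1", "y1", "prs2", "x2", "y2")
  else c("x1", "y1", "x2", "y2")
}

# Split a wide twin table into per-zygosity missingness patterns.
# outcome_type "ordinal3": y1/y2 are category levels 0..2 handled separately;
# all other variables are continuous.
prepare_twin_data <- function(data, outcome_type = "continuous",
                              include_prs = TRUE) {
  need <- c("zyg", "x1", "x2", "y1", "y2",
            if (include_prs) c("prs1", "prs2"))
  miss <- setdiff(need, names(data))
  if (length(miss))
    stopf("twin data missing column(s): %s", paste(miss, collapse = ", "))
  if (!all(data$zyg %in% c("MZ", "DZ")))
    stopf("zyg must be 'MZ' or 'DZ'")
  vars <- twin_var_names(include_prs)
  ord_vars <- if (outcome_type == "ordinal3") c("y1", "y2") else character(0)
  cont_vars <- setdiff(vars, ord_vars)
  if (length(ord_vars)) {
    lev <- unlist(data[ord_vars])
    if (!all(is.na(lev) | lev %in% 0:2))
      stopf("ordinal outcome levels must be 0, 1 or 2")
  }
  out <- list()
  for (z in c("MZ", "DZ")) {
    d <- data[data$zyg == z, , drop = FALSE]
    if (!nrow(d)) { out[[z]] <- list(); next }
    if (z == "MZ" && include_prs) {
      # MZ co-twins share a genome, so the model-implied PRS cross-twin
      # correlation is exactly 1 and the 6-variate density is singular; the
      # MZ likelihood uses a single PRS per pair (5 variables).
      swap_in <- is.na(d$prs1) & !is.na(d$prs2)
      d$prs1[swap_in] <- d$prs2[swap_in]
      delta <- abs(d$prs1 - d$prs2)
      if (any(delta > 1e-6 * pmax(1, abs(d$prs1)), na.rm = TRUE))
        warnf("MZ pairs with differing PRS values; twin-2 PRS ignored (model fixes the MZ PRS correlation at 1)")
      d$prs2 <- NA_real_
    }
    X <- as.matrix(d[cont_vars])
    O <- if (length(ord_vars)) as.matrix(d[ord_vars]) else
      matrix(numeric(0), nrow(d), 0)
    obs <- cbind(!is.na(X), if (ncol(O)) !is.na(O))
    key <- apply(obs, 1, paste, collapse = "")
    pats <- list()
    for (k in unique(key)) {
      rows <- which(key == k)
      ci_local <- which(!is.na(X[rows[1], ]))
      oi_local <- if (ncol(O)) which(!is.na(O[rows[1], ])) else integer(0)
      ci <- match(cont_vars[ci_local], vars)
      oi <- match(ord_vars[oi_local], vars)
      Zc <- X[rows, ci_local, drop = FALSE]
      pat <- list(ci = ci, oi = oi, n = length(rows), Zc = Zc,
                  olev = O[rows, oi_local, drop = FALSE])
      if (!length(oi) && length(ci))
        pat$M <- crossprod(Zc) / pat$n
      pats[[length(pats) + 1L]] <- pat
    }
    out[[z]] <- pats
  }
  attr(out, "include_prs") <- include_prs
  attr(out, "outcome_type") <- outcome_type
  out
}

# log-likelihood of one all-continuous pattern from sufficient statistics
pattern_ll_continuous <- function(S, pat) {
  Ssub <- S[pat$ci, pat$ci, drop = FALSE]
  R <- tryCatch(chol(Ssub), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  p <- length(pat$ci)
  logdet <- 2 * sum(log(diag(R)))
  Sinv <- chol2inv(R)
  -0.5 * pat$n * (p * log(2 * pi) + logdet + sum(Sinv * pat$M))
}

# log-likelihood of a pattern with observed ordinal outcome(s): multivariate
# normal density of the continuous part times the conditional threshold
# rectangle probability of the latent liabilities.
pattern_ll_ordinal <- function(S, pat, thresholds) {
  tb <- c(-Inf, thresholds, Inf)
  n <- pat$n
  if (length(pat$ci)) {
    Scc <- S[pat$ci, pat$ci, drop = FALSE]
    R <- tryCatch(chol(Scc), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    p <- length(pat$ci)
    q <- colSums(forwardsolve(t(R), t(pat$Zc))^2)
    ll_cont <- -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(R))) + q)
    Sinv <- chol2inv(R)
    Soc <- S[pat$oi, pat$ci, drop = FALSE]
    Mcond <- pat$Zc %*% t(Soc %*% Sinv)
    Rcond <- S[pat$oi, pat$oi, drop = FALSE] - Soc %*% Sinv %*% t(Soc)
  } else {
    ll_cont <- numeric(n)
    Mcond <- matrix(0, n, length(pat$oi))
    Rcond <- S[pat$oi, pat$oi, drop = FALSE]
  }
  if (any(diag(Rcond) <= 0)) return(NULL)
  if (length(pat$oi) == 2L) {
    sds <- sqrt(diag(Rcond))
    rho <- Rcond[1, 2] / prod(sds)
    if (!is.finite(rho) || abs(rho) >= 1) return(NULL)
    l1 <- (tb[pat$olev[, 1] + 1] - Mcond[, 1]) / sds[1]
    u1 <- (tb[pat$olev[, 1] + 2] - Mcond[, 1]) / sds[1]
    l2 <- (tb[pat$olev[, 2] + 1] - Mcond[, 2]) / sds[2]
    u2 <- (tb[pat$olev[, 2] + 2] - Mcond[, 2]) / sds[2]
    pr <- pbvn_rect(l1, u1, l2, u2, rho)
  } else {
    sd1 <- sqrt(Rcond[1, 1])
    l1 <- (tb[pat$olev[, 1] + 1] - Mcond[, 1]) / sd1
    u1 <- (tb[pat$olev[, 1] + 2] - Mcond[, 1]) / sd1
    pr <- pnorm(u1) - pnorm(l1)
  }
  sum(ll_cont) + sum(log(pmax(pr, 1e-300)))
}

# Total twin-sample log-likelihood at one parameter point; -Inf (NULL -> big
# penalty upstream) when the implied covariance is not positive definite.
# `params` must be a complete parameter list (see mrdoc_default_params).
twin_loglik_prepared <- function(params, prep, thresholds = NULL) {
  include_prs <- attr(prep, "include_prs")
  ll <- 0
  for (z in c("MZ", "DZ")) {
    pats <- prep[[z]]
    if (!length(pats)) next
    S <- implied_cov_full(params, z, include_prs)$cov
    for (pat in pats) {
      if (!length(pat$ci) && !length(pat$oi)) next
      v <- if (length(pat$oi)) pattern_ll_ordinal(S, pat, thresholds)
        else pattern_ll_continuous(S, pat)
      if (is.null(v) || !is.finite(v)) return(-Inf)
      ll <- ll + v
    }
  }
  ll
}

#' Twin-sample FIML log-likelihood
#'
#' Full-information maximum-likelihood log-likelihood of a wide twin table
#' under the MR-DoC (or PRS-free DoC) model at a given parameter point.
#' Continuous variables contribute multivariate-normal densities with
#' pairwise deletion of missing variables; a 3-level ordinal outcome
#' contributes the conditional bivariate-normal probability of the rectangle
#' between its fixed thresholds. Families are independent, so the value is
#' invariant to row order and, by model symmetry, to twin relabeling.
#'
#' @param params Named parameter list (see [mrdoc_implied_moments()]). For
#'   ordinal outcomes `e_y` is ignored and replaced by the unit-liability
#'   constraint value.
#' @param data Wide twin table with columns `zyg`, `x1`, `x2`, `y1`, `y2`
#'   and, if `include_prs`, `prs1`, `prs2`.
#' @param outcome_type `"continuous"` or `"ordinal3"`.
#' @param thresholds Length-2 increasing threshold vector (required for
#'   ordinal outcomes; see [estimate_thresholds()]).
#' @param include_prs Whether the PRS columns are part of the model.
#' @return Scalar log-likelihood (`-Inf` for inadmissible parameters).
#' @export
mrdoc_loglik <- function(params, data, outcome_type = "continuous",
                         thresholds = NULL, include_prs = TRUE) {
  if (outcome_type == "ordinal3") {
    if (is.null(thresholds) || length(thresholds) != 2L ||
        !(thresholds[1] < thresholds[2]))
      stopf("ordinal outcome requires increasing length-2 thresholds")
    ey <- solve_unit_liability_ey(params)
    if (is.na(ey)) return(-Inf)
    params <- utils::modifyList(as.list(params), list(e_y = ey))
  }
  params <- utils::modifyList(mrdoc_default_params(), as.list(params))
  prep <- prepare_twin_data(data, outcome_type, include_prs)
  twin_loglik_prepared(params, prep, thresholds)
}
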