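# Orchestration of the twin arm: one MR-DoC fit per exposure-outcome pair,
# BH-FDR across the family of causal tests, covE sensitivity curves, and
# hybrid-DoC follow-up of significant pairs.

#' Run the MR-DoC twin pipeline over a battery of trait pairs
#'
#' Fits the MR-DoC model to each supplied exposure-outcome pair, adjusts the
#' causal-path p-values by Benjamini-Hochberg FDR across the battery (the
#' family being all causal tests in one analysis direction), runs the covE
#' sensitivity grid per pair, and refits the significant pairs (adjusted
#' p below `alpha`) with the PRS-free hybrid DoC model. Per-pair
#' non-convergence is recorded and the run continues.
#'
#' @param pairs Named list; each element a list with `data` (wide twin table,
#'   see [fit_mrdoc()]) and optional `outcome_type` (default
#'   `"continuous"`).
#' @param covE_grid Strictly increasing covE grid containing 0, or `NULL` to
#'   skip the sensitivity stage (skipping is logged).
#' @param alpha BH-adjusted significance gate for the hybrid follow-up;
#'   default 0.05.
#' @param force_hybrid Fit the hybrid model for every pair regardless of
#'   significance.
#' @param starts,seed Optimizer multi-start settings passed to the fitters.
#' @return A list of class `mrdoc_report`: `results` (one row per pair:
#'   causal estimate, SE, p, BH-adjusted p, convergence), `fits`,
#'   `sensitivity` (per-pair curves or `NULL`), `hybrid` (fits for followed-up
#'   pairs), `log`.
#' @export
run_mrdoc_pipeline <- function(pairs, covE_grid = NULL, alpha = 0.05,
                               force_hybrid = FALSE, starts = 4, seed = 1) {
  stopifnot(is.list(pairs), length(pairs) > 0)
  if (is.null(names(pairs)) || any(!nzchar(names(pairs))))
    names(pairs) <- paste0("pair", seq_along(pairs))
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  fits <- lapply(names(pairs), function(nm) {
    p <- pairs[[nm]]
    tryCatch(
      fit_mrdoc(p$data, outcome_type = p$outcome_type %||% "continuous",
                starts = starts, seed = seed),
      error = function(e) {
        note("pair ", nm, ": fit failed (", conditionMessage(e), ")")
        structure(list(error = conditionMessage(e)),
                  class = "mrdoc_fit_failure")
      })
  })
  names(fits) <- names(pairs)

  g1_row <- function(f) {
    if (inherits(f, "mrdoc_fit_failure"))
      return(c(NA_real_, NA_real_, NA_real_, 0))
    i <- match("g1", f$estimates$param)
    c(f$estimates$estimate[i], f$estimates$se[i], f$estimates$pval[i],
      as.numeric(f$converged))
  }
  m <- t(vapply(fits, g1_row, numeric(4)))
  results <- data.frame(pair = names(pairs), estimate = m[, 1], se = m[, 2],
                        pval = m[, 3], converged = m[, 4] == 1,
                        stringsAsFactors = FALSE, row.names = NULL)
  ok <- is.finite(results$pval)
  results$pval_adj <- NA_real_
  if (any(ok)) results$pval_adj[ok] <- bh_fdr(results$pval[ok])
  results$significant <- !is.na(results$pval_adj) & results$pval_adj < alpha

  sensitivity <- NULL
  if (is.null(covE_grid) || !length(covE_grid)) {
    note("covE sensitivity stage skipped (empty grid)")
  } else {
    sensitivity <- lapply(names(pairs), function(nm) {
      p <- pairs[[nm]]
      tryCatch(
        cov_e_sensitivity(p$data,
                          outcome_type = p$outcome_type %||% "continuous",
                          grid = covE_grid, starts = starts, seed = seed),
        error = function(e) {
          note("pair ", nm, ": sensitivity failed (", conditionMessage(e),
               ")"); NULL
        })
    })
    names(sensitivity) <- names(pairs)
  }

  follow <- if (force_hybrid) names(pairs) else
    results$pair[results$significant]
  hybrid <- lapply(follow, function(nm) {
    p <- pairs[[nm]]
    tryCatch(
      fit_hybrid_doc(p$data, outcome_type = p$outcome_type %||% "continuous",
                     starts = starts, seed = seed),
      error = function(e) {
        note("pair ", nm, ": hybrid fit failed (", conditionMessage(e), ")")
        NULL
      })
  })
  names(hybrid) <- follow
  if (length(follow))
    note("hybrid DoC follow-up for: ", paste(follow, collapse = ", "))
  else note("no pair significant after BH adjustment; hybrid stage skipped")

  structure(list(results = results, fits = fits, sensitivity = sensitivity,
                 hybrid = hybrid, alpha = alpha, log = log),
            class = "mrdoc_report")
}

#' @export
print.mrdoc_report <- function(x, ...) {
  cat("MR-DoC twin pipeline report\n")
  res <- x$results
  res[2:4] <- lapply(res[2:4], function(z) signif(z, 4))
  res$pval_adj <- signif(res$pval_adj, 4)
  print(res, row.names = FALSE)
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}
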