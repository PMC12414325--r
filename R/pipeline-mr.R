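# End-to-end orchestration of the summary-statistics MR arm: instrument
# selection -> ambiguous-SNP exclusion -> Steiger filter -> confounder
# exclusion list -> two parallel estimation tracks (conservative instrument
# set with the classical battery; full set with data-driven cML selection).

#' Configuration for the two-sample MR pipeline
#'
#' @param exposure,outcome SNP record data frames ([read_sumstats()] layout)
#'   or file paths readable by [read_sumstats()].
#' @param confounders Optional confounder-SNP exclusion list (vector or file
#'   path; see [apply_exclusion_list()]).
#' @param p_exp_max,p_out_min Instrument-selection thresholds; defaults
#'   `5e-8` both.
#' @param methods Conservative-track estimators to run: subset of
#'   `"ivw"`, `"median"`, `"egger"`, `"presso"` (cML always runs on the full
#'   track).
#' @param n_boot Weighted-median bootstrap replicates.
#' @param presso_nsim PRESSO simulation replicates.
#' @param seed Seed used for every stochastic component.
#' @param out_dir Optional directory for TSV/JSON artifacts.
#' @return A list of class `mr_config`.
#' @export
mr_config <- function(exposure, outcome, confounders = NULL,
                      p_exp_max = 5e-8, p_out_min = 5e-8,
                      methods = c("ivw", "median", "egger", "presso"),
                      n_boot = 2000, presso_nsim = 1000, seed = 1,
                      out_dir = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  structure(as.list(environment()), class = "mr_config")
}

#' Run the two-sample MR pipeline
#'
#' Executes the full instrument-validity workflow and both estimation tracks:
#' the conservative track (ambiguity + Steiger + confounder-list filters,
#' then IVW/weighted-median/Egger with leave-one-out and PRESSO
#' sensitivity analyses) and the full track (all non-ambiguous
#' Steiger-passing SNPs with constrained-ML model averaging doing the
#' invalid-instrument selection). Reruns with the same config and seed are
#' reproducible; each stage appends to a structured log.
#'
#' @param config An [mr_config()].
#' @return A list of class `mr_report`: `ivs` (flagged instrument table),
#'   `conservative`/`full` (analysis tables), `estimates` (tidy data frame,
#'   one row per track x method), `loo`, `presso`, `cml`, `comparison`
#'   (IVW vs cML summary), `log`.
#' @export
run_mr_pipeline <- function(config) {
  stopifnot(inherits(config, "mr_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  exposure <- if (is.character(config$exposure))
    read_sumstats(config$exposure) else config$exposure
  outcome <- if (is.character(config$outcome))
    read_sumstats(config$outcome) else config$outcome

  ids <- select_instruments(exposure, outcome, config$p_exp_max,
                            config$p_out_min)
  if (!length(ids))
    stopf("mr pipeline stopped at instrument selection: no SNP passes p_exp < %g and p_out > %g",
          config$p_exp_max, config$p_out_min)
  note("selected ", length(ids), " candidate instrument(s)")

  ivs <- harmonize(exposure, outcome, ids)
  note(sum(ivs$flipped), " instrument(s) sign-flipped during harmonization; ",
       sum(ivs$ambiguous), " ambiguous (palindromic) excluded")
  ivs <- steiger_filter(ivs)
  note(sum(ivs$steiger_fail), " instrument(s) failed Steiger filtering")

  excl <- apply_exclusion_list(ivs, config$confounders %||% character(0))
  ivs <- excl$ivs
  full <- excl$full
  conservative <- excl$conservative
  note("full set: ", nrow(full), " instrument(s); conservative set: ",
       nrow(conservative), " (", length(excl$excluded),
       " confounder-associated excluded)")
  if (nrow(conservative) < 2)
    stopf("mr pipeline stopped: fewer than 2 instruments in the conservative set")

  run_safe <- function(fn) tryCatch(fn(), error = function(e) {
    note("estimator skipped: ", conditionMessage(e)); NULL
  })
  est <- list()
  if ("ivw" %in% config$methods)
    est$ivw <- run_safe(function() mr_ivw(conservative))
  if ("median" %in% config$methods)
    est$median <- run_safe(function()
      mr_weighted_median(conservative, n_boot = config$n_boot,
                         seed = config$seed))
  if ("egger" %in% config$methods)
    est$egger <- run_safe(function() mr_egger(conservative))

  loo <- if ("ivw" %in% config$methods && nrow(conservative) >= 3)
    run_safe(function() mr_leave_one_out(conservative)) else NULL
  presso <- if ("presso" %in% config$methods && nrow(conservative) >= 4)
    run_safe(function() mr_presso(conservative, n_sim = config$presso_nsim,
                                  seed = config$seed)) else NULL
  cml <- run_safe(function() mr_cml_ma(full, seed = config$seed))

  rows <- list()
  add_row <- function(track, r) {
    if (is.null(r)) return()
    d <- as.data.frame(r)
    d$track <- track
    rows[[length(rows) + 1L]] <<- d
  }
  for (r in est) add_row("conservative", r)
  if (!is.null(presso)) add_row("conservative", presso$corrected)
  if (!is.null(cml)) { add_row("full", cml$aic); add_row("full", cml$bic) }
  estimates <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(estimates)) {
    estimates <- estimates[c("track", setdiff(names(estimates), "track"))]
    rownames(estimates) <- NULL
  }

  comparison <- if (!is.null(est$ivw) && !is.null(cml)) {
    data.frame(
      method = c("IVW (conservative)", "cML MA-AIC (full)",
                 "cML MA-BIC (full)"),
      estimate = c(est$ivw$estimate, cml$aic$estimate, cml$bic$estimate),
      se = c(est$ivw$se, cml$aic$se, cml$bic$se),
      n_iv = c(est$ivw$n_iv, cml$aic$n_iv, cml$bic$n_iv))
  } else NULL
  if (!is.null(cml) && length(cml$aic$invalid_ivs))
    note("cML AIC-selected invalid instruments: ",
         paste(cml$aic$invalid_ivs, collapse = ", "),
         " (a priori excluded: ",
         paste(intersect(cml$aic$invalid_ivs, excl$excluded),
               collapse = ", "), ")")

  report <- structure(
    list(ivs = ivs, conservative = conservative, full = full,
         estimates = estimates, loo = loo, presso = presso, cml = cml,
         comparison = comparison, exclusion = excl[c("excluded", "not_found")],
         config = config, log = log),
    class = "mr_report")
  if (!is.null(config$out_dir)) write_mr_report(report, config$out_dir)
  report
}

write_mr_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_harmonized_ivs(report$ivs, file.path(dir, "harmonized_ivs.tsv"))
  if (!is.null(report$estimates))
    write.table(report$estimates, file.path(dir, "mr_estimates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$loo))
    write.table(report$loo, file.path(dir, "leave_one_out.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(seed = report$config$seed,
               p_exp_max = report$config$p_exp_max,
               p_out_min = report$config$p_out_min,
               excluded = report$exclusion$excluded,
               not_found = report$exclusion$not_found,
               log = report$log)
  jsonlite::write_json(side, file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.mr_report <- function(x, ...) {
  cat("Two-sample MR report\n")
  for (l in x$log) cat(" -", l, "\n")
  if (!is.null(x$estimates)) {
    est <- x$estimates[c("track", "method", "estimate", "se", "ci_low",
                         "ci_high", "pval", "n_iv")]
    est[3:7] <- lapply(est[3:7], function(z) signif(z, 4))
    print(est, row.names = FALSE)
  }
  invisible(x)
}
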