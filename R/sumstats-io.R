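#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- or comma-delimited file of per-SNP association summaries into
#' the canonical column layout used throughout the package: `snp_id`,
#' `effect_allele`, `other_allele`, `beta`, `se`, `pval`, and optionally
#' `eaf` (effect-allele frequency) and `n` (sample size).
#'
#' Rows whose required fields cannot be parsed (non-numeric `beta`/`se`/`pval`,
#' `se <= 0`, `pval` outside (0, 1], alleles not single A/C/G/T bases, or equal
#' alleles) are rejected with a warning naming the offending row numbers; the
#' rejected row numbers are also attached as attribute `"rejected_rows"`.
#' Duplicate SNP ids are a hard error: summary statistics are assumed to hold
#' one row per independent variant.
#'
#' @param path Path to a delimited text file with a header row. The delimiter
#'   is sniffed from the header (tab if present, otherwise comma).
#' @param column_map Named character vector mapping canonical names to the
#'   file's column names, e.g. `c(beta = "b", se = "se", pval = "p")`. Canonical
#'   names not listed are looked up verbatim.
#' @return A `data.frame` of validated SNP records, alleles uppercased, one row
#'   per SNP, in file order.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("snp_id\teffect_allele\tother_allele\tbeta\tse\tpval",
#'              "rs1\ta\tg\t0.1\t0.02\t1e-9"), f)
#' read_sumstats(f)
#' @seealso [write_sumstats()], [select_instruments()], [harmonize()]
#' @export
read_sumstats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stopf("summary-statistics file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE,
                    comment.char = "", quote = "\"")
  canonical <- c("snp_id", "effect_allele", "other_allele", "beta", "se",
                 "pval", "eaf", "n")
  required <- canonical[1:6]
  map <- setNames(canonical, canonical)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), canonical)
    if (length(bad))
      stopf("column_map names must be canonical fields; unknown: %s",
            paste(bad, collapse = ", "))
    map[names(column_map)] <- column_map
  }
  missing_req <- required[!(map[required] %in% names(raw))]
  if (length(missing_req))
    stopf("missing required column(s): %s (mapped from: %s)",
          paste(missing_req, collapse = ", "),
          paste(map[missing_req], collapse = ", "))

  out <- data.frame(
    snp_id = raw[[map["snp_id"]]],
    effect_allele = toupper(trimws(raw[[map["effect_allele"]]])),
    other_allele = toupper(trimws(raw[[map["other_allele"]]])),
    beta = suppressWarnings(as.numeric(raw[[map["beta"]]])),
    se = suppressWarnings(as.numeric(raw[[map["se"]]])),
    pval = suppressWarnings(as.numeric(raw[[map["pval"]]])),
    stringsAsFactors = FALSE
  )
  out$eaf <- if (map["eaf"] %in% names(raw))
    suppressWarnings(as.numeric(raw[[map["eaf"]]])) else NA_real_
  out$n <- if (map["n"] %in% names(raw))
    suppressWarnings(as.numeric(raw[[map["n"]]])) else NA_real_

  bases <- c("A", "C", "G", "T")
  bad_row <- !nzchar(out$snp_id) |
    !(out$effect_allele %in% bases) | !(out$other_allele %in% bases) |
    out$effect_allele == out$other_allele |
    !is.finite(out$beta) | !is.finite(out$se) | out$se <= 0 |
    !is.finite(out$pval) | out$pval <= 0 | out$pval > 1 |
    (!is.na(out$eaf) & (out$eaf < 0 | out$eaf > 1))
  rejected <- which(bad_row)
  if (length(rejected)) {
    warnf("rejected %d row(s) with unparseable or invalid fields (rows: %s)",
          length(rejected), paste(rejected, collapse = ", "))
    out <- out[!bad_row, , drop = FALSE]
    rownames(out) <- NULL
  }
  dup <- unique(out$snp_id[duplicated(out$snp_id)])
  if (length(dup))
    stopf("duplicate snp_id in %s: %s", path, paste(dup, collapse = ", "))
  attr(out, "rejected_rows") <- rejected
  out
}

#' Write summary statistics as tab-delimited text
#'
#' Inverse of [read_sumstats()]: a written file read back yields field-exact
#' records (columns in canonical order, TSV).
#'
#' @param records SNP record `data.frame` as returned by [read_sumstats()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(records, path) {
  cols <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval",
            "eaf", "n")
  keep <- intersect(cols, names(records))
  write.table(records[keep], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Select candidate genetic instruments
#'
#' A SNP qualifies as a candidate instrument when it is genome-wide
#' significantly associated with the exposure (`pval < p_exp_max`), has a
#' corresponding record in the outcome summary statistics, and is *not*
#' genome-wide significant for the outcome (`pval > p_out_min`) so that
#' instruments do not primarily proxy the outcome.
#'
#' @param exposure,outcome SNP record data frames ([read_sumstats()] layout).
#' @param p_exp_max Exposure significance gate; default `5e-8`.
#' @param p_out_min Outcome exclusion gate; default `5e-8`.
#' @return Character vector of selected SNP ids (exposure file order). Empty
#'   selection triggers a warning; downstream estimators refuse to run on an
#'   empty instrument set.
#' @export
select_instruments <- function(exposure, outcome,
                               p_exp_max = 5e-8, p_out_min = 5e-8) {
  keep <- exposure$pval < p_exp_max & exposure$snp_id %in% outcome$snp_id
  ids <- exposure$snp_id[keep]
  p_out <- outcome$pval[match(ids, outcome$snp_id)]
  ids <- ids[p_out > p_out_min]
  if (!length(ids))
    warnf("no SNPs pass instrument selection (p_exp < %g, p_out > %g)",
          p_exp_max, p_out_min)
  ids
}

#' Flag palindromic (strand-ambiguous) allele pairs
#'
#' A/T and C/G pairs read identically on both strands, so their orientation
#' across studies cannot be resolved from alleles alone; such SNPs are
#' excluded from harmonized instrument sets.
#'
#' @param effect_allele,other_allele Character vectors of single bases.
#' @return Logical vector, `TRUE` for palindromic pairs.
#' @export
flag_ambiguous <- function(effect_allele, other_allele) {
  a <- toupper(effect_allele); b <- toupper(other_allele)
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

# Harmonize one exposure/outcome record pair; returns a one-row data.frame.
harmonize_pair <- function(exp_rec, out_rec) {
  if (exp_rec$snp_id != out_rec$snp_id)
    stopf("harmonize: snp ids differ (%s vs %s)", exp_rec$snp_id,
          out_rec$snp_id)
  same <- exp_rec$effect_allele == out_rec$effect_allele &&
    exp_rec$other_allele == out_rec$other_allele
  swapped <- exp_rec$effect_allele == out_rec$other_allele &&
    exp_rec$other_allele == out_rec$effect_allele
  if (!same && !swapped)
    stopf("allele mismatch for %s: exposure %s/%s vs outcome %s/%s",
          exp_rec$snp_id, exp_rec$effect_allele, exp_rec$other_allele,
          out_rec$effect_allele, out_rec$other_allele)
  beta_out <- if (swapped) -out_rec$beta else out_rec$beta
  eaf_out <- if (swapped && !is.na(out_rec$eaf)) 1 - out_rec$eaf else
    out_rec$eaf
  data.frame(
    snp_id = exp_rec$snp_id,
    effect_allele = exp_rec$effect_allele,
    other_allele = exp_rec$other_allele,
    beta_exp = exp_rec$beta, se_exp = exp_rec$se, pval_exp = exp_rec$pval,
    eaf_exp = exp_rec$eaf, n_exp = exp_rec$n,
    beta_out = beta_out, se_out = out_rec$se, pval_out = out_rec$pval,
    eaf_out = eaf_out, n_out = out_rec$n,
    flipped = swapped,
    ambiguous = flag_ambiguous(exp_rec$effect_allele, exp_rec$other_allele),
    steiger_fail = FALSE, confounder_associated = FALSE,
    steiger_p = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns each instrument's outcome effect to the exposure's effect allele.
#' When the outcome file reports the same variant with effect and other
#' alleles swapped, the outcome beta is multiplied by -1 and its effect-allele
#' frequency replaced by `1 - eaf`; identically oriented records pass through
#' unchanged. Any other allele configuration (strand flips included) is an
#' error naming the SNP — strand inference is deliberately not attempted.
#' Palindromic pairs are flagged `ambiguous`.
#'
#' @param exposure,outcome SNP record data frames.
#' @param snp_ids SNPs to harmonize, typically from [select_instruments()];
#'   default is every shared SNP.
#' @return Harmonized instrument `data.frame` with per-SNP exposure and
#'   outcome effects, validity flags (`ambiguous`, `steiger_fail`,
#'   `confounder_associated`, all initialized except `ambiguous`), and
#'   `steiger_p` placeholder.
#' @export
harmonize <- function(exposure, outcome, snp_ids = NULL) {
  if (is.null(snp_ids))
    snp_ids <- intersect(exposure$snp_id, outcome$snp_id)
  if (!length(snp_ids)) stopf("harmonize: no SNPs to harmonize")
  rows <- lapply(snp_ids, function(id) {
    ei <- match(id, exposure$snp_id); oi <- match(id, outcome$snp_id)
    if (is.na(ei) || is.na(oi))
      stopf("harmonize: SNP %s missing from %s summary statistics", id,
            if (is.na(ei)) "exposure" else "outcome")
    harmonize_pair(exposure[ei, ], outcome[oi, ])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Steiger directionality filter
#'
#' For each instrument, the variance explained in each trait is computed from
#' the t-statistic, `r^2 = t^2 / (t^2 + n - 2)` with `t = beta/se`. An
#' instrument supports the assumed exposure-to-outcome direction only if it
#' explains strictly more variance in the exposure than in the outcome; ties
#' fail. `steiger_p` is the two-sided p of the z-test comparing the two
#' correlations after Fisher transformation. The t-based formula is used
#' (rather than an allele-frequency one) because `eaf` is optional input.
#'
#' @param ivs Harmonized instrument table from [harmonize()].
#' @return `ivs` with `steiger_fail` and `steiger_p` filled in. Instruments
#'   with missing sample size on either side are skipped with a warning
#'   (flag left `FALSE`, p left `NA`).
#' @export
steiger_filter <- function(ivs) {
  n_ok <- is.finite(ivs$n_exp) & is.finite(ivs$n_out) &
    ivs$n_exp > 2 & ivs$n_out > 2
  if (any(!n_ok))
    warnf("Steiger filter skipped for %d instrument(s) with missing sample size: %s",
          sum(!n_ok), paste(ivs$snp_id[!n_ok], collapse = ", "))
  t_exp <- ivs$beta_exp / ivs$se_exp
  t_out <- ivs$beta_out / ivs$se_out
  r2_exp <- t_exp^2 / (t_exp^2 + ivs$n_exp - 2)
  r2_out <- t_out^2 / (t_out^2 + ivs$n_out - 2)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (ivs$n_exp - 3) + 1 / (ivs$n_out - 3))
  ivs$steiger_fail[n_ok] <- !(r2_exp[n_ok] > r2_out[n_ok])
  ivs$steiger_p[n_ok] <- 2 * pnorm(-abs(z[n_ok]))
  ivs
}

#' Apply a confounder exclusion list
#'
#' Implements the conservative instrument-validity track: SNPs known to be
#' associated with potential confounders (supplied as a user file or id
#' vector, e.g. from a GWAS-catalog query) are flagged and removed from the
#' conservative instrument set. The full set (everything surviving ambiguity
#' and Steiger filtering) is retained alongside for the data-driven track.
#'
#' @param ivs Harmonized instrument table (after [steiger_filter()]).
#' @param confounders Either a character vector of SNP ids or a path to a
#'   text file with one id per line (an optional annotation column after
#'   whitespace or comma is ignored). Lines starting with `#` are skipped.
#' @return A list with elements `ivs` (flagged table), `full` (instrument
#'   table surviving ambiguity + Steiger filters), `conservative` (`full`
#'   minus listed SNPs), `excluded` (ids removed), and `not_found` (listed
#'   ids absent from the instrument set, informational only).
#' @export
apply_exclusion_list <- function(ivs, confounders) {
  if (length(confounders) == 1L && file.exists(confounders)) {
    lines <- readLines(confounders)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    confounders <- vapply(strsplit(lines, "[,[:space:]]+"), `[`, "", 1L)
  }
  confounders <- unique(as.character(confounders))
  not_found <- setdiff(confounders, ivs$snp_id)
  if (length(not_found))
    message("exclusion list: ", length(not_found),
            " SNP(s) not among instruments: ",
            paste(not_found, collapse = ", "))
  ivs$confounder_associated <- ivs$snp_id %in% confounders
  full <- ivs[!ivs$ambiguous & !ivs$steiger_fail, , drop = FALSE]
  conservative <- full[!full$confounder_associated, , drop = FALSE]
  list(ivs = ivs, full = full, conservative = conservative,
       excluded = intersect(confounders, full$snp_id),
       not_found = not_found)
}

#' Instruments included in analysis
#'
#' An instrument enters an analysis set iff all validity flags are `FALSE`
#' (conservative track) or all flags except `confounder_associated` are
#' `FALSE` (full track used by data-driven invalid-IV selection).
#'
#' @param ivs Flagged harmonized instrument table.
#' @param track `"conservative"` or `"full"`.
#' @return Subset of `ivs`.
#' @export
iv_analysis_set <- function(ivs, track = c("conservative", "full")) {
  track <- match.arg(track)
  keep <- !ivs$ambiguous & !ivs$steiger_fail
  if (track == "conservative") keep <- keep & !ivs$confounder_associated
  ivs[keep, , drop = FALSE]
}

#' Write / read a harmonized instrument table
#'
#' TSV round-trip of the harmonized instrument table including all flags and
#' `steiger_p`.
#'
#' @param ivs Harmonized instrument table.
#' @param path File path.
#' @return `path` invisibly; `read_harmonized_ivs` returns the table.
#' @export
write_harmonized_ivs <- function(ivs, path) {
  write.table(ivs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_harmonized_ivs
#' @export
read_harmonized_ivs <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
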