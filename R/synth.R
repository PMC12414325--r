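# Seeded synthetic-data generators with known ground truth for both analysis
# arms. Defaults emulate the study conditions: an 18-instrument landscape
# with 7 pleiotropic (confounder-driven) instruments for the summary
# statistics arm, and 199 MZ / 257 DZ pairs with 92/6.7/1.4% ordinal outcome
# prevalences for the twin arm.

#' Scenario for synthetic GWAS summary statistics
#'
#' Bundles the generating parameters of the two-sample MR test harness:
#' `J` independent SNPs with per-SNP exposure variance explained `h2_snp`,
#' a true causal effect `theta`, `n_invalid` pleiotropic instruments whose
#' direct outcome effects are drawn from
#' `N(pleiotropy_mean, pleiotropy_sd)` (directional by default, the
#' generative signature of confounder-associated instruments), GWAS sample
#' sizes implying the estimation-error scale, and an optional
#' exposure-outcome estimation-error correlation `overlap_rho` emulating
#' participant overlap between the two GWAS samples.
#'
#' @param J Number of independent SNPs; default 18.
#' @param theta True causal effect; default -0.15.
#' @param n_exp,n_out Exposure and outcome GWAS sample sizes; defaults
#'   32488 and 167500 (the latter the effective sample size of a
#'   case-control outcome GWAS with roughly 44k cases and 915k controls,
#'   `4 / (1/n_case + 1/n_control)`).
#' @param maf_range Minor-allele frequency range, in (0, 0.5].
#' @param h2_snp Variance in the exposure explained per SNP; default 0.002
#'   (comfortably genome-wide significant at `n_exp`, as a selected
#'   instrument must be).
#' @param n_invalid Number of pleiotropic (invalid) instruments; default 7.
#' @param pleiotropy_mean,pleiotropy_sd Direct-effect distribution of the
#'   invalid instruments; defaults 0.02 and 0.005. The default scale is
#'   chosen to bias naive estimators visibly while keeping the total outcome
#'   effects below genome-wide significance: a candidate instrument list, by
#'   construction, only contains SNPs that survived the outcome exclusion
#'   gate.
#' @param overlap_rho Correlation of exposure/outcome estimation errors;
#'   default 0 (no sample overlap).
#' @param noise_scale Multiplier on the estimation noise (0 gives noiseless
#'   effects while keeping the reported SEs); default 1.
#' @param swap_fraction Fraction of outcome records emitted with effect and
#'   other alleles swapped (and beta negated), exercising harmonization;
#'   default 0.25.
#' @return A list of class `sumstats_scenario`.
#' @export
sumstats_scenario <- function(J = 18, theta = -0.15, n_exp = 32488,
                              n_out = 167500, maf_range = c(0.05, 0.5),
                              h2_snp = 0.002, n_invalid = 7,
                              pleiotropy_mean = 0.02, pleiotropy_sd = 0.005,
                              overlap_rho = 0, noise_scale = 1,
                              swap_fraction = 0.25) {
  stopifnot(is_count(J), n_invalid >= 0, n_invalid <= J,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            abs(overlap_rho) <= 1, noise_scale >= 0,
            swap_fraction >= 0, swap_fraction <= 1)
  structure(as.list(environment()), class = "sumstats_scenario")
}

#' Simulate two-sample GWAS summary statistics with known causal structure
#'
#' Per SNP, a true exposure effect is drawn on the per-allele scale implied
#' by `h2_snp` and the minor-allele frequency (random sign); the true outcome
#' effect is `theta * beta_exp` plus a direct pleiotropic effect for the
#' `n_invalid` planted invalid instruments. Observed effects add estimation
#' noise with the standard errors implied by sample size and allele
#' frequency, correlated across traits by `overlap_rho`. Non-palindromic
#' allele pairs are assigned; a fraction of outcome records is emitted with
#' swapped alleles (beta negated) so the harmonization step has real work.
#'
#' @param scenario A [sumstats_scenario()].
#' @param seed RNG seed; identical seeds give identical output.
#' @return List with `exposure` and `outcome` SNP record data frames (the
#'   [read_sumstats()] layout) and `truth` (true `theta`, invalid SNP ids,
#'   per-SNP true effects, the scenario).
#' @export
simulate_sumstats <- function(scenario = sumstats_scenario(), seed = 1) {
  sc <- scenario
  with_seed(seed, {
    J <- sc$J
    snp <- sprintf("rs%06d", sample.int(999999, J))
    maf <- runif(J, sc$maf_range[1], sc$maf_range[2])
    v <- 2 * maf * (1 - maf)            # per-allele genotype variance
    # effect allele oriented as the exposure-increasing allele, as in a
    # top-hits instrument list; pleiotropy with nonzero mean is then
    # directional (the generative signature of confounded instruments)
    beta_exp_true <- sqrt(sc$h2_snp / v)
    invalid <- sort(sample.int(J, sc$n_invalid))
    alpha <- numeric(J)
    if (sc$n_invalid > 0)
      alpha[invalid] <- rnorm(sc$n_invalid, sc$pleiotropy_mean,
                              sc$pleiotropy_sd)
    beta_out_true <- sc$theta * beta_exp_true + alpha
    se_exp <- sqrt(1 / (v * sc$n_exp))
    se_out <- sqrt(1 / (v * sc$n_out))
    z1 <- rnorm(J); z2 <- rnorm(J)
    e_exp <- z1 * se_exp
    e_out <- (sc$overlap_rho * z1 + sqrt(1 - sc$overlap_rho^2) * z2) * se_out
    beta_exp <- beta_exp_true + sc$noise_scale * e_exp
    beta_out <- beta_out_true + sc$noise_scale * e_out

    # non-palindromic allele pairs
    pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                   c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
    pick <- sample.int(nrow(pairs), J, TRUE)
    ea <- pairs[pick, 1]; oa <- pairs[pick, 2]

    exposure <- data.frame(
      snp_id = snp, effect_allele = ea, other_allele = oa,
      beta = beta_exp, se = se_exp,
      pval = 2 * pnorm(-abs(beta_exp / se_exp)),
      eaf = maf, n = sc$n_exp, stringsAsFactors = FALSE)
    swap <- runif(J) < sc$swap_fraction
    outcome <- data.frame(
      snp_id = snp,
      effect_allele = ifelse(swap, oa, ea),
      other_allele = ifelse(swap, ea, oa),
      beta = ifelse(swap, -beta_out, beta_out), se = se_out,
      pval = 2 * pnorm(-abs(beta_out / se_out)),
      eaf = ifelse(swap, 1 - maf, maf), n = sc$n_out,
      stringsAsFactors = FALSE)
    list(exposure = exposure, outcome = outcome,
         truth = list(theta = sc$theta, invalid = snp[invalid],
                      beta_exp_true = setNames(beta_exp_true, snp),
                      beta_out_true = setNames(beta_out_true, snp),
                      swapped = snp[swap], scenario = sc))
  })
}

#' Scenario for synthetic twin-pair data
#'
#' Generating parameters of the MR-DoC test harness: MZ/DZ pair counts, the
#' causal path `g1`, instrument path `b1`, pleiotropy path `b2`, fixed
#' unique-environment confounding `covE`, ACE variance shares for each
#' trait's residual, optional A/C cross-trait correlations, and the outcome
#' type (3-level ordinal outcomes are cut at `thresholds`, by default the
#' quantiles of `prevalences`). Both traits are standardized to unit
#' population variance: the exposure's ACE shares apply to `1 - b1^2`, and
#' the outcome's residual paths are rescaled so its total liability variance
#' is exactly 1 (an error if the structural paths alone exceed it).
#'
#' @param n_mz,n_dz Twin-pair counts; defaults 199 and 257.
#' @param g1 Causal path exposure to outcome; default 0.3.
#' @param b1 PRS-to-exposure path; default 0.3.
#' @param b2 PRS-to-outcome (horizontal pleiotropy) path; default 0.
#' @param covE Unique-environment exposure-outcome covariance; default 0.
#' @param ace_x,ace_y Length-3 ACE shares (summing to 1) of each trait's
#'   residual variance.
#' @param ra_xy,rc_xy A/C cross-trait correlations (familial confounding);
#'   default 0.
#' @param outcome_type `"continuous"` or `"ordinal3"`.
#' @param prevalences Target category prevalences for the ordinal outcome;
#'   default `c(470, 34, 7)/511`.
#' @param thresholds Optional explicit thresholds overriding `prevalences`.
#' @return A list of class `twin_scenario` carrying both the shares and the
#'   derived path coefficients.
#' @export
twin_scenario <- function(n_mz = 199, n_dz = 257, g1 = 0.3, b1 = 0.3,
                          b2 = 0, covE = 0,
                          ace_x = c(0.5, 0.2, 0.3),
                          ace_y = c(0.4, 0.2, 0.4),
                          ra_xy = 0, rc_xy = 0,
                          outcome_type = c("continuous", "ordinal3"),
                          prevalences = c(470, 34, 7) / 511,
                          thresholds = NULL) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(is_count(n_mz), is_count(n_dz),
            length(ace_x) == 3, length(ace_y) == 3,
            all(ace_x >= 0), all(ace_y >= 0),
            abs(sum(ace_x) - 1) < 1e-8, abs(sum(ace_y) - 1) < 1e-8,
            abs(ra_xy) <= 1, abs(rc_xy) <= 1)
  vx <- 1 - b1^2
  if (vx <= 0) stopf("twin_scenario: |b1| must be < 1 for unit exposure variance")
  a_x <- sqrt(ace_x[1] * vx); c_x <- sqrt(ace_x[2] * vx)
  e_x <- sqrt(ace_x[3] * vx)
  # outcome residual scale lambda solving unit total variance; the cross
  # terms make this quadratic when A/C cross-correlations are present
  kappa <- g1 * (ra_xy * a_x * sqrt(ace_y[1]) + rc_xy * c_x * sqrt(ace_y[2]))
  const <- g1^2 + b2^2 + 2 * g1 * b1 * b2 + 2 * g1 * covE - 1
  disc <- kappa^2 - const
  if (disc <= 0)
    stopf("twin_scenario: structural paths leave no residual outcome variance")
  lambda <- -kappa + sqrt(disc)
  a_y <- lambda * sqrt(ace_y[1]); c_y <- lambda * sqrt(ace_y[2])
  e_y <- lambda * sqrt(ace_y[3])
  if (outcome_type == "ordinal3" && is.null(thresholds)) {
    stopifnot(length(prevalences) == 3, all(prevalences > 0),
              abs(sum(prevalences) - 1) < 1e-8)
    thresholds <- qnorm(cumsum(prevalences)[1:2])
  }
  params <- list(g1 = g1, g2 = 0, b1 = b1, b2 = b2,
                 a_x = a_x, c_x = c_x, e_x = e_x,
                 a_y = a_y, c_y = c_y, e_y = e_y,
                 ra_xy = ra_xy, rc_xy = rc_xy, covE = covE)
  structure(list(n_mz = n_mz, n_dz = n_dz, params = params,
                 ace_x = ace_x, ace_y = ace_y,
                 outcome_type = outcome_type, thresholds = thresholds),
            class = "twin_scenario")
}

# Draw one zygosity group from the generating path equations. Latent A and C
# vectors per trait pair are built from family-common and twin-unique parts
# so the cross-twin correlation is exactly rA (A) and 1 (C).
simulate_twin_group <- function(n, zygosity, p) {
  rA <- if (zygosity == "MZ") 1 else 0.5
  rP <- rA
  # cross-trait covariance matrices of (comp_x, comp_y)
  chol2 <- function(s11, s22, r) {
    # upper-triangular factor of [[s11^2, r s11 s22], [., s22^2]]; valid for
    # zero path coefficients where chol() would reject the singular matrix
    if (abs(r) > 1) stopf("simulate_twins: invalid component correlation")
    matrix(c(s11, 0, r * s22, s22 * sqrt(1 - r^2)), 2)
  }
  draw2 <- function(R) matrix(rnorm(2 * n), n) %*% R
  r_e <- if (p$covE == 0) 0 else p$covE / (p$e_x * p$e_y)
  RA <- chol2(p$a_x, p$a_y, p$ra_xy)
  RC <- chol2(p$c_x, p$c_y, p$rc_xy)
  RE <- chol2(p$e_x, p$e_y, r_e)
  Acom <- draw2(RA); A1 <- draw2(RA); A2 <- draw2(RA)
  A_t1 <- sqrt(rA) * Acom + sqrt(1 - rA) * A1
  A_t2 <- sqrt(rA) * Acom + sqrt(1 - rA) * A2
  Ccom <- draw2(RC)                      # shared environment: one draw per family
  E1 <- draw2(RE); E2 <- draw2(RE)
  Pcom <- rnorm(n)
  P1 <- sqrt(rP) * Pcom + sqrt(1 - rP) * rnorm(n)
  P2 <- sqrt(rP) * Pcom + sqrt(1 - rP) * rnorm(n)
  make_xy <- function(P, A, E) {
    X <- p$b1 * P + A[, 1] + Ccom[, 1] + E[, 1]
    Y <- p$g1 * X + p$b2 * P + A[, 2] + Ccom[, 2] + E[, 2]
    cbind(X, Y)
  }
  xy1 <- make_xy(P1, A_t1, E1)
  xy2 <- make_xy(P2, A_t2, E2)
  data.frame(zyg = zygosity, prs1 = P1, x1 = xy1[, 1], y1 = xy1[, 2],
             prs2 = P2, x2 = xy2[, 1], y2 = xy2[, 2],
             stringsAsFactors = FALSE)
}

#' Simulate MZ/DZ twin pairs from the MR-DoC generating model
#'
#' Draws additive-genetic, shared- and unique-environment components with the
#' zygosity-specific cross-twin correlation structure (A: 1/0.5, C: 1, E: 0;
#' PRS: 1/0.5) and constructs exposure and outcome by the same path equations
#' whose implied moments [mrdoc_implied_moments()] returns — the generator
#' and the model are cross-module oracles for each other. Ordinal outcomes
#' are the latent liability cut at the scenario thresholds.
#'
#' @param scenario A [twin_scenario()].
#' @param seed RNG seed; identical seeds give identical output.
#' @return List with `data` (wide twin table: `famid`, `zyg`, `prs1`, `x1`,
#'   `y1`, `prs2`, `x2`, `y2`) and `truth` (generating parameter list,
#'   thresholds, scenario).
#' @export
simulate_twins <- function(scenario = twin_scenario(), seed = 1) {
  sc <- scenario
  with_seed(seed, {
    mz <- simulate_twin_group(sc$n_mz, "MZ", sc$params)
    dz <- simulate_twin_group(sc$n_dz, "DZ", sc$params)
    dat <- rbind(mz, dz)
    dat <- cbind(famid = sprintf("fam%05d", seq_len(nrow(dat))), dat,
                 stringsAsFactors = FALSE)
    if (sc$outcome_type == "ordinal3") {
      cut3 <- function(y) findInterval(y, sc$thresholds)
      dat$y1 <- cut3(dat$y1); dat$y2 <- cut3(dat$y2)
    }
    list(data = dat,
         truth = list(params = sc$params, thresholds = sc$thresholds,
                      scenario = sc))
  })
}
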