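# Model-implied moments for the MR-DoC / direction-of-causation twin SEM.
#
# Structural equations per twin t:
#   X_t = g2 * Y_t + b1 * PRS_t + A_x + C_x + E_x
#   Y_t = g1 * X_t + b2 * PRS_t + A_y + C_y + E_y
# Additive-genetic components correlate 1 (MZ) / 0.5 (DZ) across twins,
# shared-environment 1, unique-environment 0; the PRS (variance 1) correlates
# 1 (MZ) / 0.5 (DZ) across twins. Within a person, cov(E_x, E_y) is the fixed
# covE; A- and C-cross-trait correlations ra_xy, rc_xy model familial
# confounding.

# Canonical full parameter list; fit code fills the free subset.
mrdoc_default_params <- function() {
  list(g1 = 0, g2 = 0, b1 = 0, b2 = 0,
       a_x = sqrt(1 / 3), c_x = sqrt(1 / 3), e_x = sqrt(1 / 3),
       a_y = sqrt(1 / 3), c_y = sqrt(1 / 3), e_y = sqrt(1 / 3),
       ra_xy = 0, rc_xy = 0, covE = 0)
}

#' Model-implied mean and covariance of a twin pair
#'
#' Assembles the expected covariance matrix over
#' `(PRS1, X1, Y1, PRS2, X2, Y2)` (or `(X1, Y1, X2, Y2)` without the
#' polygenic score) implied by the MR-DoC path parameters for one zygosity
#' group. Means are zero: observed variables are residualized and
#' standardized upstream.
#'
#' @param params Named list with elements `g1` (causal path X to Y), `g2`
#'   (reverse path, 0 in MR-DoC), `b1` (PRS to X), `b2` (PRS to Y, horizontal
#'   pleiotropy), ACE path coefficients `a_x, c_x, e_x, a_y, c_y, e_y`,
#'   cross-trait correlations `ra_xy, rc_xy`, and the fixed
#'   unique-environment covariance `covE`. Missing elements default to
#'   independence values.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param include_prs Include the PRS rows/columns (FALSE for the PRS-free
#'   hybrid DoC model).
#' @return List with `mean` (zero vector) and `cov` (symmetric matrix with
#'   dimnames).
#' @export
mrdoc_implied_moments <- function(params, zygosity = c("MZ", "DZ"),
                                  include_prs = TRUE) {
  zygosity <- match.arg(zygosity)
  p <- utils::modifyList(mrdoc_default_params(), as.list(params))
  m <- implied_cov_full(p, zygosity, include_prs)
  nm <- twin_var_names(include_prs)
  dimnames(m$cov) <- list(nm, nm)
  m$mean <- setNames(m$mean, nm)
  m
}

# Fast internal version: `p` must be a complete parameter list. Assembled
# with scalar arithmetic (no small-matrix products) because it sits inside
# the optimizer's hot loop.
implied_cov_full <- function(p, zygosity, include_prs) {
  rA <- if (zygosity == "MZ") 1 else 0.5
  rP <- rA

  ca <- p$ra_xy * p$a_x * p$a_y
  cc <- p$rc_xy * p$c_x * p$c_y
  # residual (A+C+E) covariance, within-twin and cross-twin
  uw11 <- p$a_x^2 + p$c_x^2 + p$e_x^2
  uw12 <- ca + cc + p$covE
  uw22 <- p$a_y^2 + p$c_y^2 + p$e_y^2
  ub11 <- rA * p$a_x^2 + p$c_x^2
  ub12 <- rA * ca + cc
  ub22 <- rA * p$a_y^2 + p$c_y^2

  det_ib <- 1 - p$g1 * p$g2   # [X;Y] = B [X;Y] + Gamma P + u
  if (abs(det_ib) < 1e-12)
    stopf("implied_moments: reciprocal paths g1*g2 = 1; model degenerate")
  g1 <- p$g1; g2 <- p$g2; b1 <- p$b1; b2 <- p$b2
  d2 <- det_ib^2
  # quadratic form W M W' for symmetric 2x2 M, W = [[1,g2],[g1,1]]/det
  quad <- function(m11, m12, m22) c(
    (m11 + 2 * g2 * m12 + g2^2 * m22) / d2,
    (g1 * m11 + (1 + g1 * g2) * m12 + g2 * m22) / d2,
    (g1^2 * m11 + 2 * g1 * m12 + m22) / d2)
  V <- quad(b1^2 + uw11, b1 * b2 + uw12, b2^2 + uw22)
  Cc <- quad(rP * b1^2 + ub11, rP * b1 * b2 + ub12, rP * b2^2 + ub22)
  wg1 <- (b1 + g2 * b2) / det_ib     # cov(X, own PRS)
  wg2 <- (g1 * b1 + b2) / det_ib     # cov(Y, own PRS)

  if (include_prs) {
    S <- matrix(c(
      1,        wg1,   wg2,   rP,       rP * wg1, rP * wg2,
      wg1,      V[1],  V[2],  rP * wg1, Cc[1],    Cc[2],
      wg2,      V[2],  V[3],  rP * wg2, Cc[2],    Cc[3],
      rP,       rP * wg1, rP * wg2, 1,  wg1,      wg2,
      rP * wg1, Cc[1], Cc[2], wg1,      V[1],     V[2],
      rP * wg2, Cc[2], Cc[3], wg2,      V[2],     V[3]), 6, 6)
  } else {
    S <- matrix(c(
      V[1],  V[2],  Cc[1], Cc[2],
      V[2],  V[3],  Cc[2], Cc[3],
      Cc[1], Cc[2], V[1],  V[2],
      Cc[2], Cc[3], V[2],  V[3]), 4, 4)
  }
  list(mean = numeric(nrow(S)), cov = S)
}

# Unique-environment path for Y that pins the implied liability variance of
# the ordinal outcome at 1 (identification of the threshold scale). Because
# e_y enters Var(Y) only through W[2,2]^2 * e_y^2, the constraint is linear
# in e_y^2. Returns NA when the remaining paths already exceed unit variance.
solve_unit_liability_ey <- function(params) {
  p <- utils::modifyList(mrdoc_default_params(), as.list(params))
  solve_ey_full(p)
}

solve_ey_full <- function(p) {
  p$e_y <- 0
  m <- implied_cov_full(p, "MZ", include_prs = TRUE)
  var_y0 <- m$cov[3, 3]
  w22 <- 1 / (1 - p$g1 * p$g2)
  ey2 <- (1 - var_y0) / w22^2
  if (!is.finite(ey2) || ey2 <= 0) return(NA_real_)
  sqrt(ey2)
}
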