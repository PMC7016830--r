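#' Biologically effective dose of a fractionation scheme
#'
#' Linear-quadratic BED of a total dose delivered in `n_fractions` equal
#' fractions: `BED = D * (1 + (D / n_fractions) / alpha_beta)`.  Applied
#' directly to RBE-weighted totals; no RBE-vs-dose coupling is modelled.
#'
#' @param total_dose total dose, Gy(RBE), `>= 0` (vectorised).
#' @param n_fractions number of fractions, integer `>= 1`.
#' @param alpha_beta alpha/beta ratio in Gy, > 0.  Default 3.9, the value
#'   used for late rectal effects.
#' @return BED in Gy.
#' @export
bed <- function(total_dose, n_fractions, alpha_beta = 3.9) {
  if (any(!is.finite(total_dose)) || any(total_dose < 0))
    stop("`total_dose` must be >= 0")
  if (any(n_fractions < 1)) stop("`n_fractions` must be >= 1")
  if (any(alpha_beta <= 0)) stop("`alpha_beta` must be > 0")
  total_dose * (1 + (total_dose / n_fractions) / alpha_beta)
}

#' Isoeffective total dose under a different fractionation
#'
#' Converts a total dose from one schedule to another at equal BED: the
#' positive root of `D^2 / (nf_target * alpha_beta) + D - BED_source = 0`.
#' Converting a scheme to its own fraction number returns the input dose.
#'
#' @param total_dose source total dose, Gy(RBE) (vectorised).
#' @param from_fractions source fraction number.
#' @param to_fractions target fraction number.
#' @param alpha_beta alpha/beta ratio in Gy.
#' @return isoeffective total dose in the target schedule, Gy(RBE).
#' @examples
#' # 20-fraction rectal D_2cc threshold of 57.3 Gy(RBE) on a 16-fraction
#' # schedule (alpha/beta = 3.9 Gy):
#' equivalent_total_dose(57.3, 20, 16)  # 53.5
#' @export
equivalent_total_dose <- function(total_dose, from_fractions, to_fractions,
                                  alpha_beta = 3.9) {
  if (any(to_fractions < 1)) stop("`to_fractions` must be >= 1")
  B <- bed(total_dose, from_fractions, alpha_beta)
  k <- to_fractions * alpha_beta
  (-1 + sqrt(1 + 4 * B / k)) * k / 2
}
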