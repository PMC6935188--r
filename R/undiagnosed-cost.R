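#' Annual cost of undiagnosed FASD from service-recommendation rates
#'
#' Children whose FASD is missed are assumed to use the same services as
#' diagnosed children except for a psychiatric-care component, which they
#' receive in proportion to how often psychiatric treatment is recommended
#' in their group. With `share` the fraction of the diagnosed annual cost
#' attributable to psychiatric-influenced services,
#'
#'   `c_U = c_D * (1 - share * (1 - undiagnosed_rate / diagnosed_rate))`
#'
#' The share is a calibration constant: [calibrate_psych_share()] solves it
#' so that the base-case recommendation rates (55.6% diagnosed, 33.0%
#' undiagnosed) reproduce the published pre-inflation undiagnosed cost of
#' $2713 from the diagnosed cost of $3426.
#'
#' @param c_diag_annual Annual cost of diagnosed FASD (pre-inflation basis
#'   in the base case).
#' @param diagnosed_psych_rate,undiagnosed_psych_rate Proportions of each
#'   group recommended psychiatric care, in (0, 1].
#' @param psych_cost_share Fraction of `c_diag_annual` attributable to
#'   psychiatric-influenced services, in \[0, 1\].
#' @return The annual undiagnosed-FASD cost on the same basis as
#'   `c_diag_annual`.
#' @examples
#' undiagnosed_annual_cost(3426, 0.556, 0.330) # 2713
#' @export
undiagnosed_annual_cost <- function(c_diag_annual,
                                    diagnosed_psych_rate = 0.556,
                                    undiagnosed_psych_rate = 0.330,
                                    psych_cost_share = calibrate_psych_share()) {
  if (c_diag_annual < 0) stop("'c_diag_annual' must be >= 0")
  if (diagnosed_psych_rate <= 0 || diagnosed_psych_rate > 1) {
    stop("'diagnosed_psych_rate' must be in (0, 1]")
  }
  if (undiagnosed_psych_rate <= 0 || undiagnosed_psych_rate > 1) {
    stop("'undiagnosed_psych_rate' must be in (0, 1]")
  }
  stop_unless_prob(psych_cost_share, "psych_cost_share")
  c_diag_annual *
    (1 - psych_cost_share * (1 - undiagnosed_psych_rate / diagnosed_psych_rate))
}

#' Calibrate the psychiatric cost share
#'
#' Back-solves the `psych_cost_share` of [undiagnosed_annual_cost()] so the
#' anchor inputs reproduce the anchor undiagnosed cost.
#'
#' @param c_diag_annual,c_undiag_annual Anchor annual costs (defaults: the
#'   published pre-inflation $3426 and $2713).
#' @param diagnosed_psych_rate,undiagnosed_psych_rate Anchor recommendation
#'   rates.
#' @return The calibrated share (about 0.512 at the defaults).
#' @export
calibrate_psych_share <- function(c_diag_annual = 3426,
                                  c_undiag_annual = 2713,
                                  diagnosed_psych_rate = 0.556,
                                  undiagnosed_psych_rate = 0.330) {
  if (undiagnosed_psych_rate >= diagnosed_psych_rate) {
    stop("calibration requires undiagnosed_psych_rate < diagnosed_psych_rate")
  }
  share <- (1 - c_undiag_annual / c_diag_annual) /
    (1 - undiagnosed_psych_rate / diagnosed_psych_rate)
  stop_unless_prob(share, "psych_cost_share")
  share
}
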