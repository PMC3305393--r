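# Threshold probability elicitation from dual visual-analogue-scale
# (DVAS) regret ratings.

check_dvas <- function(omission, commission) {
  if (any(!is.finite(omission)) || any(!is.finite(commission)) ||
      any(omission < 0 | omission > 100) ||
      any(commission < 0 | commission > 100)) {
    abort("DVAS ratings must be finite values in [0, 100].",
          class = "regretdca_validation")
  }
  if (any(omission == 0 & commission == 0)) {
    abort("DVAS ratings must not both be zero.",
          class = "regretdca_validation")
  }
  if (any(commission == 0)) {
    abort(paste0("degenerate preference: commission regret is 0, so the ",
                 "threshold would be 0 and hospice referral is always ",
                 "preferred."),
          class = "regretdca_degenerate_preference")
  }
  invisible(NULL)
}

#' Threshold probability from DVAS regret ratings
#'
#' Converts the two 0-100 regret ratings into the threshold probability
#' at which the decision maker is indifferent between hospice referral
#' and continued treatment:
#' `Pt = 1 / (1 + omission / commission)`,
#' where `omission` is the regret of failing to refer a patient who
#' should have been referred (the utility difference U1 - U3) and
#' `commission` the regret of an unnecessary referral (U4 - U2).
#'
#' A rating pair of (50, 25) — the patient finds a missed referral twice
#' as regrettable as an unnecessary one — yields Pt = 1/3.
#'
#' @param omission,commission Regret ratings in `[0, 100]` (vectorised).
#' @return Threshold probabilities in `(0, 1)`, full precision (round
#'   only for display).
#' @export
#' @examples
#' threshold_from_dvas(50, 25)  # 0.33 to two decimals
#' threshold_from_dvas(90, 10)  # 0.10
threshold_from_dvas <- function(omission, commission) {
  check_dvas(omission, commission)
  1 / (1 + omission / commission)
}

#' Regret ratio of omission to commission
#'
#' How many times worse the decision maker considers a missed referral
#' than an unnecessary one; equals `(1 - Pt) / Pt`.
#'
#' @inheritParams threshold_from_dvas
#' @return Positive ratios `omission / commission`.
#' @export
#' @examples
#' regret_ratio(50, 25)  # 2
regret_ratio <- function(omission, commission) {
  check_dvas(omission, commission)
  omission / commission
}

#' Harms and effects of the management strategies
#'
#' Bundles the relative risk reductions of treatment (`rrr_rx`) and
#' hospice (`rrr_hosp`), the utility losses from their harms (`h_rx`,
#' `h_hosp`, on the same 0-100 scale as the DVAS ratings), and the
#' prognostic-test harm expressed as a fraction of the omission-regret
#' scale (`h_te_norm`, i.e. Hte / (U1 - U3 + HRx - HHosp)).
#'
#' @param rrr_rx,rrr_hosp Relative risk reductions in `[0, 1)`.
#' @param h_rx,h_hosp Utility losses in `[0, 100]`.
#' @param h_te_norm Normalised test harm in `[0, 1)`.
#' @return A list of class `harms_effects`.
#' @export
#' @examples
#' harms_effects(rrr_hosp = 0.05, h_te_norm = 0.1)
harms_effects <- function(rrr_rx = 0, rrr_hosp = 0, h_rx = 0, h_hosp = 0,
                          h_te_norm = 0) {
  vals <- list(rrr_rx = rrr_rx, rrr_hosp = rrr_hosp, h_rx = h_rx,
               h_hosp = h_hosp, h_te_norm = h_te_norm)
  if (any(!vapply(vals, function(x) is.numeric(x) && length(x) == 1 &&
                    is.finite(x), logical(1)))) {
    abort("all harms/effects must be finite scalars.",
          class = "regretdca_validation")
  }
  if (rrr_rx < 0 || rrr_rx >= 1 || rrr_hosp < 0 || rrr_hosp >= 1) {
    abort("relative risk reductions must lie in [0, 1).",
          class = "regretdca_validation")
  }
  if (h_rx < 0 || h_rx > 100 || h_hosp < 0 || h_hosp > 100) {
    abort("`h_rx` and `h_hosp` must lie on the 0-100 regret scale.",
          class = "regretdca_validation")
  }
  if (h_te_norm < 0 || h_te_norm >= 1) {
    abort("`h_te_norm` must lie in [0, 1).", class = "regretdca_validation")
  }
  structure(vals, class = "harms_effects")
}

#' @export
print.harms_effects <- function(x, ...) {
  cat("<harms_effects>\n")
  cat(sprintf("  RRR treatment: %.3g   RRR hospice: %.3g\n", x$rrr_rx,
              x$rrr_hosp))
  cat(sprintf("  H treatment:   %.3g   H hospice:   %.3g   H test (norm): %.3g\n",
              x$h_rx, x$h_hosp, x$h_te_norm))
  invisible(x)
}

#' Threshold probability adjusted for harms of the strategies
#'
#' Generalises [threshold_from_dvas()] to account for utility losses due
#' to harms of treatment and of hospice:
#' `Pt = 1 / (1 + (omission + h_rx - h_hosp) / (commission - (h_rx - h_hosp)))`.
#' With `h_rx == h_hosp` this reduces exactly to the unadjusted
#' threshold.
#'
#' @inheritParams threshold_from_dvas
#' @param harms A [harms_effects()] object (only `h_rx` and `h_hosp` are
#'   used here).
#' @return Threshold probabilities in `(0, 1)`.
#' @export
#' @examples
#' threshold_with_harms(50, 25, harms_effects(h_rx = 10, h_hosp = 5))
threshold_with_harms <- function(omission, commission,
                                 harms = harms_effects()) {
  check_dvas(omission, commission)
  stopifnot(inherits(harms, "harms_effects"))
  d <- harms$h_rx - harms$h_hosp
  num <- omission + d
  den <- commission - d
  if (any(den <= 0)) {
    abort("harms dominate commission regret: (U4-U2) - (HRx-HHosp) <= 0.",
          class = c("regretdca_harms_dominate",
                    "regretdca_degenerate_preference"))
  }
  if (any(num <= 0)) {
    abort("harms dominate omission regret: (U1-U3) + (HRx-HHosp) <= 0.",
          class = c("regretdca_harms_dominate",
                    "regretdca_degenerate_preference"))
  }
  1 / (1 + num / den)
}
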