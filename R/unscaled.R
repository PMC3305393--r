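# Unscaled expected-regret forms in raw utility-difference units.
# The scaled curves divide these by the omission-regret scale
# (U1 - U3 + HRx - HHosp); keeping both forms lets each serve as an
# internal oracle for the other.

#' Expected regret in raw utility units (unscaled)
#'
#' Evaluates the expected regret of a strategy directly on the utility
#' scale of the DVAS ratings, before division by the omission-regret
#' scale `omission + h_rx - h_hosp`. For the model strategy the test
#' harm enters as a raw utility loss `h_te_raw`, and the confusion
#' fractions can be supplied either as joint counts (`counts`, with
#' `tp/n` etc.) or as conditional rates (`rates`, sensitivity-style,
#' with `tp + fn = 1` and `fp + tn = 1`) together with `prevalence` —
#' the two parameterisations are algebraically identical because
#' `prevalence * tp_cond = tp/n`.
#'
#' Dividing the returned value by `omission + h_rx - h_hosp` reproduces
#' the scaled forms ([erg_hospice_all()], [erg_treat_all()],
#' [erg_model()]) evaluated at `pt = threshold_with_harms(...)` and
#' `h_te_norm = h_te_raw / (omission + h_rx - h_hosp)`.
#'
#' @param strategy `"HospiceAll"`, `"TreatAll"` or `"UseModel"`.
#' @inheritParams threshold_from_dvas
#' @param harms A [harms_effects()] object (`h_te_norm` is ignored here;
#'   use `h_te_raw`).
#' @param prevalence Death fraction (needed for `HospiceAll`,
#'   `TreatAll`, and for `UseModel` with `rates`).
#' @param counts One row of joint confusion counts (`tp`, `fp`, `fn`,
#'   `tn`, `n`), for `UseModel`.
#' @param rates Named list/row of conditional rates `tp`, `fp`, `fn`,
#'   `tn` with `tp + fn = 1`, `fp + tn = 1`, for `UseModel`.
#' @param h_te_raw Raw utility loss of undergoing the prognostic test.
#' @return Expected regret in utility units (non-negative).
#' @export
#' @examples
#' erg_unscaled("TreatAll", 50, 25, prevalence = 0.3)  # 0.3 * 50
erg_unscaled <- function(strategy, omission, commission,
                         harms = harms_effects(), prevalence = NULL,
                         counts = NULL, rates = NULL, h_te_raw = 0) {
  strategy <- match.arg(strategy, strategy_levels())
  check_dvas(omission, commission)
  stopifnot(inherits(harms, "harms_effects"))
  d <- harms$h_rx - harms$h_hosp
  commission_scale <- commission - d  # U4 - U2 - (HRx - HHosp)
  omission_scale <- omission + d      # U1 - U3 + (HRx - HHosp)

  if (strategy == "HospiceAll") {
    stopifnot(!is.null(prevalence))
    return((1 - prevalence) * (1 - harms$rrr_hosp) * commission_scale)
  }
  if (strategy == "TreatAll") {
    stopifnot(!is.null(prevalence))
    return(prevalence * (1 - harms$rrr_rx) * omission_scale)
  }

  # UseModel: bring both parameterisations to joint fractions
  if (!is.null(counts)) {
    stopifnot(all(c("tp", "fp", "fn", "tn", "n") %in% names(counts)))
    jtp <- counts$tp / counts$n; jfp <- counts$fp / counts$n
    jfn <- counts$fn / counts$n; jtn <- counts$tn / counts$n
  } else if (!is.null(rates) && !is.null(prevalence)) {
    stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(rates)))
    jtp <- prevalence * rates$tp; jfn <- prevalence * rates$fn
    jfp <- (1 - prevalence) * rates$fp; jtn <- (1 - prevalence) * rates$tn
  } else {
    abort("UseModel needs `counts`, or `rates` plus `prevalence`.",
          class = "regretdca_validation")
  }
  bracket <- 1 - harms$rrr_hosp * (jtp + jfp) - harms$rrr_rx * (jfn + jtn)
  bracket * h_te_raw +
    (1 - harms$rrr_hosp) * jfp * commission_scale +
    (1 - harms$rrr_rx) * jfn * omission_scale
}
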