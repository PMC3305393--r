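# broom-style verbs for the package's result types

#' Tidy a decision-curve table into long form
#'
#' One row per threshold-by-strategy combination, convenient for
#' plotting and summarising with the usual grammar.
#'
#' @param x A `regret_dca` table from [decision_curves()].
#' @param ... Unused.
#' @return A tibble with columns `pt`, `strategy`, `expected_regret`,
#'   `optimal`.
#' @method tidy regret_dca
#' @export
tidy.regret_dca <- function(x, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(x), "pt", "erg_hospice_all", "erg_treat_all",
                  "erg_model", "optimal"),
    cols = dplyr::starts_with("erg_"),
    names_to = "strategy", values_to = "expected_regret"
  )
  long$strategy <- dplyr::case_match(long$strategy,
                                     "erg_hospice_all" ~ "HospiceAll",
                                     "erg_treat_all" ~ "TreatAll",
                                     "erg_model" ~ "UseModel")
  dplyr::relocate(long, "pt", "strategy", "expected_regret", "optimal")
}

#' One-row summary of a decision-curve table
#'
#' @param x A `regret_dca` table.
#' @param ... Unused.
#' @return A tibble with the cohort size, empirical prevalence, grid
#'   size, and the range and total width of the thresholds where acting
#'   on the model is optimal.
#' @method glance regret_dca
#' @export
glance.regret_dca <- function(x, ...) {
  um <- x$pt[x$optimal == "UseModel"]
  step <- if (nrow(x) > 1) x$pt[2] - x$pt[1] else NA_real_
  tibble(
    n = attr(x, "n"),
    prevalence = attr(x, "prevalence"),
    n_thresholds = nrow(x),
    usemodel_lo = if (length(um)) min(um) else NA_real_,
    usemodel_hi = if (length(um)) max(um) else NA_real_,
    usemodel_width = length(um) * step
  )
}

#' One-row summary of a synthetic cohort
#'
#' @param x A `regret_cohort` from [generate_cohort()].
#' @param ... Unused.
#' @return A tibble with the size, empirical prevalence and AUC, the
#'   calibrated logit-normal parameters and the targets.
#' @method glance regret_cohort
#' @export
glance.regret_cohort <- function(x, ...) {
  tibble(
    n = nrow(x),
    prevalence = mean(x$died),
    auc = empirical_auc(x),
    location = attr(x, "location"),
    scale = attr(x, "scale"),
    target_prevalence = attr(x, "target_prevalence"),
    target_auc = attr(x, "target_auc")
  )
}

#' Tidy a recommendation into a one-row tibble
#'
#' @param x A `hospice_recommendation` from [recommend()].
#' @param ... Unused.
#' @return A tibble with columns `pt`, `strategy_at_pt`, `death_prob`,
#'   `decision`.
#' @method tidy hospice_recommendation
#' @export
tidy.hospice_recommendation <- function(x, ...) {
  tibble(pt = x$pt, strategy_at_pt = x$strategy_at_pt,
         death_prob = x$death_prob, decision = x$decision)
}
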