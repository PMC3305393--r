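# Expected-regret decision curves for the three hospice-referral
# strategies (refer all, treat all, follow the prediction model).

check_cohort <- function(cohort) {
  cohort <- as_tibble(cohort)
  if (!all(c("p", "died") %in% names(cohort))) {
    abort("a cohort needs columns `p` and `died`.",
          class = "regretdca_validation")
  }
  if (nrow(cohort) == 0) {
    abort("empty cohort.", class = "regretdca_empty_cohort")
  }
  if (any(!is.finite(cohort$p)) || any(cohort$p < 0 | cohort$p > 1)) {
    abort("predicted probabilities `p` must be finite in [0, 1].",
          class = "regretdca_validation")
  }
  if (is.numeric(cohort$died)) {
    if (any(!cohort$died %in% c(0, 1))) {
      abort("`died` must be logical or 0/1.", class = "regretdca_validation")
    }
    cohort$died <- cohort$died == 1
  }
  if (!is.logical(cohort$died) || anyNA(cohort$died)) {
    abort("`died` must be logical or 0/1.", class = "regretdca_validation")
  }
  cohort
}

check_pt <- function(pt) {
  if (any(!is.finite(pt)) || any(pt <= 0 | pt >= 1)) {
    abort("threshold probabilities must lie strictly inside (0, 1).",
          class = "regretdca_range")
  }
  invisible(NULL)
}

#' Confusion counts of the model strategy at a threshold
#'
#' Classifies every cohort member as hospice-referred when the predicted
#' death probability satisfies `p >= pt` (the boundary is positive), and
#' tallies the counts against observed 180-day death.
#'
#' @param cohort Data frame with columns `p` (predicted death
#'   probability) and `died` (logical or 0/1).
#' @param pt Threshold probabilities in `(0, 1)` (vectorised: one output
#'   row per threshold).
#' @return Tibble with columns `pt`, `tp`, `fp`, `fn`, `tn`, `n`.
#' @export
#' @examples
#' cohort <- tibble::tibble(p = c(0.9, 0.8, 0.3, 0.1),
#'                          died = c(TRUE, FALSE, TRUE, FALSE))
#' classify_at_threshold(cohort, c(0.3, 0.5))
classify_at_threshold <- function(cohort, pt) {
  cohort <- check_cohort(cohort)
  check_pt(pt)
  n <- nrow(cohort)
  dplyr::bind_rows(lapply(pt, function(th) {
    pos <- cohort$p >= th
    tibble(
      pt = th,
      tp = sum(pos & cohort$died),
      fp = sum(pos & !cohort$died),
      fn = sum(!pos & cohort$died),
      tn = sum(!pos & !cohort$died),
      n  = n
    )
  }))
}

#' Expected regret of referring every patient to hospice
#'
#' `(1 - prevalence) * (1 - rrr_hosp) * pt / (1 - pt)`: only survivors
#' incur regret (an unnecessary referral), weighted by the regret odds
#' `pt / (1 - pt)` on the scaled regret axis and discounted by the
#' effect of hospice care.
#'
#' @param prevalence Death fraction of the population in `[0, 1]`.
#' @param pt Threshold probability in `(0, 1)` (vectorised).
#' @param rrr_hosp Relative risk reduction of hospice in `[0, 1)`.
#' @return Non-negative expected regrets on the scaled axis.
#' @export
#' @examples
#' erg_hospice_all(0.5, 0.5, rrr_hosp = 0.08)  # 0.46
erg_hospice_all <- function(prevalence, pt, rrr_hosp = 0) {
  check_pt(pt)
  (1 - prevalence) * (1 - rrr_hosp) * pt / (1 - pt)
}

#' Expected regret of continuing treatment for every patient
#'
#' `prevalence * (1 - rrr_rx)`: only patients who die within the horizon
#' incur regret (a missed referral); constant in the threshold.
#'
#' @inheritParams erg_hospice_all
#' @param rrr_rx Relative risk reduction of treatment in `[0, 1)`.
#' @return Non-negative expected regrets on the scaled axis.
#' @export
#' @examples
#' erg_treat_all(0.3, rrr_rx = 0.05)  # 0.285
erg_treat_all <- function(prevalence, rrr_rx = 0) {
  prevalence * (1 - rrr_rx)
}

#' Expected regret of acting on the prediction model
#'
#' From the confusion counts at a threshold:
#' ```
#' [1 - rrr_hosp*(tp + fp)/n - rrr_rx*(fn + tn)/n] * h_te_norm
#'   + (1 - rrr_hosp) * (fp/n) * pt/(1 - pt)
#'   + (1 - rrr_rx)  * (fn/n)
#' ```
#' False positives carry the commission regret odds, false negatives the
#' omission regret, and every tested patient carries the normalised test
#' harm (discounted by the risk reduction of the strategy they follow).
#'
#' @param counts Data frame of confusion counts with columns `tp`, `fp`,
#'   `fn`, `tn`, `n` (e.g. from [classify_at_threshold()]); may carry a
#'   `pt` column.
#' @param pt Threshold probabilities; defaults to `counts$pt`.
#' @param harms A [harms_effects()] object.
#' @return Non-negative expected regrets, one per row of `counts`.
#' @export
#' @examples
#' counts <- tibble::tibble(tp = 1, fp = 1, fn = 1, tn = 1, n = 4)
#' erg_model(counts, pt = 0.5)  # 0.5
erg_model <- function(counts, pt = NULL, harms = harms_effects()) {
  counts <- as_tibble(counts)
  stopifnot(all(c("tp", "fp", "fn", "tn", "n") %in% names(counts)),
            inherits(harms, "harms_effects"))
  pt <- pt %||% counts$pt
  if (is.null(pt)) {
    abort("supply `pt` or a `pt` column in `counts`.",
          class = "regretdca_range")
  }
  check_pt(pt)
  if (any(counts$n < 1) ||
      any(counts$tp + counts$fp + counts$fn + counts$tn != counts$n)) {
    abort("confusion counts must be non-negative and sum to `n`.",
          class = "regretdca_validation")
  }
  with(counts, {
    bracket <- 1 - harms$rrr_hosp * (tp + fp) / n -
      harms$rrr_rx * (fn + tn) / n
    bracket * harms$h_te_norm +
      (1 - harms$rrr_hosp) * (fp / n) * pt / (1 - pt) +
      (1 - harms$rrr_rx) * (fn / n)
  })
}

strategy_levels <- function() c("HospiceAll", "TreatAll", "UseModel")

# argmin with the documented tie rule: prefer the individualised strategy,
# then the status quo (UseModel > TreatAll > HospiceAll)
pick_optimal <- function(erg_hosp, erg_rx, erg_mod) {
  pref <- cbind(UseModel = erg_mod, TreatAll = erg_rx, HospiceAll = erg_hosp)
  winner <- colnames(pref)[apply(pref, 1, which.min)]
  n_ties <- sum(apply(pref, 1, function(v) sum(v == min(v)) > 1))
  if (n_ties > 0) {
    inform(paste0(n_ties, " threshold(s) had tied minimum regret; ",
                  "ties resolved UseModel > TreatAll > HospiceAll."))
  }
  winner
}

#' Expected-regret decision curves over a threshold grid
#'
#' For each threshold in `grid`, computes the expected regret of the
#' three strategies — refer everyone to hospice, continue treatment for
#' everyone, or act on the prediction model (refer when `p >= pt`) — and
#' the minimum-regret strategy. Prevalence is the cohort's empirical
#' death fraction. Ties resolve UseModel > TreatAll > HospiceAll and are
#' messaged.
#'
#' @inheritParams classify_at_threshold
#' @param grid Strictly increasing thresholds inside `(0, 1)`; default
#'   0.01 to 0.99 in steps of 0.01 (represented as `k/100` so that grid
#'   values equal two-decimal probabilities bit-for-bit, which matters
#'   for the `p >= pt` boundary).
#' @param harms A [harms_effects()] object.
#' @return A tibble of class `regret_dca` with columns `pt`,
#'   `erg_hospice_all`, `erg_treat_all`, `erg_model`, `optimal` and the
#'   confusion counts; attributes `prevalence`, `n` and `harms`.
#' @export
#' @examples
#' cohort <- generate_cohort(n = 500, seed = 7)
#' curves <- decision_curves(cohort)
#' head(curves)
decision_curves <- function(cohort, grid = (1:99) / 100,
                            harms = harms_effects()) {
  cohort <- check_cohort(cohort)
  check_pt(grid)
  if (length(grid) == 0 || is.unsorted(grid, strictly = TRUE)) {
    abort("`grid` must be strictly increasing.", class = "regretdca_range")
  }
  stopifnot(inherits(harms, "harms_effects"))
  prevalence <- mean(cohort$died)

  counts <- classify_at_threshold(cohort, grid)
  out <- dplyr::mutate(
    counts,
    erg_hospice_all = erg_hospice_all(prevalence, .data$pt,
                                      rrr_hosp = harms$rrr_hosp),
    erg_treat_all = erg_treat_all(prevalence, rrr_rx = harms$rrr_rx),
    erg_model = erg_model(counts, harms = harms),
    optimal = pick_optimal(.data$erg_hospice_all, .data$erg_treat_all,
                           .data$erg_model)
  )
  out <- dplyr::relocate(out, "pt", "erg_hospice_all", "erg_treat_all",
                         "erg_model", "optimal")
  structure(out,
            prevalence = prevalence, n = nrow(cohort), harms = harms,
            class = c("regret_dca", class(out)))
}

#' Minimum-regret strategy at a threshold
#'
#' Looks up the grid row of a decision-curve table nearest to `pt` and
#' returns its minimum-regret strategy. With the default 0.01 grid the
#' lookup error is bounded by half a grid step; exact evaluation at an
#' arbitrary threshold is available via `decision_curves(cohort, grid = pt)`.
#'
#' @param curves A `regret_dca` table from [decision_curves()].
#' @param pt A single threshold within the grid's range.
#' @return One of `"HospiceAll"`, `"TreatAll"`, `"UseModel"`.
#' @export
#' @examples
#' cohort <- generate_cohort(n = 500, seed = 7)
#' optimal_strategy_at(decision_curves(cohort), 0.4)
optimal_strategy_at <- function(curves, pt) {
  stopifnot(inherits(curves, "regret_dca"), length(pt) == 1)
  if (!is.finite(pt) || pt < min(curves$pt) || pt > max(curves$pt)) {
    abort("`pt` is outside the range of the threshold grid.",
          class = "regretdca_range")
  }
  curves$optimal[which.min(abs(curves$pt - pt))]
}

#' Read a cohort of predictions from CSV
#'
#' Expects headers `p` (predicted death probability) and `died` (0/1).
#'
#' @param path CSV file path.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path) {
  check_cohort(readr::read_csv(path, show_col_types = FALSE))
}

#' Write a decision-curve table to CSV
#'
#' Writes the columns `pt`, `erg_hospice_all`, `erg_treat_all`,
#' `erg_model`, `optimal`.
#'
#' @param curves A `regret_dca` table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  stopifnot(inherits(curves, "regret_dca"))
  readr::write_csv(
    dplyr::select(as_tibble(curves), "pt", "erg_hospice_all",
                  "erg_treat_all", "erg_model", "optimal"),
    path
  )
  invisible(path)
}
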