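# End-to-end recommendation engine: elicit the threshold, pick the
# minimum-regret strategy, consult the prognostic model when that
# strategy asks for it, and justify the decision.

#' Frequency-format restatement of a probability
#'
#' Probabilities are widely misread; restating them as natural
#' frequencies ("85 out of 100 patients ...") is the recommended way to
#' communicate risk. Rounding is half-up.
#'
#' @param p Probability in `[0, 1]`.
#' @param denominator Positive integer reference group size.
#' @return A sentence of the form
#'   `"k out of D patients with this profile are expected to die within
#'   180 days."`
#' @export
#' @examples
#' frequency_format(0.85)
#' frequency_format(0.335, 200)
frequency_format <- function(p, denominator = 100) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1),
            denominator >= 1, denominator == round(denominator))
  k <- floor(p * denominator + 0.5)  # round half up
  sprintf(paste0("%d out of %d patients with this profile are expected ",
                 "to die within 180 days."),
          as.integer(k), as.integer(denominator))
}

#' Hospice-referral recommendation for one decision maker
#'
#' Runs the full decision flow: the threshold probability is computed
#' from the DVAS ratings (harms-adjusted when `h_rx`/`h_hosp` are
#' nonzero), the minimum-regret strategy at that threshold is looked up
#' on the supplied decision curves, and — only if that strategy is to
#' act on the prediction model — the patient's death probability is
#' computed (or taken from `death_prob`) and compared against the
#' threshold with the boundary `p >= pt` referring to hospice.
#'
#' The decision is derivable without disclosing the threshold or the
#' death probability; the structured justification is attached for
#' decision makers who ask for it (`justify = FALSE` omits it).
#'
#' @inheritParams threshold_from_dvas
#' @param curves A `regret_dca` table from [decision_curves()].
#' @param harms A [harms_effects()] object.
#' @param patient Optional single patient record (data frame row) for
#'   the SUPPORT model; required (or `death_prob`) when the optimal
#'   strategy is `UseModel`.
#' @param death_prob Optional precomputed death probability, used in
#'   place of `patient`.
#' @param t Prediction horizon in days.
#' @param justify Attach the structured justification text?
#' @return A list of class `hospice_recommendation` with elements `pt`,
#'   `strategy_at_pt`, `death_prob` (`NA` unless the strategy is
#'   `UseModel`), `decision` (`"ReferToHospice"` or
#'   `"ContinueTreatment"`) and `justification`.
#' @export
#' @examples
#' cohort <- generate_cohort(n = 1000, seed = 3)
#' curves <- decision_curves(cohort)
#' recommend(71, 29, curves, death_prob = 0.85)
recommend <- function(omission, commission, curves,
                      harms = harms_effects(), patient = NULL,
                      death_prob = NULL, t = 180, justify = TRUE) {
  stopifnot(inherits(curves, "regret_dca"), inherits(harms, "harms_effects"))
  pt <- if (harms$h_rx != 0 || harms$h_hosp != 0) {
    threshold_with_harms(omission, commission, harms)
  } else {
    threshold_from_dvas(omission, commission)
  }
  strategy <- optimal_strategy_at(curves, pt)

  dp <- NA_real_
  if (strategy == "UseModel") {
    if (!is.null(death_prob)) {
      stopifnot(is.finite(death_prob), death_prob >= 0, death_prob <= 1)
      dp <- death_prob
    } else if (!is.null(patient)) {
      dp <- death_probability(patient, t = t)$death_prob
      if (length(dp) != 1) {
        abort("`patient` must be a single record.",
              class = "regretdca_validation")
      }
    } else {
      abort(paste0("missing prognostic input: the optimal strategy is to ",
                   "use the prediction model, so supply `patient` or ",
                   "`death_prob`."),
            class = "regretdca_missing_prognostic_input")
    }
    decision <- if (dp >= pt) "ReferToHospice" else "ContinueTreatment"
  } else {
    decision <- switch(strategy,
                       HospiceAll = "ReferToHospice",
                       TreatAll   = "ContinueTreatment")
  }

  rec <- structure(
    list(pt = pt, strategy_at_pt = strategy, death_prob = dp,
         decision = decision, justification = NULL),
    class = "hospice_recommendation"
  )
  if (justify) rec$justification <- justify_recommendation(rec)
  rec
}

justify_recommendation <- function(rec) {
  pt_pct <- round(100 * rec$pt)
  strategy_text <- switch(
    rec$strategy_at_pt,
    HospiceAll = paste0("At a threshold probability of ", pt_pct, "%, ",
                        "referring to hospice carries the least expected ",
                        "regret regardless of the prognostic model."),
    TreatAll = paste0("At a threshold probability of ", pt_pct, "%, ",
                      "continuing treatment carries the least expected ",
                      "regret regardless of the prognostic model."),
    UseModel = paste0("At a threshold probability of ", pt_pct, "%, ",
                      "acting on the prognostic model carries the least ",
                      "expected regret.")
  )
  list(
    pt_text = paste0("You are indifferent between hospice referral and ",
                     "continued treatment at a ", pt_pct,
                     "% probability of death within 180 days."),
    frequency_text = if (!is.na(rec$death_prob)) {
      frequency_format(rec$death_prob)
    } else {
      NA_character_
    },
    strategy_text = strategy_text
  )
}

#' @export
print.hospice_recommendation <- function(x, ...) {
  cat("<hospice_recommendation>\n")
  cat(sprintf("  threshold probability: %.0f%%\n", 100 * x$pt))
  cat("  optimal strategy:      ", x$strategy_at_pt, "\n", sep = "")
  if (!is.na(x$death_prob)) {
    cat(sprintf("  death probability:     %.0f%%\n", 100 * x$death_prob))
  }
  cat("  decision:              ", x$decision, "\n", sep = "")
  invisible(x)
}

pipeline_defaults <- function() {
  list(omission = 50, commission = 25,
       rrr_rx = 0, rrr_hosp = 0, h_rx = 0, h_hosp = 0, h_te_norm = 0,
       grid_start = 0.01, grid_stop = 0.99, grid_step = 0.01,
       n = 2000, prevalence = 0.5, target_auc = 0.79, t = 180)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    ext <- tolower(tools::file_ext(config))
    config <- switch(ext,
      json = jsonlite::fromJSON(config),
      yaml = ,
      yml  = {
        if (!requireNamespace("yaml", quietly = TRUE)) {
          abort("reading YAML configs needs the yaml package.",
                class = "regretdca_validation")
        }
        yaml::read_yaml(config)
      },
      abort(paste0("unsupported config extension `", ext, "`."),
            class = "regretdca_validation")
    )
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ",
                 paste(unknown, collapse = ", "), "."),
          class = "regretdca_validation")
  }
  utils::modifyList(defaults, as.list(config))
}

#' Run the full referral pipeline and write its artifacts
#'
#' Simulates (or loads) a prediction cohort, builds the expected-regret
#' decision curves, derives the recommendation for the configured
#' decision maker, and writes every artifact to `out_dir`: `cohort.csv`,
#' `curves.csv`, `recommendation.json` and `pipeline_log.json` (the
#' intermediate quantities: threshold, confusion counts and the three
#' regrets at the threshold's grid row, strategy, cohort provenance).
#' With a fixed `seed`, repeated runs write identical files.
#'
#' @param config A named list or a JSON/YAML file path overriding the
#'   defaults: `omission`, `commission`, `rrr_rx`, `rrr_hosp`, `h_rx`,
#'   `h_hosp`, `h_te_norm`, `grid_start`/`grid_stop`/`grid_step`, `n`,
#'   `prevalence`, `target_auc`, `t`.
#' @param out_dir Output directory (created if needed).
#' @param patient Optional single patient record (data frame or CSV/JSON
#'   path) for the SUPPORT model.
#' @param cohort Optional cohort (data frame or CSV path); when absent a
#'   synthetic cohort is generated from the config and `seed`.
#' @param seed Integer seed for cohort generation.
#' @return Invisibly, a list with the cohort, curves, recommendation and
#'   file paths.
#' @export
run_pipeline <- function(config = list(), out_dir, patient = NULL,
                         cohort = NULL, seed = 1) {
  cfg <- read_pipeline_config(config)
  harms <- harms_effects(rrr_rx = cfg$rrr_rx, rrr_hosp = cfg$rrr_hosp,
                         h_rx = cfg$h_rx, h_hosp = cfg$h_hosp,
                         h_te_norm = cfg$h_te_norm)
  if (is.character(patient)) patient <- read_patients(patient)
  if (is.character(cohort)) {
    cohort <- read_cohort(cohort)
    provenance <- "loaded from file"
  } else if (is.null(cohort)) {
    cohort <- generate_cohort(n = cfg$n, prevalence = cfg$prevalence,
                              target_auc = cfg$target_auc, seed = seed)
    provenance <- sprintf(
      "synthetic logit-normal cohort (n = %d, prevalence = %g, target AUC = %g, seed = %d)",
      cfg$n, cfg$prevalence, cfg$target_auc, seed)
  } else {
    cohort <- check_cohort(cohort)
    provenance <- "supplied in memory"
  }

  # round away seq()'s accumulation error so grid values equal plain
  # decimal thresholds bit-for-bit (the p >= pt boundary depends on it)
  grid <- round(seq(cfg$grid_start, cfg$grid_stop, by = cfg$grid_step), 10)
  curves <- decision_curves(cohort, grid = grid, harms = harms)
  rec <- recommend(cfg$omission, cfg$commission, curves, harms = harms,
                   patient = patient, t = cfg$t)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    cohort = file.path(out_dir, "cohort.csv"),
    curves = file.path(out_dir, "curves.csv"),
    recommendation = file.path(out_dir, "recommendation.json"),
    log = file.path(out_dir, "pipeline_log.json")
  )
  readr::write_csv(
    dplyr::mutate(as_tibble(cohort), died = as.integer(.data$died)),
    paths$cohort
  )
  write_curves(curves, paths$curves)

  rec_json <- list(pt = rec$pt, strategy_at_pt = rec$strategy_at_pt,
                   decision = rec$decision,
                   justification = rec$justification)
  if (!is.na(rec$death_prob)) rec_json$death_prob <- rec$death_prob
  jsonlite::write_json(rec_json, paths$recommendation, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")

  row <- which.min(abs(curves$pt - rec$pt))
  log <- list(
    cohort_provenance = provenance,
    n = nrow(cohort),
    prevalence = mean(cohort$died),
    pt = rec$pt,
    grid_row = as.list(as_tibble(curves)[row, c("pt", "tp", "fp", "fn",
                                                "tn", "n")]),
    expected_regret = as.list(as_tibble(curves)[row, c("erg_hospice_all",
                                                       "erg_treat_all",
                                                       "erg_model")]),
    strategy = rec$strategy_at_pt,
    decision = rec$decision,
    harms = unclass(harms)
  )
  jsonlite::write_json(log, paths$log, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(cohort = cohort, curves = curves, recommendation = rec,
                 paths = paths))
}
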