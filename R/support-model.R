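# SUPPORT 180-day survival model: physiology score, linear predictor,
# baseline survival and the derived probability of death.

# positive part (x)+ used by the spline terms
pos <- function(x) pmax(x, 0)

#' SUPPORT physiology score (SPS)
#'
#' Computes the SUPPORT physiology score, a spline-based aggregate of the
#' ten day-3 physiologic measures with disease-group intercepts. Variable
#' recodes are applied before any term is evaluated: white cell count is
#' raised to 9 when below 9 outside the ARF/MOSF group and capped at 40,
#' and creatinine is capped at 15. Mean blood pressure, PaO2/FiO2 and
#' albumin enter through `min()` truncations; temperature, heart rate,
#' bilirubin, creatinine and sodium enter through positive-part (linear
#' or cubic) spline terms.
#'
#' @inheritParams validate_patients
#' @param impute Passed to [validate_patients()].
#' @return The input tibble with an `sps` column appended (SPS points).
#' @export
#' @examples
#' compute_sps(example_patients())["sps"]
compute_sps <- function(patients, impute = FALSE) {
  patients <- validate_patients(patients, impute = impute)

  grp <- patients$group
  g_arf_mosf  <- as.numeric(grp %in% c("ARF", "MOSF"))
  g_copd_chf  <- as.numeric(grp %in% c("COPD", "CHF"))
  g_cirr_coma <- as.numeric(grp %in% c("Cirrhosis", "Coma"))
  g_cancer    <- as.numeric(grp %in% c("LungCancer", "ColonCancer"))

  # recodes precede every WBC/Cr term, including the ARF/MOSF block
  wbc <- patients$wbc
  wbc <- ifelse(wbc < 9 & g_arf_mosf == 0, 9, wbc)
  wbc <- pmin(wbc, 40)
  cr  <- pmin(patients$cr, 15)

  alb_t <- pmin(patients$alb, 4.6)
  temp  <- patients$temp
  hr    <- patients$hr
  bil   <- patients$bil
  na_   <- patients$na

  sps <-
    259.9 * g_arf_mosf + 263.4 * g_copd_chf +
    241.4 * g_cirr_coma + 281.5 * g_cancer -
    0.06174 * pmin(patients$pao2_fio2, 225) -
    0.6316 * pmin(patients$mean_bp, 60) +
    1.0205 * wbc - 0.3676 * pos(wbc - 8) - 0.5631 * pos(wbc - 11) +
    0.2691 * alb_t +
    0.2312 * patients$aresp -
    2.362 * temp + 1.326 * pos(temp - 36.6) + 2.473 * pos(temp - 38.3) -
    0.1579 * hr +
    9.770e-5 * pos(hr - 55)^3 - 2.189e-4 * pos(hr - 80)^3 +
    1.518e-4 * pos(hr - 110)^3 - 3.062e-5 * pos(hr - 149)^3 +
    0.9763 * bil - 0.7481 * pos(bil - 7) -
    6.8761 * cr +
    11.6058 * pos(cr - 0.600)^3 - 21.8413 * pos(cr - 1.000)^3 +
    10.3574 * pos(cr - 1.500)^3 - 0.1219 * pos(cr - 5.399)^3 -
    0.6167096 * na_ +
    0.0021118 * pos(na_ - 128)^3 - 0.0036730 * pos(na_ - 135)^3 +
    0.0006126 * pos(na_ - 139)^3 + 0.0009486 * pos(na_ - 148)^3 -
    6.278 * g_copd_chf * alb_t - 11.45 * g_cancer * alb_t +
    g_arf_mosf * (-2.3549 * wbc + 2.7494 * pos(wbc - 8) -
                    0.4638 * pos(wbc - 11))

  dplyr::mutate(patients, sps = sps)
}

#' SUPPORT survival linear predictor
#'
#' Computes the linear predictor of the SUPPORT survival model from the
#' disease-group indicators, coma score, age, cancer comorbidity, the
#' reciprocal hospital-day term, the physiology score and the two
#' age-by-group interaction brackets. Two coefficients are printed with
#' ambiguous sign in the source model description; both are applied as
#' "+" by default (a worse prognostic factor must raise the linear
#' predictor and hence lower survival) and can be flipped through the
#' `sign_*` arguments.
#'
#' @inheritParams compute_sps
#' @param sps Optional numeric vector of physiology scores; when `NULL`
#'   (and no `sps` column is present) it is computed via [compute_sps()].
#' @param sign_mosf_malig,sign_age `+1` or `-1`; signs applied to the
#'   1.1803 MOSF-with-malignancy and 0.01935 age coefficients.
#' @return The input tibble with `sps` and `xb` columns appended.
#' @export
#' @examples
#' compute_linear_predictor(example_patients())[c("group", "sps", "xb")]
compute_linear_predictor <- function(patients, sps = NULL,
                                     sign_mosf_malig = 1, sign_age = 1,
                                     impute = FALSE) {
  stopifnot(sign_mosf_malig %in% c(-1, 1), sign_age %in% c(-1, 1))
  if (is.null(sps) && "sps" %in% names(patients)) {
    patients <- validate_patients(patients, impute = impute)
  } else {
    supplied <- sps
    patients <- compute_sps(patients, impute = impute)
    if (!is.null(supplied)) patients$sps <- supplied
  }

  grp <- patients$group
  g_chf   <- as.numeric(grp == "CHF")
  g_cirr  <- as.numeric(grp == "Cirrhosis")
  g_lung  <- as.numeric(grp == "LungCancer")
  g_coma  <- as.numeric(grp == "Coma")
  g_copd_chf_cirr <- as.numeric(grp %in% c("COPD", "CHF", "Cirrhosis"))
  g_cancer <- as.numeric(grp %in% c("LungCancer", "ColonCancer"))
  malig <- as.numeric(patients$mosf_with_malignancy)
  age <- patients$age

  xb <- -3.652 + 0.8356 * g_chf + 0.9257 * g_cirr + 0.6287 * g_lung +
    sign_mosf_malig * 1.1803 * malig +
    0.01434 * patients$scoma + sign_age * 0.01935 * age +
    0.2413 * patients$cancer -
    1.863 / (patients$hday + 3.4) +
    0.08121 * patients$sps +
    age * (0.015261 * g_copd_chf_cirr + 0.009047 * g_coma -
             0.008294 * g_cancer) +
    age * (-0.012498 * g_chf - 0.004578 * g_cirr - 0.001435 * g_lung -
             0.013891 * malig)

  dplyr::mutate(patients, xb = xb)
}

#' Baseline survival table of the SUPPORT model
#'
#' The stratum-specific baseline survival probabilities tabulated at
#' days 0, 30, 60, 90, 120, 150 and 177 for the four disease strata
#' (ARF/MOSF; COPD/CHF/Cirrhosis; Coma; Lung or Colon Cancer), shipped
#' as a packaged CSV.
#'
#' @return A tibble with columns `t`, `arf_mosf`, `copd_chf_cirrhosis`,
#'   `coma`, `cancer`.
#' @export
#' @examples
#' baseline_survival_table()
baseline_survival_table <- function() {
  if (is.null(the$baseline)) {
    path <- system.file("extdata", "support_baseline_survival.csv",
                        package = "regretdca", mustWork = TRUE)
    the$baseline <- readr::read_csv(
      path,
      col_types = readr::cols(.default = readr::col_double())
    )
  }
  the$baseline
}

group_stratum <- function(group) {
  dplyr::case_match(
    group,
    c("ARF", "MOSF") ~ "arf_mosf",
    c("COPD", "CHF", "Cirrhosis") ~ "copd_chf_cirrhosis",
    "Coma" ~ "coma",
    c("LungCancer", "ColonCancer") ~ "cancer"
  )
}

#' Baseline survival probability for a disease group
#'
#' Maps the eight diagnostic groupings onto the four tabulated strata and
#' evaluates the baseline survival at time `t`: the tabulated value at
#' tabulated times, linear interpolation between adjacent tabulated
#' times, and the day-177 value for `t` in (177, 180] (the table's last
#' entry; no extrapolation below it).
#'
#' @param group Character vector of disease groups (recycled against `t`).
#' @param t Time in days, in `[0, 180]`.
#' @return Numeric vector of baseline survival probabilities.
#' @export
#' @examples
#' baseline_survival("ARF", 30)    # tabulated: 0.691
#' baseline_survival("Coma", 45)   # interpolated midpoint of 0.630, 0.609
baseline_survival <- function(group, t) {
  if (any(!group %in% support_disease_groups())) {
    abort("validation: unknown disease group.", class = "regretdca_validation")
  }
  if (any(!is.finite(t)) || any(t < 0 | t > 180)) {
    abort("`t` must lie in [0, 180] days.", class = "regretdca_range")
  }
  tab <- baseline_survival_table()
  strat <- group_stratum(group)
  t_eff <- pmin(t, max(tab$t))
  out <- numeric(length(strat))
  for (s in unique(strat)) {
    idx <- strat == s
    out[idx] <- approx(tab$t, tab[[s]], xout = t_eff[idx],
                       method = "linear", ties = "ordered")$y
  }
  out
}

#' 180-day survival probability under the SUPPORT model
#'
#' Evaluates `S_i(t) ^ exp(xb)`: the stratum baseline survival raised to
#' the exponentiated linear predictor.
#'
#' @inheritParams compute_linear_predictor
#' @param t Prediction horizon in days, in `[0, 180]` (scalar; default
#'   180, the model's horizon).
#' @return The input tibble with `sps`, `xb` and `surv_prob` appended.
#' @export
#' @examples
#' survival_probability(example_patients())[c("group", "surv_prob")]
survival_probability <- function(patients, t = 180, sps = NULL,
                                 sign_mosf_malig = 1, sign_age = 1,
                                 impute = FALSE) {
  stopifnot(length(t) == 1)
  patients <- compute_linear_predictor(
    patients, sps = sps,
    sign_mosf_malig = sign_mosf_malig, sign_age = sign_age, impute = impute
  )
  s0 <- baseline_survival(patients$group, rep(t, nrow(patients)))
  dplyr::mutate(patients, surv_prob = s0^exp(.data$xb))
}

#' Probability of death within the horizon
#'
#' The complement of [survival_probability()]; the quantity contrasted
#' with the decision maker's threshold probability.
#'
#' @inheritParams survival_probability
#' @return The input tibble with `sps`, `xb`, `surv_prob` and
#'   `death_prob` appended.
#' @export
#' @examples
#' death_probability(example_patients())[c("group", "death_prob")]
death_probability <- function(patients, t = 180, sps = NULL,
                              sign_mosf_malig = 1, sign_age = 1,
                              impute = FALSE) {
  patients <- survival_probability(
    patients, t = t, sps = sps,
    sign_mosf_malig = sign_mosf_malig, sign_age = sign_age, impute = impute
  )
  dplyr::mutate(patients, death_prob = 1 - .data$surv_prob)
}
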