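# Independent oracles and fixtures.
#
# oracle_sps()/oracle_xb() expand the SUPPORT score and linear predictor
# literally, term by scalar term, as a second implementation kept
# deliberately separate from the vectorised package code.

pp <- function(x) if (x > 0) x else 0  # scalar positive part

oracle_sps <- function(pt) {
  g <- pt$group
  in_arf_mosf <- g == "ARF" || g == "MOSF"
  in_copd_chf <- g == "COPD" || g == "CHF"
  in_cirr_coma <- g == "Cirrhosis" || g == "Coma"
  in_cancer <- g == "LungCancer" || g == "ColonCancer"

  wbc <- pt$wbc
  if (wbc < 9 && !in_arf_mosf) wbc <- 9
  if (wbc > 40) wbc <- 40
  cr <- if (pt$cr > 15) 15 else pt$cr

  terms <- c(
    259.9 * in_arf_mosf,
    263.4 * in_copd_chf,
    241.4 * in_cirr_coma,
    281.5 * in_cancer,
    -0.06174 * min(pt$pao2_fio2, 225),
    -0.6316 * min(pt$mean_bp, 60),
    1.0205 * wbc,
    -0.3676 * pp(wbc - 8),
    -0.5631 * pp(wbc - 11),
    0.2691 * min(pt$alb, 4.6),
    0.2312 * pt$aresp,
    -2.362 * pt$temp,
    1.326 * pp(pt$temp - 36.6),
    2.473 * pp(pt$temp - 38.3),
    -1.579e-1 * pt$hr,
    9.770e-5 * pp(pt$hr - 55)^3,
    -2.189e-4 * pp(pt$hr - 80)^3,
    1.518e-4 * pp(pt$hr - 110)^3,
    -3.062e-5 * pp(pt$hr - 149)^3,
    0.9763 * pt$bil,
    -0.7481 * pp(pt$bil - 7),
    -6.8761 * cr,
    11.6058 * pp(cr - 0.600)^3,
    -21.8413 * pp(cr - 1.000)^3,
    10.3574 * pp(cr - 1.500)^3,
    -0.1219 * pp(cr - 5.399)^3,
    -0.6167096 * pt$na,
    0.0021118 * pp(pt$na - 128)^3,
    -0.0036730 * pp(pt$na - 135)^3,
    0.0006126 * pp(pt$na - 139)^3,
    0.0009486 * pp(pt$na - 148)^3,
    -6.278 * in_copd_chf * min(pt$alb, 4.6),
    -11.45 * in_cancer * min(pt$alb, 4.6),
    in_arf_mosf * (-2.3549 * wbc + 2.7494 * pp(wbc - 8) -
                     0.4638 * pp(wbc - 11))
  )
  sum(terms)
}

oracle_xb <- function(pt, sps) {
  g <- pt$group
  malig <- isTRUE(pt$mosf_with_malignancy)
  terms <- c(
    -3.652,
    0.8356 * (g == "CHF"),
    0.9257 * (g == "Cirrhosis"),
    0.6287 * (g == "LungCancer"),
    1.1803 * malig,
    0.01434 * pt$scoma,
    0.01935 * pt$age,
    0.2413 * pt$cancer,
    -1.863 * (pt$hday + 3.4)^(-1),
    0.08121 * sps,
    pt$age * (0.015261 * (g %in% c("COPD", "CHF", "Cirrhosis")) +
                0.009047 * (g == "Coma") -
                0.008294 * (g %in% c("LungCancer", "ColonCancer"))),
    pt$age * (-0.012498 * (g == "CHF") - 0.004578 * (g == "Cirrhosis") -
                0.001435 * (g == "LungCancer") - 0.013891 * malig)
  )
  sum(terms)
}

# a well-behaved single patient whose fields tests perturb one at a time
base_patient <- function(...) {
  pt <- tibble::tibble(
    group = "ARF", mosf_with_malignancy = FALSE, age = 60, scoma = 0,
    hday = 2, cancer = 0, alb = 3.0, aresp = 4, bil = 1.5, cr = 1.2,
    na = 136, pao2_fio2 = 180, mean_bp = 70, wbc = 12, temp = 37.5,
    hr = 95
  )
  dots <- list(...)
  for (nm in names(dots)) pt[[nm]] <- dots[[nm]]
  pt
}

# deterministic cohort with the qualitative shape of a real prognostic
# cohort: tails deliberately miscalibrated (deaths among low-risk and
# survivors among high-risk patients are over-represented), which is
# what makes the default strategies optimal at extreme thresholds
figure4_cohort <- function() {
  mk <- function(p, n, deaths) {
    tibble::tibble(p = rep(p, n),
                   died = rep(c(TRUE, FALSE), c(deaths, n - deaths)))
  }
  mids <- seq(0.15, 0.85, by = 0.1)
  dplyr::bind_rows(
    mk(0.05, 200, 60),
    dplyr::bind_rows(lapply(mids, function(p) mk(p, 75, round(p * 75)))),
    mk(0.95, 200, 140)
  )
}

# random valid cohort for property tests
random_cohort <- function(n = 200) {
  tibble::tibble(p = stats::runif(n), died = stats::runif(n) < 0.4)
}
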