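# SUPPORT physiology score, linear predictor and survival probabilities

test_that("SPS, linear predictor and survival match the term-by-term oracle", {
  pts <- example_patients()
  scored <- survival_probability(pts)
  for (i in seq_len(nrow(pts))) {
    row <- as.list(pts[i, ])
    sps_o <- oracle_sps(row)
    xb_o <- oracle_xb(row, sps_o)
    expect_lt(abs(scored$sps[i] - sps_o), 1e-9)
    expect_lt(abs(scored$xb[i] - xb_o), 1e-9)
    s0 <- baseline_survival(row$group, 180)
    expect_lt(abs(scored$surv_prob[i] - s0^exp(xb_o)), 1e-9)
  }
})

test_that("below the first knot only the linear temperature term is active", {
  a <- compute_sps(base_patient(temp = 36.6))$sps
  b <- compute_sps(base_patient(temp = 35.6))$sps
  expect_equal(a - b, -2.362, tolerance = 1e-12)
})

test_that("WBC recode applies outside ARF/MOSF and caps apply everywhere", {
  copd <- function(w) compute_sps(base_patient(group = "COPD", wbc = w))$sps
  arf <- function(w) compute_sps(base_patient(group = "ARF", wbc = w))$sps
  expect_identical(copd(5), copd(9))   # recoded up to 9
  expect_false(isTRUE(all.equal(arf(5), arf(9))))  # no recode in ARF/MOSF
  expect_identical(copd(50), copd(40)) # cap at 40
  expect_identical(arf(50), arf(40))
  cr <- function(x) compute_sps(base_patient(cr = x))$sps
  expect_identical(cr(20), cr(15))     # creatinine cap
})

test_that("every spline term is continuous at its knot", {
  knots <- list(
    wbc = c(8, 9, 11, 40), temp = c(36.6, 38.3), hr = c(55, 80, 110, 149),
    bil = 7, cr = c(0.6, 1, 1.5, 5.399, 15), na = c(128, 135, 139, 148),
    alb = 4.6, pao2_fio2 = 225, mean_bp = 60
  )
  for (var in names(knots)) {
    for (k in knots[[var]]) {
      lo <- base_patient(); lo[[var]] <- k - 1e-9
      hi <- base_patient(); hi[[var]] <- k + 1e-9
      expect_lt(abs(compute_sps(hi)$sps - compute_sps(lo)$sps), 1e-6,
                label = paste0("jump in sps at ", var, " = ", k))
    }
  }
})

test_that("the linear predictor responds as printed to its inputs", {
  pt <- base_patient()
  s0 <- compute_sps(pt)$sps
  xb0 <- compute_linear_predictor(pt, sps = s0)$xb
  # one extra SPS point adds exactly its coefficient
  expect_equal(compute_linear_predictor(pt, sps = s0 + 1)$xb - xb0,
               0.08121, tolerance = 1e-12)
  # reciprocal hospital-day term
  xb_h1 <- compute_linear_predictor(base_patient(hday = 1))$xb
  xb_h2 <- compute_linear_predictor(base_patient(hday = 2))$xb
  expect_equal(xb_h1 - xb_h2, -1.863 / 4.4 + 1.863 / 5.4, tolerance = 1e-12)
  # ambiguous-sign coefficients are flippable
  xb_neg <- compute_linear_predictor(pt, sps = s0, sign_age = -1)$xb
  expect_equal(xb0 - xb_neg, 2 * 0.01935 * pt$age, tolerance = 1e-9)
  malig <- base_patient(group = "MOSF", mosf_with_malignancy = TRUE)
  expect_equal(
    compute_linear_predictor(malig)$xb -
      compute_linear_predictor(malig, sign_mosf_malig = -1)$xb,
    2 * 1.1803, tolerance = 1e-9
  )
})

test_that("death probability is strictly increasing in SPS", {
  pt <- base_patient()
  s0 <- compute_sps(pt)$sps
  dp <- vapply(s0 + 0:5, function(s) {
    death_probability(pt, sps = s)$death_prob
  }, numeric(1))
  expect_true(all(diff(dp) > 0))
})

test_that("baseline survival reads the table, interpolates and clamps", {
  expect_identical(baseline_survival("ARF", 30), 0.691)
  expect_identical(baseline_survival("MOSF", 30), 0.691)
  expect_identical(baseline_survival("LungCancer", 177), 0.108)
  expect_equal(baseline_survival("Coma", 45), (0.630 + 0.609) / 2,
               tolerance = 1e-12)
  # (177, 180] returns the day-177 value
  expect_identical(baseline_survival("CHF", 179), 0.733)
  expect_identical(baseline_survival("CHF", 180), 0.733)
  expect_error(baseline_survival("CHF", 181), class = "regretdca_range")
  expect_error(baseline_survival("CHF", -1), class = "regretdca_range")
  # every column is non-increasing in t
  tab <- baseline_survival_table()
  for (col in setdiff(names(tab), "t")) {
    expect_true(all(diff(tab[[col]]) <= 0))
  }
})

test_that("survival is non-increasing in t and death is its complement", {
  pts <- example_patients()
  ts <- c(0, 15, 30, 45, 90, 150, 177, 180)
  sp <- sapply(ts, function(t) survival_probability(pts, t = t)$surv_prob)
  expect_true(all(apply(sp, 1, function(x) all(diff(x) <= 0))))
  dp <- death_probability(pts, t = 90)
  expect_equal(dp$death_prob, 1 - dp$surv_prob, tolerance = 1e-15)
  expect_true(all(dp$death_prob >= 0 & dp$death_prob <= 1))
})

test_that("validation rejects bad records and imputation fills normals", {
  pt <- base_patient()
  expect_error(compute_sps(dplyr::select(pt, -"alb")),
               "alb", class = "regretdca_incomplete_record")
  expect_error(compute_sps(base_patient(alb = NA_real_)),
               "alb", class = "regretdca_incomplete_record")
  expect_error(compute_sps(base_patient(temp = 20)),
               class = "regretdca_validation")
  expect_error(compute_sps(base_patient(na = 90)),
               class = "regretdca_validation")
  expect_error(compute_sps(base_patient(group = "Sepsis")),
               class = "regretdca_validation")
  expect_error(
    compute_sps(base_patient(group = "ARF", mosf_with_malignancy = TRUE)),
    class = "regretdca_validation"
  )
  expect_message(
    imp <- compute_sps(base_patient(alb = NA_real_), impute = TRUE),
    "imputed normal value 3.5"
  )
  expect_identical(imp$sps, compute_sps(base_patient(alb = 3.5))$sps)
})

test_that("patient records round-trip through CSV and JSON", {
  pts <- example_patients()
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(pts, csv)
  expect_equal(as.data.frame(read_patients(csv)), as.data.frame(pts))
  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(pts, js, digits = NA)
  got <- read_patients(js)
  expect_equal(got$wbc, pts$wbc)
  expect_equal(death_probability(got)$death_prob,
               death_probability(pts)$death_prob, tolerance = 1e-12)
})
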