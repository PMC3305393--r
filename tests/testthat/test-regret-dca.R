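# Expected-regret curves, classification and strategy selection

four_row <- function() {
  tibble::tibble(p = c(0.9, 0.8, 0.3, 0.1),
                 died = c(TRUE, FALSE, TRUE, FALSE))
}

test_that("classification counts follow the p >= pt rule", {
  cc <- classify_at_threshold(four_row(), 0.5)
  expect_equal(unlist(cc[c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 1, fn = 1, tn = 1))
  # boundary value is classified positive
  cc <- classify_at_threshold(four_row(), 0.3)
  expect_equal(unlist(cc[c("tp", "fp", "fn", "tn")]),
               c(tp = 2, fp = 1, fn = 0, tn = 1))
  cc <- classify_at_threshold(four_row(), 1e-9)
  expect_equal(cc$tp + cc$fp, 4)
  expect_error(classify_at_threshold(four_row()[0, ], 0.5),
               class = "regretdca_empty_cohort")
  expect_error(classify_at_threshold(four_row(), 0), class = "regretdca_range")
})

test_that("strategy regrets match hand arithmetic", {
  expect_equal(erg_hospice_all(1, 0.7), 0)
  expect_equal(erg_hospice_all(0.5, 0.5), 0.5)
  expect_equal(erg_hospice_all(0.5, 0.5, rrr_hosp = 0.08), 0.46)
  expect_error(erg_hospice_all(0.5, 1), class = "regretdca_range")
  expect_equal(erg_treat_all(0), 0)
  expect_equal(erg_treat_all(0.3), 0.3)
  expect_equal(erg_treat_all(0.3, rrr_rx = 0.05), 0.285)
  counts <- tibble::tibble(tp = 1, fp = 1, fn = 1, tn = 1, n = 4)
  expect_equal(erg_model(counts, pt = 0.5), 0.5)
  expect_equal(erg_model(counts, pt = 0.5,
                         harms = harms_effects(h_te_norm = 0.1)), 0.6)
  perfect <- tibble::tibble(tp = 2, fp = 0, fn = 0, tn = 2, n = 4)
  expect_equal(erg_model(perfect, pt = c(0.2, 0.5, 0.8)), c(0, 0, 0))
})

test_that("with no effects and no harms the base regret-DCA forms emerge", {
  withr::local_seed(7)
  cohort <- random_cohort(300)
  prev <- mean(cohort$died)
  grid <- seq(0.05, 0.95, by = 0.05)
  curves <- decision_curves(cohort, grid = grid)
  odds <- grid / (1 - grid)
  expect_equal(curves$erg_hospice_all, (1 - prev) * odds, tolerance = 1e-12)
  expect_equal(curves$erg_treat_all, rep(prev, length(grid)))
  expect_equal(curves$erg_model,
               (curves$fp / curves$n) * odds + curves$fn / curves$n,
               tolerance = 1e-12)
})

test_that("counts are conserved and monotone across the grid", {
  withr::local_seed(11)
  cohort <- random_cohort(500)
  curves <- decision_curves(cohort)
  expect_true(all(curves$tp + curves$fp + curves$fn + curves$tn == curves$n))
  expect_true(all(diff(curves$tp + curves$fp) <= 0))  # positives shrink
  expect_true(all(diff(curves$fn + curves$tn) >= 0))  # negatives grow
  # the treat-all curve is flat; the hospice curve strictly increases
  expect_equal(length(unique(curves$erg_treat_all)), 1)
  expect_true(all(diff(curves$erg_hospice_all) > 0))
})

test_that("scaled regrets equal the unscaled Appendix forms over random draws", {
  withr::local_seed(99)
  for (i in 1:200) {
    om <- runif(1, 20, 100); com <- runif(1, 15, 100)
    harms <- harms_effects(rrr_rx = runif(1, 0, 0.3),
                           rrr_hosp = runif(1, 0, 0.3),
                           h_rx = runif(1, 0, 10), h_hosp = runif(1, 0, 10))
    h_te_raw <- runif(1, 0, 5)
    scale <- om + harms$h_rx - harms$h_hosp
    pt <- threshold_with_harms(om, com, harms)
    prev <- runif(1, 0.05, 0.95)
    n <- sample(50:500, 1)
    cnt <- as.list(tibble::as_tibble_row(
      c(stats::setNames(as.vector(stats::rmultinom(1, n, rep(0.25, 4))),
                        c("tp", "fp", "fn", "tn")), n = n)))
    harms_sc <- harms_effects(rrr_rx = harms$rrr_rx,
                              rrr_hosp = harms$rrr_hosp,
                              h_rx = harms$h_rx, h_hosp = harms$h_hosp,
                              h_te_norm = h_te_raw / scale)

    expect_lt(abs(erg_hospice_all(prev, pt, harms$rrr_hosp) -
                    erg_unscaled("HospiceAll", om, com, harms,
                                 prevalence = prev) / scale), 1e-9)
    expect_lt(abs(erg_treat_all(prev, harms$rrr_rx) -
                    erg_unscaled("TreatAll", om, com, harms,
                                 prevalence = prev) / scale), 1e-9)
    expect_lt(abs(erg_model(tibble::as_tibble(cnt), pt, harms_sc) -
                    erg_unscaled("UseModel", om, com, harms, counts = cnt,
                                 h_te_raw = h_te_raw) / scale), 1e-9)
  }
})

test_that("conditional-rate and joint-count forms of the model regret agree", {
  withr::local_seed(12)
  for (i in 1:100) {
    cohort <- random_cohort(sample(40:400, 1))
    if (length(unique(cohort$died)) < 2) next
    pt <- runif(1, 0.05, 0.95)
    cnt <- classify_at_threshold(cohort, pt)
    prev <- mean(cohort$died)
    rates <- list(tp = cnt$tp / sum(cohort$died),
                  fn = cnt$fn / sum(cohort$died),
                  fp = cnt$fp / sum(!cohort$died),
                  tn = cnt$tn / sum(!cohort$died))
    harms <- harms_effects(rrr_rx = 0.1, rrr_hosp = 0.05, h_rx = 4,
                           h_hosp = 2)
    a <- erg_unscaled("UseModel", 60, 40, harms, counts = cnt,
                      h_te_raw = 3)
    b <- erg_unscaled("UseModel", 60, 40, harms, prevalence = prev,
                      rates = rates, h_te_raw = 3)
    expect_lt(abs(a - b), 1e-9)
  }
})

test_that("with zero harms and effects the unscaled forms reduce to p and 1-p times the regrets", {
  h0 <- harms_effects()
  expect_equal(erg_unscaled("HospiceAll", 50, 25, h0, prevalence = 0.3),
               0.7 * 25)
  expect_equal(erg_unscaled("TreatAll", 50, 25, h0, prevalence = 0.3),
               0.3 * 50)
})

test_that("test harm raises only the model curve; effects lower their own curves", {
  cohort <- figure4_cohort()
  base <- decision_curves(cohort)
  hte <- decision_curves(cohort, harms = harms_effects(h_te_norm = 0.1))
  expect_true(all(hte$erg_model > base$erg_model))
  expect_equal(hte$erg_hospice_all, base$erg_hospice_all)
  expect_equal(hte$erg_treat_all, base$erg_treat_all)

  rx <- decision_curves(cohort, harms = harms_effects(rrr_rx = 0.08))
  expect_true(all(rx$erg_treat_all < base$erg_treat_all))
  expect_true(all(rx$erg_model <= base$erg_model))
  expect_equal(rx$erg_hospice_all, base$erg_hospice_all)

  ho <- decision_curves(cohort, harms = harms_effects(rrr_hosp = 0.08))
  expect_true(all(ho$erg_hospice_all < base$erg_hospice_all))
  expect_true(all(ho$erg_model <= base$erg_model))
  expect_equal(ho$erg_treat_all, base$erg_treat_all)
})

test_that("strategy lookup reproduces the three-region pattern on a real-shaped cohort", {
  curves <- decision_curves(figure4_cohort())
  expect_identical(optimal_strategy_at(curves, 0.10), "HospiceAll")
  expect_identical(optimal_strategy_at(curves, 0.40), "UseModel")
  expect_identical(optimal_strategy_at(curves, 0.95), "TreatAll")
  expect_error(optimal_strategy_at(curves, 0.999),
               class = "regretdca_range")
})

test_that("a perfect classifier without test harm is optimal at interior thresholds", {
  cohort <- tibble::tibble(p = rep(c(0.95, 0.05), each = 50),
                           died = rep(c(TRUE, FALSE), each = 50))
  curves <- decision_curves(cohort, grid = seq(0.1, 0.9, by = 0.1))
  expect_equal(curves$erg_model, rep(0, 9))
  expect_true(all(curves$optimal == "UseModel"))
})

test_that("ties in the argmin prefer the individualised strategy", {
  # at thresholds below every predicted probability the model refers
  # everyone, so its regret ties hospice-all exactly
  cohort <- tibble::tibble(p = rep(c(0.5, 0.7), 20),
                           died = rep(c(FALSE, TRUE), 20))
  expect_message(
    curves <- decision_curves(cohort, grid = c(0.1, 0.6)),
    "tie"
  )
  expect_equal(curves$erg_model[1], curves$erg_hospice_all[1])
  expect_identical(curves$optimal[1], "UseModel")
})

test_that("cohorts and curve tables round-trip through CSV", {
  cohort <- figure4_cohort()
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::mutate(cohort, died = as.integer(died)), f)
  expect_equal(as.data.frame(read_cohort(f)), as.data.frame(cohort))
  curves <- decision_curves(cohort, grid = seq(0.1, 0.9, by = 0.1))
  g <- withr::local_tempfile(fileext = ".csv")
  write_curves(curves, g)
  back <- readr::read_csv(g, show_col_types = FALSE)
  expect_equal(names(back),
               c("pt", "erg_hospice_all", "erg_treat_all", "erg_model",
                 "optimal"))
  expect_equal(back$erg_model, curves$erg_model, tolerance = 1e-12)
})
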