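# Synthetic prediction cohorts: (predicted death probability, observed
# death) pairs with controlled prevalence and discrimination. Risks are
# drawn from a logit-normal distribution and outcomes from
# Bernoulli(risk), so the generated cohort is calibrated by
# construction; the two distribution parameters are solved so that the
# expected prevalence and expected concordance AUC hit their targets.

# deterministic quadrature grid on the latent normal scale
logitnorm_grid <- function(k = 4000) qnorm((seq_len(k) - 0.5) / k)

expected_prevalence <- function(m, s, q) mean(plogis(m + s * q))

# expected concordance of risk vs Bernoulli(risk) outcome for the
# discretised logit-normal: AUC = E[X(1-Y) 1{X>Y}]/(prev(1-prev)) with a
# half weight on ties (the atoms of the discretisation)
expected_auc <- function(m, s, q) {
  r <- plogis(m + s * q)            # already sorted: plogis is increasing
  k <- length(r)
  prev <- mean(r)
  if (prev <= 0 || prev >= 1) return(0.5)
  csum <- cumsum(1 - r)             # sum_{j <= i} (1 - r_j)
  num <- sum(r * (csum - (1 - r))) + 0.5 * sum(r * (1 - r))
  (num / k^2) / (prev * (1 - prev))
}

#' Calibrate the logit-normal risk distribution
#'
#' Solves for the location `m` and scale `s` of a logit-normal risk
#' distribution such that, when outcomes are drawn as Bernoulli(risk),
#' the expected death fraction equals `prevalence` and the expected
#' rank-based AUC of risk versus outcome equals `target_auc`. The
#' expectations are evaluated on a fixed deterministic quantile grid
#' (`k` nodes), and the two one-dimensional root searches are nested:
#' `m` matches the prevalence at any given `s` (prevalence is monotone
#' in `m`), and `s` then matches the AUC (discrimination is monotone in
#' the latent spread).
#'
#' @param prevalence Target death fraction in `(0, 1)`.
#' @param target_auc Target discrimination in `[0.5, 1)`.
#' @param k Number of quadrature nodes.
#' @return Named numeric vector `c(m, s)`.
#' @export
#' @examples
#' calibrate_logit_normal(0.5, 0.79)
calibrate_logit_normal <- function(prevalence, target_auc, k = 4000) {
  if (!is.finite(prevalence) || prevalence <= 0 || prevalence >= 1) {
    abort("`prevalence` must lie in (0, 1).", class = "regretdca_validation")
  }
  if (!is.finite(target_auc) || target_auc < 0.5 || target_auc >= 1) {
    abort("`target_auc` must lie in [0.5, 1).", class = "regretdca_validation")
  }
  q <- logitnorm_grid(k)
  solve_m <- function(s) {
    uniroot(function(m) expected_prevalence(m, s, q) - prevalence,
            lower = -30, upper = 30, tol = 1e-10)$root
  }
  auc_gap <- function(s) expected_auc(solve_m(s), s, q) - target_auc
  s_hi <- 12
  if (auc_gap(1e-8) >= 0) {
    s <- 0
  } else if (auc_gap(s_hi) < 0) {
    abort("no logit-normal scale reaches the requested AUC.",
          class = "regretdca_calibration")
  } else {
    s <- uniroot(auc_gap, lower = 1e-8, upper = s_hi, tol = 1e-8)$root
  }
  m <- if (s == 0) qlogis(prevalence) else solve_m(s)
  c(m = m, s = s)
}

#' Generate a synthetic prediction cohort
#'
#' Draws `n` patient risks from the calibrated logit-normal distribution
#' and one Bernoulli(risk) death indicator each, emulating the
#' (predicted probability, observed 180-day death) interface of a
#' prognostic-model cohort. Because outcomes are drawn from the risks
#' themselves the cohort is perfectly calibrated in expectation; its
#' discrimination is controlled through `target_auc`.
#'
#' @param n Cohort size (`>= 10`).
#' @param prevalence Target death fraction in `(0, 1)`.
#' @param target_auc Target rank-based AUC in `[0.5, 1)`; 0.79 is the
#'   discrimination of the SUPPORT model in its development cohort.
#' @param seed Optional integer; when supplied, generation is
#'   reproducible and the caller's RNG state is left untouched.
#' @return A tibble of class `regret_cohort` with columns `p`, `died`
#'   and attributes `location`, `scale`, `target_auc`,
#'   `target_prevalence`, `seed`.
#' @export
#' @examples
#' cohort <- generate_cohort(n = 1000, prevalence = 0.5,
#'                           target_auc = 0.79, seed = 1)
#' empirical_auc(cohort)
generate_cohort <- function(n = 2000, prevalence = 0.5, target_auc = 0.79,
                            seed = NULL) {
  if (!is.finite(n) || n < 10) {
    abort("`n` must be at least 10.", class = "regretdca_validation")
  }
  par <- calibrate_logit_normal(prevalence, target_auc)
  draw <- function() {
    p <- plogis(rnorm(n, par[["m"]], par[["s"]]))
    tibble(p = p, died = rbinom(n, 1L, p) == 1L)
  }
  cohort <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(cohort,
            location = par[["m"]], scale = par[["s"]],
            target_auc = target_auc, target_prevalence = prevalence,
            seed = seed,
            class = c("regret_cohort", class(cohort)))
}

#' Empirical rank-based AUC (concordance)
#'
#' The probability that a randomly chosen patient who died carries a
#' higher predicted probability than a randomly chosen survivor, with
#' ties counted one half — computed from the ranks of `p`
#' (Mann-Whitney form).
#'
#' @param cohort Data frame with columns `p` and `died`, containing at
#'   least one death and one survivor.
#' @return The concordance AUC in `[0, 1]`.
#' @export
#' @examples
#' cohort <- tibble::tibble(p = c(0.9, 0.8, 0.3, 0.1),
#'                          died = c(TRUE, FALSE, TRUE, FALSE))
#' empirical_auc(cohort)  # 0.75
empirical_auc <- function(cohort) {
  cohort <- check_cohort(cohort)
  n1 <- sum(cohort$died)
  n0 <- sum(!cohort$died)
  if (n1 == 0 || n0 == 0) {
    abort("AUC needs both a death and a survivor in the cohort.",
          class = "regretdca_single_class")
  }
  r <- rank(cohort$p)
  (sum(r[cohort$died]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
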