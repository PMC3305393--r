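---
title: "Regret-based decision curves for hospice referral: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regret-based decision curves for hospice referral: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regretdca)
```

## The decision problem

A terminally ill patient qualifies for hospice when their life
expectancy is about six months or less, yet referrals are routinely
mistimed in both directions. regretdca frames the referral as a
threshold decision: the patient (or surrogate, or physician) should be
referred when their probability of death within 180 days, $p$, is at
least a personal threshold probability $P_t$, and should continue
curative treatment otherwise. Everything in the package serves one of
three questions: where is $P_t$ for this decision maker, which of three
management strategies carries the least expected regret at that
threshold, and what is $p$ for this patient.

## Eliciting the threshold from regret

Because there is no good option at the end of life — only the option
one can best live with — the decision maker's preferences are elicited
as *regret* rather than utility. Two visual-analogue ratings on a 0–100
scale capture

* the regret of **omission**, $U_1 - U_3$: failing to refer a patient
  who should have been referred, and
* the regret of **commission**, $U_4 - U_2$: referring a patient who
  should have continued treatment,

where $U_1, \dots, U_4$ are the utilities of the four possible
outcomes. Only the two differences are ever elicited; absolute
utilities are never needed. The indifference threshold is

$$P_t = \frac{1}{1 + \dfrac{U_1 - U_3}{U_4 - U_2}},$$

so a patient who rates the two regrets 50 and 25 — a missed referral is
twice as bad — has $P_t = 1/(1+2) = 0.33$, and a 9:1 ratio gives
$P_t = 0.10$. `threshold_from_dvas()` computes this in full precision
and rounds only for display. A commission rating of zero is surfaced as
an explicit degenerate-preference error rather than $P_t = 0$, because
the downstream curves use the odds $P_t/(1-P_t)$.

When the management strategies themselves carry harms — utility losses
$H_{Rx}$ (treatment) and $H_{Hosp}$ (hospice) on the same 0–100 scale —
the two regrets generalise to $U_1 - U_3 + H_{Rx} - H_{Hosp}$ and
$U_4 - U_2 - (H_{Rx} - H_{Hosp})$, and `threshold_with_harms()` applies

$$P_t = \frac{1}{1 + \dfrac{U_1-U_3+H_{Rx}-H_{Hosp}}
                          {U_4-U_2-(H_{Rx}-H_{Hosp})}}.$$

Whether the harms share the DVAS scale is an assumption we make
explicit: they do. If the net harm $H_{Rx}-H_{Hosp}$ swallows either
regret the adjusted threshold is undefined and the package raises a
"harms dominate" error instead of returning a boundary value.

## Expected regret of the three strategies

At a threshold $P_t$, three strategies are compared on the scaled
regret axis (regret divided by the omission-regret scale
$U_1-U_3+H_{Rx}-H_{Hosp}$, which turns the commission/omission ratio
into the odds $P_t/(1-P_t)$):

$$\mathrm{ERg[Hosp]} = (1-p)\,(1-RRR_{Hosp})\,\frac{P_t}{1-P_t}, \qquad
  \mathrm{ERg[Rx]} = p\,(1-RRR_{Rx}),$$

$$\mathrm{ERg[Model]} =
  \Big[1 - RRR_{Hosp}\tfrac{\#TP+\#FP}{n}
         - RRR_{Rx}\tfrac{\#FN+\#TN}{n}\Big]\,h_{te}
  + (1-RRR_{Hosp})\,\frac{\#FP}{n}\,\frac{P_t}{1-P_t}
  + (1-RRR_{Rx})\,\frac{\#FN}{n},$$

where $p$ is the cohort's death fraction, the confusion counts come
from classifying each cohort member by the rule $p_i \ge P_t$ (the
boundary is positive, as printed in the source model's step list), the
relative risk reductions $RRR_{Rx}$ and $RRR_{Hosp}$ discount the
regret a strategy can still incur once its effect is credited, and
$h_{te}$ is the prognostic-test harm already normalised by the
omission-regret scale. The package also carries the raw
utility-scale forms (`erg_unscaled()`); dividing them by the
omission-regret scale must reproduce the scaled forms exactly, and the
test suite holds the two routes to within $10^{-9}$ over a thousand
random parameter draws. We verified the algebra linking the joint-count
form above to its conditional-rate derivation (the identity
$p \cdot TP_{cond} = \#TP/n$ and its three siblings); both
parameterisations are implemented and tested for agreement.

`decision_curves()` sweeps a grid of thresholds (default
$0.01, \dots, 0.99$ in steps of $0.01$), returns the three curves plus
the per-threshold argmin, and `optimal_strategy_at()` looks up the
nearest grid row (lookup error bounded by half a grid step; exact
evaluation is available by passing a single-point grid). Ties in the
argmin resolve in favour of the individualised strategy, then the
status quo — UseModel over TreatAll over HospiceAll — and are messaged
when they occur. Prevalence is always the cohort's empirical death
fraction: the joint fractions $\#TP/n$ already embed the same quantity,
so mixing an external prevalence into the two reference strategies
would break the comparison.

Two numerical details matter here. Grid values are represented as
$k/100$ (not accumulated by `seq()`) so that a predicted probability
written as, say, 0.95 compares equal to the grid threshold 0.95 under
the $p \ge P_t$ rule. And the curves are reported on the scaled axis,
so regret values are comparable across decision makers only up to each
one's omission-regret scale.

## The SUPPORT survival model

The prognostic input is a re-implementation of the SUPPORT model for
180-day survival of seriously ill hospitalised adults. It proceeds in
two steps:

1. **Physiology score (SPS)** — `compute_sps()` evaluates a
   spline-based aggregate of ten day-3 physiologic measures (albumin,
   APACHE III respiration score, bilirubin, creatinine, sodium,
   PaO2/FiO2, mean blood pressure, white cell count, temperature, heart
   rate) with disease-group intercepts and an ARF/MOSF-specific white
   cell block. The variable redefinitions are applied before any term
   is evaluated: WBC is raised to 9 when below 9 outside ARF/MOSF and
   capped at 40, creatinine is capped at 15. Heart rate, creatinine and
   sodium enter through restricted-cubic-spline tails whose
   coefficients sum to zero (a transcription check the test suite
   enforces only indirectly, through continuity at every knot).
2. **Linear predictor and survival** — `compute_linear_predictor()`
   adds the group indicators, coma score, cancer comorbidity (0/1/2),
   the reciprocal hospital-day term $-1.863/(Hday+3.4)$, $0.08121\,
   \mathrm{SPS}$ and two age-interaction brackets;
   `survival_probability()` then evaluates
   $S_i(t)^{\exp(X\hat\beta)}$ against the packaged baseline survival
   table (four strata at seven time points), and `death_probability()`
   returns the complement $p = 1 - SP$.

Design choices the source description left open:

* **Two ambiguous signs.** The printed model shows "±" on the
  MOSF-with-malignancy coefficient (1.1803) and the age coefficient
  (0.01935). We implement both as "+": a malignancy and older age are
  adverse factors, and because $S_i(t) < 1$, a larger linear predictor
  lowers $S^{\exp(X\hat\beta)}$ as it must. Both signs are exposed as
  `sign_mosf_malig` / `sign_age` overrides so users who resolve the
  ambiguity against the original model publication can flip them;
  absolute probabilities should be treated with that caveat.
* **Interpolation and horizon.** The baseline table tabulates seven
  time points and no interpolant; we interpolate linearly (monotone
  preserving) and return the day-177 value for $t \in (177, 180]$
  rather than extrapolate below the last tabulated entry.
* **Missing physiology.** The default is a hard error naming the first
  missing field, because incomplete records silently degrade the
  prediction. An opt-in `impute = TRUE` substitutes documented normal
  values (albumin 3.5, bilirubin 1.01, creatinine 1.01, sodium 137,
  PaO2/FiO2 333.3, mean BP 90, WBC 9, heart rate 100, temperature 37,
  respiration score 0), messaging each substitution.
* **Validation ranges.** Temperature must lie in [25, 45] °C and sodium
  in [100, 180] mEq/L; the remaining bounds are data-entry sanity
  limits of our choosing, documented in `validate_patients()`. Only
  non-negativity is enforced for the APACHE III respiration score,
  whose valid range the model description does not state.

## The synthetic cohort generator

No patient-level dataset ships with the package, so decision curves are
exercised on synthetic cohorts of (predicted death probability,
observed death) pairs. `generate_cohort()` draws each patient's risk
from a logit-normal distribution and the outcome from
Bernoulli(risk). The location and scale are solved by
`calibrate_logit_normal()` so that the *expected* death fraction and
the *expected* rank-based AUC hit their targets: expectations are
evaluated on a fixed deterministic quantile grid (4,000 nodes), the
location is matched to the prevalence by a root search at any given
scale (prevalence is monotone in location), and an outer root search on
the scale matches the AUC (discrimination is monotone in the latent
spread). A target AUC of 0.5 correctly collapses the scale to zero.

Defaults mirror the study conditions the package emulates: prevalence
0.5 (a placeholder — the source cohort's 180-day death fraction is not
printed anywhere we can cite, so an uninformative value is used and
exposed in the config), target AUC 0.79 (the SUPPORT development-cohort
discrimination; 0.78 was the validation-cohort value), and n = 2,000 by
default with n = 10,000 used in the calibration checks — large enough
that the empirical AUC sits within ±0.02 of target while the whole
suite runs in seconds.

What the generator reproduces about real data: the prevalence, the
discrimination, and — because outcomes are drawn from the risks
themselves — perfect calibration in expectation (the test suite checks
a decile-level calibration gap below 0.02 at n = 50,000). What it does
not reproduce: the tail *mis*calibration of real prognostic models.
This has a visible consequence for the decision curves. For a perfectly
calibrated cohort one can show the model strategy weakly dominates both
defaults at every threshold — among patients with $r < P_t$ the
expected omission regret $E[r\,|\,r<P_t]$ is below the commission odds
bound, and symmetrically above the threshold — so with a harmless test
the defaults can match the model only by exact ties (at thresholds
outside the span of predicted risks), and ties resolve to UseModel.
The familiar three-region picture — hospice-all at low thresholds, the
model over a wide middle range, treat-all at high thresholds — emerges
on a calibrated cohort as soon as the test carries any harm
($h_{te} > 0$), because the flat test-harm term is then paid at every
threshold while the model's classification advantage vanishes at the
extremes. On real cohorts the same picture appears even at
$h_{te}=0$, driven by deaths among low-predicted patients (and
survivors among high-predicted ones) in excess of the calibrated rate;
the test suite reproduces that shape with a deliberately
tail-miscalibrated fixture cohort. Conclusions drawn from passing
tests therefore speak to the decision arithmetic, not to how any
particular prognostic model misbehaves in its tails.

`empirical_auc()` is the rank-based concordance (Mann–Whitney form)
with ties counted one half — generated risks essentially never tie, but
cohorts loaded from rounded CSV files do.

## The recommendation engine

`recommend()` chains the pieces in the order a bedside decision-support
flow would: threshold (harms-adjusted if treatment/hospice harms
differ), strategy lookup on the supplied curves, and only when the
strategy is UseModel, a death probability — computed from a patient
record through the SUPPORT model, or supplied directly — compared
against the threshold with $p \ge P_t$ referring to hospice. The other
two strategies never consult the prognostic model, however ill the
patient: that asymmetry is the point of the strategy comparison. The
decision is derivable without disclosing the threshold or the death
probability to the patient; the justification object (threshold
sentence, strategy sentence, and a natural-frequency restatement such
as "85 out of 100 patients with this profile ...") is attached for
those who ask. Frequencies round half-up.

`run_pipeline()` makes the whole flow reproducible on disk — cohort,
curves, recommendation and an intermediate-quantity log, byte-identical
across runs at a fixed seed — and `exec/regretdca` exposes each step as
a shell subcommand.

## Limitations

* The SUPPORT re-implementation is faithful to the published
  coefficient listing, including its two ambiguous signs; it is not a
  refit, and probabilities beyond 180 days are out of scope.
* Regret curves use empirical confusion counts with no resampling
  correction or confidence bands; on small cohorts the argmin near
  crossing points is noisy.
* The generator emulates only the (probability, outcome) interface, not
  the nineteen raw covariates, and its perfect calibration is an
  idealisation (see above).
* Threshold elicitation works entirely on regret differences; any
  analysis requiring absolute utilities is out of scope, as is
  aggregation across multiple raters.
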