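---
title: "Quantifying tongue shape complexity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tongue shape complexity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonguecomplexity)
library(dplyr)
```

## The problem

Children acquire independent control of tongue regions gradually; an
immature or disordered motor system tends to move the tongue as a single
undifferentiated mass. In midsagittal ultrasound imaging this shows up as a
*simpler* tongue-surface contour at the moment of maximal constriction.
This package quantifies that simplicity from traced tongue splines with the
two standard shape-complexity statistics, applies the conventional
token-exclusion rules, and fits the mixed-effects models used to relate
complexity to diagnosis (typically developing, TD, versus speech sound
disorder, SSD), age, consonant, and perceptual accuracy.

## The two statistics

Both statistics are derived from the signed curvature $\kappa(s)$ of the
contour, where $s \in [0, 1]$ is normalised arc length, and $\kappa$ at a
point is the reciprocal of the radius of the osculating circle (the circle
that best conforms to the curve there). We express curvature on the
normalised scale, $\kappa_{norm} = \kappa_{mm} \cdot L$ with $L$ the
contour length in mm, so that:

* **MCI** (modified curvature index)
  $= \int_0^1 |\kappa_{norm}(s)|\, ds$ is exactly the *total absolute
  turning angle* of the contour in radians. A straight line scores 0, a
  semicircular arch scores $\pi$, and the value is invariant to position,
  rotation, and uniform scale. No trimming is applied.
* **NINFL** (number of inflections) counts sign changes of the *trimmed*
  curvature sequence, plus one. Trimming zeroes curvature whose osculating
  radius exceeds $0.3 \cdot L$ (i.e. $|\kappa_{norm}| < 1/0.3 \approx
  3.33$): nearly-straight stretches do not count. Sign changes whose
  flanking points touch the first or last 5% of the contour are
  disregarded. The +1 offset encodes the convention that any contour
  carries at least one curve, so zero sign changes is reported as 1.

Token exclusion: reported NINFL over 5 removes a token from *both*
analyses; among the remaining tokens, MCI over 6 removes the token from the
MCI analysis only. Both caps are strict ("over"), so values exactly at the
cap stay.

### Resolved ambiguities in the metric definitions

Several details of the conventional procedure are stated ambiguously in the
literature; the package resolves them as follows, each behind a documented
switch where reasonable:

* **Trim direction.** The trim rule is sometimes verbalised as removing
  values "where the radius is smaller than $0.3 L$", which would remove
  *large* curvature and keep noise — the opposite of the stated intent that
  "small values are not included". The default trims curvature with radius
  *larger* than $0.3 L$ (gentle bends), keeping substantive inflections.
  The literal reading is available via `literal_trim = TRUE`.
* **Edge rule attribution.** A sign change happens between two surviving
  (supra-threshold) points. We disregard the change when *either* flanking
  point lies in an edge zone. The practical reason: the endpoint rows of a
  smoothed, finitely-differenced contour often carry spurious
  supra-threshold curvature (this is exactly the "false detections" the 5%
  rule exists for), and a midpoint convention would relocate such an
  artifact into the interior and count it.
* **Zero-skipping.** The sign-change scan skips trimmed (zero) values
  rather than resetting, so two strong opposite-sign regions separated by a
  flat stretch count one alternation.
* **Retroflex trimming** (off by default, intended for real retroflex-prone
  data): curvature is zeroed at points where the tangent's
  anterior-posterior component reverses against the dominant travel
  direction, the signature of a contour doubling back under a curled tip.
* **Smoothing window.** The conventional "6-point average" has no symmetric
  centring for an even window; we use the standard centred even-order
  moving average (the mean of the two 6-point windows offset by half a
  step, i.e. a 7-point kernel with half weights at the ends), shrinking
  symmetrically near the endpoints so no data is invented.
* **Processing order.** Default is resample (spline interpolation at equal
  arc length) → smooth → resample → curvature; `smooth_first = TRUE`
  smooths the raw trace before resampling. The final resample guarantees
  exactly equidistant samples for the trapezoidal MCI integral.

### Defaults that matter

| parameter | default | meaning |
|---|---|---|
| `n_points` | 100 | equidistant samples per contour; resolves mm-scale features on a 50–100 mm contour |
| `window` | 6 | smoothing span in points |
| `trim_factor` | 0.3 | osculating-radius threshold as a fraction of $L$ |
| `edge_fraction` | 0.05 | edge-exclusion zone at each end |
| `ninfl_cap`, `mci_cap` | 5, 6 | token-exclusion caps |

The sample count is the one genuinely free choice (the source procedures do
not state one); 100 matches common contour-analysis practice and makes the
smoothing span about 5% of the contour.

## The statistical stage

Two research designs share one fixed-effect recipe: centred age, a
treatment-coded two-level predictor (diagnosis with TD reference, or
perceptual error with correct reference, the latter fitted within the SSD
group only), five deviation-coded phoneme contrasts with /a/ as the omitted
reference (each non-reference phoneme +1 in its own column, /a/ −1 in
every column, so each contrast estimates that phoneme against the grand
mean), and the two-way interactions age:group, group:phoneme, age:phoneme
— no three-way term. Age is centred on the analysis subset after
exclusions, keeping the intercept interpretable per model. Random effects
are by-speaker: an intercept plus slopes for the phoneme contrasts, and an
error slope in the accuracy design.

* **MCI** is fitted by REML through `lme4::lmer`. t statistics use
  Satterthwaite-approximated denominator degrees of freedom, implemented
  from the non-profiled REML criterion over the variance parameters
  $(\theta, \sigma)$: $\mathrm{df}_k = 2 f_k^2 / (g_k^\top A\, g_k)$ with
  $f_k = \widehat{\mathrm{Var}}(\hat\beta_k)$, $g_k$ its finite-difference
  gradient in the variance parameters, and $A$ twice the inverse Hessian of
  the REML deviance. When a variance sits on the boundary and the Hessian
  is not invertible, residual df are used with a warning.
* **NINFL** (ordinal, 1–5 after exclusion) is fitted by an in-house
  cumulative-logit mixed model: $P(y \le k) = \mathrm{logit}^{-1}(\alpha_k -
  x^\top\beta - z^\top b)$, thresholds kept ordered by a log-difference
  parameterisation, random effects $b \sim N(0, \mathrm{diag}(\sigma^2))$,
  and the marginal likelihood maximised under the Laplace approximation
  (per-speaker Newton inner solver — the cumulative-logit log-likelihood is
  concave in the linear predictor, so the inner problem is well behaved).
  Fixed effects are tested with Wald z. If the random-slopes model fails,
  the fitter falls back to a random intercept with a warning, never
  silently.

Two deliberate simplifications, both documented here because a full
treatment is unidentifiable in this design: random effects are modelled as
*independent* (diagonal covariance) rather than fully correlated — TD
speakers contribute a single token per phoneme, which cannot inform a 6×6
covariance — and no multiple-testing correction is applied, mirroring
conventional reporting in this literature.

Auxiliary statistics: Cohen's $\kappa$ for transcription reliability (from
the confusion-matrix margins; defined as 1 when both raters are constant
and identical), percentage consonants correct per speaker (labelled
consonant tokens only; /a/ never enters the denominator), and a paired
two-tailed t test with explicit handling of zero-variance differences.

## The synthetic world

The generator exists so that every stage can be verified without any
external data. It has three layers.

**Contours** (`make_contour`): a circular base arc (the convex tongue
body; chord ~70 mm) plus Gaussian displacement bumps orthogonal to the arc
(local differentiation features) plus smooth seeded noise. Gaussian bumps
have closed-form peak extra curvature $|A|/w^2$, which lets a bump be
placed deliberately above or below the trim threshold. Ground truth
(inflection count, analytic MCI) is computed from the *noise-free*
parametric curve by dense sampling with plain finite differences — a code
path independent of the metric pipeline, so the truth can never inherit a
pipeline bug. Noise is a smooth random field (a few low-order harmonics
with a red spectrum) rather than white point jitter: vendor spline exports
are already smooth, and their residual tracing error lives at the contour
scale, not the pixel scale.

**Cohorts** (`simulate_cohort`): tokens drawn directly from the generative
form of the two models — MCI as $X\beta + Zb + \varepsilon$ truncated at 0,
NINFL from a cumulative-logit latent variable (confined to 1–5 by
construction), accuracy labels from a per-phoneme, age-dependent logistic
error curve. Defaults mirror the unbalanced cross-sectional design the
package targets: 29 TD speakers with one repetition per phoneme, 30 SSD
speakers with ten, ages 5;0–12;11 (60–155 months), and fixed effects at
published group-comparison magnitudes (e.g. +0.54 for the /r/ contrast on
the MCI scale). Values the source material does not state were chosen once
for realism and are not revisited: latent thresholds (−2.5, −0.5, 1, 2.5)
give a NINFL distribution concentrated at 1–3 for the reference vowel;
random-effect SDs (0.3 intercept / 0.25 slopes / 0.5 residual on the MCI
scale, 0.8 / 0.5 on the latent scale) put roughly a third of the variance
between speakers; SSD error rates order the consonants /r/ > /s/, /sh/ >
/l/ > /t/ and fall with age (−0.03 logits/month).

**The bridge** (`contour_cohort_bridge`) realises each simulated token as
a contour whose ground-truth complexity matches the token's generative
NINFL and MCI, so the *entire* pipeline — contours in, model estimates out
— can be exercised end to end. Two construction families cover the
(NINFL, MCI) plane:

* *shallow*: a gentle base arc carrying alternating-sign sharp bumps (one
  sign change per adjacent pair) plus optional broad sub-threshold wiggles.
  Because MCI is untrimmed, wiggles add turning mass without ever entering
  the inflection count — the key decoupling.
* *arch*: a strongly curved supra-threshold base (NINFL 1 on its own, MCI
  3.6–4.4) carrying interior grooves (each adds exactly two counted
  inflections) and optionally one posterior bump whose outer sign change
  falls inside the edge-excluded last 5% (adds exactly one), covering even
  counts at high MCI.

Candidate configurations are enumerated once and *self-validated*: each
one's achieved truth is measured by the analytic oracle and kept only if it
realises the intended count with margin on both sides of the trim
threshold (narrow features need ~30% headroom because the 6-point smoother
attenuates them ~10%; broad arches need ~10%) and with counted sign
changes well clear of the edge cut-off. A token then maps to the
nearest-in-MCI valid configuration. Achieved MCI compresses at the very
top of the target range (strong wide features would require physically
implausible displacement amplitudes), which is why the bridge's contract
is a rank-preserving correlation above 0.9, not equality.

What the synthetic world does **not** emulate: probe misalignment and
inter-session registration error, fan-line sampling geometry, retroflex
doubling-back (the retroflex trim is therefore off in synthetic tests),
real covariance between a speaker's phoneme effects, and any dependence
between a token's NINFL and MCI beyond what the two generative models
share. A green test therefore establishes that the algorithms are
implemented correctly and recover the stated generative structure — not
that the instrumentation pipeline upstream of the coordinates is sound.

## Numerical choices

* Resampling interpolates $x(s)$, $y(s)$ with cubic splines (no corner
  cutting; equal arc steps give equal chords to ~1e−9 on smooth curves).
* Curvature: central finite differences on the equidistant samples
  (default), or the signed circumscribed-circle (Menger) curvature of
  consecutive triples — the built-in cross-check; the two agree within 2%
  on analytic curves and the tests enforce it.
* The ordinal fitter optimises with `nlminb` (relative tolerance 1e−10,
  numeric gradients); per-speaker modes are warm-started across objective
  evaluations; overflowing trial steps return a large finite value rather
  than erroring. Standard errors come from a central-difference Hessian at
  the optimum; threshold SEs by the delta method.
* REML fits use lme4 defaults; the Satterthwaite Hessian uses central
  differences with step $10^{-4}\max(|\hat\theta|, 1)$.
* Ties in `ninfl_reported` at the caps: the rules are strict inequalities
  ("over 5", "over 6"), so 5 and 6.0 are kept.

## Limitations

* The cumulative-link fitter supports diagonal random-effect covariance
  only; correlated slopes would need a Cholesky parameterisation and are
  out of scope.
* Satterthwaite df are approximate and can differ from other
  implementations in the second decimal; they are labelled as approximate
  in the reports.
* The bridge's achieved MCI saturates near the exclusion cap; effect sizes
  injected at the cohort level reappear attenuated (but sign-correct) after
  the contour round trip.
* With one repetition per phoneme in the TD group, speaker-level slopes
  are weakly identified; singular fits are reported with warnings rather
  than hidden.
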