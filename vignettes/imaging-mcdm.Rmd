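---
title: "Fuzzy multi-criteria ranking of imaging for suspected pediatric appendicitis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy multi-criteria ranking of imaging for suspected pediatric appendicitis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airmcdm)
library(dplyr)
```

## The decision problem

A child presents to the emergency department with acute abdominal pain and
suspected appendicitis. Four imaging strategies are on the table —
ultrasound (US), non-contrast CT, contrast-enhanced CT, and MRI (1.5 T or
3 T) — and they trade off against each other on accuracy (sensitivity,
specificity, diagnostic precision), logistics (imaging time, ordering and
reporting delays), safety (radiation dose), patient experience
(comfortability, sedation tolerance), operator dependence, and cost. The
choice also depends on how likely appendicitis is in the first place,
which the Appendicitis Inflammatory Response (AIR) score summarizes from
bedside findings and laboratory values.

`airmcdm` formalizes this choice as a multi-criteria decision analysis
(MCDA): expert judgments on the criteria are captured on a five-level
linguistic scale, converted to triangular fuzzy numbers, defuzzified, and
fed to two independent ranking engines — PROMETHEE II (outranking flows)
and TOPSIS (closeness to the ideal) — whose agreement is then quantified.
Two engines are used deliberately: an ordering that survives a change of
aggregation philosophy is more trustworthy than one that does not.

## The AIR score

Seven items contribute points: vomiting (1), right-lower-quadrant pain
(1), rebound tenderness (low/mild/severe = 1/2/3), temperature above
38.5 °C (1), polymorphonuclear fraction 70–84.99% (1) or ≥ 85% (2), white
cell count 10.0–14.9 ×10⁹/L (1) or ≥ 15.0 (2), and CRP 10–49 g/L (1) or
≥ 50 (2). Totals of 0–4, 5–8 and 9–12 denote low, mild and high
probability of appendicitis.

Two conventions needed fixing where the printed scale is silent:

* the printed laboratory bands leave narrow gaps (84.99–85%, 14.9–15.0,
  49–50); we close them with half-open bands `[70, 85)`, `[10, 15)`,
  `[10, 50)`, which changes no unambiguous assignment;
* the imaging scenarios split patients into "low" and "high" AIR strata
  below/above 6, leaving a score of exactly 6 unassigned; `air_stratum()`
  assigns 6 to the high stratum, on the argument that a mild-probability
  score of 6 already sits in the band where cross-sectional imaging is
  being considered. This is a package convention, stated rather than
  inherited.

```{r}
air_score(tibble::tibble(
  vomiting = TRUE, rlq_pain = TRUE, rebound = "mild",
  temperature_c = 38.9, pnl_percent = 75, wbc_count = 12, crp = 30
)) |> select(air_score, air_category, air_stratum)
```

## Linguistic judgments and defuzzification

Experts rate criteria importance and (where no published number exists)
modality performance on the scale VL, L, M, H, VH. Each label is a
triangular fuzzy number on [0, 1]:

```{r}
linguistic_scale()
```

A TFN `(l, m, r)` has membership rising linearly from `l` to 1 at `m` and
falling to 0 at `r`. To run crisp ranking engines we defuzzify with a
Yager ranking index; the default is the triangle centroid
`(l + m + r) / 3`, the most common reading of that index and the one that
returns the mode for symmetric labels. A mode-weighted alternative
`(l + 2m + r) / 4` is available via `method = "weighted_mode"` for
sensitivity analysis. Both matrix entries and importance weights are
defuzzified before ranking — one defuzzification point, shared by both
engines — and the weight vector is normalized to sum to one, which is
what makes the PROMETHEE preference index provably live in [0, 1] and is
required by the TOPSIS weighting step.

The default criteria configuration weights six criteria VH (specificity,
diagnostic precision, time of imaging, user dependency, radiation dose,
comfortability), three H (sensitivity, air score, disposition) and three
M (time of order, result time, cost):

```{r}
imaging_criteria()
fuzzy_weights(imaging_criteria()$weight_label) |> round(4)
```

Directions are not published anywhere, so they are package defaults with
clinical semantics: accuracy, comfort, stratum suitability ("air score")
and disposition speed are benefits; times, cost, operator dependence and
radiation are costs. "Air score" and "disposition" as per-modality
criteria are genuinely ambiguous — we read them as *how suitable the
modality is for patients of this stratum* and *how quickly it moves the
patient to a disposition*, and both stay editable in the criteria table.

## PROMETHEE II

For alternatives $a_t, a_{t'}$ and criteria $k$ with weights $w_k$, the
preference index is
$\pi(a_t, a_{t'}) = \sum_k w_k\, p_k\!\left(f_k(a_t) - f_k(a_{t'})\right)$,
with the Gaussian preference function
$p(d) = 1 - e^{-d^2/2s^2}$ for $d > 0$ and $0$ otherwise. Leaving and
entering flows are averages over opponents,
$\Phi^+(a) = \tfrac{1}{n-1}\sum_{b} \pi(a, b)$,
$\Phi^-(a) = \tfrac{1}{n-1}\sum_{b} \pi(b, a)$, the partial order
(PROMETHEE I) compares the flow pairs, and the net flow
$\Phi^{net} = \Phi^+ - \Phi^-$ gives the total order. Net flows always
sum to zero — an algebraic identity the self-check block verifies on
every run.

Two quantities the method itself leaves open:

* **Cost criteria.** The difference is negated before the preference
  function (equivalently, the column is negated), the standard treatment.
* **Gaussian shape `s`.** Defaults to the population standard deviation
  of each defuzzified criterion column. This is parameter-free, keeps
  `s` on the scale of the data (so the analysis is invariant to positive
  rescaling of any column — percent vs fraction cannot change a ranking),
  and discriminates at the spread actually present among alternatives. A
  column with zero spread gets no preference contribution at all.
  Per-criterion overrides go in `criteria$preference_s`, and
  `sweep_preference_s()` re-runs the ranking under ±10% shape
  perturbations to show whether the winner is an artifact of the
  heuristic.

Ties in net flow are reported as indifference and kept in input order,
never silently broken.

## TOPSIS

The same defuzzified matrix is column-normalized to unit Euclidean norm,
weighted, and compared to the positive ideal $A^+$ (columnwise best:
maximum for benefits, minimum for costs) and negative ideal $A^-$ (the
reverse). With Euclidean distances $d^+_i, d^-_i$ to the two ideals, the
closeness coefficient $R_i = d^-_i / (d^-_i + d^+_i)$ ranks alternatives
descending. $R_i$ is undefined only when an alternative coincides with
both ideals (a fully degenerate matrix), which is rejected with an error
rather than patched.

## The scenario pipeline

`run_scenario()` couples the two engines to one validated input, compares
their rankings by Kendall's $\tau$ and a top-choice flag, and attaches a
self-check block (zero-sum flows, closeness bounds, permutation validity)
plus provenance (matrix hash, seed, package version). The two MRI field
strengths are kept as separate alternatives; when their rows are
identical the engines provably tie them, and the report then collapses
them into one merged entry ("MRI 1.5T/MRI 3T") rather than pretending an
order exists. Merging happens at report time only — engine math always
sees the full alternative set.

```{r}
report <- run_scenario(gen_paper_like_matrix("low"), scenario_config("low"))
report
tidy(report)
```

## What the synthetic data emulate — and what they do not

No expert decision matrix or patient-level cohort is publicly available
for this problem, so the package ships generators instead of data:

* `gen_paper_like_matrix()` fixes sensitivity and specificity to
  published accuracy values for the five modalities (US 78/83,
  non-contrast CT 90.5/100, contrast CT 100/94.8, 1.5 T MRI 96.6/95.8,
  3 T MRI 100/98, in percent) and fills the ten unpublished criteria with
  the documented linguistic defaults of `imaging_judgments()`: ultrasound
  is operator-dependent but radiation-free, fast, cheap and comfortable;
  CT is fast and precise but irradiates; MRI is accurate and
  radiation-free but slow, costly and hard for young children. Only the
  air-score suitability row differs between strata (ultrasound favored
  at low probability, cross-sectional imaging at high). Percent-scale
  accuracy values enter as crisp 0–100 numbers; the scale-invariance of
  both engines (tested) makes mapping them onto the 0–1 fuzzy scale
  unnecessary.
* `gen_cohort()` draws AIR findings conditional on disease status, with
  default item probabilities calibrated once so the closed-form expected
  score (`expected_air_score()`) is exactly 6.30 for appendicitis cases
  and 3.90 for non-cases — the reported operated / not-operated strata
  means — at a prevalence of 0.725. Band levels are drawn by inverse CDF
  from one uniform per item, so cohorts are coupled across probability
  settings at a fixed seed; measurement values are then drawn uniformly
  within the band consistent with the level.

What passing tests on these generators show is that the *machinery* is
correct and the calibration self-consistent — not that the linguistic
defaults equal the unpublished expert judgments, and not that the
generated cohorts reproduce the correlation structure of real patients
(items are conditionally independent given disease status, which real
laboratory values are not). Published net-flow values for this problem
cannot serve as recomputation targets at all: they violate the zero-sum
identity that the method's own equations imply, so the engines are
validated property-based instead (naive-oracle equivalence on random
matrices at 1e-12, zero-sum flows, dominance recovery, duplicate-row
indifference). The published TOPSIS tables are internally consistent in
six of eight rows, and those six are reproduced to ±0.0001 from their
printed distances.

With the default judgments, both engines agree on modality order between
strata only partially (Kendall τ printed in the report); the worked
example in the README shows the numbers the code actually produces. The
published analysis reported non-contrast CT first in both strata; with
our documented default judgments PROMETHEE favors the CT options ahead of
US while TOPSIS — which rewards US's radiation-free, low-cost profile
more strongly under vector normalization — places US first. We report
this disagreement rather than tuning the unpublished judgments to force
agreement; `imaging_judgments()` exists precisely so users can encode
their own expert panel.

## Numerical choices and problem sizes

* Engine-vs-oracle equivalence is asserted at 1e-12 on 100 random
  5×12 matrices; all ranking invariants use the same tolerance.
* Ties are detected at 1e-12; relation classification uses the same
  threshold.
* Display rounding is half-to-even at 4 decimals, applied only in
  printing and the text report, never in computation.
* Monte-Carlo calibration checks use cohorts of 5,000 patients (standard
  error of the mean ≈ 0.03 score points, comfortably inside the ±0.2
  acceptance band); test-suite cohorts use 1,500–2,000.
* Degenerate inputs — single alternatives, all-zero criterion columns,
  alternatives coinciding with both ideals, zero-spread columns — are
  either rejected with named errors or defined to contribute nothing,
  as documented above.

## Known limitations

* Two expert observers in a single institution stand behind the original
  weighting scheme; the defaults here are one clinically literate
  reading, not a validated consensus.
* The AIR item probabilities generate marginally calibrated cohorts, not
  realistic joint distributions.
* Criterion directions for "air score" and "disposition" are
  configurable because reasonable clinicians can disagree on their
  meaning as per-modality criteria.
* No claim of diagnostic validity is made; the package ranks imaging
  strategies under stated judgments, it does not diagnose.
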