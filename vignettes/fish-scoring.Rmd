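---
title: "Scoring 1p/19q status from FISH signal counts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring 1p/19q status from FISH signal counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fish1p19q)
```

# The problem

Dual-color FISH on 1p36/1q25 and 19q13/19p13 probe pairs yields, for every
nucleus, a pair of counts: green reference signals (1q or 19p) and red
marker signals (1p or 19q). Scoring reduces these per-nucleus **G/R
combinations** to an arm-level status — deleted, normal or imbalanced
(polysomic) — and the two arms to a case category (codeletion being the
clinically decisive one). Two things make this harder than counting spots:

* **Nuclear truncation.** On 5-µm paraffin sections many nuclei are cut,
  so signals are lost at random. A true `2/2` cell is frequently observed
  as `2/1`, `1/2` or `1/1`; a true `2/1` deleted cell as `1/1` or `2/0`.
  Observed combination frequencies are therefore mixtures smeared toward
  lower counts.
* **Normal-cell contamination.** Tumor samples contain non-neoplastic
  cells (endothelium, reactive glia), diluting the tumor signal.

# Nucleus classification: two rule sets

`ruleset_algorithm1()` implements the open analysis grid used in manual
practice: `DELETION` whenever the per-nucleus ratio red/green is at most
0.5 (this covers simple deletion, e.g. `2/1`, `3/1`, and relative deletion
on a polysomic background, e.g. `4/2`, `6/3`); `NORMAL` only for `2/2`;
`IMBALANCED` for everything else. Two conventions deserve note:

* **The 0.5 bound is inclusive.** The grid's canonical deletion exemplars
  (`2/1`, `4/2`, `6/3`) all sit *exactly* at R/G = 0.5, so a strict
  inequality would exclude the very combinations that define the class. We
  use ≤ 0.5.
* **No green signal (`0/r`, r ≥ 1)** leaves the ratio undefined. We treat
  an undefined ratio as exceeding every threshold, so these nuclei land in
  the imbalanced residual. This is the only convention that keeps the grid
  total; such combinations are rare and carry no diagnostic weight.

`ruleset_algorithm2()` implements a closed lookup of the 24 combinations
that are actually discriminant for one status subgroup in scored tumor
series: 9 deletion (`2/0 2/1 3/0 3/1 4/1 4/2 5/2 6/2 6/3`), 2 normal
(`2/2`, plus `1/2` — nominally a polysomy pattern, but in sections it
arises overwhelmingly as a truncation product of normal `2/2` cells), and
13 imbalanced (`1/3 1/4 2/3 2/4 2/5 3/3 3/4 4/3 4/4 4/5 5/4 5/5 5/6`,
treating the balanced polysomies `3/3 4/4 5/5` as imbalance). The common
artifacts `1/1` and `3/2` are deliberately `UNCLASSIFIED`: they are
frequent but distribute homogeneously across status subgroups.
`algorithm1_candidates()` records the 31-combination candidate table the
screening started from. Nuclei with no signals at all (`0/0`) are never
classified and never enter any denominator.

# From nuclei to calls

`tally_arm()` computes per-class percentages over all counted (non-`0/0`)
nuclei. The default denominator **includes** unclassified nuclei, matching
manual practice of scoring a fixed number of nuclei regardless of their
combination; `denominator = "classified"` is available for sensitivity
analyses.

Three counting methods (`call_arm()`):

* **Combination** (`call_combination()`): with cutoffs (D, I) bound to the
  rule set — (55, 30) for the open grid, (55, 20) for the lookup — the
  clauses are, in order: imbalanced if the imbalanced-class percentage
  exceeds I (*independently of deletion status*); else deleted if the
  deletion-class percentage exceeds D; else normal if deleted + imbalanced
  stay strictly below I; else imbalanced. Boundary conventions are strict
  `>` for the first two clauses and strict `<` for the normal clause, as
  the cutoffs' verbal definitions state ("exceeded", "over", "less than").
* **Ratio** (`call_ratio()`): the total red/green signal ratio over all
  counted nuclei; ≤ 0.8 deleted, (0.8, 1.15] normal, > 1.15 imbalanced
  (both boundaries inclusive on the lower side). A zero green total leaves
  the arm `UNDETERMINED`.
* **Combination + ratio** (`merge_methods()`): equal statuses stand;
  deleted beats normal; imbalanced beats both. The merge is symmetric and
  idempotent.

The quality gate (`min_nuclei`, default 100 — the conventional manual
scoring depth) returns `UNDETERMINED` with a diagnostic rather than a
call; faded archival slides typically fail here. `combine_arms()` maps the
status pair to the seven case categories. The pairs *deleted/imbalanced*
have no category of their own in the conventional seven-row partition; we
report them as imbalance of the imbalanced arm, keeping the deletion
visible in the per-arm detail. This is an explicit convention, not an
inference about what scored clinical series did with such cases.
`triage_discordance()` compares manual and automated calls per arm and
recommends extending the manual count to 200 cells for discordant cases —
the escalation that, in practice, resolves essentially all discordances in
favor of the automated result (which simply sees more cells).

# Cutoff calibration

`calibrate_cutoff()` is mean + 3 SD over per-control-case abnormal-nucleus
percentages, with the **sample** SD (n − 1): control series are small
(typically on the order of 13 cases), so the unbiased variance estimate is
the defensible choice. `calibrate_ruleset()` computes deletion-class and
imbalanced-class cutoffs per arm and shares one value across arms by
taking the **maximum** — the conservative reduction consistent with
reporting a single cutoff "for both 1p and 19q".

# Concordance and screening statistics

`cohens_kappa()` follows the textbook marginal formula; `agreement()` adds
the banding convention used in this literature (κ between 0.6 and 0.8 good,
above 0.8 high). `chi_square_homogeneity()` is the Pearson statistic
without continuity correction with asymptotic p-values.

`screen_combinations()` re-derives a closed rule set from a labeled
series. For each combination × status subgroup × source, it fits a
univariate logistic regression of subgroup membership (one-vs-rest) on the
combination's per-case frequency and takes the likelihood-ratio p-value.
Design choices, all made once:

* **Per-case frequencies, univariate, one-vs-rest.** Per-nucleus models
  would ignore the case as the sampling unit; multivariable models are not
  identifiable at ~50 cases × ~30 combinations.
* **Separation fallback.** Strong combinations separate perfectly at these
  sample sizes. Detected separation (non-convergence warnings or |β| > 15)
  falls back to a Fisher exact test on the frequency dichotomized at its
  median, keeping p-values meaningful.
* **Dual-source selection.** A combination is retained only when it is
  significant (p < 0.05, positive association) for the same subgroup in
  *both* the manual and the automated analysis; under the null this squares
  the false-selection rate (≈ α²). No multiple-testing correction is
  applied by default, matching the plain p < 0.05 screening convention; a
  Benjamini–Hochberg option exists but changes the procedure being modeled.
* **Assignment** goes to the subgroup with the smallest worse-source
  p-value among qualifying subgroups.

# The simulator

`simulate_series()` generates per-nucleus count tables with known truth:

* **Genotypes.** Deleted clone `2/1`; normal `2/2`; imbalanced clone
  `3/3` (balanced polysomy). Relative-deletion (`4/2`) or mixed-clone
  designs can be passed explicitly.
* **Contamination.** `tumor_fraction` (default 0.7, a realistic resection
  purity) of nuclei come from the tumor clone(s), the rest are `2/2`.
* **Truncation** is independent per-signal Bernoulli loss with probability
  `p_loss`. The default 0.07 is back-calculated from observed artifact
  bands in scored series: normal cases show `2/1` in roughly 12% of
  nuclei, and under this model P(2/2 → 2/1) = 2p(1−p)(1−p)² ≈ 12% at
  p ≈ 0.07. The simplest loss model that reproduces the dominance of the
  `2/1`/`1/2` artifact classes.
* **Gain.** With probability `p_gain` (default 0.02) one spurious signal
  of a random color is added (signal splitting, hybridization noise).
* **Views.** Each case is emitted twice: the full `automated` table
  (default 300 nuclei/arm) and a `manual` view subsampled to 100
  nuclei/arm. Same seed ⇒ byte-identical output.

`simulate_screening_series()` generates per-case combination-frequency
tables directly: per-status mean profiles (`screening_profiles()`,
modeled on the frequency structure of scored retrospective series, with
rare discriminant combinations floored at 0.5% in their home subgroup so
each of the 24 lookup entries carries a detectable effect, and `1/1`,
`3/2`, `1/0`, `0/1` equalized across subgroups as true nulls), Dirichlet
between-case variability (concentration 150), multinomial counts, and
per-source independent draws (so dual-source false selection behaves as
α² under the null). Default series size 53 cases (26 deleted, 8 normal,
19 imbalanced), 100 nuclei manual / 300 automated.

What the simulator does **not** model: spatial tissue structure, focal
subclones (beyond global clone fractions), fluorescence fading over
storage time (represented only via the minimum-cell QC gate), probe
cross-hybridization, and reader-specific manual biases (the manual view is
an unbiased subsample). Recovery rates on simulated data therefore speak
to the *rule logic* under truncation and contamination, not to every
failure mode of archival material.

# Experiment sizes and a known hard regime

The bundled experiments use 30 cases per status × 200 nuclei for recovery,
a 53-case series for screening, and 40 replicates for the method-contrast
experiment — sizes at which the Monte-Carlo error of the reported rates is
a few percent and a full run stays fast.

One regime is worth understanding quantitatively. Under heavy truncation
(`p_loss` = 0.15) the artifact mass sits right on the lookup's cutoffs:

* a pure normal arm shows deletion-class combinations (mostly `2/1`) in
  ~20% of counted nuclei — exactly at the 20% imbalance cutoff that
  separates normal from imbalanced, so roughly half of such arms are
  called imbalanced by the combination clause;
* a deleted arm at 70% tumor fraction reaches only ~56–57% deletion-class
  nuclei — barely above the 55% cutoff — and falls to the imbalanced
  residual clause when sampling dips below it.

With 200 nuclei per arm, overall arm-status recovery in this regime is
~62–69% (imbalanced arms ≈ 100%, deleted ≈ 65%, normal ≈ 40%), and the
combination+ratio merge cannot rescue the borderline cases because an
imbalanced combination call overrides a deleted or normal ratio call. This
is a property of the 55/20 cutoffs interacting with heavy truncation, not
of the implementation: the same arithmetic reproduces it analytically, and
scored clinical series show the same marginality (deletion-class sums of
~58% in deleted cases). It is precisely the regime in which practice
escalates to deeper manual counts. At the realistic default
`p_loss` = 0.07, recovery at the same depth exceeds 95%; with no noise and
pure clones it is exact.

# Degenerate inputs and tie-breaks, in one place

* `0/0` nuclei: excluded everywhere (numerator and denominator); a table
  consisting only of `0/0` is an error ("no countable nuclei").
* R/G = 0.5 under the grid: deletion (inclusive bound, see above).
* Ratio exactly 0.8 / 1.15: deleted / normal (inclusive lower sides).
* Percentage exactly at a cutoff: *not* deleted (55), *not* imbalanced by
  the override (I), but imbalanced by the residual clause when
  deleted + imbalanced equals the imbalance cutoff.
* Zero green total: ratio undefined → `UNDETERMINED` (ratio-bearing
  methods only).
* Constant combination frequency in screening: no information, p = 1.
* Both raters constant and identical in `cohens_kappa()`: κ = 1 (the
  chance-agreement denominator vanishes; perfect agreement is returned
  rather than 0/0).
* Contingency tables with a zero margin: rejected with a diagnostic
  rather than silently dropping the empty category.

# Limitations

The rule sets encode a specific pair of probe kits and section thickness;
other platforms may need recalibrated cutoffs (`calibrate_ruleset()`) or a
re-screened lookup (`screen_combinations()` on local data). The simulator
validates internal consistency of rules, calibration and screening; it is
not a substitute for validation on an institution's own stained series.
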