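---
title: "Methods: rubisco carboxylation kinetics from CABP titration assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rubisco carboxylation kinetics from CABP titration assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rubiscokin)
```

# The measurement model

Rubisco carboxylation is read out through a coupled enzymatic cascade:
each 3-phosphoglycerate produced by carboxylation is phosphorylated and
reduced at the cost of NADH, two NADH per carboxylation, and NADH absorbs
at 340 nm. With extinction coefficient $\varepsilon_{340} = 6220$
M$^{-1}$cm$^{-1}$ and an optical path of $l = 0.26$ cm in the microplate
well, Beer–Lambert ($A_{340} = \varepsilon_{340}\, l\, c$) converts an
absorbance slope $s$ (A/s) into a carboxylation flux

$$ v \;=\; \frac{\max(0, -s)}{\varepsilon_{340}\, l \cdot 2} $$

in molar per second (reported in nM/s). Catalysis makes $A_{340}$ *fall*;
a rising trace cannot mean catalysis and clamps to zero flux (recorded as
a clamping event).

Active sites are counted by titration with 2-carboxy-D-arabinitol-1,5-
bisphosphate (CABP), a transition-state analog that binds the rubisco
active site essentially irreversibly. Under this tight-binding assumption
a well with CABP concentration $c$ retains $E_\mathrm{eff} = \max(0, E -
c)$ free sites, so measured flux declines linearly in $c$ and hits zero
at $c = E$. Fitting $v = a + b\,c$ over the ladder
$(0, 0, 10, 20, 30, 90)$ nM gives the in-assay active-site concentration
as the x-intercept $E = -a/b$, and the rate per active site is

$$ k_\mathrm{cat} \;=\; \frac{v_0}{E}, \qquad v_0 = \text{mean flux of
the zero-CABP replicates}, $$

in s$^{-1}$ (nM/s over nM). Because $v_0$ and $E$ both scale with lysate
concentration, $k_\mathrm{cat}$ is invariant to dilution — the property
that makes crude-lysate assays quantitative. $v_0$ is taken from the
zero-CABP wells rather than the regression intercept because those wells
measure the uninhibited activity directly; the intercept is also reported
for comparison.

## Initial-slope fitting

The original study reports rates but not its windowing rule, so the rule
here is stated and configurable. Candidate windows must span at least 60 s
and end within the first half of the trace; starts advance by half the
minimum window; widths shrink from the whole search region by halving.
Candidates are visited earliest-start first, widest first, and a window is
accepted when

* its local $R^2 \ge 0.98$ (linearity), and
* its two halves, and its final third versus the whole window, agree on
  the slope within $0.05\,|s| + 4\,\mathrm{SE}$, where the SE uses a read-
  noise estimate from the earliest minimum window.

The second condition exists because $R^2$ alone stays high across the
NADH-depletion breakpoint: a window straddling the plateau onset passes
$R^2 \ge 0.98$ while silently flattening the slope by a few percent.
Using the segments' own residuals for the SE would let the breakpoint
inflate its own allowance, hence the external noise estimate. If no
window passes, the best-$R^2$ window is used and flagged `nonlinear`.

QC flags: `flat` when the whole search region shows no significant
downward trend (judged on the full region, not the selected window —
best-of-many selection biases a local slope away from zero on pure
noise); a flat trace reports zero flux. `depleted` when the trace tail
has lost essentially all of the initial slope and the signal has actually
fallen (NADH or RuBP exhaustion); `short` when no candidate window has
enough points.

## Titration fit and exclusion rule

Points past the equivalence point violate the linear model (flux is
pinned at zero there), and the original analysis is silent on their
handling. Rule adopted: refit iteratively, excluding the largest-CABP
point whenever its predicted flux is $\le 0$, stopping at 3 points;
excluded indices are reported. On the standard ladder this excludes the
90 nM well exactly when sites $< 90$ nM. A non-negative fitted slope
means CABP produced no measurable inhibition — the sample saturated the
assay and is flagged `saturated_needs_dilution` (also flagged whenever
the flux at the top CABP concentration exceeds 80% of $v_0$), mirroring
the bench practice of diluting and re-assaying.

Activity is declared at $k_\mathrm{cat} > 0.5$ s$^{-1}$ (a configurable
default with published provenance). The internal reference standard (the
same rubisco assayed in every batch) is monitored by
`batch_reference_check()`: batches whose reference $k_\mathrm{cat}$
deviates more than 20% from the grand median are flagged, never rescaled.

# The synthetic world

`simulate_titration_series()` is the forward model of the assay: linear
NADH depletion at $2 v$ after a configurable dead time (the coupled
cascade's lag is modeled as dead time, not a kinetic ramp), floored at
zero NADH and at the RuBP-limited plateau, plus Gaussian read noise, on
top of a baseline absorbance. No published raw trace exists to emulate;
this is the simplest model consistent with the assay description, and its
parameters are explicit. Initial NADH is not stated in the protocol;
the default 200 µM keeps $A_{340} \approx 0.32$ (within instrument range
given $\varepsilon l = 1617.2$ A/M) and at least ten minutes of linearity
at typical rates. "2% trace noise" in tests means a read-noise SD equal
to 2% of the catalytic signal of the uninhibited well over the full read
(`trace_noise_sd()`).

`simulate_panel()` draws per-variant rates from group-wise log-normals —
rates are positive and right-skewed — solved from printed (median, IQR):
$\mu = \log(\mathrm{median})$, $\sigma = \log(q_3/q_1)/(2\,z_{0.75})$.
A two-parameter family cannot match median and both quartiles
simultaneously; this choice reproduces the median exactly and the
quartile ratio, with quartiles landing geometrically around the median
(e.g. 8.87/10.83 instead of 8.6/10.5 for the fastest group). The default
`spec_figure2()` panel is the union of the three class-representative
comparison subsets with their published sizes (9/19 trophic, 9/9
carboxysome, 15/19/20 clade; 100 variants total). Where a group's
non-compared labels are not pinned down by the comparison it came from,
biologically coherent values are assigned (e.g. the phototroph slice is
labeled carboxysome-positive β-cyanobacterial); the non-carboxysome
phototroph stratum, for which no median is printed, reuses the printed
chemotroph distribution (2.1 [1.4–4.0] s$^{-1}$) as the nearest stated
slow-group parameterization. These assignments were fixed once, before
any test was run.

What a green test establishes: that the inference machinery recovers
known truth under this stated world — linear kinetics, Gaussian noise,
exact tight binding, log-normal group structure. What it does not: real
lysates add coupled-enzyme lags with curvature, baseline drift,
pipetting error correlated across a ladder, and partially denatured
enzyme; none of these are modeled, and parameter-recovery results here do
not certify performance on such data.

`simulate_sequence_family()` builds protein families by point
substitution from a common root (no indels), with per-site rates solved
so expected ancestor–ancestor identity matches `between_identity`
(accounting for chance re-matches, $(1-q)^2 + q^2/19$) and
member-to-ancestor identity matches `within_identity`.

# Sequence identity and representative selection

Identity is computed from a global Needleman–Wunsch alignment with affine
gaps (Gotoh), scoring match $+1$, mismatch $-1$, and a gap of length $L$
costing $-5 - L$. The denominator is configurable because cluster counts
depend on it: full alignment length (default) or the shorter sequence's
length (the convention of common heuristic clustering tools). Argument
order is canonicalized internally so identity is exactly symmetric even
under score ties. Clustering is exhaustive centroid-greedy — sequences in
descending length (ties by id), each joining the first centroid at or
above the threshold — which is deterministic and order-independent, but
can differ slightly from heuristic tools (word-length filters, accept/
reject shortcuts) on the same data; counts are therefore reported with
the identity convention in the output metadata. Staged selection
(`iterative_select()`) clusters tagged subsets at increasing thresholds
and unions the centroids, de-duplicated, reporting per-stage counts.

# Group statistics

Quartiles use linear interpolation of order statistics (R type 7),
documented because printed IQRs depend on the convention. Mann–Whitney
uses midranks; the exact two-sided p comes from the exact U distribution
(counting recursion) when $n_x n_y \le 400$ and the data are tie-free —
literal enumeration at that size is infeasible and the counting recursion
is mathematically identical — otherwise the normal approximation with tie
and continuity corrections. Kruskal–Wallis applies the standard tie
correction with a $\chi^2_{k-1}$ reference; Dunn's pairwise z uses pooled
midranks with tie correction, adjusted by Holm by default (Bonferroni and
none available) — the original analysis does not state its adjustment.
Comparisons run on active variants only, two-sided throughout. Box
summaries report quartiles and whiskers at the most extreme values within
1.5 IQR. Q10 correction is $r \cdot q_{10}^{(T_t - T_m)/10}$ with
$q_{10} = 2.2$.

# Feature attribution

The feature matrix holds five binary predictors: phototrophy, carboxysome
association, and three mutually exclusive clade indicators. The published
description conflates per-tree and per-split randomization; the reading
adopted is 100 independent 75/25 train/test splits with one depth-3 CART
tree per split (master seed 42), matching the "100 different train-test
splits" of the published figure legend; `trees_per_split` enables a
bagged forest per split instead. No bootstrap or feature subsampling by
default — with five features, subsampling is degenerate. Minimum leaf
size 2 avoids singleton-leaf overfit at depth 3.

Shapley values are exact: all $2^d$ coalitions are enumerated, with the
interventional value function $v(S)$ = mean model prediction over
background rows with the features in $S$ overwritten by the instance's
values. The background is the split's training rows and attributions are
computed on its test rows. Whether the original analysis used
interventional or path-dependent SHAP, and which background, is unstated;
the interventional form was chosen because it satisfies the dummy axiom
exactly (a feature the tree never reads gets $\phi = 0$), and efficiency
($\sum_i \phi_i = f(x) - \bar f_\mathrm{background}$) holds to numerical
precision and is asserted in tests. Reported importance is the mean
|Shapley| over test rows per split, averaged across splits, with the
across-split SD as the error bar.

# Numerical choices and degenerate inputs

* Concentrations are nM and time is seconds everywhere; $k_\mathrm{cat}$
  in s$^{-1}$.
* Negative computed flux clamps to 0 (absorbance drift is not negative
  catalysis); the clamping is recorded.
* Zero-variance responses: a constant trace window counts as perfectly
  linear with slope 0; a constant regression response yields a root-only
  tree; identical pooled samples give p = 1 with a warning.
* Exact Mann–Whitney refuses ties rather than silently approximating.
* Ladders with fewer than 3 usable points, or fewer than 2 distinct CABP
  concentrations, refuse to fit (`poor_fit`).
* All randomness flows from explicit integer seeds; identical seeds give
  byte-identical outputs, and derived seeds stay below $2^{31}$.

# Known limitations

* The coupled cascade is not modeled mechanistically; lag is a dead time.
* CABP binding is treated as instantaneous and complete; slow-binding
  kinetics near the equivalence point are not represented.
* The clustering is exhaustive ($O(n^2)$ alignments at worst); it is
  meant for hundreds of sequences, not the tens of thousands a heuristic
  tool handles.
* Power at the published clade parameterization is ~95% for the
  α-vs-β Dunn comparison at $p < 0.001$ — decisive but not certain;
  single-panel significance claims should not be over-read.
* Only carboxylation rate is inferred: no $K_M$, oxygenation, or
  specificity — the assay runs near-saturating CO$_2$.
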