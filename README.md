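# rubiscokin

Inference of per-active-site carboxylation rates (k<sub>cat,C</sub>) for
form I rubiscos from high-throughput, NADH-coupled plate-reader assays —
plus the comparative statistics and feature-attribution analyses such a
kinetic survey feeds.

## Who this is for

Enzyme kineticists and comparative biochemists running (or re-analyzing)
spectrophotometric rubisco assays in microplates: crude-lysate samples,
a CABP titration ladder per sample, hundreds of samples per study. The
package turns raw A340 traces into rates per active site with QC, selects
representative variants from sequence collections by identity clustering,
compares rate distributions across biological groups non-parametrically,
and attributes rate variation to binary biological features with exact
Shapley values. A synthetic-data generator with known ground truth makes
every stage testable without instrument data.

## The model

**Trace → flux.** Carboxylation of RuBP is coupled enzymatically to NADH
oxidation (2 NADH per carboxylation), read as declining absorbance at
340 nm. By Beer–Lambert, A<sub>340</sub> = ε<sub>340</sub>·l·c with
ε<sub>340</sub> = 6220 M⁻¹cm⁻¹ and path length l = 0.26 cm, so an initial
slope s (A/s) converts to a carboxylation flux

&nbsp;&nbsp;&nbsp;&nbsp;v = max(0, −s) / (ε<sub>340</sub>·l) / 2&nbsp;&nbsp;[M/s, reported in nM/s].

The initial slope comes from the earliest linear window of the trace
(minimum 60 s, local R² ≥ 0.98, plus a breakpoint check), with QC flags
for flat, nonlinear, and NADH/RuBP-depleted traces.

**Titration → k_cat.** CABP binds rubisco active sites essentially
irreversibly, so flux declines linearly with CABP concentration and
reaches zero at the active-site concentration: fitting v = a + b·c over
the ladder (0, 0, 10, 20, 30, 90 nM CABP) gives sites = −a/b (x-intercept;
points past the equivalence point are excluded iteratively). Then

&nbsp;&nbsp;&nbsp;&nbsp;k<sub>cat</sub> = v₀ / [sites],&nbsp;&nbsp;v₀ = mean zero-CABP flux,

in s⁻¹, invariant to lysate dilution. Samples with k<sub>cat</sub> >
0.5 s⁻¹ count as active; an internal reference standard tracks batch
drift. Rates measured at other temperatures are normalized with
`q10_correct()` (Q10 = 2.2 by default).

**Downstream.** `greedy_cluster()` / `iterative_select()` pick
representative variants by global-alignment identity (Needleman–Wunsch,
affine gaps, compiled); `compare_figure2()` runs Mann–Whitney (trophic
mode, carboxysome association) and Kruskal–Wallis + Dunn (clades) on
class-representative subsets; `importance_report()` fits depth-3
regression trees over 100 random 75/25 train/test splits and computes
exact (interventional) Shapley attributions for each feature.

## Worked example

```r
library(rubiscokin)

ac <- assay_constants()              # published assay conditions
truth <- truth_record("Synechococcus_like", kcat_true = 9.5,
                      site_conc_true = 45, noise_sd = 0.002)
series <- simulate_titration_series(truth, ac, seed = 101)
compute_kcat(series)
#> kinetic_result Synechococcus_like: v0 = 426 nM/s, sites = 45.1 nM, kcat = 9.45 s^-1 (active)
#>   qc: excluded_points:6
```

v₀ = 426 nM/s is the mean uninhibited flux, 45.1 nM the titrated
active-site concentration (the fully inhibited 90 nM point was excluded
from the line fit), and 9.45 s⁻¹ the recovered rate per active site —
within noise of the 9.5 s⁻¹ ground truth, and "active" because it exceeds
0.5 s⁻¹.

```r
pan <- simulate_panel(spec_figure2(), seed = 101)   # 100-variant synthetic survey
cmp <- compare_figure2(pan$panel)
#> carboxysome: 8.7 vs 1.6 s^-1 (fold 5.5, Mann-Whitney p = 8.2e-05)

fm <- build_feature_matrix(pan$panel)
splits <- fit_forest_over_splits(fm$X, fm$y, n_splits = 100, seed = 42)
importance_report(splits, fm$X, fm$y)
#>                 feature mean_abs_shap         sd rank
#> 1           carboxysome     2.2639320 0.18099505    1
#> 2        is_alpha_cyano     0.4971780 0.22210587    2
#> 3 trophic_mode_is_photo     0.2875744 0.09671702    3
#> 4         is_beta_cyano     0.1199346 0.28954361    4
#> 5         is_ccm_proteo     0.0000000 0.00000000    5
```

Carboxysome-associated variants run ~5.5-fold faster than their
counterparts in this panel, and carboxysome association dominates the
Shapley importances (mean |φ| in s⁻¹), followed by α-cyanobacterial
membership — the qualitative structure the generator was parameterized
to carry.

## Command line

```sh
inst/cli/rubiscokin simulate-plate --seed 3 --kcat 2 --sites 40 --out plate.csv
inst/cli/rubiscokin fit-kinetics  --traces plate.csv --out kinetics.tsv
inst/cli/rubiscokin simulate-panel --seed 4 --out panel.tsv
inst/cli/rubiscokin compare-groups --panel panel.tsv --out comparisons.json
inst/cli/rubiscokin attribute --panel panel.tsv --splits 100 --out shap.json
inst/cli/rubiscokin run --config config.json
```

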