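# clc4quant

Quantitative analysis of disease-associated **ClC-4** Cl⁻/H⁺ exchanger
variants, for electrophysiologists and cell biologists characterizing
CLC-family transporters. Missense variants of ClC-4 linked to X-linked
intellectual disability and epilepsy change transport amplitude, the
voltage dependence of activation, transport efficiency, trafficking and
heterodimerization with ClC-3. This package implements the full analysis
chain used to quantify those changes, paired with a synthetic-data
generator with known ground truth so that every estimator is validated by
parameter recovery — no external data required.

## What it computes

From whole-cell voltage-step recordings (10 ms pulses, −115…+175 mV from a
0 mV holding potential, 100 kHz sampling):

- **P/8 leak subtraction** — scaled subpulses from a −30 mV baseline cancel
  linear leak and capacitance transients, preserving nonlinear gating and
  transport currents (`p8_subtract()`);
- **steady-state I–V** and **off-gating charge** Q_off, the integral of the
  capacitive tail current at repolarization (`build_iv()`);
- **Boltzmann activation fits** of the Q–V curve,
  Q(V) = q_max·[s(V) − s(0)] with s(V) = 1/(1 + exp(−(V − V₀.₅)/k)),
  giving the activation midpoint V₀.₅ (`fit_boltzmann()`);
- **Q_off/current ratio** ρ (an inverse transport-efficiency measure) and
  the derived **transport activity**, normalized Q_off divided by ρ
  (`qoff_current_ratio()`, `transport_activity()`);
- **slope factors** — expression-normalized current amplitudes from linear
  fits of current vs whole-cell fluorescence (`fluorescence_slope()`).

From imaging and biochemistry:

- **Manders colocalization** (overlap coefficient R plus M1/M2) with Otsu
  thresholding and background subtraction (`manders_overlap()`);
- **gel densitometry** — baseline-corrected band quantification in
  molecular-weight ROIs, glycosylated-fraction and heterodimer-fraction
  statistics (`quantify_roi()`, `glycosylation_fraction()`,
  `heterodimer_fraction()`);
- **group statistics** — Shapiro–Wilk/Levene assumption gates, then
  one-way ANOVA with Tukey HSD vs WT or pairwise Mann–Whitney
  (`compare_groups()`).

The simulator (`simulate_cell()`, `simulate_cohort()`,
`synth_image_pair()`, `synth_gel_lane()`) generates all three data types
under the study conditions, with per-cell lognormal expression linked to a
fluorescence readout and every ground-truth parameter stored alongside the
traces. See the methods vignette
(`vignettes/clc4-variant-analysis.Rmd`) for the model, estimator choices
and their rationale.

## Worked example

```r
library(clc4quant)

# one wild-type cell under the study protocol
rec <- simulate_cell(clc4_variants()$WT, protocol_spec(),
                     cell_passive_spec(), seed = 1)
a <- analyze_recording(rec)
a$fit
#> Boltzmann fit (holding-referenced, 0 mV): q_max = 0.4534 pC,
#>   V0.5 = 72.16 mV, k = 24.37 mV (n = 19)
round(a$metrics[, c("v_half", "k", "rho", "i_ss_max")], 3)
#>   v_half      k   rho i_ss_max
#> 1 72.159 24.369 0.149     2.87
```

This cell's fitted midpoint (72.2 mV) scatters around the configured WT
value of 75 mV with the expected few-millivolt single-cell noise; ρ = 0.149
pC/nA recovers the designed 0.15 within 1%. At the cohort level the
scatter averages out:

```r
co <- simulate_cohort(clc4_variants()$WT, 14, protocol_spec(),
                      cell_passive_spec(), seed = 7001)
s <- analyze_cohort(co)$summary
round(s[, c("n", "n_qv", "v_half_mean", "v_half_sem", "rho_mean")], 3)
#>     n n_qv v_half_mean v_half_sem rho_mean
#> WT 14   14      74.698      0.835    0.146
```

i.e. a 14-cell cohort recovers V₀.₅ = 74.7 ± 0.8 mV (mean ± s.e.m.)
against the configured 75 mV.

## The analysis workflow

Numbered drivers under `analysis/` rerun the whole study-scale analysis
and write tidy tables to `results/`:

| script | what it does |
|---|---|
| `01_simulate_cohorts.R` | simulate the 13 full-length + 4 chimeric variant cohorts, run the trace pipeline per cell |
| `02_activation_analysis.R` | cohort V₀.₅ recovery and variant activation shifts |
| `03_expression_normalized_currents.R` | slope factors; WT vs linker-chimera doubling |
| `04_colocalization.R` | calibrated 11-image cohort, Manders coefficients |
| `05_densitometry.R` | glycosylated- and heterodimer-fraction recovery |
| `06_group_statistics.R` | assumption-gated comparisons vs WT with stars |

Run them in order with `Rscript analysis/01_simulate_cohorts.R`, etc.

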