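---
title: "Quantifying ClC-4 variant function: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ClC-4 variant function: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(clc4quant)
```

ClC-4 is an endosomal 2Cl⁻/1H⁺ exchanger whose disease-associated missense
variants alter transport amplitude, voltage dependence of activation,
transport efficiency, trafficking and heterodimerization with ClC-3.
`clc4quant` re-implements the quantitative analyses used to characterize
such variants — whole-cell current processing with P/8 leak subtraction,
off-gating charge (Q_off) integration, Boltzmann activation fits (V0.5),
Q_off/current ratios and the derived "transport activity" statistic,
expression-normalized current slopes, Manders colocalization and gel
densitometry, and the assumption-gated group statistics — together with a
synthetic-data generator that emulates the recordings, images and gel lanes
with known ground truth. Every stage is therefore testable by parameter
recovery without any external data.

## The whole-cell simulator

Each simulated cell responds to the standard step protocol (10 ms test
pulses from −115 to +175 mV in 10 mV increments, holding 0 mV, 100 kHz
sampling, 20 ms tail) with the sum of:

* a **transport current** $I(V,t) = I_{max}\, p(t)\, r(V)$, with the
  activation gate's steady state
  $p_\infty(V) = \left[1 + e^{-(V - V_{0.5})/k}\right]^{-1}$ and a strong
  outward rectifier $r(V) = \left[1 + e^{-V/v_r}\right]^{-1}$
  ($v_r = 5$ mV). $I_{max} = i_{density}\cdot e \cdot s \cdot c$ combines
  the maximal current density (40 nA per unit expression), the variant's
  relative expression $e$, its surface fraction $s$, and a per-cell
  lognormal expression factor $c$ ($\sigma_{\ln} = 0.5$). At the 0 mV
  holding potential the transport current is zero: holding sits at the
  anion reversal potential under the near-symmetric chloride solutions
  emulated here.
* **gating (capacitive) currents** $I_g = Q_{max}\, dp/dt$, so on- and
  off-gating charge are conservative by construction. The off charge
  released on repolarization after full activation at prepulse $V$ is
  $Q_{off}(V) = Q_{max}\left[p_\infty(V) - p_\infty(0)\right]$.
* **linear components** the P/8 procedure exists to cancel: ohmic leak
  (1 nS), a membrane-capacitance transient (15 pF charged through 2 MΩ of
  residual series resistance, emulating 80–85% compensation), and white
  Gaussian recording noise (15 pA per sample at 100 kHz; scale as
  $\sqrt{f_s}$ if you change the sampling rate, since physical noise has a
  fixed spectral density).

The gate relaxes exponentially with a voltage-dependent time constant
$\tau(V) = \tau_0\!\left[1 + e^{-(V + 15)/3}\right]$, $\tau_0 = 0.5$ ms:
about 0.5 ms at and above 0 mV — so the 10 ms pulse fully activates and the
tail captures >99.9% of the off charge — and effectively frozen below about
−30 mV. The freezing is what makes an *honest* P/8 test possible: the
subpulses are really simulated and really subtracted, and they leave gating
charge immobile, which is precisely the experimental rationale for placing
the P/8 baseline at −30 mV. With voltage-independent kinetics the
subpulses would themselves move several percent of $Q_{max}$ and no
subtraction scheme could recover charges to the 1% level the tests demand.

`Q_max` is set per cell so that $Q_{off}/I_{ss}$ at the variant's reference
prepulse (+135 mV full-length, +95 mV chimeras) equals the configured
`rho_ref`. Fluorescence is `fluor_gain * e * c + fluor_bg` — exact, so the
current–fluorescence relation is linear by construction and the slope
factor estimand is known.

### The variant panel

Activation midpoints in `clc4_variants()` are the published per-variant
values (WT 75.0, D15N 77.0, V275M 64.0, V536M 112.0, G544R 89.2,
R718W 80.0 mV; chimeric WT 72.0, V212G 51.2, L221V 27.8, G731R 70.0 mV).
The Boltzmann slope is never printed, so all variants default to
$k = 25$ mV, a typical order of magnitude for CLC gating-charge curves.
`rho_ref` values appear only as bar graphs in the source figures; the
defaults (0.15 pC/nA for WT-like, 0.30 for the reduced-efficiency variants
V275M/G544R/R718W, 0.25 for the chimeric V212G/L221V) are *designed* values
respecting the printed rank statements, not measurements. Loss-of-function
variants (G78S, L221P, L221V, S534L, A555V) keep the WT midpoint but get
surface fractions of 0.5–1%, which pushes their currents to the noise floor
so that downstream metrics are flagged undefined — the analysis then
reports "ND" for them, as the study does. Chimeras double the WT surface
fraction (0.2 vs 0.1), reflecting the ER-retention signal removed by the
inter-CBS linker swap.

## Trace processing

**P/8 subtraction.** Subpulses are delivered *hyperpolarizing* from the
−30 mV baseline (amplitude $-|\Delta V|/8$) and the averaged response is
scaled by the sign-matched amplitude ratio ($\mp 8$) before sample-wise
subtraction; depolarizing subpulses would climb into the activation range.
Each sweep is first baseline-corrected by its pre-pulse segment. Linear
components cancel exactly in the noise-free limit; subtraction noise is
$3\times$ the single-sweep noise ($\sqrt{1 + 64/8}$).

**Steady state** is the mean over the last 2 ms of the pulse (the gate
settles within ~3 time constants; the source never states its window).

**Off charge** is the trapezoidal integral of the tail at native sampling
over 0–10 ms after repolarization, minus a baseline estimated from the
second half of the tail. Three choices matter. The window starts at 0 ms
because P/8 subtraction already cancels the capacitance transient — a guard
interval of even 0.1 ms would discard $1 - e^{-0.2} \approx 18\%$ of a
0.5 ms tail. The baseline window (10–20 ms) begins more than fifteen
off-relaxation time constants after repolarization, so it is bias-free, and
its length halves the baseline-noise contribution to each charge point
relative to a short window. The Q–V analysis uses the *signed* convention
(inward tail charge positive); the magnitude convention is the default of
`integrate_qoff()` for direct use.

## Transport metrics

**Boltzmann fits.** The pipeline fits the holding-referenced form
$Q(V) = q_{max}\left[s(V) - s(0)\right]$ (with $s$ the Boltzmann), because
off charge measured from a 0 mV holding potential is referenced to the
gate's resting position. For WT the difference from the plain three-
parameter Boltzmann is negligible ($s(0) \approx 0.05$), but for the
chimeric L221V ($V_{0.5} = 27.8$ mV, $s(0) \approx 0.25$) the plain form is
misspecified and biases the midpoint by several millivolts. The fit is
restricted to prepulses ≥ −10 mV: below that the hyperpolarized gate is too
slow to equilibrate within 10 ms, so those points carry no activation
information. Starting values come from the data (midpoint from
half-maximal charge, $k$ from the 10–90% rise span divided by $2\ln 9$);
optimization is Levenberg–Marquardt with a multi-start Nelder–Mead
fallback. A dedicated test checks the objective never exceeds a dense
grid-search oracle.

**Per-cell quality control.** Cells whose steady transport current at the
reference prepulse is below 1 nA are flagged (`qv_ok = FALSE`) and excluded
from cohort V0.5/k statistics. Dim cells give heavy-tailed midpoint
estimates (occasional 30 mV outliers) that bias cohort means by about 1 mV.
The criterion is an expression proxy measured independently of the Q–V fit;
gating on a fit-derived signal-to-noise ratio instead *selects on fit
noise* and introduces its own bias — we measured +1.4 mV. This mirrors
routine practice: activation is analyzed in fewer cells than are recorded.

**Ratios and transport activity.** $\rho = Q_{off}/I_{ss}$ at the
reference prepulse, flagged undefined below a 0.05 nA noise floor
(loss-of-function cells). Transport activity is the normalized Q–V curve
divided by $\rho$, masked where normalized charge is below 0.05; it is
independent of absolute expression by construction, and the identity suite
checks exact inverse scaling in $\rho$. Normalization uses the per-cell
fitted $q_{max}$ (values may exceed 1 under noise; they are not clipped).

**Slope factors** are ordinary least squares of per-cell current at
+175 mV on fluorescence, with a *free* intercept: measured fluorescence has
a nonzero background, and forcing the line through the origin would bias
slopes. The intercept is reported for transparency.

## Colocalization

Synthetic image pairs place Gaussian puncta (σ = 2 px) uniformly in a
256×256 field; each channel-1 punctum is duplicated into channel 2 with
probability `overlap_prob` (independent amplitude), channel 2 gains 15
puncta of its own, and both channels receive a constant background (10
a.u.) and Gaussian noise (4 a.u.). The measurement pipeline is Otsu
thresholding per channel followed by Manders coefficients over the
foreground: the scalar overlap coefficient
$R = \sum c_1 c_2 / \sqrt{\sum c_1^2 \sum c_2^2}$ (the headline value) plus
the split coefficients $M_1, M_2$. Intensities are background-subtracted
(per-channel mean below threshold) before the sums, as in standard
colocalization tools: a background common to both channels otherwise
inflates $R$ — by +0.04 at $R = 0.83$ and +0.12 at $R = 0.6$ in this
generator — and would defeat calibration. The designed coefficient of a
spec is defined by the noise-free oracle (Manders R on the ground-truth
channels), and `calibrate_overlap()` bisects `overlap_prob` against that
oracle; the full noisy pipeline then reproduces the designed value within
±0.05 across the tested range.

## Densitometry

Lanes are baselines plus Gaussian bands on a migration axis calibrated as
$x = a - b\log_{10}(\mathrm{MW})$. Quantification integrates the
baseline-corrected profile over a molecular-weight ROI (the glycosylation
analysis uses 80–140 kDa). The baseline is a morphological opening
(rolling minimum then rolling maximum) of a lightly smoothed profile with a
window of 12× the widest band σ — wide enough to clear a Gaussian band's
~8σ support; a plain 5σ rolling minimum dips under the bands and clips
5–10% of their area, and estimating the baseline on the raw noisy profile
biases it low by the lower noise envelope. Annotated bands inside the ROI
are split at midpoints when well separated, or decomposed by a constrained
Gaussian mixture when overlapping: areas are solved by non-negative linear
least squares inside a bounded optimization over centers (±2σ of the
annotation) and widths (0.8–1.25×). The variable projection keeps heavily
overlapping clusters well conditioned, and the non-negativity constraint
removes the large positive/negative area cancellations with which an
unconstrained mixture fits noise. Fractions (glycosylated/total;
heterodimer/total lane fluorescence) round-trip designed proportions within
2%; a two-band overlapping doublet recovers areas within 5%.

## Group statistics

`compare_groups()` reproduces the testing scheme: Shapiro–Wilk per group
and Levene's test (classic, mean-centered) across groups at α = 0.05; if
all pass, one-way ANOVA with Tukey HSD comparisons against the reference
(WT), otherwise pairwise Mann–Whitney against the reference, with
`*`/`**`/`***` at 0.05/0.01/0.001. No correction is applied beyond Tukey
(the rank-sum branch is uncorrected, as in the source). Undefined metric
values are excluded but counted; the branch taken is logged and
reproducible. A 1000-replicate null calibration keeps the type-I error of
the gated scheme within binomial error of 5%.

## What the generator does and does not emulate

The simulator reproduces the *statistical structure* the analyses consume:
amplitudes, voltage dependences, charge movement, expression scatter,
recording noise, punctate colocalization, band profiles. It does not model
the transport mechanism (no 2:1 coupling stoichiometry, no pH dependence,
no single-transporter stochastics, no kinetic cycle — the capacitive
currents are phenomenological and agnostic about whether they reflect
incomplete transport cycles or gating transitions), series-resistance
voltage errors, cell-to-cell variation in V0.5 (cohort spread comes from
noise and expression, not biology), image aberrations, or gel smile/drift.
Passing recovery tests therefore validates the *estimators* under the
modeled conditions, not the biology of real recordings.

## Problem sizes and reproducibility

Cohort-level checks run at the study's cohort sizes (n = 5–14 cells per
variant; 11 images; full 100 kHz protocol). Property sweeps in the unit
tests use 10–20 kHz sampling with spectral-density-matched noise and 25
replicate cohorts, sizes chosen to exercise the estimators well away from
their asymptotic regime while keeping the default test run fast. All
randomness flows from explicit integer seeds; identical seeds reproduce
cohorts byte-for-byte.

```{r example, eval = FALSE}
# one wild-type cell, end to end
rec <- simulate_cell(clc4_variants()$WT, protocol_spec(),
                     cell_passive_spec(), seed = 1)
a <- analyze_recording(rec)
plot_qv(a$iv, a$fit)
a$metrics[, c("v_half", "k", "rho", "i_ss_max")]
```
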