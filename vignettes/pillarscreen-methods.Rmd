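---
title: "Methods: purity-gated screening and combination scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: purity-gated screening and combination scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pillarscreen)
```

# The problem

Patient-derived cancer cell (PDC) cultures are rarely pure: resected tumors
and malignant ascites carry fibroblasts and other stromal cells into the
culture. In a viability-based drug screen the stromal compartment does not
respond to targeted agents, so a culture with low tumor content can make an
effective drug look inactive. `pillarscreen` implements the analysis chain
for micropillar-chip screens of such cultures: estimate tumor purity from
immunofluorescence, gate screen validity on purity, fit dose-response
curves, and score two-drug combinations against Loewe and Bliss reference
models, with a seeded synthetic-data layer standing in for the scanner and
plate-reader outputs.

# Tumor-purity index and calibration

Carcinoma cells express the epithelial adhesion molecule EpCAM; fibroblasts
express the mesenchymal filament protein vimentin. For a spot with
background-corrected channel intensities $E$ and $V$, the purity index is

$$r = \frac{E}{E + V} \in [0, 1].$$

The index is invariant to a common optical gain on both channels, but not to
*differential* channel gain; an optional per-channel gain correction from
pure-tumor/pure-stroma control spots is supported, and by default indices
are computed from background-corrected intensities as measured.

Calibration regresses the known tumor fraction $f$ of a co-culture titration
panel on $r$ by ordinary least squares, $f = \beta_0 + \beta_1 r$.
Regressing fraction on index (rather than inverting an index-on-fraction
line) makes prediction for unknown samples a direct evaluation of the fitted
coefficients. Predictions are clipped to $[0,1]$ with clipping flagged.

```{r calibration}
panel <- make_mixture_panel(mixture_panel_spec(seed = 1))
fit_calibration(panel$true_fraction,
                purity_index(panel$epcam, panel$vimentin))
```

The screen-validity gate is strict: a sample passes only when predicted
purity exceeds 0.30. The threshold reflects the simulation result below —
under realistic readout noise the tumor subpopulation's IC50 stops being
recoverable somewhere below ~30% tumor content — and is configurable.

# Dose-response model

Normalized viability is `(raw - pos) / (neg - pos)` against the plate's
untreated (negative) and full-kill staurosporine (positive) control means,
capped at 1.5; a plate whose negative controls do not exceed its positive
controls is rejected outright. Monotherapy curves follow the decreasing
four-parameter logistic on $\log_{10}$ dose,

$$v(d) = \text{bottom} + \frac{\text{top} - \text{bottom}}
{1 + 10^{\,s\,(\log_{10} d - \log_{10}\text{ec}_{50})}},$$

fitted by bounded Levenberg-Marquardt least squares with three deterministic
starts (ec50 at the minimum, median and maximum tested dose; best residual
sum wins). Bounds are $0 \le \text{bottom} \le \text{top} \le 1.5$, slope in
$[0.2, 5]$, and ec50 within two decades of the tested range; the bounds act
as weak regularization against the pathological fits that unbounded 4PL
optimization produces on noisy 6-point curves. Zero-dose wells enter the log
axis at (min positive dose)/ratio², the usual pseudo-dose convention.
Constant responses return a flat fit with a censored IC50 rather than an
error.

The reported IC50 is *absolute* — the dose where the fitted curve crosses
viability 0.5, solved in closed form — because the screen's question is
"does the drug kill half the cells", not "where is the curve's midpoint".
When the fitted curve never crosses 0.5, or crosses outside the tested dose
range, the IC50 is censored rather than extrapolated: extrapolated IC50s are
numerically unstable and a resistant profile is a qualitative finding.

When a dose matrix's monotherapy margins are fitted (`fit_margins()`), the
zero-dose margin cell is excluded from the fit: it is the plate's
normalization anchor, and pinning it at a pseudo-dose measurably biases
shallow-slope fits (the pseudo-dose sits where a slope-0.5 curve is still
far from its plateau).

# Two-drug combination scoring

A combination experiment is a checkerboard `dose_matrix` with zero-dose
margins. Three scores are computed.

**Loewe combination index.** With monotherapy absolute IC50s $A$ and $B$,
and $(a, b)$ the combination doses on a fixed-ratio ray at which
interpolated viability is 0.5,

$$\mathrm{CI}_{50} = \frac{a}{A} + \frac{b}{B},$$

with $\mathrm{CI}_{50} < 1$ synergy and $> 1$ antagonism. The default ray is
the equipotency diagonal $b/a = B/A$, the standard checkerboard convention.
Because the printed reading of the boundary is fragile under noise,
classification uses an additivity band: CI in $[0.9, 1.1]$ is called
additive.

*Numerical choice — interpolation scale.* The ray is sampled where it
crosses the tested dose levels of either drug, and viability between samples
is interpolated piecewise-linearly in **logit** viability vs log dose (the
surface itself is interpolated bilinearly on the same scale). A Hill curve
with top 1 and bottom 0 is exactly linear in logit-vs-log-dose, so on a
sham (drug-with-itself) checkerboard this scheme reproduces
$\mathrm{CI}_{50} = 1$ essentially exactly for any Hill slope, whereas
linear interpolation of raw viability on the coarse 3-fold dilution grid is
biased by up to ~5–7% at slopes 0.5 or 3 — enough to misread a sham as
synergistic. No extrapolation beyond the tested doses is performed.

**Bliss excess map.** Expected viability under independence is the product
of the *observed* monotherapy margins, $V_A(a)\,V_B(b)$; excess = expected −
observed, so positive excess is synergy. The summary score is $100 \times$
the mean excess over positive-dose cells; scores above +10 are called
synergy, below −10 antagonism.

**Loewe excess map.** Expected viability solves the implicit Loewe equation
$a/A_v + b/B_v = 1$ per cell from the *fitted* margins (the equation needs
invertible curves), by bisection on the effect level to tolerance $10^{-6}$;
there is no closed form for unequal Hill slopes. The same bisection drives
the synthetic Loewe-additive surface generator, but the scoring path and the
generator are exercised against each other and against closed forms in the
tests, not against themselves alone.

```{r combination}
m <- simulate_dose_matrix(surface_spec(interaction = "boosted", boost = 1))
f <- fit_margins(m)
ci50(m, f$fitA, f$fitB)
```

# Synthetic data: what it emulates, and what it does not

All generators are pure functions of a spec (including its seed), so every
fixture is reproducible and no binary data ships with the package.

- **Mixture panels** emulate co-culture titrations of an EpCAM-high tumor
  line with vimentin-high fibroblasts. Expected channel intensity is the
  fraction-weighted mean of per-population means (defaults: tumor
  EpCAM/vimentin 1000/50, stroma 50/1000 RFU — chosen so each population has
  the same total signal, a reasonable approximation for similarly sized,
  similarly stained cells).
- **Dose matrices** are generated under Loewe-additive, Bliss-independent,
  or "boosted" ground truth; boosting divides both drugs' effective ec50 by
  $(1 + \text{boost})$ inside the combination region only, so the boost sign
  is a known synergy/antagonism ground truth for sign-recovery tests.
- **Mixed-population responses** model tumor cells on a Hill curve over a
  non-responding stromal floor: $v(d) = p\,\mathrm{Hill}(d) + (1 - p)$.
- **Chip scans** render circular spots on a regular grid with Gaussian
  point-spread blur and Poisson shot noise.

Readout noise is multiplicative lognormal with unit mean and a stated CV
(default 5%, triplicate) on every intensity and viability — fluorescence
noise is scale-dependent, which additive Gaussian noise would misrepresent.
Replicate count and dispersion are modelling choices, not measured values.

What the generators do *not* emulate: optical artifacts beyond the Gaussian
blur (vignetting, stitching seams, autofocus failures), cell-level
heterogeneity within a spot, plate-position effects, or drug-interaction
mechanisms beyond a uniform potency shift. Passing tests therefore
demonstrate correctness of the estimators under the stated statistical
model, not robustness to every artifact of real chip scans.

# Minimal detectable purity

At purity $p < 0.5$ a mixed-population curve never crosses viability 0.5,
so the tumor subpopulation's IC50 must be read *through* the fit: the
recovered IC50 is the dose where the fitted curve crosses the tumor
half-kill level $p\,(\text{top}+\text{bottom})/2 + (1 - p)$; for a
full-kill tumor curve the true value of that dose is the tumor ec50. A
purity is declared reliable when the recovered IC50 is defined, inside the
tested range, and within 3-fold of truth in at least 90% of simulation
runs. Censored and non-crossing fits count as failures, which is what makes
very low purities fail: a 1% response amplitude is invisible under 5% noise.

```{r mindetect}
md <- min_detectable_purity(c(0.01, 0.05, 0.1, 0.2, 0.3), n_runs = 10,
                            seed = 3)
md$rates
```

With the default screen design (6-dose 3-fold ladder from 20 µM, triplicate
wells, 5% CV) the sweep over purities 1–90% at 20 runs per purity declares
~10% the smallest reliable purity — comfortably inside the >30% validity
gate, which additionally buys margin for the noise sources the simulation
omits. Problem sizes throughout (20 runs × 8 purities; 200-run IC50
calibration checks; 100-matrix sign-recovery sweeps) were chosen as the
smallest giving stable pass/fail behaviour across seeds.

# Chip layout and image quantification

The default layout models the 532-position micropillar chip as a 19 × 28
logical grid (only the count is physically specified; the grid shape is
configurable) screening 12 compounds on a 6-dose, 3-fold ladder from 20 µM.
Replicates default to filling the chip — 7 per condition plus 28 controls
fills all 532 positions — since HTS chips are printed full. Positions are
labelled `R{row}C{col}`, 1-based, to avoid off-by-one ambiguity in files.

Spot quantification is fixed-grid (positions are known from the layout, so
blob detection would only add failure modes at low signal): the per-spot
summary is the *median* pixel inside the spot disk — robust to up to half
the pixels being debris or saturated — minus the median of a concentric
background annulus, floored at zero. Per-spot annulus background tolerates
illumination gradients that a global background estimate would not.

# Genomic association

Variant tables are filtered with strict inequalities — VAF > 5% *and* > 20
alternate reads for SNVs/indels ("greater than", not "at least"; the other
reading is common enough that the choice is stated); copy-number records
carry no VAF and pass unconditionally. Association of alteration status
with combination synergy scores uses the difference of group medians with a
two-sided, add-one-smoothed permutation p-value (default 1000 shuffles):
PDC panels are far too small for parametric assumptions. With fewer than
two samples per group the result is descriptive only. Across
alteration × combination pairs, Benjamini–Hochberg adjustment is reported
alongside the raw p-values.

# Known limitations

- The calibration line is fitted by OLS of fraction on a noisy index;
  ratio noise in the index leaves an $O(\mathrm{cv}^2)$ attenuation bias in
  the coefficients. At 5% channel CV the bias is ≲0.01 in predicted
  fraction — negligible against the 0.30 gate, but not zero.
- CI50 is defined only when both monotherapy IC50s and the 50% crossing on
  the ray exist; resistant or shallow combinations return an explicit
  `undefined` class rather than a number.
- The summary synergy score (100 × mean excess) is a mean-effect
  convention; it is comparable across combinations scored by this package
  but is not claimed numerically equal to scores from other synergy
  software.
- Purity estimation is image-based only; sequencing-based purity estimators
  are out of scope, as are alignment/variant-calling pipelines upstream of
  the variant table.
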