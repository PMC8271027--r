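---
title: "Models and methods behind pepxkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pepxkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepxkit)
```

pepxkit implements the quantitative analyses used to characterize how the
chaperones tapasin (assayed as an ERp57–tapasin conjugate) and TAPBPR
catalyze peptide exchange on MHC class I molecules. Four assay types are
covered — fluorescence-polarization (FP) exchange kinetics, methyl-CPMG
relaxation dispersion, HSQC intensity-ratio line-broadening analysis with
structure mapping, and thermal-shift melting — and each is paired with a
seeded synthetic generator so that every fitter can be validated against
known ground truth. This vignette explains the models, the defaults and
the design choices.

## FP exchange kinetics

A UV-cleaved peptide–MHC-I complex is mixed with a FITC-labeled
high-affinity peptide; binding raises the polarization of the label over
1–5 h. After subtracting the free-peptide baseline ("dFP"), each well is
fitted with the exponential association model

$$Y(t) = Y_0 - A\,e^{-K t},$$

where $Y_0$ is the plateau, $A$ the amplitude and $K$ the observed
association rate (reported as $K_{on}$). The fit is an unweighted
nonlinear least squares (`minpack.lm::nlsLM`), initialized from the data
($Y_0$ at the maximum, $A$ at the range, $K$ at $\ln 2 / t_{1/2}$) and
multi-started over $K \times \{0.1, 1, 10\}$; the lowest-RSS solution is
kept. Flat traces (range below three times a lag-1-difference noise
estimate) are refused rather than fitted.

Two derived statistics summarize catalysis:

* **fold change** $= \bar K_{cat} / \bar K_{none}$, the ratio of
  replicate-mean rates with and without catalyst;
* **relative catalytic activity**
  $= (\bar K_{mut} - \bar K_{none}) / (\bar K_{WT} - \bar K_{none})$
  for scoop-loop mutants of the catalyst, reported unclamped.

Both are invariant under a common rescaling of all rates, which matters
because the assay's absolute rates depend on unreported instrument and
concentration factors: only the ratios are comparable across studies.
Fold-change uncertainty uses first-order propagation of the replicate
SDs of the two means; whether the published ± values are SDs of ratios
or propagated SDs is not stated anywhere we could check, so propagation
is our documented convention, not an inference about the source assay.
Mutant-versus-WT comparisons use Welch's unequal-variance two-sample
$t$ test (`stats::t.test`) with raw two-sided p-values; no multiplicity
correction is applied.

### Generator and presets

`gen_fp_trace()` simulates
$FP(t) = b + Y_0 - A e^{-K t} + \mathcal N(0, \sigma)$ on an even grid,
together with a matching baseline-only well. `preset_table()` encodes one
preset per (allotype, catalyst) condition whose fold change or relative
activity is published, anchoring all rates to an arbitrary uncatalyzed
rate of $10^{-4}\,\mathrm{s^{-1}}$ and inverting the relative-activity
formula for mutants. Conventions (chosen once; ratios, not scales, are
calibrated): amplitude 150 FP units, baseline 35 FP units, noise SD 2 FP
units, 40 time points, 3 replicates per condition. The measuring window
is per-preset, $t_{end} = \min(5\,\mathrm h, \max(1\,\mathrm h, 6/K))$,
reflecting that fast catalyzed reactions are recorded on shorter windows
within the 1–5 h range — a fixed 5 h grid would leave the rise of a
30-fold-catalyzed reaction sampled by only one or two points.

```{r}
tab <- preset_table()
head(tab[, c("allotype", "catalyst", "k_true", "fold_change",
             "relative_activity")], 8)
```

Qualitative published statements ("no activity", "as efficiently as
wild type") are encoded as exact 0 / 1 presets so the catalog covers
every condition; the quantitative recovery checks use only conditions
with printed numbers.

## CPMG relaxation dispersion

Constant-time CPMG experiments report peak intensities $I(\nu)$ at pulse
frequencies $\nu_{CPMG}$, converted to effective relaxation rates by

$$R_2^{eff}(\nu) = \frac{1}{T_{CPMG}} \ln \frac{I_0}{I(\nu)},$$

with $T_{CPMG} = 40$ ms and the 15-point schedule
(0, 950, 50, 300, 150, 800, 100, 250, 400, 600, 200, 50, 500, 300,
700 Hz). The duplicated points at 50 and 300 Hz give a pooled error
estimate $\sigma = \sqrt{\sum_m \Delta_m^2 / 2m}$ over the $m$ pairs, and
stay in the fit as independent observations.

Exchange between a major and a sparsely populated state in the fast
regime follows the Luz–Meiboom closed form

$$R_2(\nu) = R_{2,0} + \frac{\phi}{k_{ex}}
  \left(1 - \frac{4\nu}{k_{ex}} \tanh\frac{k_{ex}}{4\nu}\right),
  \qquad \phi = p_a p_b \Delta\omega^2 .$$

In this form the populations and the chemical-shift difference are not
separately identifiable — only $\phi$ is — so `fit_two_state()` reports
$(R_{2,0}, k_{ex}, \phi)$ and nothing it cannot determine. The model is
linear in $(R_{2,0}, \phi)$ at fixed $k_{ex}$, so those are profiled
exactly by weighted linear least squares and only $k_{ex}$ is optimized
numerically (`nlminb` on $\log k_{ex}$, bounded to $[1, 10^7]$ 1/s,
multi-started from 200, 1000 and 5000 1/s, $\phi$ clamped at zero when
the unconstrained solution is negative). A flat model $R_2 = R_{2,0}$ is
fitted alongside, and both models' AICc
($\chi^2 + 2p + 2p(p+1)/(n-p-1)$, $\sigma$ treated as known) are
returned; `select_model()` takes the minimum with ties broken toward the
flat model.

A methyl is flagged as *dispersing* when the amplitude — mean $R_2^{eff}$
over the two lowest distinct frequencies minus the mean over the two
highest — exceeds 2 1/s. We read the published "> 2 s⁻¹" criterion as an
amplitude threshold rather than an absolute $R_2^{eff}$ threshold, since
the latter would flag rigid methyls with fast intrinsic relaxation; this
is an interpretation and is configurable. The boundary is strict:
exactly 2 1/s does not flag. The general two-site (Carver–Richards) form,
multiple-quantum-specific equations and global shared-$k_{ex}$ fits are
deliberately out of scope.

## HSQC intensity ratios and structure mapping

Line broadening on chaperone binding is quantified per residue as
$I/I_0$ between a perturbed and a reference TROSY-HSQC peak list, joined
on assignment id. The summary statistics are the mean ratio and $\delta$,
one standard deviation of the ratio distribution over quantified
residues; a residue is *significantly attenuated* when its ratio falls
strictly below $\text{mean} - \delta$. The published rule writes
"average − δ" without defining δ; one SD is our documented reading.
Residues whose reference intensity is zero cannot be quantified and are
excluded from the summary; residues whose perturbed peak vanished get
ratio 0 and are always flagged. Chemical-shift perturbations use the
conventional amide weighting
$\sqrt{\Delta\delta_H^2 + (\Delta\delta_N/5)^2}$.

For visualization, `map_to_bfactor()` writes per-residue values into the
B-factor column of a PDB file: every atom of a mapped residue receives
the value clamped to a display range (0.30–0.70 by default; zero-to-mean
is the other published convention), unmapped residues receive a −1.00
sentinel so viewers can color "unassigned" distinctly. The writer edits
only columns 61–66 of ATOM/HETATM records on the mapped chain and
preserves every other byte of the file, so the read–map–write cycle is
idempotent and verbatim outside the B column; insertion codes on the
mapped chain are refused rather than silently mismatched.

## Thermal shift

Dye-based melt curves (25–95 °C) are fitted with the Boltzmann sigmoid

$$F(T) = F_{min} + \frac{F_{max} - F_{min}}{1 + e^{(T_m - T)/s}}.$$

Real dye curves quench after the transition, so the data are truncated
after the global fluorescence maximum and the rising limb is fitted,
with $T_m$ initialized at the steepest slope. $T_m$ is invariant under
affine rescaling of the fluorescence. Replicates are fitted
independently and averaged; `delta_tm()` reports $T_m$ differences with
propagated standard errors. The generator's paired presets are
calibrated to the published 6 °C stability gap between the two
photo-peptide complexes of B*27:09.

## What the synthetic data do and do not emulate

The generators reproduce the closed-form signal models plus i.i.d.
Gaussian noise, duplicate-frequency replication, and per-condition
replicate structure. They do not emulate photocleavage chemistry,
plate-reader drift or well effects, spectrometer artifacts, peak overlap,
or non-Gaussian intensity noise. Passing the recovery suites therefore
demonstrates that the estimators are correct and well-calibrated under
the stated models — not that the models capture every feature of real
plate-reader or NMR data.

## Numerical choices and problem sizes

* FP fits: unweighted (no weighting is stated for the source assay);
  multi-start protects against half-time misestimation on noisy traces.
* CPMG: profiling the linear parameters reduces the problem to a 1-D
  bounded search, which a 100×100 brute-force grid over
  $(k_{ex}, \phi)$ confirms in the test suite (RSS within 0.1%).
* Degenerate inputs error early with specific messages (flat FP traces,
  melt curves without a transition, profiles missing the reference
  plane, all-negative $R_2^{eff}$).
* Test problem sizes were chosen to exercise the estimators at realistic
  replication: 3 replicates per FP condition (as in the assay), 50
  seeded dispersion profiles for the $k_{ex}$ recovery envelope, 100 for
  model-selection calibration, 144 single-trace fits for the
  $1/\sqrt n$ scaling check.

## Known limitations

* Fast-exchange-only dispersion model; slow/intermediate exchange data
  would bias $k_{ex}$ and $\phi$.
* Fold-change and relative-activity uncertainties use first-order
  propagation, which is optimistic when the uncatalyzed rate is small
  relative to its SD.
* PDB support covers standard fixed-width ATOM/HETATM records on a
  single mapped chain; no mmCIF, no insertion codes.
* Absolute rates, intensities and fluorescence scales in the presets are
  conventions; only ratio- and difference-valued statistics are
  calibrated to published values.
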