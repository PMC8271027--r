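# pepxkit

Quantitative analysis of chaperone-catalyzed peptide exchange on MHC
class I molecules.

MHC-I molecules present peptide antigens at the cell surface; the
ER chaperone tapasin (and its homolog TAPBPR) edits the presented
repertoire by catalyzing the exchange of suboptimal for high-affinity
peptides, with strong allele specificity. Characterizing that catalysis
quantitatively takes four assay types, and pepxkit implements the
analysis for all of them, for structural biologists and biochemists
running these experiments:

* **FP exchange kinetics** — fluorescence-polarization association
  traces are fitted with `Y(t) = Y0 − A·e^(−Kt)`; catalysis is
  summarized as the fold change `K_cat / K_none` and, for catalyst
  scoop-loop mutants, the relative activity
  `(K_mut − K_none) / (K_WT − K_none)`, with Welch tests across
  replicates.
* **Methyl-CPMG relaxation dispersion** — peak intensities become
  effective relaxation rates `R2_eff = ln(I0/I)/T_CPMG`; dispersing
  methyls (amplitude > 2 s⁻¹) are fitted with the two-state
  fast-exchange (Luz–Meiboom) model
  `R2(ν) = R2_0 + (φ/k_ex)(1 − (4ν/k_ex)·tanh(k_ex/4ν))`, with
  duplicate-based error estimates and AICc model selection against a
  no-exchange model.
* **HSQC intensity ratios** — per-residue line broadening `I/I0`
  between paired peak lists, the `mean − δ` attenuation rule, weighted
  amide chemical-shift perturbations, and painting of ratios into the
  B-factor column of a PDB structure for visualization.
* **Thermal shift** — Boltzmann sigmoid fits of dye melt curves for
  `Tm` and `ΔTm` comparisons.

Every assay has a seeded synthetic generator with known ground truth
(`gen_fp_trace()`, `gen_cpmg_profile()`, `gen_peaklist_pair()`,
`gen_melt_curve()`), and `preset_table()` provides FP presets whose
rate *ratios* are calibrated to published fold-change and
relative-activity statistics, so the whole pipeline is testable without
any experimental download.

## Worked example

Simulate the B\*27:05 allotype without catalyst, with wild-type
ERp57–tapasin, and with the L18G scoop-loop mutant (3 replicate wells
each), then fit and summarize:

```r
library(pepxkit)
tab <- preset_table()
presets <- list(get_preset("B*27:05", "none",   tab),
                get_preset("B*27:05", "Tsn-WT", tab),
                get_preset("B*27:05", "L18G",   tab))
fits <- fit_preset_conditions(presets, seed = 1)
summarize_conditions(fits)
```

```
  allotype catalyst n k_on_mean fold_change relative_activity  p_value
1  B*27:05     L18G 3  1.23e-04        1.26             0.053 4.88e-09
2  B*27:05     none 3  9.79e-05        1.00             0.000       NA
3  B*27:05   Tsn-WT 3  5.79e-04        5.92             1.000       NA
```

Read: the wild-type catalyst accelerates exchange about 6-fold on this
allotype, while the L18G mutant retains only ~5% of wild-type activity
(relative activity 0.05, indistinguishable from the ground truth the
preset encodes) — L18 is the catalytically critical loop residue here.
The Welch p-value compares the mutant's replicate rates against
wild type.

The same stages run from the shell through a thin wrapper:

```sh
Rscript inst/cli/pepxkit.R all --seed 17 --out runA
cat runA/report.txt
```

which aggregates fold changes, dispersing methyls, attenuated residues
and Tm values into a single deterministic report (identical seed ⇒
byte-identical report).

## Package layout

* `R/presets.R`, `R/generate.R` — ground-truth presets and generators
* `R/fp-kinetics.R` — association fits, fold changes, activities, Welch
* `R/cpmg.R` — R2_eff conversion, duplicate errors, two-state fits
* `R/hsqc-ratio.R` — peak pairing, I/I0 tables, attenuation flags, CSP
* `R/structmap.R` — verbatim PDB handling and B-factor painting
* `R/thermoshift.R` — Boltzmann melt fits and ΔTm
* `R/io.R`, `R/pipeline.R` — readers/writers, config, pipeline stages
* `vignettes/peptide-exchange-analysis.Rmd` — models, assumptions,
  defaults and limitations
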