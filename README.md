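# prmquant

Quantification of secretory-protein mistargeting by proximity labeling and
parallel reaction monitoring (PRM).

## The problem

Under ER stress, translocation of some secretory proteins is attenuated and
a fraction of the protein is mistargeted to the cytosol (pre-emptive
quality control). A cytosolic peroxidase (APEX2) biotinylates the cytosolic
proteome in a 1-min biotin-phenol pulse; avidin enrichment followed by
targeted PRM then quantifies how much of a model secretory protein
(FLAG-tagged transthyretin) escaped import. The catch: the readout
confounds the *mistargeted fraction* with the *labeling activity* of the
peroxidase, which several drug treatments themselves perturb. `prmquant`
implements the full computational pipeline — target-peptide selection,
transition validation, chromatogram integration, multi-factor
normalization, and fold-change statistics — together with a synthetic-data
generator that encodes the eluate-composition model, so the normalization
behavior is provable.

With labeling activity α_c, mistargeted fraction m_c, abundance a_p and
capture efficiency ε_p, expected eluate signals are
α_c·a_p·ε_p (BP-labeled cytosolic proteins), α_c·m_c·a_p·ε_p (the
secretory analyte), a_p·ε_p (labeling-independent carboxylases/avidin) and
a constant contaminant background; the TIC is their sum. Consequently the
stress/vehicle fold change of the analyte is m_c/m_ref when normalized to
APEX2 (or actin), (α_c/α_ref)·(m_c/m_ref) when normalized to the
labeling-independent factor, and in between for TIC — so the
enzyme/independent ratio diagnoses labeling-activity changes and the
enzyme scheme removes them.

## Worked example

```r
library(prmquant)

cfg <- scenario_pack("decreased", n_replicates = 6, noise_sigma = 0.1, seed = 42)
qt  <- simulate_experiment(cfg)      # peptide areas + per-run TIC
fc  <- rbind(fold_change(qt, "ENZYME"), fold_change(qt, "INDEPENDENT"),
             fold_change(qt, "TIC"), fold_change(qt, "COMPARTMENT"))
summarize_fold_change(fc)
labeling_activity_diagnostic(fc)
```

Running the bundled drivers (`Rscript analysis/04_normalization.R`) prints,
for the three simulated regimes (true mistargeting ratio 2.5 in all three):

```
comparable: fold change (stress vs vehicle) TIC 2.34 | PC 2.35 | actin 2.43 | APEX 2.30 -> diagnostic: comparable (alpha ratio 1.02)
decreased:  fold change (stress vs vehicle) TIC 1.70 | PC 1.17 | actin 2.43 | APEX 2.30 -> diagnostic: decreased (alpha ratio 0.51)
increased:  fold change (stress vs vehicle) TIC 2.89 | PC 4.70 | actin 2.43 | APEX 2.30 -> diagnostic: increased (alpha ratio 2.04)
```

When labeling activity is unchanged, all four normalization schemes agree
near the true 2.5-fold. When it is halved (or doubled) under stress, only
the enzyme (APEX2 auto-labeling) and compartment (actin) schemes still
recover ~2.5; the labeling-independent scheme is dragged down to ~1.2 (or
up to ~4.7), TIC lands in between, and the enzyme/independent disagreement
correctly classifies the regime and estimates the activity ratio
(0.51 vs true 0.5; 2.04 vs true 2.0).

The analysis workflow is a sequence of thin drivers over the package:

| script | what it does | output |
|---|---|---|
| `analysis/01_assay_panel.R` | digests TTR, filters candidates, emits the panel transition list and CV QC summary | `results/transitions.csv`, `results/panel_cv_summary.csv` |
| `analysis/02_simulate_scenarios.R` | simulates the three labeling regimes | `results/quant_*.csv` |
| `analysis/03_chromatogram_quant.R` | emits synthetic chromatograms, re-quantifies them, demonstrates interference rejection | `results/peak_areas_roundtrip.csv`, `results/validation_report.json` |
| `analysis/04_normalization.R` | compares the four normalization schemes and runs the labeling diagnostic | `results/fold_changes.csv`, `results/diagnostic.csv` |
| `analysis/05_statistics.R` | replicate CVs, Welch/Bonferroni tests, method-agreement regression | `results/welch_tests.csv`, ... |

The 20-peptide assay panel (analyte, APEX2, actin, tubulin, GAPDH, HSPA1A,
BiP, avidin, pyruvate carboxylase) with replicate CVs ships as
`assay_panel()`; its raw CVs have median 9.1% (all < 20%) and its
TIC-normalized CVs median 5.8% (all ≤ 14%).

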