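#!/usr/bin/env Rscript
# Normalization-scheme comparison and labeling-activity diagnostic on the
# simulated regimes from 02_simulate_scenarios.R. The enzyme scheme
# (peroxidase auto-labeling) cancels labeling-activity changes; the
# labeling-independent scheme (biotin carboxylase) retains them; TIC sits
# in between; their disagreement classifies the regime.

suppressPackageStartupMessages(library(prmquant))
dir.create("results", showWarnings = FALSE)

all_fc <- list(); all_diag <- list()
for (regime in c("comparable", "decreased", "increased")) {
  cfg <- scenario_pack(regime, n_replicates = 6L, noise_sigma = 0.1,
                       seed = 42L)
  qt <- simulate_experiment(cfg)
  fc <- do.call(rbind, lapply(
    c("TIC", "INDEPENDENT", "COMPARTMENT", "ENZYME"),
    function(sch) fold_change(qt, sch)))
  smry <- summarize_fold_change(fc)
  smry$regime_simulated <- regime
  all_fc[[regime]] <- smry
  d <- labeling_activity_diagnostic(fc)
  d <- d[d$condition == "stress", ]
  d$regime_simulated <- regime
  all_diag[[regime]] <- d
  stress <- smry[smry$condition == "stress", ]
  message(sprintf(
    "%s: fold change (stress vs vehicle) TIC %.2f | PC %.2f | actin %.2f | APEX %.2f -> diagnostic: %s (alpha ratio %.2f)",
    regime,
    stress$fold_change[stress$scheme == "TIC"],
    stress$fold_change[stress$scheme == "INDEPENDENT"],
    stress$fold_change[stress$scheme == "COMPARTMENT"],
    stress$fold_change[stress$scheme == "ENZYME"],
    d$regime, d$alpha_ratio))
}
write.csv(do.call(rbind, all_fc), "results/fold_changes.csv",
          row.names = FALSE)
write.csv(do.call(rbind, all_diag), "results/diagnostic.csv",
          row.names = FALSE)
message("True mistargeting ratio is 2.5 in every regime; only the enzyme ",
        "scheme recovers it when labeling activity shifts.")
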