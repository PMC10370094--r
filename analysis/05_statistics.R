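#!/usr/bin/env Rscript
# Statistics layer: replicate CVs on simulated 8-replicate data, Welch
# tests with Bonferroni correction on fold changes, and method-agreement
# regression between two sum-normalized readouts of the same experiment.

suppressPackageStartupMessages(library(prmquant))
dir.create("results", showWarnings = FALSE)

# -- CV QC on an 8-replicate single-condition acquisition -------------------
cfg <- scenario_pack("comparable", n_replicates = 8L, noise_sigma = 0.1,
                     seed = 11L)
qt <- simulate_experiment(cfg)
veh <- qt[qt$condition == "vehicle", ]
cvs <- rbind(cv_table(veh, "raw"), cv_table(veh, "tic_normalized"))
write.csv(cvs, "results/cv_table.csv", row.names = FALSE)
print(summarize_cv(cvs))

# -- Welch + Bonferroni on enzyme-normalized fold changes -------------------
tests <- list()
for (regime in c("comparable", "decreased", "increased")) {
  cfg <- scenario_pack(regime, n_replicates = 6L, noise_sigma = 0.1,
                       seed = 42L)
  fc <- fold_change(simulate_experiment(cfg), "ENZYME")
  a <- fc$fold_change[fc$condition == "stress"]
  b <- fc$fold_change[fc$condition == "vehicle"]
  # m = 6 planned stressor-vs-vehicle comparisons, as in the study design
  w <- welch_test(a, b, m = 6L)
  tests[[regime]] <- data.frame(
    regime = regime, comparison = "stress vs vehicle",
    mean_fc = mean(a), t = w$t, df = w$df, p = w$p,
    adjusted_p = w$adjusted_p, stars = significance_stars(w$adjusted_p))
}
tests <- do.call(rbind, tests)
write.csv(tests, "results/welch_tests.csv", row.names = FALSE)
print(tests, digits = 3)

# -- method agreement: two readouts of one condition series -----------------
# Simulate six conditions spanning a mistargeting dynamic range, read out
# twice with independent noise (PRM-like and densitometry-like), then
# sum-normalize each readout and regress one on the other.
m_levels <- c(0.01, 0.02, 0.05, 0.08, 0.1, 0.025)
conds <- paste0("cond", seq_along(m_levels))
shares <- function(seed) {
  withr::with_seed(seed, {
    signal <- m_levels * exp(rnorm(length(m_levels), sd = 0.1))
    sum_normalize(signal)
  })
}
prm <- shares(101L); ib <- shares(202L)
fit <- method_agreement(ib, prm)
agreement <- data.frame(condition = conds, ib_share = ib, prm_share = prm)
write.csv(agreement, "results/method_agreement_shares.csv",
          row.names = FALSE)
message(sprintf(
  "PRM vs IB shares: slope %.3f, intercept %.3f, Pearson R^2 %.3f",
  fit$slope, fit$intercept, fit$r_squared))
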