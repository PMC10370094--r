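# Brute-force tryptic digestion: walks the sequence one residue at a time
# and tests every position against the cleavage rule directly. Kept
# deliberately independent of digest_protein()'s implementation.
digest_oracle <- function(sequence) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  peps <- character(0L)
  cur <- ""
  for (i in seq_along(aa)) {
    cur <- paste0(cur, aa[i])
    cleave_here <- FALSE
    if (i < length(aa)) {
      if ((aa[i] == "K" || aa[i] == "R") && aa[i + 1L] != "P")
        cleave_here <- TRUE
    }
    if (cleave_here) {
      peps <- c(peps, cur)
      cur <- ""
    }
  }
  if (nchar(cur) > 0L) peps <- c(peps, cur)
  peps
}

random_protein_seq <- function(len) {
  paste(sample(c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N", "D",
                 "Q", "K", "E", "M", "H", "F", "R", "Y", "W"),
               len, replace = TRUE), collapse = "")
}

# Welch t with Satterthwaite df, written from the textbook formulas.
welch_oracle <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p = p)
}

# Pearson R^2 from the covariance definition, independent of stats::cor.
r_squared_oracle <- function(x, y) {
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  (sxy^2) / (sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Embed a peptide in a clean tryptic context: preceded by ...LAR| (no
# ragged end), followed by A (no P, no ragged end). Synthetic scaffold,
# not a real protein.
synthetic_parent <- function(peptide) {
  paste0("MSTAGELAR", peptide, "ASDLE")
}

# Minimal three-protein scenario for role-formula tests.
tiny_config <- function(alpha = c(vehicle = 1, stress = 0.5),
                        m = c(vehicle = 0.02, stress = 0.05),
                        abund = c(TTR = 10, APEX = 2, PC = 2),
                        eps = c(TTR = 1, APEX = 1, PC = 1),
                        n_replicates = 2L, noise_sigma = 0,
                        background_fraction = 0.2, seed = 1L) {
  proteins <- data.frame(
    protein = c("TTR", "APEX", "PC"),
    role = c("secretory_analyte", "labeled_cytosolic",
             "labeling_independent"),
    norm_role = c("analyte", "apex_factor", "independent_factor"),
    abundance = unname(abund[c("TTR", "APEX", "PC")]),
    capture_efficiency = unname(eps[c("TTR", "APEX", "PC")]),
    stringsAsFactors = FALSE)
  peptides <- data.frame(protein = c("TTR", "APEX", "PC"),
                         peptide = c("AADDTWEPFASGK", "EGLLQLPSDK",
                                     "VVEIAPAAHLDPQLR"),
                         stringsAsFactors = FALSE)
  scenario_config(conditions = names(alpha),
                  reference_condition = names(alpha)[1L],
                  labeling_activity = alpha, mistargeted_fraction = m,
                  proteins = proteins, peptides = peptides,
                  n_replicates = n_replicates, noise_sigma = noise_sigma,
                  background_fraction = background_fraction, seed = seed)
}
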