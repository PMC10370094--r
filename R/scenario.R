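#' Define a synthetic proximity-labeling/PRM experiment
#'
#' Encodes the eluate-composition model for avidin enrichments after
#' cytosolic peroxidase labeling: the eluate mixes biotin-phenol-labeled
#' cytosolic proteins (scaling with per-condition labeling activity
#' `alpha_c`), the mistargeted fraction `m_c` of one secretory analyte
#' (scaling with `alpha_c * m_c`), labeling-independent components
#' (endogenously biotinylated mitochondrial carboxylases, leached avidin),
#' and a constant contaminant background. Peptide-level noise is
#' multiplicative log-normal.
#'
#' @param conditions Character vector of condition labels.
#' @param reference_condition Label of the reference condition (must be in
#'   `conditions`).
#' @param labeling_activity Named positive numeric, per-condition relative
#'   peroxidase labeling yield alpha_c.
#' @param mistargeted_fraction Named numeric in \[0, 1\], per-condition
#'   cytosolic fraction m_c of the secretory analyte.
#' @param proteins data.frame with columns `protein`, `role` (one of
#'   `labeled_cytosolic`, `labeling_independent`, `secretory_analyte`,
#'   `background_contaminant`), `norm_role` (`analyte`, `apex_factor`,
#'   `compartment_factor`, `independent_factor`, or NA), `abundance`
#'   (positive relative input abundance) and `capture_efficiency` ((0, 1]).
#' @param peptides data.frame with columns `protein`, `peptide`; a
#'   protein's expected signal is split equally over its peptides.
#' @param n_replicates Replicate experiments per condition (default 6).
#' @param noise_sigma Standard deviation of the log-normal multiplicative
#'   peptide noise (default 0.1, consistent with raw replicate CVs of
#'   roughly 5-18%).
#' @param background_fraction Fraction of the reference-condition TIC
#'   contributed by unassigned contaminant background (default 0.2);
#'   the background is constant across conditions (labeling-independent).
#' @param seed Integer seed; simulation is deterministic given the config.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(conditions, reference_condition,
                            labeling_activity, mistargeted_fraction,
                            proteins, peptides,
                            n_replicates = 6L, noise_sigma = 0.1,
                            background_fraction = 0.2, seed = 1L) {
  cfg <- structure(list(
    conditions = as.character(conditions),
    reference_condition = reference_condition,
    labeling_activity = labeling_activity,
    mistargeted_fraction = mistargeted_fraction,
    proteins = proteins,
    peptides = peptides,
    n_replicates = as.integer(n_replicates),
    noise_sigma = noise_sigma,
    background_fraction = background_fraction,
    seed = as.integer(seed)), class = "scenario_config")
  validate_scenario(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' Enforces the model invariants: reference condition among the conditions,
#' complete and strictly positive labeling activities, mistargeted
#' fractions in \[0, 1\], exactly one secretory analyte, at least one
#' labeled cytosolic and one labeling-independent protein, peptides mapped
#' to known proteins.
#'
#' @param cfg A `scenario_config` list.
#' @return The config, invisibly; errors describe the first violation.
#' @export
validate_scenario <- function(cfg) {
  with(cfg, {
    if (!reference_condition %in% conditions)
      stop("reference_condition must be one of the conditions")
    if (!all(conditions %in% names(labeling_activity)) ||
        !all(conditions %in% names(mistargeted_fraction)))
      stop("every condition needs a labeling_activity and a mistargeted_fraction")
    if (any(labeling_activity[conditions] <= 0))
      stop("labeling_activity must be strictly positive")
    m <- mistargeted_fraction[conditions]
    if (any(m < 0 | m > 1))
      stop("mistargeted_fraction must lie in [0, 1]")
    roles <- c("labeled_cytosolic", "labeling_independent",
               "secretory_analyte", "background_contaminant")
    if (!all(proteins$role %in% roles))
      stop("unknown protein role(s): ",
           paste(setdiff(proteins$role, roles), collapse = ", "))
    if (sum(proteins$role == "secretory_analyte") != 1L)
      stop("exactly one protein must have role secretory_analyte")
    if (!any(proteins$role == "labeling_independent"))
      stop("at least one labeling_independent protein is required")
    if (!any(proteins$role == "labeled_cytosolic"))
      stop("at least one labeled_cytosolic protein is required")
    if (any(proteins$abundance <= 0))
      stop("abundances must be strictly positive")
    eps <- proteins$capture_efficiency
    if (any(!is.na(eps) & (eps <= 0 | eps > 1)))
      stop("capture_efficiency must lie in (0, 1]")
    if (!all(peptides$protein %in% proteins$protein))
      stop("peptides reference unknown protein(s)")
    if (!all(proteins$protein %in% peptides$protein))
      stop("every protein needs at least one peptide")
    if (n_replicates < 1L) stop("n_replicates must be positive")
    if (noise_sigma < 0) stop("noise_sigma must be nonnegative")
    if (background_fraction < 0 || background_fraction >= 1)
      stop("background_fraction must lie in [0, 1)")
  })
  invisible(cfg)
}

#' Noise-free expected eluate signal of one protein under one condition
#'
#' Role formulas: labeled cytosolic proteins give `alpha_c * a_p * eps_p`;
#' the secretory analyte gives `alpha_c * m_c * a_p * eps_p` (only its
#' mistargeted, hence labelable, fraction is captured); labeling-independent
#' proteins give `a_p * eps_p`; contaminant background gives the constant
#' `a_p`.
#'
#' @param protein Protein label (must appear in `cfg$proteins`).
#' @param condition Condition label.
#' @param cfg A [scenario_config()].
#' @return Nonnegative scalar expected area (protein level, summed over its
#'   peptides).
#' @export
expected_area <- function(protein, condition, cfg) {
  i <- match(protein, cfg$proteins$protein)
  if (is.na(i)) stop("unknown protein: ", protein)
  if (!condition %in% cfg$conditions) stop("unknown condition: ", condition)
  a <- cfg$proteins$abundance[i]
  eps <- cfg$proteins$capture_efficiency[i]
  alpha <- cfg$labeling_activity[[condition]]
  m <- cfg$mistargeted_fraction[[condition]]
  switch(cfg$proteins$role[i],
    labeled_cytosolic = alpha * a * eps,
    secretory_analyte = alpha * m * a * eps,
    labeling_independent = a * eps,
    background_contaminant = a)
}

# Constant unassigned contaminant background, set so that it makes up
# `background_fraction` of the noise-free reference-condition TIC.
scenario_background <- function(cfg) {
  s_ref <- sum(vapply(cfg$proteins$protein, expected_area,
                      numeric(1L), condition = cfg$reference_condition,
                      cfg = cfg))
  f <- cfg$background_fraction
  f / (1 - f) * s_ref
}

#' Simulate a synthetic PRM experiment
#'
#' Draws `n_replicates` runs per condition. Each peptide's area is its
#' noise-free expectation (the parent's [expected_area()] split equally
#' over the parent's peptides) multiplied by `exp(N(0, noise_sigma^2))`.
#' The per-run TIC is the sum of all peptide areas plus the constant
#' contaminant background. Output is bitwise-reproducible for a given
#' config (the global RNG state is left untouched).
#'
#' @param cfg A [scenario_config()].
#' @return data.frame of class `quant_table` with columns `protein`,
#'   `peptide`, `condition`, `replicate`, `area`, `tic`; attributes
#'   `true_alpha`, `true_m`, `background`, `norm_roles` and
#'   `reference_condition` carry the generating parameters.
#' @export
simulate_experiment <- function(cfg) {
  validate_scenario(cfg)
  pep <- cfg$peptides[order(cfg$peptides$protein, cfg$peptides$peptide), ,
                      drop = FALSE]
  n_per <- table(pep$protein)
  grid <- expand.grid(row = seq_len(nrow(pep)),
                      replicate = seq_len(cfg$n_replicates),
                      condition = cfg$conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  exp_prot <- outer(cfg$proteins$protein, cfg$conditions,
                    Vectorize(function(p, cond) expected_area(p, cond, cfg)))
  rownames(exp_prot) <- cfg$proteins$protein
  colnames(exp_prot) <- cfg$conditions
  mu <- exp_prot[cbind(pep$protein[grid$row], grid$condition)] /
    as.numeric(n_per[pep$protein[grid$row]])
  noise <- withr::with_seed(cfg$seed,
    exp(stats::rnorm(nrow(grid), mean = 0, sd = cfg$noise_sigma)))
  area <- mu * noise
  if (any(!is.finite(area))) stop("non-finite simulated area")
  out <- data.frame(
    protein = pep$protein[grid$row],
    peptide = pep$peptide[grid$row],
    condition = grid$condition,
    replicate = grid$replicate,
    area = area,
    stringsAsFactors = FALSE)
  bg <- scenario_background(cfg)
  run_key <- paste(out$condition, out$replicate, sep = "\r")
  run_tot <- rowsum(out$area, run_key)
  out$tic <- run_tot[run_key, 1L] + bg
  roles <- cfg$proteins$norm_role
  names(roles) <- cfg$proteins$protein
  structure(out,
            class = c("quant_table", "data.frame"),
            true_alpha = cfg$labeling_activity[cfg$conditions],
            true_m = cfg$mistargeted_fraction[cfg$conditions],
            background = bg,
            norm_roles = roles,
            reference_condition = cfg$reference_condition)
}

#' Default two-condition scenario packs
#'
#' Builds the three canonical regimes used to probe normalization behavior:
#' `"comparable"` (labeling activity equal across conditions),
#' `"decreased"` (activity halved under stress, as seen with reductant or
#' secretion-blocking treatments) and `"increased"` (activity doubled, as
#' with translocation inhibitors). Each pack has a vehicle reference with
#' mistargeted fraction `m_ref` and a stress condition at `m_factor` times
#' that.
#'
#' @param regime One of `"comparable"`, `"decreased"`, `"increased"`.
#' @param m_ref Reference mistargeted fraction (default 0.02).
#' @param m_factor Fold increase of mistargeting under stress (default 2.5,
#'   the magnitude of thapsigargin-induced pre-emptive quality control).
#' @param n_replicates,noise_sigma,seed Passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
scenario_pack <- function(regime = c("comparable", "decreased", "increased"),
                          m_ref = 0.02, m_factor = 2.5,
                          n_replicates = 6L, noise_sigma = 0.1, seed = 1L) {
  regime <- match.arg(regime)
  alpha_stress <- switch(regime, comparable = 1, decreased = 0.5,
                         increased = 2)
  proteins <- data.frame(
    protein = c("FLAGTTR", "cytAPEX", "ACTB", "PC", "CONTAM"),
    role = c("secretory_analyte", "labeled_cytosolic", "labeled_cytosolic",
             "labeling_independent", "background_contaminant"),
    norm_role = c("analyte", "apex_factor", "compartment_factor",
                  "independent_factor", NA),
    abundance = c(20, 30, 50, 15, 8),
    capture_efficiency = c(0.9, 0.9, 0.8, 0.85, 1),
    stringsAsFactors = FALSE)
  panel <- assay_panel()
  peptides <- panel[panel$protein %in%
                      c("FLAGTTR", "cytAPEX", "ACTB", "PC"),
                    c("protein", "peptide")]
  peptides <- rbind(peptides,
                    data.frame(protein = "CONTAM", peptide = "LLGGSSAGGLR"))
  scenario_config(
    conditions = c("vehicle", "stress"),
    reference_condition = "vehicle",
    labeling_activity = c(vehicle = 1, stress = alpha_stress),
    mistargeted_fraction = c(vehicle = m_ref, stress = m_ref * m_factor),
    proteins = proteins, peptides = peptides,
    n_replicates = n_replicates, noise_sigma = noise_sigma, seed = seed)
}

#' Write a quant table to CSV
#'
#' Columns: protein, peptide, condition, replicate, area, tic.
#'
#' @param qt A `quant_table` (e.g. from [simulate_experiment()]).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_quant_table <- function(qt, path) {
  utils::write.csv(as.data.frame(qt)[, c("protein", "peptide", "condition",
                                         "replicate", "area", "tic")],
                   path, row.names = FALSE)
  invisible(path)
}
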