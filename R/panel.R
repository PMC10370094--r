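#' The assayed PRM peptide panel with replicate CVs
#'
#' Returns the panel of targeted peptides used throughout the package: the
#' secretory analyte (FLAG-tagged transthyretin), the labeling peroxidase
#' (cytosolic APEX2), cytosolic compartment markers (beta/gamma-actin,
#' GAPDH, alpha-tubulin), the labeling-independent mitochondrial biotin
#' carboxylase pyruvate carboxylase (PC), leached avidin, and the stress
#' chaperones HSPA1A and BiP, together with coefficients of variance over
#' 8 technical replicates computed from raw and from TIC-normalized peak
#' areas.
#'
#' @return data.frame with columns `protein`, `peptide`, `charge`,
#'   `cv_raw`, `cv_tic`, `precursor_quant` (TRUE when the precursor ion
#'   chromatogram is used for quantification rather than summed MS2
#'   fragments), `role` (analyte / normalization_factor / qc) and
#'   `bp_labeled` (parent is a biotin-phenol labeling substrate).
#' @export
assay_panel <- function() {
  path <- system.file("extdata", "assay_panel.csv", package = "prmquant",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
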