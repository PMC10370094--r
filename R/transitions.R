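# Monoisotopic residue masses (Da), standard 20 amino acids.
AA_MONO <- c(
  G = 57.02146372, A = 71.03711379, S = 87.03202841, P = 97.05276385,
  V = 99.06841391, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857750,
  K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295)

PROTON_MASS <- 1.00727646688
WATER_MASS <- 18.0105646863

residue_masses <- function(sequence, cys_mod = 57.02146) {
  aa <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(aa), names(AA_MONO))
  if (length(bad) > 0L)
    stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  m <- unname(AA_MONO[aa])
  m[aa == "C"] <- m[aa == "C"] + cys_mod
  m
}

#' Peptide precursor m/z
#'
#' Monoisotopic \[M + zH\]^z+^ m/z with static carbamidomethylation of
#' cysteine (+57.02146 Da) applied by default, matching standard bottom-up
#' sample preparation (iodoacetamide alkylation).
#'
#' @param sequence Peptide sequence.
#' @param charge Positive integer charge state.
#' @param cys_mod Static cysteine mass shift in Da (default carbamidomethyl).
#' @return Precursor m/z (numeric scalar).
#' @export
precursor_mz <- function(sequence, charge, cys_mod = 57.02146) {
  stopifnot(charge >= 1L)
  (sum(residue_masses(sequence, cys_mod)) + WATER_MASS +
     charge * PROTON_MASS) / charge
}

#' Enumerate b/y fragment transitions for a target peptide
#'
#' Computes the precursor m/z and all singly charged b and y fragment ions,
#' retaining those inside the instrument scan range. A transition set needs
#' at least `min_fragments` in-range fragments to be usable for PRM
#' validation (conventionally three).
#'
#' @param sequence Peptide sequence.
#' @param charge Precursor charge state (>= 1; targeted peptides are
#'   typically 2+ or 3+).
#' @param min_fragments Minimum in-range fragments required (default 3).
#' @param mz_range Instrument scan range in m/z (default c(110, 2000)).
#' @param rt Expected retention time in minutes (optional; NA if unknown).
#' @param rt_window Length of the scheduling window in minutes (default 10);
#'   the window is centered on `rt`.
#' @param cys_mod Static cysteine modification mass (Da).
#' @return A list of class `transition_set`: `peptide`, `charge`,
#'   `precursor_mz`, `fragments` (data.frame `ion`, `charge`, `mz`) and
#'   `rt_window` (c(start, end), NA if `rt` missing).
#' @export
enumerate_transitions <- function(sequence, charge, min_fragments = 3L,
                                  mz_range = c(110, 2000), rt = NA_real_,
                                  rt_window = 10, cys_mod = 57.02146) {
  m <- residue_masses(sequence, cys_mod)
  n <- length(m)
  if (n < 2L) stop("peptide too short to fragment")
  b_mz <- cumsum(m)[-n] + PROTON_MASS
  y_mz <- rev(cumsum(rev(m))[-n]) + WATER_MASS + PROTON_MASS
  frags <- data.frame(
    ion = c(paste0("b", seq_len(n - 1L)), paste0("y", (n - 1L):1L)),
    charge = 1L,
    mz = c(b_mz, y_mz),
    stringsAsFactors = FALSE)
  keep <- frags$mz >= mz_range[1L] & frags$mz <= mz_range[2L]
  frags <- frags[keep, , drop = FALSE]
  if (nrow(frags) < min_fragments)
    stop("only ", nrow(frags), " fragment(s) in range for ", sequence,
         "; need at least ", min_fragments)
  rownames(frags) <- NULL
  structure(list(
    peptide = sequence,
    charge = as.integer(charge),
    precursor_mz = precursor_mz(sequence, charge, cys_mod),
    fragments = frags,
    rt_window = if (is.na(rt)) c(NA_real_, NA_real_)
                else c(rt - rt_window / 2, rt + rt_window / 2)),
    class = "transition_set")
}

#' Build a transition list table for a peptide panel
#'
#' Convenience wrapper producing a Skyline-style flat transition list
#' (one row per fragment) for a set of target peptides.
#'
#' @param panel data.frame with columns `protein`, `peptide`, `charge` and
#'   optionally `rt`.
#' @param ... Passed to [enumerate_transitions()].
#' @return data.frame: `protein`, `peptide`, `precursor_mz`, `charge`,
#'   `fragment`, `fragment_mz`, `rt_start`, `rt_end`.
#' @export
transition_list <- function(panel, ...) {
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    rt <- if ("rt" %in% names(panel)) panel$rt[i] else NA_real_
    ts <- enumerate_transitions(panel$peptide[i], panel$charge[i],
                                rt = rt, ...)
    data.frame(
      protein = panel$protein[i],
      peptide = panel$peptide[i],
      precursor_mz = ts$precursor_mz,
      charge = ts$charge,
      fragment = ts$fragments$ion,
      fragment_mz = ts$fragments$mz,
      rt_start = ts$rt_window[1L],
      rt_end = ts$rt_window[2L],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
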