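#' In silico tryptic digestion
#'
#' Cleaves a protein sequence C-terminal to every K or R that is not
#' immediately followed by proline, the classical trypsin specificity used
#' when building targeted-proteomics transition lists. At 0 missed cleavages
#' the returned peptides tile the protein exactly.
#'
#' @param sequence Protein sequence (single string of standard one-letter
#'   amino-acid codes).
#' @param missed_cleavages Maximum number of internal missed cleavage sites
#'   to allow (default 0, i.e. fully tryptic limit peptides only).
#' @return A data.frame with one row per peptide: `peptide`, `start`, `end`
#'   (1-based inclusive coordinates in the protein) and `n_missed`.
#' @examples
#' digest_protein("AAKPLRGGKMNR")   # K3 is followed by P, so not cleaved
#' @export
digest_protein <- function(sequence, missed_cleavages = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            missed_cleavages >= 0L)
  sequence <- toupper(sequence)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(aa), names(AA_MONO))
  if (length(bad) > 0L)
    stop("sequence contains non-standard residue(s): ",
         paste(bad, collapse = ", "))
  n <- length(aa)
  # cleave after position i when aa[i] is K/R and aa[i+1] is not P
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[pmin(cut_after + 1L, n)] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  out <- list()
  for (mc in 0:missed_cleavages) {
    idx <- seq_len(length(starts) - mc)
    if (length(idx) == 0L) next
    s <- starts[idx]
    e <- ends[idx + mc]
    out[[mc + 1L]] <- data.frame(
      peptide = substring(sequence, s, e),
      start = s, end = e, n_missed = mc,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Candidate-peptide filtering for PRM target selection
#'
#' Applies the sequence-level filters used when assembling a PRM panel:
#' length bounds, labile oxidation-prone residues, deamidation-prone motifs,
#' ragged tryptic ends, and sensitivity to peroxidase biotin-phenol labeling
#' (tyrosine in a BP-labeled parent). Flags are reported per peptide;
#' `too_short`, `too_long`, `labile_modification` and `labeling_sensitive`
#' are hard (exclude the peptide), while `ragged_end` and `deamidation_prone`
#' are advisory, since empirically validated panels retain peptides carrying
#' them.
#'
#' @param peptides data.frame with columns `protein`, `peptide`, `start`,
#'   `end` (as produced by [digest_protein()], plus the parent label).
#' @param parents Named character vector of parent protein sequences; names
#'   must cover `peptides$protein`. Supplies the one-residue context needed
#'   for the ragged-end rule.
#' @param bp_labeled Character vector of protein labels whose parents are
#'   biotin-phenol labeled (peroxidase substrates); tyrosine-containing
#'   peptides from these parents are flagged `labeling_sensitive`.
#' @param config List of filter settings: `min_length` (8), `max_length`
#'   (25), `labile_residues` ("M"), `deamidation_motifs` (c("NG", "QG")).
#' @return The input data.frame with one logical column per flag, a `flags`
#'   column (comma-separated flag names) and a `passing` column (no hard
#'   flag set).
#' @export
apply_filters <- function(peptides, parents, bp_labeled = character(),
                          config = list()) {
  cfg <- utils::modifyList(list(
    min_length = 8L, max_length = 25L,
    labile_residues = "M",
    deamidation_motifs = c("NG", "QG")), config)
  req <- c("protein", "peptide", "start", "end")
  if (!all(req %in% names(peptides)))
    stop("peptides must have columns: ", paste(req, collapse = ", "))
  if (!all(peptides$protein %in% names(parents)))
    stop("missing parent sequence for: ",
         paste(setdiff(unique(peptides$protein), names(parents)),
               collapse = ", "))
  pseq <- parents[peptides$protein]
  if (any(substring(pseq, peptides$start, peptides$end) != peptides$peptide))
    stop("peptide does not match its parent subsequence at [start, end]")

  len <- nchar(peptides$peptide)
  flag <- data.frame(
    too_short = len < cfg$min_length,
    too_long = len > cfg$max_length,
    labile_modification = grepl(
      paste0("[", paste(cfg$labile_residues, collapse = ""), "]"),
      peptides$peptide),
    deamidation_prone = Reduce(`|`, lapply(
      cfg$deamidation_motifs, grepl, x = peptides$peptide, fixed = TRUE)))

  # ragged end: the two residues preceding the peptide, or its last residue
  # plus the following residue, are both K/R
  kr <- function(x) !is.na(x) & x %in% c("K", "R")
  res_at <- function(pos) {
    ok <- pos >= 1L & pos <= nchar(pseq)
    out <- rep(NA_character_, length(pos))
    out[ok] <- substring(pseq[ok], pos[ok], pos[ok])
    out
  }
  prev1 <- res_at(peptides$start - 1L)
  prev2 <- res_at(peptides$start - 2L)
  last1 <- substring(peptides$peptide, len, len)
  next1 <- res_at(peptides$end + 1L)
  flag$ragged_end <- (kr(prev1) & kr(prev2)) | (kr(last1) & kr(next1))

  flag$labeling_sensitive <- grepl("Y", peptides$peptide, fixed = TRUE) &
    peptides$protein %in% bp_labeled

  hard <- c("too_short", "too_long", "labile_modification",
            "labeling_sensitive")
  out <- cbind(peptides, flag)
  out$flags <- apply(flag, 1L, function(r)
    paste(names(flag)[as.logical(r)], collapse = ","))
  out$passing <- !Reduce(`|`, flag[hard])
  out
}

#' Proteome-wide uniqueness with class-level grouping
#'
#' A target peptide is unique when every proteome entry containing it as an
#' exact substring belongs to the same protein class as its parent. By
#' default each protein is its own class; supplying `groups` merges
#' paralogues (e.g. cytoplasmic beta/gamma actins as one "actin" class) so
#' that peptides shared only within the class still count as unique.
#'
#' @param peptide Peptide sequence (string).
#' @param proteome Named character vector of protein sequences (e.g. from
#'   [read_fasta()]).
#' @param parent Label of the peptide's parent protein.
#' @param groups Optional named character vector mapping protein label to
#'   class label; proteins absent from it are their own class.
#' @return `"unique"` or `"non_unique"`.
#' @export
check_uniqueness <- function(peptide, proteome, parent, groups = NULL) {
  if (length(proteome) == 0L) stop("empty proteome")
  if (is.null(names(proteome)) || any(!nzchar(names(proteome))))
    stop("proteome entries must be named")
  cls <- function(p) {
    if (!is.null(groups) && p %in% names(groups)) unname(groups[[p]]) else p
  }
  hits <- names(proteome)[grepl(peptide, proteome, fixed = TRUE)]
  parent_class <- cls(parent)
  if (all(vapply(hits, cls, character(1L)) == parent_class))
    "unique" else "non_unique"
}

#' Read a FASTA file into a named character vector
#'
#' Identifiers are taken verbatim up to the first whitespace.
#'
#' @param path Path to a (protein) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}
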