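#' Read chromatograms from an mzML chromatogram list
#'
#' Imports a chromatogram-list mzML file through the mzR/proteowizard
#' parser and returns the traces in the package's tabular layout. The
#' chromatogram ids are carried through verbatim; when an id follows the
#' `protein|peptide|ion_label` convention used by this package's exporters
#' the three fields are split out, otherwise they are left NA and the id
#' retained. The documented tabular CSV format remains the canonical
#' exchange path; this reader exists for interoperability with
#' instrument-side tooling.
#'
#' @param path Path to an mzML file containing a chromatogram list.
#' @return data.frame: `chrom_id`, `protein`, `peptide`, `ion_label`, `rt`
#'   (minutes), `intensity`.
#' @export
read_chromatograms_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package")
  ms <- mzR::openMSfile(path, backend = "pwiz")
  on.exit(mzR::close(ms), add = TRUE)
  hdr <- mzR::chromatogramHeader(ms)
  if (nrow(hdr) == 0L) stop("no chromatograms in ", path)
  out <- lapply(seq_len(nrow(hdr)), function(i) {
    ch <- mzR::chromatogram(ms, i)
    id <- hdr$chromatogramId[i]
    parts <- strsplit(id, "|", fixed = TRUE)[[1L]]
    data.frame(
      chrom_id = id,
      protein = if (length(parts) == 3L) parts[1L] else NA_character_,
      peptide = if (length(parts) == 3L) parts[2L] else NA_character_,
      ion_label = if (length(parts) == 3L) parts[3L] else id,
      rt = ch[, 1L], intensity = ch[, 2L],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
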