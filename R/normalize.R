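norm_roles_of <- function(qt, roles = NULL) {
  if (is.null(roles)) roles <- attr(qt, "norm_roles")
  if (is.null(roles))
    stop("no norm_roles attribute on the quant table; supply `roles`")
  roles
}

scheme_factor_role <- c(TIC = NA, INDEPENDENT = "independent_factor",
                        COMPARTMENT = "compartment_factor",
                        ENZYME = "apex_factor")

#' Normalize analyte peak areas within each run
#'
#' Divides the analyte's summed peptide peak area by a within-run factor
#' signal: the MS1 TIC (`"TIC"`), the summed peptide areas of a
#' labeling-independent biotin carboxylase (`"INDEPENDENT"`, PC-like), of a
#' cytosolic compartment marker (`"COMPARTMENT"`, actin-like), or of the
#' auto-labeled peroxidase itself (`"ENZYME"`, APEX-like). All signals are
#' taken from the same run, so the result is invariant to rescaling a run.
#'
#' @param qt A `quant_table` (columns `protein`, `peptide`, `condition`,
#'   `replicate`, `area`, `tic`), e.g. from [simulate_experiment()] or
#'   [quantify_chromatograms()].
#' @param scheme One of `"TIC"`, `"INDEPENDENT"`, `"COMPARTMENT"`,
#'   `"ENZYME"`.
#' @param roles Named character vector protein -> normalization role
#'   (`analyte`, `apex_factor`, `compartment_factor`, `independent_factor`).
#'   Defaults to the table's `norm_roles` attribute.
#' @param combine How multiple factor peptides are combined: `"sum"`
#'   (default; summed area, robust to no single peptide dominating) or
#'   `"median_ratio"` (median over factor peptides of analyte/peptide
#'   ratios, robust to single-peptide interference).
#' @return data.frame: `condition`, `replicate`, `scheme`, `value`.
#' @export
normalize_areas <- function(qt, scheme = c("TIC", "INDEPENDENT",
                                           "COMPARTMENT", "ENZYME"),
                            roles = NULL, combine = c("sum", "median_ratio")) {
  scheme <- match.arg(scheme)
  combine <- match.arg(combine)
  roles <- norm_roles_of(qt, roles)
  analyte <- names(roles)[!is.na(roles) & roles == "analyte"]
  if (length(analyte) != 1L)
    stop("exactly one protein must carry the analyte role")
  run_key <- paste(qt$condition, qt$replicate, sep = "\r")
  runs <- qt[!duplicated(run_key), c("condition", "replicate")]
  keys <- run_key[!duplicated(run_key)]
  run_id <- paste0(runs$condition, "/rep", runs$replicate)

  sum_by_run <- function(mask) {
    s <- stats::setNames(rep(0, length(keys)), keys)
    if (any(mask)) {
      rs <- rowsum(qt$area[mask], run_key[mask])
      s[rownames(rs)] <- rs[, 1L]
    }
    unname(s)
  }
  a <- sum_by_run(qt$protein == analyte)
  if (scheme == "TIC") {
    fac <- qt$tic[match(keys, run_key)]
    if (any(!is.finite(fac) | fac <= 0))
      stop("zero or missing TIC in run ",
           paste(run_id[!is.finite(fac) | fac <= 0], collapse = ", "))
    value <- a / fac
  } else {
    fprot <- names(roles)[!is.na(roles) &
                            roles == scheme_factor_role[[scheme]]]
    fmask <- qt$protein %in% fprot
    fac <- sum_by_run(fmask)
    if (any(fac <= 0))
      stop("zero or absent ", scheme, " factor signal in run ",
           paste(run_id[fac <= 0], collapse = ", "))
    value <- if (combine == "sum") a / fac else {
      vapply(keys, function(k)
        stats::median(a[match(k, keys)] /
                        qt$area[fmask & run_key == k]), numeric(1L))
    }
  }
  data.frame(condition = runs$condition, replicate = runs$replicate,
             scheme = scheme, value = value, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Sum-normalize signals across conditions within a replicate
#'
#' Within one replicate experiment, divides each condition's value by the
#' sum over all conditions, yielding shares that sum to 1. This is the
#' within-experiment normalization used when comparing methods (e.g. PRM
#' against immunoblot densitometry) on the same condition series.
#'
#' @param values Numeric vector, one value per condition.
#' @return Shares summing to 1.
#' @export
sum_normalize <- function(values) {
  if (length(values) < 2L) stop("need at least 2 conditions")
  s <- sum(values)
  if (!is.finite(s) || s <= 0) stop("sum of values must be positive")
  values / s
}

#' Fold changes versus a reference condition, per paired replicate
#'
#' Normalized values are computed per run under `scheme`, then each
#' condition's value is divided by the reference condition's value from the
#' same replicate experiment (replicates pair runs across conditions).
#' Below-detection analytes (zero area) give fold change 0 with a warning.
#'
#' @inheritParams normalize_areas
#' @param reference Reference condition label; defaults to the table's
#'   `reference_condition` attribute.
#' @return data.frame of class `fold_change_table`: `condition`,
#'   `replicate`, `scheme`, `fold_change` (reference rows equal 1 exactly).
#' @export
fold_change <- function(qt, scheme = c("TIC", "INDEPENDENT", "COMPARTMENT",
                                       "ENZYME"),
                        reference = NULL, roles = NULL,
                        combine = c("sum", "median_ratio")) {
  scheme <- match.arg(scheme)
  if (is.null(reference)) reference <- attr(qt, "reference_condition")
  if (is.null(reference)) stop("no reference condition given")
  nv <- normalize_areas(qt, scheme, roles = roles, combine = combine)
  if (!reference %in% nv$condition)
    stop("reference condition ", reference, " absent from the table")
  ref <- nv[nv$condition == reference, , drop = FALSE]
  idx <- match(nv$replicate, ref$replicate)
  if (anyNA(idx))
    stop("unpaired replicate(s), no reference run: ",
         paste(unique(nv$replicate[is.na(idx)]), collapse = ", "))
  if (any(nv$value == 0))
    warning("zero analyte signal in some run(s); fold change set to 0")
  nv$fold_change <- ifelse(nv$value == 0, 0, nv$value / ref$value[idx])
  out <- nv[, c("condition", "replicate", "scheme", "fold_change")]
  class(out) <- c("fold_change_table", "data.frame")
  out
}

#' Summarize fold changes per condition
#'
#' @param fc A `fold_change_table` (possibly row-bound over schemes).
#' @return data.frame: `condition`, `scheme`, `fold_change` (mean over
#'   replicates), `sem`, `n`.
#' @export
summarize_fold_change <- function(fc) {
  sp <- split(fc, list(fc$condition, fc$scheme), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    condition = d$condition[1L], scheme = d$scheme[1L],
    fold_change = mean(d$fold_change),
    sem = stats::sd(d$fold_change) / sqrt(nrow(d)),
    n = nrow(d), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Labeling-activity diagnostic from scheme disagreement
#'
#' Compares the enzyme-normalized (or compartment-normalized) fold change
#' with the labeling-independent one. Under the eluate-composition model
#' the enzyme scheme cancels labeling activity while the independent scheme
#' retains it, so their ratio estimates `alpha_ref / alpha_c`: a ratio
#' above the equivalence band indicates decreased labeling activity under
#' the condition, below it increased activity, inside it comparable
#' activity.
#'
#' @param fc A `fold_change_table` covering the `ENZYME` (or `COMPARTMENT`)
#'   and `INDEPENDENT` schemes (row-bound).
#' @param band Equivalence band on the ratio (default c(0.8, 1.25)).
#' @return data.frame, one row per condition present in both schemes:
#'   `condition`,
#'   `ratio` (enzyme fc / independent fc), `regime` (`comparable`,
#'   `decreased` or `increased`) and `alpha_ratio` (implied
#'   `alpha_c / alpha_ref`, the reciprocal of `ratio`).
#' @export
labeling_activity_diagnostic <- function(fc, band = c(0.8, 1.25)) {
  smry <- summarize_fold_change(fc)
  enz_scheme <- if ("ENZYME" %in% smry$scheme) "ENZYME" else "COMPARTMENT"
  if (!enz_scheme %in% smry$scheme || !"INDEPENDENT" %in% smry$scheme)
    stop("diagnostic needs ENZYME (or COMPARTMENT) and INDEPENDENT fold changes")
  enz <- smry[smry$scheme == enz_scheme, , drop = FALSE]
  ind <- smry[smry$scheme == "INDEPENDENT", , drop = FALSE]
  conds <- intersect(enz$condition, ind$condition)
  ratio <- enz$fold_change[match(conds, enz$condition)] /
    ind$fold_change[match(conds, ind$condition)]
  regime <- ifelse(ratio > band[2L], "decreased",
                   ifelse(ratio < band[1L], "increased", "comparable"))
  data.frame(condition = conds, ratio = ratio, regime = regime,
             alpha_ratio = 1 / ratio, stringsAsFactors = FALSE)
}
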