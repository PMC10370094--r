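trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Integrate a transition chromatogram over peak boundaries
#'
#' Trapezoidal integration of an intensity trace over `[rt_left, rt_right]`
#' after subtracting a baseline. The default baseline is the straight line
#' between the (interpolated) boundary intensities; baseline-subtracted
#' intensities are floored at zero before integration.
#'
#' @param rt Strictly increasing retention times (minutes).
#' @param intensity Nonnegative, finite intensities (same length).
#' @param rt_left,rt_right Peak boundaries, inside the trace's RT range.
#' @param baseline `"linear"` (default) or `"none"`.
#' @return List with `area` (intensity x minutes) and `apex_rt` (RT of the
#'   maximum raw intensity inside the boundaries).
#' @export
integrate_peak <- function(rt, intensity, rt_left, rt_right,
                           baseline = c("linear", "none")) {
  baseline <- match.arg(baseline)
  stopifnot(length(rt) == length(intensity), all(is.finite(intensity)))
  if (is.unsorted(rt, strictly = TRUE)) stop("rt must be strictly increasing")
  if (rt_left >= rt_right) stop("rt_left must be below rt_right")
  if (rt_left < rt[1L] || rt_right > rt[length(rt)])
    stop("boundaries outside the trace RT range")
  inside <- rt > rt_left & rt < rt_right
  x <- c(rt_left, rt[inside], rt_right)
  y <- c(stats::approx(rt, intensity, rt_left)$y,
         intensity[inside],
         stats::approx(rt, intensity, rt_right)$y)
  if (length(x) < 3L) stop("integration window holds fewer than 3 samples")
  base <- if (baseline == "linear")
    y[1L] + (y[length(y)] - y[1L]) * (x - x[1L]) / (x[length(x)] - x[1L])
  else rep(0, length(x))
  area <- trapz(x, pmax(y - base, 0))
  list(area = area, apex_rt = x[which.max(y)])
}

#' Automatic peak boundaries around an expected retention time
#'
#' Starting from the local apex nearest `expected_rt`, boundaries extend
#' outward until the intensity falls below `min_frac` of the apex intensity
#' or a maximum half-width is reached. Deterministic; a flat-zero
#' neighborhood is reported as not found.
#'
#' @param rt,intensity The trace (as in [integrate_peak()]).
#' @param expected_rt Expected apex retention time (inside the trace).
#' @param min_frac Intensity cutoff as a fraction of the apex (default 0.01).
#' @param max_half_width Maximum boundary distance from the apex in minutes
#'   (default 1.5).
#' @return List with `rt_left`, `rt_right`, `apex_rt` and `found`; when no
#'   nonzero signal lies within `max_half_width` of `expected_rt`, `found`
#'   is FALSE and the boundaries are NA.
#' @export
auto_boundaries <- function(rt, intensity, expected_rt, min_frac = 0.01,
                            max_half_width = 1.5) {
  stopifnot(length(rt) == length(intensity))
  if (expected_rt < rt[1L] || expected_rt > rt[length(rt)])
    stop("expected_rt outside the trace")
  near <- abs(rt - expected_rt) <= max_half_width
  if (!any(near) || all(intensity[near] <= 0))
    return(list(rt_left = NA_real_, rt_right = NA_real_,
                apex_rt = NA_real_, found = FALSE))
  n <- length(intensity)
  is_apex <- intensity > 0 &
    intensity >= c(-Inf, intensity[-n]) &
    intensity >= c(intensity[-1L], -Inf)
  cand <- which(is_apex & near)
  apex <- cand[which.min(abs(rt[cand] - expected_rt))]
  cut <- min_frac * intensity[apex]
  i <- apex
  while (i > 1L && intensity[i - 1L] >= cut &&
         rt[apex] - rt[i - 1L] <= max_half_width) i <- i - 1L
  j <- apex
  while (j < n && intensity[j + 1L] >= cut &&
         rt[j + 1L] - rt[apex] <= max_half_width) j <- j + 1L
  list(rt_left = rt[i], rt_right = rt[j], apex_rt = rt[apex], found = TRUE)
}

# Per-run fragment areas, apexes and shape correlations for one peptide.
# Traces must carry a `run` id column plus ion_label/rt/intensity.
fragment_run_metrics <- function(traces, expected_rt = NULL,
                                 min_frac = 0.01, max_half_width = 1.5) {
  frag_labels <- setdiff(unique(traces$ion_label),
                         c("precursor", "MS1_TIC"))
  runs <- unique(traces$run)
  rows <- list()
  for (rn in runs) {
    tr <- traces[traces$run == rn & traces$ion_label %in% frag_labels, ,
                 drop = FALSE]
    grid <- sort(unique(tr$rt))
    mat <- vapply(frag_labels, function(f) {
      sub <- tr[tr$ion_label == f, , drop = FALSE]
      stats::approx(sub$rt, sub$intensity, grid, yleft = 0,
                    yright = 0)$y
    }, numeric(length(grid)))
    summed <- rowSums(mat)
    erts <- if (is.null(expected_rt)) grid[which.max(summed)] else expected_rt
    bnd <- auto_boundaries(grid, summed, erts, min_frac, max_half_width)
    if (!bnd$found) next
    inside <- grid >= bnd$rt_left & grid <= bnd$rt_right
    for (f in frag_labels) {
      pk <- integrate_peak(grid, mat[, f], bnd$rt_left, bnd$rt_right,
                           baseline = "none")
      cc <- suppressWarnings(stats::cor(mat[inside, f], summed[inside]))
      rows[[length(rows) + 1L]] <- data.frame(
        run = rn, fragment = f, area = pk$area, apex_rt = pk$apex_rt,
        shape_cor = if (is.na(cc)) -Inf else cc,
        rt_left = bnd$rt_left, rt_right = bnd$rt_right,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Validate PRM transitions by co-elution, constant ratio and retention time
#'
#' A fragment ion is accepted as a bona fide product ion of its precursor
#' when, across runs, (a) its chromatographic profile correlates with the
#' summed-fragment profile inside the peak boundaries at least
#' `shape_threshold`, (b) its share of the total fragment area has relative
#' spread (sd/mean) at most `ratio_tolerance`, and (c) its apex stays within
#' `rt_tolerance` minutes of the per-run consensus (median) fragment apex.
#' A peptide is quantifiable when at least `min_fragments` fragments
#' validate.
#'
#' @param traces data.frame of fragment traces for ONE peptide over one or
#'   more runs, with columns `ion_label`, `rt`, `intensity` and either a
#'   `run` column or `condition` + `replicate`. Labels `precursor` and
#'   `MS1_TIC` are ignored.
#' @param shape_threshold Minimum per-run Pearson correlation (default 0.90).
#' @param ratio_tolerance Maximum relative spread of the fragment's area
#'   share across runs (default 0.30).
#' @param rt_tolerance Maximum apex deviation in minutes (default 0.2).
#' @param min_fragments Fragments required for quantifiability (default 3).
#' @param expected_rt Optional expected apex RT used to seed the peak
#'   search; defaults to the apex of the summed-fragment trace per run.
#' @return List with `report` (one row per fragment: `min_cor`,
#'   `share_mean`, `share_spread`, `max_rt_dev`, `validated`), `validated`
#'   (character vector of accepted fragment labels) and `quantifiable`.
#' @export
validate_transitions <- function(traces, shape_threshold = 0.90,
                                 ratio_tolerance = 0.30,
                                 rt_tolerance = 0.2, min_fragments = 3L,
                                 expected_rt = NULL) {
  if (!"run" %in% names(traces)) {
    if (!all(c("condition", "replicate") %in% names(traces)))
      stop("traces need a run column or condition + replicate columns")
    traces$run <- paste(traces$condition, traces$replicate, sep = "/")
  }
  frag_labels <- setdiff(unique(traces$ion_label),
                         c("precursor", "MS1_TIC"))
  if (length(frag_labels) < 3L)
    stop("transition validation needs at least 3 fragment traces, got ",
         length(frag_labels))
  met <- fragment_run_metrics(traces, expected_rt)
  if (is.null(met) || nrow(met) == 0L)
    stop("no integrable fragment signal found")
  tot <- stats::aggregate(area ~ run, met, sum)
  met$share <- met$area / tot$area[match(met$run, tot$run)]
  consensus <- stats::aggregate(apex_rt ~ run, met, stats::median)
  met$rt_dev <- abs(met$apex_rt -
                      consensus$apex_rt[match(met$run, consensus$run)])
  rep_rows <- lapply(split(met, met$fragment), function(d) {
    share_mean <- mean(d$share)
    spread <- if (nrow(d) < 2L || share_mean <= 0) 0 else
      stats::sd(d$share) / share_mean
    data.frame(fragment = d$fragment[1L],
               min_cor = min(d$shape_cor),
               share_mean = share_mean,
               share_spread = spread,
               max_rt_dev = max(d$rt_dev),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rep_rows)
  rownames(report) <- NULL
  report$validated <- report$min_cor >= shape_threshold &
    report$share_spread <= ratio_tolerance &
    report$max_rt_dev <= rt_tolerance
  validated <- report$fragment[report$validated]
  list(report = report, validated = validated,
       quantifiable = length(validated) >= min_fragments)
}

#' Total ion current of a run
#'
#' Area under the MS1 TIC chromatogram. When the traces carry an `MS1_TIC`
#' trace it is integrated directly (no baseline); otherwise the precursor
#' trace integrals are summed. Empty input gives 0.
#'
#' @param traces data.frame of traces for one run (`ion_label`, `rt`,
#'   `intensity`).
#' @return Nonnegative scalar.
#' @export
compute_tic <- function(traces) {
  if (is.null(traces) || nrow(traces) == 0L) return(0)
  if (any(traces$ion_label == "MS1_TIC")) {
    tr <- traces[traces$ion_label == "MS1_TIC", , drop = FALSE]
    return(trapz(tr$rt, tr$intensity))
  }
  prec <- traces[traces$ion_label == "precursor", , drop = FALSE]
  if (nrow(prec) == 0L) return(0)
  key <- interaction(prec$protein, prec$peptide, drop = TRUE)
  sum(vapply(split(prec, key),
             function(d) trapz(d$rt, d$intensity), numeric(1L)))
}

#' Quantify peptides from transition chromatograms
#'
#' Runs the full chromatogram pipeline over emitted (or imported) traces:
#' per peptide, transitions are validated across runs, then each run's peak
#' area is the summed area of the validated fragments (MS2-level
#' quantification) or the integrated precursor trace for peptides listed in
#' `precursor_peptides` (used where the precursor shows little
#' interference). The per-run TIC comes from the MS1 TIC trace.
#'
#' @param traces data.frame from [read_traces()] with columns `condition`,
#'   `replicate`, `protein`, `peptide`, `ion_label`, `rt`, `intensity`.
#' @param precursor_peptides Peptides quantified from the precursor trace
#'   instead of summed validated fragments.
#' @param ... Validation thresholds passed to [validate_transitions()].
#' @return List with `areas` (a `quant_table`-shaped data.frame: `protein`,
#'   `peptide`, `condition`, `replicate`, `area`, `tic`) and `validation`
#'   (per-peptide validation reports).
#' @export
quantify_chromatograms <- function(traces, precursor_peptides = character(),
                                   ...) {
  traces$run <- paste(traces$condition, traces$replicate, sep = "/")
  runs <- unique(traces[, c("condition", "replicate", "run")])
  tics <- vapply(runs$run, function(rn)
    compute_tic(traces[traces$run == rn, , drop = FALSE]), numeric(1L))
  peps <- unique(stats::na.omit(traces[, c("protein", "peptide")]))
  areas <- list(); reports <- list()
  for (i in seq_len(nrow(peps))) {
    sub <- traces[!is.na(traces$peptide) &
                    traces$peptide == peps$peptide[i], , drop = FALSE]
    if (peps$peptide[i] %in% precursor_peptides) {
      per_run <- lapply(split(sub[sub$ion_label == "precursor", ],
                              sub$run[sub$ion_label == "precursor"]),
                        function(d) {
        bnd <- auto_boundaries(d$rt, d$intensity,
                               d$rt[which.max(d$intensity)])
        if (!bnd$found) return(0)
        integrate_peak(d$rt, d$intensity, bnd$rt_left, bnd$rt_right,
                       baseline = "none")$area
      })
      run_area <- unlist(per_run)
    } else {
      val <- validate_transitions(sub, ...)
      reports[[peps$peptide[i]]] <- val
      met <- fragment_run_metrics(sub)
      met <- met[met$fragment %in% val$validated, , drop = FALSE]
      agg <- stats::aggregate(area ~ run, met, sum)
      run_area <- stats::setNames(agg$area, agg$run)
    }
    idx <- match(names(run_area), runs$run)
    areas[[i]] <- data.frame(
      protein = peps$protein[i], peptide = peps$peptide[i],
      condition = runs$condition[idx], replicate = runs$replicate[idx],
      area = unname(run_area), tic = unname(tics[names(run_area)]),
      stringsAsFactors = FALSE)
  }
  list(areas = do.call(rbind, areas), validation = reports)
}
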