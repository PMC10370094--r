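#' Default peak-shape model for synthetic chromatograms
#'
#' Retention times are assigned deterministically, evenly spaced across the
#' usable part of the gradient; all peaks are Gaussian with a common width;
#' fragment intensities are fixed proportions of the peptide's total area.
#'
#' @param peptides Character vector of peptide sequences.
#' @param sigma_t Gaussian peak width (standard deviation) in minutes.
#' @param fragment_props Named or unnamed numeric vector (length >= 3,
#'   summing to 1) of fragment-ion intensity proportions.
#' @param grid_step XIC sampling interval in minutes.
#' @param window_half Half-width of the emitted XIC window in minutes.
#' @param run_span Retention-time range of the whole run, minutes.
#' @param tic_step Sampling interval of the emitted MS1 TIC trace.
#' @return List of peak-model parameters used by [emit_chromatograms()].
#' @export
peak_model <- function(peptides, sigma_t = 0.1,
                       fragment_props = c(f1 = 0.4, f2 = 0.3,
                                          f3 = 0.2, f4 = 0.1),
                       grid_step = 0.01, window_half = 1.2,
                       run_span = c(0, 100), tic_step = 0.1) {
  stopifnot(length(fragment_props) >= 3L,
            abs(sum(fragment_props) - 1) < 1e-9)
  if (is.null(names(fragment_props)))
    names(fragment_props) <- paste0("f", seq_along(fragment_props))
  peptides <- sort(unique(peptides))
  lo <- run_span[1L] + 0.15 * diff(run_span)
  hi <- run_span[1L] + 0.85 * diff(run_span)
  rt <- if (length(peptides) == 1L) (lo + hi) / 2 else
    seq(lo, hi, length.out = length(peptides))
  names(rt) <- peptides
  list(rt = rt, sigma_t = sigma_t, fragment_props = fragment_props,
       grid_step = grid_step, window_half = window_half,
       run_span = run_span, tic_step = tic_step)
}

gaussian_trace <- function(grid, area, mu, sigma) {
  area / (sigma * sqrt(2 * pi)) * exp(-((grid - mu)^2) / (2 * sigma^2))
}

#' Emit synthetic transition chromatograms for simulated runs
#'
#' Writes one tabular trace file per run (columns `condition`, `replicate`,
#' `protein`, `peptide`, `ion_label`, `rt`, `intensity`). Each peptide gets
#' a Gaussian precursor trace whose trapezoidal integral equals the run's
#' simulated peak area, fragment traces sharing the apex and scaled by the
#' model's intensity proportions, and the file carries an `MS1_TIC` trace
#' (sum of all precursor profiles plus a flat contaminant background) whose
#' integral equals the run's TIC. An optional interference injects a
#' co-eluting contaminant Gaussian into one fragment of one run, for
#' exercising transition validation.
#'
#' @param qt A `quant_table` from [simulate_experiment()].
#' @param dir Output directory (created if missing).
#' @param model A [peak_model()]; defaults to one over the table's peptides.
#' @param interference Optional list with elements `peptide`, `fragment`,
#'   `condition`, `replicate`, and optionally `scale` (default 3, the
#'   contaminant's area as a multiple of the affected fragment's) and
#'   `rt_offset` (minutes, default 0 = perfectly co-eluting).
#' @return Invisibly, the written file paths (empty input writes nothing).
#' @export
emit_chromatograms <- function(qt, dir, model = NULL, interference = NULL) {
  if (is.null(qt) || nrow(qt) == 0L) return(invisible(character(0L)))
  if (is.null(model)) model <- peak_model(qt$peptide)
  if (model$sigma_t < 2 * model$grid_step)
    stop("peak width ", model$sigma_t, " min is not representable on a ",
         model$grid_step, " min grid (need sigma_t >= 2 * grid_step)")
  if (!all(qt$peptide %in% names(model$rt)))
    stop("peak model lacks retention times for some peptides")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bg <- attr(qt, "background")
  if (is.null(bg)) bg <- 0
  runs <- unique(qt[, c("condition", "replicate")])
  tic_grid <- seq(model$run_span[1L], model$run_span[2L],
                  by = model$tic_step)
  paths <- character(0L)
  for (r in seq_len(nrow(runs))) {
    cond <- runs$condition[r]; rep_i <- runs$replicate[r]
    sub <- qt[qt$condition == cond & qt$replicate == rep_i, , drop = FALSE]
    blocks <- vector("list", nrow(sub) * (1L + length(model$fragment_props)))
    k <- 0L
    tic_int <- rep(bg / diff(model$run_span), length(tic_grid))
    for (i in seq_len(nrow(sub))) {
      mu <- model$rt[[sub$peptide[i]]]
      grid <- seq(mu - model$window_half, mu + model$window_half,
                  by = model$grid_step)
      prec <- gaussian_trace(grid, sub$area[i], mu, model$sigma_t)
      k <- k + 1L
      blocks[[k]] <- data.frame(
        condition = cond, replicate = rep_i, protein = sub$protein[i],
        peptide = sub$peptide[i], ion_label = "precursor",
        rt = grid, intensity = prec, stringsAsFactors = FALSE)
      tic_int <- tic_int + gaussian_trace(tic_grid, sub$area[i], mu,
                                          model$sigma_t)
      for (f in names(model$fragment_props)) {
        frag_area <- sub$area[i] * model$fragment_props[[f]]
        y <- gaussian_trace(grid, frag_area, mu, model$sigma_t)
        if (!is.null(interference) &&
            identical(interference$peptide, sub$peptide[i]) &&
            identical(interference$fragment, f) &&
            identical(interference$condition, cond) &&
            identical(as.integer(interference$replicate),
                      as.integer(rep_i))) {
          scale <- if (is.null(interference$scale)) 3 else interference$scale
          off <- if (is.null(interference$rt_offset)) 0 else
            interference$rt_offset
          y <- y + gaussian_trace(grid, scale * frag_area, mu + off,
                                  model$sigma_t)
        }
        k <- k + 1L
        blocks[[k]] <- data.frame(
          condition = cond, replicate = rep_i, protein = sub$protein[i],
          peptide = sub$peptide[i], ion_label = f,
          rt = grid, intensity = y, stringsAsFactors = FALSE)
      }
    }
    tic_block <- data.frame(
      condition = cond, replicate = rep_i, protein = NA_character_,
      peptide = NA_character_, ion_label = "MS1_TIC",
      rt = tic_grid, intensity = tic_int, stringsAsFactors = FALSE)
    out <- rbind(do.call(rbind, blocks), tic_block)
    path <- file.path(dir, sprintf("run_%s_rep%02d.csv", cond, rep_i))
    utils::write.csv(out, path, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read tabular trace files
#'
#' @param paths Character vector of trace CSV files written by
#'   [emit_chromatograms()] (or following the same column layout).
#' @return A single data.frame of traces.
#' @export
read_traces <- function(paths) {
  do.call(rbind, lapply(paths, utils::read.csv, stringsAsFactors = FALSE))
}
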