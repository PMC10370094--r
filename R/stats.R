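#' Coefficient of variance over technical replicates
#'
#' `cv = sd / mean` using the sample (n-1) standard deviation. For
#' `basis = "tic_normalized"` each replicate's area is first divided by
#' that run's TIC, removing run-to-run injection and recovery variation.
#'
#' @param areas Numeric vector of replicate peak areas (n >= 2, finite).
#' @param tic Per-replicate TIC values (required for the TIC basis).
#' @param basis `"raw"` or `"tic_normalized"`.
#' @return The CV (dimensionless fraction).
#' @export
compute_cv <- function(areas, tic = NULL,
                       basis = c("raw", "tic_normalized")) {
  basis <- match.arg(basis)
  if (length(areas) < 2L || any(!is.finite(areas)))
    stop("need at least 2 finite replicate areas")
  x <- if (basis == "tic_normalized") {
    if (is.null(tic) || length(tic) != length(areas) ||
        any(!is.finite(tic)) || any(tic <= 0))
      stop("tic_normalized basis needs a positive per-run TIC per replicate")
    areas / tic
  } else areas
  m <- mean(x)
  if (m <= 0) stop("CV undefined: mean is not positive")
  stats::sd(x) / m
}

#' Per-peptide CV table from a quant table
#'
#' @param qt A `quant_table`; CVs are computed per (protein, peptide,
#'   condition) across replicates.
#' @param basis `"raw"` or `"tic_normalized"` (see [compute_cv()]).
#' @return data.frame: `protein`, `peptide`, `condition`, `basis`, `cv`,
#'   `n`.
#' @export
cv_table <- function(qt, basis = c("raw", "tic_normalized")) {
  basis <- match.arg(basis)
  sp <- split(qt, list(qt$protein, qt$peptide, qt$condition), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    protein = d$protein[1L], peptide = d$peptide[1L],
    condition = d$condition[1L], basis = basis,
    cv = compute_cv(d$area, d$tic, basis), n = nrow(d),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Summarize CVs per basis
#'
#' Median (for even counts, the mean of the two central order statistics)
#' and maximum of the CVs, per basis.
#'
#' @param records data.frame with columns `basis` and `cv` (e.g. row-bound
#'   [cv_table()] output, or the assay panel reshaped).
#' @return data.frame: `basis`, `median_cv`, `max_cv`, `n`.
#' @export
summarize_cv <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stop("no CV records")
  sp <- split(records, records$basis)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    basis = d$basis[1L], median_cv = stats::median(d$cv),
    max_cv = max(d$cv), n = nrow(d), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Welch (heteroscedastic) two-sample t-test with Bonferroni correction
#'
#' Two-tailed Welch t-test with Satterthwaite degrees of freedom, as used
#' for comparing fold changes between treatment conditions, with the
#' Bonferroni-adjusted p-value `min(1, m * p)` for `m` planned comparisons.
#' When both groups have zero variance: equal means give `p = 1` (t = 0) by
#' convention, unequal means give `p = 0` (infinite t).
#'
#' @param group_a,group_b Numeric vectors (each n >= 2, finite).
#' @param m Number of comparisons for Bonferroni (default 1 = no
#'   correction); taken from the study design, not inferred from the data.
#' @return List: `t`, `df`, `p`, `m`, `adjusted_p`.
#' @export
welch_test <- function(group_a, group_b, m = 1L) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 observations")
  if (any(!is.finite(c(group_a, group_b)))) stop("non-finite values")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    eq <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    t_stat <- if (eq) 0 else sign(mean(group_a) - mean(group_b)) * Inf
    p <- if (eq) 1 else 0
    df <- length(group_a) + length(group_b) - 2L
  } else {
    ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
    t_stat <- unname(ht$statistic)
    df <- unname(ht$parameter)
    p <- ht$p.value
  }
  list(t = t_stat, df = df, p = p, m = as.integer(m),
       adjusted_p = min(1, m * p))
}

#' Method-agreement statistics (regression and Pearson R-squared)
#'
#' Ordinary least-squares fit of `y` on `x` plus the squared Pearson
#' correlation, as used to compare PRM-derived condition shares with an
#' orthogonal method (immunoblot densitometry).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List: `slope`, `intercept`, `r_squared`.
#' @export
method_agreement <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  if (stats::var(x) == 0) stop("slope undefined: x has zero variance")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = stats::cor(x, y)^2)
}

#' Significance stars for adjusted p-values
#'
#' Standard banding: `""` for adj. p >= 0.05, `*` for \[0.01, 0.05),
#' `**` for \[0.001, 0.01), `***` for \[0.0001, 0.001), `****` below 0.0001.
#'
#' @param adjusted_p Numeric vector of adjusted p-values.
#' @return Character vector of star annotations.
#' @export
significance_stars <- function(adjusted_p) {
  cut_pts <- c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf)
  labs <- c("****", "***", "**", "*", "")
  labs[as.integer(cut(adjusted_p, cut_pts, right = FALSE,
                      labels = FALSE))]
}
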