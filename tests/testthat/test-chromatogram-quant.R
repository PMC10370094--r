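make_gaussian <- function(area, mu, sigma, span = 5, step = sigma / 50) {
  rt <- seq(mu - span * sigma, mu + span * sigma, by = step)
  list(rt = rt,
       intensity = area / (sigma * sqrt(2 * pi)) *
         exp(-((rt - mu)^2) / (2 * sigma^2)))
}

test_that("trapezoidal integration handles rectangles and empty traces", {
  rt <- seq(0, 4, by = 0.5)
  inten <- ifelse(rt >= 1 & rt <= 3, 10, 10)  # flat 10 everywhere
  # a clean rectangle: zero outside, 10 over exactly [1, 3]
  inten <- ifelse(rt > 1 - 1e-9 & rt < 3 + 1e-9, 10, 0)
  pk <- integrate_peak(rt, inten, 1, 3, baseline = "none")
  expect_equal(pk$area, 20)
  zero <- integrate_peak(rt, rep(0, length(rt)), 1, 3, baseline = "none")
  expect_equal(zero$area, 0)
  expect_error(integrate_peak(rt, inten, 3, 1), "rt_left")
  expect_error(integrate_peak(rt, inten, -1, 3), "outside")
})

test_that("Gaussian peaks integrate to the analytic area within 0.5%", {
  for (sigma in c(0.05, 0.1, 0.3)) for (A in c(1, 50)) {
    g <- make_gaussian(A, mu = 10, sigma = sigma)
    pk <- integrate_peak(g$rt, g$intensity, 10 - 5 * sigma, 10 + 5 * sigma,
                         baseline = "none")
    expect_equal(pk$area, A, tolerance = 5e-3)
    expect_equal(pk$apex_rt, 10, tolerance = sigma / 10)
  }
})

test_that("a linear baseline is subtracted and floored at zero", {
  g <- make_gaussian(5, 10, 0.1)
  lifted <- g$intensity + 2  # constant offset
  pk <- integrate_peak(g$rt, lifted, 10 - 0.5, 10 + 0.5)
  # boundaries sit on the offset plateau, so the baseline removes it
  expect_equal(pk$area, 5, tolerance = 6e-3)
})

test_that("integration is linear and monotone in the boundaries", {
  g1 <- make_gaussian(3, 10, 0.1)
  g2 <- make_gaussian(7, 10.2, 0.1, step = 0.1 / 50)
  grid <- g1$rt
  y2 <- stats::approx(g2$rt, g2$intensity, grid, yleft = 0, yright = 0)$y
  a1 <- integrate_peak(grid, g1$intensity, grid[2], max(grid) - 0.01,
                       baseline = "none")$area
  a2 <- integrate_peak(grid, y2, grid[2], max(grid) - 0.01,
                       baseline = "none")$area
  a12 <- integrate_peak(grid, g1$intensity + y2, grid[2],
                        max(grid) - 0.01, baseline = "none")$area
  expect_equal(a12, a1 + a2, tolerance = 1e-12)
  narrow <- integrate_peak(grid, g1$intensity, 9.9, 10.1,
                           baseline = "none")$area
  wide <- integrate_peak(grid, g1$intensity, 9.7, 10.3,
                         baseline = "none")$area
  expect_true(wide >= narrow)
})

test_that("automatic boundaries capture an isolated peak", {
  g <- make_gaussian(8, 20, 0.1)
  bnd <- auto_boundaries(g$rt, g$intensity, expected_rt = 20.05)
  expect_true(bnd$found)
  area <- integrate_peak(g$rt, g$intensity, bnd$rt_left, bnd$rt_right,
                         baseline = "none")$area
  expect_gt(area, 0.99 * 8)
})

test_that("flat-zero traces are reported as not found", {
  rt <- seq(0, 10, 0.1)
  bnd <- auto_boundaries(rt, rep(0, length(rt)), expected_rt = 5)
  expect_false(bnd$found)
  expect_true(is.na(bnd$rt_left))
})

test_that("a second peak 5 minutes away is excluded from the boundaries", {
  rt <- seq(0, 20, 0.01)
  gauss <- function(A, mu) A / (0.1 * sqrt(2 * pi)) *
    exp(-((rt - mu)^2) / (2 * 0.1^2))
  inten <- gauss(4, 8) + gauss(40, 13)
  bnd <- auto_boundaries(rt, inten, expected_rt = 8)
  expect_lt(bnd$rt_right, 10)
  area <- integrate_peak(rt, inten, bnd$rt_left, bnd$rt_right,
                         baseline = "none")$area
  expect_equal(area, 4, tolerance = 0.02)
})

clean_traces <- function(n_runs = 3L, props = c(f1 = 0.4, f2 = 0.3,
                                                f3 = 0.2, f4 = 0.1),
                         area = 10) {
  out <- list()
  for (r in seq_len(n_runs)) {
    for (f in names(props)) {
      g <- make_gaussian(area * props[[f]], 30, 0.1, span = 8)
      out[[length(out) + 1L]] <- data.frame(
        run = paste0("run", r), ion_label = f, rt = g$rt,
        intensity = g$intensity, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

test_that("perfectly co-eluting fragments all validate", {
  tr <- clean_traces()
  val <- validate_transitions(tr)
  expect_setequal(val$validated, c("f1", "f2", "f3", "f4"))
  expect_true(val$quantifiable)
  expect_true(all(val$report$min_cor > 0.999))
})

test_that("exactly three passing fragments keep the peptide quantifiable", {
  tr <- clean_traces(props = c(f1 = 0.5, f2 = 0.3, f3 = 0.2))
  val <- validate_transitions(tr)
  expect_length(val$validated, 3L)
  expect_true(val$quantifiable)
  expect_error(
    validate_transitions(tr[tr$ion_label %in% c("f1", "f2"), ]),
    "at least 3")
})

test_that("an interference-injected fragment is rejected, peptide survives", {
  cfg <- tiny_config(noise_sigma = 0, n_replicates = 3L)
  qt <- simulate_experiment(cfg)
  dir <- withr::local_tempdir()
  interf <- list(peptide = "AADDTWEPFASGK", fragment = "f3",
                 condition = "vehicle", replicate = 2L, scale = 3)
  paths <- emit_chromatograms(qt, dir, interference = interf)
  traces <- read_traces(paths)
  tr <- traces[!is.na(traces$peptide) &
                 traces$peptide == "AADDTWEPFASGK", ]
  val <- validate_transitions(tr)
  expect_false("f3" %in% val$validated)
  expect_setequal(val$validated, c("f1", "f2", "f4"))
  expect_true(val$quantifiable)
  # the offending fragment fails the constant-ratio criterion
  rep_f3 <- val$report[val$report$fragment == "f3", ]
  expect_gt(rep_f3$share_spread, 0.3)
})

test_that("validation is invariant to run and fragment order", {
  tr <- clean_traces()
  set.seed(5)
  shuffled <- tr[sample(nrow(tr)), ]
  v1 <- validate_transitions(tr)
  v2 <- validate_transitions(shuffled)
  o1 <- v1$report[order(v1$report$fragment), ]
  o2 <- v2$report[order(v2$report$fragment), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("TIC equals component areas plus background, and is linear", {
  cfg <- tiny_config(noise_sigma = 0, n_replicates = 1L)
  qt <- simulate_experiment(cfg)
  dir <- withr::local_tempdir()
  traces <- read_traces(emit_chromatograms(qt, dir))
  run1 <- traces[traces$condition == "vehicle" & traces$replicate == 1L, ]
  tic <- compute_tic(run1)
  expected <- sum(qt$area[qt$condition == "vehicle" &
                            qt$replicate == 1L]) + attr(qt, "background")
  expect_equal(tic, expected, tolerance = 1e-3)
  run2 <- run1
  run2$intensity <- 2 * run2$intensity
  expect_equal(compute_tic(run2), 2 * tic)
  expect_identical(compute_tic(run1[0L, ]), 0)
})

test_that("chromatogram quantification round-trips simulated peak areas", {
  cfg <- tiny_config(noise_sigma = 0.05, n_replicates = 2L, seed = 8L)
  qt <- simulate_experiment(cfg)
  dir <- withr::local_tempdir()
  traces <- read_traces(emit_chromatograms(qt, dir))
  res <- quantify_chromatograms(traces,
                                precursor_peptides = "EGLLQLPSDK")
  merged <- merge(as.data.frame(qt), res$areas,
                  by = c("protein", "peptide", "condition", "replicate"),
                  suffixes = c(".true", ".est"))
  expect_identical(nrow(merged), nrow(qt))
  expect_equal(merged$area.est, merged$area.true, tolerance = 5e-3)
  expect_equal(merged$tic.est, merged$tic.true, tolerance = 1e-3)
})

test_that("chromatogram-list mzML files import through the standard parser", {
  skip_if_not_installed("mzR")
  path <- test_path("testdata", "synthetic_chrom.mzML")
  tr <- read_chromatograms_mzml(path)
  expect_setequal(unique(tr$ion_label),
                  c("precursor", "f1", "f2", "f3"))
  expect_identical(unique(tr$peptide), "AADDTWEPFASGK")
  prec <- tr[tr$ion_label == "precursor", ]
  # the fixture encodes a Gaussian of amplitude 100, sigma 0.1 min
  a <- integrate_peak(prec$rt, prec$intensity, min(prec$rt), max(prec$rt),
                      baseline = "none")$area
  expect_equal(a, 100 * 0.1 * sqrt(2 * pi), tolerance = 5e-3)
  val <- validate_transitions(transform(tr, run = "run1"))
  expect_setequal(val$validated, c("f1", "f2", "f3"))
})
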