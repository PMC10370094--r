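test_that("tryptic digestion follows the K/R-not-before-P rule", {
  expect_equal(digest_protein("AAKPLRGGKMNR")$peptide,
               c("AAKPLR", "GGK", "MNR"))
  expect_equal(digest_protein("PPPP")$peptide, "PPPP")
  expect_error(digest_protein("AAXK"), "non-standard")
})

test_that("digestion of human transthyretin yields the assayed peptide", {
  fa <- system.file("extdata", "ttr_p02766.fasta", package = "prmquant")
  ttr <- read_fasta(fa)
  expect_named(ttr, "TTR_HUMAN")
  peps <- digest_protein(ttr[[1L]])
  expect_true("AADDTWEPFASGK" %in% peps$peptide)
  row <- peps[peps$peptide == "AADDTWEPFASGK", ]
  expect_identical(substring(ttr[[1L]], row$start, row$end), row$peptide)
})

test_that("digestion matches a brute-force position scanner", {
  set.seed(42)
  for (i in 1:200) {
    s <- random_protein_seq(sample(5:80, 1L))
    expect_identical(digest_protein(s)$peptide, digest_oracle(s))
  }
})

test_that("limit peptides are disjoint and tile the protein", {
  set.seed(7)
  for (i in 1:25) {
    s <- random_protein_seq(sample(10:60, 1L))
    d <- digest_protein(s)
    expect_identical(paste(d$peptide, collapse = ""), s)
    expect_identical(d$start, c(1L, utils::head(d$end, -1L) + 1L))
  }
})

test_that("missed cleavages concatenate adjacent limit peptides", {
  d <- digest_protein("AAKPLRGGKMNR", missed_cleavages = 1L)
  expect_setequal(d$peptide[d$n_missed == 1L], c("AAKPLRGGK", "GGKMNR"))
  expect_setequal(d$peptide[d$n_missed == 0L], c("AAKPLR", "GGK", "MNR"))
})

test_that("sequence filters set the documented flags", {
  parent <- synthetic_parent("GALQNIIPASTGAAK")
  peps <- digest_protein(parent)
  peps$protein <- "GAPDH"
  f <- apply_filters(peps, c(GAPDH = parent), bp_labeled = "GAPDH")
  target <- f[f$peptide == "GALQNIIPASTGAAK", ]
  expect_false(any(unlist(target[c("too_short", "too_long",
                                   "labile_modification",
                                   "deamidation_prone", "ragged_end",
                                   "labeling_sensitive")])))
  expect_true(target$passing)

  # 8-25 length window boundary
  short7 <- f[f$peptide == "MSTAGELAR", ]  # 9-mer prefix passes length
  expect_false(short7$too_short)
  p2 <- synthetic_parent("LVDTWGK")  # 7-mer
  d2 <- digest_protein(p2); d2$protein <- "X"
  f2 <- apply_filters(d2, c(X = p2))
  expect_true(f2$too_short[f2$peptide == "LVDTWGK"])
  expect_false(f2$passing[f2$peptide == "LVDTWGK"])
})

test_that("tyrosine is only disqualifying in biotin-phenol-labeled parents", {
  parent <- synthetic_parent("ENNVDAVHPGYGFLSER")
  peps <- digest_protein(parent); peps$protein <- "PC"
  # PC is endogenously biotinylated, not peroxidase-labeled
  f <- apply_filters(peps, c(PC = parent), bp_labeled = character())
  expect_false(f$labeling_sensitive[f$peptide == "ENNVDAVHPGYGFLSER"])
  f2 <- apply_filters(peps, c(PC = parent), bp_labeled = "PC")
  expect_true(f2$labeling_sensitive[f2$peptide == "ENNVDAVHPGYGFLSER"])
})

test_that("ragged tryptic ends are flagged, including in transthyretin", {
  fa <- system.file("extdata", "ttr_p02766.fasta", package = "prmquant")
  ttr <- read_fasta(fa)[[1L]]
  peps <- digest_protein(ttr); peps$protein <- "TTR"
  f <- apply_filters(peps, c(TTR = ttr), bp_labeled = "TTR")
  # AADDTWEPFASGK sits right after the ...F-R-K| junction
  row <- f[f$peptide == "AADDTWEPFASGK", ]
  expect_true(row$ragged_end)
  expect_true(row$passing)  # ragged end is advisory, not excluding
})

test_that("filtering is idempotent", {
  parent <- synthetic_parent("AQIHDLVLVGGSTR")
  peps <- digest_protein(parent); peps$protein <- "HSPA1A"
  f1 <- apply_filters(peps, c(HSPA1A = parent), bp_labeled = "HSPA1A")
  f2 <- apply_filters(f1[names(peps)], c(HSPA1A = parent),
                      bp_labeled = "HSPA1A")
  expect_identical(f1, f2)
})

test_that("the full assay panel is producible and passes the default filter", {
  panel <- assay_panel()
  expect_identical(nrow(panel), 20L)
  parents <- vapply(panel$peptide, synthetic_parent, character(1L))
  names(parents) <- paste0("P", seq_len(nrow(panel)))
  soft_only <- logical(nrow(panel))
  for (i in seq_len(nrow(panel))) {
    d <- digest_protein(parents[i])
    expect_true(panel$peptide[i] %in% d$peptide)
    d$protein <- names(parents)[i]
    bp <- if (panel$bp_labeled[i]) names(parents)[i] else character()
    f <- apply_filters(d, parents[i], bp_labeled = bp)
    row <- f[f$peptide == panel$peptide[i], ]
    soft_only[i] <- row$passing
  }
  expect_true(all(soft_only))
})

test_that("uniqueness is judged at the protein-class level", {
  proteome <- c(ACTB = "MKVAPEEHPVLLTEAPLNPKSNR",
                ACTG1 = "MRVAPEEHPVLLTEAPLNPKTTK",
                TUBA1 = "MDVNAAIATIKEEF")
  expect_identical(
    check_uniqueness("DVNAAIATIK", proteome, parent = "TUBA1"), "unique")
  # shared between the two cytoplasmic actins: non-unique ungrouped...
  expect_identical(
    check_uniqueness("VAPEEHPVLLTEAPLNPK", proteome, parent = "ACTB"),
    "non_unique")
  # ...but unique once both are mapped to one actin class
  expect_identical(
    check_uniqueness("VAPEEHPVLLTEAPLNPK", proteome, parent = "ACTB",
                     groups = c(ACTB = "actin", ACTG1 = "actin")),
    "unique")
  expect_error(check_uniqueness("PEPK", character(0L), parent = "X"),
               "empty proteome")
})

test_that("fragment m/z values match an independent mass calculator", {
  ts <- enumerate_transitions("GGK", charge = 1L)
  frag <- stats::setNames(ts$fragments$mz, ts$fragments$ion)
  # frozen from pyteomics.mass.fast_mass
  expect_equal(unname(frag["y1"]), 147.11280, tolerance = 1e-7)
  expect_equal(unname(frag["y2"]), 204.13427, tolerance = 1e-7)
  expect_equal(unname(frag["b2"]), 115.05020, tolerance = 1e-7)
  expect_false("b1" %in% names(frag))  # below the 110 m/z scan floor
  expect_equal(precursor_mz("AADDTWEPFASGK", 2L), 697.814781,
               tolerance = 1e-8)
  ts2 <- enumerate_transitions("AADDTWEPFASGK", 2L,
                               mz_range = c(0, 1e6))
  f2 <- stats::setNames(ts2$fragments$mz, ts2$fragments$ion)
  expect_equal(unname(f2[c("y4", "b6", "y8")]),
               c(362.20341, 660.26238, 921.44649), tolerance = 1e-6)
})

test_that("b/y enumeration is combinatorially complete before range filtering", {
  set.seed(11)
  for (i in 1:20) {
    s <- random_protein_seq(sample(4:20, 1L))
    ts <- enumerate_transitions(s, 2L, mz_range = c(0, 1e9),
                                min_fragments = 1L)
    n <- nchar(s)
    expect_identical(sum(grepl("^b", ts$fragments$ion)), n - 1L)
    expect_identical(sum(grepl("^y", ts$fragments$ion)), n - 1L)
  }
})

test_that("static carbamidomethylation shifts every C-containing fragment", {
  mod <- enumerate_transitions("ACDK", 2L, mz_range = c(0, 1e6))
  unmod <- enumerate_transitions("ACDK", 2L, mz_range = c(0, 1e6),
                                 cys_mod = 0)
  has_c <- c(b1 = FALSE, b2 = TRUE, b3 = TRUE,
             y1 = FALSE, y2 = FALSE, y3 = TRUE)
  shift <- mod$fragments$mz - unmod$fragments$mz
  names(shift) <- mod$fragments$ion
  expect_equal(unname(shift[names(has_c)]),
               unname(ifelse(has_c, 57.02146, 0)), tolerance = 1e-9)
  # frozen unmodified values from pyteomics, plus the static shift
  expect_equal(mod$fragments$mz[mod$fragments$ion == "b2"],
               175.05358 + 57.02146, tolerance = 1e-5)
  expect_equal(mod$fragments$mz[mod$fragments$ion == "y3"],
               365.14893 + 57.02146, tolerance = 1e-5)
})

test_that("too few in-range fragments is a selection error", {
  expect_error(enumerate_transitions("GK", 1L), "at least 3")
})

test_that("transition_list emits a flat Skyline-style table", {
  panel <- data.frame(protein = "FLAGTTR", peptide = "AADDTWEPFASGK",
                      charge = 2L, rt = 40)
  tl <- transition_list(panel)
  expect_true(all(c("protein", "peptide", "precursor_mz", "fragment",
                    "fragment_mz", "rt_start", "rt_end") %in% names(tl)))
  expect_true(all(tl$rt_end - tl$rt_start == 10))
  expect_true(nrow(tl) >= 3L)
})
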