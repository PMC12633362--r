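test_that("self-comparison is perfectly concordant with zero differences", {
  truth <- simulateSiteTruth(300, seed = 41)
  st <- pileupCalls(simulateNanoporeCalls(truth = truth, seed = 1)$calls)
  rep <- compareConditions(st, st, null_band = nullBand(0.066))
  expect_equal(rep@fit@r, 1, tolerance = 1e-12)
  expect_equal(rep@ba@meanDiff, 0)
  expect_true(all(rep@pairs$delta == 0))
  expect_true(all(rep@pairs$label == "unchanged"))
})

test_that("classification against the null band uses strict exceedance", {
  band <- nullBand(0.066)
  expect_equal(as.character(classifySites(c(0.20, -0.01, 0.066, -0.066,
                                            0.0661, -0.07), band)),
               c("increased", "unchanged", "unchanged", "unchanged",
                 "increased", "decreased"))
  # labels partition any pair set
  set.seed(5)
  d <- rnorm(500, sd = 0.05)
  lab <- classifySites(d, band)
  expect_equal(sum(table(lab)), length(d))
  # asymmetric band (offset mean difference) is used as-is
  ba <- blandAltman(rnorm(100, mean = 0.02, sd = 0.01))
  off <- nullBand(ba)
  expect_equal(as.character(classifySites(0, off)),
               if (0 < ba@loaLow) "decreased" else "unchanged")
})

test_that("comparison warns on relaxed coverage and borrowed null bands", {
  st <- make_site_table(n_mod = c(10L, 20L, 30L), n_canon = c(40L, 30L, 20L),
                        pos0 = c(10L, 20L, 30L))
  expect_warning(compareConditions(st, st, min_valid_cov = 10),
                 "noisier")
  expect_warning(
    compareConditions(st, st, null_band = nullBand(0.066, "borrowed")),
    "borrowed")
  tiny <- make_site_table(n_mod = 30L, n_canon = 30L)
  expect_warning(rep <- compareConditions(tiny, tiny), "fewer than 3")
  expect_true(is.na(rep@fit@r))
})

test_that("region subsetting is strand-aware with half-open coordinates", {
  pairs <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                      pos0 = c(100L, 100L, 150L, 100L),
                      strand = c("+", "-", "+", "+"),
                      f_a = 0.1, f_b = 0.2, cov_a = 60L, cov_b = 60L,
                      delta = 0.1, log2fc = 1)
  regions <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = 51L, end = 150L), strand = "+",
    name = "gene")
  hit <- subsetSites(pairs, regions)
  # [50, 150) 0-based: pos0 100 on + kept; opposite strand and pos0 150 dropped
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$pos0, 100L)
  expect_equal(nrow(subsetSites(pairs, regions[0])), 0L)

  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t50\t150\tgene\t0\t+", path)
  expect_equal(subsetSites(pairs, path), hit)
})

test_that("injected increases are labelled against an independent null band", {
  truth <- simulateSiteTruth(1500, pi0 = 0, beta_a = 5, beta_b = 5, seed = 51)
  shifted <- injectEffect(truth, delta = 0.3, sites = 1:100)
  cov <- 500
  ctrl1 <- pileupCalls(simulateNanoporeCalls(truth = truth, cov_mean = cov,
                                             seed = 1)$calls, sample = "c1")
  ctrl2 <- pileupCalls(simulateNanoporeCalls(truth = truth, cov_mean = cov,
                                             seed = 2)$calls, sample = "c2")
  treat <- pileupCalls(simulateNanoporeCalls(truth = shifted$truth,
                                             cov_mean = cov,
                                             seed = 3)$calls, sample = "t")
  band <- nullBand(blandAltman(joinPairedSites(ctrl1, ctrl2, 50)))
  rep <- compareConditions(ctrl1, treat, null_band = band)
  lab <- rep@pairs$label
  expect_equal(sum(table(lab)), nrow(rep@pairs))
  # the bulk of sites keeps slope ~ 1 despite the injected subset
  expect_equal(rep@fit@slope, 1, tolerance = 0.05)
  injected <- rep@pairs$pos0 %in% truth$pos0[shifted$affected]
  expect_gte(mean(lab[injected] == "increased"), 0.95)
})

test_that("cross-method comparison applies the shared stoichiometry floor", {
  st <- make_site_table(n_mod = c(30L, 3L, 30L, 25L),
                        n_canon = c(70L, 97L, 70L, 75L),
                        pos0 = c(10L, 20L, 30L, 40L))
  external <- data.frame(chrom = "chr1", pos0 = c(10L, 20L, 30L, 40L),
                         strand = "+", f = c(0.32, 0.30, 0.04, 0.27))
  rep <- crossMethodCompare(st, external, min_external_f = 0.05)
  # pos 20 fails the nanopore floor (0.03), pos 30 the external floor (0.04)
  expect_equal(rep@pairs$pos0, c(10L, 40L))
  expect_error(crossMethodCompare(st, external[0, ]), "no shared sites")

  same <- data.frame(chrom = "chr1", pos0 = c(10L, 30L, 40L), strand = "+",
                     f = c(0.30, 0.30, 0.25))
  expect_equal(crossMethodCompare(st, same)@fit@r, 1, tolerance = 1e-12)
})

test_that("comparison reports round-trip to TSV + JSON", {
  truth <- simulateSiteTruth(200, seed = 61)
  a <- pileupCalls(simulateNanoporeCalls(truth = truth, seed = 1)$calls)
  b <- pileupCalls(simulateNanoporeCalls(truth = truth, seed = 2)$calls)
  rep <- compareConditions(a, b, null_band = nullBand(0.066))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeComparisonReport(rep, tsv)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(rep@pairs))
  js <- jsonlite::read_json(sub("\\.tsv$", ".json", tsv))
  expect_equal(js$fit$r, rep@fit@r, tolerance = 1e-12)
  expect_equal(js$bland_altman$loa_high, rep@ba@loaHigh, tolerance = 1e-12)
  expect_equal(js$n_pairs, nrow(rep@pairs))
})
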