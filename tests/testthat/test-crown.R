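test_that("in-silico conversion substitutes per mate and preserves length", {
  expect_equal(convertReadsInSilico("GATTACA", 1), "GGTTGCG")
  expect_equal(convertReadsInSilico("GATTACA", 2), "GACCACA")
  expect_equal(convertReadsInSilico("", 1), "")
  expect_equal(convertReadsInSilico(c("AAA", "NTN"), 2), c("AAA", "NCN"))
  expect_error(convertReadsInSilico("GAUUACA", 1), "invalid character")
})

make_records <- function(n_A, n_G, n_other = 0, pos0 = 500L, mate = 1L,
                         softclip5 = 0L, chrom = "chrSn", strand = "+",
                         prefix = "r") {
  n <- n_A + n_G + n_other
  data.frame(chrom = chrom, pos0 = pos0, strand = strand, mate = mate,
             softclip5 = softclip5,
             base = rep(c("A", "G", "T"), c(n_A, n_G, n_other)),
             read_id = paste0(prefix, seq_len(n)))
}

tss1 <- data.frame(chrom = "chrSn", pos0 = 500L, strand = "+",
                   gene_id = "RNU1-1")

test_that("non-conversion rate is A / (A + G) over qualifying reads", {
  res <- tssNonconversion(make_records(30, 70), tss1, min_valid_cov = 50)
  expect_equal(res$n_A, 30L)
  expect_equal(res$n_G, 70L)
  expect_equal(res$non_conversion, 0.30)

  none <- tssNonconversion(make_records(0, 80), tss1)
  expect_equal(none$non_conversion, 0)

  # other bases counted but excluded from the denominator
  mixed <- tssNonconversion(make_records(30, 70, n_other = 10), tss1)
  expect_equal(mixed$n_other, 10L)
  expect_equal(mixed$non_conversion, 0.30)
})

test_that("softclipped, mate-2, unannotated and shallow TSSs are excluded", {
  rec <- rbind(make_records(30, 70, prefix = "a"),
               make_records(50, 0, softclip5 = 1L, prefix = "b"),
               make_records(50, 0, mate = 2L, prefix = "c"),
               make_records(10, 10, pos0 = 999L, prefix = "d"))
  res <- tssNonconversion(rec, tss1, min_valid_cov = 50)
  expect_equal(res$non_conversion, 0.30)       # only the clean mate-1 reads
  expect_equal(attr(res, "n_unannotated"), 20L)

  shallow <- tssNonconversion(make_records(10, 20), tss1, min_valid_cov = 50)
  expect_equal(nrow(shallow), 0L)
  expect_equal(attr(shallow, "n_below_cov"), 1L)

  dup <- make_records(2, 0)
  dup$read_id <- "same"
  expect_error(tssNonconversion(dup, tss1), "duplicate read_id")
})

test_that("TSS annotation can come from BED6 with gene names", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrSn\t500\t501\tRNU1-1\t0\t+", path)
  res <- tssNonconversion(make_records(30, 70), readBed6(path))
  expect_equal(res$gene_id, "RNU1-1")
  expect_equal(res$non_conversion, 0.30)
})

test_that("paired t on per-snRNA condition means matches t.test", {
  # three snRNAs whose condition differences are 0.1, 0.2, 0.3
  counts <- data.frame(
    gene_id = rep(c("U1", "U2", "U4"), 2),
    condition = rep(c("ctrl", "treat"), each = 3),
    replicate = 1L,
    non_conversion = c(0.1, 0.2, 0.3, 0.2, 0.4, 0.6))
  res <- perSnrnaConditionStats(counts)
  expect_equal(res$t, 3.4641, tolerance = 1e-4)
  expect_equal(res$p_value, 0.0742, tolerance = 1e-3)
  expect_equal(res$df, 2L)
  expect_equal(res$mean_delta, 0.2)
  tt <- t.test(c(0.2, 0.4, 0.6), c(0.1, 0.2, 0.3), paired = TRUE)
  expect_equal(res$t, unname(tt$statistic))
  expect_equal(res$p_value, tt$p.value)

  # identical conditions: zero differences, degenerate t
  flat <- counts; flat$non_conversion <- rep(c(0.1, 0.2, 0.3), 2)
  expect_warning(res0 <- perSnrnaConditionStats(flat), "zero variance")
  expect_equal(res0$mean_delta, 0)
  expect_equal(res0$t, 0)
  expect_true(is.na(res0$p_value))

  # genes missing from one condition are excluded and counted
  lop <- rbind(counts, data.frame(gene_id = "U5", condition = "ctrl",
                                  replicate = 1L, non_conversion = 0.5))
  res1 <- perSnrnaConditionStats(lop)
  expect_equal(res1$n_genes, 3L)
  expect_equal(res1$n_excluded, 1L)
})

test_that("replicate means are averaged per condition before pairing", {
  counts <- data.frame(
    gene_id = "U1",
    condition = rep(c("ctrl", "treat"), each = 2),
    replicate = c(1L, 2L, 1L, 2L),
    non_conversion = c(0.1, 0.3, 0.5, 0.7))
  more <- within(counts, gene_id <- "U2")
  more$non_conversion <- c(0.2, 0.4, 0.5, 0.9)
  res <- perSnrnaConditionStats(rbind(counts, more))
  expect_equal(res$per_gene$mean_ctrl, c(0.2, 0.3))
  expect_equal(res$per_gene$mean_treat, c(0.6, 0.7))
})

test_that("conversion correction inverts the expected non-conversion rate", {
  expect_equal(correctForConversion(0.30, c = 1), 0.30)
  expect_equal(correctForConversion(0.40, c = 0.9), 1 / 3)
  expect_equal(correctForConversion(0.05, c = 0.9), 0)   # clamped
  expect_error(correctForConversion(0.3, c = 0), "conversion efficiency")

  # unbiased recovery: E[r] = f + (1 - f)(1 - c)
  for (f in c(0.1, 0.3, 0.6)) {
    truth <- data.frame(gene_id = paste0("g", 1:40), f = f)
    cc <- simulateCrownCounts(truth, conversion = 0.9, coverage = 1000,
                              base_error = 0, replicates = 1,
                              seed = round(100 * f))
    fhat <- correctForConversion(cc$non_conversion, c = 0.9)
    se <- sqrt(f * (1 - f) / 1000 / nrow(truth)) / 0.9
    expect_lt(abs(mean(fhat) - f), 3 * se + 1e-3)
  }
})
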