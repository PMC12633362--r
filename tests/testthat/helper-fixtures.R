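# Shared fixtures and independent oracles used across the suite.

# Brute-force pileup oracle: plain base-R tally, independent of the
# data.table aggregation path in pileupCalls().
oracle_pileup <- function(calls, tau = 0.99) {
  key <- paste(calls$chrom, calls$pos0, calls$strand, sep = "\r")
  out <- lapply(split(calls$p_mod, key), function(p) {
    n_mod <- sum(p >= tau)
    n_canon <- sum((1 - p) >= tau)
    c(n_mod = n_mod, n_canon = n_canon,
      n_fail = length(p) - n_mod - n_canon)
  })
  m <- do.call(rbind, out)
  parts <- do.call(rbind, strsplit(rownames(m), "\r", fixed = TRUE))
  df <- data.frame(chrom = parts[, 1], pos0 = as.integer(parts[, 2]),
                   strand = parts[, 3], m, row.names = NULL)
  df[order(df$chrom, df$pos0, df$strand), , drop = FALSE]
}

site_table_as_df <- function(st) {
  gr <- siteRanges(st)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   pos0 = GenomicRanges::start(gr) - 1L,
                   strand = as.character(GenomicRanges::strand(gr)),
                   n_mod = modCounts(st), n_canon = canonCounts(st),
                   n_fail = failCounts(st))
  df[order(df$chrom, df$pos0, df$strand), , drop = FALSE]
}

random_calls <- function(n, n_sites = 20, seed = 1, read_prefix = "r") {
  set.seed(seed)
  data.frame(read_id = paste0(read_prefix, seq_len(n)),
             chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
             pos0 = sample(seq_len(n_sites) * 10L, n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             p_mod = runif(n))
}

# Direct binomial two-replicate site tables at fixed coverage: the
# measurement model stripped to its sampling core (no basecaller noise).
binomial_site_table <- function(f, coverage, seed, sample = "s") {
  set.seed(seed)
  n <- length(f)
  n_mod <- rbinom(n, coverage, f)
  gr <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(start = 10L * seq_len(n), width = 1L),
    strand = "+",
    n_mod = n_mod, n_canon = coverage - n_mod,
    n_fail = rep(0L, n))
  ModSiteTable(gr, tau = 0.99, sample = sample)
}

make_site_table <- function(n_mod, n_canon, n_fail = rep(0L, length(n_mod)),
                            pos0 = 10L * seq_along(n_mod), strand = "+",
                            chrom = "chr1", tau = 0.99, sample = "s",
                            genome = NA_character_) {
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = pos0 + 1L, width = 1L),
    strand = strand,
    n_mod = as.integer(n_mod), n_canon = as.integer(n_canon),
    n_fail = as.integer(n_fail))
  ModSiteTable(gr, tau = tau, sample = sample, genome = genome)
}
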