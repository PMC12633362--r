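#' Classify a per-read modification call
#'
#' The dual confidence filter applied during pileup: a call is `MOD` when
#' the modification probability reaches the threshold, `CANON` when the
#' canonical-base probability `1 - p_mod` reaches it, and `FAIL` otherwise.
#' Both comparisons are inclusive (a probability exactly equal to `tau`
#' passes). `tau` must exceed 0.5 so that the two confident classes cannot
#' overlap.
#'
#' @param p_mod numeric vector of per-read modification probabilities in
#'   \[0, 1\].
#' @param tau confidence threshold in (0.5, 1\]; default 0.99.
#' @return factor with levels `MOD`, `CANON`, `FAIL`, one per call.
#' @examples
#' classifyCall(c(0.995, 0.005, 0.5, 0.99), tau = 0.99)
#' @export
classifyCall <- function(p_mod, tau = 0.99) {
  if (!is.numeric(p_mod) || anyNA(p_mod) || any(p_mod < 0) || any(p_mod > 1))
    stop("p_mod must be numeric in [0, 1] with no missing values")
  if (length(tau) != 1L || is.na(tau) || tau <= 0.5 || tau > 1)
    stop("tau must be a single value in (0.5, 1]")
  out <- rep.int("FAIL", length(p_mod))
  out[p_mod >= tau] <- "MOD"
  out[(1 - p_mod) >= tau] <- "CANON"
  factor(out, levels = c("MOD", "CANON", "FAIL"))
}

.validate_calls <- function(calls) {
  need <- c("read_id", "chrom", "pos0", "strand", "p_mod")
  miss <- setdiff(need, names(calls))
  if (length(miss))
    stop("calls table lacks column(s): ", paste(miss, collapse = ", "))
  bad_strand <- !calls$strand %in% c("+", "-")
  if (any(bad_strand))
    stop("malformed strand value(s): ",
         paste(unique(calls$strand[bad_strand]), collapse = ", "))
  if (any(calls$pos0 < 0)) stop("pos0 must be >= 0")
  invisible(calls)
}

#' Tabulate per-read calls into a site table
#'
#' Streams per-read modification calls through the dual confidence filter
#' ([classifyCall()]) and tallies, per distinct (chromosome, position,
#' strand) site, the number of confident modified, confident canonical and
#' discarded calls. Stoichiometry is derived from the confident counts
#' only; sites below `min_valid_cov` are retained and flagged (column
#' `pass_cov`) -- dropping them is a separate step, [filterByCoverage()].
#'
#' A read may legitimately cover many sites, but the same read reported
#' twice at the same site indicates an upstream demultiplexing or
#' deduplication fault and is an error.
#'
#' @param calls data.frame (or anything coercible) with columns `read_id`,
#'   `chrom`, `pos0` (0-based position of the candidate A), `strand`
#'   (`+`/`-`), `p_mod`.
#' @param tau confidence threshold, default 0.99.
#' @param min_valid_cov coverage floor used only to set the `pass_cov`
#'   flag; default 50.
#' @param sample sample label recorded in the result.
#' @param genome genome build tag.
#' @return A [ModSiteTable-class]; its ranges carry an extra logical
#'   metadata column `pass_cov`.
#' @examples
#' calls <- data.frame(
#'   read_id = paste0("r", 1:10), chrom = "chr1", pos0 = 100L, strand = "+",
#'   p_mod = c(rep(0.999, 6), rep(0.001, 3), 0.60))
#' st <- pileupCalls(calls, tau = 0.99)
#' stoichiometry(st)  # 6 / 9
#' @export
pileupCalls <- function(calls, tau = 0.99, min_valid_cov = 50,
                        sample = "sample", genome = NA_character_) {
  dt <- data.table::as.data.table(calls)
  .validate_calls(dt)
  if (min_valid_cov < 0) stop("min_valid_cov must be >= 0")
  chrom <- pos0 <- strand <- read_id <- p_mod <- cls <- NULL  # NSE bindings
  dup <- duplicated(dt, by = c("read_id", "chrom", "pos0", "strand"))
  if (any(dup)) {
    stop("duplicate call(s) for read(s) ",
         paste(unique(dt$read_id[dup]), collapse = ", "),
         " at the same site")
  }
  if (nrow(dt) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      n_mod = integer(), n_canon = integer(), n_fail = integer(),
      pass_cov = logical())
    return(ModSiteTable(gr, tau = tau, sample = sample, genome = genome))
  }
  dt[, cls := classifyCall(p_mod, tau)]
  agg <- dt[, list(n_mod   = sum(cls == "MOD"),
                   n_canon = sum(cls == "CANON"),
                   n_fail  = sum(cls == "FAIL")),
            by = list(chrom, pos0, strand)]
  data.table::setorder(agg, chrom, pos0, strand)
  gr <- GenomicRanges::GRanges(
    seqnames = agg$chrom,
    ranges = IRanges::IRanges(start = agg$pos0 + 1L, width = 1L),
    strand = agg$strand,
    n_mod = as.integer(agg$n_mod),
    n_canon = as.integer(agg$n_canon),
    n_fail = as.integer(agg$n_fail))
  S4Vectors::mcols(gr)$pass_cov <-
    (S4Vectors::mcols(gr)$n_mod + S4Vectors::mcols(gr)$n_canon) >= min_valid_cov
  ModSiteTable(gr, tau = tau, sample = sample, genome = genome)
}

#' Merge replicate site tables by summing counts
#'
#' Mirrors merging replicate alignments before pileup: per site, the
#' modified/canonical/failed counts are element-wise sums over the tables
#' in which the site appears, and stoichiometry is recomputed from the
#' summed counts. All tables must share the confidence threshold (counts
#' tabulated under different thresholds are not comparable) and genome
#' build.
#'
#' @param tables list of [ModSiteTable-class] objects.
#' @param sample label for the merged table; defaults to the concatenated
#'   replicate labels.
#' @return A merged `ModSiteTable` whose `replicateLabels` records the
#'   inputs.
#' @export
mergeSiteTables <- function(tables, sample = NULL) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  taus <- vapply(tables, confidenceTau, numeric(1))
  if (length(unique(taus)) != 1L)
    stop("cannot merge site tables built with different tau: ",
         paste(unique(taus), collapse = " vs "))
  genomes <- unique(stats::na.omit(vapply(tables, genomeBuild, character(1))))
  if (length(genomes) > 1L)
    stop("cannot merge site tables from different genome builds: ",
         paste(genomes, collapse = " vs "))
  chrom <- pos0 <- strand <- n_mod <- n_canon <- n_fail <- NULL
  dts <- lapply(tables, function(t) {
    gr <- siteRanges(t)
    data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      pos0 = GenomicRanges::start(gr) - 1L,
      strand = as.character(GenomicRanges::strand(gr)),
      n_mod = modCounts(t), n_canon = canonCounts(t), n_fail = failCounts(t))
  })
  agg <- data.table::rbindlist(dts)[
    , list(n_mod = sum(n_mod), n_canon = sum(n_canon), n_fail = sum(n_fail)),
    by = list(chrom, pos0, strand)]
  data.table::setorder(agg, chrom, pos0, strand)
  reps <- unlist(lapply(tables, replicateLabels))
  if (is.null(sample)) sample <- paste(reps, collapse = "+")
  gr <- GenomicRanges::GRanges(
    seqnames = agg$chrom,
    ranges = IRanges::IRanges(start = agg$pos0 + 1L, width = 1L),
    strand = agg$strand,
    n_mod = as.integer(agg$n_mod),
    n_canon = as.integer(agg$n_canon),
    n_fail = as.integer(agg$n_fail))
  ModSiteTable(gr, tau = taus[1], sample = sample, replicates = reps,
               genome = if (length(genomes)) genomes else NA_character_)
}

#' Drop sites below a valid-coverage floor
#'
#' Retains exactly the sites whose valid coverage (confident modified +
#' confident canonical calls) is at least `min_valid_cov` (inclusive, as in
#' the ">= 50 reads" convention).
#'
#' @param table a [ModSiteTable-class].
#' @param min_valid_cov integer floor, >= 0.
#' @return The filtered `ModSiteTable`.
#' @export
filterByCoverage <- function(table, min_valid_cov = 50) {
  stopifnot(is(table, "ModSiteTable"))
  if (min_valid_cov < 0) stop("min_valid_cov must be >= 0")
  table[validCoverage(table) >= min_valid_cov]
}

#' Keep only sites in a given sequence motif context
#'
#' Retains sites whose strand-oriented k-mer context around the candidate A
#' matches an IUPAC motif (default `DRACH`, the canonical m6A context:
#' D=\[AGT\], R=\[AG\], A, C, H=\[ACT\]). For minus-strand sites the
#' plus-strand reference window is reverse-complemented before matching.
#' Sites closer than the motif half-width to a contig end are dropped.
#'
#' @param table a [ModSiteTable-class].
#' @param reference a [Biostrings::DNAStringSet] or path to a FASTA file;
#'   sequence names are matched to the table's chromosomes on their first
#'   whitespace-delimited token.
#' @param motif IUPAC string of odd length with `A` at the centre.
#' @return The masked `ModSiteTable`.
#' @export
motifMask <- function(table, reference, motif = "DRACH") {
  stopifnot(is(table, "ModSiteTable"))
  if (is.character(reference)) reference <- Biostrings::readDNAStringSet(reference)
  stopifnot(is(reference, "DNAStringSet"))
  names(reference) <- sub("\\s.*$", "", names(reference))
  if (nchar(motif) %% 2L != 1L)
    stop("motif must have odd length")
  half <- (nchar(motif) - 1L) %/% 2L
  if (substr(motif, half + 1L, half + 1L) != "A")
    stop("motif must have A at its centre position")
  gr <- siteRanges(table)
  if (length(gr) == 0L) return(table)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  missing_chr <- setdiff(unique(chroms), names(reference))
  if (length(missing_chr))
    stop("chromosome(s) absent from reference: ",
         paste(missing_chr, collapse = ", "))
  pos <- GenomicRanges::start(gr)          # 1-based centre
  lens <- Biostrings::width(reference)[match(chroms, names(reference))]
  in_bounds <- (pos - half >= 1L) & (pos + half <= lens)
  keep <- logical(length(gr))
  idx <- which(in_bounds)
  if (length(idx)) {
    ctx <- Biostrings::DNAStringSet(rep("A", length(idx)))
    for (chr in unique(chroms[idx])) {
      sel <- idx[chroms[idx] == chr]
      ctx[match(sel, idx)] <- Biostrings::extractAt(
        reference[[chr]],
        IRanges::IRanges(start = pos[sel] - half, width = nchar(motif)))
    }
    minus <- as.character(GenomicRanges::strand(gr))[idx] == "-"
    if (any(minus)) ctx[minus] <- Biostrings::reverseComplement(ctx[minus])
    hit <- Biostrings::vcountPattern(motif, ctx, fixed = "subject") > 0L
    keep[idx] <- hit
  }
  table[keep]
}
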