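#' In-silico conversion of read sequences
#'
#' Conversion-based m6Am sequencing reads unmethylated
#' 2'-O-methyladenosine as G after chemical conversion, so reads are
#' converted in silico before alignment to a converted reference: every A
#' becomes G on read 1, and every T becomes C on read 2 (the reverse
#' complement of the same substitution).
#'
#' @param seq character vector of read sequences over A/C/G/T/N.
#' @param mate 1 or 2.
#' @return The converted sequences, lengths preserved.
#' @examples
#' convertReadsInSilico("GATTACA", mate = 1)  # "GGTTGCG"
#' convertReadsInSilico("GATTACA", mate = 2)  # "GACCACA"
#' @export
convertReadsInSilico <- function(seq, mate) {
  stopifnot(length(mate) == 1L, mate %in% c(1L, 2L))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop("invalid character(s) in sequence(s) ",
         paste(head(which(bad), 5), collapse = ", "),
         " (only A, C, G, T, N allowed)")
  if (mate == 1L) chartr("A", "G", seq) else chartr("T", "C", seq)
}

#' Count A/G at annotated transcription-start nucleotides
#'
#' Tallies, per annotated TSS, the bases observed at the start nucleotide
#' across qualifying reads and derives the non-conversion rate
#' `r = n_A / (n_A + n_G)`: after conversion chemistry, A indicates m6Am
#' (protected) and G indicates Am (converted), so `r` estimates m6Am
#' stoichiometry. Only read-1 records without a 5' soft-clip whose mapped
#' 5' end coincides with an annotated TSS are counted; other bases (C/T/N)
#' are tallied in `n_other` but excluded from the rate's denominator. TSSs
#' with fewer than `min_valid_cov` informative (A+G) reads are excluded.
#'
#' @param records data.frame of aligned 5'-end records (see
#'   [readStartRecords()]): `chrom`, `pos0`, `strand`, `mate`, `softclip5`,
#'   `base`, `read_id`.
#' @param tss TSS annotation: `GRanges` with a `name` metadata column
#'   (see [readBed6()]) or a data.frame with `chrom`, `pos0`, `strand`,
#'   `gene_id`.
#' @param min_valid_cov minimum `n_A + n_G` per TSS; default 50.
#' @return data.frame with one row per retained TSS: `gene_id`, `chrom`,
#'   `pos0`, `strand`, `n_A`, `n_G`, `n_other`, `non_conversion`.
#'   Attributes `n_unannotated` (qualifying records at unannotated
#'   positions) and `n_below_cov` (TSSs dropped by the coverage floor) are
#'   attached.
#' @export
tssNonconversion <- function(records, tss, min_valid_cov = 50) {
  if (is(tss, "GRanges")) {
    tss <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(tss)),
      pos0 = GenomicRanges::start(tss) - 1L,
      strand = as.character(GenomicRanges::strand(tss)),
      gene_id = S4Vectors::mcols(tss)$name)
  }
  stopifnot(all(c("chrom", "pos0", "strand", "gene_id") %in% names(tss)),
            all(nzchar(tss$gene_id)))
  tkey <- paste(tss$chrom, tss$pos0, tss$strand)
  if (anyDuplicated(tkey)) stop("TSS annotation has duplicate positions")
  qual <- records[records$mate == 1L & records$softclip5 == 0L, , drop = FALSE]
  rkey <- paste(qual$chrom, qual$pos0, qual$strand)
  idx <- match(rkey, tkey)
  n_unannot <- sum(is.na(idx))
  qual <- qual[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  dup <- duplicated(data.frame(qual$read_id, idx))
  if (any(dup))
    stop("duplicate read_id(s) at a TSS: ",
         paste(unique(qual$read_id[dup]), collapse = ", "))
  n_A <- tabulate(idx[qual$base == "A"], nbins = nrow(tss))
  n_G <- tabulate(idx[qual$base == "G"], nbins = nrow(tss))
  n_other <- tabulate(idx[!qual$base %in% c("A", "G")], nbins = nrow(tss))
  out <- data.frame(gene_id = tss$gene_id, chrom = tss$chrom,
                    pos0 = tss$pos0, strand = tss$strand,
                    n_A = n_A, n_G = n_G, n_other = n_other)
  informative <- out$n_A + out$n_G
  out$non_conversion <- ifelse(informative > 0L, out$n_A / informative,
                               NA_real_)
  below <- informative < min_valid_cov
  res <- out[!below, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_unannotated") <- n_unannot
  attr(res, "n_below_cov") <- sum(below)
  res
}

#' Per-snRNA condition means and paired t-test
#'
#' Averages the non-conversion rate over replicates within each condition
#' for every snRNA, pairs the two condition means per snRNA, and tests the
#' per-snRNA differences with a paired t-test (t = mean(d) / (sd(d) /
#' sqrt(n)), two-sided p from the t distribution on n - 1 degrees of
#' freedom). snRNAs missing from either condition are excluded and
#' counted. Also reports the average increase across snRNAs.
#'
#' @param counts data.frame with columns `gene_id`, `condition`,
#'   `replicate`, `non_conversion` (stack the outputs of
#'   [tssNonconversion()] over replicates and conditions).
#' @param ctrl,treat condition labels; the difference is treat - ctrl.
#' @return list with `per_gene` (data.frame: `gene_id`, `mean_ctrl`,
#'   `mean_treat`, `delta`), `mean_delta`, `t`, `df`, `p_value` (NA with a
#'   warning when the differences have zero variance), `n_genes`,
#'   `n_excluded`.
#' @export
perSnrnaConditionStats <- function(counts, ctrl = "ctrl", treat = "treat") {
  stopifnot(all(c("gene_id", "condition", "replicate", "non_conversion")
                %in% names(counts)),
            all(c(ctrl, treat) %in% counts$condition))
  cm <- stats::aggregate(non_conversion ~ gene_id + condition,
                         data = counts[counts$condition %in% c(ctrl, treat), ],
                         FUN = mean)
  wide <- merge(cm[cm$condition == ctrl, c("gene_id", "non_conversion")],
                cm[cm$condition == treat, c("gene_id", "non_conversion")],
                by = "gene_id", all = TRUE,
                suffixes = c("_ctrl", "_treat"))
  complete <- stats::complete.cases(wide)
  n_excluded <- sum(!complete)
  wide <- wide[complete, , drop = FALSE]
  per_gene <- data.frame(gene_id = wide$gene_id,
                         mean_ctrl = wide$non_conversion_ctrl,
                         mean_treat = wide$non_conversion_treat)
  per_gene$delta <- per_gene$mean_treat - per_gene$mean_ctrl
  d <- per_gene$delta
  n <- length(d)
  if (n < 2L) stop("need at least 2 snRNAs present in both conditions")
  sd_d <- sd(d)
  if (sd_d == 0) {
    if (all(d == 0)) {
      tstat <- 0; p <- NA_real_
    } else {
      tstat <- NA_real_; p <- NA_real_
    }
    warning("per-snRNA differences have zero variance; ",
            "paired t-test p-value undefined")
  } else {
    tstat <- mean(d) / (sd_d / sqrt(n))
    p <- 2 * pt(-abs(tstat), df = n - 1)
  }
  list(per_gene = per_gene, mean_delta = mean(d), t = tstat,
       df = n - 1L, p_value = p, n_genes = n, n_excluded = n_excluded)
}

#' Correct a non-conversion rate for incomplete conversion
#'
#' With conversion efficiency `c < 1`, a fraction `1 - c` of unmethylated
#' starts stays unconverted and inflates the raw non-conversion rate:
#' `E[r] = f + (1 - f)(1 - c)`. Inverting and clamping to \[0, 1\] gives
#' the corrected stoichiometry `(r - (1 - c)) / c`. Off by default in the
#' quantification workflow, which reports raw rates.
#'
#' @param r non-conversion rate(s) in \[0, 1\].
#' @param c conversion efficiency in (0, 1\].
#' @return Corrected stoichiometry estimate(s) in \[0, 1\].
#' @examples
#' correctForConversion(0.40, c = 0.9)  # 1/3
#' @export
correctForConversion <- function(r, c = 1) {
  if (length(c) != 1L || is.na(c) || c <= 0 || c > 1)
    stop("conversion efficiency c must be a single value in (0, 1]")
  stopifnot(all(r >= 0 & r <= 1, na.rm = TRUE))
  pmin(pmax((r - (1 - c)) / c, 0), 1)
}
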