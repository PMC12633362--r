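#' Compare two conditions' site tables
#'
#' The full two-condition workflow: joins sites covered in both samples at
#' the coverage floor ([joinPairedSites()], dropping pairs at zero in
#' both), fits the Pearson concordance ([fitConcordance()]), runs the
#' Bland-Altman analysis ([blandAltman()]), summarises the difference
#' distribution ([deltaDistribution()]) and, when an empirical null band
#' is supplied, labels every site pair as increased, decreased or
#' unchanged ([classifySites()]). Deterministic given its inputs.
#'
#' A coverage floor of 10 (the relaxed mode used to rescue low-coverage
#' genes) triggers a warning that stoichiometry estimates are markedly
#' noisier at that depth. A `"borrowed"` null band (from a different
#' comparison, e.g. when a condition has a single replicate) also warns.
#'
#' @param ctrl,treat [ModSiteTable-class] objects sharing a confidence
#'   threshold; `delta` is treated minus control.
#' @param min_valid_cov coverage floor, default 50.
#' @param null_band optional [NullBand-class] for per-site labels.
#' @param drop_zero_both passed to [joinPairedSites()].
#' @return A [ComparisonReport-class]. With fewer than 3 pairs the report
#'   carries `NA` statistics and a warning.
#' @export
compareConditions <- function(ctrl, treat, min_valid_cov = 50,
                              null_band = NULL, drop_zero_both = TRUE) {
  pairs <- joinPairedSites(ctrl, treat, min_valid_cov = min_valid_cov,
                           drop_zero_both = drop_zero_both)
  if (min_valid_cov < 50)
    warning("coverage floor ", min_valid_cov,
            " is below the calibrated 50-read minimum; ",
            "stoichiometry estimates will be noisier")
  if (!is.null(null_band) && null_band@source == "borrowed")
    warning("null band is borrowed from another comparison; ",
            "classification thresholds may not reflect this comparison's ",
            "replicate noise")
  if (nrow(pairs) < 3L) {
    warning("fewer than 3 shared sites; statistics set to NA")
    fit <- new("FitResult", r = NA_real_, pValue = NA_real_,
               slope = NA_real_, intercept = NA_real_,
               n = nrow(pairs))
    ba <- new("BlandAltmanResult", meanDiff = 0, sdDiff = NA_real_,
              loaLow = 0, loaHigh = 0, pctWithin = NA_real_,
              n = nrow(pairs))
    ds <- list()
  } else {
    fit <- fitConcordance(pairs)
    ba <- blandAltman(pairs)
    ds <- deltaDistribution(pairs)
  }
  pairs$label <- if (is.null(null_band)) {
    factor(rep(NA_character_, nrow(pairs)),
           levels = c("increased", "decreased", "unchanged"))
  } else {
    classifySites(pairs, null_band)
  }
  new("ComparisonReport", pairs = pairs, fit = fit, ba = ba,
      deltaSummary = ds, nullBand = null_band)
}

#' Classify site pairs against an empirical null band
#'
#' A site is `increased` when its difference strictly exceeds the band's
#' upper limit, `decreased` when strictly below the lower limit, and
#' `unchanged` otherwise -- a change must exceed baseline measurement
#' variability, so differences exactly on a limit are unchanged. The band
#' should come from an independent control-vs-control comparison; its
#' limits are used as-is, including any offset of the mean difference from
#' zero.
#'
#' @param pairs data.frame with a `delta` column (or numeric deltas).
#' @param null_band a [NullBand-class].
#' @return factor with levels `increased`, `decreased`, `unchanged`.
#' @export
classifySites <- function(pairs, null_band) {
  stopifnot(is(null_band, "NullBand"))
  d <- if (is.numeric(pairs)) pairs else pairs$delta
  out <- rep.int("unchanged", length(d))
  out[d > null_band@loaHigh] <- "increased"
  out[d < null_band@loaLow] <- "decreased"
  factor(out, levels = c("increased", "decreased", "unchanged"))
}

#' Subset site pairs to genomic regions
#'
#' Retains pairs whose site falls inside any of the given regions on the
#' matching strand (e.g. the m6A sites of one gene of interest). Regions
#' are BED-style 0-based half-open on disk; pass either a BED6 path or a
#' `GRanges`.
#'
#' @param pairs data.frame from [joinPairedSites()].
#' @param regions `GRanges` or path to a BED6 file ([readBed6()]).
#' @return The subset of `pairs` (possibly empty).
#' @export
subsetSites <- function(pairs, regions) {
  if (is.character(regions)) regions <- readBed6(regions)
  stopifnot(is(regions, "GRanges"))
  if (!nrow(pairs) || !length(regions)) return(pairs[integer(0), , drop = FALSE])
  sites <- GenomicRanges::GRanges(
    seqnames = pairs$chrom,
    ranges = IRanges::IRanges(start = pairs$pos0 + 1L, width = 1L),
    strand = pairs$strand)
  hits <- GenomicRanges::findOverlaps(sites, regions, ignore.strand = FALSE)
  pairs[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
}

#' Compare nanopore stoichiometries with an external method's site table
#'
#' Joins a nanopore site table with an externally measured
#' site-stoichiometry table (e.g. a chemical-deamination reference
#' dataset) and summarises concordance. Reference datasets of this kind
#' typically report only sites with stoichiometry above a floor (0.05), so
#' both sides are filtered to stoichiometries strictly above
#' `min_external_f` to keep the comparison symmetric.
#'
#' @param nanopore a [ModSiteTable-class].
#' @param external data.frame with columns `chrom`, `pos0`, `strand`, `f`.
#' @param min_external_f stoichiometry floor applied to both methods;
#'   default 0.05.
#' @param min_valid_cov nanopore coverage floor; default 50.
#' @return A [ComparisonReport-class] with the external method as sample B.
#' @export
crossMethodCompare <- function(nanopore, external, min_external_f = 0.05,
                               min_valid_cov = 50) {
  stopifnot(is(nanopore, "ModSiteTable"),
            all(c("chrom", "pos0", "strand", "f") %in% names(external)))
  np <- .table_to_dt(nanopore, "a")
  ext <- data.table::data.table(
    chrom = as.character(external$chrom),
    pos0 = as.integer(external$pos0),
    strand = as.character(external$strand),
    f_b = as.numeric(external$f), cov_b = NA_integer_)
  pairs <- merge(np, ext, by = c("chrom", "pos0", "strand"))
  pairs <- as.data.frame(pairs)
  pairs <- pairs[!is.na(pairs$f_a) & pairs$cov_a >= min_valid_cov, ]
  pairs <- pairs[pairs$f_a > min_external_f & pairs$f_b > min_external_f, ]
  if (!nrow(pairs)) stop("no shared sites after filtering")
  pairs$delta <- pairs$f_b - pairs$f_a
  pairs$log2fc <- ifelse(pairs$f_a > 0 & pairs$f_b > 0,
                         log2(pairs$f_b / pairs$f_a), NA_real_)
  fit <- fitConcordance(pairs)
  ba <- blandAltman(pairs)
  ds <- deltaDistribution(pairs)
  pairs$label <- factor(rep(NA_character_, nrow(pairs)),
                        levels = c("increased", "decreased", "unchanged"))
  new("ComparisonReport", pairs = pairs, fit = fit, ba = ba,
      deltaSummary = ds, nullBand = NULL)
}

#' Write a comparison report to disk
#'
#' Emits the per-site table as TSV and the summary statistics (fit,
#' Bland-Altman, label counts, null band) as JSON next to it.
#'
#' @param report a [ComparisonReport-class].
#' @param tsv_path per-site TSV output path.
#' @param json_path summary JSON output path; default replaces the TSV
#'   extension with `.json`.
#' @return `tsv_path`, invisibly.
#' @export
writeComparisonReport <- function(report, tsv_path,
                                  json_path = sub("\\.tsv$", ".json",
                                                  tsv_path)) {
  stopifnot(is(report, "ComparisonReport"))
  utils::write.table(report@pairs, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- list(
    fit = list(r = report@fit@r, p_value = report@fit@pValue,
               slope = report@fit@slope, intercept = report@fit@intercept,
               n = report@fit@n),
    bland_altman = list(mean_diff = report@ba@meanDiff,
                        sd_diff = report@ba@sdDiff,
                        loa_low = report@ba@loaLow,
                        loa_high = report@ba@loaHigh,
                        pct_within = report@ba@pctWithin),
    n_pairs = nrow(report@pairs),
    labels = as.list(table(report@pairs$label)),
    null_band = if (is.null(report@nullBand)) NULL else
      list(loa_low = report@nullBand@loaLow,
           loa_high = report@nullBand@loaHigh,
           source = report@nullBand@source))
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(tsv_path)
}
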