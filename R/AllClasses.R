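#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom stats sd median qt pt ecdf rnbinom rbeta rbinom runif rnorm
#'   complete.cases setNames
#' @importFrom utils head
#' @importFrom data.table data.table as.data.table setnames setorder
#'   rbindlist fread :=
NULL

setClassUnion("NullBand_OR_NULL", "NULL")

#' ModSiteTable: confidence-filtered per-site modification counts
#'
#' The central container of the package: one row per candidate modified
#' site (a single adenosine on a given strand), holding the number of
#' high-confidence modified calls (`n_mod`), high-confidence canonical
#' calls (`n_canon`) and discarded low-confidence calls (`n_fail`) observed
#' there, together with the confidence threshold `tau` under which the
#' counts were tabulated. Sites live in a [GenomicRanges::GRanges] (width-1
#' ranges, explicit strand, 0-based half-open on disk / 1-based inside R,
#' following Bioconductor convention).
#'
#' Stoichiometry at a site is `n_mod / (n_mod + n_canon)`, i.e. the modified
#' fraction among calls that passed the confidence filter; it is `NA` where
#' no call passed.
#'
#' @slot sites `GRanges` with integer metadata columns `n_mod`, `n_canon`,
#'   `n_fail`.
#' @slot tau numeric(1), the dual confidence threshold in (0.5, 1] applied
#'   to both the modified and the canonical class.
#' @slot sample character(1) sample label.
#' @slot replicates character vector of replicate labels merged into this
#'   table (length 1 for a single run).
#' @slot genome character(1) genome build tag (e.g. "hg38"); `NA` if unset.
#'
#' @seealso [pileupCalls()], [mergeSiteTables()], [filterByCoverage()],
#'   [stoichiometry()]
#' @export
setClass("ModSiteTable",
  slots = c(
    sites      = "GRanges",
    tau        = "numeric",
    sample     = "character",
    replicates = "character",
    genome     = "character"
  )
)

setValidity("ModSiteTable", function(object) {
  msg <- character()
  mc <- S4Vectors::mcols(object@sites)
  need <- c("n_mod", "n_canon", "n_fail")
  if (!all(need %in% colnames(mc))) {
    return(paste("sites must carry metadata columns", paste(need, collapse = ", ")))
  }
  for (col in need) {
    v <- mc[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0)) {
      msg <- c(msg, sprintf("'%s' must be non-negative and non-missing", col))
    }
  }
  if (length(object@tau) != 1L || is.na(object@tau) ||
      object@tau <= 0.5 || object@tau > 1) {
    msg <- c(msg, "tau must be a single value in (0.5, 1]")
  }
  if (any(GenomicRanges::width(object@sites) != 1L)) {
    msg <- c(msg, "all sites must be width-1 ranges")
  }
  if (any(as.character(GenomicRanges::strand(object@sites)) == "*")) {
    msg <- c(msg, "every site must have explicit strand (+ or -)")
  }
  key <- paste(GenomicRanges::seqnames(object@sites),
               GenomicRanges::start(object@sites),
               GenomicRanges::strand(object@sites))
  if (anyDuplicated(key)) msg <- c(msg, "site keys must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a ModSiteTable
#'
#' @param sites `GRanges` of width-1, stranded sites with integer metadata
#'   columns `n_mod`, `n_canon`, `n_fail`.
#' @param tau confidence threshold used to produce the counts.
#' @param sample sample label.
#' @param replicates replicate labels (defaults to `sample`).
#' @param genome genome build tag.
#' @return A `ModSiteTable`.
#' @export
ModSiteTable <- function(sites, tau = 0.99, sample = "sample",
                         replicates = sample, genome = NA_character_) {
  for (col in c("n_mod", "n_canon", "n_fail")) {
    S4Vectors::mcols(sites)[[col]] <- as.integer(S4Vectors::mcols(sites)[[col]])
  }
  new("ModSiteTable", sites = sites, tau = tau, sample = sample,
      replicates = replicates, genome = genome)
}

#' Pearson fit summary for paired stoichiometries
#'
#' Pearson's product-moment correlation with its two-sided p-value from the
#' t reference distribution on n - 2 degrees of freedom, plus the
#' least-squares regression of the second sample's stoichiometry on the
#' first's.
#'
#' @slot r Pearson correlation coefficient.
#' @slot pValue two-sided p-value (NA when r is undefined or n < 3).
#' @slot slope,intercept least-squares line f_B ~ f_A.
#' @slot n number of site pairs.
#' @export
setClass("FitResult",
  slots = c(r = "numeric", pValue = "numeric", slope = "numeric",
            intercept = "numeric", n = "integer"))

#' Bland-Altman agreement summary
#'
#' Mean paired difference, its sample standard deviation (n - 1
#' denominator) and the 95% limits of agreement, mean +/- 1.96 * SD. The
#' limits of a control-vs-control comparison serve as the empirical null
#' band for classifying differential sites.
#'
#' @slot meanDiff mean of per-site differences.
#' @slot sdDiff sample SD of differences.
#' @slot loaLow,loaHigh limits of agreement.
#' @slot pctWithin fraction of the differences inside `[loaLow, loaHigh]`.
#' @slot n number of differences.
#' @export
setClass("BlandAltmanResult",
  slots = c(meanDiff = "numeric", sdDiff = "numeric", loaLow = "numeric",
            loaHigh = "numeric", pctWithin = "numeric", n = "integer"))

setValidity("BlandAltmanResult", function(object) {
  if (object@loaLow > object@meanDiff || object@meanDiff > object@loaHigh)
    return("limits of agreement must bracket the mean difference")
  TRUE
})

#' Empirical null band for differential classification
#'
#' An interval of stoichiometry differences attributable to measurement
#' noise, normally taken from the limits of agreement of a
#' control-vs-control [blandAltman()] comparison. Differences beyond the
#' band are classified as changed.
#'
#' @slot loaLow,loaHigh band limits (low < high).
#' @slot source "estimated" when derived from same-condition replicates,
#'   "borrowed" when carried over from another comparison (e.g. when a
#'   condition has a single replicate and no own null is available).
#' @export
setClass("NullBand",
  slots = c(loaLow = "numeric", loaHigh = "numeric", source = "character"))

setValidity("NullBand", function(object) {
  if (!(object@loaLow < object@loaHigh)) return("loaLow must be < loaHigh")
  TRUE
})
setIs("NullBand", "NullBand_OR_NULL")

#' Construct a NullBand
#'
#' @param x either a `BlandAltmanResult` (its limits of agreement are
#'   adopted, including any offset of the mean difference from zero) or
#'   numeric(1): the half-width of a band symmetric about zero.
#' @param source provenance label, `"estimated"` or `"borrowed"`.
#' @return A `NullBand`.
#' @examples
#' nullBand(0.066)  # the +/-0.066 baseline-variability band
#' @export
nullBand <- function(x, source = c("estimated", "borrowed")) {
  source <- match.arg(source)
  if (is(x, "BlandAltmanResult")) {
    new("NullBand", loaLow = x@loaLow, loaHigh = x@loaHigh, source = source)
  } else {
    stopifnot(is.numeric(x), length(x) == 1L, x > 0)
    new("NullBand", loaLow = -x, loaHigh = x, source = source)
  }
}

#' Two-condition comparison report
#'
#' The composite result of [compareConditions()]: the joined per-site pairs
#' with differences, log2 fold changes and (when a null band was supplied)
#' per-site labels, together with the concordance fit, the Bland-Altman
#' summary and the difference-distribution summary.
#'
#' @slot pairs data.frame of per-site rows (`chrom`, `pos0`, `strand`,
#'   `f_a`, `f_b`, `cov_a`, `cov_b`, `delta`, `log2fc`, `label`).
#' @slot fit [FitResult-class].
#' @slot ba [BlandAltmanResult-class].
#' @slot deltaSummary list from [deltaDistribution()].
#' @slot nullBand the [NullBand-class] used for labelling, or `NULL`.
#' @export
setClass("ComparisonReport",
  slots = c(pairs = "data.frame", fit = "FitResult", ba = "BlandAltmanResult",
            deltaSummary = "list", nullBand = "NullBand_OR_NULL"))
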