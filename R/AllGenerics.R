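#' Accessors for ModSiteTable
#'
#' @param x a [ModSiteTable-class].
#' @return `siteRanges` the underlying `GRanges`; `modCounts`,
#'   `canonCounts`, `failCounts` integer vectors; `validCoverage`
#'   `n_mod + n_canon`; `stoichiometry` `n_mod / validCoverage` (`NA` where
#'   valid coverage is 0); `confidenceTau` the filter threshold;
#'   `sampleLabel`, `replicateLabels`, `genomeBuild` the metadata.
#' @name ModSiteTable-accessors
NULL

#' @rdname ModSiteTable-accessors
#' @export
setGeneric("siteRanges", function(x) standardGeneric("siteRanges"))
#' @rdname ModSiteTable-accessors
#' @export
setGeneric("modCounts", function(x) standardGeneric("modCounts"))
#' @rdname ModSiteTable-accessors
#' @export
setGeneric("canonCounts", function(x) standardGeneric("canonCounts"))
#' @rdname ModSiteTable-accessors
#' @export
setGeneric("failCounts", function(x) standardGeneric("failCounts"))
#' @rdname ModSiteTable-accessors
#' @export
setGeneric("validCoverage", function(x) standardGeneric("validCoverage"))
#' @rdname ModSiteTable-accessors
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))
#' @rdname ModSiteTable-accessors
#' @export
setGeneric("confidenceTau", function(x) standardGeneric("confidenceTau"))
#' @rdname ModSiteTable-accessors
#' @export
setGeneric("sampleLabel", function(x) standardGeneric("sampleLabel"))
#' @rdname ModSiteTable-accessors
#' @export
setGeneric("replicateLabels", function(x) standardGeneric("replicateLabels"))
#' @rdname ModSiteTable-accessors
#' @export
setGeneric("genomeBuild", function(x) standardGeneric("genomeBuild"))

#' @rdname ModSiteTable-accessors
setMethod("siteRanges", "ModSiteTable", function(x) x@sites)
#' @rdname ModSiteTable-accessors
setMethod("modCounts", "ModSiteTable",
          function(x) S4Vectors::mcols(x@sites)$n_mod)
#' @rdname ModSiteTable-accessors
setMethod("canonCounts", "ModSiteTable",
          function(x) S4Vectors::mcols(x@sites)$n_canon)
#' @rdname ModSiteTable-accessors
setMethod("failCounts", "ModSiteTable",
          function(x) S4Vectors::mcols(x@sites)$n_fail)
#' @rdname ModSiteTable-accessors
setMethod("validCoverage", "ModSiteTable",
          function(x) modCounts(x) + canonCounts(x))
#' @rdname ModSiteTable-accessors
setMethod("stoichiometry", "ModSiteTable", function(x) {
  vc <- validCoverage(x)
  ifelse(vc > 0L, modCounts(x) / vc, NA_real_)
})
#' @rdname ModSiteTable-accessors
setMethod("confidenceTau", "ModSiteTable", function(x) x@tau)
#' @rdname ModSiteTable-accessors
setMethod("sampleLabel", "ModSiteTable", function(x) x@sample)
#' @rdname ModSiteTable-accessors
setMethod("replicateLabels", "ModSiteTable", function(x) x@replicates)
#' @rdname ModSiteTable-accessors
setMethod("genomeBuild", "ModSiteTable", function(x) x@genome)

#' @describeIn ModSiteTable number of sites in the table
#' @param x a `ModSiteTable`.
#' @export
setMethod("length", "ModSiteTable", function(x) length(x@sites))

#' @describeIn ModSiteTable subset sites positionally or logically
#' @param i index into the sites.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "ModSiteTable", function(x, i, j, ..., drop = FALSE) {
  initialize(x, sites = x@sites[i])
})

setMethod("show", "ModSiteTable", function(object) {
  vc <- validCoverage(object)
  cat(sprintf("ModSiteTable '%s' (%s): %d sites, tau = %g\n",
              object@sample,
              paste(object@replicates, collapse = "+"),
              length(object), object@tau))
  if (length(object)) {
    cat(sprintf("  valid coverage: median %d [%d, %d]; stoichiometry: mean %.3f\n",
                as.integer(median(vc)), min(vc), max(vc),
                mean(stoichiometry(object), na.rm = TRUE)))
  }
  invisible(NULL)
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: r = %.4f (p = %.3g), f_B = %.4f * f_A + %.5f, n = %d\n",
              object@r, object@pValue, object@slope, object@intercept,
              object@n))
  invisible(NULL)
})

setMethod("show", "BlandAltmanResult", function(object) {
  cat(sprintf(paste0("Bland-Altman: mean diff = %.5f, SD = %.5f, ",
                     "95%% LoA [%.4f, %.4f], %.1f%% within, n = %d\n"),
              object@meanDiff, object@sdDiff, object@loaLow, object@loaHigh,
              100 * object@pctWithin, object@n))
  invisible(NULL)
})

setMethod("show", "NullBand", function(object) {
  cat(sprintf("NullBand (%s): [%.4f, %.4f]\n",
              object@source, object@loaLow, object@loaHigh))
  invisible(NULL)
})

setMethod("show", "ComparisonReport", function(object) {
  cat("ComparisonReport\n")
  show(object@fit)
  show(object@ba)
  if (!is.null(object@nullBand) && "label" %in% names(object@pairs)) {
    tab <- table(object@pairs$label)
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(NULL)
})
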