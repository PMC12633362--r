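.table_to_dt <- function(table, prefix) {
  gr <- siteRanges(table)
  vc <- validCoverage(table)
  f <- stoichiometry(table)
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos0 = GenomicRanges::start(gr) - 1L,
    strand = as.character(GenomicRanges::strand(gr)),
    f = f, cov = vc)
  data.table::setnames(dt, c("f", "cov"),
                       paste0(c("f_", "cov_"), prefix))
  dt
}

#' Join two site tables into per-site stoichiometry pairs
#'
#' Inner join on (chromosome, position, strand), restricted to sites whose
#' valid coverage reaches `min_valid_cov` in both samples. Pairs with zero
#' stoichiometry in both samples are removed by default -- such sites carry
#' no information about a change and would otherwise pile up at the origin.
#' The difference column is `delta = f_B - f_A` under the default sign
#' convention (treated minus control when A is the control).
#'
#' @param tableA,tableB [ModSiteTable-class] objects built with the same
#'   confidence threshold.
#' @param min_valid_cov coverage floor applied to both samples; default 50.
#' @param drop_zero_both drop pairs with `f_A = f_B = 0`; default `TRUE`.
#' @param delta_sign `"B-A"` (default) or `"A-B"`.
#' @return data.frame with columns `chrom`, `pos0`, `strand`, `f_a`, `f_b`,
#'   `cov_a`, `cov_b`, `delta`, `log2fc` (`NA` when either stoichiometry is
#'   zero).
#' @export
joinPairedSites <- function(tableA, tableB, min_valid_cov = 50,
                            drop_zero_both = TRUE,
                            delta_sign = c("B-A", "A-B")) {
  stopifnot(is(tableA, "ModSiteTable"), is(tableB, "ModSiteTable"))
  delta_sign <- match.arg(delta_sign)
  if (!isTRUE(all.equal(confidenceTau(tableA), confidenceTau(tableB))))
    stop("site tables were built with different tau (",
         confidenceTau(tableA), " vs ", confidenceTau(tableB), ")")
  a <- .table_to_dt(tableA, "a")
  b <- .table_to_dt(tableB, "b")
  pairs <- merge(a, b, by = c("chrom", "pos0", "strand"))
  pairs <- pairs[pairs$cov_a >= min_valid_cov & pairs$cov_b >= min_valid_cov, ]
  pairs <- pairs[!is.na(pairs$f_a) & !is.na(pairs$f_b), ]
  if (drop_zero_both)
    pairs <- pairs[!(pairs$f_a == 0 & pairs$f_b == 0), ]
  pairs <- as.data.frame(pairs)
  pairs$delta <- if (delta_sign == "B-A") pairs$f_b - pairs$f_a
                 else pairs$f_a - pairs$f_b
  pairs$log2fc <- ifelse(pairs$f_a > 0 & pairs$f_b > 0,
                         log2(pairs$f_b / pairs$f_a), NA_real_)
  pairs[order(pairs$chrom, pairs$pos0, pairs$strand), , drop = FALSE]
}

#' Pearson concordance and least-squares fit of paired stoichiometries
#'
#' Computes Pearson's product-moment correlation between the two samples'
#' stoichiometries, its two-sided p-value from the t reference distribution
#' on n - 2 degrees of freedom, and the least-squares regression line of
#' `f_B` on `f_A`. The statistics are computed from their closed forms.
#'
#' @param pairs data.frame from [joinPairedSites()] (columns `f_a`, `f_b`),
#'   or a list/data.frame with two numeric vectors.
#' @return A [FitResult-class]. When either vector is constant the
#'   correlation is undefined: `r` and `pValue` are `NA` with a warning
#'   (the regression slope is still defined unless `f_a` is constant).
#' @export
fitConcordance <- function(pairs) {
  x <- pairs$f_a; y <- pairs$f_b
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs")
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy <- sum((x - mx) * (y - my))
  if (sxx == 0 || syy == 0) {
    warning("constant input vector: correlation undefined")
    r <- NA_real_; p <- NA_real_
  } else {
    r <- sxy / sqrt(sxx * syy)
    if (n >= 3L && abs(r) < 1) {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    } else {
      p <- if (n >= 3L) 0 else NA_real_
    }
  }
  slope <- if (sxx > 0) sxy / sxx else NA_real_
  intercept <- if (sxx > 0) my - slope * mx else NA_real_
  new("FitResult", r = r, pValue = p, slope = slope,
      intercept = intercept, n = as.integer(n))
}

#' Bland-Altman agreement of paired stoichiometries
#'
#' Mean per-site difference, its sample standard deviation (n - 1
#' denominator) and the 95% limits of agreement
#' `mean +/- 1.96 * SD`, plus the directly counted fraction of differences
#' inside the limits. Applied to two same-condition replicates this yields
#' the empirical null band for differential classification.
#'
#' @param pairs data.frame from [joinPairedSites()] (column `delta`), or a
#'   numeric vector of differences.
#' @return A [BlandAltmanResult-class].
#' @examples
#' blandAltman(c(-0.1, 0.1))  # LoA approximately +/- 0.277
#' @export
blandAltman <- function(pairs) {
  d <- if (is.numeric(pairs)) pairs else pairs$delta
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2L) stop("need at least 2 differences (SD undefined)")
  m <- mean(d)
  s <- sd(d)
  lo <- m - 1.96 * s
  hi <- m + 1.96 * s
  new("BlandAltmanResult", meanDiff = m, sdDiff = s, loaLow = lo,
      loaHigh = hi, pctWithin = mean(d >= lo & d <= hi),
      n = as.integer(n))
}

#' Sweep coverage thresholds and summarise replicate concordance
#'
#' For each minimum-coverage threshold `T` in the grid, joins the two
#' tables at that floor and reports the number of retained site pairs, the
#' squared Pearson correlation (R^2, the coefficient of determination) and
#' the Bland-Altman mean difference and limits of agreement. Used to pick
#' the working coverage threshold: precision improves (narrower limits)
#' while retention falls as `T` grows.
#'
#' @param tableA,tableB [ModSiteTable-class] objects (typically two
#'   same-condition replicates or replicate groups).
#' @param grid integer thresholds, sorted non-negative; the default covers
#'   0 to 200 in steps of 10 plus the conventional working points 25 and
#'   50.
#' @param drop_zero_both passed to [joinPairedSites()].
#' @return data.frame with columns `T`, `n_sites`, `r`, `R2`, `mean_diff`,
#'   `loa_low`, `loa_high`. Thresholds retaining fewer than 3 pairs get
#'   `NA` statistics with a warning.
#' @export
sweepCoverageThresholds <- function(tableA, tableB,
                                    grid = sort(unique(c(seq(0, 200, by = 10),
                                                         25, 50))),
                                    drop_zero_both = TRUE) {
  if (!length(grid) || any(grid < 0) || is.unsorted(grid))
    stop("grid must be non-empty, non-negative and sorted")
  rows <- lapply(grid, function(T) {
    pairs <- joinPairedSites(tableA, tableB, min_valid_cov = T,
                             drop_zero_both = drop_zero_both)
    n <- nrow(pairs)
    if (n < 3L) {
      warning("threshold ", T, " retains ", n,
              " pairs (< 3): statistics set to NA")
      return(data.frame(T = T, n_sites = n, r = NA_real_, R2 = NA_real_,
                        mean_diff = NA_real_, loa_low = NA_real_,
                        loa_high = NA_real_))
    }
    fit <- suppressWarnings(fitConcordance(pairs))
    ba <- blandAltman(pairs)
    data.frame(T = T, n_sites = n, r = fit@r, R2 = fit@r^2,
               mean_diff = ba@meanDiff, loa_low = ba@loaLow,
               loa_high = ba@loaHigh)
  })
  do.call(rbind, rows)
}

#' Flag the smallest threshold whose precision is near its asymptote
#'
#' Scans a sweep table and returns the smallest threshold whose limits-of-
#' agreement half-width is within `rel_tol` of the half-width at the
#' largest threshold (taken as the asymptote). This is a suggestion for
#' the analyst to confirm, not an automated decision: the working threshold
#' trades precision against site retention.
#'
#' @param sweep data.frame from [sweepCoverageThresholds()].
#' @param rel_tol relative closeness to the asymptotic half-width; default
#'   0.10.
#' @return The suggested threshold (numeric), or `NA` if no row qualifies.
#' @export
suggestCoverageThreshold <- function(sweep, rel_tol = 0.10) {
  hw <- (sweep$loa_high - sweep$loa_low) / 2
  ok <- !is.na(hw)
  if (!any(ok)) return(NA_real_)
  asym <- hw[max(which(ok))]
  cand <- which(ok & hw <= asym * (1 + rel_tol))
  if (!length(cand)) return(NA_real_)
  sweep$T[min(cand)]
}

#' Distribution of per-site differences and fold changes
#'
#' Summarises the spread of stoichiometry changes between two samples: a
#' histogram and empirical CDF of `delta`, and an empirical CDF of
#' `log2(f_B/f_A)`. Under the default policy, pairs where either
#' stoichiometry is zero have no finite fold change and are dropped from
#' the log2FC ECDF, with the dropped count reported; alternatively a
#' pseudocount can be added to both stoichiometries before taking the
#' ratio.
#'
#' @param pairs data.frame from [joinPairedSites()].
#' @param breaks histogram breaks for `delta` (passed to [hist()]).
#' @param pseudocount `NULL` (default: drop non-finite fold changes) or a
#'   small positive value added to both stoichiometries.
#' @return list with `delta_hist` (breaks/counts), `delta_ecdf` and
#'   `log2fc_ecdf` (step functions from [stats::ecdf()]; the latter `NULL`
#'   when no finite value remains, with a warning), `log2fc` (the finite
#'   values used) and `n_dropped_nonfinite`.
#' @export
deltaDistribution <- function(pairs, breaks = "Sturges", pseudocount = NULL) {
  if (!nrow(pairs)) stop("pairs must be non-empty")
  h <- graphics::hist(pairs$delta, breaks = breaks, plot = FALSE)
  if (is.null(pseudocount)) {
    lfc <- pairs$log2fc
  } else {
    stopifnot(pseudocount > 0)
    lfc <- log2((pairs$f_b + pseudocount) / (pairs$f_a + pseudocount))
  }
  finite <- is.finite(lfc)
  n_drop <- sum(!finite)
  lfc <- lfc[finite]
  lfc_ecdf <- if (length(lfc)) ecdf(lfc) else {
    warning("no finite log2 fold changes")
    NULL
  }
  list(delta_hist = list(breaks = h$breaks, counts = h$counts),
       delta_ecdf = ecdf(pairs$delta),
       log2fc_ecdf = lfc_ecdf,
       log2fc = lfc,
       n_dropped_nonfinite = n_drop)
}

#' Write a threshold-sweep report
#'
#' @param sweep data.frame from [sweepCoverageThresholds()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeSweepTable <- function(sweep, path) {
  utils::write.table(sweep, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
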