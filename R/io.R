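#' Read a per-read modification call table
#'
#' Tab-separated, five columns: `read_id`, `chrom`, `pos0` (0-based),
#' `strand`, `p_mod`. A single leading header line is permitted when
#' prefixed with `#`. Rows with the wrong number of fields or a
#' non-numeric probability are reported with their line number.
#'
#' @param path file path.
#' @return data.frame suitable for [pileupCalls()].
#' @export
readCallsTable <- function(path) {
  lines <- readLines(path)
  lineno <- seq_along(lines)
  if (length(lines) && startsWith(lines[1], "#")) {
    lines <- lines[-1]; lineno <- lineno[-1]
  }
  keep <- nzchar(lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  if (!length(lines)) {
    return(data.frame(read_id = character(), chrom = character(),
                      pos0 = integer(), strand = character(),
                      p_mod = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 5L))
    stop("expected 5 tab-separated columns; line(s) ",
         paste(head(lineno[nf != 5L], 5), collapse = ", "),
         " have ", paste(unique(nf[nf != 5L]), collapse = "/"))
  m <- matrix(unlist(fields), ncol = 5L, byrow = TRUE)
  p <- suppressWarnings(as.numeric(m[, 5]))
  if (anyNA(p))
    stop("non-numeric p_mod at line(s) ",
         paste(head(lineno[is.na(p)], 5), collapse = ", "))
  out <- data.frame(read_id = m[, 1], chrom = m[, 2],
                    pos0 = as.integer(m[, 3]), strand = m[, 4], p_mod = p)
  .validate_calls(out)
  out
}

#' Write a per-read modification call table
#'
#' @param calls data.frame with the five call columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCallsTable <- function(calls, path) {
  .validate_calls(calls)
  header <- "#read_id\tchrom\tpos0\tstrand\tp_mod"
  body <- sprintf("%s\t%s\t%d\t%s\t%.6g", calls$read_id, calls$chrom,
                  as.integer(calls$pos0), calls$strand, calls$p_mod)
  writeLines(c(header, body), path)
  invisible(path)
}

.BEDMETHYL_NCOL <- 18L

#' Write a site table as bedMethyl
#'
#' One row per site, 0-based half-open single-base records in the 18-column
#' bedMethyl dialect: chrom, start, end, mod code (`a`), valid coverage,
#' strand, start, end, colour, valid coverage, percent modified (2
#' decimals), n_mod, n_canon, 0, 0, n_fail, 0, 0. Table metadata (sample,
#' tau, genome, replicates) is stored in a single leading `#` comment so
#' that [readBedMethyl()] round-trips the object; counts round-trip
#' exactly and stoichiometry is recomputed from them.
#'
#' @param table a [ModSiteTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBedMethyl <- function(table, path) {
  stopifnot(is(table, "ModSiteTable"))
  gr <- siteRanges(table)
  start0 <- GenomicRanges::start(gr) - 1L
  vc <- validCoverage(table)
  pct <- ifelse(vc > 0L, 100 * modCounts(table) / vc, 0)
  meta <- sprintf("#m6Astoich sample=%s;tau=%.10g;genome=%s;replicates=%s",
                  sampleLabel(table), confidenceTau(table),
                  genomeBuild(table),
                  paste(replicateLabels(table), collapse = ","))
  body <- sprintf(
    "%s\t%d\t%d\ta\t%d\t%s\t%d\t%d\t255,0,0\t%d\t%.2f\t%d\t%d\t0\t0\t%d\t0\t0",
    as.character(GenomicRanges::seqnames(gr)), start0, start0 + 1L,
    vc, as.character(GenomicRanges::strand(gr)), start0, start0 + 1L,
    vc, pct, modCounts(table), canonCounts(table), failCounts(table))
  writeLines(c(meta, body), path)
  invisible(path)
}

#' Read a bedMethyl site table
#'
#' Accepts the dialect written by [writeBedMethyl()] (and Modkit-style
#' tables with the same column layout). Records must be single-base
#' (end = start + 1). Metadata is recovered from the leading `#` comment
#' when present; otherwise supply `tau` explicitly.
#'
#' @param path file path.
#' @param tau fallback confidence threshold when the file has no metadata
#'   comment.
#' @return A [ModSiteTable-class].
#' @export
readBedMethyl <- function(path, tau = NA_real_) {
  lines <- readLines(path)
  lineno <- seq_along(lines)
  sample <- "sample"; genome <- NA_character_; reps <- NULL
  is_comment <- startsWith(lines, "#")
  for (h in lines[is_comment]) {
    if (grepl("^#m6Astoich ", h)) {
      kv <- strsplit(sub("^#m6Astoich ", "", h), ";", fixed = TRUE)[[1]]
      kv <- strsplit(kv, "=", fixed = TRUE)
      vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
      if (!is.na(vals["sample"])) sample <- vals[["sample"]]
      if (!is.na(vals["tau"])) tau <- as.numeric(vals[["tau"]])
      if (!is.na(vals["genome"]) && vals[["genome"]] != "NA")
        genome <- vals[["genome"]]
      if (!is.na(vals["replicates"]))
        reps <- strsplit(vals[["replicates"]], ",", fixed = TRUE)[[1]]
    }
  }
  lines <- lines[!is_comment]; lineno <- lineno[!is_comment]
  keep <- nzchar(lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  if (is.na(tau))
    stop("no tau metadata in ", path, "; supply tau explicitly")
  if (!length(lines)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      n_mod = integer(), n_canon = integer(), n_fail = integer())
    return(ModSiteTable(gr, tau = tau, sample = sample,
                        replicates = if (is.null(reps)) sample else reps,
                        genome = genome))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != .BEDMETHYL_NCOL))
    stop("expected ", .BEDMETHYL_NCOL, " columns; line(s) ",
         paste(head(lineno[nf != .BEDMETHYL_NCOL], 5), collapse = ", "),
         " differ")
  m <- matrix(unlist(fields), ncol = .BEDMETHYL_NCOL, byrow = TRUE)
  start0 <- as.integer(m[, 2]); end <- as.integer(m[, 3])
  bad <- end != start0 + 1L
  if (any(bad))
    stop("non single-base record(s) (end != start + 1) at line(s) ",
         paste(head(lineno[bad], 5), collapse = ", "))
  gr <- GenomicRanges::GRanges(
    seqnames = m[, 1],
    ranges = IRanges::IRanges(start = start0 + 1L, width = 1L),
    strand = m[, 6],
    n_mod = as.integer(m[, 12]),
    n_canon = as.integer(m[, 13]),
    n_fail = as.integer(m[, 16]))
  ModSiteTable(gr, tau = tau, sample = sample,
               replicates = if (is.null(reps)) sample else reps,
               genome = genome)
}

#' Read a BED6 region or annotation file
#'
#' Minimal strict BED6 reader (0-based half-open): chrom, start, end, name,
#' score, strand. Malformed lines are reported with their line number.
#'
#' @param path file path.
#' @return A `GRanges` with metadata column `name`.
#' @export
readBed6 <- function(path) {
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lines <- lines[keep]; lineno <- lineno[keep]
  if (!length(lines)) return(GenomicRanges::GRanges(name = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop("BED6 requires 6 columns; line(s) ",
         paste(head(lineno[nf < 6L], 5), collapse = ", "), " have fewer")
  m <- t(vapply(fields, function(f) f[1:6], character(6)))
  start0 <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- is.na(start0) | is.na(end) | end <= start0 |
    !m[, 6] %in% c("+", "-")
  if (any(bad))
    stop("malformed BED6 record(s) at line(s) ",
         paste(head(lineno[bad], 5), collapse = ", "))
  GenomicRanges::GRanges(
    seqnames = m[, 1],
    ranges = IRanges::IRanges(start = start0 + 1L, end = end),
    strand = m[, 6],
    name = m[, 4])
}

#' Read aligned 5'-end records for TSS base counting
#'
#' Tab-separated with columns `chrom`, `pos0` (0-based mapped 5' position),
#' `strand`, `mate` (1/2), `softclip5` (0/1), `base` (A/C/G/T/N),
#' `read_id`. A `#`-prefixed header line is skipped.
#'
#' @param path file path.
#' @return data.frame suitable for [tssNonconversion()].
#' @export
readStartRecords <- function(path) {
  lines <- readLines(path)
  lineno <- seq_along(lines)
  if (length(lines) && startsWith(lines[1], "#")) {
    lines <- lines[-1]; lineno <- lineno[-1]
  }
  keep <- nzchar(lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  if (!length(lines)) {
    return(data.frame(chrom = character(), pos0 = integer(),
                      strand = character(), mate = integer(),
                      softclip5 = integer(), base = character(),
                      read_id = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 7L))
    stop("expected 7 tab-separated columns; line(s) ",
         paste(head(lineno[nf != 7L], 5), collapse = ", "), " differ")
  m <- matrix(unlist(fields), ncol = 7L, byrow = TRUE)
  out <- data.frame(chrom = m[, 1], pos0 = as.integer(m[, 2]),
                    strand = m[, 3], mate = as.integer(m[, 4]),
                    softclip5 = as.integer(m[, 5]), base = m[, 6],
                    read_id = m[, 7])
  if (!all(out$base %in% c("A", "C", "G", "T", "N")))
    stop("base column must be one of A, C, G, T, N")
  out
}
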