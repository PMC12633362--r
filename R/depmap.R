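#' Read a DepMap-layout matrix
#'
#' Portal-layout CSV: first column holds cell-line/model identifiers, the
#' remaining columns one gene each, usually headed `"SYMBOL (ENTREZID)"`.
#'
#' @param path CSV path.
#' @return numeric matrix with model identifiers as row names and the
#'   original gene headers as column names.
#' @export
readDependencyMatrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids)) stop("duplicate cell-line identifiers in ", path)
  m <- as.matrix(dt[, -1, with = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Read a cell-line lineage map
#'
#' CSV with at least a model identifier column (first) and a lineage
#' column; a subtype column is carried along when present.
#'
#' @param path CSV path.
#' @return data.frame with columns `model_id`, `lineage` and optionally
#'   `subtype`.
#' @export
readLineageMap <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  out <- data.frame(model_id = as.character(dt[[1]]),
                    lineage = as.character(dt[[2]]))
  if (ncol(dt) >= 3L) out$subtype <- as.character(dt[[3]])
  out
}

.match_gene_column <- function(m, gene) {
  cols <- colnames(m)
  hit <- which(cols == gene)
  if (!length(hit))
    hit <- which(startsWith(cols, paste0(gene, " (")))
  if (!length(hit)) stop("gene '", gene, "' not found in matrix")
  if (length(hit) > 1L)
    stop("gene '", gene, "' matches multiple columns: ",
         paste(cols[hit], collapse = ", "))
  hit
}

.subset_lines <- function(m, subset) {
  if (is.null(subset)) return(m)
  keep <- intersect(rownames(m), subset)
  if (!length(keep)) stop("subset has no cell lines in common with matrix")
  m[keep, , drop = FALSE]
}

#' Count dependent cell lines for a gene
#'
#' A cell line is dependent on a gene when its dependency probability is
#' strictly greater than the threshold (0.5 by convention: a probability
#' exactly 0.5 does not qualify). Lines with a missing value for the gene
#' are excluded from both the count and the denominator -- a line without
#' a score cannot be classified.
#'
#' @param matrix dependency-probability matrix from
#'   [readDependencyMatrix()] (values in \[0, 1\]).
#' @param gene gene symbol; matched exactly against the column header, or
#'   as the symbol prefix of a `"SYMBOL (ENTREZID)"` header.
#' @param threshold dependency cut-off, default 0.5.
#' @param subset optional character vector of cell-line identifiers (e.g.
#'   the AML lines from a lineage map) to restrict the count to.
#' @return named integer vector `c(n_dependent, n_total)`.
#' @export
countDependent <- function(matrix, gene, threshold = 0.5, subset = NULL) {
  m <- .subset_lines(matrix, subset)
  v <- m[, .match_gene_column(m, gene)]
  v <- v[!is.na(v)]
  if (!length(v)) stop("all values missing for gene '", gene, "'")
  if (any(v < 0 | v > 1))
    stop("dependency probabilities must lie in [0, 1]; ",
         "is this a gene-effect matrix?")
  c(n_dependent = sum(v > threshold), n_total = length(v))
}

#' Summarise gene-effect scores for a gene
#'
#' Gene-effect scores are scaled so that 0 represents a non-essential gene
#' and -1 the median of common essential genes; more negative means more
#' dependent. Reports the count of scored lines, the median score and the
#' fractions at or below -0.5 and -1.
#'
#' @param matrix gene-effect matrix from [readDependencyMatrix()].
#' @param gene,subset as in [countDependent()].
#' @return list with `n`, `median`, `frac_le_m0.5`, `frac_le_m1`.
#' @export
summarizeGeneEffect <- function(matrix, gene, subset = NULL) {
  m <- .subset_lines(matrix, subset)
  v <- m[, .match_gene_column(m, gene)]
  v <- v[!is.na(v)]
  if (!length(v)) stop("all values missing for gene '", gene, "'")
  list(n = length(v), median = median(v),
       frac_le_m0.5 = mean(v <= -0.5),
       frac_le_m1 = mean(v <= -1))
}

#' MTT assay cell viability
#'
#' Viability percentage of a drug-treated group relative to its
#' vehicle-treated control:
#' `100 * mean(treated absorbance) / mean(control absorbance)`, computed
#' per timepoint. Absorbance is proportional to viable cell number, so the
#' ratio is scale-invariant.
#'
#' @param treated,control numeric vectors of replicate absorbances for one
#'   timepoint, or matrices with one column per timepoint (replicates in
#'   rows).
#' @return numeric vector of viability percentages (one per timepoint).
#' @examples
#' mttViability(c(0.4, 0.4), c(0.8, 0.8))  # 50
#' @export
mttViability <- function(treated, control) {
  if (is.matrix(treated) || is.matrix(control)) {
    treated <- as.matrix(treated); control <- as.matrix(control)
    if (ncol(treated) != ncol(control))
      stop("treated and control must have the same number of timepoints")
    return(vapply(seq_len(ncol(treated)), function(j)
      mttViability(treated[, j], control[, j]), numeric(1)))
  }
  if (!length(treated) || !length(control))
    stop("treated and control must be non-empty")
  mc <- mean(control)
  if (!is.finite(mc) || mc <= 0) stop("control mean absorbance must be > 0")
  100 * mean(treated) / mc
}
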