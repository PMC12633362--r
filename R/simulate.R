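#' Simulate per-site true m6A stoichiometries
#'
#' Draws per-site ground-truth stoichiometries from a mixture of a point
#' mass at zero (unmethylated candidate sites) and a Beta distribution for
#' the methylated fraction. The defaults -- 30% zeros and Beta(1.2, 2.5)
#' -- give the low-skewed, long-right-tailed distribution typical of m6A
#' site stoichiometries.
#'
#' @param n_sites number of sites.
#' @param pi0 zero-component weight.
#' @param beta_a,beta_b Beta shape parameters for methylated sites.
#' @param chrom chromosome name for the synthetic sites.
#' @param spacing distance between consecutive site positions.
#' @param seed RNG seed.
#' @return data.frame with `chrom`, `pos0`, `strand`, `f`.
#' @export
simulateSiteTruth <- function(n_sites = 2000, pi0 = 0.3, beta_a = 1.2,
                              beta_b = 2.5, chrom = "chrS", spacing = 100L,
                              seed = 1) {
  stopifnot(pi0 >= 0, pi0 <= 1, beta_a > 0, beta_b > 0, n_sites >= 1)
  set.seed(seed)
  f <- ifelse(runif(n_sites) < pi0, 0, rbeta(n_sites, beta_a, beta_b))
  data.frame(chrom = chrom,
             pos0 = spacing * seq_len(n_sites),
             strand = "+", f = f)
}

#' Shift true stoichiometries at chosen sites
#'
#' Applies an additive change to the ground truth at a designated set of
#' sites (by index or as a random fraction), clipping to \[0, 1\] --
#' standing in for a perturbation-responsive site set.
#'
#' @param truth data.frame from [simulateSiteTruth()].
#' @param delta additive shift.
#' @param sites integer indices of the affected sites; or
#' @param fraction random fraction of sites to affect (used when `sites`
#'   is `NULL`; drawn with the current RNG state).
#' @return list with `truth` (shifted copy) and `affected` (indices).
#'   An empty site set returns the truth unchanged with a warning.
#' @export
injectEffect <- function(truth, delta, sites = NULL, fraction = NULL) {
  if (is.null(sites)) {
    if (is.null(fraction)) stop("give either sites or fraction")
    sites <- which(runif(nrow(truth)) < fraction)
  }
  if (!length(sites)) {
    warning("empty effect site set; truth unchanged")
    return(list(truth = truth, affected = integer()))
  }
  if (any(sites < 1L | sites > nrow(truth)))
    stop("effect sites outside the truth table")
  truth$f[sites] <- pmin(pmax(truth$f[sites] + delta, 0), 1)
  list(truth = truth, affected = sort(sites))
}

#' Simulate per-read modification calls for one sequencing run
#'
#' Emulates the measurement process behind per-read m6A calling: per site,
#' coverage is negative binomial; each read's true state is
#' Bernoulli(f); the basecaller emits a confident call with probability
#' `q`, which is correct with probability `1 - eps`; call probabilities
#' are then drawn uniformly within the band the confidence filter maps
#' them to (above `tau` for confident-modified, below `1 - tau` for
#' confident-canonical, in between for failed calls). Draws are made in a
#' fixed site-major order from a single seeded stream, so output is
#' deterministic given the seed.
#'
#' @param truth data.frame from [simulateSiteTruth()] (possibly after
#'   [injectEffect()]); generated internally when `NULL`.
#' @param n_sites,pi0,beta_a,beta_b truth-model parameters, used only when
#'   `truth` is `NULL`.
#' @param cov_mean,cov_dispersion negative-binomial coverage mean and size.
#' @param q probability a read yields a confident call.
#' @param eps probability a confident call is wrong.
#' @param tau confidence band edge used for emitted probabilities (match
#'   the pileup threshold).
#' @param read_prefix prefix for generated read identifiers.
#' @param seed RNG seed.
#' @return list with `calls` (data.frame for [pileupCalls()]) and `truth`
#'   (the truth table, with realised `coverage` appended).
#' @export
simulateNanoporeCalls <- function(truth = NULL, n_sites = 2000, pi0 = 0.3,
                                  beta_a = 1.2, beta_b = 2.5,
                                  cov_mean = 100, cov_dispersion = 10,
                                  q = 0.95, eps = 0.002, tau = 0.99,
                                  read_prefix = "read", seed = 1) {
  stopifnot(q >= 0, q <= 1, eps >= 0, eps <= 1, tau > 0.5, tau <= 1,
            cov_mean > 0, cov_dispersion > 0)
  if (is.null(truth))
    truth <- simulateSiteTruth(n_sites, pi0, beta_a, beta_b, seed = seed)
  stopifnot(all(truth$f >= 0 & truth$f <= 1))
  set.seed(seed)
  n <- nrow(truth)
  cov <- rnbinom(n, mu = cov_mean, size = cov_dispersion)
  site <- rep.int(seq_len(n), cov)
  N <- length(site)
  modified <- runif(N) < truth$f[site]
  confident <- runif(N) < q
  correct <- runif(N) < 1 - eps
  called_mod <- ifelse(correct, modified, !modified)
  u <- runif(N)
  p_mod <- ifelse(!confident,
                  (1 - tau) + u * (2 * tau - 1),         # FAIL band
                  ifelse(called_mod,
                         tau + u * (1 - tau),            # MOD band
                         u * (1 - tau)))                 # CANON band
  calls <- data.frame(
    read_id = paste0(read_prefix, seq_len(N)),
    chrom = truth$chrom[site],
    pos0 = truth$pos0[site],
    strand = truth$strand[site],
    p_mod = p_mod)
  truth$coverage <- cov
  list(calls = calls, truth = truth)
}

#' Default synthetic snRNA TSS truth set
#'
#' 28 snRNA-like transcription-start sites (U1/U2/U4/U5 family names) with
#' low baseline m6Am stoichiometries drawn from Beta(1.5, 10), matching
#' the observation that baseline snRNA m6Am levels are generally low.
#'
#' @param n_genes number of snRNA TSSs.
#' @param seed RNG seed.
#' @return data.frame with `gene_id`, `chrom`, `pos0`, `strand`, `f`.
#' @export
simulateSnrnaTruth <- function(n_genes = 28, seed = 1) {
  set.seed(seed)
  fam <- c("RNU1", "RNU2", "RNU4", "RNU5")
  ids <- paste0(rep(fam, length.out = n_genes), "-",
                unlist(lapply(table(rep(fam, length.out = n_genes)),
                              seq_len), use.names = FALSE))
  data.frame(gene_id = sort(ids)[seq_len(n_genes)], chrom = "chrSn",
             pos0 = 1000L * seq_len(n_genes), strand = "+",
             f = rbeta(n_genes, 1.5, 10))
}

#' Simulate conversion-based TSS base counts
#'
#' Emulates conversion chemistry at snRNA transcription-start nucleotides:
#' with conversion efficiency `c`, a protected (m6Am) start reads A and an
#' unprotected one reads G unless conversion failed, so reads are A with
#' probability `f + (1 - f)(1 - c)`. A base-calling error rate leaks reads
#' into `n_other`. Counts are drawn per gene and replicate; deterministic
#' given the seed.
#'
#' @param truth data.frame with `gene_id` and `f` (see
#'   [simulateSnrnaTruth()]); extra columns are carried through.
#' @param conversion conversion efficiency `c` in (0, 1\].
#' @param coverage reads per TSS per replicate.
#' @param base_error probability a read shows a base other than A/G.
#' @param replicates number of replicates.
#' @param condition condition label stamped on the rows.
#' @param seed RNG seed.
#' @return data.frame with one row per gene and replicate: the truth
#'   columns plus `replicate`, `condition`, `n_A`, `n_G`, `n_other`,
#'   `non_conversion`.
#' @export
simulateCrownCounts <- function(truth = simulateSnrnaTruth(),
                                conversion = 0.99, coverage = 1000,
                                base_error = 0.002, replicates = 3,
                                condition = "ctrl", seed = 1) {
  if (conversion <= 0 || conversion > 1)
    stop("conversion efficiency must be in (0, 1]")
  stopifnot(all(truth$f >= 0 & truth$f <= 1), coverage >= 1,
            base_error >= 0, base_error < 1)
  set.seed(seed)
  p_nc <- truth$f + (1 - truth$f) * (1 - conversion)
  out <- do.call(rbind, lapply(seq_len(replicates), function(rep_i) {
    n_other <- rbinom(nrow(truth), coverage, base_error)
    informative <- coverage - n_other
    n_A <- rbinom(nrow(truth), informative, p_nc)
    df <- truth
    df$replicate <- rep_i
    df$condition <- condition
    df$n_A <- n_A
    df$n_G <- informative - n_A
    df$n_other <- n_other
    df$non_conversion <- ifelse(informative > 0, n_A / informative,
                                NA_real_)
    df
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a DepMap-layout dependency dataset
#'
#' Builds paired gene-effect and dependency-probability matrices plus a
#' lineage map. Lines designated dependent for a gene get probability ~
#' Uniform(0.8, 1) and effect ~ Normal(-1, 0.1); all others probability ~
#' Uniform(0, 0.3) and effect ~ Normal(0, 0.1).
#'
#' @param n_lines number of cell lines.
#' @param genes gene symbols; columns are headed `"SYMBOL (ENTREZID)"`
#'   with synthetic Entrez ids.
#' @param essential_map named list mapping a gene symbol to the cell-line
#'   identifiers dependent on it.
#' @param aml_fraction fraction of lines labelled with the AML lineage.
#' @param seed RNG seed.
#' @return list with `probability` and `effect` matrices (rows =
#'   `SIM-...` line ids) and `lineage` (data.frame `model_id`, `lineage`,
#'   `subtype`).
#' @export
simulateDependencyMatrix <- function(n_lines = 100,
                                     genes = c("FTO", "MYB", "CBFB"),
                                     essential_map = list(),
                                     aml_fraction = 0.25, seed = 1) {
  stopifnot(n_lines >= 1, length(genes) >= 1)
  set.seed(seed)
  ids <- sprintf("SIM-%06d", seq_len(n_lines))
  bad <- setdiff(unlist(essential_map), ids)
  if (length(bad))
    stop("essential_map names unknown cell line(s): ",
         paste(head(bad, 5), collapse = ", "))
  if (any(vapply(essential_map, anyDuplicated, integer(1)) > 0))
    stop("essential_map contains duplicate cell line ids")
  cols <- sprintf("%s (%d)", genes, 10000L + seq_along(genes))
  prob <- effect <- matrix(NA_real_, n_lines, length(genes),
                           dimnames = list(ids, cols))
  for (j in seq_along(genes)) {
    dep <- ids %in% essential_map[[genes[j]]]
    prob[, j] <- ifelse(dep, runif(n_lines, 0.8, 1),
                        runif(n_lines, 0, 0.3))
    effect[, j] <- ifelse(dep, rnorm(n_lines, -1, 0.1),
                          rnorm(n_lines, 0, 0.1))
  }
  n_aml <- round(aml_fraction * n_lines)
  lineage <- data.frame(
    model_id = ids,
    lineage = rep(c("Myeloid", "Other"), c(n_aml, n_lines - n_aml)),
    subtype = rep(c("AML", "Other"), c(n_aml, n_lines - n_aml)))
  list(probability = prob, effect = effect, lineage = lineage)
}
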