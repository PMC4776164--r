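#' Shannon-Wiener diversity index
#'
#' `H = -sum((n_i/N) * log(n_i/N))` over the positive entries, computed via
#' [vegan::diversity()].  The logarithm base defaults to e and is the
#' caller's record of which units H is in (nats vs bits).
#'
#' @param x non-negative abundance vector (counts or peak heights).
#' @param base logarithm base (> 0, != 1).
#' @return H, a non-negative scalar.
#' @examples
#' shannonIndex(rep(5, 4))       # log(4)
#' shannonIndex(c(1, 1, 2), 2)   # 1.5 bits
#' @export
shannonIndex <- function(x, base = exp(1)) {
  if (any(x < 0)) stop("abundances must be non-negative")
  if (sum(x) == 0) stop("undefined for an all-zero abundance vector")
  as.numeric(vegan::diversity(x, index = "shannon", base = base))
}

#' Chao1 richness estimator
#'
#' Classic form `S_obs + F1^2 / (2 F2)` (undefined contribution treated as
#' `F1 (F1 - 1) / 2` when F2 = 0, i.e. the bias-corrected fallback), and the
#' bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` where F1 and F2
#' are the singleton and doubleton counts.  Bias-corrected is the default:
#' it is defined for all inputs.
#'
#' @param counts non-negative integer count vector.
#' @param biasCorrected logical.
#' @return estimated richness (>= observed richness).
#' @examples
#' x <- c(rep(1, 4), rep(2, 2), rep(5, 4))  # S_obs 10, F1 4, F2 2
#' chao1(x, biasCorrected = FALSE)          # 14
#' chao1(x)                                 # 12
#' @export
chao1 <- function(counts, biasCorrected = TRUE) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  sObs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  est <- if (biasCorrected || f2 == 0)
    sObs + f1 * (f1 - 1) / (2 * (f2 + 1))
  else
    sObs + f1^2 / (2 * f2)
  est
}

#' Rarefy an OTU table to a common depth
#'
#' Each sample is subsampled without replacement to exactly `depth` reads
#' (a single draw per sample, via [vegan::rrarefy()]); the draw is seeded
#' and reproducible.
#'
#' @param counts integer matrix, taxa x samples, or a [RiverExperiment-class].
#' @param depth target reads per sample; must not exceed any sample's total.
#' @param seed integer seed.
#' @return object of the same kind with every sample summing to `depth`.
#' @export
rarefyTable <- function(counts, depth, seed = 1) {
  re <- NULL
  if (is(counts, "RiverExperiment")) { re <- counts; counts <- otuCounts(re) }
  tot <- colSums(counts)
  if (any(tot < depth)) {
    bad <- colnames(counts)[tot < depth][1]
    stop(sprintf("sample '%s' has only %d reads, fewer than depth %d",
                 bad, tot[bad], as.integer(depth)))
  }
  set.seed(seed)
  out <- t(suppressWarnings(vegan::rrarefy(t(counts), depth)))
  storage.mode(out) <- "integer"
  if (!is.null(re)) {
    SummarizedExperiment::assay(re, "counts") <- out
    re
  } else out
}

#' Per-sample alpha diversity summary
#'
#' @param x [RiverExperiment-class] or count matrix (taxa x samples).
#' @param depth optional rarefaction depth applied first (single seeded draw).
#' @param base Shannon log base; recorded in the output.
#' @param seed rarefaction seed.
#' @return data.frame with sample_id, observed_taxa, shannon, chao1,
#'   log_base and rarefaction_depth.
#' @export
alphaDiversity <- function(x, depth = NULL, base = exp(1), seed = 1) {
  cnt <- if (is(x, "RiverExperiment")) otuCounts(x) else as.matrix(x)
  if (!is.null(depth)) cnt <- rarefyTable(cnt, depth, seed)
  data.frame(
    sample_id = colnames(cnt),
    observed_taxa = colSums(cnt > 0),
    shannon = apply(cnt, 2, shannonIndex, base = base),
    chao1 = apply(cnt, 2, chao1),
    log_base = base,
    rarefaction_depth = if (is.null(depth)) NA_integer_ else as.integer(depth),
    row.names = NULL
  )
}
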