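#' Access the OTU count matrix
#'
#' @param x a [RiverExperiment-class].
#' @return integer matrix, taxa x samples.
#' @export
otuCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' Access the sampling design
#'
#' @param x a [RiverExperiment-class].
#' @return DataFrame with columns `season`, `site`, `spatial_group`.
#' @export
sampleDesign <- function(x)
  SummarizedExperiment::colData(x)[, c("season", "site", "spatial_group"), drop = FALSE]

#' Access the environmental covariates
#'
#' @param x a [RiverExperiment-class].
#' @return DataFrame of environmental variables (possibly zero columns).
#' @export
envTable <- function(x)
  SummarizedExperiment::colData(x)[, x@envVars, drop = FALSE]

#' Access the phylogenetic tree over the taxa
#'
#' @param x a [RiverExperiment-class].
#' @return an `ape::phylo` tree, or NULL if none is attached.
#' @export
communityTree <- function(x) S4Vectors::metadata(x)$tree

#' Per-sample relative abundances
#'
#' @param x a [RiverExperiment-class] or a count matrix (taxa x samples).
#' @return numeric matrix whose columns sum to 1.
#' @export
relativeAbundance <- function(x) {
  cnt <- if (is(x, "RiverExperiment")) otuCounts(x) else as.matrix(x)
  sweep(cnt, 2L, colSums(cnt), "/")
}

setMethod("show", "RiverExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("RiverExperiment: %d taxa x %d samples\n", nrow(object), ncol(object)))
  cat(sprintf("  seasons: %s\n", paste(sort(unique(cd$season)), collapse = ", ")))
  cat(sprintf("  sites:   %s\n", paste(sort(unique(cd$site)), collapse = ", ")))
  cat(sprintf("  spatial groups: %s\n",
              paste(unique(as.character(cd$spatial_group)), collapse = ", ")))
  if (length(object@envVars))
    cat(sprintf("  env vars: %s\n", paste(object@envVars, collapse = ", ")))
  if (!is.null(communityTree(object))) cat("  tree: attached\n")
})

setMethod("show", "CommunityCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("CommunityCube: %d seasons x %d units x %d taxa (%s)\n",
              d[1], d[2], d[3],
              if (object@standardized) "standardized" else "raw"))
})

setMethod("show", "SpatioTemporalTest", function(object) {
  cat("Spatial-vs-seasonal SSE-difference test\n")
  cat(sprintf("  n = %d samples, p = %d taxa, method = %s\n",
              object@nSamples, object@nTaxa, object@method))
  cat(sprintf("  sum(SSE_L - SSE_S) = %.4f  (null mean %.4f, null sd %.4f)\n",
              object@sumDiff, object@centering, object@scale))
  cat(sprintf("  T = %.4f, %s p-value = %.4g\n",
              object@statistic,
              if (object@alternative == "less") "one-sided (lower-tail)" else "two-sided",
              object@pValue))
  if (object@pValue < 0.05 && object@statistic < 0)
    cat("  spatial variation significantly exceeds seasonal variation (p < 0.05)\n")
})
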