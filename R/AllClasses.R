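#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' RiverExperiment: a spatio-temporal community survey
#'
#' An S4 container for an OTU count survey over a crossed season-by-site
#' river transect design.  It extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]:
#' the `"counts"` assay holds non-negative integer reads (taxa in rows,
#' samples in columns), `colData` holds the sampling design (`season`,
#' `site`, `spatial_group`) together with any environmental covariates, and
#' a rooted phylogeny over the taxa may be attached in `metadata(x)$tree`
#' for UniFrac computations.
#'
#' @slot envVars character vector naming which `colData` columns are
#'   environmental covariates (as opposed to design columns).
#'
#' @seealso [RiverExperiment()] for construction, [otuCounts()],
#'   [sampleDesign()], [envTable()], [communityTree()] for access.
#' @export
setClass("RiverExperiment",
  contains = "SummarizedExperiment",
  slots = c(envVars = "character")
)

.validRiverExperiment <- function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(cnt != round(cnt))) msg <- c(msg, "counts must be integral")
  }
  cd <- SummarizedExperiment::colData(object)
  for (col in c("season", "site", "spatial_group"))
    if (!col %in% colnames(cd)) msg <- c(msg, sprintf("colData column '%s' is required", col))
  if (all(c("season", "site") %in% colnames(cd))) {
    key <- paste(cd$season, cd$site)
    if (anyDuplicated(key))
      msg <- c(msg, "every (season, site) pair may appear at most once")
  }
  if (all(c("site", "spatial_group") %in% colnames(cd))) {
    tab <- unique(data.frame(site = cd$site, grp = cd$spatial_group))
    if (anyDuplicated(tab$site))
      msg <- c(msg, "spatial_group must be a function of site")
  }
  if (length(object@envVars) && !all(object@envVars %in% colnames(cd)))
    msg <- c(msg, "envVars must name colData columns")
  tree <- S4Vectors::metadata(object)$tree
  if (!is.null(tree)) {
    if (!inherits(tree, "phylo")) msg <- c(msg, "metadata tree must be a 'phylo' object")
    else if (!all(rownames(object) %in% tree$tip.label))
      msg <- c(msg, "all taxa must be tips of the metadata tree")
  }
  if (length(msg)) msg else TRUE
}
setValidity("RiverExperiment", .validRiverExperiment)

#' Construct a RiverExperiment
#'
#' @param counts integer matrix of reads, taxa x samples, with dimnames.
#' @param design data.frame or DataFrame keyed like the columns of `counts`
#'   (rownames or a `sample_id` column), with columns `season` (integer),
#'   `site` (integer) and `spatial_group` (character/factor).
#' @param env optional data.frame of per-sample environmental covariates,
#'   keyed the same way; missing values allowed.
#' @param tree optional rooted `phylo` tree whose tips cover the taxa.
#' @return A [RiverExperiment-class] object.
#' @examples
#' sim <- simulateCommunity(syntheticConfig(nTaxa = 40, nSites = 3, seed = 1))
#' sim
#' @export
RiverExperiment <- function(counts, design, env = NULL, tree = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  design <- .keyedFrame(design, colnames(counts), "design")
  cd <- S4Vectors::DataFrame(design)
  envVars <- character()
  if (!is.null(env)) {
    env <- .keyedFrame(env, colnames(counts), "env")
    envVars <- colnames(env)
    cd <- cbind(cd, S4Vectors::DataFrame(env))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(counts = counts),
    colData = cd,
    metadata = if (is.null(tree)) list() else list(tree = tree)
  )
  new("RiverExperiment", se, envVars = envVars)
}

# align a keyed data.frame to the sample order of the count matrix
.keyedFrame <- function(x, ids, what) {
  x <- as.data.frame(x)
  if ("sample_id" %in% colnames(x)) {
    rownames(x) <- x$sample_id
    x$sample_id <- NULL
  }
  missing <- setdiff(ids, rownames(x))
  if (length(missing))
    stop(sprintf("%s table is missing samples: %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  x[ids, , drop = FALSE]
}

#' CommunityCube: season x site x taxon data cube
#'
#' Holds the complete-crossing array `X[i, j, k]` of per-taxon community
#' values (season i, spatial unit j, taxon k) on which the spatial-versus-
#' seasonal variance test operates, plus a flag recording whether each
#' taxon has been z-scored across the n = I*J samples.
#'
#' @slot data numeric 3-d array, seasons x units x taxa, with dimnames.
#' @slot standardized logical; TRUE after [standardizeCube()].
#' @seealso [communityCube()], [standardizeCube()], [spatioTemporalTest()]
#' @export
setClass("CommunityCube",
  slots = c(data = "array", standardized = "logical")
)

setValidity("CommunityCube", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3-d array (season x unit x taxon)")
  if (anyNA(d)) return("complete crossing required: no missing cells")
  TRUE
})

#' SpatioTemporalTest: result of the SSE-difference test
#'
#' @slot sseSeasonal numeric, per-taxon residual SS under the seasonal grouping.
#' @slot sseSpatial numeric, per-taxon residual SS under the spatial grouping.
#' @slot sumDiff numeric(1), the statistic's numerator core
#'   `sum_k(SSE_L(k) - SSE_S(k))` before centering.
#' @slot centering,scale numeric(1), null mean and null standard deviation
#'   used to standardize `sumDiff`.
#' @slot statistic numeric(1), the standardized statistic T.
#' @slot pValue numeric(1).
#' @slot method character(1): "asymptotic", "montecarlo" or "permutation".
#' @slot alternative character(1): "less" (spatial dominates) or "two.sided".
#' @slot nSamples,nTaxa integer(1).
#' @slot partition list mapping spatial-group labels to unit ids.
#' @export
setClass("SpatioTemporalTest",
  slots = c(
    sseSeasonal = "numeric", sseSpatial = "numeric",
    sumDiff = "numeric", centering = "numeric", scale = "numeric",
    statistic = "numeric", pValue = "numeric",
    method = "character", alternative = "character",
    nSamples = "integer", nTaxa = "integer", partition = "list"
  )
)

setValidity("SpatioTemporalTest", function(object) {
  msg <- character()
  if (any(object@sseSeasonal < -1e-8) || any(object@sseSpatial < -1e-8))
    msg <- c(msg, "SSE values must be non-negative")
  if (object@pValue < 0 || object@pValue > 1) msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
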