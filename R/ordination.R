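#' Principal coordinates analysis of a distance matrix
#'
#' Classical scaling: the squared distances are double-centered, the Gram
#' matrix eigendecomposed, and coordinates formed from eigenvectors scaled
#' by the square roots of the positive eigenvalues (via
#' [stats::cmdscale()]).  Axes with negative eigenvalues are dropped; their
#' magnitudes are reported but excluded from the percent-explained
#' denominator (denominator = sum of positive eigenvalues).
#'
#' @param d a `dist` or symmetric matrix of dissimilarities.
#' @return list with `ids`, `coordinates` (samples x axes), `eigenvalues`
#'   (positive, per retained axis), `percentExplained` and
#'   `negativeEigenvalues`.
#' @export
communityPcoa <- function(d) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
      stop("distance matrix must be symmetric")
    d <- stats::as.dist(m)
  }
  n <- attr(d, "Size")
  # cmdscale warns when fewer than k eigenvalues are positive; the
  # positive-eigenvalue filtering below is exactly how that is handled
  sc <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- sc$eig
  tol <- max(abs(eig)) * 1e-9
  pos <- which(eig > tol)
  neg <- eig[eig < -tol]
  coords <- sc$points[, pos, drop = FALSE]
  colnames(coords) <- sprintf("PCo%d", seq_along(pos))
  list(ids = attr(d, "Labels"),
       coordinates = coords,
       eigenvalues = eig[pos],
       percentExplained = 100 * eig[pos] / sum(eig[pos]),
       negativeEigenvalues = abs(neg))
}

#' PCA of environmental data with Kaiser retention
#'
#' Variables are z-scored and the correlation matrix eigendecomposed.
#' Components with eigenvalue > 1 (Kaiser criterion) are retained; loadings
#' with absolute value above `loadingThreshold` are flagged as the variables
#' a component "represents".  Rows with missing values are excluded and
#' reported.
#'
#' @param env data.frame or matrix of environmental variables (>= 2).
#' @param loadingThreshold flag |loading| above this (default 0.70).
#' @return list with `eigenvalues`, `percentExplained`, `retained` (Kaiser),
#'   `loadings` (variables x components, eigenvectors scaled by
#'   sqrt(eigenvalue)), `strongLoadings` (logical matrix over retained
#'   components), `scores` for the complete rows, and `excludedRows`.
#' @export
envPca <- function(env, loadingThreshold = 0.70) {
  x <- as.matrix(as.data.frame(env))
  if (ncol(x) < 2) stop("need >= 2 environmental variables")
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  complete <- stats::complete.cases(x)
  excluded <- ids[!complete]
  if (length(excluded))
    message("excluding rows with missing values: ", paste(excluded, collapse = ", "))
  x <- x[complete, , drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant variable(s), z-score undefined: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  z <- scale(x)
  ev <- eigen(stats::cor(x), symmetric = TRUE)
  eig <- ev$values
  loadings <- sweep(ev$vectors, 2, sqrt(pmax(eig, 0)), "*")
  dimnames(loadings) <- list(colnames(x), sprintf("PC%d", seq_along(eig)))
  retained <- which(eig > 1)
  list(eigenvalues = eig,
       percentExplained = 100 * eig / length(eig),
       retained = retained,
       loadings = loadings,
       strongLoadings = abs(loadings[, retained, drop = FALSE]) > loadingThreshold,
       scores = z %*% ev$vectors,
       excludedRows = excluded)
}

#' Average-linkage hierarchical clustering with rescaled heights
#'
#' UPGMA (unweighted average between-group dissimilarity, via
#' [stats::hclust()]) with merge heights rescaled to
#' `Dlink/Dmax x 25`, so the final merge sits at 25 and a cut threshold is
#' expressed on that scale.
#'
#' @param d a `dist`.
#' @return list of class `"riverDendrogram"`: `hclust` (raw heights),
#'   `rescaledHeights` (in \[0, 25\]) and `maxHeight`.
#' @export
hierarchicalCluster <- function(d) {
  if (!inherits(d, "dist")) d <- stats::as.dist(as.matrix(d))
  hc <- stats::hclust(d, method = "average")
  maxH <- max(hc$height)
  structure(list(hclust = hc,
                 rescaledHeights = hc$height / maxH * 25,
                 maxHeight = maxH),
            class = "riverDendrogram")
}

#' Cut a rescaled dendrogram
#'
#' @param dend a `"riverDendrogram"` from [hierarchicalCluster()].
#' @param cut threshold on the Dlink/Dmax x 25 scale (default 15).
#' @return integer cluster labels named by sample id.
#' @export
cutDendrogram <- function(dend, cut = 15) {
  stopifnot(inherits(dend, "riverDendrogram"))
  stats::cutree(dend$hclust, h = cut / 25 * dend$maxHeight)
}

#' Log-transform environmental variables for clustering
#'
#' Zeros (and any non-positive values) in a variable are handled by adding
#' half the smallest positive observed value of that variable before the
#' log, with a message.
#'
#' @param env data.frame or matrix of non-negative variables.
#' @return matrix of logged values.
#' @export
logTransformEnv <- function(env) {
  x <- as.matrix(as.data.frame(env))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    if (any(v <= 0, na.rm = TRUE)) {
      posmin <- min(v[v > 0], na.rm = TRUE)
      message(sprintf("variable '%s': adding %.4g before log (non-positive values)",
                      colnames(x)[j], posmin / 2))
      v <- v + posmin / 2
    }
    x[, j] <- log(v)
  }
  x
}
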