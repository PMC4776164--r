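#' Build the season x unit x taxon data cube
#'
#' Arranges per-sample, per-taxon community values `X[i, j, k]` into the
#' complete-crossing cube the spatial-vs-seasonal test operates on.  From a
#' [RiverExperiment-class] the values are per-sample relative abundances.
#'
#' @param x a RiverExperiment, or a numeric matrix (taxa x samples).
#' @param design data.frame with `season` and `site` per sample (taken from
#'   the object when `x` is a RiverExperiment).
#' @return a [CommunityCube-class] (unstandardized).
#' @export
communityCube <- function(x, design = NULL) {
  if (is(x, "RiverExperiment")) {
    design <- as.data.frame(sampleDesign(x))
    vals <- relativeAbundance(x)
  } else {
    vals <- as.matrix(x)
    if (is.null(design)) stop("a design with season and site is required")
    design <- as.data.frame(design)
  }
  seasons <- sort(unique(design$season))
  units <- sort(unique(design$site))
  I <- length(seasons); J <- length(units)
  arr <- array(NA_real_, c(I, J, nrow(vals)),
               dimnames = list(season = as.character(seasons),
                               unit = as.character(units),
                               taxon = rownames(vals)))
  for (s in seq_len(ncol(vals))) {
    i <- match(design$season[s], seasons)
    j <- match(design$site[s], units)
    arr[i, j, ] <- vals[, s]
  }
  if (anyNA(arr)) {
    miss <- which(is.na(arr[, , 1]), arr.ind = TRUE)[1, ]
    stop(sprintf("incomplete crossing: no sample for season %s, unit %s",
                 seasons[miss[1]], units[miss[2]]))
  }
  new("CommunityCube", data = arr, standardized = FALSE)
}

#' Z-score each taxon of a cube
#'
#' Per taxon, the mean over all n = I*J samples is subtracted and the
#' result divided by the sample standard deviation (denominator n - 1).
#' Zero-variance taxa cannot be standardized; they are dropped with a
#' warning and the taxon dimension p shrinks accordingly.
#'
#' @param cube a [CommunityCube-class].
#' @return a standardized [CommunityCube-class].
#' @export
standardizeCube <- function(cube) {
  stopifnot(is(cube, "CommunityCube"))
  arr <- cube@data
  d <- dim(arr)
  X <- matrix(arr, d[1] * d[2], d[3])  # samples x taxa
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance taxa dropped before standardization")
    X <- X[, keep, drop = FALSE]
  }
  Z <- scale(X)
  out <- array(Z, c(d[1], d[2], ncol(Z)),
               dimnames = c(dimnames(arr)[1:2],
                            list(taxon = dimnames(arr)[[3]][keep])))
  new("CommunityCube", data = out, standardized = TRUE)
}

#' Per-taxon residual sum of squares under the seasonal grouping
#'
#' `SSE_S(k) = sum_ij (X_ij(k) - Xbar_i(k))^2` where `Xbar_i(k)` is the mean
#' over spatial units within season i.
#'
#' @param cube a [CommunityCube-class].
#' @return numeric vector, one value per taxon.
#' @export
sseSeasonal <- function(cube) {
  arr <- cube@data
  seasonMeans <- apply(arr, c(1, 3), mean)          # I x p
  dev <- sweep(arr, c(1, 3), seasonMeans)
  apply(dev^2, 3, sum)
}

#' Per-taxon residual sum of squares under the spatial grouping
#'
#' `SSE_L(k)` sums squared deviations of every sample from its spatial
#' group's mean, each group mean pooling all seasons and all units assigned
#' to that group.
#'
#' @param cube a [CommunityCube-class].
#' @param partition named list mapping group labels to unit ids (characters
#'   or integers matching the cube's unit dimnames); every unit must be
#'   assigned and every group non-empty.
#' @return numeric vector, one value per taxon.
#' @export
sseSpatial <- function(cube, partition) {
  arr <- cube@data
  units <- dimnames(arr)[[2]]
  groupOf <- .groupIndex(partition, units)
  p <- dim(arr)[3]
  out <- numeric(p)
  for (g in unique(groupOf)) {
    sub <- arr[, groupOf == g, , drop = FALSE]
    gm <- apply(sub, 3, mean)                        # pooled group mean per taxon
    out <- out + apply(sweep(sub, 3, gm)^2, 3, sum)
  }
  names(out) <- dimnames(arr)[[3]]
  out
}

.groupIndex <- function(partition, units) {
  if (length(partition) < 2) stop("partition needs >= 2 spatial groups")
  groupOf <- rep(NA_integer_, length(units))
  for (g in seq_along(partition)) {
    m <- match(as.character(partition[[g]]), units)
    if (anyNA(m))
      stop("partition names unknown unit(s): ",
           paste(setdiff(as.character(partition[[g]]), units), collapse = ", "))
    if (length(m) == 0) stop("empty spatial group in partition")
    groupOf[m] <- g
  }
  if (anyNA(groupOf))
    stop("units not assigned to any group: ",
         paste(units[is.na(groupOf)], collapse = ", "))
  groupOf
}

# exact null moments of sum_k(SSE_L - SSE_S) for a z-scored cube.
# After per-taxon z-scoring the standardized vector is uniform on the
# centered sphere of radius sqrt(n-1); the seasonal and spatial contrast
# subspaces are orthogonal for a complete crossing (every group contains
# every season equally often), so the two between-group sums of squares,
# divided by n-1, follow a Dirichlet law with shapes
# ((I-1)/2, (G-1)/2, (n-I-G+1)/2).  Hence per taxon
#   E[SSE_L - SSE_S] = E[SSB_S - SSB_L] = I - G
#   Var[SSB_S - SSB_L] = (n-1)^2 [a1(a0-a1)+a2(a0-a2)+2a1a2] / (a0^2(a0+1)).
.exactMoments <- function(n, I, G, p) {
  a1 <- (I - 1) / 2; a2 <- (G - 1) / 2; a0 <- (n - 1) / 2
  v1 <- (n - 1)^2 * (a1 * (a0 - a1) + a2 * (a0 - a2) + 2 * a1 * a2) /
    (a0^2 * (a0 + 1))
  list(center = p * (I - G), scale = sqrt(p * v1))
}

# the centering and variance printed with the statistic's original
# derivation (independence approximation between the SSB difference and the
# per-taxon sample variance); kept for comparison, mis-centered in practice
.publishedMoments <- function(n, I, G, p) {
  if (n <= 5) stop("published variance term requires n > 5")
  list(center = (I - G) * p * (n - 1) / (n - 3),
       scale = sqrt(4 * p * (n - 1)^3 / ((n - 3)^2 * (n - 5))))
}

#' The spatial-vs-seasonal SSE-difference statistic T
#'
#' Standardizes `sum_k(SSE_L(k) - SSE_S(k))` by its null mean and standard
#' deviation and refers it to N(0, 1): low T with small lower-tail p means
#' spatial variation significantly exceeds seasonal variation.
#' `varianceConstant = "exact"` (default) uses the exact null moments under
#' per-taxon z-scoring, derived from the Dirichlet decomposition of the
#' standardized ANOVA components and validated by [calibrateNull()];
#' `"published"` uses the constants `(I-G) p (n-1)/(n-3)` and
#' `4 p (n-1)^3 / ((n-3)^2 (n-5))` from the statistic's original
#' presentation, which [calibrateNull()] shows to be mis-centered.
#'
#' @param cube a [CommunityCube-class]; standardized (a raw cube is z-scored
#'   first, with a message).
#' @param partition named list mapping spatial-group labels to unit ids.
#' @param varianceConstant `"exact"` or `"published"`.
#' @param alternative `"less"` (one-sided lower tail, the default decision
#'   rule) or `"two.sided"`.
#' @return a [SpatioTemporalTest-class].
#' @examples
#' cube <- communityCube(simulateCommunity(
#'   syntheticConfig(nTaxa = 200, nSites = 3, seed = 3)))
#' tStatistic(standardizeCube(cube),
#'            partition = list(riverine = c(1, 2), estuarial = 3))
#' @export
tStatistic <- function(cube, partition,
                       varianceConstant = c("exact", "published"),
                       alternative = c("less", "two.sided")) {
  varianceConstant <- match.arg(varianceConstant)
  alternative <- match.arg(alternative)
  if (!cube@standardized) {
    message("cube is not standardized; z-scoring each taxon first")
    cube <- standardizeCube(cube)
  }
  d <- dim(cube@data)
  I <- d[1]; J <- d[2]; p <- d[3]; n <- I * J
  if (n <= 5) stop("the scale term requires n > 5 samples")
  G <- length(partition)
  sseS <- sseSeasonal(cube)
  sseL <- sseSpatial(cube, partition)
  sumDiff <- sum(sseL - sseS)
  mom <- if (varianceConstant == "exact") .exactMoments(n, I, G, p)
         else .publishedMoments(n, I, G, p)
  T <- (sumDiff - mom$center) / mom$scale
  pv <- if (alternative == "less") stats::pnorm(T) else 2 * stats::pnorm(-abs(T))
  new("SpatioTemporalTest",
      sseSeasonal = sseS, sseSpatial = sseL, sumDiff = sumDiff,
      centering = mom$center, scale = mom$scale, statistic = T,
      pValue = pv, method = "asymptotic", alternative = alternative,
      nSamples = as.integer(n), nTaxa = as.integer(p),
      partition = lapply(partition, as.character))
}

# all distinct assignments of units to groups with the given size profile;
# groups of equal size are unordered, so each set partition appears once
.enumeratePartitions <- function(units, sizes) {
  res <- list()
  seen <- new.env(hash = TRUE)
  recurse <- function(remaining, sizesLeft, acc) {
    if (!length(sizesLeft)) {
      groups <- acc[order(vapply(acc, function(g) min(as.character(g)), character(1)))]
      key <- paste(vapply(groups, function(g) paste(sort(g), collapse = ","),
                          character(1)), collapse = "|")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        res[[length(res) + 1L]] <<- acc
      }
      return(invisible())
    }
    combos <- utils::combn(remaining, sizesLeft[1], simplify = FALSE)
    for (g in combos)
      recurse(setdiff(remaining, g), sizesLeft[-1], c(acc, list(g)))
  }
  recurse(units, sizes, list())
  res
}

#' Permutation p-value for the SSE-difference test
#'
#' The null distribution of `sum_k(SSE_L - SSE_S)` is obtained by
#' re-assigning the spatial-unit labels to groups of the same sizes, with
#' seasons kept intact.  When the number of distinct assignments is at most
#' `nPerm` the full set is enumerated and the p-value is exact
#' (`#\{null <= observed\} / #assignments`, the observed assignment
#' included); otherwise `nPerm` random re-assignments are drawn and
#' `p = (1 + #\{null <= observed\}) / (1 + nPerm)`.  Note a 2|1 split of 3
#' units admits only 3 assignments, so the exact p can never fall below
#' 1/3.
#'
#' @inheritParams tStatistic
#' @param nPerm requested number of permutations (>= 99).
#' @param seed integer seed for sampled permutations.
#' @return a [SpatioTemporalTest-class] with `method = "permutation"`.
#' @export
permutationPvalue <- function(cube, partition, nPerm = 999, seed = 1) {
  if (nPerm < 99) stop("nPerm must be >= 99")
  if (!cube@standardized) {
    message("cube is not standardized; z-scoring each taxon first")
    cube <- standardizeCube(cube)
  }
  units <- dimnames(cube@data)[[2]]
  sizes <- lengths(partition)
  sseS <- sseSeasonal(cube)
  obs <- sum(sseSpatial(cube, partition) - sseS)
  all <- .enumeratePartitions(units, sizes)
  sumDiffFor <- function(groups) {
    part <- stats::setNames(groups, sprintf("g%d", seq_along(groups)))
    sum(sseSpatial(cube, part) - sseS)
  }
  tol <- 1e-8 * (1 + abs(obs))
  if (length(all) <= nPerm) {
    message("exact enumeration of ", length(all), " distinct assignments")
    null <- vapply(all, sumDiffFor, numeric(1))
    pv <- sum(null <= obs + tol) / length(null)
  } else {
    set.seed(seed)
    null <- vapply(seq_len(nPerm), function(r) {
      perm <- sample(units)
      groups <- split(perm, rep(seq_along(sizes), sizes))
      sumDiffFor(groups)
    }, numeric(1))
    pv <- (1 + sum(null <= obs + tol)) / (1 + nPerm)
  }
  d <- dim(cube@data)
  new("SpatioTemporalTest",
      sseSeasonal = sseS, sseSpatial = sseSpatial(cube, partition),
      sumDiff = obs, centering = mean(null), scale = stats::sd(null),
      statistic = (obs - mean(null)) / stats::sd(null),
      pValue = pv, method = "permutation", alternative = "less",
      nSamples = as.integer(d[1] * d[2]), nTaxa = as.integer(d[3]),
      partition = lapply(partition, as.character))
}

# fast sum_k(SSE_L - SSE_S) for an n x p matrix of z-scored values
.sumDiffMatrix <- function(Z, seasonIdx, groupIdx) {
  ssb <- function(idx) {
    gm <- rowsum(Z, idx) / as.vector(table(idx))
    sum(gm^2 * as.vector(table(idx)))
  }
  # SSE_L - SSE_S = SSB_S - SSB_L for centered data (SST cancels)
  ssb(seasonIdx) - ssb(groupIdx)
}

#' Monte-Carlo p-value under the iid normal null
#'
#' Simulates `nSim` cubes of iid standard normal values of the same shape,
#' z-scores them and compares the observed `sum_k(SSE_L - SSE_S)` with the
#' simulated null distribution:
#' `p = (1 + #\{null <= observed\}) / (1 + nSim)`.
#'
#' @inheritParams tStatistic
#' @param nSim number of null simulations.
#' @param seed integer seed.
#' @return a [SpatioTemporalTest-class] with `method = "montecarlo"`.
#' @export
monteCarloPvalue <- function(cube, partition, nSim = 2000, seed = 1) {
  if (!cube@standardized) {
    message("cube is not standardized; z-scoring each taxon first")
    cube <- standardizeCube(cube)
  }
  d <- dim(cube@data)
  I <- d[1]; J <- d[2]; p <- d[3]; n <- I * J
  units <- dimnames(cube@data)[[2]]
  seasonIdx <- rep(seq_len(I), times = J)
  groupIdx <- rep(.groupIndex(partition, units), each = I)
  sseS <- sseSeasonal(cube)
  sseL <- sseSpatial(cube, partition)
  obs <- sum(sseL - sseS)
  set.seed(seed)
  null <- vapply(seq_len(nSim), function(r) {
    Z <- scale(matrix(stats::rnorm(n * p), n, p))
    .sumDiffMatrix(Z, seasonIdx, groupIdx)
  }, numeric(1))
  pv <- (1 + sum(null <= obs)) / (1 + nSim)
  new("SpatioTemporalTest",
      sseSeasonal = sseS, sseSpatial = sseL, sumDiff = obs,
      centering = mean(null), scale = stats::sd(null),
      statistic = (obs - mean(null)) / stats::sd(null),
      pValue = pv, method = "montecarlo", alternative = "less",
      nSamples = as.integer(n), nTaxa = as.integer(p),
      partition = lapply(partition, as.character))
}

#' Calibrate the null distribution of the statistic
#'
#' Simulates iid standard-normal cubes, z-scores them, and reports the
#' empirical moments of `sum_k(SSE_L - SSE_S)` and of T together with the
#' empirical type-I error of the asymptotic test at `alpha`.  This is the
#' oracle that selects between the exact and published moment constants.
#'
#' @param I,J seasons and spatial units.
#' @param partition named list of unit ids per group (units `1..J`).
#' @param p number of taxa per cube.
#' @param nSim number of simulated cubes (>= 1000).
#' @param seed integer seed.
#' @param alpha nominal level.
#' @param varianceConstant moment constants used for T and the rejection
#'   rule.
#' @return list with `meanSumDiff`, `varSumDiff`, `meanT`, `varT`,
#'   `typeIError`, the moment constants used, and `nSim`.
#' @export
calibrateNull <- function(I = 4, J = 3,
                          partition = list(g1 = c(1, 2), g2 = 3),
                          p = 500, nSim = 1000, seed = 1, alpha = 0.05,
                          varianceConstant = c("exact", "published")) {
  if (nSim < 1000) stop("nSim must be >= 1000")
  varianceConstant <- match.arg(varianceConstant)
  n <- I * J
  G <- length(partition)
  seasonIdx <- rep(seq_len(I), times = J)
  groupIdx <- rep(.groupIndex(partition, as.character(seq_len(J))), each = I)
  mom <- if (varianceConstant == "exact") .exactMoments(n, I, G, p)
         else .publishedMoments(n, I, G, p)
  set.seed(seed)
  sumDiffs <- vapply(seq_len(nSim), function(r) {
    Z <- scale(matrix(stats::rnorm(n * p), n, p))
    .sumDiffMatrix(Z, seasonIdx, groupIdx)
  }, numeric(1))
  Tvals <- (sumDiffs - mom$center) / mom$scale
  list(meanSumDiff = mean(sumDiffs), varSumDiff = stats::var(sumDiffs),
       meanT = mean(Tvals), varT = stats::var(Tvals),
       typeIError = mean(stats::pnorm(Tvals) < alpha),
       centering = mom$center, scale = mom$scale,
       exactCentering = .exactMoments(n, I, G, p)$center,
       exactScale = .exactMoments(n, I, G, p)$scale,
       nSim = nSim)
}

#' Test whether spatial community variation exceeds seasonal variation
#'
#' High-level entry point: builds the season x unit x taxon cube of relative
#' abundances from a [RiverExperiment-class], z-scores each taxon (dropping
#' zero-variance taxa), and runs the SSE-difference test with the chosen
#' p-value method.
#'
#' @param x a RiverExperiment with a complete season x site crossing.
#' @param partition named list of site ids per spatial group; defaults to
#'   the object's `spatial_group` labels.
#' @param method `"asymptotic"` (default), `"permutation"` or
#'   `"montecarlo"`.
#' @param ... passed on to [tStatistic()], [permutationPvalue()] or
#'   [monteCarloPvalue()].
#' @return a [SpatioTemporalTest-class].
#' @export
spatioTemporalTest <- function(x, partition = NULL,
                               method = c("asymptotic", "permutation", "montecarlo"),
                               ...) {
  method <- match.arg(method)
  cube <- suppressWarnings(standardizeCube(communityCube(x)))
  if (is.null(partition)) {
    des <- unique(as.data.frame(sampleDesign(x))[, c("site", "spatial_group")])
    partition <- split(as.character(des$site), des$spatial_group)
  }
  switch(method,
    asymptotic = tStatistic(cube, partition, ...),
    permutation = permutationPvalue(cube, partition, ...),
    montecarlo = monteCarloPvalue(cube, partition, ...))
}
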