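#' BIOENV: rank environmental-variable subsets against community structure
#'
#' Every non-empty subset of environmental variables up to `maxSubsetSize`
#' is scored by the Spearman rank correlation between the Euclidean
#' inter-sample distances over that subset (variables transformed then
#' z-scored) and the community dissimilarities, both taken as lower
#' triangles.  Subsets are returned ranked by correlation, so the top row
#' is the variable combination that best "explains" community structure.
#'
#' Concentration-like variables are log-transformed by default (with the
#' half-minimum shift rule of [logTransformEnv()] where zeros occur);
#' temperature-like variables are left on their natural scale, since the
#' log of a Celsius temperature is physically meaningless.  Override with
#' `logVars`.
#'
#' @param d community `dist` (e.g. unweighted UniFrac, the default basis,
#'   or Bray-Curtis) over the same samples as `env`.
#' @param env data.frame of environmental variables.
#' @param maxSubsetSize largest subset size searched.
#' @param logVars character vector of variables to log-transform; default
#'   every variable except ones named like temperature.
#' @return data.frame of class `"bioenvResult"` with columns `subset`,
#'   `size`, `r`, sorted by `r` descending.
#' @examples
#' sim <- simulateCommunity(syntheticConfig(nTaxa = 60, nSites = 3, seed = 2))
#' d <- communityDistance(sim, "bray_curtis")
#' head(bioenvSearch(d, as.data.frame(envTable(sim)), maxSubsetSize = 2))
#' @export
bioenvSearch <- function(d, env, maxSubsetSize = ncol(env), logVars = NULL) {
  env <- as.data.frame(env)
  if (ncol(env) < 1) stop("need >= 1 environmental variable")
  ids <- attr(d, "Labels")
  if (!is.null(ids) && !is.null(rownames(env))) {
    if (!all(ids %in% rownames(env)))
      stop("env table is missing samples: ",
           paste(setdiff(ids, rownames(env)), collapse = ", "))
    env <- env[ids, , drop = FALSE]
  }
  if (nrow(env) != attr(d, "Size"))
    stop("env rows must align with the distance matrix samples")
  if (is.null(logVars))
    logVars <- setdiff(colnames(env),
                       grep("temp", colnames(env), ignore.case = TRUE, value = TRUE))
  x <- as.matrix(env)
  if (length(logVars))
    x[, logVars] <- suppressMessages(logTransformEnv(env[, logVars, drop = FALSE]))
  z <- scale(x)
  maxSubsetSize <- min(maxSubsetSize, ncol(z))
  commVec <- as.vector(d)
  rows <- list()
  for (size in seq_len(maxSubsetSize)) {
    for (sub in utils::combn(colnames(z), size, simplify = FALSE)) {
      ed <- stats::dist(z[, sub, drop = FALSE])
      r <- stats::cor(commVec, as.vector(ed), method = "spearman")
      rows[[length(rows) + 1L]] <-
        data.frame(subset = paste(sub, collapse = "+"), size = size, r = r)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$r), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bioenvResult", "data.frame")
  out
}

#' ANOSIM: analysis of similarities
#'
#' All pairwise dissimilarities are ranked (average ranks for ties) and
#' `R = (mean between-group rank - mean within-group rank) / (M / 2)` with
#' `M = n (n - 1) / 2`.  The p-value comes from permuting the group labels;
#' for two groups with few samples the distinct labelings are enumerated
#' exhaustively (exact p), otherwise `nPerm` random permutations are drawn
#' and `p = (1 + #\{R_perm >= R_obs\}) / (1 + nPerm)`.
#'
#' @param d a `dist`.
#' @param groups group labels, one per sample (>= 2 groups, each of size
#'   >= 2).
#' @param nPerm number of permutations (default 999, so the smallest
#'   achievable sampled p is 0.001).
#' @param seed integer seed.
#' @return list of class `"anosimResult"`: `R`, `pValue`, `nPerm`,
#'   `exact`, `groups`.
#' @export
anosimTest <- function(d, groups, nPerm = 999, seed = 1) {
  groups <- as.character(groups)
  n <- attr(d, "Size")
  if (length(groups) != n) stop("one group label per sample is required")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need >= 2 groups")
  if (any(sizes < 2)) stop("every group must have >= 2 samples, offending: ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  rk <- rank(as.vector(d))
  M <- n * (n - 1) / 2
  pairIdx <- utils::combn(n, 2)
  Rstat <- function(g) {
    within <- g[pairIdx[1, ]] == g[pairIdx[2, ]]
    (mean(rk[!within]) - mean(rk[within])) / (M / 2)
  }
  Robs <- Rstat(groups)
  nDistinct <- if (length(sizes) == 2) choose(n, sizes[1]) else Inf
  if (nDistinct <= nPerm) {
    lab <- names(sizes)
    combos <- utils::combn(n, sizes[[1]], simplify = FALSE)
    null <- vapply(combos, function(ix) {
      g <- rep(lab[2], n); g[ix] <- lab[1]
      Rstat(g)
    }, numeric(1))
    pv <- sum(null >= Robs - 1e-12) / length(null)
    exact <- TRUE
    nPermUsed <- length(null)
  } else {
    set.seed(seed)
    null <- vapply(seq_len(nPerm), function(r) Rstat(sample(groups)), numeric(1))
    pv <- (1 + sum(null >= Robs - 1e-12)) / (1 + nPerm)
    exact <- FALSE
    nPermUsed <- nPerm
  }
  structure(list(R = Robs, pValue = pv, nPerm = nPermUsed, exact = exact,
                 groups = sizes),
            class = "anosimResult")
}

#' @export
print.anosimResult <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%s, %d labelings)\n",
              x$R, x$pValue, if (x$exact) "exact enumeration" else "sampled permutations",
              x$nPerm))
  invisible(x)
}

#' Spearman correlation between diversity and an environmental variable
#'
#' Pairwise-complete observations; average ranks for ties; two-sided
#' p-value from the t approximation (via [stats::cor.test()]).
#'
#' @param values per-sample diversity values.
#' @param envVar per-sample covariate, same order.
#' @return named vector `c(rho, p)`.
#' @export
spearmanDiversityEnv <- function(values, envVar) {
  keep <- stats::complete.cases(values, envVar)
  x <- values[keep]; y <- envVar[keep]
  if (length(x) < 4) stop("need >= 4 paired observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("correlation undefined: all values tied in one vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  c(rho = unname(ct$estimate), p = ct$p.value)
}

#' Shared-OTU (Venn) partition across spatial groups
#'
#' An OTU belongs to a group when it has count >= 1 in any sample of that
#' group.  Returns the count of OTUs in every region of the Venn partition
#' (every non-empty combination of groups), keyed like `"urban&rural"`.
#' Region counts sum to the number of OTUs present in >= 1 sample.
#'
#' @param x count matrix (taxa x samples) or [RiverExperiment-class].
#' @param groups per-sample group labels; defaults to the object's
#'   `spatial_group`.
#' @return named integer vector of Venn region counts.
#' @export
sharedOtuCounts <- function(x, groups = NULL) {
  if (is(x, "RiverExperiment")) {
    if (is.null(groups)) groups <- as.character(sampleDesign(x)$spatial_group)
    x <- otuCounts(x)
  }
  if (is.null(groups)) stop("group labels are required")
  if (anyNA(groups)) stop("every sample needs a group label")
  if (length(groups) != ncol(x)) stop("one group label per sample is required")
  glev <- unique(groups)
  if (length(glev) < 2) stop("need >= 2 groups")
  presence <- vapply(glev, function(g)
    rowSums(x[, groups == g, drop = FALSE]) > 0, logical(nrow(x)))
  anywhere <- rowSums(presence) > 0
  membership <- apply(presence[anywhere, , drop = FALSE], 1, function(r)
    paste(glev[r], collapse = "&"))
  regions <- unlist(lapply(seq_along(glev), function(k)
    utils::combn(glev, k, paste, collapse = "&")))
  counts <- table(factor(membership, levels = regions))
  out <- as.integer(counts)
  names(out) <- regions
  out
}

#' Relative abundance by group for a taxonomy level
#'
#' Aggregates counts by a taxonomy mapping (e.g. OTU -> phylum or genus)
#' and reports each taxon's percentage of the reads within every group,
#' e.g. for "most abundant phyla per habitat" tables.
#'
#' @param x count matrix (taxa x samples) or [RiverExperiment-class].
#' @param taxonomy named character vector mapping row names of `x` to a
#'   taxonomic label; unmapped OTUs become "unclassified".
#' @param groups per-sample group labels; defaults to `spatial_group`.
#' @return matrix of percentages, taxonomy levels x groups (columns sum to
#'   100).
#' @export
groupRelativeAbundance <- function(x, taxonomy, groups = NULL) {
  if (is(x, "RiverExperiment")) {
    if (is.null(groups)) groups <- as.character(sampleDesign(x)$spatial_group)
    x <- otuCounts(x)
  }
  lab <- taxonomy[rownames(x)]
  lab[is.na(lab)] <- "unclassified"
  agg <- rowsum(x, lab)
  glev <- unique(groups)
  out <- vapply(glev, function(g) {
    tot <- rowSums(agg[, groups == g, drop = FALSE])
    100 * tot / sum(tot)
  }, numeric(nrow(agg)))
  colnames(out) <- glev
  out
}
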