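#' Match DGGE bands across lanes
#'
#' Bands whose relative-migration positions differ by at most `tolerance`
#' are merged into one reference band by single-linkage clustering along the
#' position axis (sorted positions are split wherever a gap exceeds the
#' tolerance).  Single linkage is deterministic and independent of lane
#' order.
#'
#' @param patterns named list of band-pattern data.frames
#'   (`position`, `height`), as from [readBandPatterns()] or
#'   [simulateBandPatterns()].
#' @param tolerance relative-migration merge tolerance (> 0).
#' @return list with `positions` (mean position of each reference band) and
#'   `presence` (logical matrix, reference bands x lanes).
#' @export
matchBands <- function(patterns, tolerance = 0.01) {
  if (tolerance <= 0) stop("tolerance must be > 0")
  lanes <- names(patterns)
  if (is.null(lanes)) lanes <- sprintf("L%d", seq_along(patterns))
  all <- do.call(rbind, lapply(seq_along(patterns), function(i)
    data.frame(lane = lanes[i], position = patterns[[i]]$position)))
  ord <- order(all$position)
  pos <- all$position[ord]
  cluster <- cumsum(c(1, diff(pos) > tolerance))
  refPos <- as.numeric(tapply(pos, cluster, mean))
  presence <- matrix(FALSE, length(refPos), length(lanes),
                     dimnames = list(sprintf("band%03d", seq_along(refPos)), lanes))
  idx <- cbind(cluster, match(all$lane[ord], lanes))
  presence[idx] <- TRUE
  list(positions = refPos, presence = presence)
}

#' Moving-window analysis of fingerprints along the transect
#'
#' For each pair of adjacent lanes (in the given order) the Dice similarity
#' of their matched band-presence sets is reported in percent; dips in the
#' curve mark community transitions, and local minima are returned as
#' turning points.
#'
#' @param patterns ordered named list of band patterns (>= 2 lanes).
#' @param tolerance band-matching tolerance passed to [matchBands()].
#' @return data.frame with `pair` (e.g. "S2-S3"), `similarity` (percent) and
#'   `turning_point` (logical, local minimum of the series).
#' @export
movingWindow <- function(patterns, tolerance = 0.01) {
  if (length(patterns) < 2) stop("moving-window analysis needs >= 2 lanes")
  matched <- matchBands(patterns, tolerance)
  pres <- matched$presence
  lanes <- colnames(pres)
  bands <- rownames(pres)
  sim <- vapply(seq_len(length(lanes) - 1), function(i)
    100 * suppressMessages(
      diceSimilarity(bands[pres[, i]], bands[pres[, i + 1]])),
    numeric(1))
  k <- length(sim)
  turning <- vapply(seq_len(k), function(i) {
    left <- if (i > 1) sim[i - 1] else Inf
    right <- if (i < k) sim[i + 1] else Inf
    sim[i] < left && sim[i] < right
  }, logical(1))
  data.frame(pair = paste(lanes[-length(lanes)], lanes[-1], sep = "-"),
             similarity = sim, turning_point = turning)
}

#' Shannon index of a densitometric lane
#'
#' Applies [shannonIndex()] to the peak heights of one lane, so `n_i` is a
#' peak height and `N` the sum of all peak heights of the curve.
#'
#' @param pattern band-pattern data.frame with a `height` column (>= 1 band).
#' @param base logarithm base.
#' @return H.
#' @export
laneShannon <- function(pattern, base = exp(1)) {
  if (nrow(pattern) == 0) stop("undefined for an empty lane")
  shannonIndex(pattern$height, base = base)
}
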