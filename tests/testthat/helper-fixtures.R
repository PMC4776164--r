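# small in-code fixtures shared across test files

# the 4-leaf unit tree used for UniFrac edge-enumeration checks
unitTree <- function() readNewick("((A:1,B:1):1,(C:1,D:1):1);")

# a paper-shaped 4-season x 3-unit cube with known values
toyCube <- function(seed = 11, p = 5) {
  set.seed(seed)
  arr <- array(rnorm(4 * 3 * p), c(4, 3, p),
               dimnames = list(season = 1:4, unit = 1:3,
                               taxon = paste0("t", seq_len(p))))
  new("CommunityCube", data = arr, standardized = FALSE)
}

riverPartition <- list(riverine = c("1", "2"), estuarial = "3")

# brute-force SSE oracles: explicit term-by-term double loops
bruteSseSeasonal <- function(arr) {
  p <- dim(arr)[3]
  vapply(seq_len(p), function(k) {
    s <- 0
    for (i in seq_len(dim(arr)[1])) {
      xbar <- mean(arr[i, , k])
      for (j in seq_len(dim(arr)[2])) s <- s + (arr[i, j, k] - xbar)^2
    }
    s
  }, numeric(1))
}

bruteSseSpatial <- function(arr, partition) {
  units <- dimnames(arr)[[2]]
  p <- dim(arr)[3]
  vapply(seq_len(p), function(k) {
    s <- 0
    for (g in partition) {
      js <- match(as.character(g), units)
      gbar <- mean(arr[, js, k])
      for (j in js) for (i in seq_len(dim(arr)[1]))
        s <- s + (arr[i, j, k] - gbar)^2
    }
    s
  }, numeric(1))
}

# tiny 3-site community for pipeline-level tests
smallSim <- function(seed = 5, nTaxa = 120, ...) {
  simulateCommunity(syntheticConfig(nTaxa = nTaxa, nSites = 3, seed = seed,
                                    depthMean = 2000, depthSd = 200, ...))
}
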