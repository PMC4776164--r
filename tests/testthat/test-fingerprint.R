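test_that("band matching merges within tolerance and is idempotent", {
  lanes <- list(L1 = data.frame(position = c(0.50), height = 1),
                L2 = data.frame(position = c(0.505), height = 2))
  m <- matchBands(lanes, tolerance = 0.01)
  expect_identical(length(m$positions), 1L)
  expect_true(all(m$presence))

  # identical lanes -> identical presence columns
  same <- list(A = data.frame(position = c(0.1, 0.6), height = c(1, 2)),
               B = data.frame(position = c(0.1, 0.6), height = c(3, 4)))
  ms <- matchBands(same, tolerance = 0.01)
  expect_identical(ms$presence[, "A"], ms$presence[, "B"])

  # exhaustive 3-lane fixture: {0.1,0.2}, {0.1,0.3}, {0.4}, tol 0.01
  three <- list(L1 = data.frame(position = c(0.1, 0.2), height = c(1, 1)),
                L2 = data.frame(position = c(0.1, 0.3), height = c(1, 1)),
                L3 = data.frame(position = 0.4, height = 1))
  mt <- matchBands(three, tolerance = 0.01)
  expect_identical(length(mt$positions), 4L)
  expect_equal(mt$positions, c(0.1, 0.2, 0.3, 0.4))
  expect_equal(unname(colSums(mt$presence)), c(2, 2, 1))
  expect_identical(unname(mt$presence[1, ]), c(TRUE, TRUE, FALSE))   # band at 0.1
  expect_identical(unname(mt$presence[4, ]), c(FALSE, FALSE, TRUE))  # band at 0.4

  # idempotence: re-matching the merged reference positions changes nothing
  merged <- lapply(seq_len(ncol(mt$presence)), function(j)
    data.frame(position = mt$positions[mt$presence[, j]], height = 1))
  names(merged) <- colnames(mt$presence)
  again <- matchBands(merged, tolerance = 0.01)
  expect_equal(again$positions, mt$positions)
  expect_identical(unname(again$presence), unname(mt$presence))
})

test_that("moving-window series behaves at the extremes and finds boundaries", {
  same <- replicate(4, data.frame(position = c(0.2, 0.5, 0.8), height = 1),
                    simplify = FALSE)
  names(same) <- paste0("S", 1:4)
  mw <- movingWindow(same)
  expect_equal(mw$similarity, rep(100, 3))
  expect_identical(mw$pair, c("S1-S2", "S2-S3", "S3-S4"))

  alt <- list(S1 = data.frame(position = c(0.1, 0.3), height = 1),
              S2 = data.frame(position = c(0.6, 0.9), height = 1),
              S3 = data.frame(position = c(0.1, 0.3), height = 1))
  expect_equal(movingWindow(alt)$similarity, c(0, 0))

  # a community boundary between lanes 2 and 3 is the series minimum
  grpA <- c(0.1, 0.2, 0.3, 0.4)
  grpB <- c(0.6, 0.7, 0.8, 0.9)
  lanes <- list(S1 = data.frame(position = grpA, height = 1),
                S2 = data.frame(position = c(grpA[-1], 0.45), height = 1),
                S3 = data.frame(position = grpB, height = 1),
                S4 = data.frame(position = c(grpB[-4], 0.95), height = 1))
  mwb <- movingWindow(lanes, tolerance = 0.01)
  expect_identical(mwb$pair[which.min(mwb$similarity)], "S2-S3")
  expect_true(mwb$turning_point[2])

  expect_error(movingWindow(lanes[1]), ">= 2 lanes")
})

test_that("moving-window values are percentages and reverse with lane order", {
  cfg <- syntheticConfig(nTaxa = 10, seed = 14)
  pats <- simulateBandPatterns(cfg, shareFraction = 0.6)
  mw <- movingWindow(pats, tolerance = 0.005)
  expect_true(all(mw$similarity >= 0 & mw$similarity <= 100))
  rev_mw <- movingWindow(rev(pats), tolerance = 0.005)
  expect_equal(rev(rev_mw$similarity), mw$similarity)
})

test_that("lane Shannon uses peak heights like the abundance formula", {
  expect_equal(laneShannon(data.frame(position = 0.5, height = 3)), 0)
  eq16 <- data.frame(position = seq(0.05, 0.95, length.out = 16), height = 2)
  expect_equal(laneShannon(eq16), log(16))
  # the observed fingerprint diversity band for a 12-28 band gel
  expect_gt(log(16), 2.31); expect_lt(log(16), 3.12)
  h <- data.frame(position = c(0.1, 0.2, 0.3), height = c(10, 10, 20))
  expect_equal(laneShannon(h), shannonIndex(c(1, 1, 2)))
  expect_error(laneShannon(data.frame(position = numeric(), height = numeric())),
               "empty lane")
})
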