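test_that("cube construction and standardization honour their contracts", {
  sim <- smallSim(seed = 17, nTaxa = 60)
  cube <- communityCube(sim)
  expect_s4_class(cube, "CommunityCube")
  expect_identical(dim(cube@data), c(4L, 3L, 60L))

  z <- suppressWarnings(standardizeCube(cube))
  X <- matrix(z@data, 12, dim(z@data)[3])
  expect_equal(unname(colMeans(X)), rep(0, ncol(X)), tolerance = 1e-12)
  expect_equal(unname(apply(X, 2, sd)), rep(1, ncol(X)), tolerance = 1e-12)

  # idempotence
  z2 <- standardizeCube(z)
  expect_equal(z2@data, z@data, tolerance = 1e-12)

  # constant taxon dropped with p decremented
  raw <- toyCube(p = 4)
  raw@data[, , 2] <- 5
  expect_warning(zc <- standardizeCube(raw), "zero-variance")
  expect_identical(dim(zc@data)[3], 3L)

  # incomplete crossing is refused
  cnt <- otuCounts(sim)[, -1]
  des <- as.data.frame(sampleDesign(sim))[-1, ]
  expect_error(communityCube(relativeAbundance(cnt), des), "incomplete crossing")
})

test_that("SSE terms match brute-force term-by-term loops", {
  cube <- toyCube(seed = 23, p = 7)
  expect_equal(unname(sseSeasonal(cube)), bruteSseSeasonal(cube@data))
  expect_equal(unname(sseSpatial(cube, riverPartition)),
               bruteSseSpatial(cube@data, riverPartition))

  # constant within season -> SSE_S = 0; constant within group -> SSE_L = 0
  flat <- toyCube(p = 2)
  for (i in 1:4) flat@data[i, , ] <- i
  expect_equal(unname(sseSeasonal(flat)), c(0, 0))
  grpFlat <- toyCube(p = 2)
  grpFlat@data[, 1:2, ] <- 1; grpFlat@data[, 3, ] <- 9
  expect_equal(unname(sseSpatial(grpFlat, riverPartition)), c(0, 0))

  # one group per unit: SSE_L equals within-unit-across-season SS
  one <- toyCube(seed = 3, p = 5)
  per_unit <- list(u1 = "1", u2 = "2", u3 = "3")
  byHand <- vapply(1:5, function(k)
    sum(vapply(1:3, function(j) sum((one@data[, j, k] - mean(one@data[, j, k]))^2),
               numeric(1))), numeric(1))
  expect_equal(unname(sseSpatial(one, per_unit)), byHand)

  # ANOVA decomposition bound on a standardized cube: SSE <= n - 1 per taxon
  z <- standardizeCube(toyCube(seed = 31, p = 10))
  expect_true(all(sseSeasonal(z) <= 11 + 1e-9))
  expect_true(all(sseSeasonal(z) >= 0))
  expect_true(all(sseSpatial(z, riverPartition) <= 11 + 1e-9))
})

test_that("the T statistic is exact on the algebraic identity and invariant", {
  z <- standardizeCube(toyCube(seed = 41, p = 20))
  res <- tStatistic(z, riverPartition)
  expect_s4_class(res, "SpatioTemporalTest")
  expect_equal(res@sumDiff, sum(res@sseSpatial - res@sseSeasonal))
  expect_equal(res@pValue, pnorm(res@statistic))

  # T is the affine map (sumDiff - centering)/scale, so a cube with
  # SSE_L(k) = SSE_S(k) everywhere (sumDiff 0) lands at -centering/scale
  expect_equal(res@statistic, (res@sumDiff - res@centering) / res@scale)
  expect_equal(res@statistic - res@sumDiff / res@scale,
               -res@centering / res@scale)

  # taxon order and per-taxon sign flips leave T unchanged
  perm <- sample(20)
  zPerm <- new("CommunityCube", data = z@data[, , perm], standardized = TRUE)
  expect_equal(tStatistic(zPerm, riverPartition)@statistic, res@statistic)
  flip <- z
  flip@data[, , 1:10] <- -flip@data[, , 1:10]
  expect_equal(tStatistic(flip, riverPartition)@statistic, res@statistic)

  tiny <- new("CommunityCube", data = toyCube(p = 3)@data[1:2, 1:2, , drop = FALSE],
              standardized = TRUE)
  expect_error(tStatistic(tiny, list(a = "1", b = "2")), "n > 5")
})

test_that("null calibration recovers the exact moment constants", {
  cal <- calibrateNull(I = 4, J = 3, p = 300, nSim = 1500, seed = 7)
  # per-taxon mean of SSE_L - SSE_S is I - G = 2 exactly under the null
  seMean <- sqrt(cal$varSumDiff / cal$nSim)
  expect_lt(abs(cal$meanSumDiff - 600), 3 * seMean)
  expect_equal(cal$centering, 600)
  # T is approximately standard normal
  expect_lt(abs(cal$meanT), 3 / sqrt(cal$nSim))
  expect_lt(abs(cal$varT - 1), 0.15)
  expect_gt(cal$typeIError, 0.02); expect_lt(cal$typeIError, 0.09)

  # doubling p doubles the variance of sum_diff (independent taxa)
  cal2 <- calibrateNull(I = 4, J = 3, p = 600, nSim = 1500, seed = 8)
  ratio <- cal2$varSumDiff / cal$varSumDiff
  expect_gt(ratio, 1.6); expect_lt(ratio, 2.4)

  # the published constants are visibly mis-centered relative to simulation
  calPub <- calibrateNull(I = 4, J = 3, p = 300, nSim = 1500, seed = 7,
                          varianceConstant = "published")
  expect_gt(abs(calPub$meanT), 2)
})

test_that("permutation p-values enumerate the tiny label space exactly", {
  z <- standardizeCube(toyCube(seed = 51, p = 15))
  expect_message(res <- permutationPvalue(z, riverPartition), "exact enumeration of 3")
  expect_true(res@pValue %in% c(1 / 3, 2 / 3, 1))
  expect_identical(res@method, "permutation")

  # strongly spatial data put the observed assignment at the minimum
  hits <- 0
  nrep <- 40
  for (r in seq_len(nrep)) {
    sim <- smallSim(seed = 700 + r, spatialEffect = 1.5, seasonalEffect = 0)
    zc <- suppressWarnings(standardizeCube(communityCube(sim)))
    pr <- suppressMessages(
      permutationPvalue(zc, list(riverine = c("1", "2"), estuarial = "3")))
    if (pr@pValue <= 1 / 3 + 1e-9) hits <- hits + 1
  }
  expect_gte(hits / nrep, 0.9)
})

test_that("the Monte-Carlo method agrees with the asymptotic one", {
  sim <- smallSim(seed = 61, nTaxa = 250)
  za <- spatioTemporalTest(sim, method = "asymptotic")
  zm <- spatioTemporalTest(sim, method = "montecarlo", nSim = 1500, seed = 4)
  expect_identical(zm@method, "montecarlo")
  # both should call the strong planted spatial structure significant
  expect_lt(za@pValue, 0.05)
  expect_lt(zm@pValue, 0.05)
  # and their null standardizations should agree closely
  expect_lt(abs(zm@centering - za@centering) / za@scale, 0.2)
  expect_lt(abs(zm@scale - za@scale) / za@scale, 0.15)
})
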