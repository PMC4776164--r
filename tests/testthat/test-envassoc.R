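# independent brute-force BIOENV used as the oracle: enumerates subsets and
# computes Spearman from first principles (rank + Pearson), no package calls
bruteBioenv <- function(d, envZ, maxSize) {
  commRank <- rank(as.vector(d))
  out <- list()
  vars <- colnames(envZ)
  for (size in seq_len(maxSize)) {
    for (sub in utils::combn(vars, size, simplify = FALSE)) {
      sq <- as.matrix(stats::dist(envZ[, sub, drop = FALSE]))
      ed <- sq[lower.tri(sq)]
      er <- rank(ed)
      r <- sum((commRank - mean(commRank)) * (er - mean(er))) /
        sqrt(sum((commRank - mean(commRank))^2) * sum((er - mean(er))^2))
      out[[length(out) + 1L]] <- data.frame(subset = paste(sub, collapse = "+"), r = r)
    }
  }
  df <- do.call(rbind, out)
  df[order(-df$r), ]
}

test_that("BIOENV ranking is identical to exhaustive brute force", {
  set.seed(19)
  n <- 10
  env <- data.frame(temperature = runif(n, 5, 30), salinity = rlnorm(n),
                    TN = rlnorm(n), TP = rlnorm(n), TOC = rlnorm(n),
                    row.names = paste0("s", 1:n))
  cnt <- matrix(rpois(40 * n, 4), 40, n,
                dimnames = list(paste0("t", 1:40), rownames(env)))
  d <- communityDistance(cnt, "bray_curtis")

  got <- bioenvSearch(d, env, maxSubsetSize = 5)
  # same transform as the implementation contract: log all but temperature
  z <- scale(cbind(temperature = env$temperature, log(env[, -1])))
  rownames(z) <- rownames(env)
  want <- bruteBioenv(d, z, 5)
  expect_identical(nrow(got), 31L)
  expect_identical(got$subset, want$subset)
  expect_equal(got$r, want$r)

  # k = 3 variables -> exactly 7 subsets
  expect_identical(nrow(bioenvSearch(d, env[, 1:3])), 7L)

  # best r is monotone non-decreasing in the subset-size cap
  best <- vapply(1:4, function(k) bioenvSearch(d, env, k)$r[1], numeric(1))
  expect_true(all(diff(best) >= -1e-12))
})

test_that("a variable built from the community distances ranks first with r = 1", {
  set.seed(2)
  pts <- sort(rexp(8))
  d <- dist(pts)  # 1-d geometry: distances are monotone in the coordinate
  env <- data.frame(matched = pts, noise = rnorm(8))
  got <- bioenvSearch(d, env, maxSubsetSize = 1, logVars = character())
  expect_identical(got$subset[1], "matched")
  expect_equal(got$r[1], 1)
})

test_that("BIOENV agrees with vegan's search for the best subset", {
  sim <- smallSim(seed = 77, nTaxa = 80)
  d <- communityDistance(sim, "bray_curtis")
  env <- as.data.frame(envTable(sim))[, 1:4]
  got <- bioenvSearch(d, env, maxSubsetSize = 4, logVars = character())
  ref <- vegan::bioenv(d, as.data.frame(scale(env)), method = "spearman",
                       metric = "euclidean")
  # vegan reports the best model per subset size; its top correlation must
  # equal the head of our full ranking
  expect_equal(got$r[1], max(vapply(ref$models, function(m) m$est, numeric(1))),
               tolerance = 1e-10)
})

test_that("ANOSIM matches exact enumeration and behaves under the null", {
  # perfect separation: every within-group distance below every between
  pts <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  d <- dist(pts)
  res <- anosimTest(d, rep(c("a", "b"), each = 3))
  expect_equal(res$R, 1)
  expect_true(res$exact)
  expect_identical(res$nPerm, 20L)          # C(6,3) labelings
  expect_equal(res$pValue, 1 / 10)          # 2 labelings reach R = 1

  # exact enumeration equals vegan's R on the same data
  set.seed(33)
  pts2 <- matrix(rnorm(18), 6, 3)
  d2 <- dist(pts2)
  g2 <- rep(c("a", "b"), each = 3)
  res2 <- anosimTest(d2, g2)
  ref <- vegan::anosim(d2, g2, permutations = 999)
  expect_equal(res2$R, unname(ref$statistic), tolerance = 1e-12)

  # labels independent of distances: mean R near 0
  set.seed(44)
  Rs <- vapply(1:300, function(r) {
    dd <- dist(rnorm(8))
    anosimTest(dd, sample(rep(c("x", "y"), each = 4)), nPerm = 99)$R
  }, numeric(1))
  expect_lt(abs(mean(Rs)), 3 * sd(Rs) / sqrt(length(Rs)) + 0.05)

  # R is rank-based: any strictly monotone transform of d leaves it unchanged
  expect_equal(anosimTest(d2^2, g2)$R, res2$R)
  expect_error(anosimTest(d, c("a", "a", "a", "a", "a", "b")), ">= 2 samples")
})

test_that("Spearman diversity-environment correlation handles ties by average ranks", {
  expect_equal(unname(spearmanDiversityEnv(1:6, c(2, 4, 6, 7, 9, 20))["rho"]), 1)
  expect_equal(unname(spearmanDiversityEnv(1:6, -(1:6))["rho"]), -1)

  x <- c(1, 2, 2, 3); y <- c(1, 1, 2, 3)
  got <- spearmanDiversityEnv(x, y)
  rho <- cor(rank(x), rank(y))  # average-rank Pearson
  expect_equal(unname(got["rho"]), rho)
  expect_true(got["p"] > 0 && got["p"] <= 1)

  # missing pairs dropped pairwise
  xm <- c(x, NA); ym <- c(y, 5)
  expect_equal(spearmanDiversityEnv(xm, ym), got)
  expect_error(spearmanDiversityEnv(rep(1, 5), 1:5), "tied")
  expect_error(spearmanDiversityEnv(1:3, 3:1), ">= 4")
})

test_that("shared-OTU Venn regions match per-OTU membership enumeration", {
  set.seed(55)
  cnt <- matrix(rbinom(10 * 9, 1, 0.5) * rpois(90, 3), 10, 9,
                dimnames = list(paste0("t", 1:10), paste0("s", 1:9)))
  groups <- rep(c("urban", "rural", "estuarial"), each = 3)
  got <- sharedOtuCounts(cnt, groups)

  # exhaustive oracle
  present <- sapply(c("urban", "rural", "estuarial"), function(g)
    rowSums(cnt[, groups == g, drop = FALSE]) > 0)
  patterns <- apply(present, 1, function(r)
    paste(colnames(present)[r], collapse = "&"))
  for (region in names(got))
    expect_identical(unname(got[region]), sum(patterns == region))

  expect_identical(sum(got), sum(rowSums(cnt) > 0))

  # identical presence everywhere -> everything in the all-groups region
  ones <- matrix(1L, 5, 6, dimnames = list(paste0("t", 1:5), paste0("s", 1:6)))
  g2 <- rep(c("a", "b"), each = 3)
  all2 <- sharedOtuCounts(ones, g2)
  expect_identical(unname(all2["a&b"]), 5L)
  expect_identical(sum(all2), 5L)

  # disjoint groups -> exclusive regions only
  disj <- rbind(cbind(diag(3L), matrix(0L, 3, 3)),
                cbind(matrix(0L, 3, 3), diag(3L)))
  dimnames(disj) <- list(paste0("t", 1:6), paste0("s", 1:6))
  res <- sharedOtuCounts(disj, g2)
  expect_identical(unname(res[c("a", "b")]), c(3L, 3L))
  expect_identical(unname(res["a&b"]), 0L)
})

test_that("group relative abundances aggregate a taxonomy to percentages", {
  cnt <- matrix(c(10L, 30L, 60L, 50L, 25L, 25L), 3, 2,
                dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  tax <- c(t1 = "PhylumA", t2 = "PhylumA", t3 = "PhylumB")
  out <- groupRelativeAbundance(cnt, tax, groups = c("g1", "g2"))
  expect_equal(colSums(out), c(g1 = 100, g2 = 100))
  expect_equal(out["PhylumA", "g1"], 40)
  expect_equal(out["PhylumB", "g2"], 25)
})
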