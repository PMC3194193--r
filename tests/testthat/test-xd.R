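test_that("distances to a feature set: membership, toy chain, full model", {
  m <- toyModel(list(atomRow(1, "G", "CA", "C", 0, 0, 0),
                     atomRow(2, "G", "CA", "C", 4, 0, 0),
                     atomRow(3, "G", "CA", "C", 8, 0, 0),
                     atomRow(4, "G", "CA", "C", 12, 3, 0)))
  fs <- featureSet("f", 1)
  d <- distancesToFeature(1:4, fs, m)
  expect_equal(d[1], 0)
  expect_equal(d[4], sqrt(12^2 + 3^2))   # brute force over the single atoms
  all_fs <- featureSet("all", 1:4)
  expect_equal(distancesToFeature(1:4, all_fs, m), rep(0, 4))
  expect_error(distancesToFeature(1, new("FeatureSet", name = "e",
                                         positions = integer()), m),
               "empty")
})

test_that("binning follows the half-open convention with a closed first bin", {
  expect_equal(unname(binDistances(rep(0, 5), 4, 12)), c(100, 0, 0))
  # uniform grid: one distance per bin
  expect_equal(unname(binDistances(c(2, 6, 10), 4, 12)),
               rep(100 / 3, 3))
  # boundary value d == w falls in the lower bin
  expect_equal(unname(binDistances(c(4, 4, 4, 4, 4, 4, 5), 4, 12)),
               c(600 / 7, 100 / 7, 0))
  # overflow accumulates in the last bin
  expect_equal(unname(binDistances(c(1, 100), 4, 12)), c(50, 0, 50))
  expect_error(binDistances(1, bin_width = 0), "bin_width")
})

test_that("Xd matches hand-evaluated values and null identity", {
  d0 <- distanceDistribution(c(1, 5), c(1, 5), bin_width = 4, max_dist = 8)
  expect_equal(xdStatistic(d0), 0)
  d1 <- new("DistanceDistribution", upper = c(4, 8),
            observed = c(100, 0), background = c(50, 50))
  expect_equal(xdStatistic(d1), 3.125)
  expect_equal(xdStatistic(d1, normalize = FALSE), 6.25)
})

test_that("Xd is antisymmetric and scale-covariant", {
  set.seed(14)
  for (k in 1:25) {
    n <- sample(3:12, 1)
    upper <- cumsum(runif(n, 1, 5))
    po <- randomPercentages(n)
    pa <- randomPercentages(n)
    d <- new("DistanceDistribution", upper = upper, observed = po,
             background = pa)
    swapped <- new("DistanceDistribution", upper = upper, observed = pa,
                   background = po)
    expect_identical(xdStatistic(d), -xdStatistic(swapped))
    # multiplying all distances (bin limits) by c divides Xd by c
    scaled <- new("DistanceDistribution", upper = upper * 3, observed = po,
                  background = pa)
    expect_equal(xdStatistic(scaled), xdStatistic(d) / 3, tolerance = 1e-12)
  }
})

test_that("trailing empty bins do not dilute the statistic", {
  obs <- c(1, 2, 5)
  bg <- c(1, 3, 6, 9, 11)
  a <- distanceDistribution(obs, bg, bin_width = 4, max_dist = 12)
  b <- distanceDistribution(obs, bg, bin_width = 4, max_dist = 60)
  expect_equal(xdStatistic(a), xdStatistic(b))
  expect_equal(length(a@upper), length(b@upper))
})

test_that("class comparison: identical classes and all-residue features", {
  spec <- syntheticSpec(n_residues = 50, seed = 15)
  m <- generateStructure(spec)
  fs <- featureSet("f", c(3, 9, 20))
  r <- compareClasses(c(1, 5, 12), c(1, 5, 12), fs, m)
  expect_equal(r$delta_xd, 0)
  expect_false(r$significant)
  allf <- featureSet("all", seq_len(50))
  r2 <- compareClasses(c(1, 5), c(7, 9), allf, m)
  expect_equal(r2$xd_a, 0)
  expect_equal(r2$delta_xd, 0)
  expect_error(compareClasses(integer(), 1, fs, m), "non-empty")
})

test_that("the paper-orientation flag negates the reported difference", {
  spec <- syntheticSpec(n_residues = 60, class_sizes = c(20, 15),
                        proximity_lambda = 2, seed = 16)
  b <- generateBundle(spec)
  pd <- b$mutations$seq_pos[b$mutations$class == "PD"]
  snp <- b$mutations$seq_pos[b$mutations$class == "SNP"]
  r <- compareClasses(pd, snp, b$feature, b$model)
  rp <- compareClasses(pd, snp, b$feature, b$model, paper_sign = TRUE)
  expect_equal(rp$delta_xd, -r$delta_xd)
  expect_equal(rp$significant, r$significant)
})

test_that("histogram table aligns with the comparison distributions", {
  spec <- syntheticSpec(n_residues = 60, class_sizes = c(20, 15), seed = 18)
  b <- generateBundle(spec)
  pd <- unique(b$mutations$seq_pos[b$mutations$class == "PD"])
  snp <- unique(b$mutations$seq_pos[b$mutations$class == "SNP"])
  h <- classHistograms(pd, snp, b$feature, b$model)
  expect_equal(sum(h$pct_a), 100)
  expect_equal(sum(h$pct_b), 100)
  expect_equal(sum(h$pct_background), 100)
})
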