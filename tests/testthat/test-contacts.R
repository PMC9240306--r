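makeStaticTrajectory <- function(zHeights, nFrames = 3, spacing = 0.8) {
  # beads fixed at given heights above a 3x3 phosphate lattice
  nRes <- length(zHeights)
  lat <- cgmelt:::.contactLattice(nRes, spacing = spacing, planeZ = 1)
  pept <- array(0, dim = c(nFrames, nRes, 3))
  for (r in seq_len(nRes)) {
    pept[, r, 1] <- lat$xy[r, 1]
    pept[, r, 2] <- lat$xy[r, 2]
    pept[, r, 3] <- 1 + zHeights[r]
  }
  trajectory(pept, lat$phos, seq_len(nRes), 310, lat$box)
}

test_that("contact index is the fraction of frames within the threshold", {
  bound <- makeStaticTrajectory(rep(0.5, 4))
  expect_equal(residueContactIndex(bound, 1), 1)
  expect_equal(globalContactIndex(contactProfile(bound)), 1)
  unbound <- makeStaticTrajectory(rep(3, 4))
  expect_equal(residueContactIndex(unbound, 2), 0)
  expect_error(residueContactIndex(bound, 99), "valid ids")
})

test_that("contact index is non-decreasing in the distance threshold", {
  tr <- genMarkovBindingTrajectory(0.5, nFrames = 2000, seed = 12,
                                   residueIds = 1:5)
  thresholds <- c(0.3, 0.6, 1, 1.5, 2.6, 3.5)
  gci <- vapply(thresholds, function(th)
    globalContactIndex(contactProfile(tr, threshold = th)), numeric(1))
  expect_true(all(diff(gci) >= 0))
  expect_error(contactProfile(tr, threshold = -1), "threshold")
})

test_that("two-state occupancies are recovered within +/- 0.02 at 1e4 frames", {
  tr <- genMarkovBindingTrajectory(0.6, nFrames = 10000, seed = 42,
                                   residueIds = 1:8)
  expect_equal(globalContactIndex(contactProfile(tr)), 0.6, tolerance = 0.034)
  tr3 <- genMarkovBindingTrajectory(c(0.2, 0.5, 0.9), nFrames = 10000,
                                    seed = 13, residueIds = 1:3)
  prof <- contactProfile(tr3)
  expect_true(all(abs(contactIndex(prof) - c(0.2, 0.5, 0.9)) < 0.02))
  # profile values equal independently recomputed per-residue calls
  for (r in 1:3)
    expect_equal(unname(contactIndex(prof)[r]), residueContactIndex(tr3, r))
})

test_that("statistical error shrinks like n^(-1/2)", {
  rmse <- vapply(c(1e3, 1e4, 1e5), function(n) {
    errs <- vapply(1:6, function(s) {
      tr <- genMarkovBindingTrajectory(0.5, nFrames = n, seed = 100 + s,
                                       residueIds = 1:4)
      globalContactIndex(contactProfile(tr)) - 0.5
    }, numeric(1))
    sqrt(mean(errs^2))
  }, numeric(1))
  # each decade should shrink the error by ~sqrt(10), within a factor 3
  r1 <- rmse[1] / rmse[2]
  r2 <- rmse[2] / rmse[3]
  expect_gt(r1, sqrt(10) / 3); expect_lt(r1, sqrt(10) * 3)
  expect_gt(r2, sqrt(10) / 3); expect_lt(r2, sqrt(10) * 3)
})

test_that("global contact index is the unweighted residue mean", {
  p2 <- new("ContactProfile", temperature = 310, residueIds = 1:2,
            index = c(1, 0))
  expect_equal(globalContactIndex(p2), 0.5)
  pu <- new("ContactProfile", temperature = 310, residueIds = 1:7,
            index = rep(0.37, 7))
  expect_equal(globalContactIndex(pu), 0.37)
  set.seed(8)
  v <- runif(33)
  p33 <- new("ContactProfile", temperature = 310, residueIds = 65:97,
             index = v)
  expect_equal(globalContactIndex(p33), sum(v) / 33, tolerance = 1e-13)
})

test_that("melting curves order points by temperature and reject duplicates", {
  mk <- function(T, c) new("ContactProfile", temperature = T,
                           residueIds = 1:3, index = rep(c, 3))
  cv <- meltingCurve(list(mk(450, 0.05), mk(310, 0.95)))
  expect_equal(meltingPoints(cv)$temperature, c(310, 450))
  expect_equal(meltingPoints(cv)$index, c(0.95, 0.05))
  expect_error(meltingCurve(list(mk(310, 0.1), mk(310, 0.2))), "duplicate")
  ladder <- lapply(seq(310, 450, 10), function(T) mk(T, 0.5))
  expect_length(meltingPoints(meltingCurve(ladder))$index, 15)
})

test_that("logistic melting fit recovers midpoints exactly on clean curves", {
  tl <- seq(310, 450, 10)
  clean <- new("MeltingCurve", temperature = tl,
               index = 0.05 + 0.9 / (1 + exp((tl - 372) / 15)), fit = list())
  fit <- meltingFit(fitMeltingTemperature(clean))
  expect_equal(fit$Tm, 372, tolerance = 0.1)
  expect_equal(fit$width, 15, tolerance = 0.1)
  expect_false(fit$lowConfidence)
  # symmetric curve: midpoint at the central temperature
  sym <- new("MeltingCurve", temperature = tl,
             index = 1 / (1 + exp((tl - 380) / 20)), fit = list())
  expect_equal(meltingFit(fitMeltingTemperature(sym))$Tm, 380,
               tolerance = 0.1)
})

test_that("melting fit is unbiased under realistic noise", {
  tl <- seq(310, 450, 10)
  truth <- 1 / (1 + exp((tl - 372) / 15))
  set.seed(77)
  tms <- vapply(1:50, function(r) {
    noisy <- pmin(1, pmax(0, truth + rnorm(15, sd = 0.03)))
    meltingFit(fitMeltingTemperature(
      new("MeltingCurve", temperature = tl, index = noisy, fit = list())))$Tm
  }, numeric(1))
  expect_lt(abs(mean(tms) - 372), 2)
  expect_lt(sd(tms), 6)
})

test_that("segment convergence splits evenly and flags stationarity", {
  block <- makeStaticTrajectory(c(0.5, 3, 0.5), nFrames = 4)
  rep3 <- trajectory(block@peptide[rep(1:4, 3), , ], block@phosphates,
                     block@residueIds, 310, block@box)
  sc <- segmentConvergence(rep3, 3)
  expect_equal(sc$maxDeviation, 0)
  expect_equal(sc$segmentLength, 4)
  ten <- trajectory(block@peptide[rep(1, 10), , ], block@phosphates,
                    block@residueIds, 310, block@box)
  sc10 <- segmentConvergence(ten, 3)
  expect_equal(sc10$segmentLength, 3) # one remainder frame dropped
  stat <- genMarkovBindingTrajectory(0.5, nFrames = 30000, seed = 55,
                                     residueIds = 1:6)
  expect_lt(segmentConvergence(stat, 3)$maxDeviation, 0.05)
  expect_error(segmentConvergence(block, 5), "too few frames")
})

test_that("burn-in discards the requested fraction of frames", {
  z <- c(rep(3, 10), rep(0.5, 10)) # unbound first half, bound second
  pept <- array(0, dim = c(20, 1, 3))
  lat <- cgmelt:::.contactLattice(1, planeZ = 1)
  pept[, 1, 1] <- lat$xy[1, 1]; pept[, 1, 2] <- lat$xy[1, 2]
  pept[, 1, 3] <- 1 + z
  tr <- trajectory(pept, lat$phos, 1L, 310, lat$box)
  expect_equal(residueContactIndex(tr, 1), 0.5)
  expect_equal(residueContactIndex(tr, 1, burnIn = 0.5), 1)
  expect_error(residueContactIndex(tr, 1, burnIn = 1.2), "burnIn")
})
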