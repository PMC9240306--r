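kcal <- 4.184

test_that("harmonic bias is zero at the centre and symmetric", {
  w <- umbrellaWindow(1.2, c(1.1, 1.2, 1.3), forceConstant = 1000)
  expect_equal(biasPotential(1.2, w), 0)
  expect_equal(biasPotential(1.3, w), 5) # 0.5 * 1000 * 0.1^2
  expect_equal(biasPotential(1.2 + 0.07, w), biasPotential(1.2 - 0.07, w))
})

test_that("histograms conserve counts on a shared grid and match sample moments", {
  w1 <- umbrellaWindow(1, rep(1.001, 50))
  h1 <- buildHistograms(list(w1), binWidth = 0.02)
  expect_equal(sum(h1$counts > 0), 1)
  expect_equal(sum(h1$counts), 50)
  set.seed(19)
  xs <- rnorm(5e4, mean = 1.2, sd = 0.05)
  w2 <- umbrellaWindow(1.2, xs)
  h2 <- buildHistograms(list(w2), binWidth = 0.002)
  p <- h2$counts[1, ] / sum(h2$counts)
  expect_equal(sum(p * h2$mids), mean(xs), tolerance = 1e-3)
  expect_equal(sqrt(sum(p * h2$mids^2) - sum(p * h2$mids)^2), sd(xs),
               tolerance = 1e-2)
  expect_error(buildHistograms(list(umbrellaWindow(1, 1), NULL)), "Umbrella")
})

test_that("WHAM reduces to the plain histogram without reweighting", {
  set.seed(23)
  xs <- qnorm(runif(2e4, 0.001, 0.999), 1, 0.1) # bounded, gap-free sample
  w <- umbrellaWindow(1, xs, forceConstant = 1e-9) # effectively unbiased
  h <- buildHistograms(list(w), binWidth = 0.01)
  sol <- whamSolve(h, list(w), 300)
  expect_equal(sol$p, h$counts[1, ] / sum(h$counts), tolerance = 1e-6)
  # two identical windows: no shift, same distribution
  h2 <- buildHistograms(list(w, w), binWidth = 0.01)
  sol2 <- whamSolve(h2, list(w, w), 300)
  expect_equal(sol2$windowF[2], 0, tolerance = 1e-6)
  expect_equal(sol2$p, sol$p, tolerance = 1e-8)
})

test_that("WHAM solution is self-consistent and window-order invariant", {
  u <- analyticPMF("harmonic", depth = 200 / kcal, location = 1, width = 1,
                   domain = c(0.2, 1.9))
  wins <- genUmbrellaSamples(u, centers = seq(0.4, 1.6, length.out = 11),
                             nPerWindow = 8000, seed = 3)
  h <- buildHistograms(wins)
  sol <- whamSolve(h, wins, 300, tol = 1e-9)
  # plugging the converged solution back reproduces it
  kT <- kB * 300
  W <- t(vapply(wins, function(w) biasPotential(h$mids, w),
                numeric(length(h$mids))))
  Ni <- rowSums(h$counts)
  denom <- colSums(Ni * exp(sol$windowF / kT) * exp(-W / kT))
  pBack <- ifelse(colSums(h$counts) > 0, colSums(h$counts) / denom, 0)
  pBack <- pBack / sum(pBack)
  expect_equal(pBack, sol$p, tolerance = 1e-6)
  # permuting windows leaves the distribution unchanged
  perm <- c(6, 1, 9, 2, 11, 3, 8, 4, 10, 5, 7)
  # same samples, so the default grid is identical after permutation
  hp <- buildHistograms(wins[perm], binWidth = 0.02)
  expect_equal(hp$mids, h$mids)
  # overlap diagnostics are order-based, so the permuted solve warns
  solp <- suppressWarnings(whamSolve(hp, wins[perm], 300, tol = 1e-9))
  expect_lt(max(abs(solp$p - sol$p)), 1e-8)
})

test_that("WHAM recovers a known harmonic profile with small RMSE", {
  u <- analyticPMF("harmonic", depth = 200 / kcal, location = 1, width = 1,
                   domain = c(0.2, 1.9))
  wins <- genUmbrellaSamples(u, centers = seq(0.4, 1.6, length.out = 11),
                             nPerWindow = 20000, seed = 3)
  prof <- whamPMF(wins, 300)
  ok <- prof@counts >= 100 & is.finite(prof@freeEnergy)
  resid <- prof@freeEnergy[ok] - evalPMF(u, prof@grid[ok])
  resid <- resid - mean(resid) # PMFs match up to an additive constant
  expect_lt(sqrt(mean(resid^2)), 0.3)
})

test_that("WHAM handles double-well and Morse-shaped profiles", {
  for (form in c("double_well", "morse_like")) {
    u <- analyticPMF(form, depth = 3, location = 1,
                     width = if (form == "double_well") 0.25 else 0.2,
                     domain = c(0.3, 2.4))
    wins <- genUmbrellaSamples(u, centers = seq(0.5, 1.9, length.out = 13),
                               nPerWindow = 20000, seed = 5)
    prof <- whamPMF(wins, 300)
    ok <- prof@counts >= 100 & is.finite(prof@freeEnergy)
    resid <- prof@freeEnergy[ok] - evalPMF(u, prof@grid[ok])
    resid <- resid - mean(resid)
    expect_lt(sqrt(mean(resid^2)), 0.3)
  }
})

test_that("PMF construction obeys the log identity and shift invariance", {
  mids <- seq(0.5, 2, by = 0.02)
  pu <- rep(1 / length(mids), length(mids))
  flat <- pmfFromProbability(pu, mids, 300)
  expect_true(all(abs(flat@freeEnergy) < 1e-10))
  U <- 5 * (mids - 1)^2
  p <- exp(-U / (kB * 300)); p <- p / sum(p)
  prof <- pmfFromProbability(p, mids, 300, plateauWindow = c(1.8, 2))
  dG <- prof@freeEnergy - U
  expect_lt(diff(range(dG)), 1e-6)
  prof2 <- pmfFromProbability(2 * p, mids, 300, plateauWindow = c(1.8, 2))
  expect_equal(prof2@freeEnergy, prof@freeEnergy, tolerance = 1e-12)
  expect_error(pmfFromProbability(rep(0, 5), mids[1:5], 300), "all-zero")
})

test_that("binding free energy converts well depth to kcal/mol", {
  mids <- seq(0.5, 2.5, by = 0.02)
  flat <- pmfFromProbability(rep(1, length(mids)), mids, 300)
  expect_equal(bindingFreeEnergy(flat, c(0.5, 1), c(2, 2.5)), 0)
  # square-well PMF of depth 46.024 kJ/mol is 11.0 kcal/mol
  G <- ifelse(abs(mids - 1) < 0.15, -46.024, 0)
  prof <- new("PMFProfile", grid = mids, freeEnergy = G,
              counts = rep(1, length(mids)), windowF = numeric(0),
              temperature = 300, reference = "plateau")
  expect_equal(bindingFreeEnergy(prof, c(0.6, 1.4), c(2, 2.5)), 11,
               tolerance = 1e-6)
  # integrated basin: summing Boltzmann weight over n equal bins deepens
  # the effective level by kT ln n
  nb <- sum(mids >= 0.86 & mids <= 1.14 & G < 0)
  expect_equal(bindingFreeEnergy(prof, c(0.86, 1.14), c(2, 2.5),
                                 method = "integrated"),
               11 + kB * 300 * log(nb) / 4.184, tolerance = 1e-3)
  expect_error(bindingFreeEnergy(prof, c(5, 6), c(2, 2.5)), "bound window")
})

test_that("end-to-end umbrella sampling recovers designed binding free energies", {
  dgs <- vapply(c(11, 7.5), function(D) {
    u <- analyticPMF("morse_like", depth = D, location = 1, width = 0.2,
                     domain = c(0.7, 2.4))
    wins <- genUmbrellaSamples(u, nPerWindow = 20000, seed = 7)
    prof <- whamPMF(wins, 300, plateauWindow = c(2, 2.2))
    bindingFreeEnergy(prof, c(0.8, 1.4), c(2, 2.2))
  }, numeric(1))
  expect_lt(abs(dgs[1] - 11), 0.3)
  expect_lt(abs(dgs[2] - 7.5), 0.3)
  expect_lt(abs((dgs[1] - dgs[2]) - 3.5), 0.4)
})

test_that("window overlap matches the Gaussian closed form and flags gaps", {
  set.seed(33)
  a <- rnorm(2e5)
  w1 <- umbrellaWindow(0, a, 1)
  w2 <- umbrellaWindow(2, a + 2, 1)
  h <- buildHistograms(list(w1, w2), binWidth = 0.05)
  # two unit-variance Gaussians two sd apart: overlap = 2*pnorm(-1)
  expect_equal(windowOverlap(h), 2 * pnorm(-1), tolerance = 0.01)
  same <- buildHistograms(list(w1, w1), binWidth = 0.05)
  expect_equal(windowOverlap(same), 1)
  far <- list(umbrellaWindow(0, rnorm(5000, 0, 0.05)),
              umbrellaWindow(9, rnorm(5000, 9, 0.05)))
  hf <- buildHistograms(far, binWidth = 0.05)
  expect_equal(windowOverlap(hf), 0)
  expect_error(whamSolve(hf, far, 300), "disjoint")
})

test_that("bootstrap reports a sensible uncertainty for the binding free energy", {
  u <- analyticPMF("morse_like", depth = 5, location = 1, width = 0.2,
                   domain = c(0.7, 2.4))
  wins <- genUmbrellaSamples(u, nPerWindow = 4000, seed = 9)
  bs <- bootstrapBindingFreeEnergy(wins, 300, c(0.8, 1.4), c(2, 2.2),
                                   nBoot = 20, seed = 2)
  expect_equal(bs$deltaG, 5, tolerance = 0.1)
  expect_gt(bs$se, 0)
  expect_lt(bs$se, 0.5)
  expect_length(bs$replicates, 20)
})
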