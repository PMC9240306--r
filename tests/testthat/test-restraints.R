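test_that("backbone angles match closed forms and the law-of-cosines oracle", {
  expect_equal(computeAngle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 180)
  expect_equal(computeAngle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  set.seed(101)
  for (i in 1:25) {
    x <- randomBeadGeometry(3)
    th <- computeAngle(x[1, ], x[2, ], x[3, ])
    expect_gte(th, 0); expect_lte(th, 180)
    expect_equal(th, lawOfCosinesAngle(x[1, ], x[2, ], x[3, ]),
                 tolerance = 1e-11)
    # invariant under i <-> k swap and rigid motion
    expect_equal(computeAngle(x[3, ], x[2, ], x[1, ]), th, tolerance = 1e-12)
    y <- applyRigid(x, randomRotation(), rnorm(3))
    expect_equal(computeAngle(y[1, ], y[2, ], y[3, ]), th, tolerance = 1e-9)
  }
  expect_error(computeAngle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "degenerate")
})

test_that("dihedrals follow the four-quadrant convention with correct sign", {
  # square geometry: i and l on the same side of the j-k axis is cis
  i <- c(0, 1, 0); j <- c(0, 0, 0); k <- c(1, 0, 0)
  expect_equal(computeDihedral(i, j, k, c(1, 1, 0)), 0)    # planar cis
  expect_equal(abs(computeDihedral(i, j, k, c(1, -1, 0))), 180) # planar trans
  ii <- c(0, 0, 0); jj <- c(1, 1, 0); kk <- c(2, 0, 0)
  expect_equal(computeDihedral(ii, jj, kk, c(3, 1, 0)), 180) # zigzag trans
  # rotating i by +90 about the j->k axis from cis changes phi by -90
  # (oracle built from an explicit rotation matrix)
  set.seed(7)
  for (rep in 1:10) {
    x <- randomBeadGeometry(4)
    phi0 <- computeDihedral(x[1, ], x[2, ], x[3, ], x[4, ])
    axis <- x[3, ] - x[2, ]
    iR <- rotateAboutAxis(x[1, ], x[2, ], axis, 90)
    phi1 <- computeDihedral(iR, x[2, ], x[3, ], x[4, ])
    dphi <- ((phi1 - phi0 + 180) %% 360) - 180
    expect_equal(abs(dphi), 90, tolerance = 1e-9)
    # mirror image flips the sign
    xm <- x; xm[, 3] <- -xm[, 3]
    expect_equal(computeDihedral(xm[1, ], xm[2, ], xm[3, ], xm[4, ]),
                 -phi0, tolerance = 1e-9)
  }
  expect_error(computeDihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("Gaussian restraint energies match hand evaluations and bounds", {
  p <- restraintParams("helical", Kangle = 10, thetaMin = 96, sigmaAngle = 200)
  expect_equal(angleRestraintEnergy(96, p), -10)
  expect_equal(angleRestraintEnergy(110, p), -10 * exp(-196 / 200))
  expect_gt(angleRestraintEnergy(96 + 80, p), -10 * exp(-25))
  expect_lt(angleRestraintEnergy(96 + 80, p), 0)
  pd <- restraintParams("helical", Kdihedral = 8, phiMin = -120,
                        sigmaDihedral = 400)
  expect_equal(dihedralRestraintEnergy(-120, pd), -8)
  expect_equal(dihedralRestraintEnergy(-100, pd), -8 * exp(-1))
  # periodic: a full turn leaves the energy at the well bottom
  expect_equal(dihedralRestraintEnergy(-120 + 360, pd), -8)
  expect_equal(dihedralRestraintEnergy(240, pd), dihedralRestraintEnergy(-120, pd))
  expect_error(restraintParams("helical", sigmaAngle = -1), "sigmaAngle")
  expect_error(restraintParams("helical", thetaMin = 200), "thetaMin")
})

test_that("analytic restraint forces match central finite differences", {
  p <- restraintParams("helical", Kangle = 10, thetaMin = 96,
                       sigmaAngle = 200, Kdihedral = 10, phiMin = -120,
                       sigmaDihedral = 200)
  set.seed(2024)
  for (rep in 1:120) {
    x <- randomBeadGeometry(4)
    fa <- angleRestraintForce(x[1, ], x[2, ], x[3, ], p)
    fd <- dihedralRestraintForce(x[1, ], x[2, ], x[3, ], x[4, ], p)
    # Newton's third law
    expect_lt(max(abs(colSums(fa))), 1e-9)
    expect_lt(max(abs(colSums(fd))), 1e-9)
    na <- numericForce(x[1:3, ], p, "angle")
    nd <- numericForce(x, p, "dihedral")
    expect_lt(max(abs(fa - na)) / max(abs(na), 1e-8), 1e-5)
    expect_lt(max(abs(fd - nd)) / max(abs(nd), 1e-8), 1e-5)
  }
})

test_that("restraint forces vanish at the potential minima", {
  p <- restraintParams("helical")
  ch <- genPeptideChain(state = "helical", p = p)
  pos <- positions(ch)
  f <- angleRestraintForce(pos[1, ], pos[2, ], pos[3, ], p)
  expect_lt(max(abs(f)), 1e-8)
  fd <- dihedralRestraintForce(pos[1, ], pos[2, ], pos[3, ], pos[4, ], p)
  expect_lt(max(abs(fd)), 1e-8)
})

test_that("chain restraint energy itemises one term per triplet/quadruplet", {
  p <- restraintParams("helical")
  ch4 <- genPeptideChain(residueRange = 1:4, state = "helical", p = p)
  r4 <- chainRestraintEnergy(ch4, p)
  expect_equal(nrow(r4@angleTerms), 2)
  expect_equal(nrow(r4@dihedralTerms), 1)
  # 33-bead chain at the construction minimum
  ch <- genPeptideChain(state = "helical", p = p)
  r <- chainRestraintEnergy(ch, p)
  expect_equal(nrow(r@angleTerms), 31)
  expect_equal(nrow(r@dihedralTerms), 30)
  expect_equal(r@total, -(31 * p@Kangle + 30 * p@Kdihedral), tolerance = 1e-9)
  # term-by-term oracle: independent single-term evaluations
  pos <- positions(ch)
  single <- sum(vapply(1:31, function(t)
    angleRestraintEnergy(computeAngle(pos[t, ], pos[t + 1, ], pos[t + 2, ]), p),
    numeric(1))) +
    sum(vapply(1:30, function(t)
      dihedralRestraintEnergy(
        computeDihedral(pos[t, ], pos[t + 1, ], pos[t + 2, ], pos[t + 3, ]), p),
      numeric(1)))
  expect_equal(r@total, single, tolerance = 1e-12)
  expect_error(chainRestraintEnergy(
    beadChain(matrix(rnorm(9), 3, 3), state = "helical"), p),
    "4 beads")
})

test_that("restraint energies are invariant under rigid motions", {
  p <- restraintParams("extended")
  set.seed(5)
  x <- randomBeadGeometry(8)
  ch <- beadChain(x, residueIds = 1:8, state = "extended")
  e0 <- chainRestraintEnergy(ch, p)@total
  for (rep in 1:20) {
    y <- applyRigid(x, randomRotation(), rnorm(3, sd = 5))
    e1 <- chainRestraintEnergy(beadChain(y, residueIds = 1:8,
                                         state = "extended"), p)@total
    expect_equal(e1, e0, tolerance = 1e-9)
  }
})

test_that("mirror symmetry leaves dihedral energy unchanged only at symmetric minima", {
  set.seed(9)
  x <- randomBeadGeometry(4)
  phi <- computeDihedral(x[1, ], x[2, ], x[3, ], x[4, ])
  xm <- x; xm[, 1] <- -xm[, 1]
  expect_equal(computeDihedral(xm[1, ], xm[2, ], xm[3, ], xm[4, ]), -phi,
               tolerance = 1e-9)
  # a mirror flips phi -> -phi: with the symmetric trans minimum the
  # wrapped deviation magnitude is unchanged, with an asymmetric minimum
  # it is not
  pSym <- restraintParams("extended", phiMin = 180)
  expect_equal(dihedralRestraintEnergy(-100, pSym),
               dihedralRestraintEnergy(100, pSym), tolerance = 1e-12)
  pAsym <- restraintParams("helical", phiMin = -120)
  expect_gt(abs(dihedralRestraintEnergy(-100, pAsym) -
                dihedralRestraintEnergy(100, pAsym)), 1)
})
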