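# shared helpers for the suite: random rigid transforms, finite-difference
# force oracles, and a small reference bead geometry

kB <- 0.0083145

randomRotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3))) * sample(c(-1, 1), 1)
}

applyRigid <- function(x, R, t) sweep(x %*% t(R), 2, -t)

# central finite difference of a restraint energy wrt bead coordinates
numericForce <- function(x, p, kind = c("angle", "dihedral"), h = 1e-6) {
  kind <- match.arg(kind)
  nb <- if (kind == "angle") 3L else 4L
  g <- matrix(0, nb, 3)
  en <- function(y) {
    if (kind == "angle")
      angleRestraintEnergy(computeAngle(y[1, ], y[2, ], y[3, ]), p)
    else
      dihedralRestraintEnergy(computeDihedral(y[1, ], y[2, ], y[3, ], y[4, ]), p)
  }
  for (b in seq_len(nb)) for (d in 1:3) {
    xp <- x; xm <- x
    xp[b, d] <- xp[b, d] + h
    xm[b, d] <- xm[b, d] - h
    g[b, d] <- -(en(xp) - en(xm)) / (2 * h)
  }
  g
}

# geometry with all pairwise separations well away from degeneracy
randomBeadGeometry <- function(nb) {
  repeat {
    x <- matrix(rnorm(nb * 3), nb, 3)
    d <- as.matrix(dist(x))
    if (min(d[upper.tri(d)]) > 0.3) return(x)
  }
}

# law-of-cosines oracle for the angle from the three pairwise distances
lawOfCosinesAngle <- function(ri, rj, rk) {
  a <- sqrt(sum((ri - rj)^2))
  b <- sqrt(sum((rk - rj)^2))
  c <- sqrt(sum((ri - rk)^2))
  acos((a^2 + b^2 - c^2) / (2 * a * b)) * 180 / pi
}

# rotate point x about the axis through `origin` along unit vector `u`
rotateAboutAxis <- function(x, origin, u, angleDeg) {
  th <- angleDeg * pi / 180
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  as.numeric(R %*% (x - origin)) + origin
}
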