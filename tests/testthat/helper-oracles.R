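# Independent oracles shared across tests.  These deliberately avoid the
# package's own computational paths: brute-force quadrature, dense-matrix
# representations, closed forms.

default_params <- dna_state_params()

# Gauss-Legendre nodes/weights on [-1, 1] (local copy, independent of the
# package's internal quadrature helper)
oracle_gl <- function(n) {
  k <- seq_len(n - 1)
  off <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- off
  J[cbind(k + 1, k)] <- off
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

# diagonal Wigner d element from the dense matrix exponential of J_y
oracle_wigner_d <- function(k, r, th) {
  m <- (-k):k
  Jp <- matrix(0, 2 * k + 1, 2 * k + 1)
  for (i in seq_along(m)[-length(m)]) {
    Jp[i + 1, i] <- sqrt(k * (k + 1) - m[i] * (m[i] + 1))
  }
  Jy <- (Jp - t(Jp)) / (2i)
  e <- eigen(Jy)
  D <- e$vectors %*% diag(exp(-1i * th * e$values)) %*% Conj(t(e$vectors))
  Re(D[which(m == r), which(m == r)])
}

# double Gauss-Legendre quadrature of the Gauss linking integrand for one
# pair of straight segments (both orderings included: contribution to Wr)
oracle_gauss_pair <- function(p1, p2, p3, p4, n = 300) {
  g <- oracle_gl(n)
  t1 <- (g$x + 1) / 2
  w1 <- g$w / 2
  r12 <- p2 - p1
  r34 <- p4 - p3
  cr <- c(r12[2] * r34[3] - r12[3] * r34[2],
          r12[3] * r34[1] - r12[1] * r34[3],
          r12[1] * r34[2] - r12[2] * r34[1])
  acc <- 0
  for (i in seq_len(n)) {
    a <- p1 + t1[i] * r12
    d <- matrix(a, n, 3, byrow = TRUE) -
      (matrix(p3, n, 3, byrow = TRUE) + t1 %o% r34)
    num <- drop(d %*% cr)
    den <- rowSums(d^2)^1.5
    acc <- acc + w1[i] * sum(w1 * num / den)
  }
  acc / (2 * pi)  # ordered double sum / 4 pi = unordered / 2 pi
}

# 4-D quadrature of the junction Boltzmann kernel whose SO(3) expansion the
# transfer matrix implements: for a 2-segment chain,
#   Z2 = 4 pi^2 int d(cos b1) d(cos b2) d(da) d(dg)
#        exp(a (cosTheta - 1) + b f x1 + c (cos v - 1)
#            + (tau lam / 2pi) sin v + (tau (2pi - lam) / 2pi) sin(da + dg))
#        * exp(b f x2)
# with v the relative-rotation twist angle.
oracle_z2 <- function(a, b, cc, lam, f, tau, nb = 40, na = 48) {
  g <- oracle_gl(nb)
  ang <- 2 * pi * (0:(na - 1)) / na
  wang <- 2 * pi / na
  acc <- 0
  for (i1 in seq_len(nb)) for (i2 in seq_len(nb)) {
    x1 <- g$x[i1]; x2 <- g$x[i2]
    s1 <- sqrt(1 - x1^2); s2 <- sqrt(1 - x2^2)
    cda <- cos(ang); sda <- sin(ang)
    cosTheta <- x1 * x2 + s1 * s2 * cda
    M11 <- x1 * cda * x2 + s1 * s2
    M22 <- cda
    M21 <- sda * x2
    M12 <- -x1 * sda
    phi0 <- atan2(M21 - M12, M11 + M22)
    inner <- vapply(seq_along(ang), function(ia) {
      v <- phi0[ia] + ang
      u <- ang[ia] + ang
      sum(exp(a * (cosTheta[ia] - 1) + b * f * x1 +
              cc * (cos(v) - 1) + (tau * lam / (2 * pi)) * sin(v) +
              (tau * (2 * pi - lam) / (2 * pi)) * sin(u))) * wang
    }, numeric(1))
    acc <- acc + g$w[i1] * g$w[i2] * sum(inner) * wang * exp(b * f * x2)
  }
  4 * pi^2 * acc
}

# extension of the continuum worm-like chain from the ground state of the
# Legendre-basis Hamiltonian f x - l(l+1)/(2 Lp)
oracle_wlc_extension <- function(f, Lp = 50, lmax = 60) {
  X <- matrix(0, lmax + 1, lmax + 1)
  for (l in 0:(lmax - 1)) {
    v <- (l + 1) / sqrt((2 * l + 1) * (2 * l + 3))
    X[l + 1, l + 2] <- v
    X[l + 2, l + 1] <- v
  }
  lam <- function(ff) {
    max(eigen(ff * X - diag((0:lmax) * (1:(lmax + 1))) / (2 * Lp),
              symmetric = TRUE, only.values = TRUE)$values)
  }
  h <- max(f, 0.01) * 1e-4
  (lam(f + h) - lam(f - h)) / (2 * h)
}
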