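# Mathematical kernel of the transfer matrix: diagonal Wigner small-d
# elements, their bilateral Laplace transforms, Wigner 3-j symbols and
# (spherical) modified Bessel functions.

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch (symmetric
# tridiagonal Jacobi matrix); memoized.
.twlc_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(n) {
  key <- paste0("gl", n)
  if (!is.null(.twlc_cache[[key]])) return(.twlc_cache[[key]])
  k <- seq_len(n - 1)
  off <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- off
  J[cbind(k + 1, k)] <- off
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  res <- list(x = x[ord], w = w[ord])
  .twlc_cache[[key]] <- res
  res
}

# Jacobi polynomials P^(0, b)_n(x) for n = 0..nmax, vectorized over x;
# returns (nmax+1) x length(x) matrix.
jacobi_table <- function(nmax, b, x) {
  out <- matrix(0, nmax + 1, length(x))
  out[1, ] <- 1
  if (nmax >= 1) out[2, ] <- (-b + (2 + b) * x) / 2
  if (nmax >= 2) {
    for (n in 1:(nmax - 1)) {
      # standard three-term recurrence for alpha = 0
      c1 <- 2 * (n + 1) * (n + b + 1) * (2 * n + b)
      c2 <- -(2 * n + b + 1) * b^2
      c3 <- (2 * n + b) * (2 * n + b + 1) * (2 * n + b + 2)
      c4 <- 2 * (n + b) * n * (2 * n + b + 2)
      out[n + 2, ] <- ((c2 + c3 * x) * out[n + 1, ] - c4 * out[n, ]) / c1
    }
  }
  out
}

#' Diagonal Wigner small-d matrix element
#'
#' `d^k_{rr}(theta)` via the Jacobi-polynomial closed form
#' `d^k_{rr} = cos(theta/2)^{2|r|} P^{(0, 2|r|)}_{k-|r|}(cos theta)`;
#' `d^k_{rr}(0) = 1`, and `d^k_{00} = P_k(cos theta)`.
#'
#' @param k Order (non-negative integer).
#' @param r Index with `|r| <= k`.
#' @param theta Angle(s), rad.
#' @return Numeric vector of values.
#' @export
wigner_d_diag <- function(k, r, theta) {
  r <- abs(r)
  if (r > k) stop("|r| must not exceed k")
  x <- cos(theta)
  jt <- jacobi_table(k - r, 2 * r, x)
  cos(theta / 2)^(2 * r) * jt[k - r + 1, ]
}

# table of d^j_{rr}(acos x) for all 0 <= r <= j <= kmax at nodes x:
# array [j+1, r+1, node]; zero for j < r.
wigner_d_table <- function(kmax, x) {
  key <- paste0("dtab", kmax, "_", length(x))
  if (!is.null(.twlc_cache[[key]])) return(.twlc_cache[[key]])
  M <- length(x)
  arr <- array(0, c(kmax + 1, kmax + 1, M))
  half <- sqrt((1 + x) / 2)  # cos(theta/2), theta = acos(x) in [0, pi]
  for (r in 0:kmax) {
    jt <- jacobi_table(kmax - r, 2 * r, x)
    pref <- half^(2 * r)
    for (j in r:kmax) {
      arr[j + 1, r + 1, ] <- pref * jt[j - r + 1, ]
    }
  }
  .twlc_cache[[key]] <- arr
  arr
}

#' Bilateral Laplace transform of diagonal Wigner d elements
#'
#' `L^k_r(s) = integral_{-1}^{1} d^k_{rr}(acos x) exp(-s x) dx`, evaluated by
#' Gauss-Legendre quadrature with node doubling until the relative change is
#' below `tol`.
#'
#' @param k,r Order and index, `|r| <= k`.
#' @param s Real argument (e.g. `-a`, `-b f`, or 0).
#' @param tol Relative convergence target.
#' @param nodes Starting node count.
#' @return Value of the transform.
#' @export
laplace_wigner_d <- function(k, r, s, tol = 1e-12, nodes = 64) {
  if (abs(r) > k) stop("|r| must not exceed k")
  f <- function(n) {
    gl <- gauss_legendre(n)
    sum(gl$w * wigner_d_diag(k, r, acos(gl$x)) * exp(-s * gl$x))
  }
  prev <- f(nodes)
  floor_scale <- 1e-14 * exp(abs(s))  # absolute floor for vanishing integrals
  for (i in 1:4) {
    nodes <- nodes * 2
    cur <- f(nodes)
    if (abs(cur - prev) <= max(tol * abs(cur), floor_scale)) return(cur)
    prev <- cur
  }
  stop("laplace_wigner_d did not converge: last values ", prev, ", ",
       f(nodes * 2))
}

#' Wigner 3-j symbol
#'
#' Racah's single-sum formula evaluated with log-factorials; returns 0
#' whenever the triangle or projection selection rules fail.  Accurate to
#' ~1e-12 for the moderate orders used by the transfer matrix.
#'
#' @param j1,j2,j3 Angular momenta (non-negative integers here).
#' @param m1,m2,m3 Projections.
#' @return The 3-j symbol value.
#' @export
wigner_3j <- function(j1, j2, j3, m1, m2, m3) {
  if (m1 + m2 + m3 != 0) return(0)
  if (j3 < abs(j1 - j2) || j3 > j1 + j2) return(0)
  if (abs(m1) > j1 || abs(m2) > j2 || abs(m3) > j3) return(0)
  lf <- function(n) lgamma(n + 1)
  # triangle coefficient (log)
  ltri <- (lf(j1 + j2 - j3) + lf(j1 - j2 + j3) + lf(-j1 + j2 + j3) -
           lf(j1 + j2 + j3 + 1)) / 2
  lpre <- (lf(j1 + m1) + lf(j1 - m1) + lf(j2 + m2) + lf(j2 - m2) +
           lf(j3 + m3) + lf(j3 - m3)) / 2
  tmin <- max(0, j2 - j3 - m1, j1 - j3 + m2)
  tmax <- min(j1 + j2 - j3, j1 - m1, j2 + m2)
  if (tmin > tmax) return(0)
  acc <- 0
  for (t in tmin:tmax) {
    lden <- lf(t) + lf(j3 - j2 + m1 + t) + lf(j3 - j1 - m2 + t) +
      lf(j1 + j2 - j3 - t) + lf(j1 - m1 - t) + lf(j2 + m2 - t)
    acc <- acc + (-1)^t * exp(ltri + lpre - lden)
  }
  (-1)^(j1 - j2 - m3) * acc
}

#' Modified Bessel functions used by the transfer matrix
#'
#' `bessel_i(r, x)` is the modified Bessel function of the first kind
#' `I_r(x)` for integer order and real argument (negative arguments via
#' `I_r(-x) = (-1)^r I_r(x)`); `scaled = TRUE` returns `exp(-|x|) I_r(x)`.
#' `sph_bessel_i(k, x)` is the spherical version
#' `i_k(x) = sqrt(pi / (2 x)) I_{k+1/2}(x)`, with the series limit at small
#' `x` (`i_0(0) = 1`, `i_k(0) = 0` for `k > 0`).
#'
#' @param r,k Order (non-negative integer).
#' @param x Argument (vectorized).
#' @param scaled If `TRUE`, damp by `exp(-|x|)`.
#' @return Function values.
#' @export
bessel_i <- function(r, x, scaled = FALSE) {
  sgn <- ifelse(x < 0, (-1)^r, 1)
  sgn * besselI(abs(x), r, expon.scaled = scaled)
}

#' @rdname bessel_i
#' @export
sph_bessel_i <- function(k, x, scaled = FALSE) {
  vapply(x, function(xi) {
    ax <- abs(xi)
    sgn <- if (xi < 0) (-1)^k else 1
    if (ax < 1e-6) {
      # series: x^k / (2k+1)!! (1 + x^2 / (2(2k+3)) + ...)
      dfact <- prod(seq(1, 2 * k + 1, by = 2))
      val <- ax^k / dfact * (1 + ax^2 / (2 * (2 * k + 3)))
      return(sgn * val * if (scaled) exp(-ax) else 1)
    }
    sgn * sqrt(pi / (2 * ax)) * besselI(ax, k + 0.5, expon.scaled = scaled)
  }, numeric(1))
}
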