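# Single-state transfer matrix: S-matrix assembly, boundary vector, and the
# log partition function ln Z = ln Tr(S^{N-1} V) with observables obtained by
# numerical differentiation.
#
# The S matrix entries follow the Wigner D-function expansion
#   S_kk' = pi^2 sqrt((2k+1)(2k'+1)) e^{-a-c}
#           sum_{p,s,s',r} (2p+1)(2s+1)(2s'+1) e^{ir(w - pi/2)}
#           I_r(tau (1 - lam/2pi)) I_r(c sqrt(1+chi^2))
#           L_r^p(-a) L_r^s(-b f) L_r^{s'}(0)
#           (3j: p s k; -r r 0)^2 (3j: p s' k'; -r r 0)^2
# with chi = tau lam / (2 pi c) and w = atan(chi).  Pairing the +r and -r
# terms makes every entry real: e^{ir(w-pi/2)} + c.c. = 2 cos(r (w - pi/2))
# (all other factors are even in r), so the assembly below is real and the
# imaginary residual of the partition function is identically zero.
#
# Numerical scaling: the e^{-a} prefactor is folded into the Laplace
# transforms (integrands e^{a(x-1)} <= 1) and e^{-c} into exponentially
# scaled Bessel functions, so no term ever leaves double range even at
# a, c ~ 200.
#
# Cost: everything that is expensive (the quadruple sum) is independent of
# the torque; per r the (p,s,s') contraction is cached as a stack of matrices
# T_r(a, b f), and any torque only reweights the stack.  Sweeps over tau and
# the constant-chi derivative reuse one stack.

#' Truncation settings for the transfer matrix
#'
#' @param kmax Harmonic cutoff for all D-function orders (k, k', p, s, s', r).
#'   `NULL` selects the cutoff adaptively (raised until `log Z` changes by
#'   less than `tol`).
#' @param nodes Gauss-Legendre node count for the Laplace transforms and 3-j
#'   projections (must comfortably exceed the polynomial degree 3 kmax).
#' @param tol Relative convergence target for adaptive truncation.
#' @return A `tm_truncation` list.
#' @export
tm_truncation <- function(kmax = NULL, nodes = 256, tol = 1e-6) {
  if (!is.null(kmax)) {
    stopifnot(kmax >= 0, nodes >= kmax + 10)
  }
  structure(list(kmax = kmax, nodes = nodes, tol = tol),
            class = "tm_truncation")
}

# squared 3-j tables: for each r, matrix [(p,k) x s] of
# (3j: p s k; -r r 0)^2, computed by Gauss-Legendre projection of the
# product identity d^p_rr d^s_rr = sum_k (2k+1) (3j)^2 P_k.  Memoized.
g3j_tables <- function(kmax, nodes) {
  key <- paste0("g3j", kmax, "_", nodes)
  if (!is.null(.twlc_cache[[key]])) return(.twlc_cache[[key]])
  gl <- gauss_legendre(nodes)
  dtab <- wigner_d_table(kmax, gl$x)
  K1 <- kmax + 1
  P <- matrix(dtab[, 1, ], K1, nodes)  # Legendre values [k, m]
  out <- vector("list", K1)
  for (r in 0:kmax) {
    Dr <- matrix(dtab[, r + 1, ], K1, nodes)
    # W[(s,k), m] = d^s_rr(x_m) P_k(x_m) w_m / 2
    W <- matrix(0, K1 * K1, nodes)
    for (k in 0:kmax) {
      W[(k * K1 + 1):((k + 1) * K1), ] <-
        Dr * rep(P[k + 1, ] * gl$w / 2, each = K1)
    }
    Gflat <- Dr %*% t(W)             # [p, (s,k)]
    Garr <- array(Gflat, c(K1, K1, K1))  # [p, s, k]
    out[[r + 1]] <- matrix(aperm(Garr, c(1, 3, 2)), K1 * K1, K1)  # [(p,k), s]
  }
  .twlc_cache[[key]] <- out
  out
}

# Laplace-transform tables at the quadrature nodes:
#   lam_tab[j+1, r+1] = e^{-a} L^j_r(-a)   (bend, scaled)
#   lf_tab [j+1, r+1] = L^j_r(-b f)        (force)
#   l0_tab [j+1, r+1] = L^j_r(0)
lap_tables <- function(kmax, nodes, a, bf) {
  gl <- gauss_legendre(nodes)
  dtab <- wigner_d_table(kmax, gl$x)
  K1 <- kmax + 1
  D2 <- matrix(dtab, K1 * K1, nodes)
  shape <- function(v) matrix(v, K1, K1)
  list(lam = shape(D2 %*% (gl$w * exp(a * (gl$x - 1)))),
       lf = shape(D2 %*% (gl$w * exp(bf * gl$x))),
       l0 = shape(D2 %*% gl$w))
}

# torque-independent contraction stack: T_r[k, k'] =
#   sum_p (2p+1) e^{-a} L^p_r(-a) A_r[p,k] B_r[p,k'] with
#   A_r[p,k] = sum_s (2s+1) L^s_r(-bf) (3j)^2,
#   B_r[p,k'] = sum_s' (2s'+1) L^s'_r(0) (3j)^2.
s_matrix_stack <- function(a, b_len, c, f, kmax, nodes) {
  K1 <- kmax + 1
  G <- g3j_tables(kmax, nodes)
  lt <- lap_tables(kmax, nodes, a, b_len * f)
  two <- 2 * (0:kmax) + 1
  stack <- array(0, c(K1, K1, K1))
  for (r in 0:kmax) {
    A <- matrix(G[[r + 1]] %*% (two * lt$lf[, r + 1]), K1, K1)   # [p, k]
    B <- matrix(G[[r + 1]] %*% (two * lt$l0[, r + 1]), K1, K1)   # [p, k']
    pa <- two * lt$lam[, r + 1]
    stack[, , r + 1] <- crossprod(A * pa, B)
  }
  stack
}

# torque weights applied to the stack; kappa_shift additively perturbs the
# argument of the I_r(tau (1 - lam/2pi)) linking coupling while chi, omega
# and the twist Bessel stay frozen (the constant-chi linking derivative:
# dLk_F = (1/2pi) dlnZ/d(kappa_shift)).
s_matrix_weights <- function(c, lam, tau, kappa_shift, kmax) {
  chi <- tau * lam / (2 * pi * c)
  omega <- atan(chi)
  C <- c * sqrt(1 + chi^2)
  kappa <- tau * (1 - lam / (2 * pi)) + kappa_shift
  r <- 0:kmax
  iC <- vapply(r, function(ri) besselI(C, ri, expon.scaled = TRUE),
               numeric(1)) * exp(C - c)          # e^{-c} I_r(C)
  iK <- vapply(r, function(ri) bessel_i(ri, kappa), numeric(1))
  mult <- ifelse(r == 0, 1, 2)
  mult * cos(r * (omega - pi / 2)) * iK * iC
}

#' Single-state transfer matrix
#'
#' Assembles the `(kmax+1) x (kmax+1)` transfer matrix for one structural
#' state from the dimensionless bending/twisting stiffness `a`, `c`, segment
#' length `b_len` (nm), Fuller-correction weight `lam`, force `f` (kBT/nm)
#' and torque `tau` (kBT).  Entries are real: the `+r` and `-r` harmonics of
#' the assembly pair into cosines.
#'
#' @param a,c Dimensionless bending and twisting stiffness (`Lp/b`, `Ltw/b`).
#' @param b_len Segment length, nm.
#' @param lam Fuller-correction weight.
#' @param f Force in kBT/nm.
#' @param tau Torque in kBT.
#' @param trunc A [tm_truncation()] with explicit `kmax`.
#' @param kappa_shift Additive perturbation of the linking-coupling Bessel
#'   argument (0 except inside the constant-chi linking derivative).
#' @return Real matrix with rows/columns indexed by `k = 0..kmax`.
#' @export
s_matrix <- function(a, b_len, c, lam, f, tau, trunc = tm_truncation(kmax = 30),
                     kappa_shift = 0) {
  kmax <- trunc$kmax
  if (is.null(kmax)) stop("s_matrix needs an explicit kmax")
  stack <- s_matrix_stack(a, b_len, c, f, kmax, trunc$nodes)
  s_matrix_apply(stack, c, lam, tau, kappa_shift, kmax)
}

s_matrix_apply <- function(stack, c, lam, tau, kappa_shift, kmax) {
  fac <- s_matrix_weights(c, lam, tau, kappa_shift, kmax)
  K1 <- kmax + 1
  Tm <- matrix(stack, K1 * K1, K1) %*% fac
  two <- sqrt(2 * (0:kmax) + 1)
  pi^2 * outer(two, two) * matrix(Tm, K1, K1)
}

#' Boundary vector of the transfer-matrix partition function
#'
#' `V_k = 8 pi^2 i_k(b f) sqrt(2k+1)`: the free-end boundary factor
#' `exp(b f cos beta_N)` expanded over Legendre harmonics.  At `f = 0` only
#' `k = 0` survives.
#'
#' @param b_len Segment length, nm.
#' @param f Force, kBT/nm.
#' @param trunc A [tm_truncation()] with explicit `kmax`.
#' @return Numeric vector of length `kmax + 1`.
#' @export
v_vector <- function(b_len, f, trunc = tm_truncation(kmax = 30)) {
  k <- 0:trunc$kmax
  8 * pi^2 * sph_bessel_i_vec(k, b_len * f) * sqrt(2 * k + 1)
}

sph_bessel_i_vec <- function(k, x) {
  vapply(k, function(ki) sph_bessel_i(ki, x), numeric(1))
}

# w = M^n v with per-multiplication rescaling; returns log((M^n v)[1]).
mat_pow_apply <- function(M, n, v) {
  stopifnot(n >= 0)
  logsc <- 0
  res <- v
  base <- M
  base_log <- 0
  while (n > 0) {
    if (n %% 2 == 1) {
      res <- base %*% res
      m <- max(abs(res))
      res <- res / m
      logsc <- logsc + log(m) + base_log
    }
    n <- n %/% 2
    if (n > 0) {
      base <- base %*% base
      m <- max(abs(base))
      base <- base / m
      base_log <- 2 * base_log + log(m)
    }
  }
  list(value = res, log_scale = logsc)
}

# shared worker: log Tr(M^{N-1} W) for a set of states (one = single-state,
# four = multistate block, collapsed through the repeated-row structure of
# the block matrix: the block transfer matrix is C J with C the stacked
# per-state columns and J = (I I I I), so Tr((J C)^{N-1} J Vhat) uses only
# M = sum_u S_u and w = sum_u pref_u V_u.
logz_states <- function(states, chain, constraint, trunc, params,
                        mu = NULL, kappa_shift = 0, stacks = NULL) {
  kmax <- trunc$kmax
  tau <- constraint$tau
  if (is.null(mu)) mu <- params[states, "mu"]
  names(mu) <- states
  K1 <- kmax + 1
  M <- matrix(0, K1, K1)
  w <- numeric(K1)
  for (u in states) {
    st <- dimensionless_stiffness(u, chain, params)
    b_u <- chain$b[[u]]
    lam_u <- params[u, "lam"]
    if (is.null(stacks)) {
      stack <- s_matrix_stack(st$a, b_u, st$c, constraint$f, kmax, trunc$nodes)
    } else {
      stack <- stacks[[u]]
    }
    S_u <- s_matrix_apply(stack, st$c, lam_u, tau, kappa_shift, kmax)
    dlk0 <- relaxed_linking_density(u, params)
    pref <- exp(chain$q * (-mu[[u]] + 2 * pi * (tau + kappa_shift) * dlk0))
    M <- M + pref * S_u
    w <- w + pref * v_vector(b_u, constraint$f, trunc)
  }
  pw <- mat_pow_apply(M, chain$n_segments - 1, w)
  z0 <- pw$value[1]
  if (z0 <= 0) warning("non-positive leading partition component")
  list(log_z = log(abs(z0)) + pw$log_scale, M = M)
}

#' Log partition function of a single-state chain
#'
#' `log Z = log Tr(S^{N-1} V)`, evaluated by binary matrix powering with
#' per-multiplication rescaling.  With adaptive truncation (`kmax = NULL`)
#' the cutoff is raised until `log Z` is stable to `trunc$tol` (relative).
#'
#' @param chain A [chain_spec()].
#' @param constraint A [mech_constraint()].
#' @param trunc A [tm_truncation()].
#' @param params Parameter table.
#' @param state Structural state id.
#' @return A `partition_result`: list with `log_z`, `kmax`, `imag_residual`
#'   (identically 0 for the real paired assembly), `spectral_gap`
#'   (`1 - |lambda_2| / |lambda_1|` of S) and `converged`.
#' @export
log_partition <- function(chain, constraint = mech_constraint(),
                          trunc = tm_truncation(), params = dna_state_params(),
                          state = "B") {
  adaptive_logz(state, chain, constraint, trunc, params)
}

#' Log partition function of the four-state block transfer matrix
#'
#' Multistate version: each state's transfer matrix is the single-state S
#' scaled by `exp(-q (mu_u - 2 pi tau dlk0_u))`, the block matrix repeats the
#' state rows, and the trace collapses to powers of the state-summed matrix.
#' Reduces to [log_partition()] when the other states' `mu` penalties are
#' sent to infinity.
#'
#' @inheritParams log_partition
#' @param states States included in the block (default all four).
#' @param mu Optional named override of the base-pairing energies (kBT/bp).
#' @return A `partition_result` (as [log_partition()]).
#' @export
block_partition <- function(chain, constraint = mech_constraint(),
                            trunc = tm_truncation(),
                            params = dna_state_params(),
                            states = rownames(params), mu = NULL) {
  adaptive_logz(states, chain, constraint, trunc, params, mu = mu)
}

adaptive_logz <- function(states, chain, constraint, trunc, params,
                          mu = NULL) {
  schedule <- if (is.null(trunc$kmax)) c(20, 30, 45) else trunc$kmax
  prev <- NULL
  res <- NULL
  used <- NA
  converged <- TRUE
  for (kmax in schedule) {
    tr <- tm_truncation(kmax = kmax, nodes = max(trunc$nodes, 3 * kmax + 40),
                        tol = trunc$tol)
    res <- logz_states(states, chain, constraint, tr, params, mu = mu)
    used <- kmax
    if (!is.null(prev) &&
        abs(res$log_z - prev) <= trunc$tol * max(abs(res$log_z), 1)) {
      break
    }
    if (kmax == schedule[length(schedule)] && length(schedule) > 1 &&
        !is.null(prev) &&
        abs(res$log_z - prev) > trunc$tol * max(abs(res$log_z), 1)) {
      converged <- FALSE
    }
    prev <- res$log_z
  }
  ev <- sort(Mod(eigen(res$M, only.values = TRUE)$values), decreasing = TRUE)
  structure(list(log_z = res$log_z, kmax = used, imag_residual = 0,
                 spectral_gap = 1 - ev[2] / ev[1], converged = converged),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("log Z = %.6f (kmax = %d, spectral gap %.3g, %s)\n", x$log_z,
              x$kmax, x$spectral_gap,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# Richardson-extrapolated central difference
richardson_diff <- function(g, x, h) {
  d1 <- (g(x + h) - g(x - h)) / (2 * h)
  d2 <- (g(x + h / 2) - g(x - h / 2)) / h
  (4 * d2 - d1) / 3
}

#' Transfer-matrix observables
#'
#' Extension `z = d ln Z / d f` (nm), linking-number change
#' `dLk = (1/2pi) d ln Z / d tau` evaluated at constant chi (the chi- and
#' omega-dependent twist factors are frozen during the torque step; only the
#' explicit torque in the linking coupling and in the per-state prefactors
#' varies), and superhelical density `sigma = dLk / Lk0_B`.  Derivatives are
#' Richardson-extrapolated central differences with relative step `1e-3`.
#'
#' @inheritParams block_partition
#' @param what Which observables to return.
#' @return Named list with `z` (nm), `z_over_LB`, `dlk` (turns), `sigma`.
#' @export
tm_observables <- function(chain, constraint = mech_constraint(),
                           trunc = tm_truncation(),
                           params = dna_state_params(), states = "B",
                           mu = NULL,
                           what = c("z", "dlk")) {
  kmax <- trunc$kmax
  if (is.null(kmax)) {
    kmax <- adaptive_logz(states, chain, constraint, trunc, params,
                          mu = mu)$kmax
  }
  tr <- tm_truncation(kmax = kmax, nodes = max(trunc$nodes, 3 * kmax + 40),
                      tol = trunc$tol)
  out <- list()
  LB <- chain$n_bp * attr(params, "rise_B")
  if ("z" %in% what) {
    gz <- function(f) {
      cons <- constraint
      cons$f <- f
      logz_states(states, chain, cons, tr, params, mu = mu)$log_z
    }
    h <- max(abs(constraint$f), 0.05) * 1e-3
    out$z <- richardson_diff(gz, constraint$f, h)
    out$z_over_LB <- out$z / LB
  }
  if ("dlk" %in% what) {
    stacks <- build_stacks(states, chain, constraint$f, tr, params)
    gt <- function(eps) {
      logz_states(states, chain, constraint, tr, params, mu = mu,
                  kappa_shift = eps, stacks = stacks)$log_z
    }
    h <- max(abs(constraint$tau) * 0.3, 0.02) * 1e-2
    out$dlk <- richardson_diff(gt, 0, h) / (2 * pi)
    out$sigma <- out$dlk / chain$Lk0_B
  }
  out
}

build_stacks <- function(states, chain, f, trunc, params) {
  out <- lapply(states, function(u) {
    st <- dimensionless_stiffness(u, chain, params)
    s_matrix_stack(st$a, chain$b[[u]], st$c, f, trunc$kmax, trunc$nodes)
  })
  names(out) <- states
  out
}
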