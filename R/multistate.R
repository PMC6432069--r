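# Four-state DNA: occupancies, response curves and the force-torque phase
# diagram, all built on the block transfer matrix.

# Engine caching the torque-independent contraction stacks at one force so
# that torque sweeps, occupancy derivatives and constant-chi torque
# derivatives reuse them.  Extension derivatives keep four more stacks at the
# Richardson force offsets.
tm_engine <- function(chain, f, trunc, params, states = rownames(params),
                      with_extension = TRUE) {
  kmax <- trunc$kmax
  if (is.null(kmax)) {
    cons <- mech_constraint(f = f, tau = 0)
    kmax <- adaptive_logz(states, chain, cons, trunc, params)$kmax
  }
  tr <- tm_truncation(kmax = kmax, nodes = max(trunc$nodes, 3 * kmax + 40),
                      tol = trunc$tol)
  eng <- list(chain = chain, f = f, trunc = tr, params = params,
              states = states)
  eng$stacks <- build_stacks(states, chain, f, tr, params)
  if (with_extension) {
    h <- max(abs(f), 0.05) * 1e-3
    eng$h_f <- h
    eng$stacks_f <- lapply(c(f + h, f - h, f + h / 2, f - h / 2),
                           function(fv) build_stacks(states, chain, fv, tr,
                                                     params))
  }
  eng
}

engine_logz <- function(eng, tau, mu = NULL, kappa_shift = 0,
                        stacks = eng$stacks, f = eng$f) {
  cons <- mech_constraint(f = f, tau = tau)
  logz_states(eng$states, eng$chain, cons, eng$trunc, eng$params, mu = mu,
              kappa_shift = kappa_shift, stacks = stacks)$log_z
}

engine_extension <- function(eng, tau, mu = NULL) {
  h <- eng$h_f
  f <- eng$f
  lz <- vapply(1:4, function(i) {
    fv <- c(f + h, f - h, f + h / 2, f - h / 2)[i]
    engine_logz(eng, tau, mu = mu, stacks = eng$stacks_f[[i]], f = fv)
  }, numeric(1))
  d1 <- (lz[1] - lz[2]) / (2 * h)
  d2 <- (lz[3] - lz[4]) / h
  (4 * d2 - d1) / 3
}

engine_dlk <- function(eng, tau, mu = NULL) {
  h <- max(abs(tau) * 0.3, 0.02) * 1e-2
  g <- function(eps) engine_logz(eng, tau, mu = mu, kappa_shift = eps)
  richardson_diff(g, 0, h) / (2 * pi)
}

engine_occupancy <- function(eng, tau, dmu = 1e-3) {
  params <- eng$params
  states <- eng$states
  mu0 <- params[states, "mu"]
  names(mu0) <- states
  N <- eng$chain$n_segments
  q <- eng$chain$q
  occ <- vapply(states, function(u) {
    up <- dn <- mu0
    up[u] <- up[u] + dmu
    dn[u] <- dn[u] - dmu
    d <- (engine_logz(eng, tau, mu = up) - engine_logz(eng, tau, mu = dn)) /
      (2 * dmu)
    min(max(-d / (q * N), 0), 1)  # N_u / N with N_u = -(1/q) dlnZ/dmu
  }, numeric(1))
  occ
}

#' Per-state occupancy fractions
#'
#' Expected fraction of chain segments in each structural state,
#' `N_u / N` with `N_u = -(1/q) d ln Z / d mu_u` (central difference, step
#' `dmu` kBT).  Fractions are clipped to `[0, 1]`; their sum is checked to
#' be 1 within `1e-4`.
#'
#' @inheritParams block_partition
#' @param dmu Finite-difference step in the base-pairing energy, kBT.
#' @return Named vector of occupancy fractions over `states`.
#' @export
occupancy <- function(chain, constraint = mech_constraint(),
                      trunc = tm_truncation(), params = dna_state_params(),
                      states = rownames(params), dmu = 1e-3) {
  eng <- tm_engine(chain, constraint$f, trunc, params, states,
                   with_extension = FALSE)
  occ <- engine_occupancy(eng, constraint$tau, dmu)
  if (abs(sum(occ) - 1) > 1e-4) {
    warning(sprintf("occupancies sum to %.6f (finite-difference noise)",
                    sum(occ)))
  }
  occ
}

#' Force/torque response curves of multistate DNA
#'
#' Sweeps force at constant torque (`force_extension`, `force_sigma`) or
#' torque at constant force (`torque_extension`, `torque_sigma`), computing
#' at every grid point the relative extension (normalized to the B-form
#' contour length), linking-number change, superhelical density and
#' occupancies.  Points where any occupancy crosses 0.5 between neighbours
#' are flagged as structural transitions.
#'
#' @param mode Sweep type (the `_extension` / `_sigma` pairs differ only in
#'   which column is of interest; all columns are always returned).
#' @param fixed Fixed value: torque in pN nm for force sweeps, force in pN
#'   for torque sweeps.
#' @param sweep Grid of the swept variable (pN or pN nm).
#' @inheritParams block_partition
#' @param temperature_K Temperature for unit conversion.
#' @return Data frame with columns `f_pN`, `tau_pNnm`, `z_nm`, `z_over_LB`,
#'   `dlk`, `sigma`, one `occ_*` column per state, `dominant`, `transition`.
#' @export
response_curves <- function(mode = c("force_extension", "force_sigma",
                                     "torque_extension", "torque_sigma"),
                            fixed, sweep, chain,
                            trunc = tm_truncation(kmax = 40),
                            params = dna_state_params(),
                            states = rownames(params),
                            temperature_K = 298.15) {
  mode <- match.arg(mode)
  kbt <- kbt_pN_nm(temperature_K)
  force_sweep <- mode %in% c("force_extension", "force_sigma")
  if (force_sweep) {
    grid <- data.frame(f_pN = sweep, tau_pNnm = fixed)
  } else {
    grid <- data.frame(f_pN = fixed, tau_pNnm = sweep)
  }
  LB <- chain$n_bp * attr(params, "rise_B")
  rows <- vector("list", nrow(grid))
  eng <- NULL
  for (i in seq_len(nrow(grid))) {
    f <- grid$f_pN[i] / kbt
    tau <- grid$tau_pNnm[i] / kbt
    if (is.null(eng) || eng$f != f) {
      eng <- tm_engine(chain, f, trunc, params, states)
    }
    occ <- engine_occupancy(eng, tau)
    z <- engine_extension(eng, tau)
    dlk <- engine_dlk(eng, tau)
    rows[[i]] <- data.frame(
      f_pN = grid$f_pN[i], tau_pNnm = grid$tau_pNnm[i],
      z_nm = z, z_over_LB = z / LB, dlk = dlk, sigma = dlk / chain$Lk0_B,
      t(occ), dominant = states[which.max(occ)])
  }
  out <- do.call(rbind, rows)
  names(out) <- sub("^(B|L|P|S)$", "occ_\\1", names(out))
  occ_cols <- grep("^occ_", names(out))
  crossed <- rep(FALSE, nrow(out))
  if (nrow(out) > 1) {
    for (j in occ_cols) {
      crossed[-1] <- crossed[-1] |
        (sign(out[[j]][-1] - 0.5) != sign(out[[j]][-nrow(out)] - 0.5))
    }
  }
  out$transition <- crossed
  rownames(out) <- NULL
  out
}

#' Force-torque phase diagram of DNA structural states
#'
#' Locates two families of boundaries on a force grid:
#' \describe{
#'   \item{state boundaries}{for each alternative form (L, P, S), the torque
#'     at which its occupancy crosses 50\% (bisection along torque to
#'     `tol_tau`).}
#'   \item{supercoiling boundaries}{the torque at which the computed
#'     extension falls to 50\% of the worm-like-chain extension of the
#'     locally dominant state (Marko-Siggia with that state's `Lp` and
#'     contour length).}
#' }
#'
#' @param f_grid_pN Force grid, pN.
#' @param tau_range_pNnm Torque search interval `c(lo, hi)`, pN nm.
#' @param n_tau Coarse torque scan points used to bracket crossings.
#' @inheritParams response_curves
#' @param tol_tau Bisection tolerance for boundary torques, pN nm.
#' @return List of data frames `state_boundaries` (columns `state`, `f_pN`,
#'   `tau_pNnm`) and `supercoiling_boundaries` (columns `state`, `f_pN`,
#'   `tau_pNnm`), each ordered by force within boundary label.
#' @export
phase_diagram <- function(f_grid_pN, tau_range_pNnm = c(-60, 60), n_tau = 41,
                          chain, trunc = tm_truncation(kmax = 40),
                          params = dna_state_params(),
                          states = rownames(params),
                          tol_tau = 0.1, temperature_K = 298.15) {
  kbt <- kbt_pN_nm(temperature_K)
  LB <- chain$n_bp * attr(params, "rise_B")
  taus <- seq(tau_range_pNnm[1], tau_range_pNnm[2], length.out = n_tau)
  sb <- list(); scb <- list()
  for (f_pN in f_grid_pN) {
    eng <- tm_engine(chain, f_pN / kbt, trunc, params, states)
    occs <- t(vapply(taus, function(tp) engine_occupancy(eng, tp / kbt),
                     numeric(length(states))))
    colnames(occs) <- states
    for (u in setdiff(states, "B")) {
      g <- occs[, u] - 0.5
      for (i in which(sign(g[-1]) != sign(g[-length(g)]))) {
        root <- bisect(function(tp) {
          engine_occupancy(eng, tp / kbt)[[u]] - 0.5
        }, taus[i], taus[i + 1], tol = tol_tau)
        sb[[length(sb) + 1]] <- data.frame(state = u, f_pN = f_pN,
                                           tau_pNnm = root)
      }
    }
    # supercoiling: extension vs the dominant state's WLC reference
    ratio <- function(tp) {
      occ <- engine_occupancy(eng, tp / kbt)
      dom <- states[which.max(occ)]
      Lp <- params[dom, "Lp"]
      Ldom <- LB * params[dom, "contour_ratio"]
      zwlc <- marko_siggia_extension(f_pN / kbt, Lp) * Ldom
      z <- engine_extension(eng, tp / kbt)
      list(r = z / zwlc, dom = dom)
    }
    rg <- vapply(taus, function(tp) ratio(tp)$r, numeric(1)) - 0.5
    for (i in which(sign(rg[-1]) != sign(rg[-length(rg)]))) {
      root <- bisect(function(tp) ratio(tp)$r - 0.5, taus[i], taus[i + 1],
                     tol = tol_tau)
      scb[[length(scb) + 1]] <- data.frame(state = ratio(root)$dom,
                                           f_pN = f_pN, tau_pNnm = root)
    }
  }
  bind0 <- function(l) {
    if (!length(l)) {
      return(data.frame(state = character(), f_pN = numeric(),
                        tau_pNnm = numeric()))
    }
    d <- do.call(rbind, l)
    d[order(d$state, d$f_pN, d$tau_pNnm), , drop = FALSE]
  }
  list(state_boundaries = bind0(sb), supercoiling_boundaries = bind0(scb))
}

bisect <- function(g, lo, hi, tol = 0.1, max_iter = 60) {
  glo <- g(lo)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (hi - lo < tol) return(mid)
    gm <- g(mid)
    if (sign(gm) == sign(glo)) {
      lo <- mid
      glo <- gm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}
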