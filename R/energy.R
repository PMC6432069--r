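# Elastic and total conformational energies (kBT units throughout).

#' Marko-Siggia worm-like-chain force law
#'
#' Interpolation formula for the force needed to hold a worm-like chain at
#' relative extension `z/L`:
#' `f = (1/Lp) * (z/L + 1/(4 (1 - z/L)^2) - 1/4)` with `f` in kBT/nm.
#' It reduces to the freely-jointed limit `Lp f = (3/2) z/L` at small
#' extension and to `Lp f = 1 / (4 (1 - z/L)^2)` near full extension.
#'
#' @param rel_ext Relative extension `z/L` in `[0, 1)`.
#' @param Lp Bending persistence length, nm.
#' @return Force in kBT/nm.
#' @export
marko_siggia_force <- function(rel_ext, Lp = 50) {
  stopifnot(Lp > 0)
  if (any(rel_ext < 0 | rel_ext >= 1)) {
    stop("relative extension must lie in [0, 1): force diverges at z/L = 1")
  }
  (rel_ext + 1 / (4 * (1 - rel_ext)^2) - 1 / 4) / Lp
}

#' Inverse Marko-Siggia relation: extension at a given force
#'
#' Unique root of the force law in `[0, 1)`, found by monotone bisection and
#' polished by Newton steps.
#'
#' @param f Force in kBT/nm (>= 0); vectorized.
#' @param Lp Bending persistence length, nm.
#' @return Relative extension `z/L`.
#' @export
marko_siggia_extension <- function(f, Lp = 50) {
  vapply(f, function(fi) {
    stopifnot(fi >= 0)
    if (fi == 0) return(0)
    lo <- 0; hi <- 1 - 1e-12
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (marko_siggia_force(mid, Lp) < fi) lo <- mid else hi <- mid
      if (hi - lo < 1e-14) break
    }
    (lo + hi) / 2
  }, numeric(1))
}

junction_stiffness <- function(conf) {
  # junction n uses the state of segment n (lower index)
  st <- conf$states[-conf$n_segments]
  b <- conf$b[-conf$n_segments]
  list(a = conf$params[st, "Lp"] / b, c = conf$params[st, "Ltw"] / b)
}

#' Elastic bending and twisting energy of a conformation
#'
#' Discrete twistable worm-like-chain energy:
#' `E_bend = sum_n (a_n / 2) |t_{n+1} - t_n|^2` and
#' `E_twist = sum_n (c_n / 2) (2 pi dTw_n)^2` with the cross-product twist
#' increment.  Junctions between unlike states use the lower-index segment's
#' stiffness.
#'
#' @param conf A `dna_chain`.
#' @return List with `e_bend`, `e_twist` (kBT).
#' @export
bend_twist_energy <- function(conf) {
  tg <- chain_tangents(conf)
  N <- conf$n_segments
  stopifnot(N >= 2)
  js <- junction_stiffness(conf)
  dts <- rowSums((tg[-1, , drop = FALSE] - tg[-N, , drop = FALSE])^2)
  e_bend <- sum(js$a / 2 * dts)
  s <- 2 * pi * twist_increments(conf)
  e_twist <- sum(js$c / 2 * s^2)
  list(e_bend = e_bend, e_twist = e_twist)
}

#' Total constrained energy of a conformation
#'
#' `E_tot = E_bend + E_twist + E_state - f d_z - 2 pi tau dLk` where
#' `E_state = sum_n q mu(u_n)` is the base-pairing penalty of non-B segments,
#' `d_z` the signed end-to-end extension along the force axis, and
#' `dLk = Tw + Wr_Gauss + sum_n q dlk0(u_n)` the linking-number change
#' relative to relaxed B-DNA.  All terms in kBT.
#'
#' @param conf A `dna_chain`.
#' @param constraint A [mech_constraint()].
#' @return List with components `e_bend`, `e_twist`, `e_state`, `e_force`,
#'   `e_torque`, `e_total` (kBT) and the `dlk` used (turns).
#' @export
total_energy <- function(conf, constraint = mech_constraint()) {
  el <- bend_twist_energy(conf)
  params <- conf$params
  mu <- params[conf$states, "mu"]
  e_state <- sum(conf$q * mu)
  dz <- conf$vertices[nrow(conf$vertices), 3] - conf$vertices[1, 3]
  e_force <- -constraint$f * dz
  dlk0 <- vapply(unique(conf$states), relaxed_linking_density, numeric(1),
                 params = params)
  dlk <- twist_number(conf) + writhe_gauss(conf) +
    sum(conf$q * dlk0[conf$states])
  e_torque <- -2 * pi * constraint$tau * dlk
  e_total <- el$e_bend + el$e_twist + e_state + e_force + e_torque
  c(el, list(e_state = e_state, e_force = e_force, e_torque = e_torque,
             e_total = e_total, dlk = dlk, d_z = dz))
}
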