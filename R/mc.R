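# Metropolis Monte Carlo sampling of equilibrium chain conformations under
# force and torque (single structural state).  The sampler doubles as an
# independent oracle for the transfer-matrix observables.

#' Monte Carlo run configuration
#'
#' @param n_sweeps Total sweeps (one sweep = N elementary moves).
#' @param burn_in Sweeps discarded before recording.
#' @param thin Record every `thin`-th sweep.
#' @param seed Integer RNG seed; runs are bit-reproducible given the seed.
#' @param move_mix Probabilities for (crankshaft, tail pivot, local twist).
#' @param max_rotation Maximum move rotation angle, rad.
#' @param window Maximum crankshaft span / tail length, segments (bounds the
#'   cost of the incremental writhe update).
#' @param hard_core_diameter Optional excluded-volume diameter in nm
#'   (0 disables; moves bringing non-adjacent segments closer are rejected).
#' @param record_writhe For torque-free runs, whether to evaluate the full
#'   Gauss writhe at every recorded snapshot (O(N^2) each; with torque on,
#'   the writhe is always tracked incrementally).
#' @return An `mc_config` list.
#' @export
mc_config <- function(n_sweeps = 2000, burn_in = 200, thin = 2, seed = 1,
                      move_mix = c(crankshaft = 0.45, tail_pivot = 0.25,
                                   twist = 0.30),
                      max_rotation = 0.35, window = 20,
                      hard_core_diameter = 0, record_writhe = TRUE) {
  stopifnot(n_sweeps > burn_in, burn_in >= 0, thin >= 1,
            length(move_mix) == 3, all(move_mix >= 0))
  if (abs(sum(move_mix) - 1) > 1e-9) stop("move_mix must sum to 1")
  structure(list(n_sweeps = n_sweeps, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed), move_mix = move_mix,
                 max_rotation = max_rotation, window = as.integer(window),
                 hard_core_diameter = hard_core_diameter,
                 record_writhe = record_writhe),
            class = "mc_config")
}

#' Metropolis Monte Carlo sampling of a stretched, twisted DNA
#'
#' Samples conformations of a homogeneous (B-state) discretized chain from
#' the Boltzmann distribution of the total energy, including the Gauss-writhe
#' torque coupling.  Moves are crankshaft rotations, tail pivots and local
#' twist updates; the writhe is updated incrementally through the
#' moved-vs-unmoved solid-angle cross terms.  Observable means carry batch
#' standard errors (>= 20 batches).
#'
#' @param chain A [chain_spec()].
#' @param constraint A [mech_constraint()].
#' @param mc An [mc_config()].
#' @param params Parameter table.
#' @param state Structural state of all segments.
#' @param start Optional starting `dna_chain` (default: a directly sampled
#'   torque-free Boltzmann random walk, which removes most of the burn-in).
#' @return An `ensemble_stats` list: `mean_ext`, `mean_tw`, `mean_wr`,
#'   `mean_wr_fuller`, `mean_dlk` with `*_se` errors, acceptance rates per
#'   move type, autocorrelation time estimate (in recorded samples), and the
#'   raw `samples` matrix.
#' @export
metropolis_sample <- function(chain, constraint = mech_constraint(),
                              mc = mc_config(), params = dna_state_params(),
                              state = "B", start = NULL) {
  set.seed(mc$seed)
  if (is.null(start)) {
    start <- build_fixture("random_walk", chain, params, state = state)
  }
  st <- dimensionless_stiffness(state, chain, params)
  fr <- chain_frames(start)
  frames0 <- t(vapply(fr, function(R) as.numeric(t(R)), numeric(9)))
  # pivots may regrow any tail length (global extension relaxation); the
  # crankshaft window is only restricted when the writhe must be tracked
  window <- if (constraint$tau == 0) chain$n_segments else mc$window
  res <- cpp_mc_run(frames0, chain$b[[state]], st$a, st$c,
                    constraint$f, constraint$tau,
                    mc$n_sweeps, mc$burn_in, mc$thin,
                    as.numeric(mc$move_mix), mc$max_rotation, window,
                    chain$n_segments, mc$hard_core_diameter,
                    mc$record_writhe)
  if (sum(res$accepts) == 0) {
    stop("no Monte Carlo move was accepted; reduce max_rotation")
  }
  s <- res$samples
  colnames(s) <- c("z", "tw", "wr", "wr_fuller")
  dlk <- s[, "tw"] + s[, "wr"]
  stats <- function(x) {
    if (all(is.na(x))) return(c(mean = NA_real_, se = NA_real_))
    bm <- batch_means(x)
    c(mean = mean(x), se = bm$se)
  }
  zs <- stats(s[, "z"]); tws <- stats(s[, "tw"]); wrs <- stats(s[, "wr"])
  wfs <- stats(s[, "wr_fuller"]); dls <- stats(dlk)
  acc <- as.numeric(res$accepts) / pmax(as.numeric(res$attempts), 1)
  names(acc) <- c("crankshaft", "tail_pivot", "twist")
  structure(list(
    mean_ext = zs[["mean"]], mean_ext_se = zs[["se"]],
    mean_tw = tws[["mean"]], mean_tw_se = tws[["se"]],
    mean_wr = wrs[["mean"]], mean_wr_se = wrs[["se"]],
    mean_wr_fuller = wfs[["mean"]], mean_wr_fuller_se = wfs[["se"]],
    mean_dlk = dls[["mean"]], mean_dlk_se = dls[["se"]],
    acceptance = acc,
    autocorr_time = autocorr_time(s[, "z"]),
    n_samples = nrow(s), samples = s,
    chain = chain, constraint = constraint, config = mc),
    class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf("MC ensemble (%d samples): <z> = %.2f +/- %.2f nm, <dLk> = %.3f +/- %.3f turns\n",
              x$n_samples, x$mean_ext, x$mean_ext_se, x$mean_dlk, x$mean_dlk_se))
  cat("acceptance:", paste(sprintf("%s %.2f", names(x$acceptance),
                                   x$acceptance), collapse = ", "), "\n")
  invisible(x)
}

# batch-means standard error with at least 20 batches
batch_means <- function(x, n_batches = 20) {
  n <- length(x)
  n_batches <- max(20, min(n_batches, n %/% 2))
  bsize <- n %/% n_batches
  if (bsize < 1) return(list(se = stats::sd(x) / sqrt(max(n, 1))))
  bm <- vapply(seq_len(n_batches), function(i) {
    mean(x[((i - 1) * bsize + 1):(i * bsize)])
  }, numeric(1))
  list(se = stats::sd(bm) / sqrt(n_batches))
}

# integrated autocorrelation time (in recorded samples) by initial
# positive-sequence truncation
autocorr_time <- function(x, max_lag = min(length(x) %/% 4, 200)) {
  x <- x - mean(x)
  v <- mean(x^2)
  if (v == 0) return(1)
  tau <- 1
  for (lag in seq_len(max_lag)) {
    rho <- mean(x[seq_len(length(x) - lag)] * x[-seq_len(lag)]) / v
    if (rho < 0.05) break
    tau <- tau + 2 * rho
  }
  tau
}

# --- explicit single moves on dna_chain objects (used by tests and for
#     incremental-writhe verification; the sampler applies the same updates
#     in compiled code) ---

apply_rigid_rotation <- function(conf, i0, i1, axis, angle, pivot_vertex) {
  fr <- chain_frames(conf)
  Rrot <- rotation_axis_angle(axis, angle)
  euler <- conf$euler
  for (n in i0:i1) {
    euler[n, ] <- matrix_to_euler(Rrot %*% fr[[n]])
  }
  out <- new_dna_chain(euler, conf$states, conf$q, conf$params)
  # re-anchor so that the first unmoved vertex coincides with the original
  out
}

rotation_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  ct <- cos(angle); st <- sin(angle); om <- 1 - ct
  matrix(c(ct + x * x * om, y * x * om + z * st, z * x * om - y * st,
           x * y * om - z * st, ct + y * y * om, z * y * om + x * st,
           x * z * om + y * st, y * z * om - x * st, ct + z * z * om), 3, 3)
}

#' Elementary Monte Carlo moves
#'
#' `move_crankshaft` rotates segments `i..j-1` about the chord through
#' vertices `i` and `j`; `move_tail_pivot` rotates segments `i..N` about an
#' axis through vertex `i`; `move_twist` rotates one segment's frame about
#' its own tangent (gamma increment).  All moves preserve segment lengths and
#' frame orthonormality; they return a new conformation.
#'
#' @param conf A `dna_chain`.
#' @param i,j Vertex indices (1-based; segment n runs from vertex n to n+1).
#' @param angle Rotation angle, rad.
#' @param axis Rotation axis for the pivot (length-3, normalized internally).
#' @param dphi Twist increment, rad.
#' @return A new `dna_chain`.
#' @export
move_crankshaft <- function(conf, i, j, angle) {
  stopifnot(1 <= i, i < j, j <= conf$n_segments + 1)
  axis <- conf$vertices[j, ] - conf$vertices[i, ]
  if (sqrt(sum(axis^2)) < 1e-12) stop("degenerate crankshaft chord")
  apply_rigid_rotation(conf, i, j - 1, axis, angle, i)
}

#' @rdname move_crankshaft
#' @export
move_tail_pivot <- function(conf, i, axis, angle) {
  stopifnot(1 <= i, i <= conf$n_segments)
  apply_rigid_rotation(conf, i, conf$n_segments, axis, angle, i)
}

#' @rdname move_crankshaft
#' @export
move_twist <- function(conf, i, dphi) {
  stopifnot(1 <= i, i <= conf$n_segments)
  euler <- conf$euler
  euler[i, 3] <- (euler[i, 3] + dphi) %% (2 * pi)
  new_dna_chain(euler, conf$states, conf$q, conf$params)
}
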