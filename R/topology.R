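# Twist, writhe and linking number of a discretized conformation.
#
# Tw is the sum of local twist angles between successive frames; Wr comes
# either from the exact Gauss double sum over segment pairs (mutual solid
# angles, Klenin-Langowski closed form, evaluated in C++) or from Fuller's
# single-sum surrogate expressed through the unwrapped Euler angles.

#' Local twist increments between successive frames
#'
#' `dTw_n = [u_n x u_{n+1}] . t_n / (2 pi)`, the sine of the twist angle
#' between neighbouring triads normalized to full turns.
#'
#' @param conf A `dna_chain`.
#' @return Numeric vector of length N-1.
#' @export
twist_increments <- function(conf) {
  fr <- chain_frames(conf)
  N <- conf$n_segments
  vapply(seq_len(N - 1), function(n) {
    u1 <- fr[[n]][, 1]; u2 <- fr[[n + 1]][, 1]; t1 <- fr[[n]][, 3]
    sum((c(u1[2] * u2[3] - u1[3] * u2[2],
           u1[3] * u2[1] - u1[1] * u2[3],
           u1[1] * u2[2] - u1[2] * u2[1])) * t1) / (2 * pi)
  }, numeric(1))
}

#' Twist number of a conformation
#'
#' @param conf A `dna_chain`.
#' @return Total twist in turns.
#' @export
twist_number <- function(conf) sum(twist_increments(conf))

#' Writhe by the Gauss double sum
#'
#' Exact mutual solid angles of all non-adjacent segment pairs (pairs sharing
#' a vertex contribute zero for straight segments and are skipped), summed
#' and normalized: `Wr = sum_{n<n'} Omega_nn' / (2 pi)`.
#'
#' @param conf A `dna_chain`.
#' @return Writhe in turns.
#' @export
writhe_gauss <- function(conf) {
  res <- cpp_writhe_gauss(conf$vertices)
  if (res$singular_i >= 0) {
    stop(sprintf("Gauss writhe singular: segments %d and %d coincide or intersect",
                 res$singular_i + 1L, res$singular_j + 1L))
  }
  res$wr
}

#' Fuller linking-number change and writhe
#'
#' The Fuller form follows the unwrapped Euler angles:
#' `dLk_F = (alpha_N + gamma_N - alpha_1 - gamma_1) / (2 pi)` and
#' `Wr_F = dLk_F - Tw`.  Valid only for conformations reachable from the
#' extended state without the tangent passing through -z0; a tangent at the
#' antipode makes the underlying integrand singular and raises an error.
#'
#' @param conf A `dna_chain`.
#' @return `dlk_fuller`: linking change in turns; `writhe_fuller`: writhe in
#'   turns.
#' @export
dlk_fuller <- function(conf) {
  tz <- chain_tangents(conf)[, 3]
  if (any(tz < -1 + 1e-12)) {
    stop("Fuller formula invalid: tangent (anti)parallel to -z0 at segment ",
         which.min(tz))
  }
  uw <- conf$euler_unwrapped
  N <- nrow(uw)
  unname(uw[N, "alpha"] + uw[N, "gamma"] - uw[1, "alpha"] - uw[1, "gamma"]) /
    (2 * pi)
}

#' @rdname dlk_fuller
#' @export
writhe_fuller <- function(conf) dlk_fuller(conf) - twist_number(conf)

#' Topology report for a conformation
#'
#' Collects twist, both writhe estimates, the linking-number change relative
#' to torsionally relaxed B-DNA (including the structural contribution
#' `sum_n q * dlk0(u_n)` from segments in alternative states) and the
#' superhelical density `sigma = dLk / Lk0_B`.
#'
#' @param conf A `dna_chain`.
#' @param n_bp Number of base pairs (defaults to `N * q`).
#' @return One-row data frame with columns `tw`, `wr_gauss`, `wr_fuller`,
#'   `dlk_fuller`, `dlk`, `sigma`.
#' @export
topology_report <- function(conf, n_bp = conf$n_segments * conf$q) {
  params <- conf$params
  tw <- twist_number(conf)
  wrg <- writhe_gauss(conf)
  dlkF <- tryCatch(dlk_fuller(conf), error = function(e) NA_real_)
  dlk0 <- vapply(unique(conf$states), relaxed_linking_density, numeric(1),
                 params = params)
  structural <- sum(conf$q * dlk0[conf$states])
  dlk <- tw + wrg + structural
  Lk0B <- n_bp / params["B", "h"]
  data.frame(tw = tw, wr_gauss = wrg,
             wr_fuller = if (is.na(dlkF)) NA_real_ else dlkF - tw,
             dlk_fuller = dlkF, dlk = dlk, sigma = dlk / Lk0B)
}

#' Writhe change from a local move
#'
#' Given the conformation before and after a move that rigidly displaced only
#' segments `range[1]:range[2]`, returns `Wr(after) - Wr(before)` using only
#' the cross terms between moved and unmoved segments (the internal pairs of
#' a rigidly moved block keep their mutual solid angles).  Falls back to two
#' full Gauss sums when the range covers more than half the chain.
#'
#' @param before,after `dna_chain` conformations differing only in the range.
#' @param range Integer vector `c(first, last)` of moved segments (1-based).
#' @return Writhe change in turns.
#' @export
writhe_delta <- function(before, after, range) {
  N <- before$n_segments
  i0 <- range[1]; i1 <- range[2]
  stopifnot(1 <= i0, i0 <= i1, i1 <= N)
  if ((i1 - i0 + 1) > N / 2) {
    return(writhe_gauss(after) - writhe_gauss(before))
  }
  cpp_writhe_cross(after$vertices, i0 - 1L, i1 - 1L) -
    cpp_writhe_cross(before$vertices, i0 - 1L, i1 - 1L)
}
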