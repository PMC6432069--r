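# Discretized DNA conformations: ordered rigid-body frames.
#
# Each of the N segments carries an orthonormal triad (u, v, t) obtained by
# rotating the lab frame (x0, y0, z0) with R = Rz(alpha) Ry(beta) Rz(gamma)
# (z-y-z Euler convention; the force acts along +z0).  Euler angles are stored
# both wrapped (alpha, gamma in [0, 2pi), beta in [0, pi]) and unwrapped
# (cumulative along the chain, needed by the Fuller linking number).

rot_z <- function(t) {
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}
rot_y <- function(t) {
  matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
}

euler_to_matrix <- function(alpha, beta, gamma) {
  rot_z(alpha) %*% rot_y(beta) %*% rot_z(gamma)
}

# zyz Euler angles of a rotation matrix; beta in [0, pi].
matrix_to_euler <- function(R) {
  beta <- acos(max(-1, min(1, R[3, 3])))
  if (sin(beta) > 1e-12) {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  } else {
    # degenerate: only alpha + gamma (beta ~ 0) or alpha - gamma (beta ~ pi)
    # is defined; put the whole angle into alpha.
    alpha <- atan2(R[2, 1], R[1, 1])
    if (R[3, 3] < 0) alpha <- -alpha
    gamma <- 0
  }
  c(alpha %% (2 * pi), beta, gamma %% (2 * pi))
}

wrap_pm_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y == -pi, pi, y)  # principal value in (-pi, pi]
}

new_dna_chain <- function(euler, states, q, params) {
  n <- nrow(euler)
  rise <- attr(params, "rise_B")
  b <- q * params[states, "contour_ratio"] * rise
  conf <- structure(list(euler = euler, states = states, b = b, q = q,
                         params = params, n_segments = n),
                    class = "dna_chain")
  conf$euler_unwrapped <- unwrap_euler(euler)
  conf$vertices <- chain_vertices(conf)
  conf
}

#' Segment frames of a conformation
#'
#' @param conf A `dna_chain` conformation.
#' @return A list of N 3x3 rotation matrices; columns are the triad
#'   (u, v, t) in lab coordinates, `t = R %*% c(0,0,1)`.
#' @export
chain_frames <- function(conf) {
  lapply(seq_len(conf$n_segments), function(n) {
    euler_to_matrix(conf$euler[n, 1], conf$euler[n, 2], conf$euler[n, 3])
  })
}

#' Segment tangents of a conformation
#'
#' @param conf A `dna_chain` conformation.
#' @return N x 3 matrix of unit tangent vectors.
#' @export
chain_tangents <- function(conf) {
  al <- conf$euler[, 1]; be <- conf$euler[, 2]
  cbind(sin(be) * cos(al), sin(be) * sin(al), cos(be))
}

chain_vertices <- function(conf) {
  tg <- chain_tangents(conf) * conf$b
  rbind(c(0, 0, 0), apply(tg, 2, cumsum))
}

unwrap_euler <- function(euler) {
  cum_unwrap <- function(x) x[1] + c(0, cumsum(wrap_pm_pi(diff(x))))
  cbind(alpha = cum_unwrap(euler[, 1]), gamma = cum_unwrap(euler[, 3]))
}

#' Unwrap Euler angles along the chain
#'
#' Recomputes the cumulative (unbounded) alpha and gamma angles so that
#' successive differences lie in (-pi, pi].  Wrapped angles are unchanged.
#' The unwrapped angles feed the Fuller linking-number change.
#'
#' @param conf A `dna_chain` conformation.
#' @return The conformation with refreshed `euler_unwrapped`.
#' @export
unwrap_angles <- function(conf) {
  conf$euler_unwrapped <- unwrap_euler(conf$euler)
  conf
}

#' Deterministic and random chain fixtures
#'
#' Builds standard test conformations:
#' \describe{
#'   \item{straight}{all tangents along +z; `total_twist` turns distributed
#'     uniformly over the junctions via the gamma angle.}
#'   \item{circle}{closed planar polygon in the x-z plane.}
#'   \item{helix}{regular solenoid with `turns` full turns of the tangent
#'     around +z at constant polar angle `beta0` (small `beta0` = gentle,
#'     nearly extended spiral).}
#'   \item{plectoneme}{two interwound helical strands joined by an apex cap:
#'     the tangent repeatedly points near -z, so Fuller's writhe formula
#'     fails while the Gauss double sum stays exact.}
#'   \item{random_walk}{direct Boltzmann sampling of the bend angles for
#'     stiffness `a = Lp/b` (each junction: `cos(theta) ~ exp(a cos theta)`),
#'     twist angles drawn for stiffness `c`; no Monte Carlo involved.}
#' }
#'
#' @param kind One of `"straight"`, `"circle"`, `"helix"`, `"plectoneme"`,
#'   `"random_walk"`.
#' @param chain A [chain_spec()].
#' @param params Parameter table.
#' @param state Structural state of all segments (fixtures are homogeneous).
#' @param total_twist For `straight`: total twist in turns.
#' @param turns For `helix`/`plectoneme`: number of solenoid/interwinding
#'   turns.
#' @param beta0 For `helix`: cone half-angle of the tangent, rad.
#' @param radius,pitch For `plectoneme`: superhelix radius and pitch in nm.
#' @param seed For `random_walk`: RNG seed (an integer) for reproducibility.
#' @return A `dna_chain` conformation.
#' @export
build_fixture <- function(kind = c("straight", "circle", "helix",
                                   "plectoneme", "random_walk"),
                          chain, params = dna_state_params(), state = "B",
                          total_twist = 0, turns = 5, beta0 = 0.4,
                          radius = 4, pitch = 2, seed = NULL) {
  kind <- match.arg(kind)
  N <- chain$n_segments
  states <- rep(state, N)
  euler <- switch(kind,
    straight = {
      g <- seq(0, 2 * pi * total_twist, length.out = N)
      cbind(alpha = rep(0, N), beta = rep(0, N), gamma = g %% (2 * pi))
    },
    circle = {
      if (N < 3) stop("cannot close a circle with fewer than 3 segments")
      th <- 2 * pi * (seq_len(N) - 0.5) / N
      cbind(alpha = ifelse(th <= pi, 0, pi),
            beta = ifelse(th <= pi, th, 2 * pi - th),
            gamma = rep(0, N))
    },
    helix = {
      al <- (2 * pi * turns) * (seq_len(N) - 1) / N
      cbind(alpha = al %% (2 * pi), beta = rep(beta0, N),
            gamma = (-al) %% (2 * pi))
    },
    plectoneme = {
      return(plectoneme_fixture(chain, params, state, turns, radius, pitch))
    },
    random_walk = {
      if (!is.null(seed)) set.seed(seed)
      st <- dimensionless_stiffness(state, chain, params)
      return(random_walk_fixture(N, st$a, st$c, chain$q, params, state))
    })
  new_dna_chain(euler, states, chain$q, params)
}

# Boltzmann-weighted bend/twist angles by direct (inverse-CDF / wrapped
# normal) sampling; frames built by parallel transport plus twist.
random_walk_fixture <- function(N, a, cc, q, params, state) {
  # cos(theta) has density ~ exp(a u) on [-1, 1]
  u <- 1 + log(stats::runif(N - 1) * (1 - exp(-2 * a)) + exp(-2 * a)) / a
  th <- acos(pmax(-1, pmin(1, u)))
  psi <- stats::runif(N - 1, 0, 2 * pi)    # bend azimuth
  phi <- stats::rnorm(N - 1, 0, 1 / sqrt(cc))  # twist angle, small-angle draw
  R <- diag(3)
  euler <- matrix(0, N, 3)
  euler[1, ] <- c(0, 0, 0)
  for (n in 2:N) {
    # bend through th about an axis perpendicular to t, then twist about t
    R <- R %*% rot_z(psi[n - 1]) %*% rot_y(th[n - 1]) %*%
      rot_z(phi[n - 1] - psi[n - 1])
    euler[n, ] <- matrix_to_euler(R)
  }
  new_dna_chain(euler, rep(state, N), q, params)
}

# Two interwound antiparallel helices joined by a semicircular apex.
plectoneme_fixture <- function(chain, params, state, turns, radius, pitch) {
  N <- chain$n_segments
  b <- chain$b[[state]]
  n_cap <- max(4L, ceiling(pi * radius / b))
  n_arm <- (N - n_cap) %/% 2
  if (n_arm < 8) stop("chain too short for a plectoneme fixture")
  # arc-length parametrization of a helix with radius r and pitch p
  helix_pt <- function(s, r, p, sgn, phase) {
    wl <- sqrt(r^2 + (p / (2 * pi))^2)  # length per unit phase angle
    ph <- s / wl
    c(r * cos(sgn * ph + phase), r * sin(sgn * ph + phase), p * ph / (2 * pi))
  }
  up <- t(vapply((0:(n_arm)) * b, helix_pt, numeric(3),
                 r = radius, p = pitch, sgn = 1, phase = 0))
  A <- up[nrow(up), ]
  centre <- c(0, 0, A[3])
  # apex: semicircle over the top, from strand 1's end to strand 2's start
  cap_t <- seq(0, pi, length.out = n_cap + 1)[-1]
  cap <- t(vapply(cap_t, function(th) {
    cos(th) * (A - centre) + sin(th) * c(0, 0, radius) + centre
  }, numeric(3)))
  down <- t(vapply(((n_arm):0) * b, helix_pt, numeric(3),
                   r = radius, p = pitch, sgn = 1, phase = pi))
  verts <- rbind(up, cap, down)
  # resample to N segments of length b along the polyline
  verts <- resample_polyline(verts, N, b)
  frames_from_vertices(verts, chain$q, params, state)
}

resample_polyline <- function(v, N, b) {
  seg <- sqrt(rowSums(diff(v)^2))
  s <- c(0, cumsum(seg))
  want <- seq(0, s[length(s)], length.out = N + 1)
  t(vapply(want, function(si) {
    i <- max(1, findInterval(si, s, rightmost.closed = TRUE))
    i <- min(i, nrow(v) - 1)
    w <- (si - s[i]) / max(s[i + 1] - s[i], 1e-300)
    v[i, ] * (1 - w) + v[i + 1, ] * w
  }, numeric(3)))
}

# Build parallel-transported frames along a vertex polyline.
frames_from_vertices <- function(verts, q, params, state) {
  tg <- diff(verts)
  tg <- tg / sqrt(rowSums(tg^2))
  N <- nrow(tg)
  euler <- matrix(0, N, 3)
  R <- rotation_aligning(c(0, 0, 1), tg[1, ])
  euler[1, ] <- matrix_to_euler(R)
  for (n in 2:N) {
    R <- rotation_aligning(tg[n - 1, ], tg[n, ]) %*% R
    euler[n, ] <- matrix_to_euler(R)
  }
  new_dna_chain(euler, rep(state, N), q, params)
}

# Minimal rotation taking unit vector x to unit vector y.
rotation_aligning <- function(x, y) {
  v <- c(x[2] * y[3] - x[3] * y[2],
         x[3] * y[1] - x[1] * y[3],
         x[1] * y[2] - x[2] * y[1])
  cth <- sum(x * y)
  sth <- sqrt(sum(v^2))
  if (sth < 1e-14) {
    if (cth > 0) return(diag(3))
    # antipodal: rotate by pi about any perpendicular axis
    p <- if (abs(x[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * x) * x
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - cth) / sth^2)
}

#' @export
print.dna_chain <- function(x, ...) {
  cat(sprintf("dna_chain: %d segments, states {%s}, length %.1f nm\n",
              x$n_segments, paste(unique(x$states), collapse = ","),
              sum(x$b)))
  invisible(x)
}

#' Write / read a conformation as a TSV table
#'
#' Plain-text dump with one row per segment (1-based index, start vertex,
#' Euler angles, state).  `read_chain_tsv` reconstructs the conformation
#' from the Euler angles (vertices are rederived, frames authoritative).
#'
#' @param conf A `dna_chain`.
#' @param file Path.
#' @param params,q Parameter table and segment size used on re-read.
#' @return `file` invisibly, or the re-read `dna_chain`.
#' @export
write_chain_tsv <- function(conf, file) {
  d <- data.frame(segment = seq_len(conf$n_segments),
                  x = conf$vertices[-nrow(conf$vertices), 1],
                  y = conf$vertices[-nrow(conf$vertices), 2],
                  z = conf$vertices[-nrow(conf$vertices), 3],
                  alpha = conf$euler[, 1], beta = conf$euler[, 2],
                  gamma = conf$euler[, 3], state = conf$states)
  utils::write.table(d, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_chain_tsv
#' @export
read_chain_tsv <- function(file, params = dna_state_params(), q = 1.5) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  new_dna_chain(cbind(d$alpha, d$beta, d$gamma), d$state, q, params)
}
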