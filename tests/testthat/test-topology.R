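test_that("pair solid angles match brute-force Gauss quadrature", {
  # random skew segment pairs: closed form vs adaptive double quadrature
  set.seed(42)
  for (i in 1:8) {
    pts <- matrix(rnorm(12, sd = 1.5), 4, 3)
    # keep the pair clearly separated so the oracle quadrature converges
    pts[3:4, ] <- pts[3:4, ] + 3
    ora <- oracle_gauss_pair(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    # evaluate the package's closed form through a 3-segment chain whose
    # middle segment connects the two test segments: subtract the two
    # connector pairs, leaving pair (1,3)
    # a 3-segment chain over these 4 vertices has exactly one non-adjacent
    # pair (the middle connector is skipped as adjacent to both), so the
    # chain writhe IS the pair contribution
    v <- rbind(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    wr_pair <- cpp_writhe_gauss(v)$wr
    expect_equal(wr_pair, ora, tolerance = 1e-6)
  }
})

test_that("twist number follows the printed cross-product increments", {
  ch <- chain_spec(150, 1.5, default_params)
  phi <- 0.04
  g <- ((0:99) * phi) %% (2 * pi)
  euler <- cbind(rep(0, 100), rep(0, 100), g)
  conf <- twlc:::new_dna_chain(euler, rep("B", 100), 1.5, default_params)
  expect_equal(twist_number(conf), 99 * sin(phi) / (2 * pi),
               tolerance = 1e-12)
  # mirror the material frame: twist flips sign
  euler2 <- euler
  euler2[, 3] <- (-euler[, 3]) %% (2 * pi)
  conf2 <- twlc:::new_dna_chain(euler2, rep("B", 100), 1.5, default_params)
  expect_equal(twist_number(conf2), -twist_number(conf), tolerance = 1e-12)
  # identical frames: zero
  conf3 <- build_fixture("straight", ch, default_params)
  expect_equal(twist_number(conf3), 0)
})

test_that("writhe is a pseudoscalar: mirror image negates it", {
  ch <- chain_spec(300, 1.5, default_params)
  hx <- build_fixture("helix", ch, default_params, turns = 4, beta0 = 0.8)
  mirrored <- hx$vertices
  mirrored[, 2] <- -mirrored[, 2]
  wr1 <- cpp_writhe_gauss(hx$vertices)$wr
  wr2 <- cpp_writhe_gauss(mirrored)$wr
  expect_equal(wr2, -wr1, tolerance = 1e-6)
})

test_that("Gauss writhe is invariant under rigid rotations", {
  ch <- chain_spec(200, 1.5, default_params)
  hx <- build_fixture("helix", ch, default_params, turns = 3, beta0 = 0.9)
  rot <- move_tail_pivot(hx, 1, c(1, 2, 0.5), 0.9)
  expect_equal(writhe_gauss(rot), writhe_gauss(hx), tolerance = 1e-9)
  # twist is likewise unchanged by the rigid motion
  expect_equal(twist_number(rot), twist_number(hx), tolerance = 1e-9)
})

test_that("Fuller form: extended and solenoidal chains, plectoneme failure", {
  ch <- chain_spec(200, 1.5, default_params)
  # straight twisted chain: dLk_F equals Tw exactly (gamma winding), Wr_F ~ 0
  stw <- build_fixture("straight", ch, default_params, total_twist = 2)
  expect_equal(dlk_fuller(stw), 2, tolerance = 1e-9)
  expect_equal(writhe_fuller(stw), dlk_fuller(stw) - twist_number(stw),
               tolerance = 1e-12)
  expect_lt(abs(writhe_fuller(stw)), 1e-2)  # sin(phi)/phi discretization
  # gentle long solenoid: Fuller within 2% of Gauss
  ch2 <- chain_spec(3000, 1.5, default_params)
  hx <- build_fixture("helix", ch2, default_params, turns = 60, beta0 = 1.2)
  wg <- writhe_gauss(hx)
  wf <- writhe_fuller(hx)
  expect_equal(wf / wg, 1, tolerance = 0.02)
  # Fuller writhe of the tangent cone: T (1 - cos beta0)
  expect_equal(wf, 60 * (1 - cos(1.2)), tolerance = 0.02)
  # interwound plectoneme: Fuller misses by far more than 10%
  ch3 <- chain_spec(600, 1.5, default_params)
  pl <- build_fixture("plectoneme", ch3, default_params, turns = 4,
                      radius = 4, pitch = 6)
  wgp <- writhe_gauss(pl)
  wfp <- writhe_fuller(pl)
  expect_gt(abs(wgp), 1)                       # strongly writhed
  expect_gt(abs(wfp - wgp) / abs(wgp), 0.10)
  # antipodal tangent invalidates the Fuller form
  down <- twlc:::new_dna_chain(rbind(c(0, 0, 0), c(0, pi, 0)), c("B", "B"),
                               1.5, default_params)
  expect_error(dlk_fuller(down), "-z0")
})

test_that("Calugareanu-White: Tw + Wr constant along a ribbon deformation", {
  # closed circle with 3 turns of twist, deformed into a saddle while the
  # frames are transported by the minimal rotation between old and new
  # tangents: the linking number Tw + Wr must not change
  ch <- chain_spec(300, 1.5, default_params)
  N <- ch$n_segments
  base <- build_fixture("circle", ch, default_params)
  tw0 <- 3
  euler <- base$euler
  euler[, 3] <- (euler[, 3] + 2 * pi * tw0 * (seq_len(N) - 1) / N) %% (2 * pi)
  conf <- twlc:::new_dna_chain(euler, base$states, ch$q, default_params)
  R <- N * conf$b[[1]] / (2 * pi)  # polygon radius matching segment length
  fr <- chain_frames(conf)
  lk <- NULL
  for (amp in c(0, 0.2, 0.4, 0.6)) {
    th <- 2 * pi * (seq_len(N) - 0.5) / N
    verts <- cbind(R * sin(th), R * amp * sin(2 * th), R * cos(th))
    tg <- diff(rbind(verts, verts[1, , drop = FALSE]))
    tg <- tg / sqrt(rowSums(tg^2))
    old_tg <- chain_tangents(conf)
    euler2 <- conf$euler
    for (n in seq_len(N)) {
      Rn <- twlc:::rotation_aligning(old_tg[n, ], tg[n, ]) %*% fr[[n]]
      euler2[n, ] <- twlc:::matrix_to_euler(Rn)
    }
    conf <- twlc:::new_dna_chain(euler2, conf$states, ch$q, default_params)
    conf$vertices <- rbind(verts, verts[1, , drop = FALSE])
    fr <- chain_frames(conf)
    lk_def <- twist_number(conf) + writhe_gauss(conf)
    if (is.null(lk)) {
      lk <- lk_def
    } else {
      expect_equal(lk_def, lk, tolerance = 5e-3)
    }
  }
})

test_that("topology report combines twist, writhe and structural offsets", {
  ch <- chain_spec(150, 1.5, default_params)
  conf <- build_fixture("random_walk", ch, default_params, seed = 12)
  rep1 <- topology_report(conf, n_bp = 150)
  expect_equal(rep1$dlk, rep1$tw + rep1$wr_gauss, tolerance = 1e-12)
  expect_equal(rep1$sigma, rep1$dlk / (150 / 10.4), tolerance = 1e-12)
  expect_equal(rep1$wr_fuller, rep1$dlk_fuller - rep1$tw, tolerance = 1e-12)
  # all-S chain shifts dLk by N q dlk0(S)
  sconf <- build_fixture("straight", ch, default_params, state = "S")
  repS <- topology_report(sconf, n_bp = 150)
  expect_equal(repS$dlk,
               ch$n_segments * 1.5 * relaxed_linking_density("S",
                                                             default_params),
               tolerance = 1e-9)
})

test_that("incremental writhe updates equal full recomputation and compose", {
  ch <- chain_spec(150, 1.5, default_params)
  conf <- build_fixture("random_walk", ch, default_params, seed = 3)
  expect_equal(writhe_delta(conf, conf, c(10, 30)), 0)
  m1 <- move_crankshaft(conf, 10, 31, 0.4)
  d1 <- writhe_delta(conf, m1, c(10, 30))
  expect_equal(d1, writhe_gauss(m1) - writhe_gauss(conf), tolerance = 1e-9)
  m2 <- move_crankshaft(m1, 50, 71, -0.6)
  d2 <- writhe_delta(m1, m2, c(50, 70))
  expect_equal(d1 + d2, writhe_gauss(m2) - writhe_gauss(conf),
               tolerance = 1e-9)
  # ranges beyond N/2 fall back to the full double sum
  m3 <- move_crankshaft(conf, 5, 95, 0.2)
  expect_equal(writhe_delta(conf, m3, c(5, 94)),
               writhe_gauss(m3) - writhe_gauss(conf), tolerance = 1e-9)
})
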