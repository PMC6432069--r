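tr16 <- tm_truncation(kmax = 16, nodes = 128)

test_that("S and V reduce to closed forms in the field-free limit", {
  a <- 2; cc <- 2; b <- 0.5
  S <- s_matrix(a, b, cc, 4.3, 0, 0, tr16)
  V <- v_vector(b, 0, tr16)
  expect_equal(V[1], 8 * pi^2)
  expect_true(all(abs(V[-1]) < 1e-14))
  # Tr(SV) = 64 pi^4 e^{-a-c} I_0(c) sinh(a)/a
  expect_equal(sum(S[1, ] * V),
               64 * pi^4 * exp(-a - cc) * besselI(cc, 0) * sinh(a) / a,
               tolerance = 1e-12)
  # torque-free S is diagonal (only the r = 0, s' = 0 channel survives at
  # f = 0): off-diagonal entries vanish
  expect_lt(max(abs(S - diag(diag(S)))), 1e-12 * max(abs(S)))
  # V at b f = 1: first component 8 pi^2 sinh(1)
  V1 <- v_vector(b, 2, tr16)
  expect_equal(V1[1], 8 * pi^2 * sinh(1), tolerance = 1e-12)
  expect_true(all(V1 >= 0))
})

test_that("two-segment partition function matches 4-D quadrature", {
  a <- 2; cc <- 2; b <- 0.5; lam <- 4.3; f <- 0.8; tau <- 1.3
  S <- s_matrix(a, b, cc, lam, f, tau, tr16)
  V <- v_vector(b, f, tr16)
  expect_equal(sum(S[1, ] * V), oracle_z2(a, b, cc, lam, f, tau),
               tolerance = 1e-3)
  # second point: negative torque, negative lambda, different stiffness
  S2 <- s_matrix(3.5, 0.8, 1.2, -0.5, 1.4, -2.1, tr16)
  V2 <- v_vector(0.8, 1.4, tr16)
  expect_equal(sum(S2[1, ] * V2), oracle_z2(3.5, 0.8, 1.2, -0.5, 1.4, -2.1),
               tolerance = 1e-3)
})

test_that("log partition function is extensive and converged in kmax", {
  cons <- mech_constraint(f_pN = 2, tau_pN_nm = 5)
  tr <- tm_truncation(kmax = 30)
  Ns <- vapply(c(1000, 2000, 3000), function(nbp) {
    chain_spec(nbp, 1.5, default_params)$n_segments
  }, integer(1))
  lz <- vapply(c(1000, 2000, 3000), function(nbp) {
    log_partition(chain_spec(nbp, 1.5, default_params), cons, tr,
                  default_params)$log_z
  }, numeric(1))
  # added segments contribute a fixed free energy (boundary terms cancel)
  expect_equal((lz[2] - lz[1]) / (Ns[2] - Ns[1]),
               (lz[3] - lz[2]) / (Ns[3] - Ns[2]), tolerance = 1e-9)
  # doubling the harmonic cutoff leaves log Z unchanged to 1e-5 relative
  ch1 <- chain_spec(1000, 1.5, default_params)
  for (fp in c(5, 60)) {
    consf <- mech_constraint(f_pN = fp, tau_pN_nm = 20)
    la <- log_partition(ch1, consf, tm_truncation(kmax = 35), default_params)
    lb <- log_partition(ch1, consf, tm_truncation(kmax = 60), default_params)
    expect_equal(la$log_z, lb$log_z, tolerance = 1e-5)
  }
  lz1 <- log_partition(ch1, cons, tr, default_params)
  expect_equal(lz1$imag_residual, 0)
  expect_true(lz1$spectral_gap > 0)
})

test_that("torsionless transfer matrix reproduces the worm-like chain", {
  ch <- chain_spec(10000, 1.5, default_params)
  tr <- tm_truncation(kmax = 30)
  kbt <- kbt_pN_nm()
  for (fp in c(0.5, 2, 5)) {
    ob <- tm_observables(ch, mech_constraint(f_pN = fp), tr,
                         default_params, states = "B", what = "z")
    exact <- oracle_wlc_extension(fp / kbt, 50)
    expect_equal(ob$z_over_LB, exact, tolerance = 0.015)
  }
  # rigid-rod limit: very stiff chain is fully extended under force
  p <- default_params
  p["B", "Lp"] <- 2000
  p["B", "Ltw"] <- 2000
  ch2 <- chain_spec(2000, 1.5, p)
  ob <- tm_observables(ch2, mech_constraint(f_pN = 5),
                       tm_truncation(kmax = 30), p, states = "B", what = "z")
  f_dimless <- 5 / kbt
  expect_equal(ob$z_over_LB, 1 - 1 / sqrt(4 * 2000 * f_dimless),
               tolerance = 1e-3)
  # no spontaneous extension without force
  ob0 <- tm_observables(ch, mech_constraint(f_pN = 0, tau_pN_nm = 0), tr,
                        default_params, states = "B", what = "z")
  expect_lt(abs(ob0$z_over_LB), 1e-6)
})

test_that("boundary vector choice is irrelevant for long chains", {
  # replacing V by its zero-force form changes z/L by < 0.5% at L = 20 Lp
  ch <- chain_spec(3100, 1.5, default_params)  # ~1020 nm ~ 20 Lp
  tr <- tm_truncation(kmax = 24)
  cons <- mech_constraint(f_pN = 2)
  st <- dimensionless_stiffness("B", ch, default_params)
  b <- ch$b[["B"]]
  z_with <- function(vfun) {
    g <- function(f) {
      S <- s_matrix(st$a, b, st$c, 4.3, f, 0, tr)
      v <- vfun(f)
      pw <- twlc:::mat_pow_apply(S, ch$n_segments - 1, v)
      log(pw$value[1]) + pw$log_scale
    }
    h <- cons$f * 1e-3
    (g(cons$f + h) - g(cons$f - h)) / (2 * h)
  }
  z1 <- z_with(function(f) v_vector(b, f, tr))
  z2 <- z_with(function(f) v_vector(b, 0, tr))
  expect_equal(z1, z2, tolerance = 5e-3)
})

test_that("single-state model is torque-symmetric", {
  ch <- chain_spec(3000, 1.5, default_params)
  tr <- tm_truncation(kmax = 30)
  o1 <- tm_observables(ch, mech_constraint(f_pN = 3, tau_pN_nm = 8), tr,
                       default_params, states = "B")
  o2 <- tm_observables(ch, mech_constraint(f_pN = 3, tau_pN_nm = -8), tr,
                       default_params, states = "B")
  expect_equal(o1$z, o2$z, tolerance = 1e-9)
  expect_equal(o1$dlk, -o2$dlk, tolerance = 1e-9)
  # no linking change without torque
  o0 <- tm_observables(ch, mech_constraint(f_pN = 3), tr, default_params,
                       states = "B")
  expect_lt(abs(o0$dlk), 1e-9)
})

test_that("linking response matches the twistable-rod susceptibility", {
  # nearly straight chain at high force: dLk ~ tau L / (2 pi Ltw) plus a
  # small positive writhe contribution
  ch <- chain_spec(3000, 1.5, default_params)
  cons <- mech_constraint(f_pN = 15, tau_pN_nm = 4)
  ob <- tm_observables(ch, cons, tm_truncation(kmax = 35), default_params,
                       states = "B")
  tw_only <- cons$tau * sum(rep(ch$b[["B"]], ch$n_segments)) / (2 * pi * 95)
  expect_gt(ob$dlk, tw_only)
  expect_lt(ob$dlk, 1.25 * tw_only)
})
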