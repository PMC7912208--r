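test_that("constant basis functions give exactly zero stiffness rows", {
  tr <- ou_traj()
  rc <- rc_select(1L, 2L)
  basis <- hermite_basis(4) # includes the constant He_0
  m <- ou_model()
  sys <- assemble_reversible(tr, rc, basis, m)
  expect_equal(sys$stiffness[1, ], rep(0, 4))
  expect_equal(sys$stiffness[, 1], rep(0, 4))
  sysn <- assemble_nonreversible(tr, rc, basis, m)
  expect_equal(sysn$stiffness[1, ], rep(0, 4)) # L of a constant is zero
})

test_that("reversible stiffness is symmetric to machine precision", {
  tr <- ou_traj()
  sys <- assemble_reversible(tr, rc_select(1L, 2L),
                             gaussian_basis(seq(-2, 2, 0.5), 0.2), ou_model())
  expect_equal(sys$stiffness, t(sys$stiffness))
  expect_equal(sys$mass, t(sys$mass))
  expect_gte(min(eigen(sys$mass, symmetric = TRUE, only.values = TRUE)$values),
             -1e-12)
})

test_that("quadrature OU assembly reproduces the Hermite diagonal", {
  # exact Gauss-Hermite integration: stiffness entry of He_1 equals alpha_x
  m <- ou_model(1, 5)
  sm <- galerkin_quadrature(m, rc_oscillating(0), hermite_n = 6,
                            quad_order = 40)
  expect_equal(nontrivial_rates(sm)[1:4], 1:4, tolerance = 1e-10)
})

test_that("reversible and nonreversible estimators agree within MC error", {
  tr <- ou_traj()
  rc <- rc_select(1L, 2L)
  basis <- hermite_basis(4)
  m <- ou_model()
  s1 <- assemble_reversible(tr, rc, basis, m, n_blocks = 50)
  s2 <- assemble_nonreversible(tr, rc, basis, m, n_blocks = 50)
  # blockwise SE of the entrywise difference
  d <- s1$blocks$S / rep(s1$blocks$n, each = 16) -
    s2$blocks$S / rep(s2$blocks$n, each = 16)
  se <- apply(d, c(1, 2), sd) / sqrt(50)
  gap <- abs(s1$stiffness - s2$stiffness)
  expect_true(all(gap <= 3 * se + 1e-12))
})

test_that("underdamped position-only coordinates kill the quadratic form", {
  m <- make_model("underdamped", double_well_potential(), beta = 0.4,
                  gamma = 10)
  tr <- cached_traj("ul_dw_short", function()
    simulate_em(m, dt = 1e-3, n_steps = 4e5, seed = 7))
  rc <- rc_select(1L, 4L)
  basis <- gaussian_basis(seq(-2, 2, 0.5), 0.2)
  sys <- assemble_reversible(tr, rc, basis, m)
  expect_equal(max(abs(sys$stiffness)), 0) # grad xi^T a grad xi = 0
  # nonreversible: only the p . grad_q xi term contributes, matrices nonzero
  sysn <- assemble_nonreversible(tr, rc, basis, m)
  expect_gt(max(abs(sysn$stiffness)), 0)
})

test_that("solve orders eigenvalues and reports timescales for a diagonal system", {
  sys <- structure(list(stiffness = diag(c(0, 1, 5)), mass = diag(3),
                        estimator = "reversible", offset = 0, n_samples = 1,
                        n_dropped = 0L, basis = hermite_basis(3),
                        rc_name = "x", dt = NA_real_),
                   class = "galerkin_system")
  sm <- solve(sys)
  expect_equal(sm$eigenvalues, c(0, 1, 5))
  expect_equal(as.numeric(implied_timescales(sm)), c(1, 0.2))
  expect_equal(as.numeric(implied_timescales(
    spectral_model(c(0, 0.5), diag(2), hermite_basis(2)))), 2)
})

test_that("solver flags rank deficiency and spurious negative rates", {
  sys <- structure(list(stiffness = diag(c(0, 1, 2)),
                        mass = diag(c(1, 1, 1e-14)),
                        estimator = "reversible", offset = 0, n_samples = 1,
                        n_dropped = 0L, basis = hermite_basis(3),
                        rc_name = "x", dt = NA_real_),
                   class = "galerkin_system")
  expect_error(solve(sys, n_eigs = 3), "rank")
  sm <- spectral_model(c(-0.2, 0, 0.4), diag(3), hermite_basis(3))
  expect_warning(ts <- implied_timescales(sm), "spurious")
  expect_true(is.na(ts[1]))
  expect_equal(attr(ts, "spurious"), 1L)
})

test_that("min-max ordering holds for nested bases and bounds exact rates", {
  m <- ou_model(1, 5)
  r10 <- nontrivial_rates(galerkin_quadrature(m, rc_oscillating(3),
                                              hermite_n = 10, quad_order = 50))
  r5 <- nontrivial_rates(galerkin_quadrature(m, rc_oscillating(3),
                                             hermite_n = 5, quad_order = 50))
  # Ritz values from the larger space are no larger, and both dominate kappa
  expect_true(all(r10[1:4] <= r5[1:4] + 1e-10))
  expect_true(all(r10[1:4] >= 1:4 - 1e-10)) # kappa_r = r alpha_x
})

test_that("reversible-estimator eigenvalues are real and near-nonnegative", {
  tr <- lemon_traj()
  sys <- assemble_reversible(tr, rc_polar_angle(),
                             gaussian_basis(seq(-2.8, 2.8, length.out = 15),
                                            0.1),
                             make_model("overdamped",
                                        lemon_slice_potential(), 1, 1))
  sm <- solve(sys, n_eigs = 6, mass_tol = 1e-6)
  expect_true(is.numeric(sm$eigenvalues))
  expect_gte(min(sm$eigenvalues), -1e-8)
  expect_equal(sm$discarded_imag, 0)
})

test_that("KM estimator converges to the exact-parameter estimator as dt shrinks", {
  m <- ou_model(1, 5)
  rc <- rc_select(1L, 2L)
  basis <- hermite_basis(4)
  err_at <- function(dt) {
    # fixed total simulated time keeps the sampling-noise floor well below
    # the O(dt) finite-difference discrepancy being measured
    tr <- simulate_em(m, dt = dt, n_steps = round(1e5 / dt), seed = 55)
    skm <- assemble_km(tr, rc, basis, offset_s = dt)
    sex <- assemble_nonreversible(tr, rc, basis, m)
    norm(skm$stiffness - sex$stiffness, "F") / norm(sex$stiffness, "F")
  }
  e1 <- err_at(0.08)
  e2 <- err_at(0.02)
  expect_lt(e2, 0.5 * e1) # O(dt) bias: quartering dt at least halves the error
  expect_lt(e2, 0.1)
})

test_that("KM at the smallest offset recovers the OU rate", {
  tr <- ou_traj()
  sm <- solve(assemble_km(tr, rc_select(1L, 2L), hermite_basis(3),
                          offset_s = 1e-3), n_eigs = 2, imag_tol = 0.2)
  # slowest nontrivial rate alpha_x / gamma = 1 within a few percent
  expect_equal(nontrivial_rates(sm)[1], 1, tolerance = 0.1)
})

test_that("offset scans report per-offset errors and survive failures", {
  tr <- ou_traj()
  rc <- rc_select(1L, 2L)
  basis <- hermite_basis(3)
  ref <- solve(assemble_nonreversible(tr, rc, basis, ou_model()), n_eigs = 3)
  sc <- offset_scan(tr, rc, basis, c(1e-3, 5e-3, 1e-2), ref, n_eigs = 3)
  expect_equal(nrow(sc), 6L) # 3 offsets x 2 nontrivial eigenvalues
  expect_true(all(sc$rel_error < 0.2))
  # a self-referential scan has zero error by construction
  sc0 <- offset_scan(tr, rc, basis, 1e-3,
                     solve(assemble_km(tr, rc, basis, 1e-3), n_eigs = 3))
  expect_equal(max(sc0$rel_error), 0)
  # an invalid offset yields NA rows with a message, not an abort
  scbad <- offset_scan(tr, rc, basis, c(1e-3, 0.00049), ref, n_eigs = 3)
  expect_true(any(is.na(scbad$rate)))
  expect_true(any(!is.na(scbad$error_message)))
})

test_that("doubling the sample count moves lemon t1 less than 3 bootstrap SEs", {
  tr <- lemon_traj(n_steps = 2e6)
  half <- trajectory(unclass(tr)[1:1e6, ], dt = attr(tr, "dt"),
                     seed = attr(tr, "seed"))
  m <- make_model("overdamped", lemon_slice_potential(), 1, 1)
  basis <- gaussian_basis(seq(-2.8, 2.8, length.out = 15), 0.1)
  s_half <- assemble_reversible(half, rc_polar_angle(), basis, m,
                                n_blocks = 100)
  s_full <- assemble_reversible(tr, rc_polar_angle(), basis, m)
  t_half <- implied_timescales(solve(s_half, n_eigs = 4, mass_tol = 1e-6))[1]
  t_full <- implied_timescales(solve(s_full, n_eigs = 4, mass_tol = 1e-6))[1]
  bs <- bootstrap_timescales(s_half, n_resamples = 50, n_eigs = 4,
                             mass_tol = 1e-6, seed = 3)
  expect_lt(abs(t_full - t_half), 3 * attr(bs, "se")[1])
})

test_that("singular reaction-coordinate samples are skipped and counted", {
  x <- rbind(c(0, 0), matrix(rnorm(400), ncol = 2)) # origin kills atan2 J
  tr <- trajectory(x, dt = 0.1)
  basis <- gaussian_basis(seq(-3, 3, 1), 0.5)
  m <- make_model("overdamped", lemon_slice_potential(), 1, 1)
  sys <- assemble_reversible(tr, rc_polar_angle(), basis, m)
  expect_equal(sys$n_dropped, 1L)
  expect_equal(sys$n_samples, 200L)
  expect_error(assemble_reversible(tr, rc_polar_angle(), basis, m,
                                   on_singular = "abort"), "non-finite")
})

test_that("km offset validation catches bad offsets", {
  tr <- ou_traj()
  basis <- hermite_basis(3)
  expect_error(assemble_km(tr, rc_select(1L, 2L), basis, 0.00151),
               "multiple of dt")
  expect_error(assemble_km(tr, rc_select(1L, 2L), basis, 1e6), "exceeds")
})
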