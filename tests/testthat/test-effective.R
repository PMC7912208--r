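test_that("km differences are zero for constant maps and wrap across the cut", {
  tr <- trajectory(random_points(100, 2, seed = 41), dt = 0.1)
  rc_const <- reaction_coordinate(
    map = function(x) matrix(1, nrow(x), 1),
    jacobian = function(x) array(0, c(nrow(x), 2, 1)),
    dim = 2L, name = "const")
  kd <- km_differences(tr, rc_const, 0.1)
  expect_equal(max(abs(kd$dz)), 0)
  # angular crossing: phi jumps from just below pi to just above -pi
  th <- c(3.10, 3.14, -3.12, -3.08)
  x <- cbind(cos(th), sin(th))
  kd2 <- km_differences(trajectory(x, dt = 1), rc_polar_angle(), 1)
  expect_true(all(abs(kd2$dz) < 0.1)) # net displacements, not ~2*pi jumps
})

test_that("OU conditional drift matches the closed-form transition mean", {
  # E[X_{t+s} | X_t = z] = z exp(-alpha s / gamma):
  # mean(ds)/s at z = 1, s = 0.5 is (exp(-0.5) - 1)/0.5 = -0.78694
  tr <- ou_traj()
  kd <- km_differences(tr, rc_select(1L, 2L), 0.5)
  sel <- abs(kd$z[, 1] - 1) < 0.05
  est <- mean(kd$dz[sel, 1]) / 0.5
  se <- sd(kd$dz[sel, 1]) / 0.5 / sqrt(sum(sel) / 500) # correlated samples
  expect_lt(abs(est - (exp(-0.5) - 1) / 0.5), 3 * se + 0.02)
})

test_that("binned KM estimates recover deterministic drift exactly", {
  c_ <- 0.7; dt <- 0.01
  x <- matrix((0:2000) * c_ * dt, ncol = 1)
  tr <- trajectory(x, dt = dt)
  rc <- rc_select(1L, 1L)
  for (s in c(dt, 5 * dt)) {
    kb <- km_binned(km_differences(tr, rc, s), n_bins = 10, min_count = 5)
    filled <- !is.na(kb$drift)
    expect_true(any(filled))
    expect_equal(unique(round(kb$drift[filled], 10)), c_)
    expect_equal(unique(round(kb$diffusion[filled], 10)), c_^2 * s)
  }
})

test_that("bins below min_count are masked rather than zero-filled", {
  set.seed(44)
  x <- matrix(c(rnorm(5000), rnorm(3, mean = 30)), ncol = 1)
  tr <- trajectory(x, dt = 1)
  kb <- km_binned(km_differences(tr, rc_select(1L, 1L), 1),
                  n_bins = 20, min_count = 50)
  expect_true(any(is.na(kb$drift)))
  expect_true(all(is.na(kb$drift[kb$counts < 50])))
  expect_error(km_binned(km_differences(tr, rc_select(1L, 1L), 1), n_bins = 1),
               "n_bins")
})

test_that("lemon-slice analytic effective coefficients have the stated shape", {
  eff <- lemon_effective_coefficients(1, 1, quadrature_n = 200)
  zg <- seq(-3, 3, length.out = 400)
  a <- eff$diffusion(zg)
  expect_lt(max(a) - min(a), 1e-10) # diffusion constant in the angle
  b <- eff$drift(zg)
  expect_equal(sum(abs(b)) > 0, TRUE)
  # the drift is the derivative of a periodic (even) function scaled by a
  # constant, so it is odd and integrates to zero over any symmetric arc
  zz <- seq(-2.9, 2.9, length.out = 2001)
  expect_lt(abs(pracma::trapz(zz, eff$drift(zz))), 1e-8)
  expect_equal(eff$drift(-zz), -eff$drift(zz))
  # four stable zeros: descending sign changes of the drift
  zz2 <- seq(-pi + 0.01, pi - 0.01, length.out = 4000)
  bb <- eff$drift(zz2)
  desc <- which(bb[-length(bb)] > 0 & bb[-1] <= 0)
  expect_equal(length(desc), 4L)
})

test_that("small-offset binned KM agrees with the analytic lemon coefficients", {
  tr <- lemon_traj()
  eff <- lemon_effective_coefficients(1, 1)
  kb <- km_binned(km_differences(tr, rc_polar_angle(), 1e-3),
                  n_bins = 30, min_count = 500)
  keep <- !is.na(kb$diffusion) & abs(kb$bin_centers) < 2.6
  expect_gt(sum(keep), 15)
  a_ref <- eff$diffusion(kb$bin_centers[keep])
  expect_lt(median(abs(kb$diffusion[keep] - a_ref) / a_ref), 0.1)
  b_ref <- eff$drift(kb$bin_centers[keep])
  # drift comparison on bins where the reference is well away from zero
  big <- abs(b_ref) > 2
  expect_lt(median(abs((kb$drift[keep][big] - b_ref[big]) / b_ref[big])), 0.25)
})

test_that("large offsets distort the lemon effective diffusion profile", {
  tr <- lemon_traj()
  flat <- function(s) {
    kb <- km_binned(km_differences(tr, rc_polar_angle(), s),
                    n_bins = 30, min_count = 500)
    keep <- !is.na(kb$diffusion) & abs(kb$bin_centers) < 2.4
    diff(range(kb$diffusion[keep])) / mean(kb$diffusion[keep])
  }
  expect_lt(flat(1e-3), 0.3)        # nearly constant at small offset
  expect_gt(flat(1.0), 2 * flat(1e-3)) # visibly non-constant at s = 1
})

test_that("multi-dimensional binning is rejected with a clear message", {
  tr <- trajectory(random_points(300, 2, seed = 45), dt = 1)
  kd <- km_differences(tr, rc_select(1:2, 2L), 1)
  expect_error(km_binned(kd), "one-dimensional")
})
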