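test_that("bundled potential gradients match finite differences", {
  pts2 <- random_points(20, 2, seed = 3)
  expect_lt(gradient_fd_error(ou_potential(1, 5), pts2), 1e-5)
  expect_lt(gradient_fd_error(double_well_potential(), pts2), 1e-5)
  # keep lemon-slice points away from the r = 0 and phi = pi singularities
  set.seed(4)
  r <- runif(20, 0.6, 1.6); phi <- runif(20, -2.6, 2.6)
  expect_lt(gradient_fd_error(lemon_slice_potential(),
                              cbind(r * cos(phi), r * sin(phi))), 1e-5)
  set.seed(5)
  xch <- matrix(rep(chain5_initial_state(), 10), 10, 15, byrow = TRUE) +
    matrix(rnorm(150, sd = 0.05), 10, 15)
  expect_lt(gradient_fd_error(chain5_potential(), xch), 1e-5)
})

test_that("lemon-slice energy diverges at the origin and the branch cut", {
  V <- lemon_slice_potential()$energy
  expect_gt(V(c(1e-4, 0)), 1e3)
  phi <- pi - 1e-4
  expect_gt(V(c(cos(phi), sin(phi))), 1e3)
  expect_lt(V(c(cos(pi / 4), sin(pi / 4))), 15)
})

test_that("overdamped drift and diffusion have the Langevin form", {
  m <- ou_model(1, 5, beta = 1, gamma = 1)
  expect_equal(as.numeric(m$drift(matrix(c(1, 1), 1))), c(-1, -5))
  expect_equal(m$diffusion_cov(c(0.3, -2)), 2 * diag(2))
  expect_true(m$uniformly_elliptic)
  m2 <- ou_model(1, 5, beta = 2, gamma = 4)
  expect_equal(m2$diffusion_cov(c(0, 0)), 0.25 * diag(2))
  expect_equal(as.numeric(m2$drift(matrix(c(1, 1), 1))), c(-0.25, -1.25))
})

test_that("underdamped diffusion acts on the momentum block only", {
  m <- make_model("underdamped", double_well_potential(),
                  beta = 0.4, gamma = 10)
  a <- m$diffusion_cov(rep(0, 4))
  expect_equal(a[1:2, 1:2], matrix(0, 2, 2))
  expect_equal(a[3:4, 3:4], 50 * diag(2)) # 2 gamma / beta = 50
  expect_false(m$uniformly_elliptic)
  # drift = (p, -grad V(q) - gamma p)
  b <- as.numeric(m$drift(matrix(c(1, 0, 0.5, -0.2), 1)))
  expect_equal(b[1:2], c(0.5, -0.2))
  expect_equal(b[3:4], c(-(12 - 10 + 1.5) - 10 * 0.5, -0 + 10 * 0.2))
})

test_that("parameter validation rejects bad inputs", {
  expect_error(make_model("overdamped", ou_potential(), beta = -1), "beta")
  expect_error(make_model("overdamped", ou_potential(), beta = 1, gamma = 0),
               "gamma")
  expect_error(make_model("banana", ou_potential(), 1, 1))
})

test_that("zero-noise Euler step is exact and seeded runs are reproducible", {
  m <- ou_model(1, 5)
  tr <- simulate_em(m, x0 = c(1, 0), dt = 0.1, n_steps = 1, seed = 1,
                    burn_in = 0, noise_factor = 0)
  expect_equal(tr[2, ], c(0.9, 0))
  a <- simulate_em(m, dt = 1e-3, n_steps = 2000, seed = 42)
  b <- simulate_em(m, dt = 1e-3, n_steps = 2000, seed = 42)
  expect_identical(unclass(a), unclass(b))
  c_ <- simulate_em(m, dt = 1e-3, n_steps = 2000, seed = 43)
  expect_false(identical(unclass(a), unclass(c_)))
})

test_that("R fallback stepper matches the compiled stepper deterministically", {
  pot <- ou_potential(1, 5)
  pot_r <- potential("quadratic_r", 2L, pot$energy, pot$gradient,
                     pot$parameters, minimum = c(0, 0)) # no cpp id
  m_cpp <- make_model("overdamped", pot, 1, 1)
  m_r <- make_model("overdamped", pot_r, 1, 1)
  t1 <- simulate_em(m_cpp, x0 = c(1, 0.5), dt = 0.01, n_steps = 50, seed = 9,
                    burn_in = 0, noise_factor = 0)
  t2 <- simulate_em(m_r, x0 = c(1, 0.5), dt = 0.01, n_steps = 50, seed = 9,
                    burn_in = 0, noise_factor = 0)
  expect_equal(as.numeric(t1), as.numeric(t2), tolerance = 1e-12)
})

test_that("simulation aborts with a step index on divergence", {
  # negative-curvature quadratic -> deterministic blow-up
  pot <- potential("unstable", 1L,
                   energy = function(x) -50 * x[, 1]^2,
                   gradient = function(x) matrix(-100 * x[, 1], ncol = 1),
                   minimum = 1)
  m <- make_model("overdamped", pot, 1, 1)
  expect_error(simulate_em(m, x0 = 1, dt = 1, n_steps = 50, seed = 1,
                           burn_in = 0, guard = 1e4),
               "diverged at step")
})

test_that("OU invariant statistics are recovered by long runs", {
  tr <- ou_traj()
  vx <- var(tr[, 1]); vy <- var(tr[, 2])
  # var(x) = 1/(beta alpha_x) = 1, var(y) = 1/5; allow 3 effective-SE slack
  # (samples are correlated; relaxation times are 1 and 0.2 time units)
  n_eff_x <- nrow(tr) * 1e-3 / (2 * 1)
  se_x <- sqrt(2 / n_eff_x) * 1
  expect_lt(abs(vx - 1), 3 * se_x)
  n_eff_y <- nrow(tr) * 1e-3 / (2 * 0.2)
  se_y <- sqrt(2 / n_eff_y) * 0.2
  expect_lt(abs(vy - 0.2), 3 * se_y)
})

test_that("long-run OU histogram passes a chi-square GOF test at 1%", {
  tr <- ou_traj()
  x <- tr[, 1]
  # thin to weaken autocorrelation (relaxation time 1 = 1000 steps)
  x <- x[seq(1, length(x), by = 2000)]
  edges <- qnorm(seq(0, 1, length.out = 21)) # 20 equiprobable N(0,1) bins
  counts <- table(cut(x, edges))
  p <- suppressWarnings(chisq.test(as.numeric(counts),
                                   p = rep(1 / 20, 20))$p.value)
  expect_gt(p, 0.01)
})

test_that("underdamped momenta equilibrate to variance 1/beta", {
  m <- make_model("underdamped", double_well_potential(),
                  beta = 0.4, gamma = 10)
  tr <- cached_traj("ul_dw_short", function()
    simulate_em(m, dt = 1e-3, n_steps = 4e5, seed = 7))
  # momentum relaxation time ~ 1/gamma = 0.1 -> plenty of effective samples
  expect_equal(var(tr[, 3]), 2.5, tolerance = 0.05)
  expect_equal(var(tr[, 4]), 2.5, tolerance = 0.05)
})

test_that("generator_apply reproduces analytic generator values", {
  m <- ou_model(1, 5)
  pts <- random_points(25, 2, seed = 11)
  # f(x, y) = x is an eigenfunction with rate alpha_x / gamma = 1
  lf <- generator_apply(m,
                        f_grad = function(x) cbind(1, 0 * x[, 1]),
                        f_hess = function(x) matrix(0, 2, 2),
                        points = pts)
  expect_equal(lf, -pts[, 1])
  # constants map to zero
  lc <- generator_apply(m,
                        f_grad = function(x) 0 * x,
                        f_hess = function(x) matrix(0, 2, 2),
                        points = pts)
  expect_equal(lc, rep(0, nrow(pts)))
  # quadratic f = x^2: Lf = -2x^2 + a/2*2 = -2x^2 + 2 (beta=gamma=1)
  lq <- generator_apply(m,
                        f_grad = function(x) cbind(2 * x[, 1], 0),
                        f_hess = function(x) diag(c(2, 0)),
                        points = pts)
  expect_equal(lq, -2 * pts[, 1]^2 + 2)
})

test_that("underdamped generator of a position function is p . grad_q", {
  m <- make_model("underdamped", double_well_potential(), beta = 0.4,
                  gamma = 10)
  pts <- random_points(20, 4, seed = 12)
  lf <- generator_apply(m,
                        f_grad = function(x) cbind(1, 0, 0, 0) [rep(1, nrow(x)), ],
                        f_hess = function(x) matrix(0, 4, 4),
                        points = pts)
  expect_equal(lf, pts[, 3]) # L xi = p_x for xi(q, p) = q_x
})

test_that("quadratic form matches analytic values and is symmetric", {
  m <- ou_model(1, 5)
  gh <- pracma::gaussHermite(40)
  pts <- as.matrix(expand.grid(sqrt(2) * gh$x, sqrt(2 / 5) * gh$x))
  w <- as.numeric(outer(gh$w, gh$w)) / pi
  gx <- function(x) cbind(1, 0 * x[, 1])
  expect_equal(quadratic_form(m, gx, gx, pts, w), 1, tolerance = 1e-12)
  # symmetry on random polynomial pairs over MC points
  set.seed(13)
  pts_mc <- random_points(500, 2, seed = 13)
  gf <- function(x) cbind(2 * x[, 1], x[, 2]^2)
  gg <- function(x) cbind(x[, 2], 1 - x[, 1])
  expect_equal(quadratic_form(m, gf, gg, pts_mc),
               quadratic_form(m, gg, gf, pts_mc))
  mu <- make_model("underdamped", double_well_potential(), 0.4, 10)
  expect_error(quadratic_form(mu, gx, gx, random_points(5, 4)), "degenerate")
})

test_that("generator and quadratic-form estimators agree on shared samples", {
  m <- ou_model(1, 5)
  tr <- ou_traj()
  pts <- unclass(tr)[seq(1, nrow(tr), by = 5), ]
  gf <- function(x) cbind(1, 0 * x[, 1])
  f <- function(x) x[, 1]
  # <-L f, f> two ways (f = x): quadratic form vs -mean(f * Lf)
  q1 <- quadratic_form(m, gf, gf, pts)
  lf <- generator_apply(m, gf, function(x) matrix(0, 2, 2), pts)
  v <- -f(pts) * lf
  q2 <- mean(v)
  se <- sd(v) / sqrt(nrow(pts)) +
    2 * sd(f(pts)^2) / sqrt(nrow(pts)) # correlated-sample slack
  expect_lt(abs(q1 - q2), 3 * se)
})

test_that("trajectory IO round-trips exactly in both formats", {
  m <- ou_model()
  tr <- simulate_em(m, dt = 1e-3, n_steps = 200, seed = 77)
  for (fmt in c("text", "binary")) {
    f <- tempfile(fileext = if (fmt == "text") ".tsv" else ".bin")
    write_trajectory(tr, f, format = fmt)
    tr2 <- read_trajectory(f)
    expect_identical(dim(tr2), dim(tr))
    expect_identical(as.numeric(tr2), as.numeric(tr))
    expect_equal(attr(tr2, "dt"), attr(tr, "dt"))
    expect_equal(attr(tr2, "seed"), attr(tr, "seed"))
    expect_equal(attr(tr2, "model_name"), attr(tr, "model_name"))
    unlink(f)
  }
})
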