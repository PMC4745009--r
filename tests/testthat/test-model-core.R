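test_that("turn matrix matches known rotations and is orthogonal", {
  expect_equal(build_turn_matrix(0), diag(2))
  expect_equal(build_turn_matrix(pi),
               matrix(c(-1, 0, 0, -1), 2), tolerance = 1e-12)
  expect_equal(build_turn_matrix(pi / 2),
               matrix(c(0, 1, -1, 0), 2), tolerance = 1e-12)
  set.seed(1)
  for (th in runif(20, -10, 10)) {
    Tm <- build_turn_matrix(th)
    expect_equal(t(Tm) %*% Tm, diag(2), tolerance = 1e-12)
    expect_equal(det(Tm), 1, tolerance = 1e-12)
  }
  expect_error(build_turn_matrix(NaN), "finite")
})

test_that("process mean damps and rotates the previous displacement", {
  p0 <- function(g1) process_params(c(g1, 0), c(0, 0), diag(2), c(0.9, 0.1))
  expect_equal(process_mean(c(3, -2), 2, p0(0.5)), c(0, 0))
  expect_equal(process_mean(c(1, 0), 1, p0(1)), c(1, 0))
  expect_equal(process_mean(c(2, 0), 1, p0(0.95)), c(1.9, 0))
  # rotation by theta2 = pi reverses course
  pr <- process_params(c(0.9, 0.5), c(0, pi), diag(2), c(0.9, 0.1))
  expect_equal(process_mean(c(2, 2), 2, pr), c(-1, -1), tolerance = 1e-12)
  expect_error(process_mean(c(1, 1), 3, pr), "state")
})

test_that("process log-density matches the quadratic-form oracle", {
  prm <- process_params(c(0.95, 0.1), c(0, pi),
                        matrix(c(2, 0.5, 0.5, 1), 2), c(0.9, 0.1))
  # at the mode with identity covariance the density is 1/(2*pi)
  prm_i <- process_params(c(1, 0), c(0, 0), diag(2), c(0.9, 0.1))
  x_prev2 <- c(0, 0); x_prev <- c(1, 0)
  mode_x <- x_prev + process_mean(x_prev - x_prev2, 1, prm_i)
  expect_equal(process_logdensity(mode_x, x_prev, x_prev2, 1, prm_i),
               log(1 / (2 * pi)))
  # symmetric deviations about the mean give equal densities
  for (d in list(c(0.7, 0), c(0, 1.3), c(0.4, -0.9))) {
    expect_equal(
      process_logdensity(mode_x + d, x_prev, x_prev2, 1, prm_i),
      process_logdensity(mode_x - d, x_prev, x_prev2, 1, prm_i))
  }
  # arbitrary inputs vs independently coded density
  set.seed(42)
  for (i in 1:10) {
    xs <- matrix(rnorm(6, sd = 3), 3, 2)
    st <- sample(1:2, 1)
    mu <- process_mean(xs[2, ] - xs[1, ], st, prm)
    expect_equal(
      process_logdensity(xs[3, ], xs[2, ], xs[1, ], st, prm),
      oracle_dmvnorm2((xs[3, ] - xs[2, ]) - mu, prm$sigma))
  }
  # the density is maximised in x_t exactly at the process mean
  opt <- optim(mode_x + c(1, 1), function(z)
    -process_logdensity(z, x_prev, x_prev2, 1, prm_i))
  expect_equal(opt$par, mode_x, tolerance = 1e-3)
})

test_that("transition matrix is row-stochastic with the stated layout", {
  A <- build_transition_matrix(0.90, 0.10)
  expect_equal(A, rbind(c(0.90, 0.10), c(0.10, 0.90)))
  expect_equal(build_transition_matrix(1, 0), diag(2))
  expect_equal(build_transition_matrix(0.5, 0.5),
               matrix(0.5, 2, 2))
  set.seed(2)
  for (i in 1:20) {
    A <- build_transition_matrix(runif(1), runif(1))
    expect_equal(rowSums(A), c(1, 1), tolerance = 1e-12)
  }
  expect_error(build_transition_matrix(1.2, 0.5), "\\[0, 1\\]")
})

test_that("stationary distribution solves pi A = pi", {
  expect_equal(stationary_distribution(build_transition_matrix(0.9, 0.1)),
               c(0.5, 0.5))
  expect_equal(stationary_distribution(build_transition_matrix(0.5, 0.5)),
               c(0.5, 0.5))
  expect_equal(stationary_distribution(build_transition_matrix(0.8, 0.4)),
               c(2 / 3, 1 / 3))
  set.seed(3)
  for (i in 1:20) {
    A <- build_transition_matrix(runif(1, 0.01, 0.99), runif(1, 0.01, 0.99))
    p <- stationary_distribution(A)
    expect_equal(drop(p %*% A), p, tolerance = 1e-10)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  expect_error(stationary_distribution(diag(2)), "reducible|degenerate")
})

test_that("Gaussian observation density matches univariate-product oracle", {
  expect_equal(obs_logdensity_gaussian(c(1, 2), c(1, 2), diag(2)),
               log(1 / (2 * pi)))
  om <- diag(2) * 0.05^2
  y <- c(0.05, 0); x <- c(0, 0)
  expect_equal(obs_logdensity_gaussian(y, x, om),
               dnorm(0.05, 0, 0.05, log = TRUE) + dnorm(0, 0, 0.05, log = TRUE))
  # integrates to 1 over a fine grid
  g <- seq(-0.4, 0.4, length.out = 201)
  h <- diff(g)[1]
  dens <- outer(g, g, Vectorize(function(a, b)
    exp(obs_logdensity_gaussian(c(a, b), c(0, 0), om))))
  expect_equal(sum(dens) * h^2, 1, tolerance = 1e-3)
  expect_error(obs_logdensity_gaussian(c(1, 1), c(0, 0), matrix(0, 2, 2)),
               "singular|positive")
})

test_that("t observation density is a rescalable, heavy-tailed axis product", {
  y <- c(1.3, -0.4); x <- c(1, 0); tau <- c(0.3, 0.2)
  # psi = 1 leaves tau unchanged
  expect_equal(obs_logdensity_t(y, x, tau, nu = 3, psi = 1),
               obs_logdensity_t(y, x, tau, nu = 3))
  # psi rescales exactly like inflating tau
  expect_equal(obs_logdensity_t(y, x, tau, nu = 3, psi = 2),
               obs_logdensity_t(y, x, 2 * tau, nu = 3))
  # Normal limit as nu -> infinity
  expect_equal(obs_logdensity_t(y, x, tau, nu = 1e6),
               obs_logdensity_gaussian(y, x, diag(tau^2)), tolerance = 1e-3)
  # heavier tail for small nu at 10 tau from the centre
  far <- x + 10 * tau
  expect_gt(obs_logdensity_t(far, x, tau, nu = 2),
            obs_logdensity_t(far, x, tau, nu = 100))
  expect_error(obs_logdensity_t(y, x, c(-1, 1), 3), "positive")
  expect_error(obs_logdensity_t(y, x, tau, 3, psi = 0), "positive")
})

test_that("straight-line interpolation hits endpoints and midpoint", {
  expect_equal(interpolate_position(c(1, 2), c(5, 6), 0), c(1, 2))
  expect_equal(interpolate_position(c(1, 2), c(5, 6), 1), c(5, 6))
  expect_equal(interpolate_position(c(0, 0), c(2, 4), 0.5), c(1, 2))
  expect_error(interpolate_position(c(0, 0), c(1, 1), 1.2), "\\[0, 1\\]")
})

test_that("parameter constructors enforce their invariants", {
  expect_error(process_params(c(0.1, 0.9), c(0, pi), diag(2), c(0.9, 0.1)),
               "gamma")
  expect_error(process_params(c(0.9, 0.1), c(0, pi),
                              matrix(c(1, 2, 2, 1), 2), c(0.9, 0.1)),
               "positive definite")
  expect_error(process_params(c(0.9, 0.1), c(0, pi), diag(2), c(1.1, 0.1)),
               "probabilities")
  expect_error(obs_params("gps"), "omega")
  expect_error(obs_params("argos",
                          tau = data.frame(lc = "3", tau_x = -1, tau_y = 1,
                                           nu = 2)),
               "positive")
  expect_error(latent_path(matrix(0, 2, 2), c(1, 1)), "T >= 3")
  expect_error(latent_path(matrix(0, 4, 2), c(1, 2, 3, 1)), "state")
})
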