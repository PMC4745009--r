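test_that("retained-draw bookkeeping follows the burn-in/thinning arithmetic", {
  set.seed(31)
  for (i in 1:25) {
    n_iter <- sample(100:5000, 1)
    n_burnin <- sample(seq_len(n_iter - 10), 1)
    thin <- sample(1:25, 1)
    cfg <- fit_config("ssm", n_iter = n_iter, n_burnin = n_burnin,
                      thin = thin)
    # oracle: count the post-burn-in iterations that survive thinning
    oracle <- sum(seq_len(n_iter - n_burnin) %% thin == 0)
    expect_identical(unname(n_retained(cfg)["per_chain"]), oracle)
    expect_identical(unname(n_retained(cfg)["total"]), oracle * 2L)
  }
  expect_error(fit_config(n_iter = 100, n_burnin = 100), "n_burnin")
  expect_error(fit_config(n_chains = 1), "R-hat")
})

test_that("a fitted object honours the retained-draw count", {
  set.seed(32)
  prm <- table1_params()
  sims <- simulate_scenario(scenario_table1("large", "none", n_tracks = 1,
                                            track_length = 60, seed = 9))
  cfg <- fit_config("ssm", n_iter = 730, n_burnin = 301, thin = 7, seed = 2)
  f <- fit(sims[[1]], cfg)
  expect_equal(dim(f$draws)[1], (730 - 301) %/% 7)
  expect_equal(dim(f$draws)[3], 2)
  expect_true(all(f$states[[1]] %in% 1:2))
})

test_that("chain initialisation is over-dispersed yet deterministic", {
  sims <- simulate_scenario(scenario_table1("large", "gps", n_tracks = 2,
                                            track_length = 40, seed = 3))
  cfg <- fit_config("hssm", obs = obs_params("gps", omega = diag(2) * 0.05^2),
                    seed = 77)
  prepared <- lapply(jointssm:::as_track_list(sims),
                     jointssm:::prepare_track, obs = cfg$obs, time_step = 1)
  i1 <- initialize_chain(prepared, cfg, 1)
  i1b <- initialize_chain(prepared, cfg, 1)
  i2 <- initialize_chain(prepared, cfg, 2)
  expect_identical(i1, i1b)
  expect_false(identical(i1$params, i2$params))
  # parameters start inside the prior support
  expect_true(i1$params$gamma[1] > i1$params$gamma[2])
  expect_true(abs(i1$params$theta[1]) < pi / 2)
  # both behavioural states represented in the initial sequence
  for (tr in i1$tracks) expect_setequal(sort(unique(tr$b0)), 1:2)
})

test_that("joint log posterior equals a hand-summed term-by-term oracle", {
  set.seed(34)
  y <- matrix(rnorm(8, sd = 2), 4, 2)
  track <- data.frame(time_h = 0:3, x_km = y[, 1], y_km = y[, 2])
  om <- diag(2) * 0.05^2
  cfg <- fit_config("ssm", time_step = 1, obs = obs_params("gps", omega = om))
  x <- y + matrix(rnorm(8, sd = 0.05), 4, 2)
  b <- c(1L, 2L, 2L, 1L)
  prm <- process_params(c(0.9, 0.2), c(0.1, 3), diag(2) * 4, c(0.8, 0.3))
  lp <- joint_log_posterior(list(list(x = x, b = b)),
                            list(process = prm), track, cfg)
  # oracle: enumerate every term with independent arithmetic
  A <- rbind(c(0.8, 0.2), c(0.3, 0.7))
  pi0 <- c(0.3, 0.2) / 0.5
  rot <- function(th) rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  proc <- 0
  for (t in 3:4) {
    mu <- prm$gamma[b[t]] * rot(prm$theta[b[t]]) %*% (x[t - 1, ] - x[t - 2, ])
    proc <- proc + oracle_dmvnorm2((x[t, ] - x[t - 1, ]) - mu, prm$sigma)
  }
  chain <- log(pi0[b[1]]) + log(A[b[1], b[2]]) + log(A[b[2], b[3]]) +
    log(A[b[3], b[4]])
  obs <- sum(vapply(1:4, function(t)
    oracle_dmvnorm2(y[t, ] - x[t, ], om), numeric(1)))
  anchors <- sum(dnorm(x[1, ], y[1, ], 50, log = TRUE)) +
    sum(dnorm(x[2, ], y[1, ], 50, log = TRUE))
  prior <- -log(0.9) - 2 * log(pi) - log(2) +
    sum(log(2) + dt(2 / 10, 3, log = TRUE) - log(10),
        log(2) + dt(2 / 10, 3, log = TRUE) - log(10))
  expect_equal(lp, proc + chain + obs + anchors + prior)

  # additivity: a second independent track adds exactly its own terms
  y2 <- matrix(rnorm(8, sd = 2), 4, 2)
  track2 <- data.frame(time_h = 0:3, x_km = y2[, 1], y_km = y2[, 2])
  x2 <- y2
  b2 <- c(2L, 2L, 1L, 1L)
  lp12 <- joint_log_posterior(list(list(x = x, b = b), list(x = x2, b = b2)),
                              list(process = prm), list(track, track2), cfg)
  lp2_only <- joint_log_posterior(list(list(x = x2, b = b2)),
                                  list(process = prm), track2, cfg)
  expect_equal(lp12 - lp, lp2_only - prior)

  # out-of-support parameters give -Inf, not an exception
  bad <- process_params(c(0.9, 0.2), c(0.1, 3), diag(2) * 4, c(0.8, 0.3))
  bad$gamma <- c(0.2, 0.9)
  expect_identical(joint_log_posterior(list(list(x = x, b = b)),
                                       list(process = bad), track, cfg),
                   -Inf)
})

test_that("conditional state draws match exact enumeration", {
  tp <- toy_path(6)
  draws <- sample_states_conditional(tp$x, tp$params, n_draws = 1e4)
  exact <- oracle_state_marginals(tp$x, tp$params)
  emp <- colMeans(draws == 2)
  expect_lt(max(abs(emp - exact)), 0.02)

  # uninformative emissions: marginals revert to the chain's stationary law
  x_flat <- matrix(1, 8, 2)
  prm <- process_params(c(0.9, 0.1), c(0, pi), diag(2), c(0.8, 0.4))
  d2 <- sample_states_conditional(x_flat, prm, n_draws = 1e4)
  pi0 <- stationary_distribution(build_transition_matrix(0.8, 0.4))
  expect_lt(max(abs(colMeans(d2 == 1) - pi0[1])), 3 * sqrt(0.25 / 1e4) + 0.01)

  # absorbing chain: every draw is a constant sequence
  prm_abs <- process_params(c(0.9, 0.1), c(0, pi), diag(2), c(1, 0))
  d3 <- sample_states_conditional(tp$x, prm_abs, n_draws = 200)
  expect_true(all(apply(d3, 1, function(r) length(unique(r)) == 1)))
})

test_that("error-free joint fits recover the generating parameters", {
  sims <- simulate_scenario(scenario_table1("large", "none", n_tracks = 3,
                                            track_length = 150, seed = 41))
  cfg <- fit_config("hssm", n_iter = 3000, n_burnin = 1500, thin = 3,
                    seed = 8, obs = obs_params("none"))
  f <- fit(sims, cfg)
  pm <- apply(f$draws, 2, mean)
  expect_lt(abs(pm["gamma1"] - 0.95), 0.1)
  expect_lt(abs(pm["gamma2"] - 0.10), 0.1)
  expect_lt(abs(pm["alpha1"] - 0.90), 0.1)
  expect_lt(abs(pm["alpha2"] - 0.10), 0.1)
  # fixing parameters at truth and updating only states is the FFBS draw:
  # posterior mean states correlate strongly with truth
  s <- summarise_states(f, 1)
  expect_gt(cor(s$mean, sims[[1]]$truth$b), 0.5)
})

test_that("hSSM on a single individual reproduces the SSM posterior", {
  sims <- simulate_scenario(scenario_table1("large", "none", n_tracks = 1,
                                            track_length = 100, seed = 55))
  cfg_s <- fit_config("ssm", n_iter = 2000, n_burnin = 1000, thin = 2,
                      seed = 12, obs = obs_params("none"))
  cfg_h <- fit_config("hssm", n_iter = 2000, n_burnin = 1000, thin = 2,
                      seed = 12, obs = obs_params("none"))
  fs <- fit(sims[[1]], cfg_s)
  fh <- fit(sims, cfg_h)
  # identical pooling over a singleton: same sampler path, same posterior
  expect_identical(fs$draws, fh$draws)
  # and with a different seed, overlapping 95% intervals per parameter
  cfg_h$seed <- 13
  fh2 <- fit(sims, cfg_h)
  for (p in c("gamma1", "gamma2", "alpha1", "alpha2")) {
    i1 <- hpdi(as.vector(fs$draws[, p, ]))
    i2 <- hpdi(as.vector(fh2$draws[, p, ]))
    expect_true(i1[1] <= i2[2] && i2[1] <= i1[2])
  }
})

test_that("irregular heavy-tailed tracks fit on a coarser latent grid", {
  set.seed(61)
  prm <- table1_params()
  p <- simulate_path(121, prm)
  tru <- irregularize(p, mean_rate = 8.5)
  ap <- obs_params("argos", tau = argos_error_classes())
  o <- add_argos_noise(tru, ap)
  cfg <- fit_config("ssm", time_step = 6, n_iter = 1500, n_burnin = 700,
                    thin = 2, seed = 4, obs = ap)
  f <- fit(o, cfg)
  T_lat <- dim(f$states[[1]])[2]
  expect_gte(T_lat, floor(120 / 6))
  expect_true(all(f$states[[1]] %in% 1:2))
  expect_true(all(is.finite(f$draws)))
  expect_equal(dim(f$x_mean[[1]]), c(T_lat, 2))
  # the latent path tracks the coarse shape of the truth
  grid_idx <- seq(1, 121, by = 6)[seq_len(T_lat)]
  expect_gt(cor(f$x_mean[[1]][, 1], p$x[grid_idx, 1]), 0.9)
})

test_that("psi concentrates near 1 when data use the packaged scales", {
  sims <- simulate_scenario(scenario_table1("large", "argos", n_tracks = 3,
                                            track_length = 120, seed = 71))
  cfg <- fit_config("hssm", n_iter = 4000, n_burnin = 2000, thin = 2,
                    seed = 5,
                    obs = obs_params("argos", tau = argos_error_classes()))
  f <- fit(sims, cfg)
  psi_means <- apply(f$draws[, c("psi_1", "psi_2", "psi_3"), ], 2, mean)
  expect_lt(abs(mean(psi_means) - 1), 0.25)
  expect_true(all(psi_means > 0.4 & psi_means < 1.8))
})
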