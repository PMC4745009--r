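#' MCMC configuration for SSM / hSSM fits
#'
#' @param model_form `"ssm"` fits each track separately with its own
#'   movement parameters; `"hssm"` fits all tracks jointly with shared
#'   movement parameters (behavioural states and latent locations are always
#'   individual-level, as is `psi` under Argos errors).
#' @param time_step latent time-step duration in hours (1 for hourly
#'   simulated data; 6 is typical for irregular satellite data).
#' @param n_chains number of independent chains (>= 2, needed for R-hat).
#' @param n_iter iterations per chain.
#' @param n_burnin burn-in iterations discarded per chain (< `n_iter`).
#' @param thin thinning interval (>= 1); `floor((n_iter - n_burnin)/thin)`
#'   draws are retained per chain.
#' @param seed integer root seed; chain `c` uses a substream derived from
#'   `(seed, c)`.
#' @param priors prior specification, see [default_priors()].
#' @param obs an [obs_params()] describing the error regime of the tracks.
#' @param monitor parameter names used for convergence summaries.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(model_form = c("ssm", "hssm"), time_step = 1,
                       n_chains = 2, n_iter = 10000, n_burnin = 5000,
                       thin = 5, seed = 1L, priors = default_priors(),
                       obs = obs_params("none"),
                       monitor = c("gamma1", "gamma2", "theta1", "theta2",
                                   "alpha1", "alpha2")) {
  model_form <- match.arg(model_form)
  if (n_burnin >= n_iter) stop("`n_burnin` must be < `n_iter`", call. = FALSE)
  if (thin < 1) stop("`thin` must be >= 1", call. = FALSE)
  if (n_chains < 2) stop("`n_chains` must be >= 2 (required for R-hat)",
                         call. = FALSE)
  if (time_step <= 0) stop("`time_step` must be > 0", call. = FALSE)
  structure(list(model_form = model_form, time_step = time_step,
                 n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed), priors = priors, obs = obs,
                 monitor = monitor),
            class = "fit_config")
}

#' Default priors for the switching CRW state-space model
#'
#' Switching probabilities `alpha1`, `alpha2` get Beta(1, 1) priors. Move
#' persistence is given the ordered prior `gamma1 ~ U(0, 1)`,
#' `gamma2 | gamma1 ~ U(0, gamma1)`, which enforces the identifiability
#' constraint `gamma1 > gamma2` and prevents label switching. Turn angles
#' are uniform on state-specific ranges: `theta1 ~ U(-pi/2, pi/2)` (transient
#' movement is near-straight) and `theta2 ~ U(pi/2, 3*pi/2)` (ARS movement
#' tends to reverse). The process covariance is parameterised as per-axis
#' SDs with half-t(3) priors of scale `sigma_scale` km and a correlation
#' uniform on (-1, 1). The Argos rescale `psi` is uniform on
#' `(0, psi_max)` per individual. The first two latent locations get vague
#' Gaussian priors of SD `xinit_sd` km centred on the first observation.
#'
#' @param sigma_scale half-t scale for the process SDs (km).
#' @param psi_max upper bound of the uniform prior on `psi`.
#' @param xinit_sd SD (km) of the vague prior anchoring `x[1]`, `x[2]`.
#' @return Named list of prior settings.
#' @export
default_priors <- function(sigma_scale = 10, psi_max = 10, xinit_sd = 50) {
  list(sigma_scale = sigma_scale, psi_max = psi_max,
       theta1_lo = -pi / 2, theta1_hi = pi / 2,
       theta2_lo = pi / 2, theta2_hi = 3 * pi / 2,
       xinit_sd = xinit_sd)
}

#' Retained-draw bookkeeping
#'
#' Number of posterior draws retained after burn-in and thinning:
#' `floor((n_iter - n_burnin) / thin)` per chain, times `n_chains` in total.
#'
#' @param config a [fit_config()].
#' @return Named vector with elements `per_chain` and `total`.
#' @export
n_retained <- function(config) {
  per <- (config$n_iter - config$n_burnin) %/% config$thin
  c(per_chain = per, total = per * config$n_chains)
}

# ---- track preparation -----------------------------------------------------

# Normalise assorted track inputs into a list of observation data frames
# with columns time_h, x_km, y_km, lc.
as_track_list <- function(tracks) {
  if (inherits(tracks, "simulated_track")) tracks <- list(tracks)
  if (is.data.frame(tracks)) {
    if ("id" %in% names(tracks) && length(unique(tracks$id)) > 1) {
      tracks <- split(tracks, tracks$id)
    } else tracks <- list(tracks)
  }
  lapply(tracks, function(tr) {
    if (inherits(tr, "simulated_track")) tr <- tr$observations
    tr <- as.data.frame(tr)
    if (!all(c("time_h", "x_km", "y_km") %in% names(tr)))
      stop("each track needs columns time_h, x_km, y_km", call. = FALSE)
    if (is.null(tr$lc)) tr$lc <- NA_character_
    tr[order(tr$time_h), c("time_h", "x_km", "y_km", "lc")]
  })
}

# Build the per-track data structure consumed by the C++ sampler.
prepare_track <- function(obs_df, obs, time_step) {
  m <- map_observations_to_steps(obs_df$time_h, obs_df$time_h[1], time_step)
  T_ <- max(attr(m, "n_steps"), 3L)
  obs_code <- match(obs$regime, c("none", "gps", "argos")) - 1L
  if (obs_code == 0L) {
    if (any(m$j != 0) || !identical(sort(unique(m$t)), seq_len(T_)))
      stop("error-free regime requires one observation at every grid time",
           call. = FALSE)
  }
  tau <- matrix(0, nrow(obs_df), 2)
  nu <- rep(1, nrow(obs_df))
  if (obs_code == 2L) {
    if (anyNA(obs_df$lc))
      stop("argos regime requires a location class for every observation",
           call. = FALSE)
    i <- match(as.character(obs_df$lc), obs$tau$lc)
    if (anyNA(i))
      stop("unknown Argos location class in track: ",
           paste(unique(obs_df$lc[is.na(i)]), collapse = ", "), call. = FALSE)
    tau <- cbind(obs$tau$tau_x[i], obs$tau$tau_y[i])
    nu <- obs$tau$nu[i]
  }
  # linear interpolation of observations onto the regular grid: baseline
  # latent path (exact for the error-free regime)
  grid_h <- (seq_len(T_) - 1) * time_step
  rel <- obs_df$time_h - obs_df$time_h[1]
  x0 <- cbind(stats::approx(rel, obs_df$x_km, xout = grid_h, rule = 2)$y,
              stats::approx(rel, obs_df$y_km, xout = grid_h, rule = 2)$y)
  list(y = as.matrix(obs_df[, c("x_km", "y_km")]),
       tidx0 = m$t - 1L, j = m$j, T = T_, obs_code = obs_code,
       tau = tau, nu = nu, x_base = x0,
       anchor1 = as.numeric(obs_df[1, c("x_km", "y_km")]),
       anchor2 = as.numeric(obs_df[1, c("x_km", "y_km")]))
}

#' Over-dispersed chain initialisation
#'
#' Draws initial parameter values independently from their priors for each
#' chain (ensuring the over-dispersion assumed by the R-hat diagnostic),
#' initialises latent locations from linearly interpolated observations plus
#' chain-specific jitter, and assigns initial states by thresholding
#' empirical step lengths at their median (long steps start in the transient
#' state). Deterministic given `(config$seed, chain_index)`.
#'
#' @param prepared list of prepared tracks (internal structure built by
#'   [fit()]; exposed mainly for testing).
#' @param config a [fit_config()].
#' @param chain_index chain number (1-based).
#' @return List with elements `params` (gamma, theta, alpha, sigma, psi) and
#'   per-track `x0`, `b0`.
#' @keywords internal
#' @export
initialize_chain <- function(prepared, config, chain_index) {
  set.seed((config$seed * 1009L + chain_index) %% 2147483647L)
  pr <- config$priors
  g1 <- runif(1)
  g2 <- g1 * runif(1)
  th1 <- runif(1, pr$theta1_lo, pr$theta1_hi)
  th2 <- runif(1, pr$theta2_lo, pr$theta2_hi)
  a1 <- runif(1)
  a2 <- runif(1)
  # half-t(3) prior draws for the SDs, capped to keep initial adaptation
  # numerically sane (the cap excises ~1% of prior mass)
  sx <- min(abs(stats::rt(1, 3)) * pr$sigma_scale, 5 * pr$sigma_scale)
  sy <- min(abs(stats::rt(1, 3)) * pr$sigma_scale, 5 * pr$sigma_scale)
  sx <- max(sx, 0.01)
  sy <- max(sy, 0.01)
  rho <- runif(1, -0.9, 0.9)
  psi <- pmax(runif(length(prepared), 0, pr$psi_max), 0.1)
  tracks_init <- lapply(prepared, function(tr) {
    x0 <- tr$x_base
    if (tr$obs_code != 0L)
      x0 <- x0 + matrix(rnorm(length(x0), 0, 0.1), nrow(x0), 2)
    step <- sqrt(rowSums(diff(x0)^2))
    b0 <- c(1L, ifelse(step >= median(step), 1L, 2L))
    list(x0 = x0, b0 = b0)
  })
  list(params = list(gamma = c(g1, g2), theta = c(th1, th2),
                     alpha = c(a1, a2), sigma = c(sx, sy, rho), psi = psi),
       tracks = tracks_init)
}

# ---- fitting ---------------------------------------------------------------

#' Fit the switching CRW state-space model by MCMC
#'
#' Runs `n_chains` independent Metropolis-within-Gibbs chains: exact
#' forward-filtering backward-sampling updates for the behavioural states,
#' conjugate (Metropolis-corrected) Beta updates for the switching
#' probabilities, and adaptive random-walk Metropolis updates for the
#' remaining parameters and, under observation error, the latent locations.
#' Proposal adaptation is frozen at the end of burn-in.
#'
#' With `model_form = "hssm"` all tracks are fitted jointly, sharing the
#' movement parameters (`gamma`, `theta`, `alpha`, `sigma`); states, latent
#' locations, and `psi` remain individual-level. With `model_form = "ssm"`
#' and several tracks, each track is fitted separately and a list of fits is
#' returned.
#'
#' @param tracks a track data frame (`time_h`, `x_km`, `y_km`, optional
#'   `lc`, optional `id`), a `simulated_track`, or a list of either.
#' @param config a [fit_config()].
#' @return An `ssm_fit` object (or an `ssm_fit_list` for `"ssm"` with
#'   several tracks) with elements:
#'   \describe{
#'     \item{draws}{array `n_retained x n_params x n_chains` of parameter
#'       draws.}
#'     \item{states}{per-track list of `n_retained x T x n_chains` integer
#'       arrays of behavioural-state draws.}
#'     \item{x_mean}{per-track posterior mean latent path (T x 2, km).}
#'     \item{rhat}{potential scale reduction factors for monitored
#'       parameters.}
#'   }
#' @export
fit <- function(tracks, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  obs_list <- as_track_list(tracks)
  if (config$model_form == "ssm" && length(obs_list) > 1) {
    fits <- lapply(seq_along(obs_list), function(k) {
      cfg <- config
      cfg$seed <- (config$seed + 7919L * k) %% 2147483647L
      fit_joint(obs_list[k], cfg)
    })
    return(structure(fits, class = "ssm_fit_list"))
  }
  fit_joint(obs_list, config)
}

fit_joint <- function(obs_list, config) {
  prepared <- lapply(obs_list, prepare_track, obs = config$obs,
                     time_step = config$time_step)
  M <- length(prepared)
  fixed <- list(x_scale0 = 0.5)
  if (config$obs$regime == "gps") {
    om <- config$obs$omega
    sds <- sqrt(diag(om))
    fixed <- list(omega_sd = c(sds, om[1, 2] / prod(sds)),
                  x_scale0 = max(mean(sds), 1e-3))
  } else if (config$obs$regime == "argos") {
    fixed <- list(x_scale0 = max(stats::median(config$obs$tau$tau_x) / 2,
                                 1e-3))
  }
  chains <- lapply(seq_len(config$n_chains), function(ch) {
    ini <- initialize_chain(prepared, config, ch)
    dat <- lapply(seq_len(M), function(m)
      c(prepared[[m]][c("y", "tidx0", "j", "T", "obs_code", "tau", "nu",
                        "anchor1", "anchor2")],
        ini$tracks[[m]][c("x0", "b0")]))
    run_switch_mcmc_cpp(dat, ini$params, config$priors, fixed,
                        config$n_iter, config$n_burnin, config$thin)
  })
  n_ret <- chains[[1]]$n_retained
  par_names <- c("gamma1", "gamma2", "theta1", "theta2", "alpha1", "alpha2",
                 "sigma_x", "sigma_y", "rho", paste0("psi_", seq_len(M)))
  draws <- array(NA_real_, c(n_ret, length(par_names), config$n_chains),
                 dimnames = list(NULL, par_names, NULL))
  for (ch in seq_len(config$n_chains)) draws[, , ch] <- chains[[ch]]$params
  states <- lapply(seq_len(M), function(m) {
    arr <- array(NA_integer_, c(n_ret, prepared[[m]]$T, config$n_chains))
    for (ch in seq_len(config$n_chains)) arr[, , ch] <- chains[[ch]]$states[[m]]
    arr
  })
  x_mean <- lapply(seq_len(M), function(m) {
    Reduce(`+`, lapply(chains, function(c) c$x_mean[[m]])) / config$n_chains
  })
  rh <- vapply(config$monitor, function(p)
    gelman_rubin(draws[, p, , drop = TRUE]), numeric(1))
  structure(list(draws = draws, states = states, x_mean = x_mean,
                 rhat = rh, config = config, n_retained = n_ret,
                 n_tracks = M),
            class = "ssm_fit")
}

#' @export
print.ssm_fit <- function(x, ...) {
  cat(sprintf("Switching CRW state-space model fit (%s)\n",
              x$config$model_form))
  cat(sprintf("  %d track(s), %d chains x %d retained draws\n",
              x$n_tracks, x$config$n_chains, x$n_retained))
  pm <- apply(x$draws, 2, mean)
  show <- intersect(x$config$monitor, names(pm))
  cat("  posterior means: ",
      paste(sprintf("%s=%.3f", show, pm[show]), collapse = ", "), "\n")
  cat(sprintf("  max R-hat (monitored): %.3f\n", max(x$rhat)))
  invisible(x)
}

#' Exact conditional draws of the behavioural state sequence
#'
#' Draws state sequences from their exact full conditional distribution
#' given a fixed latent path and fixed parameters, by forward filtering and
#' backward sampling over the two-state chain with the CRW process densities
#' as emissions. The initial state follows the stationary distribution of
#' the transition matrix.
#'
#' @param x T x 2 matrix of (fixed) locations, km.
#' @param params a [process_params()].
#' @param n_draws number of independent sequences to draw.
#' @return `n_draws x T` integer matrix of states in `{1, 2}`.
#' @export
sample_states_conditional <- function(x, params, n_draws = 1) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 3, ncol(x) == 2)
  sg <- params$sigma
  sds <- sqrt(diag(sg))
  ffbs_draws_cpp(x, params$gamma, params$theta,
                 c(sds, sg[1, 2] / prod(sds)), params$alpha, n_draws)
}

# ---- reference log posterior ----------------------------------------------

#' Joint log posterior of the switching CRW state-space model
#'
#' Reference (pure R) evaluation of the un-normalised joint log posterior:
#' process densities, behavioural-chain probabilities (stationary initial
#' state plus Markov transitions), observation densities appropriate to the
#' error regime (with straight-line interpolation for off-grid
#' observations), and log priors. Parameters outside the prior support give
#' `-Inf`. Used as the slow, transparent counterpart of the compiled
#' sampler.
#'
#' @param latents list per track with elements `x` (T x 2) and `b` (states).
#' @param params list with `process` (a [process_params()]) and optional
#'   `psi` (per-track rescales, Argos regime).
#' @param tracks a track input accepted by [fit()].
#' @param config a [fit_config()].
#' @return Scalar log posterior (un-normalised by the marginal likelihood).
#' @export
joint_log_posterior <- function(latents, params, tracks, config) {
  obs_list <- as_track_list(tracks)
  prepared <- lapply(obs_list, prepare_track, obs = config$obs,
                     time_step = config$time_step)
  pr <- config$priors
  pp <- params$process
  psi <- params$psi %||% rep(1, length(prepared))
  # prior support
  if (pp$gamma[1] <= pp$gamma[2] || any(pp$gamma < 0) || any(pp$gamma > 1) ||
      any(pp$alpha < 0) || any(pp$alpha > 1) ||
      pp$theta[1] <= pr$theta1_lo || pp$theta[1] >= pr$theta1_hi ||
      pp$theta[2] <= pr$theta2_lo || pp$theta[2] >= pr$theta2_hi ||
      any(psi <= 0) || any(psi >= pr$psi_max))
    return(-Inf)
  sds <- sqrt(diag(pp$sigma))
  rho <- pp$sigma[1, 2] / prod(sds)
  if (abs(rho) >= 1) return(-Inf)
  A <- build_transition_matrix(pp$alpha[1], pp$alpha[2])
  pi0 <- stationary_distribution(A)
  lp <- -log(pp$gamma[1]) - 2 * log(pi) +
    sum(log(2) + dt(sds / pr$sigma_scale, 3, log = TRUE) -
          log(pr$sigma_scale)) - log(2) -
    length(prepared) * log(pr$psi_max) * (config$obs$regime == "argos")
  for (m in seq_along(prepared)) {
    tr <- prepared[[m]]
    x <- as.matrix(latents[[m]]$x)
    b <- as.integer(latents[[m]]$b)
    T_ <- tr$T
    stopifnot(nrow(x) == T_, length(b) == T_)
    lp <- lp + log(pi0[b[1]])
    for (t in 2:T_) lp <- lp + log(A[b[t - 1], b[t]])
    for (t in 3:T_)
      lp <- lp + process_logdensity(x[t, ], x[t - 1, ], x[t - 2, ], b[t], pp)
    if (tr$obs_code != 0L) {
      lp <- lp +
        dnorm(x[1, 1], tr$anchor1[1], pr$xinit_sd, log = TRUE) +
        dnorm(x[1, 2], tr$anchor1[2], pr$xinit_sd, log = TRUE) +
        dnorm(x[2, 1], tr$anchor2[1], pr$xinit_sd, log = TRUE) +
        dnorm(x[2, 2], tr$anchor2[2], pr$xinit_sd, log = TRUE)
      for (i in seq_len(nrow(tr$y))) {
        t0 <- tr$tidx0[i] + 1L
        mu <- if (tr$j[i] > 0)
          interpolate_position(x[t0, ], x[t0 + 1L, ], tr$j[i]) else x[t0, ]
        lp <- lp + if (tr$obs_code == 1L)
          obs_logdensity_gaussian(tr$y[i, ], mu, config$obs$omega)
        else
          obs_logdensity_t(tr$y[i, ], mu, tr$tau[i, ], tr$nu[i], psi[m])
      }
    }
  }
  lp
}

`%||%` <- function(a, b) if (is.null(a)) b else a
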