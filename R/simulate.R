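#' Default Argos location-class error table
#'
#' Per-quality-class t-distribution error scales (`tau_x`, `tau_y`, km) and
#' degrees of freedom (`nu`) for the six standard Argos classes
#' (3, 2, 1, 0, A, B). The shipped table
#' (`extdata/argos_error_classes_synthetic.csv`) is a synthetic set of
#' representative values constructed for this package — magnitudes decrease
#' with nominal class quality and tails are heaviest for the low-quality
#' classes — not an empirically calibrated error model. Supply your own table
#' (same columns) whenever a validated one is available for your tags.
#'
#' @param path optional path to a replacement CSV with columns
#'   `lc, tau_x, tau_y, nu`.
#' @return Data frame with columns `lc`, `tau_x`, `tau_y`, `nu`.
#' @export
argos_error_classes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "argos_error_classes_synthetic.csv",
                        package = "jointssm", mustWork = TRUE)
  tab <- read.csv(path, colClasses = c(lc = "character"))
  need <- c("lc", "tau_x", "tau_y", "nu")
  if (!all(need %in% names(tab)))
    stop("Argos class table must have columns lc, tau_x, tau_y, nu",
         call. = FALSE)
  if (any(tab$tau_x <= 0) || any(tab$tau_y <= 0) || any(tab$nu <= 0))
    stop("all tau and nu must be positive", call. = FALSE)
  tab
}

#' Simulate a behavioural state sequence
#'
#' Draws a Markov chain of behavioural states with transition matrix `alpha`.
#'
#' @param length number of states to draw (>= 1).
#' @param alpha 2x2 row-stochastic transition matrix
#'   (see [build_transition_matrix()]).
#' @param initial_state state at time 1 (1 or 2).
#' @return Integer vector of states in `{1, 2}`.
#' @export
simulate_states <- function(length, alpha, initial_state = 1L) {
  if (length < 1) stop("`length` must be >= 1", call. = FALSE)
  alpha <- as.matrix(alpha)
  if (any(abs(rowSums(alpha) - 1) > 1e-9) || any(alpha < 0))
    stop("`alpha` must be row-stochastic", call. = FALSE)
  if (!initial_state %in% c(1, 2))
    stop("`initial_state` must be 1 or 2", call. = FALSE)
  b <- integer(length)
  b[1] <- as.integer(initial_state)
  if (length > 1) {
    u <- runif(length - 1)
    for (t in 2:length)
      b[t] <- if (u[t - 1] < alpha[b[t - 1], 1]) 1L else 2L
  }
  b
}

# one draw from N2(mu, cov) via Cholesky
rmvnorm2 <- function(mu, cov) {
  L <- chol(cov)
  drop(mu + t(L) %*% rnorm(2))
}

#' Simulate a switching-CRW movement path
#'
#' Generates a latent path under the two-state switching first-difference
#' CRW: states follow the behavioural Markov chain and each displacement is
#' drawn `d_t ~ N2(gamma_b * T(theta_b) %*% d_{t-1}, sigma)`. The path starts
#' at `origin` with an initial displacement drawn from `N2(0, sigma)`, and
#' the initial state is drawn from the stationary distribution of `alpha`
#' unless given.
#'
#' @param length number of locations T (>= 3).
#' @param params a [process_params()] object.
#' @param dt time step in hours (default 1).
#' @param origin starting location (km).
#' @param initial_state optional fixed state at time 1; default draws from
#'   the stationary distribution.
#' @return A [latent_path()] object.
#' @export
simulate_path <- function(length, params, dt = 1, origin = c(0, 0),
                          initial_state = NULL) {
  if (length < 3) stop("`length` must be >= 3", call. = FALSE)
  check_covariance(params$sigma, "sigma")
  alpha <- build_transition_matrix(params$alpha[1], params$alpha[2])
  if (is.null(initial_state)) {
    pi0 <- stationary_distribution(alpha)
    initial_state <- if (runif(1) < pi0[1]) 1L else 2L
  }
  b <- simulate_states(length, alpha, initial_state)
  x <- matrix(0, length, 2)
  x[1, ] <- origin
  d <- rmvnorm2(c(0, 0), params$sigma)
  x[2, ] <- x[1, ] + d
  for (t in 3:length) {
    mu <- process_mean(d, b[t], params)
    d <- rmvnorm2(mu, params$sigma)
    x[t, ] <- x[t - 1, ] + d
  }
  latent_path(x, b, dt)
}

#' Add Gaussian (GPS-like) observation error
#'
#' @param path a [latent_path()].
#' @param omega 2x2 positive semi-definite observation covariance (km^2);
#'   a zero matrix returns the truth unchanged.
#' @return Data frame with columns `time_h`, `x_km`, `y_km`, `lc` (NA).
#' @export
add_gps_noise <- function(path, omega) {
  omega <- as.matrix(omega)
  check_covariance(omega, "omega", strict = FALSE)
  T_ <- nrow(path$x)
  err <- matrix(0, T_, 2)
  if (any(omega != 0)) {
    L <- chol(omega + diag(1e-300, 2))
    err <- matrix(rnorm(2 * T_), T_, 2) %*% L
  }
  data.frame(time_h = (seq_len(T_) - 1) * path$dt,
             x_km = path$x[, 1] + err[, 1],
             y_km = path$x[, 2] + err[, 2],
             lc = NA_character_)
}

#' Add heavy-tailed (Argos-like) observation error
#'
#' Each observation receives a quality class drawn from `class_probs`; its
#' per-axis error is a location-scale t draw with scale `psi * tau_q` and
#' degrees of freedom `nu_q` for the drawn class.
#'
#' @param path a [latent_path()], or a data frame with columns
#'   `time_h`, `x_km`, `y_km` of true positions (e.g. from [irregularize()]).
#' @param obs an [obs_params()] with `regime = "argos"`.
#' @param class_probs named probability vector over the classes of the table
#'   (default uniform).
#' @return Data frame with columns `time_h`, `x_km`, `y_km`, `lc`.
#' @export
add_argos_noise <- function(path, obs, class_probs = NULL) {
  if (!identical(obs$regime, "argos"))
    stop("`obs` must have regime = \"argos\"", call. = FALSE)
  tab <- obs$tau
  if (nrow(tab) == 0) stop("empty Argos class table", call. = FALSE)
  if (is.null(class_probs))
    class_probs <- setNames(rep(1 / nrow(tab), nrow(tab)), tab$lc)
  if (abs(sum(class_probs) - 1) > 1e-8)
    stop("`class_probs` must sum to 1", call. = FALSE)
  if (!all(names(class_probs) %in% tab$lc))
    stop("`class_probs` names must match the class table", call. = FALSE)
  tru <- if (inherits(path, "latent_path")) {
    data.frame(time_h = (seq_len(nrow(path$x)) - 1) * path$dt,
               x_km = path$x[, 1], y_km = path$x[, 2])
  } else as.data.frame(path)
  n <- nrow(tru)
  lc <- sample(names(class_probs), n, replace = TRUE, prob = class_probs)
  i <- match(lc, tab$lc)
  ex <- obs$psi * tab$tau_x[i] * stats::rt(n, df = tab$nu[i])
  ey <- obs$psi * tab$tau_y[i] * stats::rt(n, df = tab$nu[i])
  data.frame(time_h = tru$time_h, x_km = tru$x_km + ex,
             y_km = tru$y_km + ey, lc = lc)
}

#' Resample a path at irregular Poisson-process times
#'
#' Emulates the irregular sampling of satellite fixes: observation times are
#' drawn as a Poisson process with the given mean daily rate over the span of
#' the path, and true positions at those times are obtained by straight-line
#' interpolation of the latent path (noise is added afterwards by the error
#' models).
#'
#' @param path a [latent_path()].
#' @param mean_rate mean number of observations per day (> 0).
#' @return Data frame with columns `time_h`, `x_km`, `y_km` of interpolated
#'   true positions at strictly increasing times.
#' @export
irregularize <- function(path, mean_rate) {
  if (mean_rate <= 0) stop("`mean_rate` must be > 0", call. = FALSE)
  T_ <- nrow(path$x)
  span_h <- (T_ - 1) * path$dt
  # Poisson process: exponential inter-arrival gaps, rate per hour
  rate_h <- mean_rate / 24
  times <- cumsum(rexp(ceiling(span_h * rate_h * 3) + 10, rate_h))
  times <- times[times < span_h]
  if (length(times) < 3)
    stop("sampling rate too low: fewer than 3 observations", call. = FALSE)
  step <- pmin(floor(times / path$dt) + 1, T_ - 1)
  j <- times / path$dt - (step - 1)
  xx <- (1 - j) * path$x[step, 1] + j * path$x[step + 1, 1]
  yy <- (1 - j) * path$x[step, 2] + j * path$x[step + 1, 2]
  data.frame(time_h = times, x_km = xx, y_km = yy)
}

#' Simulation scenario definition
#'
#' A scenario bundles the movement parameters, error regime, and replication
#' protocol of one cell of the simulation study. [scenario_table1()] builds
#' the canonical study cells: large (0.85) or small (0.55) difference in move
#' persistence between states, crossed with no error, GPS error, or Argos
#' error.
#'
#' @param delta_gamma_label `"large"` (gamma = 0.95 vs 0.10) or `"small"`
#'   (0.65 vs 0.10).
#' @param error_regime `"none"`, `"gps"`, or `"argos"`.
#' @param n_tracks number of replicate tracks.
#' @param track_length locations per track.
#' @param params a [process_params()]; built from `delta_gamma_label` by
#'   [scenario_table1()].
#' @param obs an [obs_params()] matching `error_regime`.
#' @param argos_class_probs optional named probability vector over Argos
#'   classes (default uniform over the error table's classes).
#' @param seed integer root seed for the scenario.
#' @return An object of class `scenario`.
#' @export
scenario <- function(delta_gamma_label, error_regime, n_tracks, track_length,
                     params, obs, argos_class_probs = NULL, seed = 1L) {
  stopifnot(track_length >= 3, n_tracks >= 1)
  error_regime <- match.arg(error_regime, c("none", "gps", "argos"))
  if (error_regime == "argos" && !is.null(argos_class_probs) &&
      abs(sum(argos_class_probs) - 1) > 1e-8)
    stop("`argos_class_probs` must sum to 1", call. = FALSE)
  structure(
    list(delta_gamma_label = delta_gamma_label, error_regime = error_regime,
         n_tracks = as.integer(n_tracks),
         track_length = as.integer(track_length), params = params, obs = obs,
         argos_class_probs = argos_class_probs, seed = as.integer(seed),
         id = paste0("dg-", delta_gamma_label, "_", error_regime)),
    class = "scenario"
  )
}

#' @rdname scenario
#' @param gps_sd GPS error SD per axis, km (study value 0.05).
#' @param sigma_sd process SD per axis, km (study value 5).
#' @export
scenario_table1 <- function(delta_gamma_label = c("large", "small"),
                            error_regime = c("none", "gps", "argos"),
                            n_tracks = 50, track_length = 200, seed = 1L,
                            gps_sd = 0.05, sigma_sd = 5,
                            argos_class_probs = NULL) {
  delta_gamma_label <- match.arg(delta_gamma_label)
  error_regime <- match.arg(error_regime)
  g1 <- if (delta_gamma_label == "large") 0.95 else 0.65
  params <- process_params(gamma = c(g1, 0.10), theta = c(0, pi),
                           sigma = diag(2) * sigma_sd^2,
                           alpha = c(0.90, 0.10))
  obs <- switch(error_regime,
    none = obs_params("none"),
    gps = obs_params("gps", omega = diag(2) * gps_sd^2),
    argos = obs_params("argos", tau = argos_error_classes()))
  scenario(delta_gamma_label, error_regime, n_tracks, track_length,
           params, obs, argos_class_probs, seed)
}

#' Simulate all tracks of a scenario
#'
#' Generates `n_tracks` independent truth-annotated tracks. Reproducible:
#' track `k` uses the deterministic substream seed
#' `(scenario seed * 10007 + k) mod 2^31`, so any single track can be
#' regenerated in isolation.
#'
#' @param scn a [scenario()].
#' @return List of `simulated_track` objects, each with elements `truth`
#'   (a [latent_path()]), `observations` (data frame `time_h, x_km, y_km,
#'   lc`), `scenario_id`, and `track_id`.
#' @export
simulate_scenario <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  lapply(seq_len(scn$n_tracks), function(k) {
    set.seed((scn$seed * 10007 + k) %% 2147483647)
    truth <- simulate_path(scn$track_length, scn$params)
    obsv <- switch(scn$error_regime,
      none = data.frame(time_h = (seq_len(scn$track_length) - 1) * truth$dt,
                        x_km = truth$x[, 1], y_km = truth$x[, 2],
                        lc = NA_character_),
      gps = add_gps_noise(truth, scn$obs$omega),
      argos = add_argos_noise(truth, scn$obs, scn$argos_class_probs))
    structure(list(truth = truth, observations = obsv,
                   scenario_id = scn$id,
                   track_id = sprintf("%s_t%02d", scn$id, k)),
              class = "simulated_track")
  })
}
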