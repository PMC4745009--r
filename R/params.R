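#' Movement-process parameters for the switching CRW
#'
#' Bundles the parameters of the two-state switching first-difference
#' correlated random walk: per-state move persistence `gamma`, per-state mean
#' turn angle `theta`, the shared process covariance `sigma`, and the
#' behavioural transition probabilities `alpha`.
#'
#' State 1 is the transient (fast, directionally persistent) state and state 2
#' the area-restricted search (ARS) state. For identifiability the transient
#' state must have the larger persistence: `gamma[1] > gamma[2]`.
#'
#' @param gamma numeric length 2, move persistence per state, each in
#'   `[0, 1]`, with `gamma[1] > gamma[2]`.
#' @param theta numeric length 2, mean turn angle per state in radians
#'   (counter-clockwise rotation of the previous displacement).
#' @param sigma 2x2 symmetric positive-definite process covariance (km^2).
#'   A single covariance is shared by both behavioural states.
#' @param alpha numeric length 2: `alpha[1]` is the probability of remaining
#'   in the transient state, `alpha[2]` the probability of switching from ARS
#'   to transient. The full 2x2 transition matrix is
#'   `rbind(c(a1, 1 - a1), c(a2, 1 - a2))`.
#'
#' @return An object of class `process_params`.
#' @seealso [build_transition_matrix()], [simulate_path()]
#' @examples
#' process_params(gamma = c(0.95, 0.10), theta = c(0, pi),
#'                sigma = diag(2) * 25, alpha = c(0.90, 0.10))
#' @export
process_params <- function(gamma, theta, sigma, alpha) {
  stopifnot(length(gamma) == 2, length(theta) == 2, length(alpha) == 2)
  if (!all(is.finite(gamma)) || any(gamma < 0) || any(gamma > 1))
    stop("each `gamma` must be finite and in [0, 1]", call. = FALSE)
  if (gamma[1] <= gamma[2])
    stop("identifiability requires gamma[1] (transient) > gamma[2] (ARS)",
         call. = FALSE)
  if (!all(is.finite(theta)))
    stop("`theta` must be finite", call. = FALSE)
  sigma <- as.matrix(sigma)
  check_covariance(sigma, "sigma")
  if (!all(is.finite(alpha)) || any(alpha < 0) || any(alpha > 1))
    stop("`alpha` entries must be probabilities in [0, 1]", call. = FALSE)
  structure(
    list(gamma = as.numeric(gamma), theta = as.numeric(theta),
         sigma = sigma, alpha = as.numeric(alpha)),
    class = "process_params"
  )
}

#' Observation-error parameters
#'
#' Describes the location-error regime attached to a track or scenario:
#' `"none"` (observations equal the true locations), `"gps"` (bivariate
#' Gaussian error with covariance `omega`), or `"argos"` (per-axis
#' location-scale t errors with per-quality-class scale `tau` and degrees of
#' freedom `nu`, plus a per-individual multiplicative rescale `psi` of the
#' scales).
#'
#' @param regime one of `"none"`, `"gps"`, `"argos"`.
#' @param omega 2x2 positive semi-definite observation covariance (km^2);
#'   required for `regime = "gps"`.
#' @param tau data frame with columns `lc`, `tau_x`, `tau_y` (km) giving the
#'   per-class error scales; required for `regime = "argos"`.
#' @param nu numeric vector of per-class degrees of freedom, parallel to the
#'   rows of `tau` (or a `nu` column inside `tau`).
#' @param psi positive rescale factor applied to all `tau` (default 1).
#'
#' @return An object of class `obs_params`.
#' @export
obs_params <- function(regime = c("none", "gps", "argos"),
                       omega = NULL, tau = NULL, nu = NULL, psi = 1) {
  regime <- match.arg(regime)
  if (!is.numeric(psi) || length(psi) != 1 || !is.finite(psi) || psi <= 0)
    stop("`psi` must be a single positive number", call. = FALSE)
  if (regime == "gps") {
    if (is.null(omega)) stop("`omega` is required for the gps regime",
                             call. = FALSE)
    omega <- as.matrix(omega)
    check_covariance(omega, "omega", strict = FALSE)
  }
  if (regime == "argos") {
    if (is.null(tau)) stop("`tau` is required for the argos regime",
                           call. = FALSE)
    tau <- as.data.frame(tau)
    if (!is.null(nu)) tau$nu <- nu
    need <- c("lc", "tau_x", "tau_y", "nu")
    if (!all(need %in% names(tau)))
      stop("`tau` must have columns lc, tau_x, tau_y, nu", call. = FALSE)
    if (nrow(tau) == 0) stop("empty Argos class table", call. = FALSE)
    if (any(tau$tau_x <= 0) || any(tau$tau_y <= 0) || any(tau$nu <= 0))
      stop("all tau and nu must be positive", call. = FALSE)
  }
  structure(list(regime = regime, omega = omega, tau = tau, psi = psi),
            class = "obs_params")
}

check_covariance <- function(m, name, strict = TRUE) {
  if (!is.matrix(m) || any(dim(m) != 2) || !all(is.finite(m)))
    stop(sprintf("`%s` must be a finite 2x2 matrix", name), call. = FALSE)
  if (abs(m[1, 2] - m[2, 1]) > 1e-8 * (1 + max(abs(m))))
    stop(sprintf("`%s` must be symmetric", name), call. = FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (strict && any(ev <= 0))
    stop(sprintf("`%s` must be positive definite", name), call. = FALSE)
  if (!strict && any(ev < -1e-10))
    stop(sprintf("`%s` must be positive semi-definite", name), call. = FALSE)
  invisible(m)
}

#' Latent path container
#'
#' A true movement path on a regular time grid: locations `x` (km) and
#' behavioural states `b` (1 = transient, 2 = ARS) with time step `dt` hours.
#'
#' @param x numeric T x 2 matrix of true locations (km).
#' @param b integer vector of length T of states in `{1, 2}`.
#' @param dt time-step duration in hours.
#' @return An object of class `latent_path`.
#' @export
latent_path <- function(x, b, dt = 1) {
  x <- as.matrix(x)
  b <- as.integer(b)
  if (ncol(x) != 2 || nrow(x) < 3)
    stop("`x` must be a T x 2 matrix with T >= 3", call. = FALSE)
  if (length(b) != nrow(x))
    stop("`x` and `b` must have equal length", call. = FALSE)
  if (!all(b %in% c(1L, 2L)))
    stop("every state must be 1 (transient) or 2 (ARS)", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  structure(list(x = x, b = b, dt = dt), class = "latent_path")
}
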