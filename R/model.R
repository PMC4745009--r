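#' Turn-angle rotation matrix
#'
#' Builds the 2x2 rotation matrix encoding the mean turn angle between
#' successive displacements of the correlated random walk. The convention is
#' a counter-clockwise rotation:
#' `T(theta) = rbind(c(cos, -sin), c(sin, cos))`.
#'
#' @param theta turn angle in radians.
#' @return A 2x2 orthogonal matrix with determinant 1.
#' @examples
#' build_turn_matrix(0)      # identity: straight-ahead persistence
#' build_turn_matrix(pi)     # course reversal, typical of ARS movement
#' @export
build_turn_matrix <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1 || !is.finite(theta))
    stop("`theta` must be a single finite number (radians)", call. = FALSE)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Expected next displacement of the switching CRW
#'
#' The first-difference CRW centres each displacement on a damped, rotated
#' copy of the previous one: `gamma_b * T(theta_b) %*% d_prev`.
#'
#' @param d_prev previous 2-D displacement (km).
#' @param state behavioural state, 1 or 2.
#' @param params a [process_params()] object.
#' @return Expected 2-D displacement (km).
#' @export
process_mean <- function(d_prev, state, params) {
  if (!state %in% c(1, 2)) stop("`state` must be 1 or 2", call. = FALSE)
  if (!all(is.finite(d_prev)) || length(d_prev) != 2)
    stop("`d_prev` must be a finite 2-vector", call. = FALSE)
  drop(params$gamma[state] * build_turn_matrix(params$theta[state]) %*% d_prev)
}

# log of the bivariate normal density, parameterised by covariance
dmvnorm2_log <- function(r, cov) {
  r <- as.numeric(r)
  det <- cov[1, 1] * cov[2, 2] - cov[1, 2] * cov[2, 1]
  if (!is.finite(det) || det <= 0)
    stop("covariance is singular or not positive definite", call. = FALSE)
  q <- (cov[2, 2] * r[1]^2 - 2 * cov[1, 2] * r[1] * r[2] +
          cov[1, 1] * r[2]^2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

#' Process log-density of one CRW step
#'
#' Log density of the displacement `x_t - x_prev` under the switching CRW:
#' bivariate Normal with mean [process_mean()] of the previous displacement
#' `x_prev - x_prev2` and covariance `sigma`.
#'
#' @param x_t,x_prev,x_prev2 2-D locations (km) at times t, t-1, t-2.
#' @inheritParams process_mean
#' @return Scalar log-density.
#' @export
process_logdensity <- function(x_t, x_prev, x_prev2, state, params) {
  stopifnot(all(is.finite(c(x_t, x_prev, x_prev2))))
  mu <- process_mean(x_prev - x_prev2, state, params)
  dmvnorm2_log((x_t - x_prev) - mu, params$sigma)
}

#' Behavioural-state transition matrix
#'
#' Assembles the 2x2 row-stochastic transition matrix of the behavioural
#' Markov chain from its two free probabilities: `alpha1`, the probability of
#' remaining in the transient state, and `alpha2`, the probability of
#' switching from ARS back to transient.
#'
#' @param alpha1,alpha2 probabilities in `[0, 1]`.
#' @return 2x2 matrix `rbind(c(alpha1, 1 - alpha1), c(alpha2, 1 - alpha2))`.
#' @export
build_transition_matrix <- function(alpha1, alpha2) {
  for (a in c(alpha1, alpha2))
    if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a < 0 || a > 1)
      stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  matrix(c(alpha1, alpha2, 1 - alpha1, 1 - alpha2), 2, 2)
}

#' Stationary distribution of the behavioural chain
#'
#' Solves `pi %*% A = pi` for the two-state chain in closed form. Used to
#' initialise simulated and sampled state sequences.
#'
#' @param alpha 2x2 row-stochastic transition matrix.
#' @return Probability pair `(P(state 1), P(state 2))`.
#' @export
stationary_distribution <- function(alpha) {
  alpha <- as.matrix(alpha)
  stopifnot(all(dim(alpha) == 2))
  if (any(abs(rowSums(alpha) - 1) > 1e-9) || any(alpha < 0))
    stop("`alpha` must be row-stochastic", call. = FALSE)
  s1 <- alpha[1, 2]  # switch rate out of state 1
  s2 <- alpha[2, 1]  # switch rate out of state 2
  if (s1 <= 0 && s2 <= 0)
    stop("chain is reducible: both states absorbing", call. = FALSE)
  if (s1 + s2 <= 0) stop("degenerate chain", call. = FALSE)
  c(s2, s1) / (s1 + s2)
}

#' Gaussian observation log-density (GPS-like error)
#'
#' @param y observed 2-D location (km).
#' @param x true 2-D location (km).
#' @param omega 2x2 positive-definite observation covariance (km^2).
#' @return Scalar log-density of `y` about `x`.
#' @export
obs_logdensity_gaussian <- function(y, x, omega) {
  omega <- as.matrix(omega)
  dmvnorm2_log(y - x, omega)
}

#' Heavy-tailed observation log-density (Argos-like error)
#'
#' Per-axis location-scale t errors: the two coordinate axes are independent
#' t variates centred at `x` with scales `psi * tau` and shared degrees of
#' freedom `nu`. Small `nu` gives the occasional very large errors typical of
#' Argos satellite fixes; `psi` is a per-individual rescaling of the fixed
#' per-class scales.
#'
#' @param y observed 2-D location (km).
#' @param x true 2-D location (km).
#' @param tau length-2 positive scale pair (km), one per axis.
#' @param nu degrees of freedom (> 0).
#' @param psi positive rescale factor (default 1).
#' @return Scalar log-density.
#' @export
obs_logdensity_t <- function(y, x, tau, nu, psi = 1) {
  if (any(tau <= 0) || nu <= 0 || psi <= 0)
    stop("`tau`, `nu` and `psi` must be positive", call. = FALSE)
  tau <- rep_len(tau, 2)
  sc <- psi * tau
  r <- (y - x) / sc
  sum(dt(r, df = nu, log = TRUE) - log(sc))
}

#' Straight-line interpolation between latent locations
#'
#' Position a fraction `j` of the way from `x_prev` to `x_curr`; links
#' irregularly timed observations to the regular latent grid under the
#' assumption of straight-line travel within a time step.
#'
#' @param x_prev,x_curr 2-D locations (km).
#' @param j fraction of the time step elapsed, in `[0, 1]`.
#' @return Interpolated 2-D location (km).
#' @export
interpolate_position <- function(x_prev, x_curr, j) {
  if (!is.numeric(j) || length(j) != 1 || is.na(j) || j < 0 || j > 1)
    stop("`j` must lie in [0, 1]", call. = FALSE)
  (1 - j) * x_prev + j * x_curr
}
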