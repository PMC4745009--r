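#' Map irregular observation times onto a regular latent grid
#'
#' Assigns each observation to the latent time step it falls in and the
#' fraction of that step elapsed before it: `t_i = 1 + floor((time - start)
#' / time_step)` and `j_i` the fractional remainder in `[0, 1)`. Observation
#' `i` is then linked to the latent locations by straight-line interpolation
#' between `x[t_i]` and `x[t_i + 1]` (see [interpolate_position()]).
#'
#' @param obs_times numeric observation times (hours), sorted ascending.
#' @param start_time time of the first latent state (hours).
#' @param time_step latent step duration (hours, > 0).
#' @return Data frame with columns `t` (1-based interval index) and `j`
#'   (fraction in `[0, 1)`), one row per observation, plus attribute
#'   `n_steps`, the number of latent steps needed to cover all observations.
#' @export
map_observations_to_steps <- function(obs_times, start_time = obs_times[1],
                                      time_step = 6) {
  if (time_step <= 0) stop("`time_step` must be > 0", call. = FALSE)
  if (is.unsorted(obs_times))
    stop("`obs_times` must be sorted ascending", call. = FALSE)
  rel <- (obs_times - start_time) / time_step
  if (any(rel < 0)) stop("observations before `start_time`", call. = FALSE)
  t_i <- floor(rel) + 1L
  j <- rel - (t_i - 1L)
  # guard against float round-down at exact grid times
  snap <- j > 1 - 1e-9
  t_i[snap] <- t_i[snap] + 1L
  j[snap] <- 0
  out <- data.frame(t = as.integer(t_i), j = j)
  attr(out, "n_steps") <- max(out$t + as.integer(out$j > 0))
  out
}

#' Retain the longest run of observations without long gaps
#'
#' Splits a track wherever the gap between successive observations exceeds
#' `max_gap` days and keeps the longest contiguous run (the first, on ties).
#' Mirrors the pre-processing commonly applied to Argos deployments before
#' state-space filtering.
#'
#' @param track data frame with a `time_h` column (hours), sorted ascending.
#' @param max_gap maximum tolerated gap in days (default 4).
#' @return The retained sub-track, with attribute `dropped` giving the number
#'   of discarded observations.
#' @export
filter_gaps <- function(track, max_gap = 4) {
  track <- as.data.frame(track)
  if (is.unsorted(track$time_h))
    stop("track times must be sorted", call. = FALSE)
  n <- nrow(track)
  if (n == 0) stop("empty track", call. = FALSE)
  gaps_d <- diff(track$time_h) / 24
  run_id <- cumsum(c(0, gaps_d > max_gap))
  lens <- tabulate(run_id + 1L)
  keep <- which(run_id == (which.max(lens) - 1L))
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- n - length(keep)
  out
}
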