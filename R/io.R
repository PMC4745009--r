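#' Read animal track tables from CSV
#'
#' Expects one row per observed location with columns `id`, `time`, `x`,
#' `y`, optionally `lc` (Argos quality class), and optionally a
#' `coordinate_system` hint (`"planar_km"` or `"lonlat"`). `time` may be an
#' ISO-8601 timestamp or a numeric step/hour value; timestamps are converted
#' to hours from the first observation of each individual. Longitude /
#' latitude inputs are converted to local planar km by an equirectangular
#' projection about each track's centroid (origin recorded in attributes).
#' Rows are sorted by time within individual; duplicate timestamps or
#' unparseable fields raise validation errors naming the offending rows.
#'
#' @param path CSV file path.
#' @param coordinate_system `"planar_km"` (default) or `"lonlat"`;
#'   overridden by a `coordinate_system` column if present.
#' @return Named list of track data frames (`time_h`, `x_km`, `y_km`, `lc`),
#'   one per individual, in the form accepted by [fit()].
#' @export
read_tracks <- function(path, coordinate_system = c("planar_km", "lonlat")) {
  coordinate_system <- match.arg(coordinate_system)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "time", "x", "y")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$coordinate_system))
    coordinate_system <- raw$coordinate_system[1]
  if (is.character(raw$time)) {
    num <- suppressWarnings(as.numeric(raw$time))
    if (all(!is.na(num))) {
      raw$time_h <- num
    } else {
      ts <- as.POSIXct(rep(NA_real_, nrow(raw)), origin = "1970-01-01",
                       tz = "UTC")
      for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")) {
        todo <- is.na(ts)
        if (!any(todo)) break
        ts[todo] <- as.POSIXct(strptime(raw$time[todo], fmt, tz = "UTC"))
      }
      bad <- which(is.na(ts))
      if (length(bad))
        stop("unparseable time in row(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      raw$time_h <- as.numeric(difftime(ts, min(ts), units = "hours"))
    }
  } else raw$time_h <- as.numeric(raw$time)
  if (anyNA(raw$time_h) || anyNA(raw$x) || anyNA(raw$y)) {
    bad <- which(is.na(raw$time_h) | is.na(raw$x) | is.na(raw$y))
    stop("missing/unparseable values in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(raw$lc)) raw$lc <- NA_character_
  out <- lapply(split(raw, raw$id), function(d) {
    o <- order(d$time_h)
    if (is.unsorted(d$time_h))
      message("track ", d$id[1], ": rows re-sorted by time")
    d <- d[o, ]
    dup <- which(duplicated(d$time_h))
    if (length(dup))
      stop("duplicate timestamps for individual ", d$id[1], " at row(s): ",
           paste(dup, collapse = ", "), call. = FALSE)
    if (identical(coordinate_system, "lonlat")) {
      km <- lonlat_to_km(d$x, d$y)
      tr <- data.frame(time_h = d$time_h - d$time_h[1],
                       x_km = km$x_km, y_km = km$y_km,
                       lc = as.character(d$lc))
      attr(tr, "origin_lonlat") <- attr(km, "origin")
    } else {
      tr <- data.frame(time_h = d$time_h - d$time_h[1],
                       x_km = d$x, y_km = d$y, lc = as.character(d$lc))
    }
    tr
  })
  out
}

#' Write simulated tracks (and their truth) to CSV
#'
#' @param sims list of `simulated_track` objects from [simulate_scenario()].
#' @param obs_path CSV path for observations (columns `id, time, x, y, lc`).
#' @param truth_path optional CSV path for latent truth
#'   (columns `id, step, x_true, y_true, b_true`).
#' @return Invisibly, the observation data frame written.
#' @export
write_tracks <- function(sims, obs_path, truth_path = NULL) {
  obs <- do.call(rbind, lapply(sims, function(s)
    data.frame(id = s$track_id, time = s$observations$time_h,
               x = s$observations$x_km, y = s$observations$y_km,
               lc = s$observations$lc)))
  # full double precision so planar coordinates round-trip bit-exactly
  out <- obs
  for (cl in c("time", "x", "y")) out[[cl]] <- sprintf("%.17g", out[[cl]])
  write.csv(out, obs_path, row.names = FALSE, na = "", quote = FALSE)
  if (!is.null(truth_path)) {
    tru <- do.call(rbind, lapply(sims, function(s)
      data.frame(id = s$track_id, step = seq_along(s$truth$b),
                 x_true = s$truth$x[, 1], y_true = s$truth$x[, 2],
                 b_true = s$truth$b)))
    write.csv(tru, truth_path, row.names = FALSE)
  }
  invisible(obs)
}

#' Equirectangular lon/lat to local planar km
#'
#' Projects longitude/latitude onto a local planar frame about the track
#' centroid: `x = R * cos(lat0) * (lon - lon0)`, `y = R * (lat - lat0)` in
#' radians, `R = 6371` km. Adequate plumbing for regional tracks; all core
#' model mathematics is projection-agnostic.
#'
#' @param lon,lat coordinate vectors in degrees.
#' @param origin optional `c(lon0, lat0)`; defaults to the centroid.
#' @return Data frame `x_km`, `y_km` with attribute `origin`.
#' @export
lonlat_to_km <- function(lon, lat, origin = NULL) {
  if (is.null(origin)) origin <- c(mean(lon), mean(lat))
  R <- 6371
  out <- data.frame(
    x_km = R * cos(origin[2] * pi / 180) * (lon - origin[1]) * pi / 180,
    y_km = R * (lat - origin[2]) * pi / 180)
  attr(out, "origin") <- origin
  out
}

# ---- configuration files ---------------------------------------------------

.scenario_keys <- c("delta_gamma_label", "error_regime", "n_tracks",
                    "track_length", "seed", "gps_sd", "sigma_sd",
                    "argos_class_probs", "type")
.fit_keys <- c("model_form", "time_step", "n_chains", "n_iter", "n_burnin",
               "thin", "seed", "regime", "gps_sd", "monitor", "type")

#' Load a scenario or fit configuration from YAML/JSON
#'
#' The file must carry a `type` key (`"scenario"` or `"fit"`); remaining
#' keys mirror the arguments of [scenario_table1()] or [fit_config()], with
#' documented defaults filled in for anything omitted. Unknown keys are
#' rejected with a suggestion for the closest valid key, so typos never
#' silently fall back to defaults.
#'
#' @param path YAML (or JSON, a YAML subset) file path.
#' @return A [scenario()] or [fit_config()] object.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  type <- cfg$type
  if (is.null(type) || !type %in% c("scenario", "fit"))
    stop("config must declare type: scenario or fit", call. = FALSE)
  valid <- if (type == "scenario") .scenario_keys else .fit_keys
  unknown <- setdiff(names(cfg), valid)
  if (length(unknown)) {
    sug <- vapply(unknown, function(k) {
      d <- utils::adist(k, valid)
      valid[which.min(d)]
    }, character(1))
    stop("unknown config key(s): ",
         paste(sprintf("'%s' (did you mean '%s'?)", unknown, sug),
               collapse = ", "), call. = FALSE)
  }
  cfg$type <- NULL
  if (type == "scenario") {
    probs <- cfg$argos_class_probs
    if (!is.null(probs)) probs <- unlist(probs)
    do.call(scenario_table1,
            c(cfg[setdiff(names(cfg), "argos_class_probs")],
              if (!is.null(probs)) list(argos_class_probs = probs)))
  } else {
    regime <- cfg$regime %||% "none"
    gps_sd <- cfg$gps_sd %||% 0.05
    cfg$regime <- NULL
    cfg$gps_sd <- NULL
    obs <- switch(regime,
      none = obs_params("none"),
      gps = obs_params("gps", omega = diag(2) * gps_sd^2),
      argos = obs_params("argos", tau = argos_error_classes()))
    if (!is.null(cfg$monitor)) cfg$monitor <- unlist(cfg$monitor)
    do.call(fit_config, c(cfg, list(obs = obs)))
  }
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the configuration
#' snapshot, root seed, package version, and MD5 checksums of any input
#' files. Deterministic stages reproduce bit-exactly from a manifest;
#' seeded stochastic stages reproduce draw-exactly.
#'
#' @param path output JSON path.
#' @param config the configuration object used (scenario or fit config).
#' @param seed the root seed of the run.
#' @param inputs character vector of input file paths to checksum.
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(path, config, seed, inputs = character()) {
  man <- list(
    package = "jointssm",
    version = as.character(packageVersion("jointssm")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass_deep(config),
    input_md5 = as.list(tools::md5sum(inputs)))
  writeLines(yaml::as.yaml(man), path)
  invisible(man)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep)
  else if (is.matrix(x)) apply(x, 1, c, simplify = FALSE)
  else x
}
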