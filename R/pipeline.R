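# End-to-end orchestration: one config in, an artifact directory of
# delimited tables + GeoJSON out, with a manifest capturing every parameter
# and the seed so a run can be reproduced exactly.

#' Run configuration
#'
#' Validated bag of pipeline parameters. Unknown keys are rejected before any
#' compute. All parameters are echoed into the run manifest.
#'
#' @param mode `"synthetic"` (simulate a cohort) or `"files"` (read sensor /
#'   GPS / field files).
#' @param n_birds cohort size in synthetic mode.
#' @param colony `c(lat, lon)`.
#' @param seed master seed; per-stage child seeds are derived from it by a
#'   fixed affine hash so stages are individually reproducible.
#' @param inbound_policy,outbound_policy policy kinds (see [nav_policy()]).
#' @param alpha alignment weight for CURRENT_ALIGNED.
#' @param arrival_radius metres.
#' @param field_days temporal extent of the synthetic field (days).
#' @param scenario_args extra arguments passed to [trip_scenario()].
#' @param paths named list for `mode = "files"`: `field` (long-format current
#'   table), `streams` and `gps` (character vectors, one file per bird,
#'   dialects `t,heading,speed,depth` and `t,lat,lon`).
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"), n_birds = 3,
                       colony = c(-42.08, -63.86), seed = 1L,
                       inbound_policy = "DRIFT_TOLERANT",
                       outbound_policy = "DRIFT_TOLERANT",
                       alpha = NULL, arrival_radius = 500,
                       field_days = 5, scenario_args = list(),
                       paths = list()) {
  mode <- match.arg(mode)
  known <- names(formals(trip_scenario))
  bad <- setdiff(names(scenario_args), known)
  if (length(bad) > 0) {
    stop("unknown scenario_args key(s): ", paste(bad, collapse = ", "))
  }
  bad_paths <- setdiff(names(paths), c("field", "streams", "gps"))
  if (length(bad_paths) > 0) {
    stop("unknown paths key(s): ", paste(bad_paths, collapse = ", "))
  }
  structure(as.list(environment())[names(formals(run_config))],
            class = "run_config")
}

# Stable per-stage child seeds from the master seed.
.child_seed <- function(seed, stage) {
  stages <- c(field = 1L, trips = 2L, gps = 3L, boot = 4L)
  (as.integer(seed) * 7919L + stages[[stage]] * 104729L) %% 2147483647L
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — current field, tracks (simulated or
#' reconstructed from files), travel-vector decomposition, energetics, dive
#' table, fixed-heading ABM, binned summaries — and writes the artifact
#' tables plus a JSON manifest into `out_dir`. Re-running the same config
#' and seed reproduces the outputs byte for byte.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return (invisibly) a list of class `nav_run` with elements `field`,
#'   `trips`, `tracks`, `vectors`, `dives`, `abm`, `summaries`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("tidenav_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  colony <- config$colony

  if (config$mode == "synthetic") {
    field <- default_study_field(days = config$field_days)
    trips <- lapply(seq_len(config$n_birds), function(k) {
      args <- c(list(
        colony = colony,
        inbound_policy = nav_policy(config$inbound_policy,
                                    alpha = config$alpha),
        outbound_policy = nav_policy(config$outbound_policy),
        arrival_radius = config$arrival_radius,
        seed = .child_seed(config$seed, "trips") + k
      ), config$scenario_args)
      simulate_trip(do.call(trip_scenario, args), field)
    })
    tracks <- lapply(trips, function(tr) {
      reconstruct_track(tr$stream, tr$gps, colony)
    })
  } else {
    if (is.null(config$paths$field)) stop("mode 'files' needs paths$field")
    field <- load_current_field(config$paths$field)
    trips <- NULL
    tracks <- mapply(function(sp, gp) {
      reconstruct_track(utils::read.csv(sp), utils::read.csv(gp), colony)
    }, config$paths$streams, config$paths$gps, SIMPLIFY = FALSE)
  }

  vectors <- lapply(seq_along(tracks), function(k) {
    tk <- tracks[[k]]
    inb <- tk[tk$phase == "INBOUND", ]
    v <- compute_vector_set(inb, field, colony)
    v <- add_energetics(v, colony)
    v$bird_id <- k
    v$dist_to_colony <- inb$dist_to_colony
    v$prop <- return_proportion(v$dist_to_colony)
    v
  })
  vec_all <- do.call(rbind, vectors)

  dives <- do.call(rbind, lapply(seq_along(tracks), function(k) {
    tk <- tracks[[k]]
    d <- dive_table(tk$depth, tk$t, tk$phase)
    if (nrow(d) > 0) d$bird_id <- k else d$bird_id <- integer(0)
    d
  }))

  abm <- if (!is.null(trips)) {
    run_agent_cohort(trips, colony, field, config$arrival_radius)
  } else {
    do.call(rbind, lapply(seq_along(tracks), function(k) {
      inb <- tracks[[k]][tracks[[k]]$phase == "INBOUND", ]
      res <- run_agent(inb$speed_water, c(inb$lat[1], inb$lon[1]), colony,
                       field, inb$t[1], config$arrival_radius)
      data.frame(bird_id = k, outcome = res$outcome,
                 landing_offset_m = res$landing_offset_m,
                 duration_s = res$duration_s)
    }))
  }

  summaries <- list(
    ease_bins_real = bin_by_distance_proportion(vec_all$bird_id, vec_all$prop,
                                                vec_all$ease_real_any),
    ease_bins_comp = bin_by_distance_proportion(vec_all$bird_id, vec_all$prop,
                                                vec_all$ease_comp_any),
    against_bins = bin_by_distance_proportion(vec_all$bird_id, vec_all$prop,
                                              as.numeric(vec_all$against_current)),
    heading_hist = heading_histogram(vec_all$bird_id, vec_all$dev_water),
    current_classes = time_in_current_classes(vec_all$bird_id, vec_all$cur_u,
                                              vec_all$against_current)
  )

  manifest <- list(
    package = "tidenav",
    version = as.character(utils::packageVersion("tidenav")),
    seed = config$seed,
    config = .flatten_config(config),
    n_birds = length(tracks),
    created = "run manifest (timestamps omitted for reproducibility)"
  )

  run <- structure(list(field = field, trips = trips, tracks = tracks,
                        vectors = vec_all, dives = dives, abm = abm,
                        summaries = summaries, manifest = manifest,
                        out_dir = out_dir), class = "nav_run")
  export_tables(run, out_dir)
  invisible(run)
}

.flatten_config <- function(config) {
  cfg <- unclass(config)
  cfg$scenario_args <- NULL
  cfg$paths <- NULL
  c(lapply(cfg, function(x) if (is.null(x)) "NULL" else x),
    list(scenario_args = config$scenario_args, paths = config$paths))
}

#' @export
print.nav_run <- function(x, ...) {
  cat("<nav_run>\n")
  cat(sprintf("  %d birds; %d inbound vector rows; %d dives\n",
              length(x$tracks), nrow(x$vectors), nrow(x$dives)))
  cat(sprintf("  ABM outcomes: %s\n",
              paste(sprintf("%s=%d", names(table(x$abm$outcome)),
                            table(x$abm$outcome)), collapse = ", ")))
  cat(sprintf("  artifacts: %s\n", x$out_dir))
  invisible(x)
}

#' @export
summary.nav_run <- function(object, ...) {
  cc <- object$summaries$current_classes$grand
  cat("Cohort summary\n")
  cat(sprintf("  birds: %d\n", length(object$tracks)))
  cat(sprintf("  time in eastward currents: %.1f%% +/- %.1f%% (sd)\n",
              100 * cc[["p_east_mean"]], 100 * cc[["p_east_sd"]]))
  cat(sprintf("  time against the current: %.1f%% +/- %.1f%%\n",
              100 * cc[["p_against_mean"]], 100 * cc[["p_against_sd"]]))
  cat(sprintf("  ABM median landing offset: %.0f m\n",
              stats::median(object$abm$landing_offset_m)))
  invisible(object)
}

#' Export run artifacts
#'
#' Writes the vector/energetics feature table, dive table, ABM cohort table
#' and binned summaries as CSV, each track as a GeoJSON LineString with
#' per-vertex properties, and the manifest as JSON.
#'
#' @param run a `nav_run` from [run_pipeline()].
#' @param out_dir directory.
#' @return (invisibly) the paths written.
#' @export
export_tables <- function(run, out_dir = run$out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vectors = file.path(out_dir, "vectors.csv"),
    dives = file.path(out_dir, "dives.csv"),
    abm = file.path(out_dir, "abm_cohort.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  utils::write.csv(run$vectors, paths[["vectors"]], row.names = FALSE)
  utils::write.csv(run$dives, paths[["dives"]], row.names = FALSE)
  utils::write.csv(run$abm, paths[["abm"]], row.names = FALSE)
  for (nm in c("ease_bins_real", "ease_bins_comp", "against_bins",
               "heading_hist")) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(run$summaries[[nm]], p, row.names = FALSE)
    paths[nm] <- p
  }
  jsonlite::write_json(run$manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (k in seq_along(run$tracks)) {
    p <- file.path(out_dir, sprintf("track_%02d.geojson", k))
    write_track_geojson(run$tracks[[k]], p)
    paths[sprintf("track_%02d", k)] <- p
  }
  invisible(paths)
}

#' Write a track as GeoJSON
#'
#' A `Feature` with a `LineString` geometry (lon, lat vertex order per the
#' GeoJSON spec) and per-vertex property arrays.
#'
#' @param track data.frame with `lat`, `lon` and any further columns, which
#'   become property arrays.
#' @param path output file.
#' @return (invisibly) `path`.
#' @export
write_track_geojson <- function(track, path) {
  props <- track[, setdiff(names(track), c("lat", "lon")), drop = FALSE]
  gj <- list(
    type = "Feature",
    geometry = list(
      type = "LineString",
      coordinates = unname(apply(cbind(track$lon, track$lat), 1, as.list,
                                 simplify = FALSE))
    ),
    properties = as.list(props)
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
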