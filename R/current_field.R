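#' Gridded tidal current field
#'
#' Container for hourly U/V water-velocity snapshots on a regular lon/lat
#' grid. `u` is the eastward and `v` the northward component (m/s), following
#' the standard oceanographic convention; headings are degrees clockwise from
#' true north.
#'
#' @param lon_axis,lat_axis strictly increasing, regularly spaced axes
#'   (decimal degrees).
#' @param time_axis epoch-seconds at exact 3600 s spacing.
#' @param u,v numeric arrays indexed `[time, lat, lon]`, metres per second.
#' @return an object of class `current_field`.
#' @seealso [build_harmonic_field()], [sample_current()], [load_current_field()]
#' @export
current_field <- function(lon_axis, lat_axis, time_axis, u, v) {
  .check_axis(lon_axis, "lon_axis")
  .check_axis(lat_axis, "lat_axis")
  .check_axis(time_axis, "time_axis")
  if (length(time_axis) > 1 && any(abs(diff(time_axis) - 3600) > 1e-6)) {
    stop("time_axis must have exact hourly (3600 s) spacing")
  }
  dims <- c(length(time_axis), length(lat_axis), length(lon_axis))
  for (nm in c("u", "v")) {
    g <- get(nm)
    if (!is.array(g) || !identical(dim(g), as.integer(dims))) {
      stop(sprintf("%s must be an array with dim [time, lat, lon] = [%s]",
                   nm, paste(dims, collapse = ", ")))
    }
    if (anyNA(g) || any(!is.finite(g))) {
      stop(sprintf("%s contains missing or non-finite values", nm))
    }
  }
  structure(
    list(lon_axis = as.numeric(lon_axis), lat_axis = as.numeric(lat_axis),
         time_axis = as.numeric(time_axis), u = u, v = v),
    class = "current_field"
  )
}

.check_axis <- function(ax, name) {
  if (length(ax) < 1 || anyNA(ax)) stop(sprintf("%s is empty or has NA", name))
  if (length(ax) > 1) {
    d <- diff(ax)
    if (any(d <= 0)) stop(sprintf("%s must be strictly increasing", name))
    if (max(d) - min(d) > 1e-6 * max(abs(d))) {
      stop(sprintf("%s must be regularly spaced", name))
    }
  }
  invisible(TRUE)
}

#' @export
print.current_field <- function(x, ...) {
  cat("<current_field>\n")
  cat(sprintf("  lon: [%.4f, %.4f] x %d\n", min(x$lon_axis), max(x$lon_axis),
              length(x$lon_axis)))
  cat(sprintf("  lat: [%.4f, %.4f] x %d\n", min(x$lat_axis), max(x$lat_axis),
              length(x$lat_axis)))
  cat(sprintf("  time: %d hourly snapshots from %.0f\n", length(x$time_axis),
              x$time_axis[1]))
  cat(sprintf("  speed range: %.3f - %.3f m/s\n",
              min(sqrt(x$u^2 + x$v^2)), max(sqrt(x$u^2 + x$v^2))))
  invisible(x)
}

#' Harmonic specification for a synthetic tidal field
#'
#' A sum-of-sinusoids description of a reversing tidal flow:
#' `u(t) = sum A_u * g(lon,lat) * sin(2*pi*t/T + phase)` and likewise for
#' `v`. The default emulates the semi-diurnal east-west regime of a
#' mid-latitude gulf: a dominant constituent of period 44,712 s (~12.42 h)
#' plus a weaker first overtone that makes eastward peaks stronger than
#' westward ones while keeping the time split between the two phases near
#' 50/50 and the time-mean flow zero.
#'
#' @param constituents data.frame with columns `amp_u`, `amp_v` (m/s, >= 0),
#'   `period` (s, > 0) and `phase` (radians).
#' @param modulation optional `function(lon, lat)` returning a dimensionless
#'   spatial amplitude factor; default is uniform 1.
#' @return an object of class `harmonic_spec`.
#' @export
harmonic_spec <- function(constituents, modulation = NULL) {
  req <- c("amp_u", "amp_v", "period", "phase")
  if (!is.data.frame(constituents) || !all(req %in% names(constituents))) {
    stop("constituents must be a data.frame with amp_u, amp_v, period, phase")
  }
  if (any(constituents$amp_u < 0) || any(constituents$amp_v < 0)) {
    stop("amplitudes must be >= 0")
  }
  if (any(constituents$period <= 0)) stop("periods must be > 0")
  structure(list(constituents = constituents, modulation = modulation),
            class = "harmonic_spec")
}

#' @rdname harmonic_spec
#' @param amp_u,amp_v fundamental amplitudes (m/s) for the default spec.
#' @export
default_tidal_spec <- function(amp_u = 0.9, amp_v = 0.12) {
  harmonic_spec(data.frame(
    amp_u  = c(amp_u, amp_u * 0.28),
    amp_v  = c(amp_v, amp_v * 0.25),
    period = c(44712, 22356),
    phase  = c(0, -pi / 3)
  ))
}

#' Build a synthetic harmonic current field
#'
#' Evaluates a [harmonic_spec()] on a regular grid at hourly snapshots.
#' Deterministic for a given spec; the time-mean of each component over an
#' integer number of periods is zero.
#'
#' @param spec a [harmonic_spec()].
#' @param lon_axis,lat_axis regular axes in decimal degrees.
#' @param time_range numeric length-2 `c(start, end)` epoch-seconds; snapshots
#'   are generated at `seq(start, end, by = 3600)`.
#' @return a [current_field()].
#' @export
build_harmonic_field <- function(spec, lon_axis, lat_axis, time_range) {
  stopifnot(inherits(spec, "harmonic_spec"))
  if (length(lon_axis) < 1 || length(lat_axis) < 1) stop("empty grid axes")
  if (length(time_range) != 2 || time_range[2] < time_range[1]) {
    stop("time_range must be c(start, end) with end >= start")
  }
  time_axis <- seq(time_range[1], time_range[2], by = 3600)
  nt <- length(time_axis); nlat <- length(lat_axis); nlon <- length(lon_axis)
  g <- if (is.null(spec$modulation)) {
    matrix(1, nlat, nlon)
  } else {
    outer(lat_axis, lon_axis, function(la, lo) spec$modulation(lo, la))
  }
  u <- array(0, c(nt, nlat, nlon))
  v <- array(0, c(nt, nlat, nlon))
  for (k in seq_len(nrow(spec$constituents))) {
    cst <- spec$constituents[k, ]
    s <- sin(2 * pi * time_axis / cst$period + cst$phase)
    # outer over time x (lat, lon)
    u <- u + cst$amp_u * outer(s, g)
    v <- v + cst$amp_v * outer(s, g)
  }
  dim(u) <- c(nt, nlat, nlon)
  dim(v) <- c(nt, nlat, nlon)
  current_field(lon_axis, lat_axis, time_axis, u, v)
}

#' Sample the current field at points in space and time
#'
#' Bilinear interpolation in space on the snapshot at the nearest hourly
#' timestamp (half-hour ties round down). Exact at grid nodes. Queries
#' outside the grid hull or time range are errors carrying the nearest node,
#' not extrapolations.
#'
#' @param field a [current_field()].
#' @param lon,lat,t numeric vectors (recycled to common length).
#' @return data.frame with columns `u`, `v` (m/s).
#' @export
sample_current <- function(field, lon, lat, t) {
  stopifnot(inherits(field, "current_field"))
  n <- max(length(lon), length(lat), length(t))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n); t <- rep_len(t, n)

  lx <- field$lon_axis; ly <- field$lat_axis; tx <- field$time_axis
  if (any(lon < lx[1] - 1e-12) || any(lon > lx[length(lx)] + 1e-12) ||
      any(lat < ly[1] - 1e-12) || any(lat > ly[length(ly)] + 1e-12)) {
    bad <- which(lon < lx[1] | lon > lx[length(lx)] |
                 lat < ly[1] | lat > ly[length(ly)])[1]
    stop(sprintf(
      "query (%.5f, %.5f) outside current-field hull [%.5f..%.5f, %.5f..%.5f]; nearest node (%.5f, %.5f)",
      lon[bad], lat[bad], lx[1], lx[length(lx)], ly[1], ly[length(ly)],
      lx[which.min(abs(lx - lon[bad]))], ly[which.min(abs(ly - lat[bad]))]
    ))
  }
  if (any(t < tx[1] - 1e-9) || any(t > tx[length(tx)] + 1e-9)) {
    stop("query time outside field time range")
  }

  # nearest hourly snapshot, half-hour ties round down
  off <- (t - tx[1]) / 3600
  k <- floor(off)
  frac <- off - k
  ti <- ifelse(frac <= 0.5, k, k + 1) + 1
  ti <- pmin(pmax(ti, 1L), length(tx))

  dlon <- if (length(lx) > 1) lx[2] - lx[1] else 1
  dlat <- if (length(ly) > 1) ly[2] - ly[1] else 1
  i <- pmin(pmax(floor((lon - lx[1]) / dlon) + 1, 1), max(length(lx) - 1, 1))
  j <- pmin(pmax(floor((lat - ly[1]) / dlat) + 1, 1), max(length(ly) - 1, 1))
  i2 <- pmin(i + 1, length(lx)); j2 <- pmin(j + 1, length(ly))
  wx <- if (length(lx) > 1) (lon - lx[i]) / dlon else 0
  wy <- if (length(ly) > 1) (lat - ly[j]) / dlat else 0

  bil <- function(g) {
    idx <- function(jj, ii) g[cbind(ti, jj, ii)]
    (1 - wx) * (1 - wy) * idx(j, i) + wx * (1 - wy) * idx(j, i2) +
      (1 - wx) * wy * idx(j2, i) + wx * wy * idx(j2, i2)
  }
  data.frame(u = bil(field$u), v = bil(field$v))
}

#' Convert between U/V components and speed/heading
#'
#' Headings are degrees clockwise from true north on [0, 360); `u` is
#' eastward, `v` northward. The zero vector maps to speed 0 with heading 0.
#'
#' @param u,v velocity components (m/s).
#' @return `uv_to_speed_dir`: data.frame with `speed` and `heading`.
#' @export
uv_to_speed_dir <- function(u, v) {
  stopifnot(all(is.finite(u)), all(is.finite(v)))
  speed <- sqrt(u^2 + v^2)
  heading <- .wrap360(.rad2deg(atan2(u, v)))
  heading[speed == 0] <- 0
  data.frame(speed = speed, heading = heading)
}

#' @rdname uv_to_speed_dir
#' @param speed speed in m/s (>= 0).
#' @param heading degrees clockwise from true north.
#' @return `speed_dir_to_uv`: data.frame with `u` and `v`.
#' @export
speed_dir_to_uv <- function(speed, heading) {
  if (any(speed < 0)) stop("speed must be >= 0")
  h <- .deg2rad(heading)
  data.frame(u = speed * sin(h), v = speed * cos(h))
}

#' Read or write a current field as a long-format delimited table
#'
#' Dialect: columns `time,lon,lat,u,v`, one row per grid cell per snapshot,
#' epoch-second times. The full outer grid must be present; a missing cell is
#' a format error. `write_current_field()` followed by `load_current_field()`
#' round-trips exactly (values are printed at full precision).
#'
#' @param path file path.
#' @return `load_current_field`: a [current_field()].
#' @export
load_current_field <- function(path) {
  d <- utils::read.csv(path)
  req <- c("time", "lon", "lat", "u", "v")
  if (!all(req %in% names(d))) {
    stop("format error: expected columns time,lon,lat,u,v")
  }
  lon_axis <- sort(unique(d$lon))
  lat_axis <- sort(unique(d$lat))
  time_axis <- sort(unique(d$time))
  nexp <- length(lon_axis) * length(lat_axis) * length(time_axis)
  if (nrow(d) != nexp || anyNA(d)) {
    stop(sprintf("format error: expected full %d-cell grid, found %d rows",
                 nexp, nrow(d)))
  }
  o <- order(match(d$lon, lon_axis), match(d$lat, lat_axis),
             match(d$time, time_axis))
  d <- d[o, ]
  dims <- c(length(time_axis), length(lat_axis), length(lon_axis))
  u <- array(d$u, dims)
  v <- array(d$v, dims)
  current_field(lon_axis, lat_axis, time_axis, u, v)
}

#' @rdname load_current_field
#' @param field a [current_field()].
#' @export
write_current_field <- function(field, path) {
  stopifnot(inherits(field, "current_field"))
  grid <- expand.grid(time = field$time_axis, lat = field$lat_axis,
                      lon = field$lon_axis, KEEP.OUT.ATTRS = FALSE)
  d <- data.frame(time = grid$time, lon = grid$lon, lat = grid$lat,
                  u = as.vector(field$u), v = as.vector(field$v))
  utils::write.csv(format(d, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
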