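#' Detect dives in a 1 Hz depth series
#'
#' A dive is a maximal contiguous run of samples with depth strictly greater
#' than the threshold (default 0.3 m).
#'
#' @param depth metres, positive down, 1 Hz.
#' @param t optional time stamps (epoch-seconds); defaults to 0-based index.
#' @param threshold metres (default 0.3).
#' @return data.frame with one row per dive: `start_t`, `end_t`, `start_i`,
#'   `end_i`, `max_depth`, `duration_s`.
#' @export
detect_dives <- function(depth, t = seq_along(depth) - 1, threshold = 0.3) {
  under <- depth > threshold
  r <- rle(under)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  if (length(keep) == 0) {
    return(data.frame(start_t = numeric(0), end_t = numeric(0),
                      start_i = integer(0), end_i = integer(0),
                      max_depth = numeric(0), duration_s = numeric(0)))
  }
  si <- starts[keep]; ei <- ends[keep]
  data.frame(
    start_t = t[si], end_t = t[ei], start_i = si, end_i = ei,
    max_depth = vapply(seq_along(si),
                       function(k) max(depth[si[k]:ei[k]]), numeric(1)),
    duration_s = t[ei] - t[si] + 1
  )
}

#' Count wiggle-based prey pursuits within one dive
#'
#' Vertical velocity is the centred first difference of depth (positive
#' down). A wiggle is a maximal interval between sign changes of vertical
#' velocity that opposes the enclosing dive trend: an upward excursion before
#' the time of maximum depth (descent/bottom), or a downward excursion after
#' it (bottom/ascent). A wiggle counts as a prey pursuit when its absolute
#' vertical velocity exceeds `v_thresh` (default 0.3 m/s) for at least
#' `min_dur` contiguous seconds (default 1 s).
#'
#' @param depth 1 Hz depth samples of a single dive.
#' @param v_thresh m/s (default 0.3, strict exceedance).
#' @param min_dur seconds (default 1).
#' @param phase restrict counting to `"all"` (default), `"descent"` (before
#'   maximum depth) or `"ascent"` (after maximum depth).
#' @return integer pursuit count.
#' @export
detect_pursuits <- function(depth, v_thresh = 0.3, min_dur = 1,
                            phase = c("all", "descent", "ascent")) {
  phase <- match.arg(phase)
  n <- length(depth)
  if (n < 3) return(0L)
  vv <- c(depth[2] - depth[1],
          (depth[3:n] - depth[1:(n - 2)]) / 2,
          depth[n] - depth[n - 1])
  i_max <- which.max(depth)
  trend <- ifelse(seq_len(n) <= i_max, 1, -1) # +1 descending, -1 ascending
  opposing <- sign(vv) != 0 & sign(vv) == -trend
  if (phase == "descent") opposing <- opposing & seq_len(n) <= i_max
  if (phase == "ascent") opposing <- opposing & seq_len(n) > i_max
  r <- rle(opposing)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  need <- max(1L, as.integer(round(min_dur)))
  count <- 0L
  for (k in keep) {
    seg <- abs(vv[starts[k]:ends[k]]) > v_thresh
    rr <- rle(seg)
    if (any(rr$values & rr$lengths >= need)) count <- count + 1L
  }
  count
}

#' Dive table with pursuit counts
#'
#' Runs [detect_dives()] on a depth series and annotates each dive with its
#' pursuit count and (optionally) the trip phase at the dive start.
#'
#' @param depth,t as in [detect_dives()].
#' @param phase_labels optional character vector (same length as `depth`)
#'   of OUTBOUND/INBOUND labels.
#' @param threshold,v_thresh,min_dur detection parameters.
#' @return data.frame: `start_t`, `end_t`, `max_depth`, `n_pursuits`, `phase`.
#' @export
dive_table <- function(depth, t = seq_along(depth) - 1, phase_labels = NULL,
                       threshold = 0.3, v_thresh = 0.3, min_dur = 1) {
  d <- detect_dives(depth, t, threshold)
  d$n_pursuits <- vapply(seq_len(nrow(d)), function(k) {
    detect_pursuits(depth[d$start_i[k]:d$end_i[k]], v_thresh, min_dur)
  }, integer(1))
  d$phase <- if (is.null(phase_labels)) NA_character_ else
    phase_labels[d$start_i]
  d[, c("start_t", "end_t", "max_depth", "n_pursuits", "phase")]
}

#' Prey pursuit rate
#'
#' Total pursuits per second of elapsed time; additive across disjoint bins.
#'
#' @param n_pursuits pursuit counts.
#' @param duration_s total elapsed seconds.
#' @return pursuits per second.
#' @export
pursuit_rate <- function(n_pursuits, duration_s) {
  if (duration_s <= 0) stop("duration must be > 0")
  sum(n_pursuits) / duration_s
}
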