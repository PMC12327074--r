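# Per-bird normalised summaries: current-condition classification, distance
# and angle binning with grand means across birds, fraction-within
# statistics, and a bird-level bootstrapped two-sample KS comparison.

#' Classify current strength
#'
#' `SLACK` for current speed < 0.3 m/s, `APPRECIABLE` for >= 0.3 m/s.
#'
#' @param speed current speed (m/s).
#' @return character vector.
#' @export
classify_current <- function(speed) {
  ifelse(speed < 0.3, "SLACK", "APPRECIABLE")
}

#' Proportion-of-return coordinate
#'
#' Maps distance-to-colony to the proportion of the straight-line return
#' completed: `1 - dist / dist_at_inbound_start`, clipped to [0, 1].
#'
#' @param dist_to_colony metres.
#' @param dist_at_start metres at the inbound start (default the first
#'   element).
#' @return numeric in [0, 1].
#' @export
return_proportion <- function(dist_to_colony, dist_at_start =
                                dist_to_colony[1]) {
  pmin(pmax(1 - dist_to_colony / dist_at_start, 0), 1)
}

#' Bin a per-sample series by distance proportion, per bird, then grand mean
#'
#' Computes the mean of `value` in each proportion bin separately for each
#' bird, then the unweighted grand mean and standard error across birds.
#' Birds with no samples in a bin are dropped from that bin's grand mean; the
#' SE uses the n-1 denominator.
#'
#' @param bird factor/vector of bird ids, one per sample.
#' @param prop proportion-of-return coordinate in [0, 1].
#' @param value the per-sample quantity to summarise.
#' @param width bin width (default 0.05).
#' @return data.frame `bin_lo`, `bin_hi`, `bin_mid`, `grand_mean`,
#'   `grand_se`, `n_birds`, plus attribute `per_bird` (bird x bin matrix).
#' @export
bin_by_distance_proportion <- function(bird, prop, value, width = 0.05) {
  stopifnot(length(bird) == length(prop), length(prop) == length(value))
  edges <- seq(0, 1, by = width)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  nb <- length(edges) - 1
  idx <- pmin(pmax(findInterval(prop, edges, rightmost.closed = TRUE), 1), nb)
  birds <- unique(bird)
  per_bird <- matrix(NA_real_, length(birds), nb,
                     dimnames = list(as.character(birds), NULL))
  for (k in seq_along(birds)) {
    sel <- bird == birds[k]
    m <- tapply(value[sel], factor(idx[sel], levels = seq_len(nb)), mean)
    per_bird[k, ] <- as.numeric(m)
  }
  grand_mean <- apply(per_bird, 2, mean, na.rm = TRUE)
  grand_se <- apply(per_bird, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  })
  n_birds <- apply(per_bird, 2, function(x) sum(!is.na(x)))
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    bin_mid = (edges[-length(edges)] + edges[-1]) / 2,
                    grand_mean = grand_mean, grand_se = grand_se,
                    n_birds = n_birds)
  attr(out, "per_bird") <- per_bird
  out
}

#' Per-bird normalised circular heading histogram
#'
#' Histograms signed heading deviations on `(-180, 180]` with the given bin
#' width, normalises each bird's counts to proportions (summing to 1), and
#' averages across birds to grand mean relative frequencies.
#'
#' @param bird bird ids, one per sample.
#' @param devs signed deviations in `(-180, 180]` degrees.
#' @param bin_width degrees (default 15; must divide 360).
#' @return data.frame `bin_lo`, `bin_hi`, `bin_mid`, `grand_mean`,
#'   `grand_se`, `n_birds`; attribute `per_bird` holds the bird x bin
#'   proportion matrix (rows sum to 1).
#' @export
heading_histogram <- function(bird, devs, bin_width = 15) {
  stopifnot(360 %% bin_width == 0)
  edges <- seq(-180, 180, by = bin_width)
  nb <- length(edges) - 1
  # bins are (lo, hi]: shift left edge membership
  idx <- pmin(pmax(ceiling((devs + 180) / bin_width), 1), nb)
  birds <- unique(bird)
  per_bird <- matrix(0, length(birds), nb,
                     dimnames = list(as.character(birds), NULL))
  for (k in seq_along(birds)) {
    cnt <- tabulate(idx[bird == birds[k]], nbins = nb)
    tot <- sum(cnt)
    per_bird[k, ] <- if (tot > 0) cnt / tot else NA_real_
  }
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             bin_mid = (edges[-length(edges)] + edges[-1]) / 2,
             grand_mean = apply(per_bird, 2, mean, na.rm = TRUE),
             grand_se = apply(per_bird, 2, function(x) {
               x <- x[!is.na(x)]
               if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
             }),
             n_birds = sum(!is.na(per_bird[, 1]))) -> out
  attr(out, "per_bird") <- per_bird
  out
}

#' Mean per-bird proportion of deviations within a limit
#'
#' For each bird, the proportion of samples with `|dev| <= limit`; returns
#' the unweighted mean across birds.
#'
#' @param bird bird ids.
#' @param devs signed deviations (degrees).
#' @param limit degrees.
#' @return a single proportion.
#' @export
fraction_within <- function(bird, devs, limit) {
  p <- tapply(abs(devs) <= limit, bird, mean)
  mean(p)
}

#' Two-sample Kolmogorov-Smirnov D statistic
#'
#' Classical `D = sup |ECDF_a - ECDF_b|` over the pooled sample points.
#'
#' @param a,b numeric samples.
#' @return the D statistic in [0, 1].
#' @export
ks_d <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  pts <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a)(pts)
  fb <- stats::ecdf(b)(pts)
  max(abs(fa - fb))
}

#' Bird-level bootstrapped KS comparison
#'
#' Per replicate, resamples birds with replacement within each group, pools
#' the resampled birds' samples, and computes [ks_d()]. Reports the mean D
#' and the 2.5/97.5 percentile interval. Resampling the individual (not the
#' sample) respects intra-individual dependence. A within-bird block
#' bootstrap is available as an alternative unit.
#'
#' @param group_a,group_b named lists of per-bird numeric vectors (>= 2 birds
#'   each).
#' @param n_boot number of replicates (default 1000, >= 100).
#' @param seed integer seed; identical seeds give identical results.
#' @param unit `"bird"` (default) resamples birds; `"block"` additionally
#'   resamples contiguous blocks of `block_len` samples within each chosen
#'   bird.
#' @param block_len block length in samples for `unit = "block"`.
#' @return list `D_mean`, `ci_low`, `ci_high`, `D` (replicate vector).
#' @export
bootstrap_ks <- function(group_a, group_b, n_boot = 1000, seed = 1,
                         unit = c("bird", "block"), block_len = 600) {
  unit <- match.arg(unit)
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("need at least two birds per group to resample individuals")
  }
  if (n_boot < 100) stop("n_boot must be >= 100")
  set.seed(seed)
  draw <- function(group) {
    ids <- sample.int(length(group), replace = TRUE)
    if (unit == "bird") {
      unlist(group[ids], use.names = FALSE)
    } else {
      unlist(lapply(group[ids], function(x) {
        if (length(x) <= block_len) return(x)
        nb <- ceiling(length(x) / block_len)
        starts <- sample.int(length(x) - block_len + 1, nb, replace = TRUE)
        unlist(lapply(starts, function(s) x[s:(s + block_len - 1)]))
      }), use.names = FALSE)
    }
  }
  D <- vapply(seq_len(n_boot), function(i) ks_d(draw(group_a), draw(group_b)),
              numeric(1))
  list(D_mean = mean(D),
       ci_low = stats::quantile(D, 0.025, names = FALSE),
       ci_high = stats::quantile(D, 0.975, names = FALSE),
       D = D)
}

#' Time spent in current classes
#'
#' Per-bird proportions of time in eastward (`u > 0`) versus westward
#' currents (u = 0 counts as westward, a measure-zero convention), and with
#' versus against the current (against = absolute water-frame heading
#' difference from the current direction strictly exceeding 90 degrees);
#' grand mean and SD across birds.
#'
#' @param bird bird ids, one per sample.
#' @param cur_u eastward current component (m/s).
#' @param against logical against-current flags (see [against_current()]).
#' @return list with `per_bird` (data.frame `bird`, `p_east`, `p_against`)
#'   and `grand` (means and sds).
#' @export
time_in_current_classes <- function(bird, cur_u, against) {
  pb <- data.frame(
    bird = sort(unique(bird)),
    p_east = as.numeric(tapply(cur_u > 0, bird, mean)),
    p_against = as.numeric(tapply(against, bird, mean))
  )
  list(per_bird = pb,
       grand = c(p_east_mean = mean(pb$p_east), p_east_sd = stats::sd(pb$p_east),
                 p_against_mean = mean(pb$p_against),
                 p_against_sd = stats::sd(pb$p_against)))
}

#' Straight-line return efficiency
#'
#' The proportion of the return not lost to the landing offset:
#' `1 - landing_offset / trip_distance`, e.g. a 300 m offset on a 50 km
#' return is 99.4% efficient.
#'
#' @param trip_distance metres (or any unit shared with `landing_offset`).
#' @param landing_offset same unit.
#' @return proportion in [0, 1].
#' @export
return_efficiency <- function(trip_distance, landing_offset) {
  stopifnot(trip_distance > 0, landing_offset >= 0)
  1 - landing_offset / trip_distance
}
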