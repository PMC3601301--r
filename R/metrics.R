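#' Willmore-Tolhurst population sparseness
#'
#' \deqn{S = \frac{1 - (\sum_j r_j / N)^2 / (\sum_j r_j^2 / N)}{1 - 1/N}}
#' where `r_j` is the spike count of neuron `j` over the measurement
#' interval.  S equals 1 when a single neuron carries all activity and 0
#' when all neurons fire equally; it is invariant to rescaling all rates by
#' a positive constant.
#'
#' @param r nonnegative spike counts (or rates) per neuron
#' @return sparseness in `[0, 1]`
#' @export
sparseness <- function(r) {
  n <- length(r)
  stopifnot(n >= 2, all(r >= 0))
  if (all(r == 0)) stop("sparseness undefined: no activity")
  (1 - (sum(r) / n)^2 / (sum(r^2) / n)) / (1 - 1 / n)
}

#' Winner-take-all peak-rate measure
#'
#' The highest single-neuron firing rate in the window, subject to the
#' sparseness constraint that at least half of the neurons fire below
#' `threshold` (2 Hz); otherwise the measure is zero.  Exactly half counts
#' as satisfying the constraint.
#'
#' @param rates firing rates per neuron (Hz)
#' @param threshold sparseness constraint rate (Hz)
#' @return Hz (zero when the constraint fails)
#' @export
wta_peak_measure <- function(rates, threshold = 2) {
  if (mean(rates < threshold) >= 0.5) max(rates) else 0
}

# rate-weighted centroid of activity per consecutive frame
activity_centroids <- function(record, pop, layout, window, frame = 100) {
  d <- record[record$pop == pop & record$time >= window[1] &
                record$time < window[2], ]
  breaks <- seq(window[1], window[2], by = frame)
  idx <- findInterval(d$time, breaks, rightmost.closed = TRUE)
  t(vapply(seq_len(length(breaks) - 1), function(f) {
    nn <- d$neuron[idx == f]
    if (!length(nn)) return(c(NA_real_, NA_real_))
    colMeans(layout$pos[nn, , drop = FALSE])
  }, numeric(2)))
}

#' Classify the dynamical state of a simulation
#'
#' Operational taxonomy on the excitatory population, evaluated on the
#' third second of activity (window `[2000, 3000]` ms by default):
#' * `epileptic` - at least half of the neurons fire at >= 2 Hz
#'   (indiscriminate firing);
#' * `wta` - sparseness > 0.9 and the rate-weighted centroid of the active
#'   patch moves less than one grid spacing per 100-ms frame on average;
#' * `traveling_wave` - sparse frames whose centroid drifts beyond that
#'   bound;
#' * `transient_rhythmic` - the window classifies as `wta` but seconds 1-2
#'   show periodic population-wide synchrony (autocorrelation peak > 0.5);
#' * `other` - anything else, including an empty record.
#'
#' @param record a `spike_record`
#' @param layout the [grid_layout()] of the classified population
#' @param pop population name
#' @param window measurement window (ms)
#' @param early_window window tested for transient rhythmicity (ms)
#' @param frame centroid-tracking frame (ms)
#' @return one of `"wta"`, `"traveling_wave"`, `"transient_rhythmic"`,
#'   `"epileptic"`, `"other"`
#' @export
classify_dynamics <- function(record, layout, pop = "exc",
                              window = c(2000, 3000),
                              early_window = c(1000, 2000), frame = 100) {
  rates <- spike_rates(record, pop, window)
  if (all(rates == 0)) return("other")
  if (mean(rates >= 2) >= 0.5) return("epileptic")
  s <- sparseness(rates)
  cen <- activity_centroids(record, pop, layout, window, frame)
  steps <- sqrt(rowSums(diff(cen)^2))
  steps <- steps[is.finite(steps)]
  drifting <- length(steps) > 0 && mean(steps) >= layout$spacing
  if (s > 0.9 && !drifting) {
    if (is_rhythmic(record, pop, early_window)) return("transient_rhythmic")
    return("wta")
  }
  # sparse activity per frame that keeps moving: traveling wave
  per_frame_sparse <- {
    d <- record[record$pop == pop & record$time >= window[1] &
                  record$time < window[2], ]
    breaks <- seq(window[1], window[2], by = frame)
    idx <- findInterval(d$time, breaks, rightmost.closed = TRUE)
    fr <- vapply(seq_len(length(breaks) - 1), function(f) {
      cnt <- tabulate(d$neuron[idx == f], nbins = layout$n)
      if (all(cnt == 0)) NA_real_ else sparseness(cnt)
    }, numeric(1))
    median(fr, na.rm = TRUE)
  }
  if (!is.na(per_frame_sparse) && per_frame_sparse > 0.9 && drifting)
    return("traveling_wave")
  "other"
}

# periodic population-wide synchrony: autocorrelation of the 5-ms binned
# population rate has a peak > 0.5 at a nonzero lag (10-300 ms)
is_rhythmic <- function(record, pop, window, bin = 5) {
  d <- record[record$pop == pop & record$time >= window[1] &
                record$time < window[2], ]
  if (nrow(d) < 10) return(FALSE)
  breaks <- seq(window[1], window[2], by = bin)
  cnt <- tabulate(findInterval(d$time, breaks, rightmost.closed = TRUE),
                  nbins = length(breaks) - 1)
  if (stats::sd(cnt) == 0) return(FALSE)
  ac <- stats::acf(cnt, lag.max = 60, plot = FALSE)$acf[-1]
  max(ac[2:60]) > 0.5
}

#' Orientation preference and selectivity from tuning responses
#'
#' Given per-neuron spike counts at each probe orientation, the preferred
#' angle is half the argument of the orientation-doubled resultant
#' \eqn{z = \sum_\theta r(\theta) e^{i 2 \theta}} and the selectivity is
#' `|z| / sum(r)` (0 for uniform responses, 1 for response at a single
#' orientation; two equal peaks 90 degrees apart cancel to 0).
#'
#' @param responses `neurons x orientations` matrix of spike counts
#' @param thetas probe orientations (degrees), one per column
#' @return data frame with `preferred` (degrees in `[0, 180)`),
#'   `selectivity` in `[0, 1]`, and total `response`
#' @export
orientation_tuning <- function(responses, thetas) {
  stopifnot(ncol(responses) == length(thetas))
  ang <- 2 * thetas * pi / 180
  zr <- responses %*% cos(ang)
  zi <- responses %*% sin(ang)
  tot <- rowSums(responses)
  pref <- (atan2(zi, zr) / 2 * 180 / pi) %% 180
  sel <- ifelse(tot > 0, sqrt(zr^2 + zi^2) / tot, 0)
  pref[tot == 0] <- NA
  data.frame(preferred = as.numeric(pref), selectivity = as.numeric(sel),
             response = tot)
}

#' Absolute circular difference between orientations (period 180 degrees)
#'
#' @param a,b angles in degrees
#' @return difference in `[0, 90]`
#' @export
orientation_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Orientation-map smoothness with a permutation null
#'
#' Statistic: median absolute circular difference (period 180) between the
#' preferences of 4-neighbor pairs on the grid.  The null distribution comes
#' from random permutations of the map positions; the reported `p_bound` is
#' the fraction of permutations with an equal-or-smaller statistic (plus the
#' observed map, as is standard for permutation tests).
#'
#' @param preferred preference angle per neuron (degrees; NA allowed)
#' @param rows,cols grid dimensions (column-major neuron indexing)
#' @param n_perm number of permutations (>= 99 recommended)
#' @param seed RNG seed for the permutations
#' @return list with `statistic`, `null` (vector), `p_bound`
#' @export
map_smoothness <- function(preferred, rows, cols, n_perm = 99,
                           seed = NULL) {
  stopifnot(length(preferred) == rows * cols)
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(preferred, rows, cols)
  pairs_stat <- function(m) {
    dh <- orientation_diff(m[, -1], m[, -cols])
    dv <- orientation_diff(m[-1, ], m[-rows, ])
    median(c(dh, dv), na.rm = TRUE)
  }
  obs <- pairs_stat(m)
  null <- vapply(seq_len(n_perm), function(i)
    pairs_stat(matrix(sample(preferred), rows, cols)), numeric(1))
  list(statistic = obs, null = null,
       p_bound = (sum(null <= obs) + 1) / (n_perm + 1))
}

#' Joint-position error against the nearest training posture
#'
#' For every test posture the closest training posture under Euclidean
#' distance in joint space is found; the per-joint absolute angle
#' differences are pooled across joints and trials.
#'
#' @param test,train matrices with one posture per row, columns = joints
#'   (degrees)
#' @return list with `median`, `max` and the pooled `errors` vector
#' @export
joint_position_error <- function(test, train) {
  test <- as.matrix(test)
  train <- as.matrix(train)
  stopifnot(ncol(test) == ncol(train), nrow(train) >= 1)
  errs <- lapply(seq_len(nrow(test)), function(i) {
    d2 <- rowSums((train - matrix(test[i, ], nrow(train), ncol(train),
                                  byrow = TRUE))^2)
    abs(test[i, ] - train[which.min(d2), ])
  })
  pooled <- unlist(errs)
  list(median = median(pooled), max = max(pooled), errors = pooled)
}
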