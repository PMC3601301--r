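#' Calibrate the injected current that yields a target peak firing rate
#'
#' Thalamic drive is specified as an image/pattern of relative intensities;
#' the absolute current scale is found by bisection so that a neuron
#' receiving the maximum intensity fires at approximately `target` Hz
#' (100 Hz by default) over a 1-s probe.
#'
#' @param params neuron parameters of the driven class
#' @param target desired peak rate (Hz)
#' @param tol acceptable deviation (Hz)
#' @param duration probe length (ms)
#' @param dt probe step (ms)
#' @return calibrated current amplitude (pA)
#' @export
calibrate_input_current <- function(params = neuron_params("thalamic"),
                                    target = 100, tol = 5,
                                    duration = 1000, dt = 1) {
  rate_at <- function(amp) {
    st <- list(v = params[["vr"]], u = 0)
    n_spk <- 0
    for (t in seq_len(round(duration / dt))) {
      s <- step_neurons(params, st, i_ext = amp, dt = dt)
      st <- s$state
      n_spk <- n_spk + sum(s$fired)
    }
    n_spk / (duration / 1000)
  }
  lo <- 0
  hi <- 200
  while (rate_at(hi) < target) {
    hi <- hi * 2
    if (hi > 1e5) stop("calibration failed: rate target unreachable")
  }
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    r <- rate_at(mid)
    if (abs(r - target) <= tol) return(mid)
    if (r < target) lo <- mid else hi <- mid
  }
  stop("calibration did not converge to ", target, " +/- ", tol, " Hz")
}

#' Random thalamic stimulus pattern
#'
#' A fixed random subset of thalamic cells (fraction `sparsity`) receives
#' the calibrated current amplitude; the rest receive none.  The same seed
#' reproduces the same pattern.
#'
#' @param n_thalamic number of thalamic neurons
#' @param sparsity fraction of driven cells
#' @param amplitude current to each driven cell (pA); see
#'   [calibrate_input_current()]
#' @param seed RNG seed
#' @return current vector (pA)
#' @export
random_pattern <- function(n_thalamic, sparsity = 0.5, amplitude,
                           seed = NULL) {
  stopifnot(sparsity >= 0, sparsity <= 1, amplitude >= 0)
  if (!is.null(seed)) set.seed(seed)
  on <- sample.int(n_thalamic, round(sparsity * n_thalamic))
  cur <- rep(0, n_thalamic)
  cur[on] <- amplitude
  cur
}

#' Elongated oriented Gaussian stimulus image
#'
#' Anisotropic Gaussian intensity profile evaluated on the input grid,
#' rotated by `theta`.  Coordinates run over the unit square; intensities
#' are nonnegative with the maximum at the stimulus center.  Orientation is
#' defined modulo 180 degrees.
#'
#' @param center `c(x, y)` in `[0,1]^2`
#' @param theta orientation (degrees, 0 = major axis along x)
#' @param sigma_major,sigma_minor Gaussian spread along/across the major
#'   axis (visual-field units)
#' @param peak peak intensity
#' @param grid `c(rows, cols)` of the input sheet
#' @return `rows x cols` intensity matrix
#' @export
oriented_gaussian_image <- function(center = c(0.5, 0.5), theta = 0,
                                    sigma_major = 0.25, sigma_minor = 0.05,
                                    peak = 1, grid = c(22, 22)) {
  xs <- (seq_len(grid[2]) - 0.5) / grid[2]
  ys <- (seq_len(grid[1]) - 0.5) / grid[1]
  gx <- matrix(rep(xs, each = grid[1]), grid[1], grid[2]) - center[1]
  gy <- matrix(rep(ys, times = grid[2]), grid[1], grid[2]) - center[2]
  th <- theta * pi / 180
  a <- gx * cos(th) + gy * sin(th)    # along major axis
  b <- -gx * sin(th) + gy * cos(th)   # across
  peak * exp(-a^2 / (2 * sigma_major^2) - b^2 / (2 * sigma_minor^2))
}

#' Random training set of oriented stimuli
#'
#' @param n number of stimuli
#' @param seed RNG seed
#' @param margin keep centers at least this far from the field edge
#' @return data frame with `x`, `y`, `theta`
#' @export
random_oriented_stimuli <- function(n, seed = NULL, margin = 0.15) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(x = runif(n, margin, 1 - margin),
             y = runif(n, margin, 1 - margin),
             theta = runif(n, 0, 180))
}

#' Map an intensity image to thalamic currents
#'
#' Linear map: current = `amplitude * intensity / max intensity reference`.
#' Pixel `(row, col)` drives thalamic neuron `row + (col-1)*rows`
#' (column-major), matching [grid_layout()] indexing.
#'
#' @param img intensity matrix
#' @param amplitude calibrated current at unit intensity (pA)
#' @return current vector
#' @export
image_to_currents <- function(img, amplitude) {
  amplitude * as.numeric(img)
}

#' Simulated two-joint planar arm
#'
#' Link lengths are in visual-field units with the shoulder at the origin.
#' `theta1` is the shoulder angle from the x-axis, `theta2` the elbow
#' flexion relative to the upper arm; over `theta2` in (0, 180) the map from
#' joint space to end-effector position is injective.
#'
#' @param l1,l2 link lengths
#' @param theta1_range,theta2_range working joint ranges (degrees)
#' @return an `arm_model` list
#' @export
arm_model <- function(l1 = 1, l2 = 0.8, theta1_range = c(40, 140),
                      theta2_range = c(40, 140), frame_fraction = 0.6) {
  # camera frame fitted to the workspace of the central `frame_fraction` of
  # the joint ranges (population-vector commands are convex combinations of
  # preferred angles and cannot reach the extremes), so the blob's excursion
  # uses the full field of view
  shrink <- function(r) mean(r) + c(-0.5, 0.5) * frame_fraction * diff(r)
  t1r <- shrink(theta1_range); t2r <- shrink(theta2_range)
  th <- expand.grid(t1 = seq(t1r[1], t1r[2], length.out = 25),
                    t2 = seq(t2r[1], t2r[2], length.out = 25))
  a1 <- th$t1 * pi / 180
  a12 <- (th$t1 + th$t2) * pi / 180
  xs <- l1 * cos(a1) + l2 * cos(a12)
  ys <- l1 * sin(a1) + l2 * sin(a12)
  padx <- 0.1 * diff(range(xs)); pady <- 0.1 * diff(range(ys))
  structure(list(l1 = l1, l2 = l2, theta1_range = theta1_range,
                 theta2_range = theta2_range,
                 frame = list(x = range(xs) + c(-padx, padx),
                              y = range(ys) + c(-pady, pady))),
            class = "arm_model")
}

#' Forward kinematics of the two-joint arm
#'
#' Angles outside the working range are clamped with a warning.
#'
#' @param arm an [arm_model()]
#' @param theta `c(theta1, theta2)` degrees
#' @return end-effector position `c(x, y)`
#' @export
arm_forward <- function(arm, theta) {
  cl <- c(min(max(theta[1], arm$theta1_range[1]), arm$theta1_range[2]),
          min(max(theta[2], arm$theta2_range[1]), arm$theta2_range[2]))
  if (any(abs(cl - theta) > 1e-9))
    warning("joint angles outside working range; clamped")
  t1 <- cl[1] * pi / 180
  t12 <- (cl[1] + cl[2]) * pi / 180
  c(arm$l1 * cos(t1) + arm$l2 * cos(t12),
    arm$l1 * sin(t1) + arm$l2 * sin(t12))
}

#' Render the camera view of the arm's end effector
#'
#' A bright isotropic Gaussian blob is drawn at the image position of the
#' end effector, emulating the bright marker the visual system tracks.  The
#' camera frame is fixed, so the blob centroid moves continuously and
#' injectively with the joint angles.
#'
#' @param arm an [arm_model()]
#' @param theta joint angles (degrees)
#' @param grid image dimensions `c(rows, cols)`
#' @param sigma_px blob spread in pixels
#' @param peak peak intensity
#' @return intensity matrix (`rows x cols`)
#' @export
render_arm_view <- function(arm, theta, grid = c(22, 22), sigma_px = 2,
                            peak = 1) {
  pos <- arm_forward(arm, theta)
  fx <- (pos[1] - arm$frame$x[1]) / diff(arm$frame$x)   # in [0,1]
  fy <- (pos[2] - arm$frame$y[1]) / diff(arm$frame$y)
  cx <- fx * grid[2] + 0.5
  cy <- fy * grid[1] + 0.5
  cols <- matrix(rep(seq_len(grid[2]), each = grid[1]), grid[1], grid[2])
  rows <- matrix(rep(seq_len(grid[1]), times = grid[2]), grid[1], grid[2])
  peak * exp(-((cols - cx)^2 + (rows - cy)^2) / (2 * sigma_px^2))
}
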