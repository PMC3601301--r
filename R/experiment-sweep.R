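#' Default fixed couplings and sweep ranges for the coupling-strength sweep
#'
#' The excitatory-to-excitatory total and the thalamic input totals are held
#' constant; the sweep varies the total excitatory-to-inhibitory (`ei`) and
#' inhibitory-to-excitatory (`ie`) conductances, with the
#' inhibitory-to-inhibitory total locked at `ii_factor` times `ie`.  The
#' default ranges bracket the epileptic-to-WTA transition of the CAS
#' architecture (found by pilot search; the printed axes of the original
#' heat map are not recoverable).
#'
#' @return named list with `couplings`, `struct`, `gains`, `ei_range`,
#'   `ie_range`, `ii_factor`, `sparsity`
#' @export
sweep_defaults <- function() {
  list(couplings = list(ee = 400, ei = 400, ie = 2500, ii = 6000,
                        te = 80, ti = 15),
       struct = structure_defaults(), gains = gain_defaults(),
       ei_range = c(50, 400), ie_range = c(10, 2500),
       ii_factor = 2.4, sparsity = 0.5)
}

#' Canonical strong-coupling WTA operating point
#'
#' The coupling totals, structural parameters and input settings at which
#' the full-size CAS network (59x59 excitatory, 30x30 inhibitory, 22x22
#' thalamic over 2 mm x 2 mm) reliably settles into a stable winner-take-all
#' state by the third second: localized high-rate patches with the remainder
#' of the sheet silenced.
#'
#' @return named list with `couplings`, `struct`, `gains`, `sparsity`
#' @export
wta_exemplar <- function() {
  d <- sweep_defaults()
  list(couplings = d$couplings, struct = d$struct, gains = d$gains,
       sparsity = d$sparsity)
}

#' Simulate the canonical WTA exemplar once
#'
#' Builds the full-size CAS network at the [wta_exemplar()] operating
#' point, drives it with a fixed random thalamic pattern calibrated to a
#' ~100 Hz peak input rate, simulates `duration` ms and measures the third
#' second.
#'
#' @param seed controls wiring, pattern and initial state
#' @param exc,inh,thal population dimensions
#' @param duration,window simulated time and measurement window (ms)
#' @param input_amplitude thalamic current (pA); calibrated when `NULL`
#' @return list with `sparseness`, `active_fraction` (excitatory neurons at
#'   >= 2 Hz), `peak_measure`, `state`, `rates`, and the `record`
#' @export
run_wta_exemplar <- function(seed = 1, exc = c(59, 59), inh = c(30, 30),
                             thal = c(22, 22), duration = 3000,
                             window = c(2000, 3000),
                             input_amplitude = NULL) {
  ex <- wta_exemplar()
  set.seed(seed)
  net <- make_architecture("cas", exc = exc, inh = inh, thal = thal,
                           couplings = ex$couplings, struct = ex$struct,
                           gains = ex$gains)
  if (is.null(input_amplitude)) input_amplitude <- calibrate_input_current()
  pat <- random_pattern(net$populations$thal$layout$n, ex$sparsity,
                        input_amplitude, seed = seed + 100)
  cfg <- sim_config(duration = duration, seed = seed + 200,
                    record_window = window)
  rec <- simulate_network(net, list(thal = pat), cfg)
  rates <- spike_rates(rec, "exc", window)
  list(sparseness = sparseness(rates), active_fraction = mean(rates >= 2),
       peak_measure = wta_peak_measure(rates),
       state = classify_dynamics(rec, net$populations$exc$layout),
       rates = rates, record = rec)
}

#' Coupling-strength sweep over one architecture
#'
#' Every grid cell simulates the same wiring, the same random initial
#' state and the same random thalamic pattern; only the total
#' excitatory-to-inhibitory and inhibitory-to-excitatory conductances
#' differ (weights are rescaled multiplicatively, preserving per-neuron
#' sums at the new totals).  STDP is off, short-term plasticity on.  Each
#' cell runs `duration` ms and the third second is measured: sparseness of
#' excitatory spiking, the peak-rate WTA measure, and the dynamical-state
#' label.  A cell that fails numerically is marked invalid without
#' aborting the sweep.
#'
#' @param architecture passed to [make_architecture()]
#' @param ei_values,ie_values swept totals (nS); defaults span
#'   `defaults$ei_range` / `defaults$ie_range` on a `grid` x `grid` lattice
#' @param grid lattice resolution when values are not given explicitly
#' @param exc,inh,thal population dimensions
#' @param seed controls wiring, initial state and stimulus (all shared
#'   across cells)
#' @param duration,window simulated time and measurement window (ms)
#' @param defaults see [sweep_defaults()]
#' @param input_amplitude calibrated thalamic drive (pA); calibrated to a
#'   ~100 Hz peak rate when `NULL`
#' @return a `sweep_result` data frame with one row per cell
#' @export
run_sweep <- function(architecture = "cas", ei_values = NULL,
                      ie_values = NULL, grid = 8,
                      exc = c(59, 59), inh = c(30, 30), thal = c(22, 22),
                      seed = 1, duration = 3000, window = c(2000, 3000),
                      defaults = sweep_defaults(),
                      input_amplitude = NULL) {
  if (is.null(ei_values))
    ei_values <- seq(defaults$ei_range[1], defaults$ei_range[2],
                     length.out = grid)
  if (is.null(ie_values))
    ie_values <- seq(defaults$ie_range[1], defaults$ie_range[2],
                     length.out = grid)
  set.seed(seed)
  net <- make_architecture(architecture, exc = exc, inh = inh, thal = thal,
                           couplings = defaults$couplings,
                           struct = defaults$struct,
                           gains = defaults$gains)
  if (is.null(input_amplitude))
    input_amplitude <- calibrate_input_current()
  pattern <- random_pattern(net$populations$thal$layout$n,
                            defaults$sparsity, input_amplitude)
  cfg <- sim_config(duration = duration, seed = seed + 1,
                    record_window = window)
  base <- defaults$couplings
  cells <- expand.grid(ei = ei_values, ie = ie_values)
  res <- lapply(seq_len(nrow(cells)), function(ci) {
    ei <- cells$ei[ci]; ie <- cells$ie[ci]
    net2 <- net
    net2$projections$ei$weight <- net$projections$ei$weight * ei / base$ei
    net2$projections$ei$s_total <- ei
    net2$projections$ie$weight <- net$projections$ie$weight * ie / base$ie
    net2$projections$ie$s_total <- ie
    ii <- defaults$ii_factor * ie
    net2$projections$ii$weight <- net$projections$ii$weight * ii / base$ii
    net2$projections$ii$s_total <- ii
    tryCatch({
      rec <- simulate_network(net2, list(thal = pattern), cfg)
      rates <- spike_rates(rec, "exc", window)
      data.frame(
        ei = ei, ie = ie,
        sparseness = if (all(rates == 0)) NA_real_ else sparseness(rates),
        peak_measure = wta_peak_measure(rates),
        active_fraction = mean(rates >= 2),
        state = classify_dynamics(rec, net$populations$exc$layout),
        valid = TRUE)
    }, error = function(e)
      data.frame(ei = ei, ie = ie, sparseness = NA_real_,
                 peak_measure = NA_real_, active_fraction = NA_real_,
                 state = "invalid", valid = FALSE))
  })
  out <- do.call(rbind, res)
  attr(out, "architecture") <- architecture
  attr(out, "seed") <- seed
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Maximum sparseness per architecture over the same sweep
#'
#' Runs the (possibly subsampled) coupling sweep for each architecture
#' under identical stimulus and state seeds and reports the maximum
#' third-second excitatory sparseness attained anywhere on the grid.
#'
#' @param architectures character vector of architecture names
#' @param ... passed to [run_sweep()]
#' @return named numeric vector of sparseness maxima
#' @export
compare_architectures <- function(architectures = c("center_surround",
                                                    "inverse", "random",
                                                    "cas"), ...) {
  vapply(architectures, function(a) {
    s <- run_sweep(architecture = a, ...)$sparseness
    if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE)
  }, numeric(1))
}
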