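#' Simulation configuration
#'
#' @param dt integration step (ms); the membrane equation internally takes
#'   two half-steps per tick
#' @param duration simulated time (ms)
#' @param plasticity_cadence interval between weight updates and synaptic
#'   scaling (ms); must be a multiple of `dt`
#' @param seed RNG seed for the random initial recovery variables
#' @param record_window `c(t_start, t_end)` (ms) during which spikes are
#'   kept; `NULL` records everything
#' @return a `sim_config` list
#' @export
sim_config <- function(dt = 1, duration = 3000, plasticity_cadence = 50,
                       seed = NULL, record_window = NULL) {
  stopifnot(dt > 0, duration > 0)
  if (abs(plasticity_cadence / dt - round(plasticity_cadence / dt)) > 1e-9)
    stop("plasticity_cadence must be a multiple of dt")
  if (!is.null(record_window))
    stopifnot(length(record_window) == 2,
              record_window[1] < record_window[2])
  structure(list(dt = dt, duration = duration,
                 plasticity_cadence = plasticity_cadence, seed = seed,
                 record_window = record_window), class = "sim_config")
}

stdp_defaults <- function() {
  list(a_plus = 0.005, a_minus = 0.001, tau_plus = 20, tau_minus = 20,
       tau_c = 1000)
}

#' Instantiate the C++ simulation engine for a network
#'
#' Initial conditions: `v = -60` mV for every neuron, recovery `u` drawn
#' uniformly from 0-100 pA (using the current R RNG stream), all
#' conductances zero, short-term plasticity factors at 1, eligibility traces
#' at zero.
#'
#' @param net a `cas_network`
#' @param config a [sim_config()]
#' @return an engine handle (external pointer with metadata) of class
#'   `cas_engine`
#' @export
create_engine <- function(net, config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  pops <- lapply(net$populations, function(p) {
    st <- init_neuron_state(p$layout$n)
    list(n = p$layout$n, params = as.numeric(p$params), v = st$v, u = st$u)
  })
  projs <- lapply(net$projections, function(pr) {
    list(src = pr$src, dst = pr$dst, pre = as.integer(pr$pre),
         post = as.integer(pr$post), weight = pr$weight,
         inhibitory = isTRUE(pr$inhibitory), nmda_gain = pr$nmda_gain,
         gabab_gain = pr$gabab_gain, gabash_gain = pr$gabash_gain,
         tau_x = pr$tau_x, p = pr$p, plastic = isTRUE(pr$plastic),
         alpha = pr$alpha, s_total = pr$s_total,
         s_max = if (is.finite(pr$s_max)) pr$s_max else 1e18)
  })
  ptr <- .engine_create(pops, projs, config$dt, stdp_defaults(),
                        as.integer(round(config$plasticity_cadence /
                                           config$dt)))
  structure(list(ptr = ptr, net = net, config = config,
                 pop_names = names(net$populations),
                 proj_names = names(net$projections)),
            class = "cas_engine")
}

#' Advance an engine and collect spikes
#'
#' External currents are constant over the chunk; closed-loop experiments
#' call this repeatedly with updated currents.
#'
#' @param engine a `cas_engine`
#' @param duration chunk length (ms)
#' @param currents named list (by population) of injected depolarizing
#'   current vectors (pA); omitted populations receive none
#' @param record keep the spikes of this chunk
#' @return a `spike_record` data frame (`time`, `pop`, `neuron`); empty when
#'   `record = FALSE`
#' @export
run_engine <- function(engine, duration, currents = list(), record = TRUE) {
  ext <- lapply(engine$pop_names, function(nm) currents[[nm]])
  n_ticks <- as.integer(round(duration / engine$config$dt))
  raw <- .engine_run(engine$ptr, n_ticks, ext, record)
  spike_record(data.frame(time = raw$time,
                          pop = engine$pop_names[raw$pop],
                          neuron = raw$neuron),
               pop_sizes = vapply(engine$net$populations,
                                  function(p) p$layout$n, numeric(1)))
}

spike_record <- function(df, pop_sizes) {
  structure(df, class = c("spike_record", "data.frame"),
            pop_sizes = pop_sizes)
}

#' Run a network under a stimulus
#'
#' Orchestrates one complete simulation: engine creation (fresh initial
#' state from `config$seed`), tick loop over the stimulus segments, and
#' spike collection restricted to `config$record_window`.  Identical
#' network, stimulus and config give byte-identical spike records.
#'
#' Per tick the engine decays conductances, integrates the membrane and
#' recovery equations under the synaptic plus injected current, detects and
#' resets spikes, relaxes the short-term plasticity factors, delivers spikes
#' to target conductances (taking effect the next tick), and accumulates
#' STDP on plastic pathways; every `plasticity_cadence` ms weights integrate
#' their eligibility trace and are homeostatically rescaled.
#'
#' @param net a `cas_network`
#' @param stimulus either a current-vector list as in [run_engine()]
#'   (constant over the whole run) or a list of segments
#'   `list(duration=, currents=)`
#' @param config a [sim_config()]
#' @return a `spike_record`
#' @export
simulate_network <- function(net, stimulus, config = sim_config()) {
  eng <- create_engine(net, config)
  if (length(stimulus) == 0) {
    stimulus <- list(list(duration = config$duration, currents = list()))
  } else if (!is.null(stimulus$duration)) {
    stimulus <- list(stimulus)               # one explicit segment
  } else if (!(is.list(stimulus[[1]]) &&
               !is.null(stimulus[[1]]$duration))) {
    # constant currents for the whole run
    stimulus <- list(list(duration = config$duration, currents = stimulus))
  }
  win <- config$record_window
  t0 <- 0
  recs <- list()
  for (seg in stimulus) {
    rec_this <- is.null(win) ||
      (t0 < win[2] && t0 + seg$duration > win[1])
    recs[[length(recs) + 1]] <-
      run_engine(eng, seg$duration, seg$currents, record = rec_this)
    t0 <- t0 + seg$duration
  }
  out <- do.call(rbind, recs)
  if (!is.null(win)) out <- out[out$time >= win[1] & out$time < win[2], ]
  rownames(out) <- NULL
  spike_record(out, pop_sizes = vapply(net$populations,
                                       function(p) p$layout$n, numeric(1)))
}

#' Per-neuron spike counts and firing rates
#'
#' @param record a `spike_record`
#' @param pop population name
#' @param window `c(t0, t1)` ms; `NULL` uses all recorded spikes
#' @return numeric vector, one entry per neuron of the population
#' @export
spike_counts <- function(record, pop = "exc", window = NULL) {
  n <- attr(record, "pop_sizes")[[pop]]
  d <- record[record$pop == pop, ]
  if (!is.null(window)) d <- d[d$time >= window[1] & d$time < window[2], ]
  tabulate(d$neuron, nbins = n)
}

#' @rdname spike_counts
#' @export
spike_rates <- function(record, pop = "exc", window) {
  spike_counts(record, pop, window) / (diff(window) / 1000)
}

#' Write a spike raster as columnar text with a JSON metadata sidecar
#'
#' @param record a `spike_record`
#' @param file output path (`.tsv`); metadata goes to `paste0(file,".json")`
#' @param meta list of run metadata to store alongside
#' @export
write_spike_record <- function(record, file, meta = list()) {
  utils::write.table(as.data.frame(record), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta$pop_sizes <- as.list(attr(record, "pop_sizes"))
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE)
}
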