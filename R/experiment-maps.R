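#' Annealed GABA conductance schedule
#'
#' Inhibition onto excitatory cells rises linearly from zero at the start
#' of training to its plateau value one quarter of the way through, and
#' stays there.  Mimics the developmental shift of GABAergic signaling and
#' plays the role of the annealing schedule of abstract map-formation
#' models: early on a large fraction of the sheet is active for every
#' stimulus, late only a small winning patch.
#'
#' @param t simulated time (s)
#' @param plateau plateau conductance gain
#' @param total total training time (s)
#' @param ramp_end_fraction fraction of `total` at which the plateau is
#'   reached
#' @return gain at `t`
#' @export
gaba_annealing_schedule <- function(t, plateau = 1, total,
                                    ramp_end_fraction = 0.25) {
  stopifnot(total > 0, ramp_end_fraction > 0)
  pmin(pmax(t, 0) / (ramp_end_fraction * total), 1) * plateau
}

#' Default couplings and learning parameters for map training
#'
#' @return named list
#' @export
map_defaults <- function() {
  list(couplings = list(ee = 50, ei = 250, ie = 600, ii = 1440,
                        te = 150, ti = 15),
       struct = utils::modifyList(structure_defaults(),
                                  list(sigma_local = 0.15, r_min = 0.3,
                                       r_max = 0.7, sigma_annulus = 0.1,
                                       n_syn_annulus = 8,
                                       thal_rule = "topographic")),
       alpha = 80, s_max_frac = 0.12,
       sigma_major = 0.12, sigma_minor = 0.03)
}

#' Train an orientation map with STDP under annealed inhibition
#'
#' A CAS network with topographically limited thalamic input is driven by
#' elongated oriented Gaussian stimuli at random positions and
#' orientations; the thalamic-to-excitatory pathway is plastic (STDP with
#' synaptic scaling) while the GABA conductance onto excitatory cells
#' follows [gaba_annealing_schedule()].  Each stimulus is presented
#' `reps` times for `present_ms` each.  The trained map is then probed
#' with plasticity frozen (see [probe_orientation_map()]).
#'
#' The default scale (20x20 excitatory sheet, 200 stimuli x 3 repetitions,
#' 300 simulated seconds) is a desk-scale reduction of the full protocol
#' (60x60 sheet, 4000 stimuli x 20 repetitions, 40000 s); the training loop
#' is identical at any scale.
#'
#' @param exc,inh,thal population dimensions
#' @param n_stimuli,reps,present_ms stimulus protocol
#' @param alpha STDP learning rate on the input pathway
#' @param seed controls wiring, initial state and the stimulus set
#' @param defaults see [map_defaults()]
#' @param thal_radius maximum thalamic axon reach (mm)
#' @param probe run the orientation probe after training
#' @return list with `map` (preference/selectivity per excitatory neuron),
#'   `smoothness`, `active_fraction` (per presentation), `layout`,
#'   `presentation_s`
#' @export
train_orientation_map <- function(exc = c(20, 20), inh = c(10, 10),
                                  thal = c(22, 22), n_stimuli = 200,
                                  reps = 3, present_ms = 500,
                                  alpha = NULL, seed = 1,
                                  defaults = map_defaults(),
                                  thal_radius = 0.65, probe = TRUE) {
  if (is.null(alpha)) alpha <- defaults$alpha
  set.seed(seed)
  struct <- defaults$struct
  struct$thal_rule <- "topographic"
  struct$thal_radius <- thal_radius
  net <- make_architecture("cas", exc = exc, inh = inh, thal = thal,
                           couplings = defaults$couplings, struct = struct)
  # plastic input pathway: cap per-synapse weight so receptive fields must
  # keep several strong inputs rather than collapsing onto one
  net$projections$te$plastic <- TRUE
  net$projections$te$alpha <- alpha
  net$projections$te$s_max <- defaults$s_max_frac * defaults$couplings$te
  net$projections$te$weight <- scale_synapses(
    net$projections$te$weight, net$projections$te$post,
    net$projections$te$n_post, defaults$couplings$te,
    net$projections$te$s_max)

  amp <- calibrate_input_current()
  stims <- random_oriented_stimuli(n_stimuli)
  total_s <- n_stimuli * reps * present_ms / 1000
  cfg <- sim_config(duration = present_ms, seed = seed + 1)
  eng <- create_engine(net, cfg)
  ie_idx <- which(eng$proj_names == "ie")
  n_exc <- net$populations$exc$layout$n

  order_all <- unlist(lapply(seq_len(reps), function(r)
    sample.int(n_stimuli)))
  active_fraction <- numeric(length(order_all))
  t_s <- 0
  for (k in seq_along(order_all)) {
    st <- stims[order_all[k], ]
    img <- oriented_gaussian_image(c(st$x, st$y), st$theta,
                                   defaults$sigma_major,
                                   defaults$sigma_minor, 1, thal)
    .engine_set_gain(eng$ptr, ie_idx,
                     gaba_annealing_schedule(t_s, 1, total_s))
    rec <- run_engine(eng, present_ms, list(thal = image_to_currents(img, amp)))
    active_fraction[k] <- mean(spike_counts(rec, "exc") > 0)
    t_s <- t_s + present_ms / 1000
  }

  out <- list(net = net, engine = eng,
              active_fraction = active_fraction,
              layout = net$populations$exc$layout,
              presentation_s = total_s, input_amplitude = amp)
  if (probe) {
    pr <- probe_orientation_map(eng, thal, amp,
                                sigma_major = defaults$sigma_major,
                                sigma_minor = defaults$sigma_minor)
    out$map <- pr$map
    out$responses <- pr$responses
    out$smoothness <- map_smoothness(pr$map$preferred, exc[1], exc[2],
                                     n_perm = 99, seed = seed + 2)
  }
  out
}

#' Probe orientation preferences of a trained network
#'
#' Presents every probe orientation at a lattice of positions with
#' plasticity frozen and inhibition at its plateau, accumulating each
#' excitatory neuron's spike count per orientation; preference and
#' selectivity follow the orientation-doubled vector average
#' ([orientation_tuning()]).
#'
#' @param eng a `cas_engine` with a trained network
#' @param thal input grid dimensions
#' @param amp calibrated current amplitude (pA)
#' @param thetas probe orientations (degrees)
#' @param positions matrix of probe centers (rows = probes, columns x,y in
#'   `[0,1]`)
#' @param present_ms probe presentation time
#' @param sigma_major,sigma_minor probe stimulus shape
#' @return list with `map` data frame and the raw `responses` matrix
#' @export
probe_orientation_map <- function(eng, thal = c(22, 22), amp,
                                  thetas = seq(0, 157.5, by = 22.5),
                                  positions = as.matrix(expand.grid(
                                    seq(0.15, 0.85, length.out = 6),
                                    seq(0.15, 0.85, length.out = 6))),
                                  present_ms = 250,
                                  sigma_major = 0.25, sigma_minor = 0.05) {
  for (q in seq_along(eng$proj_names))
    .engine_set_alpha(eng$ptr, q, 0)   # freeze plasticity during probing
  ie_idx <- which(eng$proj_names == "ie")
  .engine_set_gain(eng$ptr, ie_idx, 1)
  n_exc <- eng$net$populations$exc$layout$n
  responses <- matrix(0, n_exc, length(thetas))
  for (ti in seq_along(thetas)) {
    for (pi in seq_len(nrow(positions))) {
      img <- oriented_gaussian_image(positions[pi, ], thetas[ti],
                                     sigma_major, sigma_minor, 1, thal)
      rec <- run_engine(eng, present_ms,
                        list(thal = image_to_currents(img, amp)))
      responses[, ti] <- responses[, ti] + spike_counts(rec, "exc")
    }
  }
  list(map = orientation_tuning(responses, thetas), responses = responses)
}
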