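#' Receptor time constants and reversal potentials
#'
#' Five receptor types are simulated: AMPA, NMDA, GABA-A, GABA-B and a slow
#' hyperpolarizing (SH) conductance used to bias neurons to stay off for long
#' periods (only active in the visuomotor experiment).  Each conductance
#' follows first-order kinetics \eqn{g' = -g/\tau}.
#'
#' @return named numeric vector of decay constants (ms) or reversal
#'   potentials (mV)
#' @export
receptor_tau <- function() {
  c(ampa = 5, nmda = 150, gabaa = 6, gabab = 150, sh = 5000)
}

#' @rdname receptor_tau
#' @export
receptor_reversal <- function() {
  c(ampa = 0, nmda = 0, gabaa = -70, gabab = -90, sh = -90)
}

#' Per-neuron receptor conductance state
#'
#' @param n number of postsynaptic neurons
#' @return list of five zero vectors, one per receptor type
#' @export
receptor_state <- function(n) {
  z <- rep(0, n)
  list(ampa = z, nmda = z, gabaa = z, gabab = z, sh = z)
}

#' Exponential decay of receptor conductances
#'
#' Applies the exact exponential update `g <- g * exp(-dt/tau)` to every
#' receptor channel.
#'
#' @param state a [receptor_state()]
#' @param dt elapsed time (ms)
#' @return decayed state
#' @export
decay_conductances <- function(state, dt) {
  stopifnot(dt > 0)
  tau <- receptor_tau()
  for (r in names(tau)) state[[r]] <- state[[r]] * exp(-dt / tau[[r]])
  state
}

#' Total synaptic current (outward positive)
#'
#' \deqn{I_{syn} = g_{AMPA} v + g_{NMDA} \frac{[(v+80)/60]^2}{1+[(v+80)/60]^2} v
#'   + g_{GABA_A}(v+70) + g_{GABA_B}(v+90) + g_{SH}(v+90)}
#' The NMDA term carries the voltage-dependent magnesium-block factor, which
#' vanishes exactly at -80 mV.
#'
#' @param state a [receptor_state()]
#' @param v membrane potential per neuron (mV)
#' @return current per neuron (pA); positive values hyperpolarize
#' @export
synaptic_current <- function(state, v) {
  stopifnot(all(is.finite(v)))
  mg <- ((v + 80) / 60)^2
  mg <- mg / (1 + mg)
  state$ampa * (v - 0) + state$nmda * mg * (v - 0) +
    state$gabaa * (v + 70) + state$gabab * (v + 90) + state$sh * (v + 90)
}

#' Deliver presynaptic spikes to receptor conductances
#'
#' Each firing of an excitatory presynaptic neuron `j` increments
#' `g_AMPA` of its targets by `x_j * s_ij` and `g_NMDA` by
#' `nmda_gain * x_j * s_ij`, where `s_ij` is the synaptic weight (nS) and
#' `x_j` the short-term plasticity factor.  Inhibitory sources increment
#' `g_GABA_A`, `g_GABA_B` (scaled by `gabab_gain`) and `g_SH` (scaled by
#' `gabash_gain`, zero outside the visuomotor experiment).
#'
#' This is the R reference path; the C++ engine performs the identical
#' update inside [simulate_network()].
#'
#' @param projection a projection as built by the `build_*` wiring
#'   functions: list with `pre`, `post`, `weight` and pathway gains
#' @param spikes logical vector of presynaptic spike flags
#' @param receptors [receptor_state()] of the target population
#' @param x short-term plasticity factor per presynaptic neuron (default 1)
#' @return updated receptor state
#' @export
deliver_spikes <- function(projection, spikes, receptors, x = NULL) {
  n_pre <- projection$n_pre
  if (length(spikes) != n_pre)
    stop("spike vector length does not match presynaptic population size")
  if (is.null(x)) x <- rep(1, n_pre)
  act <- spikes[projection$pre]
  if (!any(act)) return(receptors)
  g <- x[projection$pre[act]] * projection$weight[act]
  tgt <- projection$post[act]
  n_post <- projection$n_post
  add <- function(vec, inc) {
    vec + as.numeric(unname(
      tapply(inc, factor(tgt, levels = seq_len(n_post)), sum, default = 0)))
  }
  if (isTRUE(projection$inhibitory)) {
    receptors$gabaa <- add(receptors$gabaa, g)
    receptors$gabab <- add(receptors$gabab, projection$gabab_gain * g)
    receptors$sh <- add(receptors$sh, projection$gabash_gain * g)
  } else {
    receptors$ampa <- add(receptors$ampa, g)
    receptors$nmda <- add(receptors$nmda, projection$nmda_gain * g)
  }
  receptors
}

#' Short-term plasticity pathway constants
#'
#' Recovery time constant (ms) and spike-triggered reset multiplier for each
#' source/target class combination.  `p < 1` gives depression, `p > 1`
#' facilitation.
#'
#' @param src,dst neuron class of the presynaptic and postsynaptic
#'   population (`"excitatory"`, `"inhibitory"`, `"thalamic"`)
#' @return list with `tau_x` (ms) and `p`
#' @export
stp_pathway_params <- function(src, dst) {
  key <- paste(substr(src, 1, 1), substr(dst, 1, 1), sep = "")
  switch(key,
    ee = list(tau_x = 150, p = 0.8),
    ei = list(tau_x = 150, p = 0.8),
    ie = list(tau_x = 150, p = 0.8),
    ii = list(tau_x = 150, p = 0.8),
    te = list(tau_x = 150, p = 0.7),
    ti = list(tau_x = 200, p = 0.5),
    stop("no short-term plasticity entry for pathway ", src, " -> ", dst))
}

#' Short-term plasticity update
#'
#' The per-presynaptic-neuron factor `x` relaxes exponentially toward its
#' equilibrium value 1 with time constant `tau_x` (exact update), then every
#' neuron that fired has `x <- p * x` applied.
#'
#' @param x factor per presynaptic neuron
#' @param spikes logical spike flags
#' @param tau_x recovery time constant (ms)
#' @param p reset multiplier
#' @param dt elapsed time (ms)
#' @return updated `x`
#' @export
stp_update <- function(x, spikes, tau_x, p, dt = 1) {
  stopifnot(dt > 0)
  x <- 1 - (1 - x) * exp(-dt / tau_x)
  x[spikes] <- p * x[spikes]
  x
}

#' STDP window
#'
#' Exponential spike-timing-dependent plasticity window over the interspike
#' interval `t = t_post - t_pre`: potentiation `+A_plus * exp(-t/tau_plus)`
#' for `t > 0` (pre before post) and depression
#' `-A_minus * exp(-|t|/tau_minus)` for `t <= 0`.
#'
#' @param t interspike interval(s), ms
#' @param a_plus,a_minus window amplitudes (defaults 0.005 and 0.001)
#' @param tau_plus,tau_minus window time constants (ms, default 20)
#' @return weight-change factor per interval
#' @export
stdp_window <- function(t, a_plus = 0.005, a_minus = 0.001,
                        tau_plus = 20, tau_minus = 20) {
  ifelse(t > 0, a_plus * exp(-t / tau_plus),
         -a_minus * exp(-abs(t) / tau_minus))
}

#' Apply the 50-ms weight update from the eligibility trace
#'
#' The eligibility trace `c` accumulates STDP events and decays with a 1-s
#' time constant; weights integrate it (`ds/dt = c`) by one Euler step per
#' application interval, so `delta s = c * interval/1000`.
#'
#' @param weights synaptic weights (nS)
#' @param trace eligibility trace per synapse (nS/s)
#' @param interval application interval (ms, default 50)
#' @return updated weights
#' @export
apply_weight_updates <- function(weights, trace, interval = 50) {
  weights + trace * interval / 1000
}

#' Homeostatic synaptic scaling
#'
#' Per postsynaptic neuron, weights are clipped to `[0, s_max]`, multiplied
#' by `s_total / sum` so the incoming total matches the target, then
#' re-clipped.  If capping makes the target unreachable the weights are left
#' at the cap; a neuron with no incoming synapses is left untouched with a
#' warning.
#'
#' @param weights synaptic weights (nS)
#' @param post postsynaptic neuron index per synapse (1-based)
#' @param n_post number of postsynaptic neurons
#' @param s_total target incoming sum (nS); scalar or per-neuron vector
#' @param s_max per-synapse cap (nS)
#' @return scaled weights
#' @export
scale_synapses <- function(weights, post, n_post, s_total, s_max = Inf) {
  stopifnot(all(s_total > 0))
  s_total <- rep_len(s_total, n_post)
  w <- pmin(pmax(weights, 0), s_max)
  sums <- as.numeric(tapply(w, factor(post, levels = seq_len(n_post)),
                            sum, default = 0))
  empty <- tabulate(post, nbins = n_post) == 0
  if (any(empty))
    warning(sum(empty), " neuron(s) have no incoming synapses on a scaled ",
            "pathway; left untouched")
  f <- ifelse(sums > 0, s_total / sums, 1)
  pmin(w * f[post], s_max)
}
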