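#' Izhikevich neuron parameter sets
#'
#' Parameters of the two-variable quadratic integrate-and-fire model
#' \deqn{C \dot v = k (v - v_r)(v - v_t) - u - I_{syn} + I_{ext}}
#' \deqn{\dot u = a \{ b (v - v_r) - u \}}
#' with peak-and-reset: when \eqn{v > v_{peak}} the neuron spikes and
#' \eqn{v \leftarrow c}, \eqn{u \leftarrow u + d}.  Units: mV, pA, nS, ms, pF.
#'
#' Excitatory and thalamic cells default to the published regular-spiking
#' parameter set; inhibitory cells to a linearized fast-spiking set.  Any
#' field can be overridden.
#'
#' @param class one of `"excitatory"`, `"inhibitory"`, `"thalamic"`
#' @param ... named overrides of `C`, `k`, `vr`, `vt`, `a`, `b`, `c`, `d`,
#'   `vpeak`
#' @return an object of class `neuron_params` (named numeric vector)
#' @export
neuron_params <- function(class = c("excitatory", "inhibitory", "thalamic"),
                          ...) {
  class <- match.arg(class)
  p <- switch(class,
    excitatory = c(C = 100, k = 0.7, vr = -60, vt = -40, a = 0.03, b = -2,
                   c = -50, d = 100, vpeak = 35),
    thalamic   = c(C = 100, k = 0.7, vr = -60, vt = -40, a = 0.03, b = -2,
                   c = -50, d = 100, vpeak = 35),
    inhibitory = c(C = 20, k = 1, vr = -55, vt = -40, a = 0.2, b = 2,
                   c = -45, d = 0, vpeak = 25))
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown neuron parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(dots)] <- unlist(dots)
  }
  if (p[["C"]] <= 0) stop("capacitance C must be positive")
  if (p[["vt"]] <= p[["vr"]]) stop("threshold vt must exceed resting vr")
  if (p[["vpeak"]] <= p[["vt"]]) stop("vpeak must exceed vt")
  structure(p, class = "neuron_params", neuron_class = class)
}

#' Initial neuron state
#'
#' All membrane potentials start at -60 mV; the recovery variable is drawn
#' independently per neuron, uniformly from 0-100 pA.
#'
#' @param n number of neurons
#' @param v0 initial membrane potential (mV), default -60
#' @param u optional explicit recovery values; drawn uniformly if `NULL`
#' @return list with numeric vectors `v` and `u`
#' @export
init_neuron_state <- function(n, v0 = -60, u = NULL) {
  if (is.null(u)) u <- runif(n, 0, 100)
  stopifnot(length(u) == n)
  list(v = rep(v0, n), u = as.numeric(u))
}

#' Advance Izhikevich neurons by one time step
#'
#' Explicit integration of the model: the membrane potential is advanced in
#' two half-steps of `dt/2` (the quadratic term is stiff near spike onset),
#' then the recovery variable takes one full Euler step, then neurons with
#' `v > vpeak` are flagged as spiking and reset.  Each neuron spikes at most
#' once per step.
#'
#' `i_syn` follows the outward-positive convention of the conductance sum
#' (see [synaptic_current()]) and is subtracted; `i_ext` is an injected
#' depolarizing drive and is added.
#'
#' @param params a [neuron_params()] object
#' @param state list with vectors `v`, `u`
#' @param i_syn synaptic current per neuron (pA, outward positive)
#' @param i_ext injected current per neuron (pA, depolarizing positive)
#' @param dt step size (ms)
#' @return list with updated `state` and logical vector `fired`
#' @export
step_neurons <- function(params, state, i_syn = 0, i_ext = 0, dt = 1) {
  stopifnot(dt > 0, all(is.finite(i_syn)), all(is.finite(i_ext)))
  v <- state$v
  u <- state$u
  n <- length(v)
  i_syn <- rep_len(i_syn, n)
  i_ext <- rep_len(i_ext, n)
  for (h in 1:2) {
    dv <- (params[["k"]] * (v - params[["vr"]]) * (v - params[["vt"]]) -
             u - i_syn + i_ext) / params[["C"]]
    v <- ifelse(v > params[["vpeak"]], v, v + 0.5 * dt * dv)
  }
  u <- u + dt * params[["a"]] *
    (params[["b"]] * (pmin(v, params[["vpeak"]]) - params[["vr"]]) - u)
  if (any(!is.finite(v)) || any(!is.finite(u)))
    stop("non-finite neuron state after step; check parameters and dt")
  fired <- v > params[["vpeak"]]
  v[fired] <- params[["c"]]
  u[fired] <- u[fired] + params[["d"]]
  list(state = list(v = v, u = u), fired = fired)
}
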