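# shared fixtures: all built in code, small enough for fast tests

tiny_struct <- function() {
  utils::modifyList(structure_defaults(),
                    list(sigma_local = 0.3, n_syn_local = 15,
                         r_min = 0.3, r_max = 1.9, sigma_annulus = 0.5,
                         n_syn_annulus = 15, n_syn_thal = 8))
}

# small CAS network: 12x12 excitatory, 6x6 inhibitory, 6x6 thalamic
tiny_cas <- function(seed = 1, couplings = list(ee = 100, ei = 100,
                                                ie = 300, ii = 720,
                                                te = 60, ti = 15)) {
  set.seed(seed)
  make_architecture("cas", exc = c(12, 12), inh = c(6, 6), thal = c(6, 6),
                    couplings = couplings, struct = tiny_struct())
}

# single-population network with no synapses (isolated neurons)
bare_population <- function(n = 1, class = "excitatory") {
  structure(list(
    architecture = "bare",
    populations = list(exc = list(name = "exc", class = class,
                                  layout = grid_layout(n, 1),
                                  params = neuron_params(class))),
    projections = list()), class = "cas_network")
}

# two-population network with one configurable projection, for plasticity
# and delivery tests
two_pop_net <- function(n_pre = 4, n_post = 3, weight = 2, plastic = FALSE,
                        alpha = 0, s_total = NULL, s_max = Inf,
                        inhibitory = FALSE, nmda_gain = 0.5,
                        gabab_gain = 0.2, gabash_gain = 0) {
  pre_layout <- grid_layout(n_pre, 1)
  post_layout <- grid_layout(n_post, 1)
  pre <- rep(seq_len(n_pre), each = n_post)
  post <- rep(seq_len(n_post), times = n_pre)
  w <- rep(weight, length(pre))
  proj <- structure(list(
    pre = pre, post = post, weight = w,
    n_pre = n_pre, n_post = n_post,
    rule = "all_to_all", rule_params = list(),
    src = 1, dst = 2, inhibitory = inhibitory,
    nmda_gain = nmda_gain, gabab_gain = gabab_gain,
    gabash_gain = gabash_gain,
    tau_x = 150, p = 0.8, plastic = plastic, alpha = alpha,
    s_total = if (is.null(s_total)) -1 else s_total,
    s_max = s_max), class = "cas_projection")
  structure(list(
    architecture = "two-pop",
    populations = list(
      pre = list(name = "pre", class = if (inhibitory) "inhibitory"
                 else "excitatory",
                 layout = pre_layout,
                 params = neuron_params(if (inhibitory) "inhibitory"
                                        else "excitatory")),
      post = list(name = "post", class = "excitatory",
                  layout = post_layout,
                  params = neuron_params("excitatory"))),
    projections = list(main = proj)), class = "cas_network")
}

# synthetic spike record helper
fake_record <- function(time, pop, neuron, pop_sizes) {
  structure(data.frame(time = time, pop = pop, neuron = neuron),
            class = c("spike_record", "data.frame"), pop_sizes = pop_sizes)
}
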