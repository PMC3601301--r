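test_that("conductances decay exponentially with the receptor constants", {
  st <- receptor_state(1)
  expect_identical(decay_conductances(st, 5), st)   # zero fixed point

  tau <- receptor_tau()
  st$ampa <- 10
  expect_equal(decay_conductances(st, 5)$ampa, 10 / exp(1))
  st2 <- receptor_state(1); st2$sh <- 1
  expect_equal(decay_conductances(st2, 5000)$sh, 1 / exp(1))
  # e-fold at t = tau for every receptor type; exactness over repeated steps
  for (r in names(tau)) {
    s <- receptor_state(1); s[[r]] <- 3
    expect_equal(decay_conductances(s, tau[[r]])[[r]], 3 / exp(1))
    for (i in 1:7) s <- decay_conductances(s, 1)
    expect_equal(s[[r]], 3 * exp(-7 / tau[[r]]))
  }
})

test_that("synaptic current follows the conductance sum with magnesium block", {
  z <- receptor_state(3)
  expect_equal(synaptic_current(z, c(-80, 0, 50)), rep(0, 3))
  # NMDA contributes exactly nothing at -80 mV
  st <- receptor_state(1); st$nmda <- 7
  expect_equal(synaptic_current(st, -80), 0)
  # pure AMPA at rest: outward-positive convention gives -60 pA at -60 mV
  st <- receptor_state(1); st$ampa <- 1
  expect_equal(synaptic_current(st, -60), -60)
  # GABA-A reversal -70, GABA-B and SH reversal -90
  st <- receptor_state(1); st$gabaa <- 2
  expect_equal(synaptic_current(st, -70), 0)
  st <- receptor_state(1); st$gabab <- 2; st$sh <- 3
  expect_equal(synaptic_current(st, -90), 0)
})

test_that("spike delivery routes conductances by source class with gains", {
  net <- two_pop_net(n_pre = 2, n_post = 3, weight = 2, nmda_gain = 0.5)
  proj <- net$projections$main
  rec <- receptor_state(3)
  expect_identical(deliver_spikes(proj, c(FALSE, FALSE), rec), rec)
  out <- deliver_spikes(proj, c(TRUE, FALSE), rec)
  expect_equal(out$ampa, rep(2, 3))
  expect_equal(out$nmda, rep(1, 3))
  expect_equal(out$gabaa, rep(0, 3))
  # short-term factor scales the increment
  out2 <- deliver_spikes(proj, c(TRUE, FALSE), rec, x = c(0.5, 1))
  expect_equal(out2$ampa, rep(1, 3))
  # inhibitory source: GABA-A, GABA-B (gain) and SH (gain, zero by default)
  neti <- two_pop_net(n_pre = 2, n_post = 2, weight = 3, inhibitory = TRUE,
                      gabab_gain = 0.2, gabash_gain = 0)
  outi <- deliver_spikes(neti$projections$main, c(TRUE, TRUE),
                         receptor_state(2))
  expect_equal(outi$gabaa, rep(6, 2))
  expect_equal(outi$gabab, rep(1.2, 2))
  expect_equal(outi$sh, rep(0, 2))   # gain zero outside the reach experiment
  expect_equal(outi$ampa, rep(0, 2))
})

test_that("short-term plasticity recovers to one and resets by p per spike", {
  expect_equal(stp_update(1, FALSE, 150, 0.8, dt = 10), 1)
  expect_equal(stp_update(1, TRUE, 150, 0.8, dt = 1e-9), 0.8,
               tolerance = 1e-6)
  # periodic firing converges to the closed-form fixed point
  for (case in list(c(100, 150, 0.8), c(10, 200, 0.5), c(50, 150, 1.2))) {
    T_ <- case[1]; tau_x <- case[2]; p <- case[3]
    x <- 1
    x_before <- NA
    for (i in 1:300) {
      x <- 1 - (1 - x) * exp(-T_ / tau_x)   # relax for one period
      x_before <- x
      x <- p * x
    }
    xstar <- (1 - exp(-T_ / tau_x)) / (1 - p * exp(-T_ / tau_x))
    expect_equal(x_before, xstar, tolerance = 1e-8)
    # the package update reproduces the same trajectory
    xs <- 1
    for (i in 1:300) xs <- stp_update(xs, TRUE, tau_x, p, dt = T_)
    expect_equal(xs, p * xstar, tolerance = 1e-8)
  }
  # x stays in (0, 1] for depressing synapses
  x <- 1
  for (i in 1:100) {
    x <- stp_update(x, i %% 3 == 0, 150, 0.5, dt = 1)
    expect_true(x > 0 && x <= 1)
  }
})

test_that("STDP window has the stated amplitudes, decay and antisymmetry", {
  expect_equal(stdp_window(1e-12), 0.005, tolerance = 1e-6)
  expect_equal(stdp_window(0), -0.001)
  expect_equal(stdp_window(20), 0.005 / exp(1))
  expect_equal(stdp_window(-20), -0.001 / exp(1))
  t <- seq(-100, 100, by = 0.5)
  w <- stdp_window(t)
  expect_true(all(w[t > 0] >= 0))
  expect_true(all(w[t <= 0] <= 0))
})

test_that("weight updates integrate the eligibility trace per interval", {
  expect_equal(apply_weight_updates(c(1, 2), c(0, 0)), c(1, 2))
  expect_equal(apply_weight_updates(1, 0.1, interval = 50), 1.005)
})

test_that("synaptic scaling restores per-neuron sums with clipping", {
  expect_equal(scale_synapses(c(1, 2, 3), c(1, 1, 1), 1, 3),
               c(0.5, 1, 1.5))
  w <- c(1, 2, 3)
  expect_equal(scale_synapses(w, c(1, 1, 1), 1, 6), w)   # already at target
  # clip to s_max, rescale, re-clip
  expect_equal(scale_synapses(c(5, 5), c(1, 1), 1, 6, s_max = 4), c(3, 3))
  # per-neuron grouping
  out <- scale_synapses(c(1, 1, 4), c(1, 1, 2), 2, c(4, 8))
  expect_equal(out, c(2, 2, 8))
  # empty neuron warns, others scaled
  expect_warning(out2 <- scale_synapses(c(1, 3), c(1, 1), 2, 8),
                 "no incoming")
  expect_equal(out2, c(2, 6))
  # property: conservation and bounds over random cases
  set.seed(42)
  for (i in 1:20) {
    n_post <- sample(2:5, 1)
    post <- sample(seq_len(n_post), 40, replace = TRUE)
    w <- runif(40, 0, 3)
    smax <- runif(1, 1, 4)
    stot <- runif(1, 0.5, 4)
    out <- scale_synapses(w, post, n_post, stot, smax)
    expect_true(all(out >= 0 & out <= smax + 1e-12))
    sums <- tapply(out, factor(post, levels = seq_len(n_post)), sum,
                   default = stot)
    # sums match the target exactly unless the cap bound; a shortfall is
    # only legitimate when at least one synapse sits at the cap
    has_cap <- tapply(out, factor(post, levels = seq_len(n_post)),
                      function(x) any(x >= smax - 1e-9), default = TRUE)
    expect_true(all(sums <= stot + 1e-9))
    expect_true(all(abs(sums - stot) < 1e-9 | has_cap))
  }
})
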