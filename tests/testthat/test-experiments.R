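# fast, reduced-scale checks of the three experiment drivers; the full-scale
# statistical claims live in test-acceptance.R

test_that("sweep results carry per-cell metrics and are deterministic", {
  d <- sweep_defaults()
  d$struct <- tiny_struct()
  d$couplings <- list(ee = 100, ei = 100, ie = 300, ii = 720,
                      te = 60, ti = 15)
  sw <- run_sweep("cas", ei_values = c(50, 100), ie_values = c(50, 300),
                  exc = c(12, 12), inh = c(6, 6), thal = c(6, 6),
                  seed = 1, duration = 1500, window = c(500, 1500),
                  defaults = d, input_amplitude = 700)
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw), 4)
  expect_true(all(sw$valid))
  expect_true(all(sw$state %in% c("wta", "traveling_wave",
                                  "transient_rhythmic", "epileptic",
                                  "other")))
  sw2 <- run_sweep("cas", ei_values = c(50, 100), ie_values = c(50, 300),
                   exc = c(12, 12), inh = c(6, 6), thal = c(6, 6),
                   seed = 1, duration = 1500, window = c(500, 1500),
                   defaults = d, input_amplitude = 700)
  expect_identical(as.data.frame(sw), as.data.frame(sw2))
  # the maximum over a subset of cells never exceeds the full-grid maximum
  expect_lte(max(sw$sparseness[1:2], na.rm = TRUE),
             max(sw$sparseness, na.rm = TRUE))
})

test_that("the annealing schedule ramps linearly to its plateau", {
  expect_equal(gaba_annealing_schedule(0, 1, total = 100), 0)
  expect_equal(gaba_annealing_schedule(25, 1, total = 100), 1)
  expect_equal(gaba_annealing_schedule(80, 1, total = 100), 1)
  expect_equal(gaba_annealing_schedule(12.5, 1, total = 100), 0.5)
  expect_equal(gaba_annealing_schedule(12.5, 3, total = 100), 1.5)
})

test_that("map training runs at reduced scale and conserves plastic sums", {
  res <- train_orientation_map(n_stimuli = 12, reps = 1, present_ms = 300,
                               seed = 3, probe = FALSE)
  expect_length(res$active_fraction, 12)
  expect_true(all(res$active_fraction >= 0 & res$active_fraction <= 1))
  eng <- res$engine
  q <- which(eng$proj_names == "te")
  syn <- casnet:::.engine_get_synapses(eng$ptr, q)
  sums <- tapply(syn$weight, syn$post, sum)
  target <- res$net$projections$te$s_total
  # conservation up to cap-induced shortfall
  expect_true(all(sums <= target + 1e-6))
  expect_gt(mean(abs(sums - target) < 1e-6), 0.95)
})

test_that("population-vector decoding averages preferred angles by rate", {
  lay <- grid_layout(4, 4)
  arm <- arm_model()
  map <- motor_map(lay, arm)
  expect_equal(range(map[, 1]), arm$theta1_range, tolerance = 12)
  r <- rep(0, 16); r[5] <- 3
  expect_equal(decode_population_vector(r, map, c(0, 0)),
               as.numeric(map[5, ]))
  r2 <- rep(0, 16); r2[c(2, 9)] <- 4
  expect_equal(decode_population_vector(r2, map, c(0, 0)),
               as.numeric((map[2, ] + map[9, ]) / 2))
  expect_equal(decode_population_vector(rep(0, 16), map, c(77, 88)),
               c(77, 88))
  expect_equal(decode_population_vector(c(2, rep(0, 15)),
                                        cbind(c(10, rep(0, 15)),
                                              c(20, rep(0, 15))),
                                        c(0, 0)), c(10, 20))
})

test_that("a short babbling phase logs distinct postures per spot and keeps
           visuomotor sums normalized", {
  d <- reach_defaults()
  d$reps <- 1
  sys <- build_reach_system(d, seed = 4)
  suppressWarnings(tr <- run_babbling(sys, seed = 5))
  expect_equal(dim(tr$train_log), c(9, 2))
  expect_true(all(is.finite(tr$train_log)))
  # nine spots produce nine distinct equilibrium postures
  expect_equal(nrow(unique(round(tr$train_log, 1))), 9)
  eng <- tr$engine
  q <- which(eng$proj_names == "vm")
  syn <- casnet:::.engine_get_synapses(eng$ptr, q)
  sums <- tapply(syn$weight, syn$post, sum)
  expect_true(all(abs(sums - d$vm_total) < 1e-6))
  expect_true(all(syn$weight >= 0 &
                    syn$weight <= d$vm_smax_frac * d$vm_total + 1e-9))
})
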