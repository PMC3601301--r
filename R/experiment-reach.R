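#' Predetermined motor map of preferred joint angles
#'
#' Each motor excitatory neuron is assigned a preferred pair of joint
#' angles; preferences vary linearly with grid position (first joint along
#' columns, second along rows), so nearby neurons prefer similar angles and
#' the map tiles the working ranges.
#'
#' @param layout [grid_layout()] of the motor excitatory population
#' @param arm an [arm_model()] supplying the joint ranges
#' @return `n x 2` matrix of preferred angles (degrees)
#' @export
motor_map <- function(layout, arm = arm_model()) {
  fx <- layout$pos[, 1] / layout$extent
  fy <- layout$pos[, 2] / layout$extent
  cbind(theta1 = arm$theta1_range[1] + fx * diff(arm$theta1_range),
        theta2 = arm$theta2_range[1] + fy * diff(arm$theta2_range))
}

#' Population-vector decoding of motor activity
#'
#' The preferred joint angles of all motor neurons, weighted by their
#' firing rates and normalized by the total rate, give the commanded
#' equilibrium posture.  With no activity the previous posture is held.
#'
#' @param rates firing rates per motor neuron (Hz, nonnegative)
#' @param map preferred-angle matrix from [motor_map()]
#' @param fallback posture returned when the total rate is zero
#' @return `c(theta1, theta2)` degrees
#' @export
decode_population_vector <- function(rates, map, fallback) {
  stopifnot(all(rates >= 0), length(rates) == nrow(map))
  tot <- sum(rates)
  if (tot == 0) return(fallback)
  as.numeric(crossprod(map, rates) / tot)
}

#' Default sizes, couplings and protocol for the visuomotor experiment
#'
#' Two CAS areas: a visual sheet (V) receiving camera input through the
#' thalamic grid and a motor sheet (M) read out by population-vector
#' decoding.  V excitatory neurons project all-to-all and plastically to M
#' excitatory neurons.  Desk-scale reduction of the original areas
#' (V 3481+900, M 1600+400).
#'
#' @return named list
#' @export
reach_defaults <- function() {
  list(v_exc = c(20, 20), v_inh = c(10, 10), thal = c(22, 22),
       m_exc = c(20, 20), m_inh = c(10, 10),
       v_couplings = list(ee = 20, ei = 100, ie = 100, ii = 240,
                          te = 150, ti = 15),
       m_couplings = list(ee = 50, ei = 250, ie = 1200, ii = 2880),
       struct = utils::modifyList(structure_defaults(),
                                  list(sigma_local = 0.15, r_min = 0.3,
                                       r_max = 0.7, sigma_annulus = 0.1,
                                       n_syn_annulus = 8,
                                       thal_rule = "topographic")),
       m_struct = utils::modifyList(structure_defaults(),
                                    list(sigma_local = 0.15, r_min = 0.3,
                                         r_max = 0.7, sigma_annulus = 0.1,
                                         n_syn_annulus = 8,
                                         thal_rule = "uniform",
                                         n_syn_thal = 1)),
       vm_total = 15, vm_smax_frac = 0.12, vm_alpha = 80,
       sh_gain = 0.2, sh_off_s = 45,
       trial_ms = 450, motor_period_ms = 250, reps = 15, blank_ms = 300,
       settle_ms = 100,
       stim_sigma = 0.3, stim_gain = 5,
       gabash_pathways = c("v_ie", "v_ii", "m_ie", "m_ii"))
}

all_to_all_projection <- function(pre, post, s_total, s_max) {
  w <- runif(pre$n * post$n, 0.5, 1.5)
  wiring <- list(pre = rep(seq_len(pre$n), times = post$n),
                 post = rep(seq_len(post$n), each = pre$n),
                 weight = w, n_pre = pre$n, n_post = post$n)
  pr <- finish_projection(wiring, "all_to_all", list(s_total = s_total))
  pr$weight <- scale_synapses(pr$weight, pr$post, pr$n_post, s_total, s_max)
  pr
}

#' Build the coupled visual + motor system with a simulated arm world
#'
#' @param defaults see [reach_defaults()]
#' @param arm an [arm_model()]
#' @param seed RNG seed controlling all wiring and initial weights
#' @return list with the combined `cas_network`, the `arm`, the motor
#'   [motor_map()], stimulation spot centers, and metadata
#' @export
build_reach_system <- function(defaults = reach_defaults(),
                               arm = arm_model(), seed = 1) {
  set.seed(seed)
  struct <- defaults$struct
  struct$thal_rule <- "topographic"
  v <- make_architecture("cas", exc = defaults$v_exc, inh = defaults$v_inh,
                         thal = defaults$thal,
                         couplings = defaults$v_couplings, struct = struct)
  # the motor sheet gets no thalamic input; the placeholder input pathways
  # built here are dropped below (their sparse-wiring warnings with them)
  m <- suppressWarnings(
    make_architecture("cas", exc = defaults$m_exc, inh = defaults$m_inh,
                      thal = c(2, 2),
                      couplings = c(defaults$m_couplings,
                                    list(te = 1, ti = 1)),
                      struct = defaults$m_struct))
  pops <- list(thal = v$populations$thal,
               v_exc = v$populations$exc, v_inh = v$populations$inh,
               m_exc = m$populations$exc, m_inh = m$populations$inh)
  pops$v_exc$name <- "v_exc"; pops$v_inh$name <- "v_inh"
  pops$m_exc$name <- "m_exc"; pops$m_inh$name <- "m_inh"
  idx <- c(thal = 1, v_exc = 2, v_inh = 3, m_exc = 4, m_inh = 5)
  remap <- function(pr, src, dst) { pr$src <- idx[[src]]; pr$dst <- idx[[dst]]; pr }
  projections <- list(
    v_ee = remap(v$projections$ee, "v_exc", "v_exc"),
    v_ei = remap(v$projections$ei, "v_exc", "v_inh"),
    v_ie = remap(v$projections$ie, "v_inh", "v_exc"),
    v_ii = remap(v$projections$ii, "v_inh", "v_inh"),
    v_te = remap(v$projections$te, "thal", "v_exc"),
    v_ti = remap(v$projections$ti, "thal", "v_inh"),
    m_ee = remap(m$projections$ee, "m_exc", "m_exc"),
    m_ei = remap(m$projections$ei, "m_exc", "m_inh"),
    m_ie = remap(m$projections$ie, "m_inh", "m_exc"),
    m_ii = remap(m$projections$ii, "m_inh", "m_inh"))
  vm <- all_to_all_projection(pops$v_exc$layout, pops$m_exc$layout,
                              defaults$vm_total,
                              defaults$vm_smax_frac * defaults$vm_total)
  vm <- attach_pathway(vm, idx[["v_exc"]], idx[["m_exc"]],
                       "excitatory", "excitatory",
                       s_total = defaults$vm_total,
                       s_max = defaults$vm_smax_frac * defaults$vm_total,
                       gains = gain_defaults(), plastic = TRUE,
                       alpha = defaults$vm_alpha)
  projections$vm <- vm
  net <- structure(list(architecture = "cas-visuomotor",
                        populations = pops, projections = projections),
                   class = "cas_network")
  mlayout <- pops$m_exc$layout
  spots <- as.matrix(expand.grid(x = mlayout$extent * c(0.15, 0.5, 0.85),
                                 y = mlayout$extent * c(0.15, 0.5, 0.85)))
  list(net = net, arm = arm, motor_map = motor_map(mlayout, arm),
       spots = spots, defaults = defaults, seed = seed)
}

# current bump injected into motor excitatory neurons around a spot center
spot_current <- function(layout, center, amplitude, sigma) {
  d2 <- (layout$pos[, 1] - center[1])^2 + (layout$pos[, 2] - center[2])^2
  amplitude * exp(-d2 / (2 * sigma^2))
}

# advance the closed sensorimotor loop by one motor period: constant camera
# input rendered from the current posture, optional motor stimulation, then
# population-vector decoding of the motor rates in the period
reach_step <- function(eng, sys, posture, period_ms, m_current, amp) {
  img <- render_arm_view(sys$arm, posture)
  cur <- list(thal = image_to_currents(img, amp))
  if (!is.null(m_current)) cur$m_exc <- m_current
  rec <- run_engine(eng, period_ms, cur)
  rates <- spike_counts(rec, "m_exc") / (period_ms / 1000)
  decode_population_vector(rates, sys$motor_map, fallback = posture)
}

#' Motor-babbling training phase
#'
#' Repeatedly injects current into one of nine spots of the motor sheet
#' (450 ms per trial, `reps` repetitions of the nine postures).  The evoked
#' motor patch drives the arm through population-vector decoding every
#' 250 ms; the camera view of the resulting posture feeds the visual sheet,
#' and STDP with sum normalization on the all-to-all visual-to-motor
#' pathway associates co-active visual and motor patches.  The slow
#' hyperpolarizing receptor is active (gain `sh_gain`) for the first
#' `sh_off_s` simulated seconds, then switched off.
#'
#' @param sys from [build_reach_system()]
#' @param seed seed for the engine's initial state
#' @param stim_amplitude peak injected current (pA); calibrated when `NULL`
#' @return list with the live `engine`, the training posture log (matrix,
#'   9 rows per repetition), and the input amplitude
#' @export
run_babbling <- function(sys, seed = 1, stim_amplitude = NULL) {
  d <- sys$defaults
  cfg <- sim_config(duration = d$trial_ms, seed = seed)
  eng <- create_engine(sys$net, cfg)
  for (nm in d$gabash_pathways)
    .engine_set_gabash(eng$ptr, which(eng$proj_names == nm), d$sh_gain)
  amp <- calibrate_input_current()
  if (is.null(stim_amplitude)) stim_amplitude <- d$stim_gain * amp
  mlayout <- sys$net$populations$m_exc$layout
  posture <- c(90, 90)
  n_spots <- nrow(sys$spots)
  log <- matrix(NA_real_, d$reps * n_spots, 2)
  sh_on <- TRUE
  t_ms <- 0
  for (rep in seq_len(d$reps)) {
    for (k in seq_len(n_spots)) {
      # short blank between trials: the previous winner patch dies out, so
      # the next stimulation selects its own patch rather than inheriting
      run_engine(eng, d$blank_ms, list(), record = FALSE)
      t_ms <- t_ms + d$blank_ms
      mcur <- spot_current(mlayout, sys$spots[k, ], stim_amplitude,
                           d$stim_sigma)
      # an early decode ~100 ms after stimulation onset mirrors the fast
      # open-loop settling of the stimulated patch; afterwards the arm is
      # re-decoded on the regular motor cadence, so the camera shows the
      # commanded posture for most of the trial
      chunks <- diff(unique(sort(c(0, d$settle_ms,
                                   seq(d$motor_period_ms, d$trial_ms,
                                       by = d$motor_period_ms),
                                   d$trial_ms))))
      for (chunk in chunks) {
        posture <- reach_step(eng, sys, posture, chunk, mcur, amp)
        t_ms <- t_ms + chunk
        if (sh_on && t_ms >= d$sh_off_s * 1000) {
          for (nm in d$gabash_pathways)
            .engine_set_gabash(eng$ptr, which(eng$proj_names == nm), 0)
          sh_on <- FALSE
        }
      }
      log[(rep - 1) * n_spots + k, ] <- posture
    }
  }
  list(engine = eng, train_log = log, input_amplitude = amp,
       stim_amplitude = stim_amplitude)
}

#' Visually guided reaching test
#'
#' Motor stimulation is off and plasticity frozen; the bright target is
#' rendered at each of the nine visual locations occupied during training
#' (the camera positions of the trained postures).  The visual response
#' drives the motor sheet through the learned pathway; the decoded posture
#' after settling (the final motor period of each 450-ms trial) is logged
#' and compared with the nearest training posture.
#'
#' @param trained result of [run_babbling()]
#' @param sys from [build_reach_system()]
#' @param repeats presentations per target location
#' @return list with `test_log`, `target_postures` and the pooled
#'   [joint_position_error()]
#' @export
run_reach_test <- function(trained, sys, repeats = 1) {
  d <- sys$defaults
  eng <- trained$engine
  for (q in seq_along(eng$proj_names))
    .engine_set_alpha(eng$ptr, q, 0)
  n_spots <- nrow(sys$spots)
  # the nine postures reached at the end of training (last repetition)
  targets <- trained$train_log[(nrow(trained$train_log) - n_spots + 1):
                                 nrow(trained$train_log), , drop = FALSE]
  log <- matrix(NA_real_, repeats * n_spots, 2)
  side <- c(sys$arm$theta1_range[1], sys$arm$theta2_range[1])
  for (r in seq_len(repeats)) {
    for (k in seq_len(n_spots)) {
      # blank interval between placements: activity dies out so each target
      # is evaluated from rest rather than from the previous trial's patch
      run_engine(eng, d$blank_ms, list(), record = FALSE)
      posture <- side   # arm starts at its side; vision shows the target
      shown <- targets[k, ]
      decoded <- posture
      remaining <- d$trial_ms
      while (remaining > 0) {
        chunk <- min(d$motor_period_ms, remaining)
        img <- render_arm_view(sys$arm, shown)
        cur <- list(thal = image_to_currents(img, trained$input_amplitude))
        rec <- run_engine(eng, chunk, cur)
        rates <- spike_counts(rec, "m_exc") / (chunk / 1000)
        decoded <- decode_population_vector(rates, sys$motor_map,
                                            fallback = decoded)
        remaining <- remaining - chunk
      }
      log[(r - 1) * n_spots + k, ] <- decoded
    }
  }
  list(test_log = log, target_postures = targets,
       error = joint_position_error(log, trained$train_log))
}

#' One full visuomotor learning experiment
#'
#' Builds the system, runs motor babbling, then the visually guided test.
#'
#' @param seed controls wiring, initial weights and state
#' @param alpha learning rate on the visual-to-motor pathway (0 gives the
#'   no-learning ablation)
#' @param defaults see [reach_defaults()]
#' @return list with `train_log`, `test_log`, `error`
#' @export
reach_experiment <- function(seed = 1, alpha = NULL,
                             defaults = reach_defaults()) {
  if (!is.null(alpha)) defaults$vm_alpha <- alpha
  sys <- build_reach_system(defaults, seed = seed)
  trained <- run_babbling(sys, seed = seed + 1)
  test <- run_reach_test(trained, sys)
  list(train_log = trained$train_log, test_log = test$test_log,
       error = test$error, sys = sys, trained = trained)
}
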