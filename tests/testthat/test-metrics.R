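test_that("sparseness identities and example value hold", {
  expect_equal(sparseness(c(0, 0, 5, 0)), 1)
  expect_equal(sparseness(rep(3, 10)), 0)
  expect_equal(sparseness(c(4, 2, 0, 0)), (1 - 0.45) / 0.75)
  r <- c(4, 2, 0, 0, 7, 1)
  expect_equal(sparseness(r), sparseness(13 * r))   # scale invariance
  expect_error(sparseness(rep(0, 5)), "no activity")
  expect_error(sparseness(c(-1, 2, 3)))
})

test_that("the peak-rate WTA measure applies the half-below-2Hz constraint", {
  expect_equal(wta_peak_measure(rep(10, 20)), 0)
  r <- c(rep(0, 60), rep(80, 40))
  expect_equal(wta_peak_measure(r), 80)
  # exactly half below the threshold counts as satisfied
  r2 <- c(rep(0, 50), rep(40, 50))
  expect_equal(wta_peak_measure(r2), 40)
  r3 <- c(rep(1.9, 49), rep(40, 51))
  expect_equal(wta_peak_measure(r3), 0)
  expect_gte(wta_peak_measure(runif(100, 0, 50)), 0)
})

test_that("dynamical states are classified from constructed rasters", {
  lay <- grid_layout(10, 10)
  sizes <- c(exc = 100)
  # one static active block firing through the window -> wta
  block <- 34:36
  t <- rep(seq(2000, 2995, by = 5), each = length(block))
  rec <- fake_record(t, "exc", rep(block, 200), sizes)
  expect_equal(classify_dynamics(rec, lay), "wta")
  # a small block translating across a larger sheet -> traveling wave
  lay_big <- grid_layout(20, 20)
  sizes_big <- c(exc = 400)
  steps <- seq(2000, 2980, by = 20)
  lead <- seq_along(steps) * 6   # moves 6 neurons (0.6 mm) per 20 ms
  tt <- rep(steps, each = 30) + rep(seq(0, 18, length.out = 30),
                                    times = length(steps))
  nn <- as.integer(rep(lead, each = 30) + rep(0:2, times = 10 * length(steps)))
  keep <- nn <= 400
  rec_w <- fake_record(tt[keep], "exc", nn[keep], sizes_big)
  expect_equal(classify_dynamics(rec_w, lay_big), "traveling_wave")
  # all neurons firing at ~20 Hz -> epileptic
  set.seed(1)
  n_ev <- 100 * 20
  rec_e <- fake_record(runif(n_ev, 2000, 3000), "exc",
                       rep(1:100, each = 20), sizes)
  expect_equal(classify_dynamics(rec_e, lay), "epileptic")
  # empty record -> other
  rec_0 <- fake_record(numeric(0), character(0), integer(0), sizes)
  expect_equal(classify_dynamics(rec_0, lay), "other")
})

test_that("orientation tuning follows the doubled-angle vector average", {
  resp <- matrix(0, 3, 4)
  thetas <- c(0, 45, 90, 135)
  resp[1, 2] <- 10                       # responds only at 45 degrees
  resp[2, ] <- 5                         # uniform
  resp[3, c(2, 4)] <- 8                  # two peaks 90 degrees apart
  out <- orientation_tuning(resp, thetas)
  expect_equal(out$preferred[1], 45)
  expect_equal(out$selectivity[1], 1)
  expect_equal(out$selectivity[2], 0, tolerance = 1e-12)
  expect_equal(out$selectivity[3], 0, tolerance = 1e-12)
})

test_that("orientation differences use the 180-degree period", {
  expect_equal(orientation_diff(10, 170), 20)
  expect_equal(orientation_diff(0, 90), 90)
  expect_equal(orientation_diff(179, 1), 2)
})

test_that("map smoothness separates smooth maps from scrambled ones", {
  rows <- cols <- 12
  expect_equal(map_smoothness(rep(42, rows * cols), rows, cols,
                              seed = 1)$statistic, 0)
  # synthetic pinwheel: orientation = half the polar angle around the center
  gx <- rep(seq_len(cols), each = rows) - (cols + 1) / 2
  gy <- rep(seq_len(rows), times = cols) - (rows + 1) / 2
  pinwheel <- (atan2(gy, gx) * 90 / pi) %% 180
  sm <- map_smoothness(pinwheel, rows, cols, n_perm = 99, seed = 2)
  expect_true(all(sm$null > sm$statistic))
  expect_equal(sm$p_bound, 1 / 100)
  # iid random map sits inside its own null distribution
  set.seed(3)
  rnd <- runif(rows * cols, 0, 180)
  sm_r <- map_smoothness(rnd, rows, cols, n_perm = 99, seed = 4)
  expect_gt(sm_r$p_bound, 0.05)
})

test_that("joint position error matches a brute-force nearest-neighbor scan", {
  train <- as.matrix(expand.grid(t1 = c(60, 90, 120), t2 = c(60, 90, 120)))
  expect_equal(joint_position_error(train, train)$max, 0)
  test1 <- train
  test1[5, 1] <- test1[5, 1] + 2
  expect_equal(joint_position_error(test1, train)$max, 2)
  set.seed(5)
  test <- cbind(runif(25, 55, 125), runif(25, 55, 125))
  got <- joint_position_error(test, train)
  brute <- unlist(lapply(seq_len(nrow(test)), function(i) {
    best <- Inf; err <- NULL
    for (j in seq_len(nrow(train))) {
      d <- sum((test[i, ] - train[j, ])^2)
      if (d < best) { best <- d; err <- abs(test[i, ] - train[j, ]) }
    }
    err
  }))
  expect_equal(sort(got$errors), sort(brute))
  expect_equal(got$median, median(brute))
  expect_equal(got$max, max(brute))
})
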