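test_that("wiring is deterministic under a fixed seed", {
  a <- build_local_gaussian(grid_layout(8, 8), grid_layout(8, 8), 0.3, 10,
                            exclude_self = TRUE, seed = 7)
  b <- build_local_gaussian(grid_layout(8, 8), grid_layout(8, 8), 0.3, 10,
                            exclude_self = TRUE, seed = 7)
  expect_identical(a, b)
  net1 <- tiny_cas(seed = 3)
  net2 <- tiny_cas(seed = 3)
  expect_identical(net1$projections, net2$projections)
})

test_that("annular sources respect the radii and peak near the annulus
           center", {
  pre <- grid_layout(20, 20)
  post <- grid_layout(20, 20)
  set.seed(1)
  pr <- build_annular(pre, post, 0.4, 1.2, 0.3, 20, exclude_self = TRUE)
  d <- sqrt(rowSums((pre$pos[pr$pre, ] - post$pos[pr$post, ])^2))
  expect_true(all(d >= 0.4 & d <= 1.2))
  # distance histogram peaks at (r_min + r_max)/2 over many draws
  h <- hist(d, breaks = seq(0.4, 1.2, by = 0.1), plot = FALSE)
  expect_lt(abs(h$mids[which.max(h$counts)] - 0.8), 0.2)
  # r_min = 0 reduces to a disc
  set.seed(2)
  pr0 <- build_annular(pre, post, 0, 0.8, 0.3, 20, exclude_self = TRUE)
  d0 <- sqrt(rowSums((pre$pos[pr0$pre, ] - post$pos[pr0$post, ])^2))
  expect_true(all(d0 <= 0.8))
  expect_error(build_annular(grid_layout(3, 3), grid_layout(3, 3),
                             5, 6, 0.3, 2), "candidate|annulus")
})

test_that("realized in-degree matches the requested expectation", {
  pre <- grid_layout(12, 12)
  post <- grid_layout(4, 4)
  n_syn <- 12
  set.seed(9)
  degs <- replicate(300, {
    pr <- build_uniform_random(pre, post, n_syn)
    length(pr$pre) / post$n
  })
  se <- sd(degs) / sqrt(length(degs))
  expect_lt(abs(mean(degs) - n_syn), 3 * se + 0.05)
  # local Gaussian rule too
  set.seed(10)
  degs_g <- replicate(300, {
    pr <- build_local_gaussian(pre, post, 0.5, n_syn)
    length(pr$pre) / post$n
  })
  se_g <- sd(degs_g) / sqrt(length(degs_g))
  expect_lt(abs(mean(degs_g) - n_syn), 3 * se_g + 0.05)
})

test_that("uniform random connectivity is source-uniform and duplicate-free", {
  pre <- grid_layout(10, 10)
  post <- grid_layout(1, 1)
  set.seed(11)
  counts <- rep(0, pre$n)
  for (i in 1:400) {
    pr <- build_uniform_random(pre, post, 10)
    expect_false(any(duplicated(cbind(pr$pre, pr$post))))
    counts[pr$pre] <- counts[pr$pre] + 1
  }
  # chi-square goodness of fit against equal selection probability
  p <- suppressWarnings(chisq.test(counts)$p.value)
  expect_gt(p, 0.001)
})

test_that("topographic limitation bounds source distance and relaxes to
           uniform at infinite radius", {
  pre <- grid_layout(12, 12)
  post <- grid_layout(10, 10)
  set.seed(12)
  pr <- build_topographic_limited(pre, post, 0.65, 8)
  d <- sqrt(rowSums((pre$pos[pr$pre, ] - post$pos[pr$post, ])^2))
  expect_true(all(d <= 0.65))
  pr_inf <- build_topographic_limited(pre, post, Inf, 8)
  deg <- length(pr_inf$pre) / post$n
  expect_lt(abs(deg - 8), 2)
})

test_that("initial incoming weight sums equal the pathway coupling target", {
  net <- tiny_cas(seed = 5)
  for (nm in names(net$projections)) {
    pr <- net$projections[[nm]]
    sums <- tapply(pr$weight, pr$post, sum)
    expect_equal(as.numeric(sums), rep(pr$s_total, length(sums)),
                 tolerance = 1e-9)
  }
})

test_that("architectures wire the pathways as named", {
  st <- tiny_struct()
  set.seed(21)
  cas <- make_architecture("cas", exc = c(12, 12), inh = c(6, 6),
                           thal = c(6, 6), struct = st)
  expect_equal(cas$projections$ie$rule, "annular")
  expect_equal(cas$projections$ee$rule, "local_gaussian")
  d_ie <- {
    pr <- cas$projections$ie
    sqrt(rowSums((cas$populations$inh$layout$pos[pr$pre, ] -
                    cas$populations$exc$layout$pos[pr$post, ])^2))
  }
  expect_true(all(d_ie >= st$r_min & d_ie <= st$r_max))

  set.seed(22)
  inv <- make_architecture("inverse", exc = c(12, 12), inh = c(6, 6),
                           thal = c(6, 6), struct = st)
  expect_equal(inv$projections$ee$rule, "annular")
  expect_equal(inv$projections$ie$rule, "local_gaussian")
  d_ee <- {
    pr <- inv$projections$ee
    sqrt(rowSums((inv$populations$exc$layout$pos[pr$pre, ] -
                    inv$populations$exc$layout$pos[pr$post, ])^2))
  }
  expect_true(all(d_ee >= st$r_min & d_ee <= st$r_max))

  set.seed(23)
  cs <- make_architecture("center_surround", exc = c(12, 12), inh = c(6, 6),
                          thal = c(6, 6), struct = st)
  expect_equal(cs$projections$ie$rule, "local_gaussian")
  expect_gt(cs$projections$ie$rule_params$sigma,
            cs$projections$ee$rule_params$sigma)

  set.seed(24)
  rnd <- make_architecture("random", exc = c(12, 12), inh = c(6, 6),
                           thal = c(6, 6), struct = st)
  for (nm in c("ee", "ei", "ie", "ii"))
    expect_equal(rnd$projections[[nm]]$rule, "uniform_random")
})

test_that("wiring survives a text round trip", {
  set.seed(31)
  pr <- build_uniform_random(grid_layout(6, 6), grid_layout(4, 4), 5)
  f <- tempfile(fileext = ".tsv")
  write_wiring(pr, f)
  back <- read_wiring(f)
  expect_equal(back$pre, pr$pre)
  expect_equal(back$post, pr$post)
  expect_equal(back$weight, pr$weight, tolerance = 1e-12)
  expect_equal(back$rule, pr$rule)
  unlink(f)
})
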