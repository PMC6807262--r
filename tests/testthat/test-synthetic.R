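test_that("profiles have the documented spectral geometry", {
  p <- make_profiles()
  wl <- p$wavelengths
  expect_length(wl, 200)
  expect_equal(range(wl), c(975, 1646))
  expect_true(all(p$base > 0))
  # global maximum within +/- 2 bands of one of the two peaks
  step <- diff(wl)[1]
  argmax <- wl[which.max(p$base)]
  expect_true(min(abs(argmax - c(1109, 1284))) <= 2 * step)
  # local minima within a few bands of the two valleys
  for (v in c(1204, 1456)) {
    i <- which.min(abs(wl - v))
    lo <- max(1, i - 8)
    win <- p$base[lo:min(200, i + 8)]
    expect_lte(abs(lo - 1 + which.min(win) - i), 3)
  }
  # variety differences concentrated in 975-1120 nm
  d <- p$deltas[1, ]
  inw <- wl >= 975 & wl <= 1120
  expect_lt(mean(abs(d[!inw])), 0.1 * mean(abs(d[inw])))
})

test_that("separation scales the class geometry down to identity", {
  p0 <- make_profiles(separation = 0)
  expect_equal(max(abs(p0$deltas)), 0)
  expect_equal(bayes_pixel_accuracy(p0), 1 / 3)
  p1 <- make_profiles(separation = 1)
  p2 <- make_profiles(separation = 2)
  expect_equal(p2$deltas, 2 * p1$deltas)
  expect_gt(bayes_pixel_accuracy(p2), bayes_pixel_accuracy(p1))
})

test_that("the calibrated separation hits the Bayes target exactly", {
  expect_equal(bayes_pixel_accuracy(make_profiles(bayes_target = 0.8)), 0.8)
  expect_equal(bayes_pixel_accuracy(make_profiles(bayes_target = 0.9)), 0.9)
})

test_that("the closed-form Bayes rate matches a Monte-Carlo oracle", {
  p <- make_profiles()
  set.seed(17)
  n <- 20000
  u <- p$deltas[3, ] - p$deltas[2, ]
  uhat <- u / sqrt(sum(u^2))
  # simulate pixels (no shading: it is removed by normalization) and apply
  # the optimal rule: nearest projected class mean
  cls <- sample(1:3, n, replace = TRUE)
  proj_means <- as.numeric(p$deltas %*% uhat)
  t_vals <- proj_means[cls] + rnorm(n, 0, p$pixel_sd) +
    rnorm(n, 0, p$seed_sd) * sum(uhat)
  decided <- apply(abs(outer(t_vals, proj_means, "-")), 1, which.min)
  mc <- mean(decided == cls)
  expect_equal(mc, bayes_pixel_accuracy(p), tolerance = 0.015)
})

test_that("scenes are deterministic, balanced, and well formed", {
  p <- make_profiles()
  s1 <- generate_scene(p, n_per_variety = 3, rng_seed = 4)
  s2 <- generate_scene(p, n_per_variety = 3, rng_seed = 4)
  expect_identical(s1$cube$data, s2$cube$data)
  expect_identical(s1$regions$label_map, s2$regions$label_map)
  s3 <- generate_scene(p, n_per_variety = 3, rng_seed = 5)
  expect_false(identical(s1$cube$data, s3$cube$data))
  expect_equal(s1$regions$n_seeds, 9)
  expect_equal(unname(table(s1$labels)), rep(3L, 3), ignore_attr = TRUE)
  # every labeled region has a truth label
  expect_length(s1$labels, s1$regions$n_seeds)
  expect_error(generate_scene(p, n_per_variety = 3, image_size = c(20, 20)),
               "cannot place")
})

test_that("noise-free seeds reproduce their profile exactly", {
  p <- make_profiles(pixel_sd = 1e-12, seed_sd = 0)
  s <- generate_scene(p, n_per_variety = 1, shading_sd = 0, rng_seed = 2)
  tab <- extract_pixel_spectra(s$cube, s$regions)
  for (k in 1:3) {
    rows <- tab$spectra[tab$seed_ids == k, , drop = FALSE]
    prof <- p$base + p$deltas[as.integer(s$labels[k]), ]
    expect_equal(max(abs(sweep(rows, 2, prof))), 0, tolerance = 1e-9)
  }
})

test_that("splits are balanced, seed-disjoint, and deterministic", {
  p <- make_profiles()
  sp <- generate_splits(p, n_train = 4, n_val = 2, n_pred = 3, rng_seed = 8)
  ids <- lapply(sp, function(s) unique(s$pixel$seed_ids))
  expect_length(intersect(ids$train, ids$val), 0)
  expect_length(intersect(ids$train, ids$pred), 0)
  expect_length(intersect(ids$val, ids$pred), 0)
  expect_length(ids$train, 12); expect_length(ids$val, 6)
  expect_length(ids$pred, 9)
  for (s in sp) {
    seed_labels <- s$pixel$labels[!duplicated(s$pixel$seed_ids)]
    expect_true(all(table(seed_labels) == length(seed_labels) / 3))
    expect_equal(nrow(s$object$spectra), length(unique(s$pixel$seed_ids)))
    npx <- table(s$pixel$seed_ids)
    expect_true(all(npx >= 70 & npx <= 90))
  }
  sp2 <- generate_splits(p, n_train = 4, n_val = 2, n_pred = 3, rng_seed = 8)
  expect_identical(sp$train$pixel$spectra, sp2$train$pixel$spectra)
})
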