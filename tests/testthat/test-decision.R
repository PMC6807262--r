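classes3 <- c("ZH37", "ZH41", "ZH55")

test_that("vote implements the largest-percentage rule", {
  v <- vote(rep(classes3, c(60, 30, 10)), classes = classes3)
  expect_equal(as.character(v$final_label), "ZH37")
  expect_equal(unname(v$percentages), c(0.6, 0.3, 0.1))
  expect_equal(sum(v$percentages), 1)
  expect_equal(v$n_pixels, 100)
  # a seed with 52.16% of pixels called ZH55 is assigned ZH55
  n <- 10000
  labs <- rep(classes3, c(2392, 2392, 5216))
  v2 <- vote(labs, classes = classes3)
  expect_equal(as.character(v2$final_label), "ZH55")
  expect_equal(unname(v2$percentages["ZH55"]), 0.5216)
  expect_error(vote(character(0)), "empty")
})

test_that("vote ties break to the lowest class index and order is irrelevant", {
  labs <- rep(c("ZH41", "ZH55"), each = 5)
  v <- vote(labs, classes = classes3)
  expect_equal(as.character(v$final_label), "ZH41")
  set.seed(3)
  labs2 <- sample(rep(classes3, c(20, 50, 30)))
  expect_equal(vote(labs2, classes = classes3)$percentages,
               vote(sort(labs2), classes = classes3)$percentages)
})

test_that("evaluate reports per-class and overall accuracy with confusion", {
  truth <- factor(rep(classes3, each = 4), levels = classes3)
  expect_equal(evaluate(truth, truth)$overall, 100)
  expect_true(all(evaluate(truth, truth)$per_class == 100))
  const <- factor(rep("ZH37", 12), levels = classes3)
  expect_equal(evaluate(const, truth)$overall, 100 / 3, tolerance = 1e-10)
  # hand-built 3x3 confusion
  pred <- factor(c("ZH37", "ZH37", "ZH41", "ZH55",
                   "ZH41", "ZH41", "ZH41", "ZH37",
                   "ZH55", "ZH55", "ZH37", "ZH55"), levels = classes3)
  ev <- evaluate(pred, truth)
  expect_equal(unname(ev$per_class), 100 * c(2 / 4, 3 / 4, 3 / 4))
  expect_equal(ev$overall, 100 * 8 / 12)
  expect_equal(sum(ev$confusion), 12)
  expect_equal(unname(diag(ev$confusion)), c(2, 3, 3))
  expect_equal(ev$overall, 100 * sum(diag(ev$confusion)) / sum(ev$confusion))
  expect_error(evaluate(pred[1:3], truth), "length")
})

test_that("prediction maps color seed pixels by class over black", {
  m <- matrix(FALSE, 6, 7)
  m[2:3, 2:3] <- TRUE      # seed 1 (4 px)
  m[5, 5:6] <- TRUE        # seed 2 (2 px)
  regions <- label_seeds(m, min_area = 1)
  labels <- factor(c(rep("ZH37", 4), rep("ZH55", 2)), levels = classes3)
  img <- prediction_map(regions, labels)
  expect_equal(dim(img), c(6, 7, 3))
  expect_equal(img[1, 1, ], c(0, 0, 0))              # background black
  expect_equal(img[2, 2, ], c(0, 0, 1))              # blue = ZH37
  expect_equal(img[5, 5, ], unname(col2rgb("orange")[, 1] / 255))
  # mixed labels within a seed land on the right pixels (extraction order)
  labels2 <- factor(c("ZH37", "ZH41", "ZH37", "ZH37", "ZH55", "ZH55"),
                    levels = classes3)
  img2 <- prediction_map(regions, labels2)
  expect_equal(img2[2, 3, ], c(1, 1, 0))             # 2nd pixel in raster order
  # round trip through PNG
  path <- tempfile(fileext = ".png")
  write_map_png(img2, path)
  expect_equal(png::readPNG(path), img2, tolerance = 1 / 255)
  unlink(path)
  expect_error(prediction_map(regions, labels[1:3]), "label")
})

test_that("classify_seeds ties the stages together end to end", {
  profiles <- make_profiles(separation = 8)  # widely separated varieties
  scene <- generate_scene(profiles, n_per_variety = 2, rng_seed = 9)
  splits <- generate_splits(profiles, n_train = 6, n_val = 2, n_pred = 2,
                            rng_seed = 10)
  trp <- preprocess_pipeline(splits$train$pixel)
  fit <- spectral_cnn(trp, config = cnn_config(seed = 12), epochs = 40)
  res <- classify_seeds(fit, scene$cube, scene$regions)
  expect_equal(nrow(res$votes), scene$regions$n_seeds)
  expect_equal(res$votes$n_pixels, unname(scene$regions$areas))
  expect_true(all(abs(rowSums(as.matrix(
    res$votes[, paste0("pct_", classes3)])) - 1) < 1e-12))
  # with training pixel accuracy this high, votes must match the truth
  tr_acc <- mean(predict(fit, trp) == trp$labels)
  if (tr_acc > 0.8)
    expect_equal(as.character(res$votes$final_label),
                 as.character(scene$labels))
})

test_that("vote accuracy dominates pixel accuracy when pixels beat chance", {
  # synthetic prediction sets: per-class pixel accuracy 0.6, 100-px seeds
  set.seed(31)
  n_seeds <- 60
  truth <- factor(rep(classes3, each = n_seeds / 3), levels = classes3)
  pixel_acc <- replicate(20, {
    labs <- lapply(seq_len(n_seeds), function(i) {
      correct <- runif(100) < 0.6
      out <- ifelse(correct, as.character(truth[i]),
                    sample(setdiff(classes3, truth[i]), 100, replace = TRUE))
      out
    })
    votes <- vapply(labs, function(l)
      as.character(vote(l, classes = classes3)$final_label), "")
    c(pixel = mean(unlist(labs) == rep(as.character(truth), each = 100)),
      vote = mean(votes == as.character(truth)))
  })
  expect_true(all(pixel_acc["vote", ] >= pixel_acc["pixel", ]))
})
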