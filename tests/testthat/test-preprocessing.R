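test_that("area normalization matches its closed form and is idempotent", {
  expect_equal(area_normalize(c(1, 3)), c(0.25, 0.75))
  expect_equal(area_normalize(rep(3.7, 10)), rep(1 / 10, 10))
  set.seed(1)
  X <- matrix(runif(50 * 40, 0.1, 1), 50, 40)
  N <- area_normalize(X)
  expect_true(all(abs(rowSums(N) - 1) < 1e-9))
  expect_equal(area_normalize(N), N)             # idempotent
  expect_equal(N, X / rowSums(X))                # Eq.-style closed form
  expect_error(area_normalize(c(1, -1)), "degenerate")
  expect_error(area_normalize(rbind(c(1, 2), c(0, 0))), "degenerate")
})

test_that("moving average equals the brute-force double loop on 100 spectra", {
  set.seed(7)
  brute <- function(x, w) {
    h <- w %/% 2
    sapply(seq_along(x), function(i) {
      lo <- max(1, i - h); hi <- min(length(x), i + h)
      mean(x[lo:hi])
    })
  }
  for (r in 1:100) {
    n <- sample(10:64, 1)
    x <- rnorm(n)
    expect_equal(moving_average(x, 7), brute(x, 7), tolerance = 1e-12)
  }
  x <- rnorm(30)
  expect_equal(moving_average(x, 5), brute(x, 5), tolerance = 1e-12)
})

test_that("moving average preserves constants and interior linearity", {
  expect_equal(moving_average(rep(2.5, 20)), rep(2.5, 20))
  ramp <- seq(0, 1, length.out = 20)
  sm <- moving_average(ramp, 7)
  expect_equal(sm[4:17], ramp[4:17])   # symmetric window on linear data
  expect_error(moving_average(rnorm(10), 4), "odd")
  expect_error(moving_average(rnorm(5), 7), "exceeds")
})

test_that("db6 decomposition reproduces frozen PyWavelets reference values", {
  # reference computed with pywt.dwt(x, 'db6', mode='symmetric')
  x <- sin((1:32) * 0.3) + 0.1 * (0:31)
  d <- seedspec:::.dwt_rows(matrix(x, 1))
  expect_equal(ncol(d$cA), 21)
  expect_equal(d$cA[1, 1:3],
               c(1.829883208813612, 2.0857485885516667, 1.924136959581824),
               tolerance = 1e-12)
  expect_equal(d$cD[1, 1:3],
               c(0.06649879490320823, -0.10198760770627822,
                 0.036397585774752265),
               tolerance = 1e-12)
  # multilevel coefficient lengths on the 200-band grid, as pywt computes
  dec <- seedspec:::.wavedec_rows(matrix(rnorm(200), 1), 3)
  expect_equal(sapply(dec$details, ncol), c(105, 58, 34))
  expect_equal(ncol(dec$cA), 34)
})

test_that("wavelet transform reconstructs perfectly and denoising behaves", {
  set.seed(11)
  X <- matrix(rnorm(5 * 200), 5, 200)
  expect_equal(wavelet_denoise(X, threshold = "none"), X, tolerance = 1e-10)
  # constants live in the approximation band
  expect_equal(wavelet_denoise(rep(4, 200)), rep(4, 200), tolerance = 1e-8)
  expect_length(wavelet_denoise(rnorm(64)), 64)
  # denoising a smooth bump + white noise reduces the error to the clean signal
  wl <- seq(975, 1646, length.out = 200)
  clean <- 0.5 + 0.3 * exp(-(wl - 1200)^2 / (2 * 60^2))
  noisy <- clean + rnorm(200, 0, 0.02)
  den <- wavelet_denoise(noisy)
  expect_lt(mean((den - clean)^2), mean((noisy - clean)^2))
  expect_error(wavelet_denoise(rnorm(8)), "short")
})

test_that("the pipeline applies denoise, normalize, smooth in that order", {
  tab <- random_table(n_seeds = 3, px = 2, bands = 64)
  out <- preprocess_pipeline(tab)
  expect_equal(dim(out$spectra), dim(tab$spectra))
  expect_identical(out$seed_ids, tab$seed_ids)
  expect_identical(out$labels, tab$labels)
  # the stages do not commute: smoothing before normalizing differs
  x <- tab$spectra[1, ]
  pipeline <- moving_average(area_normalize(wavelet_denoise(x)))
  expect_equal(out$spectra[1, ], pipeline, tolerance = 1e-12)
  other_order <- area_normalize(moving_average(wavelet_denoise(x)))
  expect_gt(max(abs(pipeline - other_order)), 0)
  # empty tables pass through
  empty <- spectra_table(matrix(0, 0, 64), tab$wavelengths, integer(),
                         level = "pixel")
  expect_equal(nrow(preprocess_pipeline(empty)$spectra), 0)
})

test_that("per-seed averaging conserves structure and checks labels", {
  wl <- c(1000, 1100)
  tab <- spectra_table(rbind(c(0, 1), c(1, 0), c(0.3, 0.7), c(0.3, 0.7)),
                       wl, seed_ids = c(1, 1, 2, 2),
                       labels = factor(c("a", "a", "b", "b")),
                       level = "pixel")
  avg <- average_by_seed(tab)
  expect_equal(avg$level, "object")
  expect_equal(nrow(avg$spectra), 2)
  expect_equal(avg$spectra[1, ], c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(avg$spectra[2, ], c(0.3, 0.7), ignore_attr = TRUE)
  expect_equal(as.character(avg$labels), c("a", "b"))
  bad <- spectra_table(tab$spectra, wl, seed_ids = c(1, 1, 1, 2),
                       labels = factor(c("a", "b", "a", "b")),
                       level = "pixel")
  expect_error(average_by_seed(bad), "label")
})

test_that("spectra tables survive a CSV round trip", {
  tab <- random_table(n_seeds = 4, px = 3, bands = 8)
  path <- tempfile(fileext = ".csv")
  write_spectra(tab, path)
  back <- read_spectra(path)
  expect_equal(back$spectra, tab$spectra, ignore_attr = TRUE)
  expect_equal(back$wavelengths, tab$wavelengths)
  expect_equal(as.character(back$labels), as.character(tab$labels))
  expect_equal(back$seed_ids, tab$seed_ids)
  unlink(path)
})
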