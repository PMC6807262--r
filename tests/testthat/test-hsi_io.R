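test_that("calibrate matches the element-wise closed form on random cubes", {
  set.seed(42)
  for (rep in 1:3) {
    raw <- random_cube(5, 5, 4, seed = rep)
    w <- array(runif(100, 0.8, 1.2), c(5, 5, 4))
    d <- array(runif(100, 0.0, 0.2), c(5, 5, 4))
    out <- calibrate(raw, w, d)
    # brute-force element loop oracle
    expect_equal(out$kind, "reflectance")
    ref <- array(NA_real_, dim(raw$data))
    for (i in 1:5) for (j in 1:5) for (b in 1:4)
      ref[i, j, b] <- (raw$data[i, j, b] - d[i, j, b]) /
        (w[i, j, b] - d[i, j, b])
    expect_equal(out$data, ref, tolerance = 1e-15)
  }
})

test_that("calibration identities: white -> 1, dark -> 0, midpoint -> 0.5", {
  w <- array(runif(60, 0.7, 1.0), c(3, 4, 5))
  d <- array(runif(60, 0.0, 0.2), c(3, 4, 5))
  wl <- seq(1000, 1400, length.out = 5)
  as_cube <- function(a) hsi_cube(a, wl)
  expect_equal(calibrate(as_cube(w), w, d)$data, array(1, c(3, 4, 5)))
  expect_equal(calibrate(as_cube(d), w, d)$data, array(0, c(3, 4, 5)))
  expect_equal(calibrate(as_cube((w + d) / 2), w, d)$data,
               array(0.5, c(3, 4, 5)))
})

test_that("a single reference line broadcasts along the scan axis", {
  raw <- random_cube(6, 4, 3, seed = 7)
  wline <- matrix(runif(12, 0.8, 1.0), 4, 3)   # cols x bands
  dline <- matrix(runif(12, 0.0, 0.1), 4, 3)
  out_line <- calibrate(raw, wline, dline)
  wfull <- aperm(array(wline, c(4, 3, 6)), c(3, 1, 2))
  dfull <- aperm(array(dline, c(4, 3, 6)), c(3, 1, 2))
  out_full <- calibrate(raw, wfull, dfull)
  expect_identical(out_line$data, out_full$data)
})

test_that("degenerate references and out-of-range reflectance are handled", {
  raw <- random_cube(2, 2, 2)
  w <- array(0.5, c(2, 2, 2))
  expect_error(calibrate(raw, w, w), "degenerate")
  # values outside [0, 1] are preserved, with a message
  d <- array(0, c(2, 2, 2))
  big <- hsi_cube(array(2, c(2, 2, 2)), raw$wavelengths)
  expect_message(out <- calibrate(big, w, d), "outside")
  expect_equal(out$data, array(4, c(2, 2, 2)))
})

test_that("cropping the raw instrument grid to 975-1646 nm keeps 200 bands", {
  profiles <- make_profiles(grid = "raw")
  expect_length(profiles$wavelengths, 256)
  scene <- generate_scene(profiles, n_per_variety = 1, rng_seed = 1)
  cropped <- crop_bands(scene$cube, 975, 1646)
  expect_equal(dim(cropped)[3], 200)
  expect_true(all(cropped$wavelengths >= 975 & cropped$wavelengths <= 1646))
  # idempotent, and full-range crop is the identity
  expect_identical(crop_bands(cropped, 975, 1646), cropped)
  full <- crop_bands(scene$cube, min(scene$cube$wavelengths),
                     max(scene$cube$wavelengths))
  expect_identical(full$data, scene$cube$data)
  expect_error(crop_bands(scene$cube, 2000, 2100), "no bands")
})

test_that("ENVI write/read round-trips bit-exactly in every interleave", {
  cube <- random_cube(4, 6, 5, kind = "reflectance")
  for (il in c("bil", "bsq", "bip")) {
    path <- tempfile()
    write_cube(cube, path, interleave = il)
    hdr <- readLines(paste0(path, ".hdr"))
    expect_true(any(grepl(paste0("interleave = ", il), hdr)))
    back <- read_cube(path)
    expect_identical(back$data, cube$data)
    expect_identical(back$wavelengths, cube$wavelengths)
    expect_identical(back$kind, "reflectance")
    unlink(c(path, paste0(path, ".hdr")))
  }
})

test_that("inconsistent or incomplete ENVI headers are format errors", {
  cube <- random_cube(4, 6, 5)
  path <- tempfile()
  write_cube(cube, path)
  hdr_path <- paste0(path, ".hdr")
  hdr <- readLines(hdr_path)
  writeLines(sub("bands = 5", "bands = 7", hdr), hdr_path)
  expect_error(read_cube(path), "bands")
  writeLines(hdr[!grepl("^interleave", hdr)], hdr_path)
  expect_error(read_cube(path), "interleave")
  writeLines(hdr[!grepl("^wavelength =", hdr)], hdr_path)
  expect_error(read_cube(path), "wavelength")
  unlink(c(path, hdr_path))
})

test_that("cube invariants are enforced at construction", {
  expect_error(hsi_cube(array(1, c(2, 2, 3)), c(1000, 1100)), "match")
  expect_error(hsi_cube(array(1, c(2, 2, 2)), c(1100, 1000)), "increasing")
})
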