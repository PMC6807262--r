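# Synthetic data emulating line-scan NIR seed imagery: three varieties
# sharing one smooth base reflectance curve (peaks near 1109/1284 nm,
# valleys near 1204/1456 nm), variety differences confined to a smooth
# bump in 975-1120 nm, a per-seed additive offset, a smooth multiplicative
# within-seed shading field, and iid per-band pixel noise. Because the
# class means are collinear and the noise Gaussian, the Bayes-optimal
# per-pixel accuracy has a closed form, which anchors the end-to-end tests.

.VARIETIES <- c("ZH37", "ZH41", "ZH55")

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# 200-band analysis grid (975-1646 nm) and the instrument-like 256-band raw
# grid: the analysis grid extended by 29 bands below and 27 above at the
# same spacing, so cropping to 975-1646 nm returns exactly 200 bands.
.band_grid <- function(grid = c("analysis", "raw")) {
  grid <- match.arg(grid)
  d <- (1646 - 975) / 199
  if (grid == "analysis") seq(975, 1646, length.out = 200)
  else 975 + d * (-29:226)
}

.gauss_bump <- function(wl, center, width) exp(-(wl - center)^2 / (2 * width^2))

# shared base reflectance curve; closed form so it can be evaluated on any
# band grid
.base_curve <- function(wl) {
  0.40 +
    0.10 * .gauss_bump(wl, 1109, 42) +
    0.13 * .gauss_bump(wl, 1284, 55) -
    0.07 * .gauss_bump(wl, 1204, 26) -
    0.16 * .gauss_bump(wl, 1456, 55)
}

# variety-difference direction: a smooth bump concentrated in 975-1120 nm
.delta_shape <- function(wl) .gauss_bump(wl, 1045, 28)

#' Variety spectral profiles
#'
#' Builds the three variety profiles used by the scene and split
#' generators. All varieties share a smooth base spectrum; their
#' differences lie along one smooth bump concentrated in 975-1120 nm, with
#' collinear, equally spaced class means. The difference amplitude is
#' calibrated so that at `separation = 1` the Bayes-optimal per-pixel
#' classification accuracy (see [bayes_pixel_accuracy()]) equals
#' `bayes_target`; `separation` then scales the calibrated spacing
#' (`separation = 0` gives three identical profiles).
#'
#' @param separation multiplier on the calibrated class spacing.
#' @param pixel_sd per-band iid Gaussian pixel noise sd (reflectance units).
#' @param seed_sd sd of the per-seed additive offset (constant across
#'   bands).
#' @param bayes_target Bayes pixel accuracy at `separation = 1`.
#' @param grid `"analysis"` (200 bands, 975-1646 nm) or `"raw"` (256
#'   bands, ~874-1734 nm, for exercising band cropping).
#' @return An object of class `variety_profiles`: `wavelengths`, `base`,
#'   `deltas` (3 x bands matrix, rows ZH37/ZH41/ZH55), `pixel_sd`,
#'   `seed_sd`, `spacing` (projected distance of adjacent class means).
#' @export
make_profiles <- function(separation = 1, pixel_sd = 0.040, seed_sd = 1.5e-3,
                          bayes_target = 0.80,
                          grid = c("analysis", "raw")) {
  stopifnot(separation >= 0, pixel_sd > 0, seed_sd >= 0,
            bayes_target > 1 / 3, bayes_target < 1)
  wl <- .band_grid(match.arg(grid))
  base <- .base_curve(wl)
  g <- .delta_shape(wl)
  gnorm <- sqrt(sum(g^2))
  # sd of the optimal projection's noise: iid pixel noise plus the
  # projected per-seed offset (constant across bands)
  sigma_t <- sqrt(pixel_sd^2 + (seed_sd * sum(g) / gnorm)^2)
  spacing_cal <- 2 * qnorm((3 * bayes_target + 1) / 4) * sigma_t
  amp <- separation * spacing_cal / gnorm
  deltas <- outer(c(-1, 0, 1) * amp, g)
  rownames(deltas) <- .VARIETIES
  structure(list(wavelengths = wl, base = base, deltas = deltas,
                 names = .VARIETIES, pixel_sd = pixel_sd, seed_sd = seed_sd,
                 spacing = separation * spacing_cal),
            class = "variety_profiles")
}

#' @export
print.variety_profiles <- function(x, ...) {
  cat(sprintf(
    "<variety_profiles> %s; %d bands (%.1f-%.1f nm)\n",
    paste(x$names, collapse = "/"), length(x$wavelengths),
    min(x$wavelengths), max(x$wavelengths)))
  cat(sprintf("  class spacing %.4g, pixel_sd %.4g, seed_sd %.4g; Bayes pixel accuracy %.3f\n",
              x$spacing, x$pixel_sd, x$seed_sd, bayes_pixel_accuracy(x)))
  invisible(x)
}

#' Bayes-optimal per-pixel accuracy of a profile set
#'
#' For three equiprobable classes whose means are collinear and equally
#' spaced along a direction u, observed under Gaussian noise with sd
#' `sigma` along u, the optimal rule thresholds the projection at the two
#' midpoints; its accuracy is `(4 * pnorm(D / (2 * sigma)) - 1) / 3` where
#' D is the adjacent-mean spacing. The projection noise combines the iid
#' pixel noise with the projected per-seed offset. (The multiplicative
#' shading field is excluded: it scales whole spectra and is removed
#' exactly by area normalization.)
#'
#' @param profiles a [make_profiles()] object.
#' @return Bayes accuracy in \[1/3, 1\].
#' @export
bayes_pixel_accuracy <- function(profiles) {
  stopifnot(inherits(profiles, "variety_profiles"))
  u <- profiles$deltas[3, ] - profiles$deltas[2, ]
  un <- sqrt(sum(u^2))
  if (un == 0) return(1 / 3)
  uhat <- u / un
  m <- as.numeric(profiles$deltas %*% uhat)
  sp <- diff(m)
  stopifnot(abs(sp[1] - sp[2]) < 1e-8 * max(abs(sp)))
  sigma_t <- sqrt(profiles$pixel_sd^2 +
                    (profiles$seed_sd * sum(uhat))^2)
  (4 * pnorm(sp[1] / (2 * sigma_t)) - 1) / 3
}

# smooth multiplicative shading field over pixel coordinates: a random
# plane wave with marginal sd `sd`
.shading_field <- function(rows, cols, sd, wavelength = 8) {
  theta <- runif(1, 0, pi)
  phase <- runif(1, 0, 2 * pi)
  1 + sd * sqrt(2) * sin(2 * pi * (outer(rows, rep(1, length(cols))) * cos(theta) +
                                     outer(rep(1, length(rows)), cols) * sin(theta)) /
                           wavelength + phase)
}

# relabel a truth label map in raster order of first pixels (the same rule
# label_seeds uses) and build a seed_regions object from it
.regions_from_map <- function(lab) {
  n <- max(lab)
  if (n > 0) {
    idx <- which(lab > 0, arr.ind = TRUE)
    raster <- (idx[, 1] - 1L) * ncol(lab) + idx[, 2]
    first <- tapply(raster, lab[lab > 0], min)
    perm <- order(order(first))          # old label -> new label
    lab[lab > 0] <- perm[lab[lab > 0]]
  }
  out <- label_seeds(lab > 0, min_area = 0L)
  # label_seeds on the connected mask reproduces the same raster-order
  # labels as long as regions are disjoint, which generate_scene enforces
  stopifnot(identical(out$label_map, unname(lab)))
  list(regions = out, perm = if (n > 0) perm else integer())
}

#' Generate a synthetic seed scene
#'
#' Places non-overlapping elliptical "seeds" of the three varieties on a
#' dark background and fills in their spectra: each seed draws an additive
#' offset ~ N(0, `seed_sd`), each pixel gets the seed's profile times a
#' smooth within-seed shading field plus iid N(0, `pixel_sd`) band noise.
#' Truth masks and labels are recorded; truth regions are labeled in
#' raster order of first pixel, the same rule [label_seeds()] uses.
#'
#' @param profiles a [make_profiles()] object.
#' @param n_per_variety seeds per variety.
#' @param image_size optional c(rows, cols); defaults to a grid just large
#'   enough. Errors if the requested seeds cannot be placed.
#' @param seed_axes range of ellipse semi-axes in pixels.
#' @param shading_sd marginal sd of the multiplicative shading field.
#' @param background background reflectance level.
#' @param rng_seed integer seed; the same seed reproduces the scene
#'   exactly.
#' @return An object of class `synthetic_scene`: `cube` (reflectance
#'   [hsi_cube]), `regions` (truth `seed_regions`), `labels` (factor per
#'   seed), `rng_seed`.
#' @export
generate_scene <- function(profiles, n_per_variety = 3, image_size = NULL,
                           seed_axes = c(4, 5.5), shading_sd = 0.02,
                           background = 0.04, rng_seed = 1) {
  stopifnot(inherits(profiles, "variety_profiles"), n_per_variety >= 1)
  n <- 3L * as.integer(n_per_variety)
  cell <- ceiling(2 * max(seed_axes)) + 7L
  ncx <- ceiling(sqrt(n))
  ncy <- ceiling(n / ncx)
  if (is.null(image_size)) {
    image_size <- c(ncy * cell, ncx * cell)
  } else {
    image_size <- as.integer(image_size)
    if (image_size[1] < ncy * cell || image_size[2] < ncx * cell)
      stop("cannot place ", n, " seeds in a ", image_size[1], " x ",
           image_size[2], " image (need at least ", ncy * cell, " x ",
           ncx * cell, ")")
  }
  nb <- length(profiles$wavelengths)
  .with_seed(rng_seed, {
    lab <- matrix(0L, image_size[1], image_size[2])
    varieties0 <- rep(.VARIETIES, length.out = n)
    jit_max <- cell / 2 - max(seed_axes) - 1.5
    for (k in seq_len(n)) {
      cy <- ((k - 1) %/% ncx) * cell + cell / 2 +
        runif(1, -jit_max, jit_max)
      cx <- ((k - 1) %% ncx) * cell + cell / 2 +
        runif(1, -jit_max, jit_max)
      a <- runif(1, seed_axes[1], seed_axes[2])
      b <- runif(1, seed_axes[1], seed_axes[2])
      th <- runif(1, 0, pi)
      rr <- row(lab) - cy
      cc <- col(lab) - cx
      u <- rr * cos(th) + cc * sin(th)
      v <- -rr * sin(th) + cc * cos(th)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      if (any(lab[inside] != 0)) stop("internal: seed placement overlap")
      lab[inside] <- k
    }
    rf <- .regions_from_map(lab)
    regions <- rf$regions
    labels <- factor(varieties0, levels = .VARIETIES)[order(rf$perm)]
    # fill spectra
    cube_mat <- matrix(0, image_size[1] * image_size[2], nb)
    bg_n <- sum(regions$label_map == 0)
    bg_idx <- which(regions$label_map == 0)
    cube_mat[bg_idx, ] <- background +
      matrix(rnorm(bg_n * nb, 0, profiles$pixel_sd), bg_n, nb)
    for (k in seq_len(regions$n_seeds)) {
      pix <- which(regions$label_map == k)
      npx <- length(pix)
      prof <- profiles$base +
        profiles$deltas[as.integer(labels[k]), ] +
        rnorm(1, 0, profiles$seed_sd)
      shade_img <- .shading_field(seq_len(image_size[1]),
                                  seq_len(image_size[2]), shading_sd)
      shade <- shade_img[pix]
      cube_mat[pix, ] <- outer(shade, prof) +
        matrix(rnorm(npx * nb, 0, profiles$pixel_sd), npx, nb)
    }
    cube <- hsi_cube(array(cube_mat, c(image_size[1], image_size[2], nb)),
                     profiles$wavelengths, kind = "reflectance")
    structure(list(cube = cube, regions = regions, labels = labels,
                   rng_seed = rng_seed),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d seeds (%s) in a %d x %d x %d cube (seed %d)\n",
              x$regions$n_seeds,
              paste(levels(x$labels), table(x$labels), sep = "=",
                    collapse = ", "),
              dim(x$cube)[1], dim(x$cube)[2], dim(x$cube)[3], x$rng_seed))
  invisible(x)
}

# draw the pixel spectra of one seed without spatial layout (split
# generation); shading enters as a per-pixel multiplicative scalar with
# the same marginal sd as the scene's smooth field
.draw_seed_pixels <- function(profiles, variety_idx, n_px, shading_sd) {
  prof <- profiles$base + profiles$deltas[variety_idx, ] +
    rnorm(1, 0, profiles$seed_sd)
  shade <- 1 + rnorm(n_px, 0, shading_sd)
  outer(shade, prof) +
    matrix(rnorm(n_px * length(prof), 0, profiles$pixel_sd), n_px)
}

#' Generate train/validation/prediction spectra splits
#'
#' Draws balanced, seed-disjoint splits of pixel spectra directly from the
#' profiles (no spatial layout), plus the per-seed raw average spectra.
#' Each seed contributes a uniformly drawn number of pixels in
#' `pixels_per_seed`.
#'
#' @param profiles a [make_profiles()] object.
#' @param n_train,n_val,n_pred seeds per variety in each split.
#' @param pixels_per_seed inclusive range of pixels per seed.
#' @param shading_sd marginal sd of the per-pixel multiplicative shading.
#' @param rng_seed integer seed.
#' @return A list with elements `train`, `val`, `pred`; each a list of a
#'   pixel-level and an object-level [spectra_table] (`pixel`, `object`).
#'   Seed ids are disjoint across splits.
#' @export
generate_splits <- function(profiles, n_train = 60, n_val = 20, n_pred = 60,
                            pixels_per_seed = c(70, 90), shading_sd = 0.02,
                            rng_seed = 1) {
  stopifnot(inherits(profiles, "variety_profiles"),
            n_train >= 1, n_val >= 1, n_pred >= 1)
  counts <- c(train = n_train, val = n_val, pred = n_pred)
  .with_seed(rng_seed, {
    next_id <- 1L
    out <- list()
    for (split in names(counts)) {
      nseed <- counts[[split]] * 3L
      variety <- rep(1:3, counts[[split]])   # interleaved, balanced
      npx <- sample(seq(pixels_per_seed[1], pixels_per_seed[2]), nseed,
                    replace = TRUE)
      ids <- next_id:(next_id + nseed - 1L)
      next_id <- next_id + nseed
      sp <- vector("list", nseed)
      for (i in seq_len(nseed))
        sp[[i]] <- .draw_seed_pixels(profiles, variety[i], npx[i],
                                     shading_sd)
      pixel <- spectra_table(do.call(rbind, sp), profiles$wavelengths,
                             seed_ids = rep(ids, npx),
                             labels = factor(.VARIETIES[rep(variety, npx)],
                                             levels = .VARIETIES),
                             level = "pixel")
      out[[split]] <- list(pixel = pixel, object = average_by_seed(pixel))
    }
    out
  })
}
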