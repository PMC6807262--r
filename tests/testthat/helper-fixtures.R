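# shared fixtures, all generated in code

# small random cube with a strictly increasing wavelength grid
random_cube <- function(rows = 5, cols = 5, bands = 4, seed = 1,
                        kind = "raw") {
  set.seed(seed)
  hsi_cube(array(runif(rows * cols * bands), c(rows, cols, bands)),
           seq(1000, by = 10, length.out = bands), kind = kind)
}

# labeled random spectra table
random_table <- function(n_seeds = 6, px = 4, bands = 32, seed = 1,
                         level = "pixel") {
  set.seed(seed)
  n <- n_seeds * px
  spectra_table(matrix(runif(n * bands, 0.2, 0.8), n, bands),
                seq(975, 1646, length.out = bands),
                seed_ids = rep(seq_len(n_seeds), each = px),
                labels = factor(rep(rep(c("ZH37", "ZH41", "ZH55"),
                                        length.out = n_seeds), each = px),
                                levels = c("ZH37", "ZH41", "ZH55")),
                level = level)
}

# linearly separable object-level table on which the CNN must train to 100%
separable_table <- function(n_per_class = 10, bands = 200, seed = 1,
                            noise = 0.05) {
  set.seed(seed)
  n <- 3 * n_per_class
  cls <- rep(1:3, each = n_per_class)
  wl <- seq(975, 1646, length.out = bands)
  X <- matrix(rnorm(n * bands, 0, noise), n, bands)
  shapes <- rbind(0.5 + 0.3 * sin(seq(0, 6, length.out = bands)),
                  0.5 + 0.3 * cos(seq(0, 6, length.out = bands)),
                  0.5 + 0.3 * sin(seq(0, 12, length.out = bands)))
  for (i in seq_len(n)) X[i, ] <- X[i, ] + shapes[cls[i], ]
  spectra_table(X, wl, seed_ids = seq_len(n),
                labels = factor(c("ZH37", "ZH41", "ZH55")[cls],
                                levels = c("ZH37", "ZH41", "ZH55")),
                level = "object")
}
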