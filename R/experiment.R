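#' PCA scores of average spectra
#'
#' Mean-centered principal component analysis of an object-level table,
#' for qualitative class-separability inspection. Returns the leading
#' scores and the fraction of variance each component explains.
#'
#' @param object_table an object-level [spectra_table] (pixel-level input
#'   works but is not the usual exploration mode).
#' @param n_pcs number of components to keep.
#' @return A list of class `pca_scores`: `scores` (n x k matrix),
#'   `explained` (variance fractions of the kept components),
#'   `explained_full` (fractions of every component), `labels`. If the
#'   data rank is below `n_pcs` a warning is issued and fewer components
#'   are returned.
#' @export
pca_scores <- function(object_table, n_pcs = 3L) {
  stopifnot(inherits(object_table, "spectra_table"))
  X <- object_table$spectra
  if (nrow(X) < 2L) stop("need at least 2 spectra for PCA")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-8)
  k <- min(n_pcs, rank, ncol(pc$x))
  if (k < n_pcs)
    warning("data rank ", rank, " below requested ", n_pcs,
            " components; returning ", k)
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 explained = ev[seq_len(k)], explained_full = ev,
                 labels = object_table$labels),
            class = "pca_scores")
}

#' @export
print.pca_scores <- function(x, ...) {
  cat(sprintf("<pca_scores> %d spectra, %d PCs explaining %s%% (total %.3f%%)\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.3f", 100 * x$explained), collapse = "/"),
              100 * sum(x$explained)))
  invisible(x)
}

#' Scatter plot of two principal components
#'
#' @param x a [pca_scores()] object.
#' @param comps which two components to draw.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pca_scores <- function(x, comps = c(1, 2), ...) {
  s <- x$scores
  col <- if (is.null(x$labels)) 1 else as.integer(x$labels) + 1L
  graphics::plot(s[, comps[1]], s[, comps[2]], col = col,
                 pch = 19, cex = 0.6,
                 xlab = sprintf("PC%d (%.1f%%)", comps[1],
                                100 * x$explained[comps[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", comps[2],
                                100 * x$explained[comps[2]]), ...)
  if (!is.null(x$labels))
    graphics::legend("topright", levels(x$labels), col = 2:4, pch = 19,
                     cex = 0.8)
  invisible(x)
}

# first k seeds per variety (appearance order) of a labeled table
.first_k_seeds <- function(table, k) {
  per_seed <- !duplicated(table$seed_ids)
  ids <- table$seed_ids[per_seed]
  labs <- table$labels[per_seed]
  keep_ids <- unlist(lapply(levels(labs), function(l) {
    cand <- ids[labs == l]
    if (length(cand) < k)
      stop("split has only ", length(cand), " seeds of ", l,
           ", need ", k)
    cand[seq_len(k)]
  }))
  subset_rows(table, table$seed_ids %in% keep_ids)
}

# preprocess the pixel tables of all splits once and derive object tables
# (averages of the preprocessed pixel spectra, as the pipeline defines)
.prep_splits <- function(splits) {
  lapply(splits, function(s) {
    px <- preprocess_pipeline(s$pixel)
    list(pixel = px, object = average_by_seed(px))
  })
}

#' Training-set-size sweep
#'
#' Trains one model per training-set size and reports accuracies across
#' splits, reproducing the sample-size experiment design: object-wise
#' models predict average spectra; pixel-wise models predict both
#' pixel-wise spectra and (as a third mode) average spectra.
#'
#' @param splits output of [generate_splits()] (raw tables; preprocessing
#'   is applied internally).
#' @param sizes training seeds per variety, one model per entry.
#' @param mode `"object"` or `"pixel"`.
#' @param config a [cnn_config()]; `config$seed` makes the sweep
#'   deterministic.
#' @param epochs training epochs (overrides `config$epochs`).
#' @param out_csv optional path; the results table is written as CSV.
#' @return A data frame with one row per size: accuracies in percent
#'   (`tra_acc`, `val_acc`, `pre_acc`, and for pixel mode also
#'   `pre_object_acc`), plus the training wall time in seconds.
#' @export
run_sweep <- function(splits, sizes, mode = c("object", "pixel"),
                      config = cnn_config(), epochs = 60L, out_csv = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(diff(sizes) >= 0), all(sizes >= 1))
  pp <- .prep_splits(splits)
  rows <- lapply(sizes, function(k) {
    tr <- .first_k_seeds(pp$train[[mode]], k)
    t0 <- proc.time()[["elapsed"]]
    fit <- spectral_cnn(tr, val = NULL, config = config, epochs = epochs)
    elapsed <- proc.time()[["elapsed"]] - t0
    acc <- function(tab) {
      100 * mean(predict(fit, tab, type = "class") == tab$labels)
    }
    row <- data.frame(n_train = k, tra_acc = acc(tr),
                      val_acc = acc(pp$val[[mode]]),
                      pre_acc = acc(pp$pred[[mode]]))
    if (mode == "pixel") row$pre_object_acc <- acc(pp$pred$object)
    row$time_s <- elapsed
    row
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) write.csv(format(out, digits = 6), out_csv,
                                   row.names = FALSE)
  out
}

#' Pixel-wise vs majority-vote comparison
#'
#' Trains a pixel-wise model and reports, for each split, the per-variety
#' and overall accuracy of (a) raw per-pixel prediction and (b) per-seed
#' majority voting — the two decision strategies. Vote accuracy is
#' measured over seeds, pixel accuracy over pixels.
#'
#' @param splits output of [generate_splits()].
#' @param size training seeds per variety (default: all available).
#' @param config a [cnn_config()].
#' @param epochs training epochs.
#' @param out_csv optional CSV path.
#' @return A list with `report` (data frame: `Set`, one column per
#'   variety, `All`; rows Tra/Val/Pre x pixel/vote, accuracies in
#'   percent) and `fit` (the trained model).
#' @export
run_vote_comparison <- function(splits, size = NULL, config = cnn_config(),
                                epochs = 60L, out_csv = NULL) {
  pp <- .prep_splits(splits)
  if (is.null(size)) {
    labs <- pp$train$pixel$labels[!duplicated(pp$train$pixel$seed_ids)]
    size <- min(table(labs))
  }
  tr <- .first_k_seeds(pp$train$pixel, size)
  fit <- spectral_cnn(tr, val = NULL, config = config, epochs = epochs)
  classes <- fit$classes
  sets <- list(Tra = tr, Val = pp$val$pixel, Pre = pp$pred$pixel)
  mkrow <- function(set_name, ev) {
    row <- data.frame(Set = set_name)
    for (cl in classes) row[[cl]] <- unname(ev$per_class[cl])
    row$All <- ev$overall
    row
  }
  pixel_rows <- list(); vote_rows <- list()
  for (nm in names(sets)) {
    tab <- sets[[nm]]
    pred <- predict(fit, tab, type = "class")
    pixel_rows[[nm]] <- mkrow(paste0(nm, "-pixel"),
                              evaluate(pred, tab$labels, classes = classes))
    votes <- vote_seeds(pred, tab$seed_ids, classes = classes)
    seed_truth <- tab$labels[!duplicated(tab$seed_ids)]
    vote_rows[[nm]] <- mkrow(paste0(nm, "-vote"),
                             evaluate(votes$final_label, seed_truth,
                                      classes = classes))
  }
  report <- do.call(rbind, c(pixel_rows, vote_rows))
  rownames(report) <- NULL
  if (!is.null(out_csv)) write.csv(format(report, digits = 6), out_csv,
                                   row.names = FALSE)
  list(report = report, fit = fit)
}
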