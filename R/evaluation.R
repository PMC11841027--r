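# Model evaluation: true skill statistic, continuous Boyce index, and
# spatial block cross-validation folds.

#' True skill statistic
#'
#' `max over thresholds of (sensitivity + specificity - 1)`, with the
#' threshold search performed exactly over the sorted unique predicted
#' values (classification rule: predicted value >= threshold). Invariant to
#' strictly monotone transforms of the predictions.
#'
#' @param predictions numeric predictions (any monotone score).
#' @param labels 0/1 observed labels; both classes must be present.
#' @return TSS in `[0, 1]` (the all-absent threshold bounds it below at 0).
#' @export
tss <- function(predictions, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("TSS undefined: labels contain a single class")
  o <- order(predictions, decreasing = TRUE)
  p <- predictions[o]; y <- labels[o]
  np <- sum(y == 1); nn <- sum(y == 0)
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  # evaluate at the last index of each tie group (threshold = that value)
  last <- which(c(p[-1] != p[-length(p)], TRUE))
  sens <- tp[last] / np
  spec <- (nn - fp[last]) / nn
  max(0, max(sens + spec - 1))
}

#' Continuous Boyce index
#'
#' Spearman rank correlation between the midpoints of overlapping
#' suitability windows and the predicted-to-expected presence ratio in each
#' window (P/E: the share of test presences falling in the window divided by
#' the share of background). Defaults: 101 windows of width 10% of the
#' background suitability range — the classic continuous construction.
#'
#' @param pred_presence predicted suitability at the test presences.
#' @param pred_background predicted suitability over the background/region.
#' @param n_windows number of overlapping windows (default 101).
#' @param window_width window width as a fraction of the suitability range
#'   (default 0.1).
#' @return CBI in `[-1, 1]`, or `NA` (flagged via attribute `reason`) when
#'   predictions are constant or too few windows are populated.
#' @export
cbi <- function(pred_presence, pred_background, n_windows = 101,
                window_width = 0.1) {
  rng <- range(pred_background)
  if (diff(rng) <= 0)
    return(structure(NA_real_, reason = "constant predictions"))
  w <- window_width * diff(rng)
  starts <- seq(rng[1], rng[2] - w, length.out = n_windows)
  mids <- starts + w / 2
  pe <- vapply(starts, function(s) {
    e <- mean(pred_background >= s & pred_background <= s + w)
    if (e == 0) return(NA_real_)
    mean(pred_presence >= s & pred_presence <= s + w) / e
  }, 0)
  ok <- is.finite(pe)
  if (sum(ok) < 3 || sd(pe[ok]) == 0)
    return(structure(NA_real_, reason = "degenerate P/E curve"))
  cor(mids[ok], pe[ok], method = "spearman")
}

#' Spatially blocked cross-validation folds
#'
#' Tiles the points into contiguous `block_size_deg` lon/lat blocks and
#' allocates whole blocks to folds, greedily balancing presence counts (each
#' new block goes to the fold with the fewest presences so far, ties broken
#' towards the fold with fewer blocks). Every point lands in exactly one
#' fold.
#'
#' @param lon,lat point coordinates in degrees.
#' @param presence 0/1 flag per point (balancing target).
#' @param block_size_deg block edge length in degrees.
#' @param n_folds number of folds.
#' @param seed integer seed (shuffles equal-count block order).
#' @return integer fold assignment per point.
#' @export
block_cv_split <- function(lon, lat, presence, block_size_deg, n_folds = 2,
                           seed = NULL) {
  bx <- floor(normalize_lon(lon) / block_size_deg)
  by <- floor(lat / block_size_deg)
  block <- paste(bx, by, sep = ":")
  ub <- unique(block)
  if (length(ub) < n_folds)
    stop(sprintf("only %d non-empty spatial block(s) for %d folds; use a smaller block size",
                 length(ub), n_folds))
  pres_per_block <- vapply(ub, function(b) sum(presence[block == b]), 0)
  if (sum(pres_per_block > 0) < 2)
    stop("all presences fall in a single spatial block; use a smaller block size")
  ord <- with_seed(seed, {
    jitter_rank <- runif(length(ub))
    order(-pres_per_block, jitter_rank)
  })
  fold_of_block <- integer(length(ub))
  fold_pres <- numeric(n_folds)
  fold_nblk <- integer(n_folds)
  for (b in ord) {
    f <- order(fold_pres, fold_nblk)[1]
    fold_of_block[b] <- f
    fold_pres[f] <- fold_pres[f] + pres_per_block[b]
    fold_nblk[f] <- fold_nblk[f] + 1L
  }
  fold_of_block[match(block, ub)]
}
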