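# PCA validation of divergence calls: principal components of the paired
# environmental space, per-axis mean-score differences between the two
# presence groups, a 1000-replicate label-permutation null, and a
# Bonferroni-corrected Welch t-test.

#' Principal-component space of a paired comparison
#'
#' Pools presence rows of both basins (each basin capped at `cap` by a
#' seeded subsample) with matched background rows (`ratio` background rows
#' per presence, per basin), centres and scales every variable to unit
#' variance, and fits a PCA on the pooled rows. Axis signs are
#' canonicalized so each axis's largest-|loading| variable loads
#' positively. Scores carry group labels `presence-A`, `presence-B`,
#' `background-A`, `background-B`.
#'
#' @param pres_a,pres_b presence model frames (variables as columns).
#' @param bg_a,bg_b background model frames.
#' @param variables variables to use.
#' @param cap per-basin presence cap (default 1000).
#' @param ratio background:presence ratio (default 10).
#' @param seed integer seed for the subsampling.
#' @return class `pca_space`: `loadings`, `explained` (variance
#'   fractions), `scores`, `group`, `n_axes`.
#' @export
build_pca <- function(pres_a, pres_b, bg_a, bg_b, variables,
                      cap = 1000, ratio = 10, seed = NULL) {
  take <- function(df, n, s) {
    if (nrow(df) <= n) return(df)
    df[with_seed(s, sample.int(nrow(df), n)), , drop = FALSE]
  }
  pres_a <- take(pres_a, cap, spawn_seed(seed %||% 0, "pa"))
  pres_b <- take(pres_b, cap, spawn_seed(seed %||% 0, "pb"))
  bg_a <- take(bg_a, ratio * nrow(pres_a), spawn_seed(seed %||% 0, "ba"))
  bg_b <- take(bg_b, ratio * nrow(pres_b), spawn_seed(seed %||% 0, "bb"))
  x <- rbind(as.matrix(pres_a[, variables, drop = FALSE]),
             as.matrix(pres_b[, variables, drop = FALSE]),
             as.matrix(bg_a[, variables, drop = FALSE]),
             as.matrix(bg_b[, variables, drop = FALSE]))
  if (nrow(x) < length(variables)) stop("fewer rows than variables")
  group <- rep(c("presence-A", "presence-B", "background-A", "background-B"),
               c(nrow(pres_a), nrow(pres_b), nrow(bg_a), nrow(bg_b)))
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(p$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  p$rotation <- sweep(p$rotation, 2, flip, "*")
  p$x <- sweep(p$x, 2, flip, "*")
  structure(list(loadings = p$rotation,
                 explained = p$sdev^2 / sum(p$sdev^2),
                 scores = p$x, group = group,
                 n_axes = NA_integer_),
            class = "pca_space")
}

#' Number of leading axes to analyse
#'
#' The elbow rule formalized: the smallest `k` whose cumulative explained
#' variance reaches `target` (default 0.70), bounded to `[2, 4]`.
#'
#' @param explained vector of explained-variance fractions (>= 2 axes).
#' @param target cumulative-variance target (default 0.70).
#' @return integer axis count in `[2, 4]`.
#' @export
select_axes <- function(explained, target = 0.70) {
  stopifnot(length(explained) >= 2)
  cum <- cumsum(explained)
  k <- if (any(cum >= target)) which(cum >= target)[1] else length(explained)
  as.integer(min(4, max(2, k)))
}

#' Absolute difference of mean presence scores on one axis
#' @param pca a `pca_space`.
#' @param axis axis index.
#' @return `|mean(score | presence-A) - mean(score | presence-B)|`.
#' @export
axis_mean_difference <- function(pca, axis) {
  a <- pca$scores[pca$group == "presence-A", axis]
  b <- pca$scores[pca$group == "presence-B", axis]
  if (length(a) == 0 || length(b) == 0) stop("empty presence group")
  abs(mean(a) - mean(b))
}

#' Permutation ("jack-knife") null for one PCA axis
#'
#' Each of `n_reps` replicates permutes the basin labels over the pooled
#' presence scores (holding group sizes fixed) and recomputes the absolute
#' mean-score difference; the 95% CI is the nearest-rank [alpha/2,
#' 1-alpha/2] percentile interval. The observed difference exceeding the
#' upper bound is the divergence signal.
#'
#' @param pca a `pca_space`.
#' @param axis axis index.
#' @param n_reps replicates (default 1000; < 100 sets a warning flag).
#' @param alpha test level (default 0.05).
#' @param seed integer seed.
#' @param method `"permutation"` (default) resamples basin labels over the
#'   pooled presence scores; `"jackknife"` is the strict delete-one
#'   variant (one replicate per pooled observation, `n_reps` ignored),
#'   whose null describes the statistic's sampling wobble rather than the
#'   no-difference hypothesis.
#' @return class `axis_divergence`: `axis`, `observed`, `null_values`,
#'   `lower`, `upper`, `outside_ci`, `exceeds_upper`, and (filled by
#'   [bonferroni_test()]) `p_adjusted`, `significant`.
#' @export
jackknife_null <- function(pca, axis, n_reps = 1000, alpha = 0.05,
                           seed = NULL,
                           method = c("permutation", "jackknife")) {
  method <- match.arg(method)
  pres <- pca$group %in% c("presence-A", "presence-B")
  s <- pca$scores[pres, axis]
  g <- pca$group[pres]
  if (length(s) < 20) stop("need at least 20 pooled presence scores")
  na <- sum(g == "presence-A")
  obs <- axis_mean_difference(pca, axis)
  vals <- if (method == "permutation") {
    with_seed(seed, vapply(seq_len(n_reps), function(i) {
      idx <- sample.int(length(s), na)
      abs(mean(s[idx]) - mean(s[-idx]))
    }, 0))
  } else {
    n_reps <- length(s)
    vapply(seq_along(s), function(i) {
      gi <- g[-i]; si <- s[-i]
      abs(mean(si[gi == "presence-A"]) - mean(si[gi == "presence-B"]))
    }, 0)
  }
  lo <- nearest_rank(vals, alpha / 2)
  hi <- nearest_rank(vals, 1 - alpha / 2)
  structure(list(axis = axis, observed = obs, null_values = vals,
                 lower = lo, upper = hi,
                 outside_ci = obs < lo || obs > hi,
                 exceeds_upper = obs > hi,
                 warn_few_reps = n_reps < 100,
                 p_adjusted = NA_real_, significant = NA),
            class = "axis_divergence")
}

#' Bonferroni-corrected Welch t-test across axes
#'
#' Two-sample unequal-variance t-test of presence-A vs presence-B scores on
#' each of the `k` analysed axes; p-values are multiplied by `k * m` (axes
#' times comparisons in the study) and clipped at 1. When `axes` results
#' from [jackknife_null()] are supplied, their `significant` field is set
#' to `outside_ci & p_adjusted < alpha`.
#'
#' @param pca a `pca_space`.
#' @param k number of axes tested.
#' @param m number of species-by-pair comparisons corrected over
#'   (default 1).
#' @param axes optional list of `axis_divergence` objects to annotate.
#' @param alpha significance level (default 0.05).
#' @return data.frame (`axis`, `t`, `df`, `p_raw`, `p_adjusted`), or, when
#'   `axes` is given, the annotated list with the table as attribute
#'   `"tests"`.
#' @export
bonferroni_test <- function(pca, k, m = 1, axes = NULL, alpha = 0.05) {
  a <- pca$scores[pca$group == "presence-A", , drop = FALSE]
  b <- pca$scores[pca$group == "presence-B", , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2) stop("need >= 2 scores per presence group")
  tab <- do.call(rbind, lapply(seq_len(k), function(ax) {
    tt <- t.test(a[, ax], b[, ax], var.equal = FALSE)
    data.frame(axis = ax, t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value,
               p_adjusted = min(1, tt$p.value * k * m))
  }))
  if (is.null(axes)) return(tab)
  for (i in seq_along(axes)) {
    ax <- axes[[i]]$axis
    axes[[i]]$p_adjusted <- tab$p_adjusted[tab$axis == ax]
    axes[[i]]$significant <- axes[[i]]$outside_ci &&
      axes[[i]]$p_adjusted < alpha
  }
  attr(axes, "tests") <- tab
  axes
}

#' Run the full PCA validation for one paired comparison
#'
#' Builds the PCA space, selects the leading axes, runs the permutation
#' null and the Bonferroni-corrected t-test per axis.
#'
#' @inheritParams build_pca
#' @param m total comparisons for the Bonferroni correction.
#' @param n_reps permutation replicates (default 1000).
#' @param alpha test level.
#' @return list with `pca`, `k`, and `axes` (annotated
#'   `axis_divergence` list).
#' @export
pca_validation <- function(pres_a, pres_b, bg_a, bg_b, variables,
                           cap = 1000, ratio = 10, m = 1, n_reps = 1000,
                           alpha = 0.05, seed = NULL) {
  pca <- build_pca(pres_a, pres_b, bg_a, bg_b, variables, cap, ratio, seed)
  k <- select_axes(pca$explained)
  pca$n_axes <- k
  axes <- lapply(seq_len(k), function(ax)
    jackknife_null(pca, ax, n_reps, alpha,
                   seed = spawn_seed(seed %||% 0, "jk", ax)))
  axes <- bonferroni_test(pca, k, m, axes, alpha)
  list(pca = pca, k = k, axes = axes)
}

#' Combine the overlap-test call with the PCA evidence
#'
#' The ensemble overlap test is the primary detector and the PCA the
#' validator: a diverged call is confirmed iff at least one analysed axis
#' is significant, otherwise it is downgraded to neutral with a flag;
#' non-diverged calls pass through unchanged.
#'
#' @param enm_call a `divergence_call`.
#' @param axes list of annotated `axis_divergence` objects.
#' @return a `divergence_call` with `validated` and `downgraded` fields.
#' @export
combine_evidence <- function(enm_call, axes) {
  out <- enm_call
  out$validated <- NA
  out$downgraded <- FALSE
  if (enm_call$class == "diverged") {
    sig <- any(vapply(axes, function(a) isTRUE(a$significant), TRUE))
    out$validated <- sig
    if (!sig) {
      out$class <- "neutral"
      out$binary_diverged <- 0L
      out$downgraded <- TRUE
    }
  }
  out
}
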