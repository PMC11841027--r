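# Sensitivity diagnostics: stability of Schoener's D under resampled
# presence counts, and a logistic regression of the divergence call on
# between-basin observation imbalance.

#' Overlap stability under resampled presence counts
#'
#' For each requested sample size, subsamples both basins' presences
#' without replacement to that size, redraws the 10:1 targeted background,
#' refits both basin ensembles and recomputes Schoener's D; the curve is
#' assembled against the full-data D. Sizes exceeding the available count
#' are skipped and logged.
#'
#' @param occ one species' occurrence records (`basin`/`status` assigned).
#' @param seascape a `seascape`.
#' @param basin_a,basin_b basin labels.
#' @param variables model covariates.
#' @param density targeted-group density grid (default uniform over ocean).
#' @param config an [enm_config()].
#' @param sizes resampling levels (default 25, 50, 100, 250, 500, 1000).
#' @param n_replicates replicates per level (default 10).
#' @param seed integer seed.
#' @return class `resampling_curve`: data.frame (`n`, `replicate`, `d`)
#'   with attributes `full_d`, `skipped`, `summary` (per-level mean/SD).
#' @export
resample_overlap <- function(occ, seascape, basin_a, basin_b, variables,
                             density = NULL, config = enm_config(),
                             sizes = c(25, 50, 100, 250, 500, 1000),
                             n_replicates = 10, seed = 1L) {
  if (!is.null(occ$status)) occ <- occ[occ$status == "ok", , drop = FALSE]
  clim <- seascape$clim
  if (is.null(density)) density <- uniform_density(seascape)
  ctx <- pair_context(seascape, variables, c(basin_a, basin_b), config)
  rows_a <- ctx_pres_rows(ctx, occ[occ$basin == basin_a, , drop = FALSE], clim)
  rows_b <- ctx_pres_rows(ctx, occ[occ$basin == basin_b, , drop = FALSE], clim)
  # the background draw and CV split are seeded from the subsample itself,
  # so the only randomness across replicates is the subsample: replicates
  # at the full presence count are exactly degenerate
  fit_d <- function(ra, rb) {
    ra <- sort(ra); rb <- sort(rb)
    s0 <- spawn_seed(seed, "fit", length(ra), sum(ra), length(rb), sum(rb))
    surf <- list()
    for (side in c("a", "b")) {
      r <- if (side == "a") ra else rb
      basin <- if (side == "a") basin_a else basin_b
      ids <- slot_id(ctx$slots$cell[r], ctx$slots$month[r], ctx$ncell_grid)
      n_bg <- min(config$ratio * length(r), config$cap)
      bgr <- with_seed(spawn_seed(s0, side, "bg"),
                       draw_ctx_rows(ctx, basin, density, n_bg,
                                     exclude_ids = ids, what = "background"))
      ens <- fit_ensemble_ctx(r, bgr, ctx, config,
                              seed = spawn_seed(s0, side, "cv"))
      if (is.null(ens)) return(NA_real_)
      surf[[side]] <- restrict_and_normalize(project_ctx(ens, ctx),
                                             ctx$slots$cells)
    }
    schoeners_d(surf$a, surf$b)
  }
  full_d <- fit_d(rows_a, rows_b)
  avail <- min(length(rows_a), length(rows_b))
  sizes <- sort(unique(sizes))
  skipped <- sizes[sizes > avail]
  keep <- sizes[sizes <= avail]
  rows <- list()
  for (n in keep) {
    for (r in seq_len(n_replicates)) {
      sub <- with_seed(spawn_seed(seed, "lvl", n, r),
                       list(ra = rows_a[sample.int(length(rows_a), n)],
                            rb = rows_b[sample.int(length(rows_b), n)]))
      d <- fit_d(sub$ra, sub$rb)
      rows[[length(rows) + 1]] <- data.frame(n = n, replicate = r, d = d)
    }
  }
  curve <- do.call(rbind, rows)
  smry <- do.call(rbind, lapply(split(curve, curve$n), function(d)
    data.frame(n = d$n[1], mean_d = mean(d$d, na.rm = TRUE),
               sd_d = sd(d$d[is.finite(d$d)]),
               abs_dev = mean(abs(d$d - full_d), na.rm = TRUE))))
  structure(curve, class = c("resampling_curve", class(curve)),
            full_d = full_d, skipped = skipped, summary = smry)
}

#' Logistic regression of divergence on observation imbalance
#'
#' Fits `binary_diverged ~ |n_A - n_B|` by logistic regression across the
#' comparison table — the check that divergence calls are not an artefact
#' of unequal sampling between basins.
#'
#' @param table comparison data.frame with columns `binary_diverged`,
#'   `n_a`, `n_b` (>= 30 rows, both outcome classes present).
#' @return class `imbalance_regression`: `coefficient`, `se`, `z`, `p`
#'   (likelihood-ratio test, robust to separation), `p_wald`, `pseudo_r2`
#'   (McFadden), `n`.
#' @export
imbalance_regression <- function(table) {
  stopifnot(all(c("binary_diverged", "n_a", "n_b") %in% names(table)))
  if (nrow(table) < 30) stop("need at least 30 comparisons")
  y <- table$binary_diverged
  if (length(unique(y)) < 2) stop("single-class outcome: regression undefined")
  imb <- abs(table$n_a - table$n_b)
  if (var(imb) == 0)
    stop("observation imbalance is constant across comparisons")
  fit <- suppressWarnings(glm(y ~ imb, family = binomial()))
  null <- glm(y ~ 1, family = binomial())
  s <- suppressWarnings(summary(fit))$coefficients
  # likelihood-ratio p: immune to the Wald collapse under separation
  lr <- null$deviance - fit$deviance
  structure(list(coefficient = s["imb", "Estimate"],
                 se = s["imb", "Std. Error"],
                 z = s["imb", "z value"],
                 p = stats::pchisq(lr, df = 1, lower.tail = FALSE),
                 p_wald = s["imb", "Pr(>|z|)"],
                 pseudo_r2 = 1 - as.numeric(logLik(fit)) /
                   as.numeric(logLik(null)),
                 n = nrow(table)),
            class = "imbalance_regression")
}
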