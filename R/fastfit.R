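# Fast fitting path for the overlap machinery. A pairwise comparison (and
# each of its ~200 null replicates) fits the same three algorithms over
# subsets of one fixed (cell, month) slot table, so the per-algorithm
# feature matrices — linear, standardized linear+quadratic, and the natural
# spline basis — are built once per comparison support, with
# standardization and knots taken from the support's environmental
# distribution. Individual fits then reduce to row indexing plus the
# compiled IRLS solve.

pair_context <- function(seascape, variables, basins, config) {
  slots <- basin_slots(seascape, variables, basins)
  x <- slots$x
  feats <- list()
  ctr <- colMeans(x); scl <- apply(x, 2, sd); scl[scl == 0] <- 1
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  feats$glm <- list(X = cbind(1, z),
                    spec = list(algorithm = "glm", vars = colnames(x),
                                center = ctr, scale = scl))
  feats$maxent <- list(X = cbind(1, z, z^2),
                       spec = list(algorithm = "maxent", vars = colnames(x),
                                   center = ctr, scale = scl))
  bases <- list(); gmats <- list()
  for (v in colnames(x)) {
    bases[[v]] <- ns_knots(x[, v])
    gmats[[v]] <- ns_basis(x[, v], bases[[v]])
  }
  feats$gam <- list(X = cbind(1, do.call(cbind, gmats)),
                    spec = list(algorithm = "gam", vars = colnames(x),
                                bases = bases))
  labs <- basin_labels(seascape$mask)
  list(slots = slots, feats = feats,
       basin = labs[seascape$mask[slots$cell]],
       ncell_grid = length(seascape$clim$lon) * length(seascape$clim$lat),
       dim = c(length(seascape$clim$lon), length(seascape$clim$lat)))
}

# fit the configured algorithms on slot rows of a pair context
fit_ensemble_ctx <- function(pres_rows, bg_rows, ctx, config, seed = NULL,
                             gate = TRUE, species = NA) {
  rows <- c(pres_rows, bg_rows)
  y <- c(rep(1, length(pres_rows)), rep(0, length(bg_rows)))
  folds <- block_cv_split(ctx$slots$lon[rows], ctx$slots$lat[rows], y,
                          config$block_size_deg, config$n_folds, seed = seed)
  components <- list()
  for (alg in config$algorithms) {
    X <- ctx$feats[[alg]]$X
    pen <- component_penalty(alg, ncol(X), config$reg_mult)
    tss_f <- cbi_f <- rep(NA_real_, config$n_folds)
    for (f in seq_len(config$n_folds)) {
      tr <- rows[folds != f]; ytr <- y[folds != f]
      te <- rows[folds == f]; yte <- y[folds == f]
      if (length(unique(yte)) < 2 || sum(ytr) < 10) next
      ft <- irls_logistic(X[tr, , drop = FALSE], ytr, pen)
      pred <- plogis(pmin(30, pmax(-30,
        drop(X[te, , drop = FALSE] %*% ft$coefficients))))
      tss_f[f] <- tss(pred, yte)
      if (gate && sum(yte) >= 20)
        cbi_f[f] <- cbi(pred[yte == 1], pred[yte == 0],
                        config$cbi_windows, config$cbi_width)
    }
    ft <- irls_logistic(X[rows, , drop = FALSE], y, pen)
    flagged <- FALSE
    if (!ft$converged || max(abs(ft$coefficients)) > 30) {
      ft <- irls_logistic(X[rows, , drop = FALSE], y,
                          pen + c(0, rep(0.1, ncol(X) - 1)))
      flagged <- TRUE
    }
    model <- structure(list(algorithm = alg,
                            coefficients = drop(ft$coefficients),
                            spec = ctx$feats[[alg]]$spec, edf = ft$edf,
                            converged = ft$converged, flagged = flagged),
                       class = "component_model")
    mt <- mean(tss_f, na.rm = TRUE)
    components[[alg]] <- list(model = model, fold_tss = tss_f,
                              fold_cbi = cbi_f,
                              tss = if (is.nan(mt)) NA_real_ else mt,
                              cbi = if (all(is.na(cbi_f))) NA_real_
                                    else mean(cbi_f, na.rm = TRUE))
    components[[alg]]$retained <- is.finite(mt) && mt > config$tss_threshold
  }
  if (gate) {
    retained <- names(components)[vapply(components, `[[`, TRUE, "retained")]
    if (length(retained) == 0) return(NULL)
    w <- vapply(components[retained], `[[`, 0, "tss")
  } else {
    retained <- names(components)
    w <- pmax(vapply(components, function(cm)
      if (is.finite(cm$tss)) cm$tss else 0, 0), 0)
    if (sum(w) == 0) w <- rep(1, length(w))
    names(w) <- retained
  }
  structure(list(species = species, components = components,
                 weights = w / sum(w),
                 variables = colnames(ctx$slots$x), config = config),
            class = "ensemble_model")
}

# project an ensemble fitted on a pair context onto the context's cells
project_ctx <- function(ens, ctx) {
  pred <- 0
  for (a in names(ens$weights)) {
    beta <- ens$components[[a]]$model$coefficients
    pred <- pred + ens$weights[[a]] *
      plogis(pmin(30, pmax(-30, drop(ctx$feats[[a]]$X %*% beta))))
  }
  vals <- rowMeans(matrix(pred, length(ctx$slots$cells), ctx$slots$n_months))
  new_surface(ctx$slots$cells, vals, ctx$dim)
}
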