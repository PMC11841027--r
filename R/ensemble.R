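# Weighted ensembles of the three component algorithms: targeted-group
# background selection, shared spatial-block cross-validation, TSS-based
# retention (> 0.3) and weighting, projection to suitability surfaces, and
# suitability-weighted mean niche values.

#' Ensemble / overlap-test configuration
#'
#' Collects the tunable parameters shared by ensemble fitting and the
#' background-similarity null: component algorithms, cross-validation
#' layout, background ratio and cap, TSS retention threshold, CBI windows,
#' null replicate count and test level.
#'
#' @param algorithms component algorithms to fit.
#' @param n_folds spatial CV folds (default 2).
#' @param block_size_deg CV block edge in degrees (default 15).
#' @param ratio background:presence ratio (default 10).
#' @param cap background cap (default 1000).
#' @param tss_threshold component retention threshold (default 0.3).
#' @param reg_mult maxent-like regularisation multiplier (default 1).
#' @param cbi_windows,cbi_width CBI window count / fractional width.
#' @param n_reps background-similarity null replicates (default 100).
#' @param alpha test level (default 0.05).
#' @param directions `"both"` or `"single"` direction null testing.
#' @return list of class `enm_config`.
#' @export
enm_config <- function(algorithms = component_algorithms(), n_folds = 2,
                       block_size_deg = 15, ratio = 10, cap = 1000,
                       tss_threshold = 0.3, reg_mult = 1,
                       cbi_windows = 101, cbi_width = 0.1,
                       n_reps = 100, alpha = 0.05, directions = "both") {
  stopifnot(alpha > 0, alpha < 0.5, ratio > 0, cap > 0, n_folds >= 2)
  structure(list(algorithms = algorithms, n_folds = n_folds,
                 block_size_deg = block_size_deg, ratio = ratio, cap = cap,
                 tss_threshold = tss_threshold, reg_mult = reg_mult,
                 cbi_windows = cbi_windows, cbi_width = cbi_width,
                 n_reps = n_reps, alpha = alpha, directions = directions),
            class = "enm_config")
}

#' Pooled occurrence density over grid cells (targeted-group weights)
#'
#' Counts records of *all* species per ocean cell and normalizes; the
#' resulting surface is the targeted-group sampling-effort proxy used to
#' draw background points with the same spatial bias as the survey. A
#' pseudocount added to every ocean cell keeps unvisited cells drawable
#' and, when the target group is small, shrinks the estimator toward
#' uniform (a handful of species cannot separate survey effort from their
#' own shared niches); the default is the mean count per ocean cell.
#'
#' @param occ pooled occurrence data.frame (all species).
#' @param seascape a `seascape`.
#' @param pseudocount added to every ocean cell; default
#'   `max(0.5, mean records per ocean cell)`.
#' @return matrix over the grid, `NA` off-ocean, summing to 1 over ocean.
#' @export
occurrence_density <- function(occ, seascape, pseudocount = NULL) {
  mask <- seascape$mask
  oc <- ocean_cells(mask)
  if (is.null(pseudocount)) pseudocount <- max(0.5, nrow(occ) / length(oc))
  d <- matrix(NA_real_, nrow(mask), ncol(mask))
  d[oc] <- pseudocount
  if (nrow(occ) > 0) {
    gi <- grid_index(seascape$clim, occ$lon, occ$lat)
    cell <- gi$i + (gi$j - 1L) * nrow(mask)
    tab <- table(cell[cell %in% oc])
    d[as.integer(names(tab))] <- d[as.integer(names(tab))] + as.integer(tab)
  }
  d[oc] <- d[oc] / sum(d[oc])
  d
}

# (cell, month) slot table over the ocean cells of the given basins, with
# the environmental covariates pre-extracted. Reused for background
# sampling, null pseudo-presence draws, and surface projection.
basin_slots <- function(seascape, variables, basins = NULL) {
  clim <- seascape$clim; mask <- seascape$mask
  cells <- ocean_cells(mask, basins)
  nm <- length(clim$months)
  nlon <- length(clim$lon); nlat <- length(clim$lat)
  ncell <- nlon * nlat
  cell <- rep(cells, nm)
  month <- rep(clim$months, each = length(cells))
  x <- matrix(NA_real_, length(cell), length(variables),
              dimnames = list(NULL, variables))
  for (v in variables) {
    if (identical(v, "bathymetry")) {
      x[, v] <- clim$bathymetry[cell]
    } else {
      x[, v] <- clim$fields[[v]][cell + (match(month, clim$months) - 1L) * ncell]
    }
  }
  i <- (cell - 1) %% nlon + 1
  j <- (cell - 1) %/% nlon + 1
  list(x = x, cell = cell, month = month, lon = clim$lon[i], lat = clim$lat[j],
       cells = cells, n_months = nm)
}

slot_id <- function(cell, month, ncell) cell + (month - 1) * ncell

#' Select targeted-group background points
#'
#' Draws `min(ratio * n_presences, cap)` background (cell, month) slots
#' without replacement with probability proportional to the pooled
#' occurrence density, never duplicating a presence slot.
#'
#' @param presences presence data.frame (`lon, lat, month`).
#' @param density grid matrix from [occurrence_density()] (or any
#'   nonnegative weight surface).
#' @param seascape a `seascape`.
#' @param basins optional basin restriction for the background cells.
#' @param ratio background:presence ratio (default 10).
#' @param cap maximum background size (default 1000).
#' @param seed integer seed.
#' @return data.frame `lon, lat, month` of background points.
#' @export
select_background <- function(presences, density, seascape, basins = NULL,
                              ratio = 10, cap = 1000, seed = NULL) {
  slots <- basin_slots(seascape, names(seascape$clim$fields)[1], basins)
  n_bg <- min(ratio * nrow(presences), cap)
  ncell <- length(seascape$clim$lon) * length(seascape$clim$lat)
  gi <- grid_index(seascape$clim, presences$lon, presences$lat)
  pres_ids <- slot_id(gi$i + (gi$j - 1L) * length(seascape$clim$lon),
                      presences$month, ncell)
  w <- density[slots$cell]
  w[slot_id(slots$cell, slots$month, ncell) %in% pres_ids] <- 0
  w[!is.finite(w) | w < 0] <- 0
  if (sum(w > 0) < n_bg)
    stop(sprintf("background shortfall: %d slots with positive weight, %d required",
                 sum(w > 0), n_bg))
  idx <- with_seed(seed, sample.int(length(w), n_bg, prob = w))
  data.frame(lon = slots$lon[idx], lat = slots$lat[idx],
             month = slots$month[idx])
}

# Core fitter: presences and background given as slot-row lists
# (x matrix, lon, lat). Returns an ensemble_model or NULL when no
# component clears the TSS retention threshold. With `gate = FALSE`
# (null-model replicates) no component is discarded: weights are
# proportional to max(TSS, 0), equal if all are zero — pseudo-presences
# drawn from the background density carry no niche signal, so a skill gate
# would leave the null undefined.
fit_ensemble_core <- function(pres, bg, config, seed = NULL, species = NA,
                              gate = TRUE) {
  x <- rbind(pres$x, bg$x)
  y <- c(rep(1, nrow(pres$x)), rep(0, nrow(bg$x)))
  lon <- c(pres$lon, bg$lon); lat <- c(pres$lat, bg$lat)
  folds <- block_cv_split(lon, lat, y, config$block_size_deg,
                          config$n_folds, seed = seed)
  components <- list()
  for (alg in config$algorithms) {
    tss_f <- cbi_f <- rep(NA_real_, config$n_folds)
    for (f in seq_len(config$n_folds)) {
      tr <- folds != f; te <- folds == f
      if (length(unique(y[te])) < 2 || sum(y[tr]) < 10) next
      m <- fit_component(alg, x[tr, , drop = FALSE], y[tr],
                         reg_mult = config$reg_mult)
      pred <- predict(m, x[te, , drop = FALSE])
      tss_f[f] <- tss(pred, y[te])
      if (sum(y[te]) >= 20)
        cbi_f[f] <- cbi(pred[y[te] == 1], pred[y[te] == 0],
                        config$cbi_windows, config$cbi_width)
    }
    final <- fit_component(alg, x, y, reg_mult = config$reg_mult)
    components[[alg]] <- list(model = final,
                              fold_tss = tss_f, fold_cbi = cbi_f,
                              tss = mean(tss_f, na.rm = TRUE),
                              cbi = if (all(is.na(cbi_f))) NA_real_
                                    else mean(cbi_f, na.rm = TRUE))
    components[[alg]]$retained <-
      is.finite(components[[alg]]$tss) &&
      components[[alg]]$tss > config$tss_threshold
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
                 weights = w / sum(w), variables = colnames(pres$x),
                 config = config),
            class = "ensemble_model")
}

#' Build a TSS-weighted ensemble from fitted components
#'
#' Retains components with mean cross-validated TSS above the threshold and
#' weights them proportionally to TSS. The ensemble prediction is the
#' weighted mean of component probabilities, hence a convex combination.
#'
#' @param components list of entries `list(model, tss, cbi)` as produced by
#'   the fold evaluation (names = algorithms).
#' @param tss_threshold retention threshold (default 0.3).
#' @param species optional species id.
#' @return an `ensemble_model`; errors if no component passes.
#' @export
build_ensemble <- function(components, tss_threshold = 0.3, species = NA) {
  for (a in names(components))
    components[[a]]$retained <- is.finite(components[[a]]$tss) &&
      components[[a]]$tss > tss_threshold
  retained <- names(components)[vapply(components, `[[`, TRUE, "retained")]
  if (length(retained) == 0)
    stop("no component with TSS > ", tss_threshold, "; species excluded")
  w <- vapply(components[retained], `[[`, 0, "tss")
  structure(list(species = species, components = components,
                 weights = w / sum(w),
                 variables = components[[1]]$model$spec$vars,
                 config = NULL),
            class = "ensemble_model")
}

#' Fit a species' ensemble from occurrence and background model frames
#'
#' Public wrapper over the core fitter: takes presence and background model
#' frames (as from [match_environment()]), fits all configured algorithms
#' under one shared spatial block split, evaluates per-fold TSS/CBI, and
#' returns the TSS-weighted ensemble (or `NULL`, with a `reason` attribute,
#' when no component clears the retention threshold).
#'
#' @param pres_frame presence model frame (`lon`, `lat` plus variables).
#' @param bg_frame background model frame.
#' @param variables covariate names to use.
#' @param config an [enm_config()].
#' @param seed integer seed for the block split.
#' @param species optional species id.
#' @return an `ensemble_model` or `NULL`.
#' @export
fit_species_enm <- function(pres_frame, bg_frame, variables,
                            config = enm_config(), seed = NULL,
                            species = NA) {
  pres <- list(x = as.matrix(pres_frame[, variables, drop = FALSE]),
               lon = pres_frame$lon, lat = pres_frame$lat)
  bg <- list(x = as.matrix(bg_frame[, variables, drop = FALSE]),
             lon = bg_frame$lon, lat = bg_frame$lat)
  fit_ensemble_core(pres, bg, config, seed = seed, species = species)
}

#' Predict from an ensemble model
#' @param object an `ensemble_model`.
#' @param newx covariate matrix.
#' @param ... unused.
#' @return weighted-mean probability of presence in `[0, 1]`.
#' @export
predict.ensemble_model <- function(object, newx, ...) {
  out <- 0
  for (a in names(object$weights))
    out <- out + object$weights[[a]] *
      predict(object$components[[a]]$model, newx)
  out
}

#' Project an ensemble to a suitability surface
#'
#' Predicts suitability for every (ocean cell, month) slot, averages the
#' monthly layers to one annual surface, and stores a normalized copy
#' summing to 1 over the projected cells.
#'
#' @param ensemble an `ensemble_model`.
#' @param seascape a `seascape`.
#' @param basins optional basin restriction of the projected cells.
#' @param slots optional precomputed [basin_slots()] table (speed path).
#' @return class `suitability_surface`: `cells` (grid linear indices),
#'   `values` (annual suitability), `norm` (normalized copy), `dim`.
#' @export
project_ensemble <- function(ensemble, seascape, basins = NULL, slots = NULL) {
  miss <- setdiff(ensemble$variables,
                  c(names(seascape$clim$fields), "bathymetry"))
  if (length(miss)) stop("climatology lacks model variable(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(slots)) slots <- basin_slots(seascape, ensemble$variables, basins)
  pred <- predict(ensemble, slots$x)
  vals <- rowMeans(matrix(pred, length(slots$cells), slots$n_months))
  new_surface(slots$cells, vals,
              c(length(seascape$clim$lon), length(seascape$clim$lat)))
}

new_surface <- function(cells, values, dim) {
  if (any(values < 0)) stop("negative suitability values")
  tot <- sum(values)
  if (tot <= 0) stop("all-zero suitability surface")
  structure(list(cells = cells, values = values, norm = values / tot,
                 dim = dim), class = "suitability_surface")
}

#' Suitability-weighted mean niche values
#'
#' For each variable `v`, `sum_cells(suitability * v) / sum_cells(suitability)`
#' using the month-averaged climatology at the surface's cells (bathymetry
#' is static). Linear in `v` and invariant to positive rescaling of the
#' surface.
#'
#' @param surface a `suitability_surface`.
#' @param seascape a `seascape`.
#' @param variables variables to average (default: all fields + bathymetry).
#' @return named numeric vector of mean niche values.
#' @export
mean_niche_values <- function(surface, seascape,
                              variables = c(names(seascape$clim$fields),
                                            "bathymetry")) {
  clim <- seascape$clim
  w <- surface$values
  if (sum(w) <= 0) stop("all-zero suitability surface")
  ncell <- length(clim$lon) * length(clim$lat)
  vapply(variables, function(v) {
    vals <- if (identical(v, "bathymetry")) clim$bathymetry[surface$cells]
    else {
      m <- vapply(seq_along(clim$months), function(k)
        clim$fields[[v]][surface$cells + (k - 1) * ncell],
        numeric(length(surface$cells)))
      rowMeans(matrix(m, nrow = length(surface$cells)))
    }
    sum(w * vals) / sum(w)
  }, 0)
}
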