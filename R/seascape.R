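# Synthetic seascapes: gridded monthly climatologies, basin masks, and
# presence records drawn from known Gaussian niche functions. Every
# downstream stage of the pipeline can therefore be validated against truth.

default_field_params <- function() {
  list(
    temperature = list(mean = 27, lat_gradient = -0.55, corr_length = 3, noise_sd = 0.8),
    salinity    = list(mean = 35, lat_gradient =  0.02, corr_length = 4, noise_sd = 0.4),
    nitrate     = list(mean = 5,  lat_gradient =  0.10, corr_length = 3, noise_sd = 2.0),
    mld         = list(mean = 40, lat_gradient =  0.30, corr_length = 3, noise_sd = 8.0),
    chlorophyll = list(mean = 0.8, lat_gradient = 0,    corr_length = 2, noise_sd = 0.2,
                       depth_gradient = -0.10, min = 0.01),
    wind_stress = list(mean = 0.10, lat_gradient = 0.001, corr_length = 5, noise_sd = 0.02)
  )
}

#' Specification of a synthetic seascape
#'
#' Describes a rectangular ocean grid: extent, resolution, number of basins,
#' per-variable field parameters (mean, latitudinal gradient per degree of
#' |latitude|, spatial correlation length in degrees, monthly noise SD, an
#' optional depth gradient per km, and an optional `corr_with`/`corr` pair
#' tying the field's anomalies to another field), and bathymetry parameters
#' (coastal shelf width in cells, shelf and maximum depth in metres, number
#' of land columns at the west and east edges). Basins are longitude strips
#' of the ocean cells, so every basin spans the full latitude range and the
#' basins' environmental distributions are matched by construction.
#'
#' @param lon_range,lat_range numeric length-2 extents in degrees.
#' @param resolution cell size in degrees (default 1).
#' @param n_basins number of basins (>= 2).
#' @param months number of monthly layers (default 12).
#' @param fields named list of per-variable parameter lists; see Details.
#' @param bathymetry list with `shelf_width` (cells), `shelf_depth` and
#'   `max_depth` (m), `land_cols` (columns of land at each coast).
#' @param basin_labels character labels, one per basin.
#' @param seed integer seed driving all field noise.
#' @return an object of class `seascape_spec`.
#' @export
seascape_spec <- function(lon_range = c(-60, 30), lat_range = c(-45, 45),
                          resolution = 1, n_basins = 2, months = 12,
                          fields = default_field_params(),
                          bathymetry = list(shelf_width = 4, shelf_depth = 50,
                                            max_depth = 4000, land_cols = 1),
                          basin_labels = NULL, seed = 1L) {
  stopifnot(length(lon_range) == 2, length(lat_range) == 2)
  if (!(resolution > 0)) stop("resolution must be > 0")
  if (n_basins < 2) stop("n_basins must be >= 2")
  if (months < 1) stop("months must be >= 1")
  if (diff(lon_range) < resolution || diff(lat_range) < resolution)
    stop("degenerate extent: grid has zero cells at this resolution")
  if (is.null(basin_labels)) basin_labels <- paste0("B", seq_len(n_basins))
  stopifnot(length(basin_labels) == n_basins)
  structure(list(lon_range = lon_range, lat_range = lat_range,
                 resolution = resolution, n_basins = n_basins, months = months,
                 fields = fields, bathymetry = bathymetry,
                 basin_labels = basin_labels, seed = as.integer(seed)),
            class = "seascape_spec")
}

# Spatially correlated unit-variance noise: white noise smoothed with a
# separable Gaussian kernel of the stated correlation length (in cells),
# then restandardized.
correlated_noise <- function(nlon, nlat, length_cells) {
  z <- matrix(rnorm(nlon * nlat), nlon, nlat)
  if (length_cells > 0) {
    smoother <- function(n) {
      d <- abs(outer(seq_len(n), seq_len(n), "-"))
      k <- exp(-0.5 * (d / length_cells)^2)
      k / rowSums(k)
    }
    z <- smoother(nlon) %*% z %*% t(smoother(nlat))
  }
  s <- sd(as.vector(z))
  if (s > 0) z <- z / s
  z
}

#' Generate a synthetic seascape (climatology + basin mask)
#'
#' Builds a static bathymetry grid (shelf-to-open-ocean depth gradient from
#' the land columns at the map edges), a basin mask partitioning the ocean
#' cells into longitude strips, and monthly environmental fields. Each field
#' is a deterministic structure (mean + latitudinal gradient + optional depth
#' gradient) plus independent spatially-correlated monthly noise; a field
#' with `corr_with = "temperature", corr = r` has its anomalies built as
#' `r * z(temperature) + sqrt(1 - r^2) * own noise`, giving the screening
#' step a collinear pair to remove. Temperature decreases away from the
#' equator whenever its `lat_gradient` is negative (the default).
#'
#' @param spec a [seascape_spec()].
#' @return an object of class `seascape`: list with `clim` (class
#'   `climatology`: `lon`, `lat`, `months`, `fields` (named list of
#'   lon x lat x month arrays), `bathymetry` matrix in metres) and `mask`
#'   (integer lon x lat matrix, `NA` = land, `0` = excluded, `>= 1` = basin
#'   id, with a `labels` attribute).
#' @export
generate_environment <- function(spec) {
  stopifnot(inherits(spec, "seascape_spec"))
  res <- spec$resolution
  lon <- seq(spec$lon_range[1] + res / 2, spec$lon_range[2], by = res)
  lat <- seq(spec$lat_range[1] + res / 2, spec$lat_range[2], by = res)
  lon <- lon[lon < spec$lon_range[2]]
  lat <- lat[lat < spec$lat_range[2]]
  nlon <- length(lon); nlat <- length(lat)
  if (nlon < 1 || nlat < 1) stop("degenerate extent: grid has zero cells")

  bp <- spec$bathymetry
  land_cols <- bp$land_cols %||% 1
  ocean_cols <- seq(land_cols + 1, nlon - land_cols)
  if (length(ocean_cols) < spec$n_basins)
    stop("degenerate extent: fewer ocean columns than basins")
  dist_coast <- pmin(ocean_cols - land_cols, (nlon - land_cols + 1) - ocean_cols)
  depth_col <- bp$shelf_depth +
    (bp$max_depth - bp$shelf_depth) * pmin(1, dist_coast / bp$shelf_width)
  bathy <- matrix(NA_real_, nlon, nlat)
  bathy[ocean_cols, ] <- depth_col

  mask <- matrix(NA_integer_, nlon, nlat)
  strip <- as.integer(cut(seq_along(ocean_cols), breaks = spec$n_basins))
  mask[ocean_cols, ] <- rep(strip, nlat)
  attr(mask, "labels") <- spec$basin_labels
  class(mask) <- c("basin_mask", class(mask))

  ocean <- !is.na(mask) & mask > 0
  fields <- with_seed(spec$seed, {
    out <- list()
    lat_abs <- matrix(abs(lat), nlon, nlat, byrow = TRUE)
    # independent fields first so corr_with targets exist
    ord <- order(!vapply(spec$fields, function(p) is.null(p$corr_with), TRUE))
    for (v in names(spec$fields)[ord]) {
      p <- spec$fields[[v]]
      base <- p$mean + (p$lat_gradient %||% 0) * lat_abs
      if (!is.null(p$depth_gradient))
        base <- base + p$depth_gradient * bathy / 1000
      arr <- array(NA_real_, c(nlon, nlat, spec$months))
      for (m in seq_len(spec$months)) {
        own <- correlated_noise(nlon, nlat, (p$corr_length %||% 0) / res)
        if (!is.null(p$corr_with)) {
          tgt <- out[[p$corr_with]]
          if (is.null(tgt)) stop("corr_with target not generated: ", p$corr_with)
          tz <- tgt[, , m]
          mu <- mean(tz[ocean]); s <- sd(tz[ocean])
          z <- if (s > 0) (tz - mu) / s else tz * 0
          anom <- p$corr * z + sqrt(1 - p$corr^2) * own
        } else {
          anom <- own
        }
        layer <- base + (p$noise_sd %||% 0) * anom
        if (!is.null(p$min)) layer <- pmax(layer, p$min)
        layer[!ocean] <- NA_real_
        arr[, , m] <- layer
      }
      out[[v]] <- arr
    }
    out[names(spec$fields)]
  })

  for (v in names(fields))
    if (!all(is.finite(fields[[v]][ocean])))
      stop("non-finite values generated for field ", v)

  clim <- structure(list(lon = lon, lat = lat, months = seq_len(spec$months),
                         fields = fields, bathymetry = bathy),
                    class = "climatology")
  structure(list(clim = clim, mask = mask, spec = spec), class = "seascape")
}

#' Basin labels of a mask
#' @param mask a `basin_mask`.
#' @return character vector of basin labels.
#' @export
basin_labels <- function(mask) attr(mask, "labels")

# linear indices of ocean cells (basin-labelled, not excluded)
ocean_cells <- function(mask, basins = NULL) {
  keep <- !is.na(mask) & mask > 0
  if (!is.null(basins)) {
    ids <- match(basins, basin_labels(mask))
    if (anyNA(ids)) stop("unknown basin label(s): ",
                         paste(basins[is.na(ids)], collapse = ", "))
    keep <- keep & matrix(mask %in% ids, nrow(mask), ncol(mask))
  }
  which(keep)
}

#' Known niche truth for a synthetic species
#'
#' The generating niche is a product of independent Gaussian kernels, one per
#' environmental variable: suitability is
#' `max_suitability * prod_v exp(-((v - optimum_v)/breadth_v)^2 / 2)`,
#' so it always lies in `[0, max_suitability]`. In the basin named by
#' `diverged_basin` the optimum is shifted by `divergence_delta` — the
#' engineered divergence signal the overlap test must detect.
#'
#' @param optimum named numeric vector of niche optima (field units).
#' @param breadth named positive numeric vector of niche breadths (SD of the
#'   Gaussian kernel, field units).
#' @param divergence_delta named numeric vector of optimum offsets applied in
#'   `diverged_basin` (default: no shift).
#' @param diverged_basin basin label receiving the shifted optimum, or `NULL`.
#' @param max_suitability peak suitability in (0, 1].
#' @return an object of class `niche_truth`.
#' @export
niche_truth <- function(optimum, breadth, divergence_delta = NULL,
                        diverged_basin = NULL, max_suitability = 1) {
  stopifnot(length(optimum) >= 1, !is.null(names(optimum)))
  breadth <- rep_len(breadth, length(optimum))
  names(breadth) <- names(optimum)
  if (any(breadth <= 0)) stop("breadth must be positive")
  if (!(max_suitability > 0 && max_suitability <= 1))
    stop("max_suitability must lie in (0, 1]")
  if (is.null(divergence_delta)) {
    divergence_delta <- setNames(numeric(length(optimum)), names(optimum))
  } else {
    dd <- setNames(numeric(length(optimum)), names(optimum))
    dd[names(divergence_delta)] <- divergence_delta
    divergence_delta <- dd
  }
  structure(list(optimum = optimum, breadth = breadth,
                 divergence_delta = divergence_delta,
                 diverged_basin = diverged_basin,
                 max_suitability = max_suitability),
            class = "niche_truth")
}

# suitability array (lon x lat x month) under a niche truth; NA off-ocean
suitability_grid <- function(truth, clim, mask) {
  nlon <- length(clim$lon); nlat <- length(clim$lat)
  nm <- length(clim$months)
  shifted <- !is.null(truth$diverged_basin)
  if (shifted) {
    bid <- match(truth$diverged_basin, basin_labels(mask))
    if (is.na(bid)) stop("diverged_basin not in mask labels")
    in_b <- matrix(!is.na(mask) & mask == bid, nlon, nlat)
  }
  s <- array(1, c(nlon, nlat, nm))
  for (v in names(truth$optimum)) {
    if (identical(v, "bathymetry")) {
      vals <- array(rep(clim$bathymetry, nm), c(nlon, nlat, nm))
    } else {
      vals <- clim$fields[[v]]
      if (is.null(vals)) stop("truth variable absent from climatology: ", v)
    }
    opt <- matrix(truth$optimum[[v]], nlon, nlat)
    if (shifted) opt[in_b] <- opt[in_b] + truth$divergence_delta[[v]]
    opt <- array(rep(opt, nm), c(nlon, nlat, nm))
    s <- s * exp(-0.5 * ((vals - opt) / truth$breadth[[v]])^2)
  }
  s * truth$max_suitability
}

#' Sampling-effort surface over ocean cells
#'
#' @param seascape a `seascape`.
#' @param type `"uniform"`, or `"coastal"` which concentrates effort on
#'   shallow cells as `exp(-depth / decay)` to emulate ship-track bias.
#' @param decay e-folding depth (m) of the coastal preset.
#' @return matrix over the grid, `NA` off-ocean, summing to 1 over ocean.
#' @export
effort_surface <- function(seascape, type = c("uniform", "coastal"),
                           decay = 500) {
  type <- match.arg(type)
  mask <- seascape$mask
  e <- matrix(NA_real_, nrow(mask), ncol(mask))
  oc <- ocean_cells(mask)
  e[oc] <- if (type == "uniform") 1 else exp(-seascape$clim$bathymetry[oc] / decay)
  e[oc] <- e[oc] / sum(e[oc])
  e
}

#' Sample presence records from a known niche
#'
#' Draws `n` records without replacement over (cell, month) slots with
#' probability proportional to suitability x effort, so each slot yields at
#' most one record — the sampling analogue of one observation per cell per
#' month. Records carry the species label and the basin of their cell.
#'
#' @param truth a [niche_truth()].
#' @param seascape a `seascape` (or pass `clim` and `mask` explicitly).
#' @param n number of records (>= 1).
#' @param effort optional effort matrix from [effort_surface()] (default
#'   uniform).
#' @param basins optional basin labels restricting the sampled cells.
#' @param species species id stored on the records.
#' @param seed integer seed or `NULL`.
#' @return data.frame with columns `species, lon, lat, month, basin`.
#' @export
sample_occurrences <- function(truth, seascape, n, effort = NULL,
                               basins = NULL, species = "sp1", seed = NULL) {
  stopifnot(n >= 1)
  clim <- seascape$clim; mask <- seascape$mask
  s <- suitability_grid(truth, clim, mask)
  oc <- ocean_cells(mask, basins)
  if (is.null(effort)) effort <- effort_surface(seascape, "uniform")
  nm <- length(clim$months)
  # slot weights: suitability(cell, month) * effort(cell)
  w <- matrix(s[rep(oc, nm) + (rep(seq_len(nm), each = length(oc)) - 1) *
                  nrow(mask) * ncol(mask)],
              length(oc), nm)
  w <- w * effort[oc]
  wv <- as.vector(w)
  pos <- sum(wv > 0)
  if (pos < n)
    stop(sprintf("requested %d occurrences but only %d (cell, month) slots have positive probability", n, pos))
  idx <- with_seed(seed, sample.int(length(wv), n, replace = FALSE, prob = wv))
  cell <- oc[(idx - 1) %% length(oc) + 1]
  month <- (idx - 1) %/% length(oc) + 1
  i <- (cell - 1) %% nrow(mask) + 1
  j <- (cell - 1) %/% nrow(mask) + 1
  data.frame(species = species, lon = clim$lon[i], lat = clim$lat[j],
             month = clim$months[month],
             basin = basin_labels(mask)[mask[cell]],
             stringsAsFactors = FALSE)
}

#' Build a full two-or-more-basin synthetic scenario
#'
#' Generates the seascape, draws per-species niche truths (temperature
#' optima spread over `optimum_range`), and samples `n_per_basin` presence
#' records per species in each of the first two basins. A non-zero `delta`
#' shifts each species' temperature optimum by that amount in the second
#' basin — the known divergence signal.
#'
#' @param spec a [seascape_spec()].
#' @param n_species number of species.
#' @param n_per_basin presences per species in every basin of the mask.
#' @param optimum_range range of temperature optima across species.
#' @param breadth temperature niche breadth (deg C).
#' @param delta temperature-optimum shift in the second basin (deg C).
#' @param n_jitter fractional spread of per-species-per-basin sample sizes:
#'   counts are drawn uniformly in `[1 - n_jitter, 1 + n_jitter] *
#'   n_per_basin` (default 0, exact counts).
#' @param effort_type `"uniform"` or `"coastal"` sampling effort.
#' @param seed master seed; per-species sampling seeds are spawned from it.
#' @return class `synthetic_scenario`: the seascape plus `occurrences`
#'   (all species pooled), `truths` (named list), and `effort`.
#' @export
make_scenario <- function(spec = seascape_spec(), n_species = 20,
                          n_per_basin = 75, optimum_range = c(8, 18),
                          breadth = 3, delta = 0, n_jitter = 0,
                          effort_type = "uniform", seed = 1L) {
  sea <- generate_environment(spec)
  labs <- basin_labels(sea$mask)
  effort <- effort_surface(sea, effort_type)
  opts <- with_seed(spawn_seed(seed, "optima"),
                    runif(n_species, optimum_range[1], optimum_range[2]))
  truths <- list(); occ <- vector("list", n_species)
  for (k in seq_len(n_species)) {
    sp <- sprintf("sp%03d", k)
    tr <- niche_truth(optimum = c(temperature = opts[k]),
                      breadth = c(temperature = breadth),
                      divergence_delta = c(temperature = delta),
                      diverged_basin = labs[2])
    truths[[sp]] <- tr
    occ[[k]] <- do.call(rbind, lapply(labs, function(b) {
      n_b <- if (n_jitter > 0)
        round(n_per_basin * with_seed(spawn_seed(seed, sp, b, "n"),
                                      runif(1, 1 - n_jitter, 1 + n_jitter)))
      else n_per_basin
      sample_occurrences(tr, sea, n_b, effort, basins = b,
                         species = sp, seed = spawn_seed(seed, sp, b))
    }))
  }
  structure(c(sea, list(occurrences = do.call(rbind, occ), truths = truths,
                        effort = effort, seed = as.integer(seed))),
            class = c("synthetic_scenario", "seascape"))
}

#' Simulate a species-by-pair comparison table with known smooth effects
#'
#' Produces the input of the divergence-drivers model with known truth: for
#' each row, a pair label, a mean temperature niche and a mean bathymetry
#' niche drawn uniformly over their ranges, and a binary divergence outcome
#' drawn as `Bernoulli(plogis(f_temp(T) + g_bath(B) + pair_effect +
#' pair_smooth(T)))`. The generating functions are stored as the `truth`
#' attribute.
#'
#' @param n_rows number of comparisons (>= 50).
#' @param n_pairs number of basin-pair labels.
#' @param f_temp,g_bath functions of temperature / bathymetry on the logit
#'   scale (default: zero).
#' @param pair_effects named numeric vector of per-pair intercepts (default
#'   zero).
#' @param pair_smooths optional named list of functions of temperature added
#'   for specific pairs (group-level deviations from the global trend).
#' @param temp_range,bath_range covariate ranges.
#' @param seed integer seed.
#' @return data.frame (`species`, `pair`, `diverged`, `temperature`,
#'   `bathymetry`) with a `truth` attribute.
#' @export
generate_hgam_table <- function(n_rows = 552, n_pairs = 14,
                                f_temp = function(t) 0 * t,
                                g_bath = function(b) 0 * b,
                                pair_effects = NULL, pair_smooths = NULL,
                                temp_range = c(0, 30),
                                bath_range = c(0, 5000), seed = 1L) {
  if (n_rows < 50) stop("n_rows must be >= 50")
  pairs <- sprintf("P%02d", seq_len(n_pairs))
  if (is.null(pair_effects)) pair_effects <- setNames(numeric(n_pairs), pairs)
  with_seed(seed, {
    pair <- sample(rep_len(pairs, n_rows))
    temperature <- runif(n_rows, temp_range[1], temp_range[2])
    bathymetry <- runif(n_rows, bath_range[1], bath_range[2])
    eta <- f_temp(temperature) + g_bath(bathymetry) + pair_effects[pair]
    if (!is.null(pair_smooths)) {
      for (p in names(pair_smooths)) {
        sel <- pair == p
        eta[sel] <- eta[sel] + pair_smooths[[p]](temperature[sel])
      }
    }
    if (!all(is.finite(plogis(eta)))) stop("non-finite linear predictor")
    out <- data.frame(species = sprintf("cmp%04d", seq_len(n_rows)),
                      pair = pair, diverged = rbinom(n_rows, 1, plogis(eta)),
                      temperature = temperature, bathymetry = bathymetry,
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- list(f_temp = f_temp, g_bath = g_bath,
                               pair_effects = pair_effects,
                               pair_smooths = pair_smooths)
    out
  })
}
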