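# File formats: occurrence CSV, climatology / mask / surface CSV (long
# format), reports as CSV/JSON, configuration as YAML.

#' Write / read occurrence CSV
#'
#' Columns `species, lon, lat, month, basin` (plus any extra columns);
#' UTF-8, comma-separated, "." decimal, mandatory header. Reading
#' validates coordinates and months and names the offending row.
#'
#' @param occ occurrence data.frame.
#' @param path file path.
#' @return `read_occurrences` returns the validated data.frame.
#' @export
write_occurrences <- function(occ, path) {
  write.csv(occ, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  occ <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat", "month")
  miss <- setdiff(need, names(occ))
  if (length(miss)) stop("malformed occurrence CSV, missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(!(occ$month %in% 1:12))
  if (length(bad)) stop("invalid month outside 1..12 at row ", bad[1])
  bad <- which(!(occ$lat >= -90 & occ$lat <= 90))
  if (length(bad)) stop("invalid latitude at row ", bad[1])
  validate_occurrences(occ)
}

#' Write / read a climatology as long-format CSV
#'
#' Long format with columns `variable, lon, lat, month, value`; the static
#' bathymetry is stored with an empty month. Reading reconstructs the
#' gridded arrays from the unique sorted coordinates.
#'
#' @param clim a `climatology`.
#' @param path file path.
#' @return `read_climatology` returns a `climatology`.
#' @export
write_climatology <- function(clim, path) {
  nlon <- length(clim$lon); nlat <- length(clim$lat)
  grids <- expand.grid(lon = clim$lon, lat = clim$lat)
  rows <- lapply(names(clim$fields), function(v) {
    do.call(rbind, lapply(seq_along(clim$months), function(k)
      data.frame(variable = v, lon = grids$lon, lat = grids$lat,
                 month = clim$months[k],
                 value = as.vector(clim$fields[[v]][, , k]))))
  })
  rows[[length(rows) + 1]] <- data.frame(variable = "bathymetry",
                                         lon = grids$lon, lat = grids$lat,
                                         month = NA_integer_,
                                         value = as.vector(clim$bathymetry))
  write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_climatology
#' @export
read_climatology <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("variable", "lon", "lat", "month", "value")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("malformed climatology CSV, missing column(s): ",
                         paste(miss, collapse = ", "))
  lon <- sort(unique(d$lon)); lat <- sort(unique(d$lat))
  months <- sort(unique(d$month[!is.na(d$month)]))
  fields <- list()
  for (v in setdiff(unique(d$variable), "bathymetry")) {
    arr <- array(NA_real_, c(length(lon), length(lat), length(months)))
    dv <- d[d$variable == v, ]
    arr[cbind(match(dv$lon, lon), match(dv$lat, lat),
              match(dv$month, months))] <- dv$value
    fields[[v]] <- arr
  }
  bathy <- matrix(NA_real_, length(lon), length(lat))
  db <- d[d$variable == "bathymetry", ]
  bathy[cbind(match(db$lon, lon), match(db$lat, lat))] <- db$value
  structure(list(lon = lon, lat = lat, months = months, fields = fields,
                 bathymetry = bathy), class = "climatology")
}

#' Write / read a basin mask as CSV
#'
#' Columns `lon, lat, basin` with `land` and `excluded` as reserved
#' labels.
#'
#' @param mask a `basin_mask`.
#' @param clim the matching `climatology` (for the coordinates).
#' @param path file path.
#' @return `read_mask` returns a `basin_mask` (with a `lon`/`lat`
#'   attribute).
#' @export
write_mask <- function(mask, clim, path) {
  labs <- basin_labels(mask)
  g <- expand.grid(lon = clim$lon, lat = clim$lat)
  v <- as.vector(unclass(mask))
  g$basin <- ifelse(is.na(v), "land", ifelse(v == 0, "excluded", labs[v]))
  write.csv(g, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  lon <- sort(unique(d$lon)); lat <- sort(unique(d$lat))
  labs <- setdiff(unique(d$basin), c("land", "excluded"))
  labs <- sort(labs)
  m <- matrix(NA_integer_, length(lon), length(lat))
  idx <- cbind(match(d$lon, lon), match(d$lat, lat))
  m[idx] <- ifelse(d$basin == "land", NA_integer_,
                   ifelse(d$basin == "excluded", 0L, match(d$basin, labs)))
  attr(m, "labels") <- labs
  class(m) <- c("basin_mask", class(m))
  m
}

#' Write a suitability surface as CSV
#' @param surface a `suitability_surface`.
#' @param clim the matching `climatology`.
#' @param path file path.
#' @export
write_surface <- function(surface, clim, path) {
  i <- (surface$cells - 1) %% surface$dim[1] + 1
  j <- (surface$cells - 1) %/% surface$dim[1] + 1
  write.csv(data.frame(lon = clim$lon[i], lat = clim$lat[j],
                       suitability = surface$values,
                       normalized = surface$norm),
            path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Validated bundle of all tunable pipeline parameters; round-trips
#' losslessly through YAML via [write_config()] / [read_config()].
#'
#' @param outdir output directory.
#' @param seed master seed; all stage seeds are spawned from it.
#' @param n_species,n_per_basin,n_basins,delta,n_jitter,grid_cells,resolution
#'   synthetic-scenario shape (grid_cells per side).
#' @param thin_cell_deg thinning cell (default 0.5).
#' @param buffer_deg basin boundary buffer (default 0.5).
#' @param ratio,cap background ratio and cap.
#' @param n_reps null replicates (default 100).
#' @param alpha test level.
#' @param pca_reps PCA permutation replicates (default 1000).
#' @param resampling_levels resampling sizes for the stability audit.
#' @param min_per_pair HGAM pair inclusion threshold (default 10).
#' @param n_folds,block_size_deg spatial CV layout.
#' @param stages stages to run, a subset of the default order.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("nichediverge"), seed = 1L,
                            n_species = 12, n_per_basin = 75, n_basins = 2,
                            delta = 0, n_jitter = 0.15, grid_cells = 30,
                            resolution = 3,
                            thin_cell_deg = 0.5, buffer_deg = 0.5,
                            ratio = 10, cap = 1000, n_reps = 100,
                            alpha = 0.05, pca_reps = 1000,
                            resampling_levels = c(25, 50, 100, 250, 500, 1000),
                            min_per_pair = 10, n_folds = 2,
                            block_size_deg = 15,
                            stages = c("simulate", "prep", "enm", "overlap",
                                       "pca", "robustness", "hgam")) {
  stopifnot(thin_cell_deg > 0, buffer_deg >= 0, ratio > 0, cap > 0,
            n_reps > 0, pca_reps > 0, min_per_pair > 0, grid_cells >= 4,
            resolution > 0)
  if (!(alpha > 0 && alpha < 0.5)) stop("alpha must lie in (0, 0.5)")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `read_config` returns the validated `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Serialize / restore a fitted ensemble as versioned JSON
#'
#' Stores the retained components' algorithms, coefficients, feature
#' specifications (standardization constants, spline knots), per-fold
#' skill, and the ensemble weights. `read_ensemble` reconstructs an
#' `ensemble_model` whose predictions equal the original's.
#'
#' @param ensemble an `ensemble_model`.
#' @param path file path.
#' @return `read_ensemble` returns an `ensemble_model`.
#' @export
write_ensemble <- function(ensemble, path) {
  comp <- lapply(ensemble$components, function(cm) {
    list(algorithm = cm$model$algorithm,
         coefficients = cm$model$coefficients,
         spec = cm$model$spec,
         tss = cm$tss, cbi = cm$cbi, retained = cm$retained,
         fold_tss = cm$fold_tss)
  })
  jsonlite::write_json(
    list(format_version = 1L,
         species = ensemble$species,
         variables = ensemble$variables,
         weights = as.list(ensemble$weights),
         components = comp),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$format_version) || j$format_version != 1L)
    stop("unsupported ensemble serialization version")
  fix_spec <- function(spec) {
    spec$vars <- unlist(spec$vars)
    for (f in c("center", "scale"))
      if (!is.null(spec[[f]])) spec[[f]] <- unlist(spec[[f]])
    if (!is.null(spec$bases))
      spec$bases <- lapply(spec$bases, function(b)
        if (is.null(b) || length(b) == 0) NULL
        else list(knots = unlist(b$knots), boundary = unlist(b$boundary)))
    spec
  }
  comps <- lapply(j$components, function(cm) {
    model <- structure(list(algorithm = cm$algorithm,
                            coefficients = unlist(cm$coefficients),
                            spec = fix_spec(cm$spec)),
                       class = "component_model")
    list(model = model, tss = cm$tss, cbi = cm$cbi,
         retained = isTRUE(cm$retained), fold_tss = unlist(cm$fold_tss))
  })
  structure(list(species = j$species, components = comps,
                 weights = unlist(j$weights), variables = unlist(j$variables),
                 config = NULL),
            class = "ensemble_model")
}

# stable content hash (hex) of an R object, for the run manifest
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  sprintf("%08x", as.integer(h))
}
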