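# Shared fixtures, built once per test run. The standard validation
# seascape is a 30 x 30 ocean grid at 3 degree resolution spanning 45S-45N,
# two longitude-strip basins with matched environmental distributions.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

test_spec <- function(seed = 5, n_basins = 2) {
  seascape_spec(lon_range = c(0, 90), lat_range = c(-45, 45),
                resolution = 3, n_basins = n_basins, seed = seed)
}

test_sea <- function() cached("sea", generate_environment(test_spec()))

test_vars <- c("temperature", "salinity", "nitrate", "mld", "chlorophyll",
               "wind_stress")

fast_config <- function(...) enm_config(n_reps = 30, ...)

# presence + background model frames for one synthetic species
species_frames <- function(sea, optimum, n, seed, breadth = 3,
                           basins = NULL) {
  tr <- niche_truth(c(temperature = optimum), c(temperature = breadth))
  occ <- sample_occurrences(tr, sea, n, basins = basins, species = "sp",
                            seed = seed)
  pres <- match_environment(occ, sea, test_vars)
  bg <- select_background(occ, nichediverge:::uniform_density(sea), sea,
                          basins = basins, seed = seed + 1)
  bgf <- match_environment(cbind(species = "bg", bg), sea, test_vars)
  list(occ = occ, pres = pres, bg = bgf, truth = tr)
}

# minimal hand-built seascape with a north/south basin split at the
# equator, for buffer-assignment tests
equator_sea <- function() {
  lon <- seq(-4.5, 4.5, by = 1)
  lat <- seq(-4.5, 4.5, by = 1)
  mask <- matrix(rep(ifelse(lat < 0, 1L, 2L), each = length(lon)),
                 length(lon), length(lat))
  attr(mask, "labels") <- c("S", "N")
  class(mask) <- c("basin_mask", class(mask))
  clim <- structure(list(
    lon = lon, lat = lat, months = 1:2,
    fields = list(temperature = array(15, c(length(lon), length(lat), 2))),
    bathymetry = matrix(1000, length(lon), length(lat))),
    class = "climatology")
  list(clim = clim, mask = mask)
}
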