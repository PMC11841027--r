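# Occurrence conditioning: spatial thinning, basin assignment with boundary
# buffers, species inclusion filters, climatology matching, and
# collinearity screening of the candidate predictors.

# half-open [lo, hi) cell index of points on a climatology grid; NA outside
grid_index <- function(clim, lon, lat) {
  res <- if (length(clim$lon) > 1) clim$lon[2] - clim$lon[1] else
    if (length(clim$lat) > 1) clim$lat[2] - clim$lat[1] else 1
  ox <- clim$lon[1] - res / 2; oy <- clim$lat[1] - res / 2
  i <- floor((normalize_lon(lon) - ox) / res) + 1
  j <- floor((lat - oy) / res) + 1
  i[i < 1 | i > length(clim$lon)] <- NA
  j[j < 1 | j > length(clim$lat)] <- NA
  list(i = as.integer(i), j = as.integer(j), res = res, ox = ox, oy = oy)
}

validate_occurrences <- function(occ) {
  need <- c("species", "lon", "lat", "month")
  miss <- setdiff(need, names(occ))
  if (length(miss)) stop("occurrence table lacks columns: ",
                         paste(miss, collapse = ", "))
  bad <- which(!(occ$lat >= -90 & occ$lat <= 90) |
                 !(occ$month %in% 1:12) | !is.finite(occ$lon))
  if (length(bad)) stop("invalid occurrence rows (lat/month/lon): row ",
                        paste(head(bad, 5), collapse = ", "))
  occ$lon <- normalize_lon(occ$lon)
  occ
}

#' Thin occurrences to one record per species, grid cell and month
#'
#' Collapses duplicates within `cell_deg` x `cell_deg` half-open cells,
#' keeping, within each (species, cell, month) group, the record with the
#' lexicographically smallest (latitude, longitude) — a deterministic,
#' order-insensitive retention rule, which also makes thinning idempotent.
#'
#' @param occ occurrence data.frame (`species, lon, lat, month`, ...).
#' @param cell_deg thinning cell size in degrees (default 0.5).
#' @return the thinned occurrence data.frame.
#' @export
thin_occurrences <- function(occ, cell_deg = 0.5) {
  occ <- validate_occurrences(occ)
  if (nrow(occ) == 0) return(occ)
  cx <- floor(occ$lon / cell_deg)
  cy <- floor(occ$lat / cell_deg)
  key <- paste(occ$species, cx, cy, occ$month, sep = "\r")
  ord <- order(key, occ$lat, occ$lon)
  occ <- occ[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign ocean-basin labels with a boundary buffer
#'
#' Each record gets the basin label of its grid cell. A record is flagged
#' `"buffered"` (and excluded downstream) if any grid cell within Chebyshev
#' distance `buffer_deg` of the point carries a *different* basin label — a
#' grid-native proxy for polygon buffering of shifting basin boundaries.
#' Records on land or on excluded (marginal-sea) cells are flagged
#' `"excluded"`.
#'
#' @param occ occurrence data.frame.
#' @param seascape a `seascape` (climatology grid + basin mask).
#' @param buffer_deg buffer width in degrees (default 0.5).
#' @return `occ` with `basin` and `status` columns (`"ok"`, `"buffered"`,
#'   `"excluded"`).
#' @export
assign_basins <- function(occ, seascape, buffer_deg = 0.5) {
  occ <- validate_occurrences(occ)
  clim <- seascape$clim; mask <- seascape$mask
  gi <- grid_index(clim, occ$lon, occ$lat)
  if (anyNA(gi$i) || anyNA(gi$j))
    stop("basin mask does not cover all occurrence records")
  labs <- basin_labels(mask)
  res <- gi$res
  reach <- ceiling(buffer_deg / res)
  n <- nrow(occ)
  basin <- rep(NA_character_, n)
  status <- rep("ok", n)
  for (r in seq_len(n)) {
    i <- gi$i[r]; j <- gi$j[r]
    own <- mask[i, j]
    if (is.na(own) || own == 0) { status[r] <- "excluded"; next }
    basin[r] <- labs[own]
    x <- occ$lon[r]; y <- occ$lat[r]
    for (di in -reach:reach) {
      ii <- i + di
      if (ii < 1 || ii > nrow(mask)) next
      for (dj in -reach:reach) {
        jj <- j + dj
        if (jj < 1 || jj > ncol(mask) || (di == 0 && dj == 0)) next
        lab <- mask[ii, jj]
        if (is.na(lab) || lab == 0 || lab == own) next
        lo_x <- gi$ox + (ii - 1) * res; hi_x <- lo_x + res
        lo_y <- gi$oy + (jj - 1) * res; hi_y <- lo_y + res
        dx <- max(0, lo_x - x, x - hi_x)
        dy <- max(0, lo_y - y, y - hi_y)
        if (max(dx, dy) <= buffer_deg) { status[r] <- "buffered"; break }
      }
      if (status[r] == "buffered") break
    }
  }
  occ$basin <- basin
  occ$status <- status
  occ
}

#' Filter species by per-basin and total observation counts
#'
#' Retains species with at least `min_per_basin` records in each of at least
#' `min_basins` basins and at least `min_total` records overall. Buffered and
#' excluded records do not count. Idempotent.
#'
#' @param occ occurrence data.frame with `basin` and `status` columns.
#' @param min_per_basin minimum records per qualifying basin (default 50).
#' @param min_basins minimum number of qualifying basins (default 2).
#' @param min_total minimum total records (default 100).
#' @return list with `occurrences` (records of retained species, status
#'   `"ok"` only) and `report` (per-species per-basin counts and the
#'   retention decision).
#' @export
filter_species <- function(occ, min_per_basin = 50, min_basins = 2,
                           min_total = 100) {
  if (is.null(occ$basin) || is.null(occ$status))
    stop("basins must be assigned before filtering (run assign_basins)")
  ok <- occ[occ$status == "ok" & !is.na(occ$basin), , drop = FALSE]
  if (nrow(ok) == 0) {
    return(list(occurrences = ok,
                report = data.frame(species = character(), basin = character(),
                                    n = integer(), retained = logical())))
  }
  counts <- aggregate(list(n = rep(1L, nrow(ok))),
                      by = list(species = ok$species, basin = ok$basin), sum)
  keep_sp <- vapply(split(counts, counts$species), function(d) {
    sum(d$n >= min_per_basin) >= min_basins && sum(d$n) >= min_total
  }, TRUE)
  counts$retained <- keep_sp[counts$species]
  out <- ok[ok$species %in% names(keep_sp)[keep_sp], , drop = FALSE]
  rownames(out) <- NULL
  list(occurrences = out, report = counts[order(counts$species, counts$basin), ])
}

#' Screen predictors for multicollinearity (Spearman r and VIF)
#'
#' Computes the pairwise Spearman correlation matrix and rank-based variance
#' inflation factors, then iteratively removes variables until every
#' remaining pair has `|r| < r_thresh` and every VIF is below `vif_thresh`.
#' When a VIF violation exists, the variable with the highest VIF is removed;
#' a remaining correlation-only violation removes, from the worst pair, the
#' member with the larger mean `|r|` to all other variables. VIFs are
#' computed on the rank-transformed data (the scale of the Spearman screen)
#' by explicit regression of each variable on the rest.
#'
#' @param env numeric matrix or data.frame of candidate predictors at the
#'   occurrence (+ background) cells; >= 2 columns, >= 10 rows, no constant
#'   columns.
#' @param r_thresh Spearman correlation threshold (default 0.75).
#' @param vif_thresh VIF threshold (default 5).
#' @return class `screening_report`: `spearman` (initial full matrix),
#'   `vif` (final VIFs of retained variables), `removed` (data.frame of
#'   removals with reasons), `retained` (character vector).
#' @export
screen_collinearity <- function(env, r_thresh = 0.75, vif_thresh = 5) {
  env <- as.matrix(as.data.frame(env))
  if (ncol(env) < 2) stop("need at least two variables to screen")
  if (nrow(env) < 10) stop("need at least 10 rows to screen")
  if (!all(is.finite(env))) stop("non-finite values in predictor matrix")
  cst <- apply(env, 2, function(x) var(x) == 0)
  if (any(cst)) stop("constant column(s): ",
                     paste(colnames(env)[cst], collapse = ", "))
  rk <- apply(env, 2, rank)
  spearman_full <- cor(rk)
  vif_of <- function(m) {
    vapply(seq_len(ncol(m)), function(j) {
      fit <- stats::lm.fit(cbind(1, m[, -j, drop = FALSE]), m[, j])
      rss <- sum(fit$residuals^2)
      tss <- sum((m[, j] - mean(m[, j]))^2)
      r2 <- 1 - rss / tss
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, 0)
  }
  retained <- colnames(env)
  removed <- data.frame(variable = character(), reason = character(),
                        vif = numeric(), max_abs_r = numeric(),
                        stringsAsFactors = FALSE)
  while (length(retained) >= 2) {
    m <- rk[, retained, drop = FALSE]
    R <- cor(m)
    vifs <- setNames(vif_of(m), retained)
    off <- abs(R); diag(off) <- 0
    viol_r <- max(off) >= r_thresh
    viol_v <- max(vifs) >= vif_thresh
    if (!viol_r && !viol_v) break
    if (viol_v) {
      drop_var <- names(which.max(vifs))
      reason <- sprintf("VIF %.2f >= %.2f", vifs[drop_var], vif_thresh)
    } else {
      worst <- which(off == max(off), arr.ind = TRUE)[1, ]
      pair <- retained[worst]
      mean_r <- rowMeans(off)[pair]
      drop_var <- pair[which.max(mean_r)]
      reason <- sprintf("|r| %.2f >= %.2f with %s", max(off), r_thresh,
                        setdiff(pair, drop_var))
    }
    removed <- rbind(removed, data.frame(
      variable = drop_var, reason = reason,
      vif = unname(vifs[drop_var]),
      max_abs_r = max(off[drop_var, ]), stringsAsFactors = FALSE))
    retained <- setdiff(retained, drop_var)
  }
  m <- rk[, retained, drop = FALSE]
  final_vif <- if (length(retained) >= 2) setNames(vif_of(m), retained)
               else setNames(rep(1, length(retained)), retained)
  structure(list(spearman = spearman_full, vif = final_vif,
                 removed = removed, retained = retained),
            class = "screening_report")
}

#' Attach environmental covariates to occurrence records
#'
#' Joins each record to its grid cell's monthly climatology values; the
#' static bathymetry is joined month-independently. Records falling outside
#' the grid or on cells with missing values are dropped with a counted
#' warning.
#'
#' @param occ occurrence data.frame.
#' @param seascape a `seascape`.
#' @param variables variables to extract (default: all fields plus
#'   bathymetry).
#' @return a model frame: `occ`'s columns plus one column per variable.
#' @export
match_environment <- function(occ, seascape,
                              variables = c(names(seascape$clim$fields),
                                            "bathymetry")) {
  occ <- validate_occurrences(occ)
  clim <- seascape$clim
  gi <- grid_index(clim, occ$lon, occ$lat)
  nlon <- length(clim$lon); nlat <- length(clim$lat)
  cell <- gi$i + (gi$j - 1L) * nlon
  ok <- !is.na(gi$i) & !is.na(gi$j) & occ$month %in% clim$months
  vals <- matrix(NA_real_, nrow(occ), length(variables),
                 dimnames = list(NULL, variables))
  for (v in variables) {
    if (identical(v, "bathymetry")) {
      vals[ok, v] <- clim$bathymetry[cell[ok]]
    } else {
      arr <- clim$fields[[v]]
      if (is.null(arr)) stop("variable absent from climatology: ", v)
      vals[ok, v] <- arr[cell[ok] + (match(occ$month[ok], clim$months) - 1L) *
                           nlon * nlat]
    }
  }
  ok <- ok & apply(vals, 1, function(r) all(is.finite(r)))
  if (any(!ok))
    warning(sum(!ok), " record(s) dropped: outside grid or missing climatology")
  cbind(occ[ok, , drop = FALSE], as.data.frame(vals[ok, , drop = FALSE]))
}
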