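# Between-basin niche overlap: Schoener's D on a common support, the
# background-similarity permutation null (100 replicate refits per
# direction), and the diverged / conserved / neutral classification.

#' Schoener's D between two normalized suitability surfaces
#'
#' `D = 1 - 0.5 * sum_cells |p1 - p2|` over the shared cell set: 0 for
#' disjoint distributions, 1 for identical ones; symmetric, and `1 - D` is
#' half the L1 distance between the two distributions.
#'
#' @param s1,s2 `suitability_surface` objects on the same cells, or bare
#'   numeric vectors already summing to 1.
#' @return D in `[0, 1]`.
#' @export
schoeners_d <- function(s1, s2) {
  p1 <- if (inherits(s1, "suitability_surface")) s1$norm else s1
  p2 <- if (inherits(s2, "suitability_surface")) s2$norm else s2
  if (inherits(s1, "suitability_surface") &&
      inherits(s2, "suitability_surface") &&
      !identical(s1$cells, s2$cells))
    stop("surfaces are defined on different cell sets")
  if (length(p1) != length(p2)) stop("surfaces differ in length")
  1 - 0.5 * sum(abs(p1 - p2))
}

#' Restrict a surface to a cell subset and renormalize
#'
#' Restricts a projected surface to the comparison support (typically the
#' union of the two basins' ocean cells) and renormalizes it to sum to 1
#' there, so both populations' surfaces live on a common measure space.
#'
#' @param surface a `suitability_surface`.
#' @param cells grid linear indices of the support.
#' @return a `suitability_surface` on `cells`.
#' @export
restrict_and_normalize <- function(surface, cells) {
  idx <- match(cells, surface$cells)
  if (anyNA(idx)) stop("support cells missing from the surface")
  vals <- surface$values[idx]
  if (sum(vals) <= 0) stop("all-zero suitability on the requested support")
  new_surface(cells, vals, surface$dim)
}

# weighted draw of slot rows; excl = slot ids to exclude
draw_slots <- function(slots, density, n, ncell, exclude_ids = NULL,
                       what = "slots") {
  w <- density[slots$cell]
  w[!is.finite(w) | w < 0] <- 0
  if (!is.null(exclude_ids))
    w[slot_id(slots$cell, slots$month, ncell) %in% exclude_ids] <- 0
  if (sum(w > 0) < n)
    stop(sprintf("%s shortfall: %d positive-weight slots, %d required",
                 what, sum(w > 0), n))
  sample.int(length(w), n, prob = w)
}

# weighted draw of context rows restricted to one basin
draw_ctx_rows <- function(ctx, basin, density, n, exclude_ids = NULL,
                          what = "slots") {
  w <- density[ctx$slots$cell]
  w[ctx$basin != basin] <- 0
  w[!is.finite(w) | w < 0] <- 0
  if (!is.null(exclude_ids))
    w[slot_id(ctx$slots$cell, ctx$slots$month, ctx$ncell_grid) %in%
        exclude_ids] <- 0
  if (sum(w > 0) < n)
    stop(sprintf("%s shortfall in basin %s: %d positive-weight slots, %d required",
                 what, basin, sum(w > 0), n))
  # exponential-key weighted sampling without replacement (equivalent in
  # law to successive weighted draws, but vectorized)
  keys <- rep(Inf, length(w))
  pos <- w > 0
  keys[pos] <- stats::rexp(sum(pos)) / w[pos]
  order(keys)[seq_len(n)]
}

# map occurrence records to rows of a pair context's slot table
ctx_pres_rows <- function(ctx, occ, clim) {
  gi <- grid_index(clim, occ$lon, occ$lat)
  ids <- slot_id(gi$i + (gi$j - 1L) * ctx$dim[1], occ$month, ctx$ncell_grid)
  idx <- match(ids, slot_id(ctx$slots$cell, ctx$slots$month, ctx$ncell_grid))
  if (anyNA(idx)) stop("presence record off the comparison support")
  idx
}

# uniform-over-ocean fallback density
uniform_density <- function(seascape) {
  d <- matrix(NA_real_, length(seascape$clim$lon), length(seascape$clim$lat))
  oc <- ocean_cells(seascape$mask)
  d[oc] <- 1 / length(oc)
  d
}

#' Background-similarity null distribution for one direction
#'
#' Each replicate draws `n_pres` pseudo-presences from the receiving
#' basin's targeted-group background density, fits the identical ensemble
#' configuration on them (with its own 10:1 background, drawn from the same
#' density), projects onto the comparison support, and computes Schoener's
#' D against the reference surface. Replicate components are weighted by
#' `max(TSS, 0)` without the retention gate: pseudo-presences carry no
#' niche signal by construction, so gating would leave the null undefined.
#' A replicate that fails numerically is redrawn (at most 3 extra
#' attempts, then flagged). Percentile bounds use the nearest-rank method.
#'
#' @param surface_ref normalized reference surface (the observed model of
#'   the *other* basin) on the comparison support.
#' @param n_pres number of pseudo-presences per replicate (the observed
#'   presence count of the reference basin).
#' @param seascape a `seascape`.
#' @param basin_from basin label supplying pseudo-presences and background.
#' @param density targeted-group density grid ([occurrence_density()]);
#'   default uniform over ocean.
#' @param variables model covariates.
#' @param config an [enm_config()] (`n_reps`, `alpha` are used here).
#' @param seed integer seed.
#' @param ctx optional precomputed pair context (speed path; internal).
#' @return class `null_distribution`: `direction`, replicate `values`,
#'   nearest-rank `lower`/`upper` bounds at level `alpha`, `n_failed`,
#'   `flagged`.
#' @export
background_similarity_test <- function(surface_ref, n_pres, seascape,
                                       basin_from, density = NULL, variables,
                                       config = enm_config(), seed = NULL,
                                       ctx = NULL) {
  if (is.null(ctx)) ctx <- pair_context(seascape, variables, NULL, config)
  if (is.null(density)) density <- uniform_density(seascape)
  n_bg <- min(config$ratio * n_pres, config$cap)
  vals <- rep(NA_real_, config$n_reps)
  n_failed <- 0L
  with_seed(seed, {
    for (r in seq_len(config$n_reps)) {
      ens <- NULL
      for (attempt in 1:4) {
        pr <- draw_ctx_rows(ctx, basin_from, density, n_pres,
                            what = "pseudo-presence")
        pr_ids <- slot_id(ctx$slots$cell[pr], ctx$slots$month[pr],
                          ctx$ncell_grid)
        bgr <- draw_ctx_rows(ctx, basin_from, density, n_bg,
                             exclude_ids = pr_ids, what = "background")
        ens <- tryCatch(
          fit_ensemble_ctx(pr, bgr, ctx, config, gate = FALSE),
          error = function(e) NULL)
        if (!is.null(ens)) break
        n_failed <- n_failed + 1L
      }
      if (is.null(ens)) next
      surf <- restrict_and_normalize(project_ctx(ens, ctx),
                                     surface_ref$cells)
      vals[r] <- schoeners_d(surface_ref, surf)
    }
  })
  ok <- vals[is.finite(vals)]
  if (length(ok) == 0) stop("all null replicates failed in basin ", basin_from)
  structure(list(direction = basin_from, values = vals,
                 lower = nearest_rank(ok, config$alpha / 2),
                 upper = nearest_rank(ok, 1 - config$alpha / 2),
                 alpha = config$alpha, n_failed = n_failed,
                 flagged = anyNA(vals)),
            class = "null_distribution")
}

#' Classify a pairwise comparison against its two directional nulls
#'
#' Per direction: diverged if observed D is strictly below the lower bound,
#' conserved if strictly above the upper bound, neutral otherwise (ties
#' resolve inward, conservatively). Pair level: diverged if at least one
#' direction diverged and none conserved; conserved symmetrically; both
#' neutral is "fully neutral"; a diverged/conserved conflict is neutral
#' with a flag. `binary_diverged` is 1 iff the pair-level class is
#' diverged.
#'
#' @param d_obs observed Schoener's D.
#' @param null_ab,null_ba `null_distribution` objects for the two
#'   directions (`null_ba` may be `NULL` in single-direction mode).
#' @return class `divergence_call`: per-direction verdicts, pair-level
#'   `class`, `binary_diverged`, `conflict` flag.
#' @export
classify_divergence <- function(d_obs, null_ab, null_ba = NULL) {
  verdict <- function(nd) {
    if (is.null(nd)) return(NULL)
    if (d_obs < nd$lower) "diverged"
    else if (d_obs > nd$upper) "conserved"
    else "neutral"
  }
  v <- c(verdict(null_ab), verdict(null_ba))
  conflict <- all(c("diverged", "conserved") %in% v)
  cls <- if (conflict) "neutral"
  else if ("diverged" %in% v) "diverged"
  else if ("conserved" %in% v) "conserved"
  else "neutral"
  structure(list(directions = v, class = cls,
                 binary_diverged = as.integer(cls == "diverged"),
                 conflict = conflict),
            class = "divergence_call")
}

#' Full pairwise niche-overlap comparison for one species
#'
#' Fits one ensemble per basin on that basin's presences (with
#' targeted-group background), projects both onto the union of the two
#' basins' cells, computes observed Schoener's D, runs the
#' background-similarity null in both directions (or one, per the config),
#' and classifies the pair.
#'
#' @param occ occurrence records of one species with `basin`/`status`
#'   columns (only `status == "ok"` rows are used).
#' @param seascape a `seascape`.
#' @param basin_a,basin_b basin labels to compare.
#' @param density targeted-group density grid; default uniform over ocean.
#' @param variables model covariates.
#' @param config an [enm_config()].
#' @param seed integer seed.
#' @param min_n minimum presences per basin (default 50).
#' @return class `paired_comparison`: species, pair label (`"A-B"`),
#'   per-basin counts, observed `d`, the two `null_distribution`s, the
#'   `divergence_call`, and the two surfaces.
#' @export
compare_basin_pair <- function(occ, seascape, basin_a, basin_b,
                               density = NULL, variables,
                               config = enm_config(), seed = 1L,
                               min_n = 50) {
  if (basin_a == basin_b) stop("the two basins must differ")
  if (!is.null(occ$status)) occ <- occ[occ$status == "ok", , drop = FALSE]
  species <- unique(occ$species)
  if (length(species) != 1) stop("expected records of exactly one species")
  if (is.null(density)) density <- uniform_density(seascape)
  ctx <- pair_context(seascape, variables, c(basin_a, basin_b), config)
  occ_a <- occ[occ$basin == basin_a, , drop = FALSE]
  occ_b <- occ[occ$basin == basin_b, , drop = FALSE]
  if (nrow(occ_a) < min_n || nrow(occ_b) < min_n)
    stop(sprintf("fewer than %d presences in a basin (%d / %d)",
                 min_n, nrow(occ_a), nrow(occ_b)))

  fit_side <- function(occ_side, basin) {
    rows <- ctx_pres_rows(ctx, occ_side, seascape$clim)
    ids <- slot_id(ctx$slots$cell[rows], ctx$slots$month[rows],
                   ctx$ncell_grid)
    n_bg <- min(config$ratio * length(rows), config$cap)
    bgr <- with_seed(spawn_seed(seed, species, basin, "bg"),
                     draw_ctx_rows(ctx, basin, density, n_bg,
                                   exclude_ids = ids, what = "background"))
    ens <- fit_ensemble_ctx(rows, bgr, ctx, config,
                            seed = spawn_seed(seed, species, basin, "cv"),
                            species = species)
    if (is.null(ens))
      stop("no retained component for ", species, " in basin ", basin)
    restrict_and_normalize(project_ctx(ens, ctx), ctx$slots$cells)
  }
  surf_a <- fit_side(occ_a, basin_a)
  surf_b <- fit_side(occ_b, basin_b)
  d_obs <- schoeners_d(surf_a, surf_b)

  null_ab <- background_similarity_test(
    surf_a, nrow(occ_a), seascape, basin_b, density, variables, config,
    seed = spawn_seed(seed, species, "null", basin_a, basin_b), ctx = ctx)
  null_ba <- NULL
  if (identical(config$directions, "both"))
    null_ba <- background_similarity_test(
      surf_b, nrow(occ_b), seascape, basin_a, density, variables, config,
      seed = spawn_seed(seed, species, "null", basin_b, basin_a), ctx = ctx)
  call <- classify_divergence(d_obs, null_ab, null_ba)
  structure(list(species = species,
                 pair = paste(basin_a, basin_b, sep = "-"),
                 n_a = nrow(occ_a), n_b = nrow(occ_b), d = d_obs,
                 null_ab = null_ab, null_ba = null_ba, call = call,
                 surface_a = surf_a, surface_b = surf_b),
            class = "paired_comparison")
}
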