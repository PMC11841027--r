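# Drivers of divergence: hierarchical binomial GAM of the binary
# divergence call on species' mean niche values — global thin-plate
# smooths of bathymetry and temperature, per-pair temperature smooths with
# a shared first-order penalty (group-level deviations from the global
# trend), and a pair random intercept.

hgam_blocks <- function(fit) {
  st <- summary(fit)$s.table
  rn <- rownames(st)
  list(bathymetry = rn[rn == "s(bathymetry)"],
       temperature = rn[rn == "s(temperature)"],
       temperature_by_pair = rn[grepl("^s\\(temperature\\):pair", rn)],
       pair = rn[rn == "s(pair)"])
}

#' Assemble the comparison table for the drivers model
#'
#' Joins the binary divergence calls to the species' suitability-weighted
#' mean niche values and drops basin pairs with fewer than `min_per_pair`
#' comparisons (small groups bias both fixed and random effects).
#'
#' @param calls data.frame with `species`, `pair`, `binary_diverged`.
#' @param niche_values data.frame with `species`, `temperature`,
#'   `bathymetry` (mean niche values).
#' @param min_per_pair minimum comparisons per pair (default 10).
#' @return data.frame (`species`, `pair`, `diverged`, `temperature`,
#'   `bathymetry`) with attributes `dropped_pairs` and `dropped_species`.
#' @export
assemble_table <- function(calls, niche_values, min_per_pair = 10) {
  stopifnot(all(c("species", "pair", "binary_diverged") %in% names(calls)),
            all(c("species", "temperature", "bathymetry") %in%
                  names(niche_values)))
  m <- merge(calls, niche_values, by = "species")
  dropped_species <- setdiff(calls$species, niche_values$species)
  m <- m[complete.cases(m[, c("binary_diverged", "temperature",
                              "bathymetry")]), ]
  cnt <- table(m$pair)
  dropped_pairs <- names(cnt)[cnt < min_per_pair]
  m <- m[!(m$pair %in% dropped_pairs), , drop = FALSE]
  out <- data.frame(species = m$species, pair = m$pair,
                    diverged = as.integer(m$binary_diverged),
                    temperature = m$temperature, bathymetry = m$bathymetry,
                    stringsAsFactors = FALSE)
  attr(out, "dropped_pairs") <- dropped_pairs
  attr(out, "dropped_species") <- dropped_species
  out
}

#' Fit the hierarchical GAM of divergence drivers
#'
#' Penalized-likelihood binomial fit of
#' `diverged ~ s(bathymetry, k = 4) + s(temperature, k = 4, m = 2) +
#' s(temperature, by = pair, k = 4, m = 1, shared penalty) +
#' s(pair, bs = "re")`, with smoothing parameters chosen by REML and
#' shrinkage (`select = TRUE`) so smooths can vanish. Whole term blocks
#' whose approximate p-value is >= `p_drop` after shrinkage (for the
#' factor-smooth block: all of its per-pair terms) are removed and the
#' model refitted once.
#'
#' @param table comparison table from [assemble_table()] (or
#'   [generate_hgam_table()]).
#' @param p_drop drop threshold for insignificant smoothers (default 0.05).
#' @return class `hgam_fit`: `model` (the mgcv fit), `terms` (summary
#'   table), `dropped` (removed blocks), `deviance_explained`, `r2_adj`,
#'   `n`.
#' @export
fit_hgam <- function(table, p_drop = 0.05) {
  stopifnot(all(c("pair", "diverged", "temperature", "bathymetry") %in%
                  names(table)))
  table$pair <- factor(table$pair)
  if (nlevels(table$pair) < 2) stop("need at least 2 retained pairs")
  if (length(unique(table$diverged)) < 2)
    stop("single-class outcome: model undefined")
  blocks <- c(
    bathymetry = "s(bathymetry, bs = \"tp\", k = 4)",
    temperature = "s(temperature, bs = \"tp\", k = 4, m = 2)",
    temperature_by_pair =
      "s(temperature, by = pair, bs = \"tp\", k = 4, m = 1, id = 1)",
    pair = "s(pair, bs = \"re\")")
  fit_with <- function(keep) {
    form <- stats::as.formula(paste("diverged ~",
                                    paste(blocks[keep], collapse = " + ")))
    mgcv::gam(form, family = binomial(), data = table, method = "REML",
              select = TRUE)
  }
  keep <- names(blocks)
  fit <- fit_with(keep)
  st <- summary(fit)$s.table
  bl <- hgam_blocks(fit)
  block_p <- vapply(keep, function(b) {
    rows <- bl[[b]]
    if (length(rows) == 0) return(NA_real_)
    min(st[rows, "p-value"])
  }, 0)
  dropped <- keep[is.finite(block_p) & block_p >= p_drop]
  if (length(dropped) > 0 && length(dropped) < length(keep)) {
    keep <- setdiff(keep, dropped)
    fit <- fit_with(keep)
  } else dropped <- character(0)
  sm <- summary(fit)
  structure(list(model = fit, terms = sm$s.table, dropped = dropped,
                 retained = keep,
                 deviance_explained = deviance_explained(fit),
                 r2_adj = sm$r.sq, n = nrow(table), data = table),
            class = "hgam_fit")
}

#' Fraction of deviance explained
#' @param fit an `hgam_fit` or an mgcv `gam` fit.
#' @return `1 - residual deviance / null deviance`, in `[0, 1]`.
#' @export
deviance_explained <- function(fit) {
  m <- if (inherits(fit, "hgam_fit")) fit$model else fit
  if (m$null.deviance <= 0) stop("null deviance is zero")
  1 - m$deviance / m$null.deviance
}

#' Centred partial effect of one model term
#'
#' Evaluates a term's contribution to the linear predictor (logit scale)
#' over an even grid of its covariate, with pointwise standard errors.
#' Values above 0 mark niche values at which populations are more likely
#' to be classified as diverged.
#'
#' @param fit an `hgam_fit`.
#' @param term `"bathymetry"`, `"temperature"`, `"temperature_by_pair"`,
#'   or `"pair"` (the random intercept).
#' @param grid_size grid points over the observed covariate range
#'   (default 100).
#' @return class `partial_effect`: data.frame with the covariate grid (and
#'   `pair` for per-pair terms), `effect`, `se`.
#' @export
partial_effects <- function(fit, term, grid_size = 100) {
  stopifnot(inherits(fit, "hgam_fit"))
  if (term %in% fit$dropped)
    stop("term was removed during model selection: ", term)
  if (!term %in% fit$retained) stop("unknown or unfitted term: ", term)
  tab <- fit$data
  tab$pair <- factor(tab$pair)
  med <- vapply(tab[, c("temperature", "bathymetry")], median, 0)
  bl <- hgam_blocks(fit$model)
  grid_for <- function(v) seq(min(tab[[v]]), max(tab[[v]]),
                              length.out = grid_size)
  if (term %in% c("bathymetry", "temperature")) {
    nd <- data.frame(temperature = med[["temperature"]],
                     bathymetry = med[["bathymetry"]],
                     pair = levels(tab$pair)[1])
    nd <- nd[rep(1, grid_size), ]
    rownames(nd) <- NULL
    nd[[term]] <- grid_for(term)
    pr <- predict(fit$model, nd, type = "terms", terms = bl[[term]],
                  se.fit = TRUE)
    out <- data.frame(value = nd[[term]], effect = unname(drop(pr$fit)),
                      se = unname(drop(pr$se.fit)))
  } else if (term == "temperature_by_pair") {
    g <- grid_for("temperature")
    nd <- expand.grid(temperature = g, pair = levels(tab$pair))
    nd$bathymetry <- med[["bathymetry"]]
    pr <- predict(fit$model, nd, type = "terms", terms = bl[[term]],
                  se.fit = TRUE)
    # each row's own pair column of the per-level terms
    col <- match(paste0("s(temperature):pair", nd$pair), colnames(pr$fit))
    pick <- cbind(seq_len(nrow(nd)), col)
    out <- data.frame(value = nd$temperature, pair = nd$pair,
                      effect = pr$fit[pick], se = pr$se.fit[pick])
  } else {  # pair random intercept
    nd <- data.frame(temperature = med[["temperature"]],
                     bathymetry = med[["bathymetry"]],
                     pair = levels(tab$pair))
    pr <- predict(fit$model, nd, type = "terms", terms = bl[[term]],
                  se.fit = TRUE)
    out <- data.frame(pair = nd$pair, effect = unname(drop(pr$fit)),
                      se = unname(drop(pr$se.fit)))
  }
  rownames(out) <- NULL
  structure(out, class = c("partial_effect", class(out)), term = term)
}
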