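# End-to-end orchestration: simulate -> prep -> enm -> overlap -> pca ->
# robustness -> hgam, with per-stage seeding spawned from one master seed,
# per-stage attrition logging, CSV/JSON artifacts and a run manifest.

log_stage <- function(...) message("[nichediverge] ", sprintf(...))

#' Run the full niche-divergence pipeline on a synthetic scenario
#'
#' Executes the configured stages in order: generate the synthetic
#' seascape and occurrences; thin, buffer-assign basins, filter species and
#' screen predictors; fit each species' global ensemble and extract mean
#' niche values; run the pairwise overlap test with background-similarity
#' nulls for every basin pair with enough presences; validate diverged
#' calls with the PCA permutation test; audit observation-imbalance
#' effects; and fit the drivers HGAM when at least two pairs remain. All
#' randomness derives from the master seed, so two runs with the same
#' config produce identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  manifest <- list(config_hash = config_hash(unclass(config)),
                   seed = config$seed, stages = list(),
                   version = as.character(utils::packageVersion("nichediverge")))
  out <- list(config = config)
  run <- function(s) s %in% config$stages
  econf <- enm_config(n_folds = config$n_folds,
                      block_size_deg = config$block_size_deg,
                      ratio = config$ratio, cap = config$cap,
                      n_reps = config$n_reps, alpha = config$alpha)

  # --- simulate ---------------------------------------------------------
  ext <- config$grid_cells * config$resolution
  spec <- seascape_spec(lon_range = c(0, ext), lat_range = c(-ext / 2, ext / 2),
                        resolution = config$resolution,
                        n_basins = config$n_basins,
                        seed = spawn_seed(config$seed, "seascape"))
  scen <- make_scenario(spec, n_species = config$n_species,
                        n_per_basin = config$n_per_basin,
                        delta = config$delta, n_jitter = config$n_jitter,
                        seed = spawn_seed(config$seed, "scenario"))
  if (run("simulate")) {
    log_stage("simulate: %d species, %d occurrence records",
              config$n_species, nrow(scen$occurrences))
    write_occurrences(scen$occurrences, file.path(config$outdir, "occurrences.csv"))
    write_climatology(scen$clim, file.path(config$outdir, "climatology.csv"))
    write_mask(scen$mask, scen$clim, file.path(config$outdir, "mask.csv"))
    manifest$stages$simulate <- list(n_records = nrow(scen$occurrences))
  }
  out$scenario <- scen

  # --- prep -------------------------------------------------------------
  occ <- thin_occurrences(scen$occurrences, config$thin_cell_deg)
  occ <- assign_basins(occ, scen, config$buffer_deg)
  filt <- filter_species(occ)
  occ <- filt$occurrences
  vars <- c(names(scen$clim$fields), "bathymetry")
  frame_all <- match_environment(occ, scen, vars)
  density <- occurrence_density(occ, scen)
  bg_all <- select_background(occ, density, scen, ratio = 1,
                              cap = config$cap,
                              seed = spawn_seed(config$seed, "screen-bg"))
  bg_frame_all <- match_environment(cbind(species = "background", bg_all),
                                    scen, vars)
  screening <- screen_collinearity(rbind(frame_all[, vars],
                                         bg_frame_all[, vars]))
  vars <- screening$retained
  if (run("prep")) {
    log_stage("prep: %d -> %d records, %d species retained, variables: %s",
              nrow(scen$occurrences), nrow(occ),
              length(unique(occ$species)), paste(vars, collapse = ", "))
    write_occurrences(occ, file.path(config$outdir, "occurrences_prepped.csv"))
    write.csv(filt$report, file.path(config$outdir, "species_inclusion.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(retained = screening$retained,
           removed = screening$removed,
           spearman = as.data.frame(screening$spearman)),
      file.path(config$outdir, "screening.json"), auto_unbox = TRUE,
      digits = NA)
    manifest$stages$prep <- list(n_records = nrow(occ),
                                 n_species = length(unique(occ$species)),
                                 variables = vars)
  }
  out$screening <- screening

  species <- sort(unique(occ$species))
  labs <- basin_labels(scen$mask)

  # --- enm: global ensembles and mean niche values ----------------------
  niche_vals <- NULL; skill <- NULL
  if (run("enm") || run("hgam")) {
    rows <- list(); sk <- list()
    for (sp in species) {
      o <- occ[occ$species == sp, , drop = FALSE]
      pres <- match_environment(o, scen, vars)
      bg <- select_background(o, density, scen, ratio = config$ratio,
                              cap = config$cap,
                              seed = spawn_seed(config$seed, "bg", sp))
      bgf <- match_environment(cbind(species = "bg", bg), scen, vars)
      ens <- fit_species_enm(pres, bgf, vars, econf,
                             seed = spawn_seed(config$seed, "enm", sp),
                             species = sp)
      if (is.null(ens)) { log_stage("enm: %s excluded (no retained component)", sp); next }
      for (a in names(ens$components)) {
        cm <- ens$components[[a]]
        sk[[length(sk) + 1]] <- data.frame(species = sp, algorithm = a,
                                           tss = cm$tss, cbi = cm$cbi,
                                           retained = cm$retained)
      }
      surf <- project_ensemble(ens, scen)
      mnv <- mean_niche_values(surf, scen, vars)
      rows[[length(rows) + 1]] <-
        cbind(data.frame(species = sp), as.data.frame(as.list(mnv)))
    }
    niche_vals <- do.call(rbind, rows)
    skill <- do.call(rbind, sk)
    if (run("enm")) {
      log_stage("enm: %d/%d species modelled", nrow(niche_vals), length(species))
      write.csv(skill, file.path(config$outdir, "skill.csv"), row.names = FALSE)
      write.csv(niche_vals, file.path(config$outdir, "mean_niche_values.csv"),
                row.names = FALSE)
      manifest$stages$enm <- list(n_modelled = nrow(niche_vals))
    }
  }
  out$niche_values <- niche_vals; out$skill <- skill

  # --- overlap + pca ----------------------------------------------------
  comparisons <- list(); comp_rows <- list(); pca_rows <- list()
  if (run("overlap")) {
    for (sp in species) {
      o <- occ[occ$species == sp, , drop = FALSE]
      cnt <- table(o$basin)
      eligible <- names(cnt)[cnt >= 50]
      if (length(eligible) < 2) next
      pairs <- utils::combn(sort(match(eligible, labs)), 2)
      for (pc in seq_len(ncol(pairs))) {
        ba <- labs[pairs[1, pc]]; bb <- labs[pairs[2, pc]]
        cmp <- tryCatch(
          compare_basin_pair(o, scen, ba, bb, density, vars, econf,
                             seed = spawn_seed(config$seed, "cmp", sp)),
          error = function(e) {
            log_stage("overlap: %s %s-%s skipped (%s)", sp, ba, bb,
                      conditionMessage(e))
            NULL
          })
        if (is.null(cmp)) next
        call <- cmp$call
        pca_res <- NULL
        if (run("pca")) {
          pres <- match_environment(o, scen, vars)
          bga <- select_background(o[o$basin == ba, ], density, scen,
                                   basins = ba, ratio = config$ratio,
                                   cap = config$cap,
                                   seed = spawn_seed(config$seed, "pcabg", sp, ba))
          bgb <- select_background(o[o$basin == bb, ], density, scen,
                                   basins = bb, ratio = config$ratio,
                                   cap = config$cap,
                                   seed = spawn_seed(config$seed, "pcabg", sp, bb))
          pca_res <- pca_validation(
            pres[pres$basin == ba, ], pres[pres$basin == bb, ],
            match_environment(cbind(species = "bg", bga), scen, vars),
            match_environment(cbind(species = "bg", bgb), scen, vars),
            vars, cap = config$cap, ratio = config$ratio,
            m = max(1, length(species)), n_reps = config$pca_reps,
            alpha = config$alpha,
            seed = spawn_seed(config$seed, "pca", sp, ba, bb))
          call <- combine_evidence(call, pca_res$axes)
          for (a in pca_res$axes)
            pca_rows[[length(pca_rows) + 1]] <- data.frame(
              species = sp, pair = cmp$pair, axis = a$axis,
              explained = pca_res$pca$explained[a$axis],
              observed = a$observed, lower = a$lower, upper = a$upper,
              p_adjusted = a$p_adjusted, significant = a$significant)
        }
        comparisons[[length(comparisons) + 1]] <- cmp
        comp_rows[[length(comp_rows) + 1]] <- data.frame(
          species = sp, pair = cmp$pair, n_a = cmp$n_a, n_b = cmp$n_b,
          d = cmp$d, null_ab_lo = cmp$null_ab$lower,
          null_ab_hi = cmp$null_ab$upper,
          null_ba_lo = if (is.null(cmp$null_ba)) NA else cmp$null_ba$lower,
          null_ba_hi = if (is.null(cmp$null_ba)) NA else cmp$null_ba$upper,
          class = call$class, binary_diverged = call$binary_diverged)
      }
    }
    comp_tab <- do.call(rbind, comp_rows)
    log_stage("overlap: %d comparisons, %d diverged",
              length(comparisons), sum(comp_tab$binary_diverged %||% 0))
    write.csv(comp_tab, file.path(config$outdir, "comparisons.csv"),
              row.names = FALSE)
    if (length(pca_rows)) {
      write.csv(do.call(rbind, pca_rows),
                file.path(config$outdir, "pca_validation.csv"),
                row.names = FALSE)
    }
    manifest$stages$overlap <- list(n_comparisons = length(comparisons))
    out$comparisons <- comp_tab
  }

  # --- robustness -------------------------------------------------------
  if (run("robustness") && !is.null(out$comparisons)) {
    ir <- tryCatch(imbalance_regression(out$comparisons),
                   error = function(e) {
                     log_stage("robustness: skipped (%s)", conditionMessage(e))
                     NULL
                   })
    if (!is.null(ir)) {
      jsonlite::write_json(unclass(ir),
                           file.path(config$outdir, "imbalance_regression.json"),
                           auto_unbox = TRUE, digits = NA)
      log_stage("robustness: imbalance p = %.3f", ir$p)
      out$imbalance <- ir
      manifest$stages$robustness <- list(p = ir$p)
    }
  }

  # --- hgam -------------------------------------------------------------
  if (run("hgam") && !is.null(out$comparisons) && !is.null(niche_vals)) {
    tab <- assemble_table(out$comparisons, niche_vals,
                          min_per_pair = config$min_per_pair)
    if (length(unique(tab$pair)) >= 2 &&
        length(unique(tab$diverged)) == 2) {
      hf <- fit_hgam(tab)
      terms_df <- data.frame(term = rownames(hf$terms), hf$terms,
                             row.names = NULL, check.names = FALSE)
      write.csv(terms_df, file.path(config$outdir, "hgam_terms.csv"),
                row.names = FALSE)
      jsonlite::write_json(
        list(deviance_explained = hf$deviance_explained,
             r2_adj = hf$r2_adj, n = hf$n, dropped = hf$dropped),
        file.path(config$outdir, "hgam_fit.json"), auto_unbox = TRUE,
        digits = NA)
      log_stage("hgam: deviance explained %.1f%%", 100 * hf$deviance_explained)
      out$hgam <- hf
      manifest$stages$hgam <- list(deviance_explained = hf$deviance_explained)
    } else {
      log_stage("hgam: skipped (fewer than 2 pairs or single-class outcome)")
    }
  }

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest$files <- unique(c(list.files(config$outdir), "manifest.json"))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}
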