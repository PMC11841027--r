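test_that("noise-free fields reproduce the configured structure exactly", {
  spec <- seascape_spec(lon_range = c(-5, 5), lat_range = c(-5, 5),
                        resolution = 1, months = 2,
                        fields = list(temperature = list(
                          mean = 27, lat_gradient = -0.5, corr_length = 0,
                          noise_sd = 0)),
                        seed = 1)
  sea <- generate_environment(spec)
  j0 <- which(sea$clim$lat == -0.5)  # |lat| = 0.5 row nearest the equator
  i <- which(!is.na(sea$mask[, j0]))[1]
  expect_equal(sea$clim$fields$temperature[i, j0, 1], 27 - 0.5 * 0.5)
  # temperature decreases away from the equator along every ocean column
  tt <- sea$clim$fields$temperature[i, , 1]
  expect_true(all(diff(tt[sea$clim$lat >= 0]) <= 0))
})

test_that("generation is bit-identical under a fixed seed", {
  s1 <- generate_environment(test_spec(seed = 11))
  s2 <- generate_environment(test_spec(seed = 11))
  expect_identical(s1$clim$fields, s2$clim$fields)
  expect_identical(s1$mask, s2$mask)
})

test_that("degenerate extents are rejected", {
  expect_error(seascape_spec(lon_range = c(0, 0.5), resolution = 1),
               "degenerate")
  expect_error(seascape_spec(resolution = -1), "resolution")
})

test_that("a corr_with field tracks its target (Spearman r on ocean cells)", {
  spec <- test_spec(seed = 21)
  spec$fields$oxygen <- list(mean = 250, noise_sd = 20, corr_length = 3,
                             corr_with = "temperature", corr = -0.95)
  sea <- generate_environment(spec)
  oc <- nichediverge:::ocean_cells(sea$mask)
  r <- cor(sea$clim$fields$temperature[, , 1][oc],
           sea$clim$fields$oxygen[, , 1][oc], method = "spearman")
  expect_lt(r, -0.75)
})

test_that("basins partition the ocean and occurrences stay in-basin", {
  sea <- test_sea()
  oc <- which(!is.na(sea$mask))
  expect_true(all(sea$mask[oc] %in% 1:2))
  tr <- niche_truth(c(temperature = 15), c(temperature = 3))
  occ <- sample_occurrences(tr, sea, 300, basins = "B2", seed = 3)
  expect_true(all(occ$basin == "B2"))
  gi <- nichediverge:::grid_index(sea$clim, occ$lon, occ$lat)
  cells <- gi$i + (gi$j - 1L) * length(sea$clim$lon)
  expect_true(all(!is.na(sea$mask[cells])))
  # per (cell, month) slots are sampled at most once
  expect_false(any(duplicated(data.frame(cells, occ$month))))
})

test_that("a flat niche with uniform effort samples cells uniformly", {
  sea <- test_sea()
  tr <- niche_truth(c(temperature = 15), c(temperature = 1e6))
  occ <- sample_occurrences(tr, sea, 4000, species = "s", seed = 2)
  gi <- nichediverge:::grid_index(sea$clim, occ$lon, occ$lat)
  cells <- gi$i + (gi$j - 1L) * length(sea$clim$lon)
  cnt <- table(factor(cells, levels = nichediverge:::ocean_cells(sea$mask)))
  x2 <- sum((cnt - mean(cnt))^2 / mean(cnt))
  expect_gt(pchisq(x2, length(cnt) - 1, lower.tail = FALSE), 0.001)
})

test_that("sampled environments match the suitability-weighted oracle", {
  sea <- test_sea()
  tr <- niche_truth(c(temperature = 15), c(temperature = 2))
  n <- 500
  occ <- sample_occurrences(tr, sea, n, species = "s", seed = 17)
  fr <- match_environment(occ, sea, "temperature")
  # oracle: direct summation of suitability x temperature over all slots
  s <- nichediverge:::suitability_grid(tr, sea$clim, sea$mask)
  oc <- nichediverge:::ocean_cells(sea$mask)
  ncell <- length(sea$clim$lon) * length(sea$clim$lat)
  w <- tv <- NULL
  for (m in seq_along(sea$clim$months)) {
    w <- c(w, s[oc + (m - 1) * ncell])
    tv <- c(tv, sea$clim$fields$temperature[oc + (m - 1) * ncell])
  }
  mu <- sum(w * tv) / sum(w)
  sd_w <- sqrt(sum(w * (tv - mu)^2) / sum(w))
  expect_lt(abs(mean(fr$temperature) - mu), 3 * sd_w / sqrt(n))
})

test_that("a divergence delta shifts the sampled environments as engineered", {
  sea <- test_sea()
  tr <- niche_truth(c(temperature = 14), c(temperature = 3),
                    divergence_delta = c(temperature = 4),
                    diverged_basin = "B2")
  oa <- sample_occurrences(tr, sea, 200, basins = "B1", seed = 5)
  ob <- sample_occurrences(tr, sea, 200, basins = "B2", seed = 6)
  ta <- match_environment(oa, sea, "temperature")$temperature
  tb <- match_environment(ob, sea, "temperature")$temperature
  expect_gt(mean(tb) - mean(ta), 0)
})

test_that("sampling rejects requests beyond the available slots", {
  spec <- seascape_spec(lon_range = c(0, 12), lat_range = c(0, 9),
                        resolution = 3, months = 1, seed = 1)
  sea <- generate_environment(spec)
  tr <- niche_truth(c(temperature = 20), c(temperature = 5))
  expect_error(sample_occurrences(tr, sea, 1000, seed = 1), "slots")
})

test_that("cell-level occurrence law matches suitability x effort", {
  spec <- seascape_spec(lon_range = c(0, 90), lat_range = c(-45, 45),
                        resolution = 1, seed = 3)
  sea <- generate_environment(spec)
  tr <- niche_truth(c(temperature = 15), c(temperature = 3))
  n <- 2000
  occ <- sample_occurrences(tr, sea, n, species = "s", seed = 7)
  s <- nichediverge:::suitability_grid(tr, sea$clim, sea$mask)
  oc <- nichediverge:::ocean_cells(sea$mask)
  ncell <- length(sea$clim$lon) * length(sea$clim$lat)
  p_cell <- rowSums(vapply(seq_along(sea$clim$months),
                           function(m) s[oc + (m - 1) * ncell],
                           numeric(length(oc))))
  p_cell <- p_cell / sum(p_cell)
  gi <- nichediverge:::grid_index(sea$clim, occ$lon, occ$lat)
  cnt <- tabulate(match(gi$i + (gi$j - 1L) * length(sea$clim$lon), oc),
                  nbins = length(oc))
  ord <- order(p_cell)
  bins <- cut(cumsum(p_cell[ord]), seq(0, 1, 0.05), include.lowest = TRUE)
  obs <- tapply(cnt[ord], bins, sum)
  ex <- tapply(p_cell[ord], bins, sum) * n
  x2 <- sum((obs - ex)^2 / ex)
  expect_gt(pchisq(x2, length(obs) - 1, lower.tail = FALSE), 0.001)
})

test_that("comparison-table generator honours its truth", {
  # zero effects: a fair coin
  t0 <- generate_hgam_table(n_rows = 2000, seed = 1)
  expect_lt(abs(mean(t0$diverged) - 0.5), 3 * sqrt(0.25 / 2000))
  # saturating temperature effect: everything diverges
  t1 <- generate_hgam_table(n_rows = 200, f_temp = function(t) 0 * t + 50,
                            seed = 2)
  expect_equal(mean(t1$diverged), 1)
  # decreasing temperature effect: cold tercile diverges more than warm
  t2 <- generate_hgam_table(n_rows = 3000,
                            f_temp = function(t) 1.5 - 0.1 * t, seed = 3)
  ter <- cut(t2$temperature, quantile(t2$temperature, c(0, 1/3, 2/3, 1)),
             include.lowest = TRUE)
  rates <- tapply(t2$diverged, ter, mean)
  expect_gt(rates[[1]], rates[[3]])
  # non-finite smooths are rejected
  expect_error(generate_hgam_table(n_rows = 60,
                                   f_temp = function(t) t * NA, seed = 4),
               "non-finite")
})
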