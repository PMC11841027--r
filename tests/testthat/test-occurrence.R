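test_that("thinning keeps one record per species, half-degree cell and month", {
  occ <- data.frame(species = "a",
                    lon = c(10.1, 10.3, 10.1, 11.2),
                    lat = c(20.1, 20.2, 20.1, 20.1),
                    month = c(3, 3, 4, 3))
  th <- thin_occurrences(occ)
  expect_equal(nrow(th), 3)  # duplicate-cell March pair collapses
  # months 3 and 4 in the same cell both survive
  expect_setequal(th$month[th$lon < 11], c(3, 4))
  # scattered records are untouched
  sc <- data.frame(species = "a", lon = seq(0, 9) + 0.1,
                   lat = rep(0.1, 10), month = 1)
  expect_equal(nrow(thin_occurrences(sc)), 10)
})

test_that("thinning is idempotent, order-insensitive and keeps the smallest (lat, lon)", {
  set.seed(4)
  occ <- data.frame(species = sample(c("a", "b"), 200, TRUE),
                    lon = runif(200, 0, 3), lat = runif(200, 0, 3),
                    month = sample(1:3, 200, TRUE))
  t1 <- thin_occurrences(occ)
  expect_identical(thin_occurrences(t1), t1)
  t2 <- thin_occurrences(occ[sample(nrow(occ)), ])
  expect_identical(t1[order(t1$species, t1$lon, t1$lat, t1$month), ],
                   t2[order(t2$species, t2$lon, t2$lat, t2$month), ])
  grp <- occ[floor(occ$lon / 0.5) == 0 & floor(occ$lat / 0.5) == 0 &
               occ$species == "a" & occ$month == 1, ]
  if (nrow(grp) > 0) {
    kept <- t1[floor(t1$lon / 0.5) == 0 & floor(t1$lat / 0.5) == 0 &
                 t1$species == "a" & t1$month == 1, ]
    expect_equal(kept$lat, min(grp$lat))
  }
})

test_that("basin assignment buffers records near the inter-basin boundary", {
  sea <- equator_sea()
  occ <- data.frame(species = "a",
                    lon = c(0.2, 0.2, 0.2),
                    lat = c(0.25, 3.2, -3.2),
                    month = 1)
  ab <- assign_basins(occ, sea, buffer_deg = 0.5)
  expect_equal(ab$status, c("buffered", "ok", "ok"))
  expect_equal(ab$basin[2:3], c("N", "S"))
})

test_that("records on land or excluded cells are flagged excluded", {
  sea <- equator_sea()
  sea$mask[1, 1] <- NA   # land
  sea$mask[2, 1] <- 0L   # marginal sea
  occ <- data.frame(species = "a", lon = c(-4.2, -3.2), lat = c(-4.2, -4.2),
                    month = 1)
  ab <- assign_basins(occ, sea, buffer_deg = 0.5)
  expect_equal(ab$status, c("excluded", "excluded"))
})

test_that("species filters enforce per-basin and total thresholds", {
  mk <- function(sp, basin, n)
    data.frame(species = sp, lon = runif(n), lat = runif(n),
               month = 1, basin = basin, status = "ok")
  occ <- rbind(mk("keep", "A", 60), mk("keep", "B", 55),
               mk("drop1", "A", 120), mk("drop1", "B", 10),
               mk("edge", "A", 50), mk("edge", "B", 50))
  fs <- filter_species(occ)
  expect_setequal(unique(fs$occurrences$species), c("keep", "edge"))
  rep1 <- fs$report
  expect_false(any(rep1$retained[rep1$species == "drop1"]))
  # idempotent
  fs2 <- filter_species(fs$occurrences)
  expect_equal(nrow(fs2$occurrences), nrow(fs$occurrences))
})

test_that("collinearity screening retains independent predictors", {
  set.seed(1)
  env <- data.frame(a = rnorm(1000), b = rnorm(1000))
  sr <- screen_collinearity(env)
  expect_setequal(sr$retained, c("a", "b"))
  expect_true(all(abs(sr$vif - 1) < 0.05))
})

test_that("a strongly correlated pair loses one member", {
  set.seed(2)
  x <- rnorm(1000)
  env <- data.frame(temp = x, oxy = 0.91 * x + sqrt(1 - 0.91^2) * rnorm(1000),
                    other = rnorm(1000))
  sr <- screen_collinearity(env)
  expect_equal(nrow(sr$removed), 1)
  expect_true(sr$removed$variable %in% c("temp", "oxy"))
  expect_true("other" %in% sr$retained)
})

test_that("an exactly collinear triple is pruned until max VIF < 5", {
  set.seed(3)
  a <- rnorm(500); b <- rnorm(500)
  sr <- screen_collinearity(data.frame(a = a, b = b, c = a + b))
  expect_lt(max(sr$vif), 5)
  expect_gte(nrow(sr$removed), 1)
  # VIF oracle: explicit regression of each retained column on the rest
  rk <- apply(cbind(a = a, b = b, c = a + b)[, sr$retained], 2, rank)
  for (j in seq_along(sr$retained)) {
    fit <- lm.fit(cbind(1, rk[, -j, drop = FALSE]), rk[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((rk[, j] - mean(rk[, j]))^2)
    expect_equal(unname(sr$vif[j]), 1 / (1 - r2), tolerance = 1e-8)
  }
})

test_that("constant columns are rejected with a message", {
  expect_error(screen_collinearity(data.frame(a = rnorm(20), b = rep(1, 20))),
               "constant")
})

test_that("environment matching equals direct grid lookup", {
  sea <- test_sea()
  tr <- niche_truth(c(temperature = 15), c(temperature = 4))
  occ <- sample_occurrences(tr, sea, 100, species = "s", seed = 9)
  fr <- match_environment(occ, sea)
  expect_equal(nrow(fr), 100)
  # independent lookup loop
  for (r in sample(100, 10)) {
    i <- which.min(abs(sea$clim$lon - occ$lon[r]))
    j <- which.min(abs(sea$clim$lat - occ$lat[r]))
    expect_equal(fr$temperature[r],
                 sea$clim$fields$temperature[i, j, occ$month[r]])
    expect_equal(fr$bathymetry[r], sea$clim$bathymetry[i, j])
  }
  # monthly climatologies differ across months at one cell
  o2 <- data.frame(species = "s", lon = occ$lon[1], lat = occ$lat[1],
                   month = c(2, 8))
  f2 <- match_environment(o2, sea, "temperature")
  expect_false(f2$temperature[1] == f2$temperature[2])
})

test_that("records outside the grid are dropped with a warning", {
  sea <- test_sea()
  occ <- data.frame(species = "s", lon = c(10, 170), lat = c(0, 0), month = 1)
  expect_warning(fr <- match_environment(occ, sea), "dropped")
  expect_equal(nrow(fr), 1)
})
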