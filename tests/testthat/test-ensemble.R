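test_that("background selection honours the 10:1 ratio and the cap", {
  sea <- test_sea()
  dens <- nichediverge:::uniform_density(sea)
  tr <- niche_truth(c(temperature = 14), c(temperature = 3))
  p30 <- sample_occurrences(tr, sea, 30, species = "s", seed = 1)
  expect_equal(nrow(select_background(p30, dens, sea, seed = 2)), 300)
  p500 <- sample_occurrences(tr, sea, 500, species = "s", seed = 3)
  bg <- select_background(p500, dens, sea, seed = 4)
  expect_equal(nrow(bg), 1000)
  # no background slot duplicates a presence (cell, month)
  key <- function(d) paste(round(d$lon, 6), round(d$lat, 6), d$month)
  expect_length(intersect(key(bg), key(p500)), 0)
})

test_that("uniform density gives near-uniform background cells", {
  sea <- test_sea()
  dens <- nichediverge:::uniform_density(sea)
  tr <- niche_truth(c(temperature = 14), c(temperature = 3))
  p <- sample_occurrences(tr, sea, 100, species = "s", seed = 5)
  bg <- do.call(rbind, lapply(1:4, function(s)
    select_background(p, dens, sea, seed = s)))
  gi <- nichediverge:::grid_index(sea$clim, bg$lon, bg$lat)
  cnt <- table(factor(gi$i + (gi$j - 1L) * length(sea$clim$lon),
                      levels = nichediverge:::ocean_cells(sea$mask)))
  x2 <- sum((cnt - mean(cnt))^2 / mean(cnt))
  expect_gt(pchisq(x2, length(cnt) - 1, lower.tail = FALSE), 0.001)
})

test_that("background shortfalls are reported with counts", {
  sea <- test_sea()
  dens <- nichediverge:::uniform_density(sea)
  dens[!is.na(dens)] <- 0
  oc <- nichediverge:::ocean_cells(sea$mask)
  dens[oc[1:5]] <- 1
  tr <- niche_truth(c(temperature = 14), c(temperature = 3))
  p <- sample_occurrences(tr, sea, 50, species = "s", seed = 1)
  expect_error(select_background(p, dens, sea, seed = 2), "shortfall")
})

test_that("components fit, predict in [0,1], and separate separable data", {
  set.seed(6)
  x <- matrix(runif(400, 0, 30), ncol = 1, dimnames = list(NULL, "temperature"))
  y <- as.integer(x[, 1] > 15)
  for (alg in c("maxent", "glm", "gam")) {
    m <- fit_component(alg, x, y)
    p <- predict(m, x)
    expect_true(all(p >= 0 & p <= 1))
  }
  m <- fit_component("glm", x, y)
  expect_identical(tss(predict(m, x), y), 1)
})

test_that("the maxent-like quadratic recovers a unimodal optimum", {
  set.seed(7)
  xg <- seq(0, 30, 0.5)
  pres <- rnorm(300, 15, 2)
  bg <- runif(3000, 0, 30)
  x <- matrix(c(pres, bg), ncol = 1, dimnames = list(NULL, "temperature"))
  m <- fit_component("maxent", x, c(rep(1, 300), rep(0, 3000)))
  pg <- predict(m, matrix(xg, ncol = 1, dimnames = list(NULL, "temperature")))
  expect_lt(abs(xg[which.max(pg)] - 15), 1)
})

test_that("ensembles retain on TSS > 0.3 and weight by TSS", {
  fit1 <- fit_component("glm", matrix(c(rnorm(50, 2), rnorm(500)), ncol = 1,
                                      dimnames = list(NULL, "v")),
                        rep(c(1, 0), c(50, 500)))
  comps <- list(maxent = list(model = fit1, tss = 0.6, cbi = NA),
                glm = list(model = fit1, tss = 0.4, cbi = NA))
  ens <- build_ensemble(comps)
  expect_equal(unname(ens$weights), c(0.6, 0.4))
  # a component at exactly the threshold is not retained
  ens2 <- build_ensemble(list(maxent = list(model = fit1, tss = 0.6, cbi = NA),
                              glm = list(model = fit1, tss = 0.3, cbi = NA)))
  expect_equal(unname(ens2$weights), 1)
  expect_named(ens2$weights, "maxent")
  # a single retained component is the ensemble
  x <- matrix(rnorm(100), ncol = 1, dimnames = list(NULL, "v"))
  expect_equal(predict(ens2, x), predict(fit1, x))
  # no component passing is an error
  expect_error(build_ensemble(list(glm = list(model = fit1, tss = 0.2,
                                              cbi = NA))),
               "TSS")
})

test_that("ensemble predictions are convex combinations of components", {
  sea <- test_sea()
  fr <- species_frames(sea, 14, 150, seed = 41)
  ens <- fit_species_enm(fr$pres, fr$bg, test_vars, fast_config(), seed = 1)
  expect_s3_class(ens, "ensemble_model")
  x <- as.matrix(fr$bg[, test_vars])
  pe <- predict(ens, x)
  pc <- vapply(names(ens$weights),
               function(a) predict(ens$components[[a]]$model, x),
               numeric(nrow(x)))
  expect_true(all(pe >= apply(pc, 1, min) - 1e-12))
  expect_true(all(pe <= apply(pc, 1, max) + 1e-12))
})

test_that("a constant model projects a uniform, correctly normalized surface", {
  sea <- test_sea()
  m <- structure(list(algorithm = "glm", coefficients = c(0.5, rep(0, 6)),
                      spec = list(algorithm = "glm", vars = test_vars,
                                  center = rep(0, 6), scale = rep(1, 6))),
                 class = "component_model")
  ens <- structure(list(species = "s",
                        components = list(glm = list(model = m, tss = 0.5,
                                                     cbi = NA,
                                                     retained = TRUE)),
                        weights = c(glm = 1), variables = test_vars),
                   class = "ensemble_model")
  surf <- project_ensemble(ens, sea)
  expect_true(all(abs(surf$values - plogis(0.5)) < 1e-12))
  expect_equal(unique(round(surf$norm, 15)), 1 / length(surf$cells))
  expect_equal(sum(surf$norm), 1, tolerance = 1e-9)
  # land cells never enter the normalized sum
  expect_true(all(!is.na(sea$mask[surf$cells])))
  expect_error(project_ensemble(ens, list(clim = list(fields = list()),
                                          mask = sea$mask)),
               "lacks")
})

test_that("mean niche values are suitability-weighted means with the stated invariances", {
  sea <- test_sea()
  cells <- nichediverge:::ocean_cells(sea$mask)
  dimg <- c(length(sea$clim$lon), length(sea$clim$lat))
  unif <- nichediverge:::new_surface(cells, rep(0.4, length(cells)), dimg)
  mnv <- mean_niche_values(unif, sea, c("temperature", "bathymetry"))
  tbar <- mean(apply(sea$clim$fields$temperature, c(1, 2), mean)[cells])
  expect_equal(unname(mnv["temperature"]), tbar)
  expect_equal(unname(mnv["bathymetry"]), mean(sea$clim$bathymetry[cells]))
  # single positive cell -> that cell's value
  v <- rep(0, length(cells)); v[7] <- 0.9
  one <- nichediverge:::new_surface(cells, v, dimg)
  expect_equal(unname(mean_niche_values(one, sea, "bathymetry")),
               sea$clim$bathymetry[cells[7]])
  # invariant to positive rescaling of the surface
  r1 <- mean_niche_values(nichediverge:::new_surface(cells, v * 3, dimg),
                          sea, "temperature")
  expect_equal(mean_niche_values(one, sea, "temperature"), r1)
  # each mean lies within the variable's range
  fr <- species_frames(sea, 12, 120, seed = 51)
  ens <- fit_species_enm(fr$pres, fr$bg, test_vars, fast_config(), seed = 3)
  surf <- project_ensemble(ens, sea)
  m2 <- mean_niche_values(surf, sea)
  expect_gte(m2["temperature"], min(sea$clim$fields$temperature, na.rm = TRUE))
  expect_lte(m2["temperature"], max(sea$clim$fields$temperature, na.rm = TRUE))
})
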