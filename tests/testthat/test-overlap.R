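test_that("Schoener's D equals the direct formula on hand cases", {
  expect_equal(schoeners_d(c(0.5, 0.5), c(1, 0)), 0.5)
  p <- runif(20); p <- p / sum(p)
  expect_equal(schoeners_d(p, p), 1)
  q <- c(rep(0, 10), runif(10)); q <- q / sum(q)
  r <- c(runif(10), rep(0, 10)); r <- r / sum(r)
  expect_equal(schoeners_d(q, r), 0)
})

test_that("Schoener's D is symmetric and 1 - D is half the L1 distance", {
  set.seed(8)
  for (i in 1:25) {
    p <- runif(100); p <- p / sum(p)
    q <- runif(100); q <- q / sum(q)
    r <- runif(100); r <- r / sum(r)
    expect_equal(schoeners_d(p, q), schoeners_d(q, p))
    # triangle inequality of the underlying L1 metric
    expect_lte((1 - schoeners_d(p, r)),
               (1 - schoeners_d(p, q)) + (1 - schoeners_d(q, r)) + 1e-12)
  }
})

test_that("restriction renormalizes on the comparison support", {
  cells <- 1:10
  s <- nichediverge:::new_surface(cells, rep(2, 10), c(5, 2))
  r5 <- restrict_and_normalize(s, 3:7)
  expect_equal(r5$norm, rep(0.2, 5))
  su <- restrict_and_normalize(s, cells)
  expect_equal(schoeners_d(su, su), 1)
  expect_error(restrict_and_normalize(s, 9:12), "missing")
})

test_that("nearest-rank percentile bounds use ranks 3 and 98 on 100 replicates", {
  x <- sample(1:100)
  expect_equal(nichediverge:::nearest_rank(x, 0.025), 3)
  expect_equal(nichediverge:::nearest_rank(x, 0.975), 98)
})

test_that("classification follows the directional null-bound rules", {
  nd <- function(lo, hi) structure(list(lower = lo, upper = hi),
                                   class = "null_distribution")
  below <- classify_divergence(0.2, nd(0.4, 0.6), nd(0.3, 0.5))
  expect_equal(below$class, "diverged")
  expect_equal(below$binary_diverged, 1L)
  inside <- classify_divergence(0.45, nd(0.4, 0.6), nd(0.3, 0.5))
  expect_equal(inside$class, "neutral")
  expect_equal(inside$binary_diverged, 0L)
  above <- classify_divergence(0.8, nd(0.4, 0.6), nd(0.3, 0.5))
  expect_equal(above$class, "conserved")
  expect_equal(above$binary_diverged, 0L)
  # conflicting directions resolve to neutral with a flag
  conf <- classify_divergence(0.55, nd(0.6, 0.8), nd(0.3, 0.5))
  expect_equal(conf$class, "neutral")
  expect_true(conf$conflict)
  # ties at a bound resolve inward (neutral)
  tie <- classify_divergence(0.4, nd(0.4, 0.6), nd(0.4, 0.6))
  expect_equal(tie$class, "neutral")
})

test_that("the background-similarity null stores the configured replicates", {
  sea <- test_sea()
  scen <- cached("scen_null_small",
                 make_scenario(test_spec(seed = 5), n_species = 2,
                               n_per_basin = 60, delta = 0, seed = 31))
  occ <- scen$occurrences[scen$occurrences$species == "sp001", ]
  occ$status <- "ok"
  cmp <- compare_basin_pair(occ, scen, "B1", "B2", NULL, test_vars,
                            enm_config(n_reps = 100), seed = 3)
  expect_length(cmp$null_ab$values, 100)
  expect_length(cmp$null_ba$values, 100)
  expect_true(all(cmp$null_ab$values >= 0 & cmp$null_ab$values <= 1,
                  na.rm = TRUE))
  expect_true(cmp$null_ab$lower <= cmp$null_ab$upper)
  expect_true(cmp$d >= 0 && cmp$d <= 1)
  expect_equal(cmp$pair, "B1-B2")
  # same seed reproduces the comparison exactly
  cmp2 <- compare_basin_pair(occ, scen, "B1", "B2", NULL, test_vars,
                             enm_config(n_reps = 100), seed = 3)
  expect_identical(cmp$d, cmp2$d)
  expect_identical(cmp$null_ab$values, cmp2$null_ab$values)
})

test_that("pairwise comparison enforces its preconditions", {
  sea <- test_sea()
  occ <- data.frame(species = "s", lon = runif(20, 1, 40),
                    lat = runif(20, -30, 30), month = 1,
                    basin = rep(c("B1", "B2"), 10), status = "ok")
  expect_error(compare_basin_pair(occ, sea, "B1", "B1", NULL, test_vars),
               "differ")
  expect_error(compare_basin_pair(occ, sea, "B1", "B2", NULL, test_vars),
               "fewer than")
})
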