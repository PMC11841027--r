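pca_frames <- function(n = 100, shift = 0, seed = 1, p = 4) {
  nichediverge:::with_seed(seed, {
    L <- matrix(0, p, p)
    L[lower.tri(L, diag = TRUE)] <- c(2, 0.5, 0.3, 0.2, 1, 0.2, 0.1,
                                      0.8, 0.1, 0.6)[seq_len(p * (p + 1) / 2)]
    draw <- function(m) {
      z <- matrix(rnorm(m * p), m, p) %*% t(L)
      colnames(z) <- paste0("v", seq_len(p))
      as.data.frame(z)
    }
    pa <- draw(n); pb <- draw(n)
    pb$v1 <- pb$v1 + shift * 2   # v1 SD is ~2: shift in SD units
    list(pa = pa, pb = pb, ba = draw(10 * n), bb = draw(10 * n))
  })
}

test_that("PCA pools groups, caps presences, and canonicalizes signs", {
  fr <- pca_frames(1500, seed = 2)
  vars <- paste0("v", 1:4)
  pca <- build_pca(fr$pa, fr$pb, fr$ba, fr$bb, vars, cap = 1000, ratio = 10,
                   seed = 3)
  expect_equal(sum(pca$group == "presence-A"), 1000)    # capped from 1500
  expect_equal(sum(pca$group == "background-A"), 10000)
  expect_true(all(diff(pca$explained) <= 1e-12))
  expect_lte(sum(pca$explained), 1 + 1e-9)
  # loadings orthonormal; dominant-variance direction on PC1
  expect_equal(crossprod(pca$loadings), diag(4), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_gt(pca$explained[1], 0.5)
  expect_equal(which.max(abs(pca$loadings[, 1])), 1L, ignore_attr = TRUE)
  # canonical sign: largest-|loading| variable positive on every axis
  for (ax in 1:4)
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, ax])), ax], 0)
  # 10:1 background rows per presence
  fr2 <- pca_frames(200, seed = 4)
  pca2 <- build_pca(fr2$pa, fr2$pb, fr2$ba, fr2$bb, vars, seed = 5)
  expect_equal(sum(pca2$group == "background-A"), 2000)
})

test_that("axis selection applies the cumulative-variance elbow rule", {
  expect_equal(select_axes(c(0.32, 0.21, 0.14, 0.1, 0.08)), 4)
  expect_equal(select_axes(c(0.8, 0.1, 0.05)), 2)
  expect_equal(select_axes(c(0.4, 0.35, 0.1)), 2)
})

test_that("axis mean differences behave on degenerate inputs", {
  fr <- pca_frames(50, seed = 6)
  vars <- paste0("v", 1:4)
  pca <- build_pca(fr$pa, fr$pa, fr$ba, fr$bb, vars, seed = 7)
  expect_equal(axis_mean_difference(pca, 1), 0)
  pca$scores <- matrix(c(1, 1, -1, -1), 4, 1)
  pca$group <- c("presence-A", "presence-A", "presence-B", "presence-B")
  expect_equal(axis_mean_difference(pca, 1), 2)
})

test_that("a known variable-space shift propagates through the loadings", {
  delta <- c(3, 0, 0, 0)
  fr <- pca_frames(4000, seed = 8)
  fr$pb <- fr$pa + matrix(delta, nrow(fr$pa), 4, byrow = TRUE)
  vars <- paste0("v", 1:4)
  pca <- build_pca(fr$pa, fr$pb, fr$ba, fr$bb, vars, seed = 9)
  # propagate the shift through the scaling and the loadings: with
  # orthonormal loadings, the axis-wise mean differences compose to the
  # norm of the standardized shift
  sds <- apply(rbind(as.matrix(fr$pa), as.matrix(fr$pb),
                     as.matrix(fr$ba), as.matrix(fr$bb))[, vars], 2, sd)
  diffs <- vapply(1:4, function(ax) axis_mean_difference(pca, ax), 0)
  expect_equal(sqrt(sum(diffs^2)), sqrt(sum((delta / sds)^2)),
               tolerance = 0.02)
})

test_that("the permutation null is centred and stores its replicates", {
  fr <- pca_frames(100, seed = 10)
  vars <- paste0("v", 1:4)
  pca <- build_pca(fr$pa, fr$pb, fr$ba, fr$bb, vars, seed = 11)
  jk <- jackknife_null(pca, 1, n_reps = 1000, seed = 12)
  expect_length(jk$null_values, 1000)
  expect_lt(median(jk$null_values), 3 * sd(pca$scores[, 1]) / sqrt(100))
  expect_true(jk$lower <= jk$upper)
  expect_false(jk$warn_few_reps)
  expect_true(jackknife_null(pca, 1, n_reps = 50, seed = 1)$warn_few_reps)
})

test_that("the delete-one jackknife mode yields one replicate per observation", {
  fr <- pca_frames(60, seed = 15)
  vars <- paste0("v", 1:4)
  pca <- build_pca(fr$pa, fr$pb, fr$ba, fr$bb, vars, seed = 16)
  jk <- jackknife_null(pca, 1, method = "jackknife")
  expect_length(jk$null_values, 120)
  # each replicate moves the statistic only O(1/n) from the observed value
  expect_lt(max(abs(jk$null_values - jk$observed)), 10 / 60)
})

test_that("Bonferroni adjustment multiplies, clips, and never decreases", {
  fr <- pca_frames(100, seed = 13)
  vars <- paste0("v", 1:4)
  pca <- build_pca(fr$pa, fr$pb, fr$ba, fr$bb, vars, seed = 14)
  tab <- bonferroni_test(pca, k = 3, m = 2)
  expect_equal(tab$p_adjusted, pmin(1, tab$p_raw * 6))
  expect_true(all(tab$p_adjusted >= tab$p_raw))
  # identical groups: adjusted p = 1
  pca2 <- pca
  pca2$scores <- rbind(pca$scores[pca$group == "presence-A", ],
                       pca$scores[pca$group == "presence-A", ])
  pca2$group <- rep(c("presence-A", "presence-B"), each = 100)
  expect_equal(bonferroni_test(pca2, k = 2)$p_adjusted, c(1, 1))
  # huge separation stays significant under heavy correction
  pca3 <- pca2
  pca3$scores[pca3$group == "presence-B", 1] <-
    pca3$scores[pca3$group == "presence-B", 1] + 10 * sd(pca3$scores[, 1])
  expect_lt(bonferroni_test(pca3, k = 1, m = 1e4)$p_adjusted[1], 0.05)
})

test_that("evidence combination validates or downgrades diverged calls", {
  call <- function(cls) structure(list(class = cls,
                                       binary_diverged = as.integer(cls ==
                                                                      "diverged")),
                                  class = "divergence_call")
  ax <- function(sig) list(axis = 1, significant = sig)
  v <- combine_evidence(call("diverged"), list(ax(TRUE), ax(FALSE)))
  expect_equal(v$class, "diverged"); expect_true(v$validated)
  d <- combine_evidence(call("diverged"), list(ax(FALSE)))
  expect_equal(d$class, "neutral"); expect_true(d$downgraded)
  expect_equal(d$binary_diverged, 0L)
  c2 <- combine_evidence(call("conserved"), list(ax(TRUE)))
  expect_equal(c2$class, "conserved"); expect_false(c2$downgraded)
})
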