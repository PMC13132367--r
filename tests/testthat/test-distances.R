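# Nearest-neighbour and triad distances: exact oracles, invariances,
# exclusion sentinels.

test_that("hand-checkable geometry: 3-4-5 triangle and triad max rule", {
  tab <- toy_cells(rbind(c(0, 0), c(3, 4), c(10, 0), c(0, 2)),
                   c("cDC1", "CD8T", "CD8T", "CD4T"))
  d <- mean_min_distance(tab, "cDC1", "CD8T")
  expect_equal(as.numeric(d), 5)
  tr <- triad_radius(tab)
  expect_equal(unname(tr$radii), 5)   # max(nearest CD8 = 5, nearest CD4 = 2)
  # co-located partners give zero radius
  tab0 <- toy_cells(rbind(c(1, 1), c(1, 1), c(1, 1)),
                    c("cDC1", "CD8T", "CD4T"))
  expect_equal(triad_radius(tab0)$mean, 0)
})

test_that("adding a to-cell never increases the mean minimum distance", {
  for (s in 1:5) {
    tab <- random_pattern(150, seed = 70 + s)
    d1 <- as.numeric(mean_min_distance(tab, "cDC1", "CD8T"))
    extra <- toy_cells(cbind(runif(1, 0, 1000), runif(1, 0, 1000)), "CD8T")
    extra$cell_id <- "extra"
    d2 <- as.numeric(mean_min_distance(rbind(tab, extra), "cDC1", "CD8T"))
    expect_lte(d2, d1)
  }
})

test_that("statistics agree exactly with brute-force oracles", {
  for (s in 1:10) {
    tab <- random_pattern(sample(50:400, 1), seed = 100 + s)
    expect_equal(as.numeric(mean_min_distance(tab, "cDC1", "CD8T")),
                 oracle_nn_mean(tab, "cDC1", "CD8T"), tolerance = 0)
    tr <- triad_radius(tab)
    expect_equal(unname(tr$radii), oracle_triad(tab), tolerance = 0)
    # per-cell triad radius >= per-cell NN distance to CD8, always
    d8 <- attr(mean_min_distance(tab, "cDC1", "CD8T"), "per_cell")
    expect_true(all(tr$radii >= d8 - 1e-12))
  }
})

test_that("distance statistics are invariant under rigid motions", {
  tab <- random_pattern(200, seed = 55)
  th <- 0.7; dx <- 123.4; dy <- -56.7
  rot <- tab
  rot$x_um <- cos(th) * tab$x_um - sin(th) * tab$y_um + dx
  rot$y_um <- sin(th) * tab$x_um + cos(th) * tab$y_um + dy
  expect_equal(as.numeric(mean_min_distance(rot, "cDC1", "CD8T")),
               as.numeric(mean_min_distance(tab, "cDC1", "CD8T")),
               tolerance = 1e-9)
  expect_equal(triad_radius(rot)$mean, triad_radius(tab)$mean,
               tolerance = 1e-9)
})

test_that("missing phenotypes exclude the sample rather than erroring", {
  tab <- toy_cells(rbind(c(0, 0), c(5, 5)), c("CD8T", "CD4T"))
  d <- mean_min_distance(tab, "cDC1", "CD8T")
  expect_true(is_excluded(d))
  expect_match(d$reason, "cDC1")
  expect_true(is_excluded(triad_radius(tab)))
  ds <- distance_summary(tab, "s1")
  expect_true(is.na(ds$mean_dist_cdc1_cd8))
})

test_that("mean triad radius dominates both pairwise means on every sample", {
  for (s in 1:5) {
    tab <- random_pattern(250, seed = 200 + s)
    tr <- triad_radius(tab)$mean
    expect_gte(tr, as.numeric(mean_min_distance(tab, "cDC1", "CD8T")) - 1e-12)
    expect_gte(tr, as.numeric(mean_min_distance(tab, "cDC1", "CD4T")) - 1e-12)
  }
})

test_that("group comparison of per-sample distances behaves at the null", {
  v <- setNames(c(1, 2, 3, 1, 2, 3), paste0("s", 1:6))
  res <- group_distance_compare(v, rep(c("R", "NR"), each = 3))
  expect_equal(res$p, 1)
  # NA (excluded) samples are dropped with a count
  v2 <- c(v, s7 = NA_real_)
  res2 <- group_distance_compare(v2, c(rep(c("R", "NR"), each = 3), "R"))
  expect_equal(res2$n_excluded, 1)
  expect_error(group_distance_compare(v, rep("R", 6)), "two non-empty groups")
})
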