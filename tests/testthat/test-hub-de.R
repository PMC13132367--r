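# Differential expression between hub classes and preranked enrichment.

# Fabricate a classified hub_set directly from a count matrix and classes.
fake_hubset <- function(counts, classes) {
  hubs <- data.frame(hub_id = colnames(counts),
                     center_cell = colnames(counts),
                     center_type = NA_character_,
                     x_um = 0, y_um = 0, n_cells = 1, class = classes,
                     stringsAsFactors = FALSE)
  structure(list(hubs = hubs, counts = counts,
                 members = as.list(colnames(counts))), class = "hub_set")
}

test_that("a fully separating gene gets positive log2FC and small q", {
  set.seed(8)
  counts <- matrix(rpois(40 * 30, 5), 30, 40,
                   dimnames = list(sprintf("g%02d", 1:30),
                                   sprintf("h%02d", 1:40)))
  classes <- rep(c("cDC1-rich", "cDC1-devoid"), each = 20)
  counts["g01", ] <- ifelse(classes == "cDC1-rich", rpois(40, 20), 0)
  de <- hub_de(fake_hubset(counts, classes))
  row <- de[de$gene == "g01", ]
  expect_gt(row$log2fc, 1)
  expect_lt(row$q, 0.05)
  expect_true(all(diff(de$q[order(de$p)]) >= -1e-12))  # q monotone in p
})

test_that("identical classes give zero log2FC everywhere", {
  counts <- matrix(rpois(20 * 10, 6), 10, 20,
                   dimnames = list(paste0("g", 1:10), paste0("h", 1:20)))
  counts[, 11:20] <- counts[, 1:10]
  de <- hub_de(fake_hubset(counts, rep(c("cDC1-rich", "cDC1-devoid"), each = 10)))
  expect_equal(de$log2fc, rep(0, 10))
})

test_that("backend is pluggable and errors are informative", {
  counts <- matrix(rpois(100, 5), 10, 10,
                   dimnames = list(paste0("g", 1:10), paste0("h", 1:10)))
  hs <- fake_hubset(counts, rep(c("cDC1-rich", "cDC1-devoid"), each = 5))
  de <- hub_de(hs, backend = function(a, b) t.test(log1p(a), log1p(b))$p.value)
  expect_true(all(de$p >= 0 & de$p <= 1))
  expect_error(hub_de(fake_hubset(counts, rep(NA_character_, 10))),
               "classified")
  expect_error(hub_de(fake_hubset(counts, c("cDC1-rich",
                                            rep("cDC1-devoid", 9)))),
               ">= 2 hubs")
})

test_that("permuted class labels give uniform p-values", {
  set.seed(21)
  mu <- rlnorm(500, log(10), 1)
  counts <- matrix(rpois(500 * 60, mu), 500, 60,
                   dimnames = list(sprintf("g%03d", 1:500),
                                   sprintf("h%02d", 1:60)))
  classes <- sample(rep(c("cDC1-rich", "cDC1-devoid"), each = 30))
  de <- hub_de(fake_hubset(counts, classes))
  ks <- suppressWarnings(ks.test(de$p, "punif"))
  expect_gt(ks$p.value, 0.05)
})

test_that("preranked enrichment: size rule, hand-walk ES, antisymmetry", {
  stats_eq <- setNames(rep(2, 10), paste0("g", 1:10))
  sets <- list(all = paste0("g", 1:10), top2 = c("g1", "g2"))
  res <- preranked_gsea(stats_eq, sets, n_perm = 50, seed = 1, min_size = 2)
  expect_match(res$note[res$set == "all"], "skipped")
  # two hits of weight 1/2 each before any miss -> ES exactly 1
  expect_equal(res$es[res$set == "top2"], 1)

  set.seed(4)
  stats <- setNames(rnorm(50), paste0("g", 1:50))
  sets2 <- list(a = paste0("g", 1:8), b = paste0("g", 40:50))
  r1 <- preranked_gsea(stats, sets2, n_perm = 50, seed = 2)
  r2 <- preranked_gsea(-stats, sets2, n_perm = 50, seed = 2)
  expect_equal(r2$es, -r1$es, tolerance = 1e-12)
  # |ES| <= 1 and NES shares the ES sign
  expect_true(all(abs(r1$es) <= 1))
  expect_true(all(sign(r1$nes) == sign(r1$es)))
  # a set disjoint from the ranking is skipped
  r3 <- preranked_gsea(stats, list(gone = paste0("x", 1:5)), n_perm = 10, seed = 1)
  expect_match(r3$note, "skipped")
})

test_that("permutation p-values are calibrated for random sets", {
  set.seed(6)
  stats <- setNames(rnorm(80), paste0("g", 1:80))
  ps <- vapply(1:40, function(i) {
    set.seed(1000 + i)
    gs <- list(s = sample(names(stats), 8))
    preranked_gsea(stats, gs, n_perm = 200, seed = 1000 + i)$p
  }, numeric(1))
  # uniform-ish: no mass piling below 0.05 beyond binomial noise
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps), 0.3)
})
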