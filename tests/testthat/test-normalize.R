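# log2-CPM, detectability, meta-signal, importance filter, intersection.

test_that("log2_cpm arithmetic, pseudocount and scale invariance", {
  m <- matrix(c(999, 1e6 - 999, 0, 1e6), 2,
              dimnames = list(c("g1", "g2"), c("A", "B")))
  norm <- log2_cpm(m)
  expect_equal(norm["g1", "A"], log2(1000), tolerance = 1e-9)
  expect_equal(norm["g1", "B"], 0)  # zero count -> exactly 0
  # doubling all counts (hence library sizes) leaves CPM unchanged
  expect_equal(unclass(log2_cpm(m * 2)), unclass(norm),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(attr(norm, "unit"), "log2-CPM")
  expect_error(log2_cpm(m, factors = c(-1, 1)), "positive")
})

test_that("detectability filter thresholds are inclusive", {
  m <- matrix(c(5, 5, 0, 0,
                5, 0, 0, 0,
                4, 4, 4, 4,
                9, 9, 9, 9), 4, byrow = TRUE,
              dimnames = list(c("boundary", "rare", "low", "high"),
                              paste0("s", 1:4)))
  kept <- detectability_filter(m)
  expect_true("boundary" %in% kept)   # 2/4 = 50% at exactly 5 counts
  expect_true("high" %in% kept)
  expect_false("rare" %in% kept)
  expect_false("low" %in% kept)       # never reaches 5
  # TPM mode: threshold is 1 TPM
  tkept <- detectability_filter(m, tpm_mode = TRUE)
  expect_true(all(c("boundary", "low", "high") %in% tkept))
})

test_that("meta-signal equals the z-score for single or duplicated candidates", {
  set.seed(42)
  m <- matrix(rnorm(60, 8), 3, 20,
              dimnames = list(c("a", "b", "c"), sprintf("s%02d", 1:20)))
  m["b", ] <- m["a", ]
  ms1 <- meta_signal(m, "a")
  expect_equal(unname(ms1), unname((m["a", ] - mean(m["a", ])) / sd(m["a", ])))
  expect_equal(cor(ms1, m["a", ], method = "spearman"), 1)
  expect_equal(meta_signal(m, c("a", "b")), ms1)
  m["c", ] <- 5
  expect_warning(meta_signal(m, c("a", "c")), "zero-variance")
})

test_that("meta-signal recovers the latent on synthetic cohorts", {
  sim <- gen_bulk_cohort(bulk_sim_params(n_samples = 200, n_genes = 800, seed = 31))
  norm <- log2_cpm(sim$counts, compute_tmm_factors(sim$counts))
  ms <- meta_signal(norm, sim$signature_genes$cDC1)
  expect_gt(cor(ms, sim$latents[, "cDC1"], method = "spearman"), 0.7)
})

test_that("importance filter keeps the concordant and drops noise", {
  set.seed(7)
  n <- 100
  meta <- rnorm(n)
  m <- rbind(same = meta, anti = -meta,
             noise = matrix(rnorm(20 * n), 20))
  rownames(m) <- c("same", "anti", paste0("noise", 1:20))
  colnames(m) <- paste0("s", 1:n)
  kept <- gene_importance_filter(m, rownames(m), meta)
  expect_true("same" %in% kept)
  expect_false("anti" %in% kept)  # rule is one-sided in sign
  # independent noise genes survive rarely (null rho > 0.4 at n = 100)
  expect_lt(mean(paste0("noise", 1:20) %in% kept), 0.05 + 1e-9)
  st <- attr(kept, "stats")
  expect_equal(st$rho[st$gene == "same"], 1)
  expect_error(gene_importance_filter(m, rownames(m), rep(1, n)), "constant")
})

test_that("cross-cohort intersection and ordering", {
  expect_setequal(cross_cohort_intersect(list(c("A", "B", "C"), c("B", "C", "D"))),
                  c("B", "C"))
  expect_equal(cross_cohort_intersect(list(c("X", "Y"))), c("X", "Y"))
  expect_warning(out <- cross_cohort_intersect(list("A", "B")), "empty")
  expect_length(out, 0)
  s1 <- structure(c("A", "B"), rho = c(A = 0.5, B = 0.9))
  s2 <- structure(c("A", "B"), rho = c(A = 0.6, B = 0.8))
  expect_equal(cross_cohort_intersect(list(s1, s2)), c("B", "A"))
})
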