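# Response-group rank tests and correlation panels.

clin3v3 <- data.frame(sample_id = paste0("s", 1:6),
                      response = c("PR", "PR", "CR", "PD", "PD", "PD"),
                      stringsAsFactors = FALSE)

test_that("exact two-sided Mann-Whitney on fully separated small groups", {
  scores <- setNames(c(1, 2, 3, 4, 5, 6), paste0("s", 1:6))
  res <- group_compare(scores, clin3v3)
  row <- res[res$pair == "CR/PR vs PD", ]
  expect_equal(row$U, 0)
  expect_equal(row$p, 0.1)           # 2 * 1/20, enumeration of orderings
  expect_equal(row$note, "exact")
  expect_match(res$note[res$pair == "CR/PR vs SD"], "skipped")
})

test_that("identical groups give p = 1", {
  scores <- setNames(rep(c(1, 2, 3), 2), paste0("s", 1:6))
  res <- group_compare(scores, clin3v3)
  expect_equal(res$p[res$pair == "CR/PR vs PD"], 1)
})

test_that("U test is invariant to the monotone 1-10 rescaling (regression)", {
  set.seed(14)
  scores <- setNames(rnorm(40), paste0("s", 1:40))
  clin <- data.frame(sample_id = paste0("s", 1:40),
                     response = rep(c("PR", "SD", "PD", "PD"), 10))
  p_raw <- group_compare(scores, clin)$p
  p_scaled <- group_compare(setNames(minmax_rescale(scores), names(scores)),
                            clin)$p
  expect_equal(p_raw, p_scaled)
})

test_that("a 1-SD response effect is detected in most synthetic cohorts", {
  hits <- 0
  for (s in 1:10) {
    sim <- gen_bulk_cohort(bulk_sim_params(n_samples = 100, n_genes = 600,
                                           response_effect = 1, seed = 400 + s))
    norm <- log2_cpm(sim$counts, compute_tmm_factors(sim$counts))
    sc <- enrichment_score(norm, gene_signature("cDC1", sim$signature_genes$cDC1))
    res <- group_compare(sc, sim$clinical)
    p <- res$p[res$pair == "CR/PR vs PD"]
    hits <- hits + (is.finite(p) && p < 0.05)
  }
  expect_gte(hits, 8)
})

test_that("correlation panel: identities, sampling accuracy, degeneracies", {
  set.seed(5)
  x <- rnorm(500)
  y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(500)
  res <- correlation_panel(list(a = x, self = x, neg = -x, b = y))
  get <- function(v1, v2) res[res$var1 == v1 & res$var2 == v2, ]
  expect_equal(get("a", "self")$r, 1)
  expect_equal(get("a", "neg")$r, -1)
  expect_lt(abs(get("a", "b")$r - 0.6), 0.08)
  resz <- correlation_panel(list(a = x[1:10], z = rep(1, 10)))
  expect_true(is.na(resz$r))
  expect_match(resz$note, "zero variance")
  # spearman route
  ress <- correlation_panel(list(a = x[1:50], b = exp(x[1:50])), "spearman")
  expect_equal(ress$r, 1)
})
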