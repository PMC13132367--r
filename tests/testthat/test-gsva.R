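# Kernel-CDF rank enrichment scoring vs an independently coded oracle,
# plus rescaling.

fixed_toy_matrix <- function(p = 20, n = 6, seed = 99) {
  set.seed(seed)
  m <- matrix(rnorm(p * n, mean = 6, sd = 2), p, n,
              dimnames = list(sprintf("G%02d", seq_len(p)),
                              sprintf("S%d", seq_len(n))))
  m
}

test_that("scores match the clean-room oracle to 1e-8 on the toy matrix", {
  m <- fixed_toy_matrix()
  sig <- c("G01", "G04", "G07", "G13", "G19")
  expect_equal(enrichment_score(m, sig), oracle_gsva(m, sig),
               tolerance = 1e-8)
  # and with a different tau
  expect_equal(enrichment_score(m, sig, tau = 0.75),
               oracle_gsva(m, sig, tau = 0.75), tolerance = 1e-8)
})

test_that("identical columns give identical scores (exchangeability)", {
  m <- fixed_toy_matrix(15, 1)
  m <- m[, rep(1, 5)]
  colnames(m) <- paste0("S", 1:5)
  expect_warning(sc <- enrichment_score(m, c("G01", "G02", "G03")),
                 "zero-variance")
  expect_equal(unname(sc), rep(unname(sc[1]), 5))
})

test_that("forcing signature genes to extreme ranks orders the scores", {
  set.seed(3)
  m <- fixed_toy_matrix(20, 4)
  sig <- c("G01", "G02", "G03")
  m[sig, 1] <- max(m) + 5   # top ranks in sample 1
  m[sig, 2] <- min(m) - 5   # bottom ranks in sample 2
  sc <- enrichment_score(m, sig)
  expect_gt(sc[["S1"]], sc[["S2"]])
})

test_that("score properties: bounds, sample permutation, absent genes", {
  for (s in 1:5) {
    m <- fixed_toy_matrix(30, 8, seed = s)
    sig <- sample(rownames(m), 6)
    sc <- enrichment_score(m, sig)
    expect_true(all(abs(sc) <= 1))
    perm <- sample(ncol(m))
    expect_equal(unname(enrichment_score(m[, perm], sig)), unname(sc[perm]),
                 tolerance = 1e-12)
    expect_equal(enrichment_score(m, c(sig, "NOT_A_GENE")), sc)
  }
  expect_error(enrichment_score(fixed_toy_matrix(), c("G01", "ABSENT")),
               "fewer than 2")
})

test_that("min-max rescaling maps onto [1, 10] with endpoints attained", {
  expect_equal(minmax_rescale(c(-0.5, 0, 0.5)), c(1, 5.5, 10))
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(20)
    r <- minmax_rescale(x)
    expect_equal(range(r), c(1, 10))
    expect_equal(which.min(r), which.min(x))
  }
  expect_warning(r <- minmax_rescale(rep(2, 4)), "degenerate")
  expect_equal(r, rep(5.5, 4))
})

test_that("score_signatures tabulates raw and rescaled values per signature", {
  m <- fixed_toy_matrix(25, 6)
  tab <- score_signatures(m, list(cDC1 = c("G01", "G02", "G03"),
                                  CD8 = c("G10", "G11", "G12")))
  expect_equal(nrow(tab), 12)
  expect_true(all(tab$rescaled_score >= 1 & tab$rescaled_score <= 10))
})
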