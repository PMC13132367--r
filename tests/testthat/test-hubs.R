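# QC, candidate detection, consensus, hub construction and classification.

test_that("qc_filter drops cells strictly below the molecule threshold", {
  m <- matrix(c(49, 50, 51), 1, dimnames = list("BATF3", NULL))
  ctm <- toy_ctm(rbind(m, OTHER = c(0, 0, 0)))
  out <- qc_filter(ctm, 50)
  expect_equal(ncol(out$counts), 2)
  expect_equal(unname(out$totals), c(50, 51))
  empty <- qc_filter(toy_ctm(matrix(0, 2, 3,
                                    dimnames = list(c("BATF3", "X"), NULL))), 50)
  expect_equal(ncol(empty$counts), 0)
})

test_that("threshold detection finds the valley between separated modes", {
  set.seed(1)
  n <- 200
  batf3 <- c(sample(0:1, n / 2, TRUE), sample(20:30, n / 2, TRUE))
  counts <- rbind(BATF3 = batf3, CLEC9A = 0, XCR1 = 0,
                  CD8A = rpois(n, 3), CD8B = rpois(n, 3),
                  BG1 = rpois(n, 5))
  ctm <- toy_ctm(counts)
  # CD8 sums here are unimodal Poisson -> its Otsu fallback warning is expected
  calls <- suppressWarnings(detect_threshold(ctm))
  thr <- attr(calls, "thresholds")
  expect_gt(thr[["cDC1"]], log1p(1))
  expect_lt(thr[["cDC1"]], log1p(20))
  expect_true(all(calls$cDC1[(n / 2 + 1):n]))
  expect_false(any(calls$cDC1[1:(n / 2)]))
})

test_that("all-zero canonical sums yield no positives with a warning", {
  counts <- rbind(BATF3 = 0, CLEC9A = 0, XCR1 = 0,
                  CD8A = c(rep(0, 10), rep(9, 10)), CD8B = 1, BG1 = 5)
  expect_warning(calls <- detect_threshold(toy_ctm(counts)), "zero")
  expect_false(any(calls$cDC1))
  expect_error(detect_threshold(toy_ctm(counts[-1, , drop = FALSE])),
               "BATF3")
})

test_that("the KDE valley matches a brute-force grid search", {
  ctm <- gen_spatial_transcriptome(st_sim_params(n_cells = 1000, seed = 44))
  calls <- detect_threshold(ctm)
  s <- attr(calls, "sums")[, "cDC1"]
  d <- density(s, bw = max(bw.nrd0(s), 0.5), n = 512)
  peaks <- integer(0)
  for (i in 2:511) if (d$y[i] > d$y[i - 1] && d$y[i] > d$y[i + 1])
    peaks <- c(peaks, i)
  top2 <- sort(peaks[order(-d$y[peaks])][1:2])
  valley <- d$x[top2[1] + which.min(d$y[top2[1]:top2[2]]) - 1L]
  expect_equal(attr(calls, "thresholds")[["cDC1"]], valley, tolerance = 1e-12)
})

test_that("cluster detection recovers planted types and is seeded", {
  ctm <- gen_spatial_transcriptome(st_sim_params(n_cells = 800, seed = 15))
  clu <- detect_cluster(ctm, seed = 15)
  truth <- ctm$cells$true_type
  cdc1_ok <- mean(clu$call[truth == "cDC1"] %in% c("cDC1", "mixture"))
  expect_gte(cdc1_ok, 0.95)
  expect_identical(clu$call, detect_cluster(ctm, seed = 15)$call)
  # null folds -> no cluster is canonically elevated
  ctm0 <- gen_spatial_transcriptome(st_sim_params(n_cells = 400, marker_fold = 1,
                                                  activation_fold = 1, seed = 5))
  clu0 <- detect_cluster(ctm0, seed = 5)
  expect_true(all(clu0$call == "none"))
  expect_warning(detect_cluster(toy_ctm(matrix(rpois(60, 5), 6, 10,
    dimnames = list(c("BATF3", "CLEC9A", "XCR1", "CD8A", "CD8B", "B"), NULL))),
    k = 15, seed = 1), "reduced")
})

test_that("consensus applies agreement, veto, and the canonical-sum tie-break", {
  thr <- data.frame(cell_id = c("a", "b", "c", "d"),
                    cDC1 = c(TRUE, TRUE, TRUE, FALSE),
                    CD8 = c(FALSE, FALSE, TRUE, FALSE),
                    call = c("cDC1", "cDC1", "both", "none"),
                    stringsAsFactors = FALSE)
  attr(thr, "sums") <- matrix(c(5, 5, 7, 0,   # cDC1 sums
                                0, 0, 3, 0),  # CD8 sums
                              ncol = 2, dimnames = list(letters[1:4],
                                                        c("cDC1", "CD8")))
  clu <- data.frame(cell_id = c("a", "b", "c", "d"), cluster = 1:4,
                    call = c("cDC1", "none", "mixture", "none"),
                    stringsAsFactors = FALSE)
  cons <- consensus_candidates(thr, clu)
  expect_equal(cons$consensus, c("cDC1", "none", "cDC1", "none"))
  expect_error(consensus_candidates(thr, clu[c(2, 1, 3, 4), ]), "aligned")
})

test_that("hub membership obeys the radius cut and the brute-force oracle", {
  counts <- matrix(rpois(15, 4), 5, 3,
                   dimnames = list(c("BATF3", "XCR1", "CLEC9A", "CD8A", "G"), NULL))
  ctm <- toy_ctm(counts, x = c(0, 5, 15), y = c(0, 0, 0))
  hs <- build_hubs(ctm, ctm$cells$cell_id[1], radius_um = 10)
  expect_equal(hs$hubs$n_cells, 2)
  expect_setequal(hs$members[[1]], ctm$cells$cell_id[1:2])
  expect_equal(unname(hs$counts[, 1]), unname(rowSums(counts[, 1:2])))
  # isolated candidate keeps only itself
  iso <- build_hubs(ctm, ctm$cells$cell_id[3], radius_um = 4)
  expect_equal(iso$hubs$n_cells, 1)
  expect_equal(unname(iso$counts[, 1]), unname(counts[, 3]))

  # oracle equivalence on a 1000-cell instance
  ctm2 <- gen_spatial_transcriptome(st_sim_params(n_cells = 1000, seed = 33))
  cand <- ctm2$cells$cell_id[ctm2$cells$true_type != "other"]
  hs2 <- build_hubs(ctm2, cand, radius_um = 10)
  for (k in sample(length(cand), 25)) {
    i <- match(cand[k], ctm2$cells$cell_id)
    d <- sqrt((ctm2$cells$x_um - ctm2$cells$x_um[i])^2 +
              (ctm2$cells$y_um - ctm2$cells$y_um[i])^2)
    expect_setequal(hs2$members[[k]], ctm2$cells$cell_id[d <= 10])
  }
})

test_that("hub construction is invariant to cell order and rigid motions", {
  ctm <- gen_spatial_transcriptome(st_sim_params(n_cells = 500, seed = 20))
  cand <- ctm$cells$cell_id[ctm$cells$true_type == "cDC1"]
  hs <- classify_hubs(build_hubs(ctm, cand))
  set.seed(1)
  perm <- sample(ncol(ctm$counts))
  ctm_p <- cell_transcript_matrix(ctm$counts[, perm], ctm$cells[perm, ])
  hs_p <- classify_hubs(build_hubs(ctm_p, cand))
  expect_equal(hs_p$counts, hs$counts)
  expect_equal(hs_p$hubs$class, hs$hubs$class)
  # rotation + translation
  th <- 1.1
  cells_r <- ctm$cells
  cells_r$x_um <- cos(th) * ctm$cells$x_um - sin(th) * ctm$cells$y_um + 50
  cells_r$y_um <- sin(th) * ctm$cells$x_um + cos(th) * ctm$cells$y_um - 20
  hs_r <- classify_hubs(build_hubs(cell_transcript_matrix(ctm$counts, cells_r),
                                   cand))
  expect_equal(hs_r$hubs$n_cells, hs$hubs$n_cells)
  expect_equal(hs_r$counts, hs$counts)
})

test_that("classification follows the single-molecule rule", {
  counts <- matrix(0, 4, 3, dimnames = list(c("BATF3", "XCR1", "CLEC9A", "G"),
                                            NULL))
  counts["XCR1", 1] <- 1
  counts["G", ] <- 5
  ctm <- toy_ctm(counts, x = c(0, 100, 200), y = c(0, 0, 0))
  hs <- classify_hubs(build_hubs(ctm, ctm$cells$cell_id))
  expect_equal(hs$hubs$class, c("cDC1-rich", "cDC1-devoid", "cDC1-devoid"))
})

test_that("consensus-cDC1-centered hubs are rich by construction", {
  ctm <- gen_spatial_transcriptome(st_sim_params(n_cells = 800, seed = 9))
  cons <- consensus_candidates(detect_threshold(ctm),
                               detect_cluster(ctm, seed = 9))
  hs <- classify_hubs(build_hubs(ctm, cons))
  cdc1_centered <- hs$hubs$center_type == "cDC1"
  expect_true(all(hs$hubs$class[cdc1_centered] == "cDC1-rich"))
})

test_that("hub densities partition into rich and devoid", {
  h <- data.frame(class = c("cDC1-rich", "cDC1-rich", "cDC1-devoid"))
  out <- hub_density_by_group(list(s1 = h), areas_mm2 = c(s1 = 0.2),
                              n_cells = c(s1 = 500), labels = c(s1 = "R"))
  expect_equal(out$density_mm2, c(10, 5))
  expect_equal(sum(out$n_hubs), 3)
  expect_equal(out$density_per_1k_cells, c(4, 2))
})
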