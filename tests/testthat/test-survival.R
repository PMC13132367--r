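# Median-split log-rank and decile Cox association.

sim_surv <- function(n, loghr_per_unit, covariate, seed, censor = 30) {
  set.seed(seed)
  t_raw <- rexp(n, rate = 0.1 * exp(loghr_per_unit * covariate))
  list(time = pmin(t_raw, censor), event = as.integer(t_raw <= censor))
}

test_that("identical arm survival gives a null log-rank", {
  values <- rep(c(1, 9), each = 10)           # low/high split
  time <- rep(c(2, 4, 6, 8, 12, 3, 5, 7, 9, 11), 2)  # same curves per arm
  event <- rep(1, 20)
  res <- survival_median_split(values, time, event)
  expect_lt(res$chisq, 0.01)
  expect_gt(res$p, 0.9)
  expect_true(all(c("arm", "time", "n_risk", "survival") %in% names(res$km)))
})

test_that("median split detects a strong hazard effect and is scale-free", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    grp <- rep(0:1, each = 100)               # HR 0.3 for the high group
    sv <- sim_surv(200, log(0.3), grp, seed = s)
    res <- survival_median_split(grp + runif(200, 0, 0.1), sv$time, sv$event)
    hits <- hits + (res$p < 0.05)
  }
  expect_gte(hits, 9)
  # months -> days leaves the statistic unchanged (rank invariance)
  sv <- sim_surv(100, 0, rnorm(100), seed = 77)
  v <- rnorm(100)
  a <- survival_median_split(v, sv$time, sv$event)
  b <- survival_median_split(v, sv$time * 30.44, sv$event)
  expect_equal(a$chisq, b$chisq, tolerance = 1e-9)
  expect_error(survival_median_split(rep(1, 100), sv$time, sv$event), "equal")
})

test_that("ties go to the low arm in the median split", {
  values <- c(1, 1, 1, 5, 9, 9)   # median 3 -> {1,1,1} low; exact median ties low
  arm <- survival_median_split(values, 1:6, rep(1, 6))$arm
  expect_equal(as.character(arm), c("low", "low", "low", "high", "high", "high"))
  values2 <- c(1, 2, 2, 2, 8, 9)  # median 2: the three 2s all go low
  arm2 <- survival_median_split(values2, 1:6, rep(1, 6))$arm
  expect_equal(sum(arm2 == "low"), 4)
})

test_that("decile Cox: null coverage, parameter recovery, rank invariance", {
  # null: covariate independent of hazard
  set.seed(10)
  v <- rnorm(500)
  sv <- sim_surv(500, 0, v * 0, seed = 10)
  res <- cox_decile(v, sv$time, sv$event)
  expect_gt(res$hr, 0.9); expect_lt(res$hr, 1.1)

  # per-decile log-hazard -0.1 -> HR ~ 0.905
  set.seed(11)
  v2 <- runif(500)
  dec <- decile_index(v2)
  sv2 <- sim_surv(500, -0.1, dec, seed = 11)
  res2 <- cox_decile(v2, sv2$time, sv2$event)
  ci <- res2$coef + c(-1.96, 1.96) * res2$se
  expect_gt(-0.1, ci[1]); expect_lt(-0.1, ci[2])
  expect_lt(abs(res2$hr - 0.905), 0.05)

  # deciles depend only on ranks: exp() transform changes nothing
  res3 <- cox_decile(exp(v2), sv2$time, sv2$event)
  expect_equal(res3$hr, res2$hr, tolerance = 1e-12)
  expect_error(cox_decile(rep(2, 10), 1:10, rep(1, 10)), "constant")
  expect_error(cox_decile(1:10, 1:10, rep(0, 10)), "event")
})
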