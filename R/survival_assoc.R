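# Survival association of cDC1 abundance: median split log-rank and
# decile Cox model.

#' Median-split log-rank test with Kaplan-Meier curves
#'
#' Samples are classified high if their stratifier value is strictly above
#' the median (ties go to the low arm, a deterministic and conservative
#' rule) and the two arms are compared with the standard log-rank test.
#'
#' @param values per-sample stratifier (e.g. cDC1 density); must not be
#'   constant.
#' @param time survival time (any unit; the test is rank-invariant).
#' @param event event indicator (1 = event, 0 = censored).
#' @return List: \code{chisq}, \code{p} (1 df), \code{arm} (factor low/high),
#'   \code{km} (data.frame of time, n_risk, survival per arm).
#' @export
survival_median_split <- function(values, time, event) {
  if (length(unique(values)) < 2L) stop_("stratifier values are all equal")
  if (any(time < 0)) stop_("negative survival times")
  arm <- factor(ifelse(values > median(values), "high", "low"),
                levels = c("low", "high"))
  if (min(table(arm)) < 2L) stop_("each arm needs >= 2 samples after the split")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ arm)
  fit <- survival::survfit(survival::Surv(time, event) ~ arm)
  strata <- rep(names(fit$strata), fit$strata)
  km <- data.frame(arm = sub("^arm=", "", strata), time = fit$time,
                   n_risk = fit$n.risk, survival = fit$surv,
                   stringsAsFactors = FALSE)
  list(chisq = sd_$chisq, p = pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
       arm = arm, km = km)
}

#' Decile index of a covariate (rank-based, ties collapse)
#'
#' @param values numeric vector.
#' @return Integer deciles 1-10 (\code{ceiling(10 * rank / n)} with maximum
#'   tie ranks, so any order-preserving transform of \code{values} yields
#'   identical deciles).
#' @export
decile_index <- function(values) {
  as.integer(ceiling(10 * rank(values, ties.method = "max") / length(values)))
}

#' Cox proportional-hazards model on covariate deciles
#'
#' The covariate is converted to its decile index (1-10 by empirical ranks,
#' ties collapsing into the same decile) and entered as a numeric covariate
#' in a Cox model with Efron tie handling. The reported hazard ratio is per
#' decile increase.
#'
#' @param values per-sample covariate (non-constant).
#' @param time survival time.
#' @param event event indicator (>= 1 event required).
#' @return List: \code{hr} (per decile increase), \code{coef}, \code{se},
#'   \code{p}, \code{deciles}.
#' @export
cox_decile <- function(values, time, event) {
  if (length(unique(values)) < 2L) stop_("covariate is constant")
  if (sum(event) < 1L) stop_("at least one event required")
  dec <- decile_index(values)
  fit <- survival::coxph(survival::Surv(time, event) ~ dec, ties = "efron")
  s <- summary(fit)
  list(hr = unname(exp(coef(fit))), coef = unname(coef(fit)),
       se = unname(s$coefficients[, "se(coef)"]),
       p = unname(s$coefficients[, "Pr(>|z|)"]), deciles = dec)
}
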