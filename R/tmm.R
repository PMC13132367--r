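# Trimmed mean of M-values normalization (Robinson & Oshlack 2010).

#' Compute TMM normalization factors
#'
#' Trimmed-mean-of-M-values factors for between-sample normalization of
#' RNA-seq counts. The reference sample is the one whose upper-quartile
#' count fraction is closest to the mean upper quartile; per sample,
#' gene-wise log ratios (M) and average log expression (A) against the
#' reference are trimmed (30\% on M, 5\% on A) and combined with
#' inverse-asymptotic-variance weights. Factors are renormalized to have
#' geometric mean exactly 1; the effective library size is
#' \code{lib_size * factor}.
#'
#' @param counts a \code{\link{count_matrix}} or gene-by-sample matrix
#'   (>= 2 samples).
#' @param logratio_trim fraction trimmed on M (default 0.3).
#' @param sum_trim fraction trimmed on A (default 0.05).
#' @return Named numeric vector of per-sample factors, geometric mean 1.
#' @export
compute_tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  cm <- as_count_matrix(counts)
  x <- cm$counts
  if (ncol(x) < 2L) stop_("TMM needs at least 2 samples")
  lib <- cm$lib_sizes
  zero <- which(lib == 0)
  if (length(zero))
    stop_("sample(s) with all-zero counts: ",
          paste(colnames(x)[zero], collapse = ", "))

  # Reference column: upper-quartile fraction closest to the mean.
  f75 <- apply(x, 2, quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))

  f <- vapply(seq_len(ncol(x)), function(j) {
    tmm_pair(x[, j], x[, ref], lib[j], lib[ref], logratio_trim, sum_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(x))
}

# One observation column against the reference; returns 2^(weighted trimmed
# mean of M-values).
tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim) {
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  keep <- is.finite(m) & is.finite(a)
  m <- m[keep]; a <- a[keep]; v <- v[keep]
  if (length(m) == 0L || max(abs(m)) < 1e-6) return(1)

  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2)) return(1)
  2^(sum(m[keep2] / v[keep2]) / sum(1 / v[keep2]))
}
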