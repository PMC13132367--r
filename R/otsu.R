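# Otsu and iterative triclass Otsu thresholding of marker intensities.

#' Otsu threshold on a 256-bin histogram
#'
#' Exhaustive search over bin boundaries for the threshold maximizing the
#' between-class variance. Ties (e.g. two separated point masses, where every
#' boundary between them is equally good) are broken by the middle candidate
#' bin, keeping the threshold centered and deterministic.
#'
#' @param values numeric vector (>= 2 distinct values).
#' @param n_bins histogram resolution (default 256).
#' @return Threshold value (a bin boundary); positivity is \code{value > thr}.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (length(values) < 2L || rng[1] == rng[2])
    stop_("Otsu thresholding needs >= 2 distinct values")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  cnt <- tabulate(pmin(findInterval(values, edges, rightmost.closed = TRUE),
                       n_bins), nbins = n_bins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w <- cumsum(cnt)
  s <- cumsum(cnt * mids)
  n <- w[n_bins]; tot <- s[n_bins]
  w0 <- w[-n_bins]; w1 <- n - w0
  mu0 <- s[-n_bins] / w0
  mu1 <- (tot - s[-n_bins]) / w1
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[!is.finite(bcv)] <- -Inf
  best <- which(bcv == max(bcv))
  k <- best[ceiling(length(best) / 2)]
  edges[k + 1L]
}

#' Iterative triclass Otsu threshold
#'
#' Repeatedly applies Otsu's method: after each pass, values above the upper
#' class mean are committed to foreground, values below the lower class mean
#' to background, and the region between the two class means is
#' "to-be-determined" and re-thresholded. Iteration stops when the TBD
#' region is stable or holds under \code{min_frac} of the original values;
#' the threshold of the final pass is returned. Designed for strongly skewed
#' marker-intensity distributions where a single Otsu pass over-calls the
#' bright tail.
#'
#' @param values numeric vector of marker intensities (>= 2 distinct values).
#' @param min_frac stop when the TBD region falls below this fraction of the
#'   input (default 0.01).
#' @param max_iter safety cap on iterations.
#' @param n_bins histogram resolution per pass.
#' @return Final threshold; positivity is \code{value > thr}.
#' @export
triclass_otsu <- function(values, min_frac = 0.01, max_iter = 100L,
                          n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) < 2L || min(values) == max(values))
    stop_("triclass Otsu needs >= 2 distinct values")
  n0 <- length(values)
  region <- values
  thr <- NA_real_
  for (it in seq_len(max_iter)) {
    thr <- otsu_threshold(region, n_bins)
    mu0 <- mean(region[region <= thr])
    mu1 <- mean(region[region > thr])
    tbd <- region[region > mu0 & region <= mu1]
    if (length(tbd) == length(region) && isTRUE(all.equal(sort(tbd), sort(region))))
      break  # stable
    if (length(tbd) < max(2, min_frac * n0) || length(unique(tbd)) < 2L)
      break
    region <- tbd
  }
  thr
}

#' Triclass-Otsu thresholds for a set of markers
#'
#' @param table cell table with one intensity column per marker.
#' @param markers marker column names (default BATF3, CD3, CD8).
#' @return Named numeric vector of per-marker positivity thresholds, each
#'   within the observed intensity range.
#' @export
marker_thresholds <- function(table, markers = c("BATF3", "CD3", "CD8")) {
  miss <- setdiff(markers, names(table))
  if (length(miss)) stop_("missing marker column(s): ", paste(miss, collapse = ", "))
  vapply(markers, function(m) triclass_otsu(table[[m]]), numeric(1))
}
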