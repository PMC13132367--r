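# Kernel-CDF rank enrichment scoring (the 'gsva' method of Hänzelmann,
# Castelo & Guinney 2013), implemented directly for continuous log-scale
# expression input.

#' Per-sample gene-set enrichment score (kernel-CDF rank statistic)
#'
#' For each gene, a Gaussian-kernel estimate of the expression CDF across
#' samples (bandwidth = gene SD / 4) expresses each sample's value relative
#' to the gene's cohort distribution. Within each sample, genes are ordered
#' by that statistic and assigned the symmetric rank score |i - p/2|; a
#' weighted Kolmogorov-Smirnov random walk over the ordered genes (weight
#' exponent tau, default 1) then contrasts signature genes against the rest.
#' The score is the maximum positive deviation plus the minimum (negative)
#' deviation of the walk, so it lies in [-1, 1].
#'
#' Signature genes absent from the matrix are ignored; zero-variance genes
#' are excluded from the ranking with a warning.
#'
#' @param norm normalized log-scale gene-by-sample matrix (>= 2 samples).
#' @param sig a \code{\link{gene_signature}} or character vector of genes
#'   (>= 2 present in the matrix).
#' @param tau rank-weight exponent (default 1).
#' @return Named per-sample numeric vector of scores in [-1, 1].
#' @export
enrichment_score <- function(norm, sig, tau = 1) {
  genes <- if (inherits(sig, "gene_signature")) sig$genes else as.character(sig)
  if (ncol(norm) < 2L) stop_("enrichment scoring needs >= 2 samples")
  sds <- apply(norm, 1, sd)
  if (any(sds == 0))
    warning("zero-variance gene(s) held at mid-CDF in enrichment ranking: ",
            paste(head(rownames(norm)[sds == 0], 5), collapse = ", "),
            if (sum(sds == 0) > 5) ", ..." else "")
  present <- intersect(genes, rownames(norm))
  if (length(present) < 2L)
    stop_("fewer than 2 signature genes present in the matrix")

  z <- gene_kcdf(norm)
  p <- nrow(z)
  in_set <- rownames(z) %in% present

  scores <- vapply(seq_len(ncol(z)), function(j) {
    ord <- order(z[, j], decreasing = TRUE)
    rank_stat <- numeric(p)
    rank_stat[ord] <- abs(seq_len(p) - p / 2)
    ks_walk_es(in_set[ord], rank_stat[ord]^tau)
  }, numeric(1))
  setNames(scores, colnames(z))
}

# Gaussian-kernel CDF estimate per gene: z[i, j] = mean_k Phi((x_ij - x_ik)/h_i)
# with h_i = sd_i / 4. A constant gene sits at its own CDF midpoint (the
# h -> 0 limit of the exchangeable case), keeping degenerate inputs
# well-defined.
gene_kcdf <- function(x) {
  out <- x
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    h <- sd(v) / 4
    out[i, ] <- if (h == 0) rep(0.5, length(v))
                else rowMeans(pnorm(outer(v, v, "-") / h))
  }
  out
}

# Weighted KS random walk: inside steps weighted by w, outside steps uniform;
# returns max positive + min negative deviation (difference-of-extrema score).
ks_walk_es <- function(inside, w) {
  w_in <- w * inside
  denom_in <- sum(w_in)
  n_out <- sum(!inside)
  if (denom_in == 0 || n_out == 0) return(0)
  walk <- cumsum(w_in) / denom_in - cumsum(!inside) / n_out
  max(c(walk, 0)) + min(c(walk, 0))
}

#' Min-max rescale scores to a fixed display range
#'
#' Linear map of a score vector onto [lo, hi] computed within one cohort and
#' signature, used for cross-cohort display only; statistical tests always
#' run on the unscaled values. A constant vector maps to the midpoint with a
#' warning.
#'
#' @param x numeric scores (>= 1 value).
#' @param lo,hi target range endpoints (defaults 1 and 10).
#' @return Rescaled numeric vector with min -> lo and max -> hi.
#' @export
minmax_rescale <- function(x, lo = 1, hi = 10) {
  if (length(x) == 0L) stop_("empty score vector")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("degenerate score vector: all values rescaled to the midpoint")
    return(rep((lo + hi) / 2, length(x)))
  }
  lo + (x - rng[1]) * (hi - lo) / (rng[2] - rng[1])
}

#' Score several signatures and tabulate raw plus rescaled values
#'
#' @param norm normalized gene-by-sample matrix.
#' @param signatures named list of \code{\link{gene_signature}} objects or
#'   character vectors.
#' @param tau rank-weight exponent passed to \code{\link{enrichment_score}}.
#' @return data.frame with columns \code{sample_id}, \code{signature},
#'   \code{raw_score}, \code{rescaled_score} (rescaled within this
#'   cohort/signature to [1, 10]).
#' @export
score_signatures <- function(norm, signatures, tau = 1) {
  if (is.null(names(signatures)))
    names(signatures) <- vapply(signatures, function(s)
      if (inherits(s, "gene_signature")) s$name else "custom", character(1))
  out <- lapply(names(signatures), function(nm) {
    raw <- enrichment_score(norm, signatures[[nm]], tau = tau)
    data.frame(sample_id = names(raw), signature = nm, raw_score = unname(raw),
               rescaled_score = minmax_rescale(unname(raw)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
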