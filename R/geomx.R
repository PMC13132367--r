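# Tumor-compartment correlation stage for probe-based spatial profiling.

#' Median-ratio size factors
#'
#' DESeq-style size factors: per sample, the median ratio of counts to the
#' gene-wise geometric mean, computed over genes expressed in every sample.
#'
#' @param counts gene-by-sample matrix of raw counts.
#' @return Named per-sample size factors.
#' @export
median_ratio_factors <- function(counts) {
  x <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  logx <- log(x)
  geo <- rowMeans(logx)
  use <- is.finite(geo)
  if (!any(use)) stop_("no gene is expressed in all samples")
  sf <- apply(logx[use, , drop = FALSE], 2, function(col) exp(median(col - geo[use])))
  sf
}

#' Anchor-gene Spearman correlations in the tumor compartment
#'
#' Samples below \code{min_total} raw counts are removed (QC), counts are
#' normalized by median-ratio size factors, and the Spearman correlation of
#' the anchor gene (BATF3, the cDC1 surrogate) with each partner transcript
#' is reported with a two-sided p-value.
#'
#' @param counts gene-by-sample raw count matrix (or
#'   \code{\link{count_matrix}}).
#' @param anchor_gene anchor transcript (default \code{"BATF3"}).
#' @param partners character vector of partner transcripts.
#' @param min_total per-sample raw-count QC threshold (default 50,000;
#'   samples with strictly fewer are dropped).
#' @return data.frame: \code{partner}, \code{rho}, \code{p}, \code{n};
#'   attribute \code{n_excluded}.
#' @export
tumor_compartment_correlations <- function(counts, anchor_gene = "BATF3",
                                           partners, min_total = 50000) {
  x <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  miss <- setdiff(c(anchor_gene, partners), rownames(x))
  if (length(miss)) stop_("gene(s) not in matrix: ", paste(miss, collapse = ", "))
  keep <- colSums(x) >= min_total
  n_excl <- sum(!keep)
  x <- x[, keep, drop = FALSE]
  if (ncol(x) < 3L) stop_("fewer than 3 samples pass the ", min_total,
                          "-count QC filter")
  sf <- median_ratio_factors(x)
  nx <- sweep(x, 2, sf, "/")
  a <- nx[anchor_gene, ]
  if (sd(a) == 0) stop_("anchor gene '", anchor_gene, "' is constant")
  rows <- lapply(partners, function(g) {
    st <- spearman_test(a, nx[g, ])
    data.frame(partner = g, rho = st[["rho"]], p = st[["p"]], n = ncol(nx),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), n_excluded = n_excl)
}
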