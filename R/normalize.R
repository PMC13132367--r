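# Normalization and cross-cohort signature derivation.

#' log2 counts-per-million with effective library sizes
#'
#' \code{log2(count / (lib_size * factor) * 1e6 + 1)}: the +1 pseudocount
#' makes zero counts map to exactly 0 and keeps values non-negative.
#'
#' @param counts a \code{\link{count_matrix}} or gene-by-sample matrix.
#' @param factors per-sample positive normalization factors (e.g. from
#'   \code{\link{compute_tmm_factors}}); default all 1.
#' @return Gene-by-sample matrix of class \code{normalized_matrix} with
#'   attributes \code{unit = "log2-CPM"} and \code{factors}.
#' @export
log2_cpm <- function(counts, factors = NULL) {
  cm <- as_count_matrix(counts)
  x <- cm$counts
  if (is.null(factors)) factors <- setNames(rep(1, ncol(x)), colnames(x))
  if (length(factors) != ncol(x)) stop_("one factor per sample required")
  if (any(factors <= 0)) stop_("normalization factors must be positive")
  eff <- cm$lib_sizes * factors
  out <- log2(sweep(x, 2, eff, "/") * 1e6 + 1)
  structure(out, unit = "log2-CPM", factors = factors,
            class = c("normalized_matrix", class(out)))
}

#' Wrap an externally normalized matrix (e.g. log2-TPM)
#'
#' Cohorts distributed only as normalized values (log2-TPM) skip TMM and are
#' used as provided; this tags them for provenance so downstream stages treat
#' them identically to log2-CPM matrices.
#'
#' @param x gene-by-sample numeric matrix of log-scale values.
#' @param unit unit tag, default \code{"log2-TPM"}.
#' @return The matrix with class \code{normalized_matrix} and a unit attribute.
#' @export
as_normalized_matrix <- function(x, unit = "log2-TPM") {
  if (!is.matrix(x) || !is.numeric(x)) stop_("'x' must be a numeric matrix")
  if (is.null(rownames(x))) stop_("gene rownames required")
  structure(x, unit = unit, factors = setNames(rep(1, ncol(x)), colnames(x)),
            class = c("normalized_matrix", class(x)))
}

#' Cohort-wise gene detectability filter
#'
#' Retains genes with at least \code{min_count} raw counts (or >= 1 TPM in
#' TPM mode) in at least \code{min_frac} of the samples; both comparisons are
#' inclusive (a gene at exactly the count threshold in exactly half the
#' samples passes the defaults).
#'
#' @param counts a \code{\link{count_matrix}}/matrix of raw counts, or a TPM
#'   matrix when \code{tpm_mode = TRUE}.
#' @param min_count raw-count threshold (default 5); ignored in TPM mode,
#'   where the threshold is 1 TPM.
#' @param min_frac minimum fraction of samples (default 0.5).
#' @param tpm_mode treat \code{counts} as TPM values.
#' @return Character vector of retained gene ids.
#' @export
detectability_filter <- function(counts, min_count = 5, min_frac = 0.5,
                                 tpm_mode = FALSE) {
  check_number(min_count, "min_count", lower = 1e-12)
  check_number(min_frac, "min_frac", lower = 1e-12, upper = 1)
  x <- if (tpm_mode) {
    if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  } else as_count_matrix(counts)$counts
  thr <- if (tpm_mode) 1 else min_count
  frac <- rowMeans(x >= thr)
  rownames(x)[frac >= min_frac]
}

#' Per-sample meta-signal over candidate genes
#'
#' The mean of gene-wise z-scored normalized values over the candidate genes:
#' a scale-free per-sample summary of the candidate pool used to rank each
#' gene's importance. Zero-variance genes are excluded with a warning.
#'
#' @param norm normalized gene-by-sample matrix.
#' @param candidates character vector of candidate genes (>= 1 present).
#' @return Named per-sample numeric vector.
#' @export
meta_signal <- function(norm, candidates) {
  present <- intersect(candidates, rownames(norm))
  if (length(present) == 0L) stop_("no candidate gene present in the matrix")
  m <- norm[present, , drop = FALSE]
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    warning("excluding zero-variance gene(s) from meta-signal: ",
            paste(present[sds == 0], collapse = ", "))
    m <- m[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    if (nrow(m) == 0L) stop_("all candidate genes have zero variance")
  }
  z <- (m - rowMeans(m)) / sds
  colMeans(z)
}

# Spearman rho (average ranks on ties) with two-sided p from the t transform.
spearman_test <- function(x, y) {
  n <- length(x)
  rho <- cor(rank(x), rank(y))
  if (is.na(rho)) return(c(rho = NA_real_, p = NA_real_))
  if (abs(rho) >= 1 - 1e-12) return(c(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2))
}

#' Gene importance filter against the meta-signal
#'
#' Keeps candidate genes whose Spearman correlation with the per-sample
#' meta-signal exceeds \code{rho_min} (strict, one-sided in sign) with a
#' two-sided unadjusted p below \code{alpha}.
#'
#' @param norm normalized gene-by-sample matrix (>= 3 samples).
#' @param candidates candidate gene ids.
#' @param meta per-sample meta-signal (from \code{\link{meta_signal}}).
#' @param rho_min correlation threshold (default 0.4, strict >).
#' @param alpha p-value threshold (default 0.05, unadjusted).
#' @return Character vector of kept genes with attribute \code{stats}, a
#'   data.frame of per-candidate \code{rho} and \code{p}.
#' @export
gene_importance_filter <- function(norm, candidates, meta, rho_min = 0.4,
                                   alpha = 0.05) {
  if (ncol(norm) < 3L) stop_("importance filter needs >= 3 samples")
  if (sd(meta) == 0) stop_("meta-signal is constant")
  present <- intersect(candidates, rownames(norm))
  st <- t(vapply(present, function(g) spearman_test(norm[g, ], meta),
                 numeric(2)))
  stats <- data.frame(gene = present, rho = st[, "rho"], p = st[, "p"],
                      row.names = NULL, stringsAsFactors = FALSE)
  keep <- !is.na(stats$rho) & stats$rho > rho_min & stats$p < alpha
  structure(stats$gene[keep], stats = stats,
            rho = setNames(stats$rho[keep], stats$gene[keep]))
}

#' Intersect per-cohort gene sets
#'
#' The cross-study robustness step: genes surviving the importance filter in
#' every cohort, ordered by their mean correlation (descending) when the
#' inputs carry per-gene \code{rho} attributes.
#'
#' @param sets list (>= 1) of character vectors, optionally with a named
#'   \code{rho} attribute as produced by \code{\link{gene_importance_filter}}.
#' @return Character vector (possibly empty, with a warning).
#' @export
cross_cohort_intersect <- function(sets) {
  if (!is.list(sets) || length(sets) == 0L) stop_("need >= 1 cohort gene set")
  common <- Reduce(intersect, lapply(sets, as.character))
  if (length(common) == 0L) {
    warning("empty cross-cohort intersection")
    return(character(0))
  }
  rhos <- vapply(common, function(g) {
    r <- vapply(sets, function(s) {
      rr <- attr(s, "rho")
      if (is.null(rr) || !g %in% names(rr)) NA_real_ else rr[[g]]
    }, numeric(1))
    mean(r, na.rm = TRUE)
  }, numeric(1))
  if (all(is.nan(rhos))) common else common[order(-rhos)]
}

#' Derive a signature for one cell type across cohorts
#'
#' Convenience chain: detectability filter, meta-signal, importance filter in
#' each cohort, then the cross-cohort intersection.
#'
#' @param cohorts list of lists, each with elements \code{counts}
#'   (a \code{\link{count_matrix}}) and optionally precomputed \code{norm};
#'   TMM factors are computed when \code{norm} is absent.
#' @param candidates candidate gene pool (union of cell-type annotated sets).
#' @param rho_min,alpha importance-filter thresholds.
#' @param min_count,min_frac detectability thresholds.
#' @param name signature name for the returned \code{\link{gene_signature}}.
#' @return A \code{gene_signature} of the intersected genes
#'   (provenance \code{"importance-passed"}); NULL if the intersection is
#'   empty.
#' @export
derive_signature <- function(cohorts, candidates, name = "custom",
                             rho_min = 0.4, alpha = 0.05,
                             min_count = 5, min_frac = 0.5) {
  kept <- lapply(cohorts, function(co) {
    det <- detectability_filter(co$counts, min_count, min_frac)
    cand <- intersect(candidates, det)
    norm <- co$norm %||% log2_cpm(co$counts, compute_tmm_factors(co$counts))
    ms <- meta_signal(norm, cand)
    gene_importance_filter(norm, cand, ms, rho_min, alpha)
  })
  genes <- cross_cohort_intersect(kept)
  if (length(genes) == 0L) return(NULL)
  gene_signature(name, genes, provenance = "importance-passed")
}
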