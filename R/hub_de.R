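# Differential expression between cDC1-rich and cDC1-devoid hubs.

#' Hub differential expression (rich vs devoid)
#'
#' Per-gene two-sided rank-sum test on log1p aggregated hub counts, with
#' Benjamini-Hochberg correction. The log2 fold change is computed on class
#' mean counts with a +1 pseudocount. The test backend is pluggable: a
#' zero-inflated NB (or any other) test can be slotted in via \code{backend}.
#'
#' @param hubset a classified \code{\link{build_hubs}} result (>= 2 hubs per
#'   class).
#' @param backend either \code{"ranksum"} (default) or a function
#'   \code{f(x_rich, x_devoid)} returning a two-sided p-value for one gene's
#'   aggregated count vectors.
#' @return data.frame (one row per gene): \code{gene}, \code{log2fc}
#'   (rich vs devoid), \code{statistic}, \code{p}, \code{q} (BH).
#' @export
hub_de <- function(hubset, backend = "ranksum") {
  stopifnot(inherits(hubset, "hub_set"))
  cls <- hubset$hubs$class
  if (anyNA(cls)) stop_("hubs are not classified; run classify_hubs() first")
  rich <- cls == "cDC1-rich"
  if (sum(rich) < 2L || sum(!rich) < 2L)
    stop_("need >= 2 hubs in each class (rich: ", sum(rich),
          ", devoid: ", sum(!rich), ")")
  xr <- hubset$counts[, rich, drop = FALSE]
  xd <- hubset$counts[, !rich, drop = FALSE]
  log2fc <- log2((rowMeans(xr) + 1) / (rowMeans(xd) + 1))

  if (identical(backend, "ranksum")) {
    test_fun <- function(a, b) {
      ht <- suppressWarnings(wilcox.test(log1p(a), log1p(b), exact = FALSE,
                                         correct = TRUE))
      c(stat = unname(ht$statistic), p = ht$p.value)
    }
  } else if (is.function(backend)) {
    test_fun <- function(a, b) c(stat = NA_real_, p = backend(a, b))
  } else stop_("'backend' must be \"ranksum\" or a function")

  res <- t(vapply(seq_len(nrow(hubset$counts)),
                  function(i) test_fun(xr[i, ], xd[i, ]), numeric(2)))
  p <- res[, "p"]
  p[is.na(p)] <- 1  # constant genes carry no evidence
  data.frame(gene = rownames(hubset$counts), log2fc = log2fc,
             statistic = res[, "stat"], p = p, q = p.adjust(p, "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}
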