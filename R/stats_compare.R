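# Response-group comparisons and correlation panels.

# Two-sided Mann-Whitney U: exact when combined n <= 20 with no ties,
# otherwise normal approximation with tie correction (and continuity
# correction).
mw_test <- function(x, y) {
  exact <- (length(x) + length(y)) <= 20 && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value, exact = exact)
}

#' Compare signature scores between clinical response groups
#'
#' Two-sided Mann-Whitney U tests on raw (unscaled) scores for the pairs
#' CR/PR vs SD, CR/PR vs PD and SD vs PD. Pairs with an empty group are
#' skipped with a note. Exact p-values are used for combined n <= 20 with no
#' ties; otherwise the normal approximation with tie correction.
#'
#' @param scores named per-sample numeric vector (names = sample ids) of raw
#'   scores.
#' @param clinical data.frame with columns \code{sample_id} and either
#'   \code{response_group} (CR/PR, SD, PD) or \code{response} (CR/PR/SD/PD,
#'   grouped internally via \code{\link{group_response}}).
#' @return data.frame: \code{pair}, group sizes \code{n1}, \code{n2},
#'   \code{U}, \code{p}, \code{note}.
#' @export
group_compare <- function(scores, clinical) {
  if (is.null(names(scores))) stop_("'scores' must be named by sample id")
  grp <- if ("response_group" %in% names(clinical)) clinical$response_group
         else group_response(clinical$response)
  grp <- setNames(as.character(grp), clinical$sample_id)[names(scores)]
  pairs <- list(c("CR/PR", "SD"), c("CR/PR", "PD"), c("SD", "PD"))
  rows <- lapply(pairs, function(pr) {
    x <- scores[!is.na(grp) & grp == pr[1]]
    y <- scores[!is.na(grp) & grp == pr[2]]
    if (length(x) == 0L || length(y) == 0L)
      return(data.frame(pair = paste(pr, collapse = " vs "), n1 = length(x),
                        n2 = length(y), U = NA_real_, p = NA_real_,
                        note = "skipped: empty group", stringsAsFactors = FALSE))
    mt <- mw_test(x, y)
    data.frame(pair = paste(pr, collapse = " vs "), n1 = length(x),
               n2 = length(y), U = mt$U, p = mt$p,
               note = if (mt$exact) "exact" else "normal approx.",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise correlation panel
#'
#' Pearson (or Spearman) correlations with two-sided p-values from the t
#' transform for every pair of the supplied vectors (e.g. signature scores
#' and single-gene log2(CPM+1) values). Zero-variance vectors yield missing
#' results with a note.
#'
#' @param vectors named list of equal-length paired numeric vectors
#'   (length >= 3).
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return data.frame: \code{var1}, \code{var2}, \code{r}, \code{p},
#'   \code{n}, \code{note}.
#' @export
correlation_panel <- function(vectors, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.list(vectors) || length(vectors) < 2L || is.null(names(vectors)))
    stop_("'vectors' must be a named list of >= 2 vectors")
  len <- unique(lengths(vectors))
  if (length(len) != 1L) stop_("vectors must be paired (equal length)")
  if (len < 3L) stop_("need length >= 3")
  nms <- names(vectors)
  combs <- utils::combn(nms, 2)
  rows <- apply(combs, 2, function(pr) {
    x <- vectors[[pr[1]]]; y <- vectors[[pr[2]]]
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L || sd(x) == 0 || sd(y) == 0)
      return(data.frame(var1 = pr[1], var2 = pr[2], r = NA_real_,
                        p = NA_real_, n = length(x),
                        note = "undefined: zero variance or too few pairs",
                        stringsAsFactors = FALSE))
    if (method == "pearson") {
      ht <- cor.test(x, y, method = "pearson")
      data.frame(var1 = pr[1], var2 = pr[2], r = unname(ht$estimate),
                 p = ht$p.value, n = length(x), note = "",
                 stringsAsFactors = FALSE)
    } else {
      st <- spearman_test(x, y)
      data.frame(var1 = pr[1], var2 = pr[2], r = st[["rho"]], p = st[["p"]],
                 n = length(x), note = "", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
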