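# Preranked gene-set enrichment (weighted Kolmogorov-Smirnov statistic with
# gene-label permutations).

# Enrichment score of one set over a ranking (stats sorted decreasing).
# Hits step by |stat|^1 / sum; misses by 1/(n - m). ES is the deviation of
# largest magnitude (sign retained).
gsea_es <- function(stat_sorted, hit) {
  w <- abs(stat_sorted) * hit
  denom <- sum(w)
  n_out <- sum(!hit)
  if (denom == 0 || n_out == 0) return(list(es = 0, walk = numeric(0)))
  walk <- cumsum(w) / denom - cumsum(!hit) / n_out
  i <- which.max(abs(walk))
  list(es = walk[i], walk = walk, argmax = i)
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov enrichment over a ranked gene list
#' (weight = |stat|, exponent 1). For each set, significance comes from
#' \code{n_perm} random same-size gene-label permutations: the permutation
#' p-value and the normalized enrichment score NES = ES / mean |ES| of
#' same-sign permutation scores. Sets outside [\code{min_size},
#' \code{max_size}] or disjoint from the ranking are skipped with a note.
#'
#' @param stats named numeric vector of per-gene ranking statistics (e.g.
#'   signed DE statistics); ranked internally in decreasing order.
#' @param gene_sets named list of character vectors.
#' @param n_perm number of gene-label permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @param min_size,max_size set-size bounds after intersection with the
#'   ranking (defaults 3 and half the ranked list).
#' @return data.frame: \code{set}, \code{size}, \code{es}, \code{nes},
#'   \code{p}, \code{leading_edge} (comma-joined genes up to the ES
#'   extremum), \code{note}.
#' @export
preranked_gsea <- function(stats, gene_sets, n_perm = 1000L, seed = 1L,
                           min_size = 3L, max_size = floor(length(stats) / 2)) {
  if (is.null(names(stats))) stop_("'stats' must be named by gene")
  if (is.null(names(gene_sets))) stop_("'gene_sets' must be named")
  ord <- order(stats, decreasing = TRUE)
  s <- stats[ord]
  genes <- names(s)
  n <- length(s)

  with_seed(substream_seed(seed, "gsea"), {
    rows <- lapply(names(gene_sets), function(nm) {
      inset <- genes %in% gene_sets[[nm]]
      m <- sum(inset)
      if (m < min_size || m > max_size)
        return(data.frame(set = nm, size = m, es = NA_real_, nes = NA_real_,
                          p = NA_real_, leading_edge = "",
                          note = sprintf("skipped: size %d outside [%d, %d]",
                                         m, min_size, max_size),
                          stringsAsFactors = FALSE))
      obs <- gsea_es(s, inset)
      perm <- vapply(seq_len(n_perm), function(i) {
        hit <- logical(n)
        hit[sample.int(n, m)] <- TRUE
        gsea_es(s, hit)$es
      }, numeric(1))
      same <- perm[sign(perm) == sign(obs$es)]
      nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
      p <- if (length(same)) (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
           else NA_real_
      le <- if (obs$es >= 0) genes[seq_len(obs$argmax)][inset[seq_len(obs$argmax)]]
            else genes[obs$argmax:n][inset[obs$argmax:n]]
      data.frame(set = nm, size = m, es = obs$es, nes = nes, p = p,
                 leading_edge = paste(le, collapse = ","), note = "",
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
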