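# Immune candidate detection and 10-micron niche (hub) construction for
# imaging spatial transcriptomics.

#' Default canonical gene lists for candidate detection
#' @return Named list: cDC1 = BATF3/CLEC9A/XCR1, CD8 = CD8A/CD8B.
#' @export
canonical_genes <- function() {
  list(cDC1 = c("BATF3", "CLEC9A", "XCR1"), CD8 = c("CD8A", "CD8B"))
}

#' Drop low-quality cells by total molecule count
#'
#' @param ctm a \code{\link{cell_transcript_matrix}}.
#' @param min_molecules minimum total molecules per cell (default 50); cells
#'   with strictly fewer are removed.
#' @return Filtered \code{cell_transcript_matrix}.
#' @export
qc_filter <- function(ctm, min_molecules = 50) {
  stopifnot(inherits(ctm, "cell_transcript_matrix"))
  keep <- ctm$totals >= min_molecules
  cell_transcript_matrix(ctm$counts[, keep, drop = FALSE],
                         ctm$cells[keep, , drop = FALSE])
}

# log1p of the per-cell canonical-gene count sum for one type; genes absent
# from the panel contribute zero.
canonical_sum <- function(ctm, genes) {
  present <- intersect(genes, rownames(ctm$counts))
  if (length(present) == 0L) return(setNames(rep(0, ncol(ctm$counts)),
                                             colnames(ctm$counts)))
  s <- if (length(present) == 1L) ctm$counts[present, ]
       else colSums(ctm$counts[present, , drop = FALSE])
  setNames(s, colnames(ctm$counts))
}

# Valley of a bimodal KDE: minimum of the density between the two highest
# modes; NULL when the density has fewer than two local maxima. The Silverman
# bandwidth is floored at half the unit spacing of log1p counts so count
# discreteness cannot manufacture spurious modes at individual integers.
kde_valley <- function(s, n_grid = 512L, min_bw = 0.5) {
  d <- density(s, bw = max(stats::bw.nrd0(s), min_bw), n = n_grid)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(peaks) < 2L) return(NULL)
  top2 <- sort(peaks[order(-y[peaks])][1:2])
  between <- top2[1]:top2[2]
  d$x[between[which.min(y[between])]]
}

#' Threshold-based immune candidate detection
#'
#' For each cell type, the per-cell log1p sum of canonical gene counts is
#' assumed bimodal (expressing vs non-expressing cells); cells above the
#' local minimum (valley) of a Gaussian KDE (Silverman bandwidth) between the
#' two highest modes are called positive. When no second mode exists the
#' valley falls back to an Otsu threshold on the sums, with a warning.
#'
#' @param ctm a \code{\link{cell_transcript_matrix}} (canonical genes must be
#'   in the panel).
#' @param canonical named list of canonical genes per type (default
#'   \code{\link{canonical_genes}}).
#' @return data.frame: \code{cell_id}, one logical column per type, and
#'   \code{call} in \{cDC1, CD8, both, none\}; attributes \code{thresholds}
#'   and \code{sums} (log1p canonical sums per type).
#' @export
detect_threshold <- function(ctm, canonical = canonical_genes()) {
  stopifnot(inherits(ctm, "cell_transcript_matrix"))
  miss <- setdiff(unlist(canonical), rownames(ctm$counts))
  if (length(miss)) stop_("canonical gene(s) not in panel: ",
                          paste(miss, collapse = ", "))
  types <- names(canonical)
  sums <- vapply(types, function(t) log1p(canonical_sum(ctm, canonical[[t]])),
                 numeric(ncol(ctm$counts)))
  sums <- matrix(sums, ncol = length(types),
                 dimnames = list(colnames(ctm$counts), types))
  thr <- setNames(numeric(length(types)), types)
  pos <- matrix(FALSE, nrow(sums), length(types), dimnames = dimnames(sums))
  for (t in types) {
    s <- sums[, t]
    if (all(s == 0)) {
      warning("all canonical sums are zero for type ", t, "; no positives")
      thr[t] <- Inf
      next
    }
    v <- kde_valley(s)
    if (is.null(v)) {
      warning("no second mode for type ", t, "; falling back to Otsu threshold")
      v <- otsu_threshold(s)
    }
    thr[t] <- v
    pos[, t] <- s > v
  }
  call <- rep("none", nrow(sums))
  for (t in types) call[pos[, t] & call == "none"] <- t
  call[rowSums(pos) > 1L] <- "both"
  out <- data.frame(cell_id = rownames(sums), pos, call = call,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, thresholds = thr, sums = sums)
}

# igraph renamed cluster_leiden's resolution argument across versions.
leiden_communities <- function(g, resolution) {
  fm <- names(formals(igraph::cluster_leiden))
  if ("resolution" %in% fm)
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution)
  else
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution_parameter = resolution)
}

#' Cluster-based immune candidate detection
#'
#' Leiden community detection (modularity objective, resolution 2.0 for fine
#' granularity) on a k-nearest-neighbour graph over depth-normalized log1p
#' counts. A cluster is positive for a cell type when its mean canonical sum
#' exceeds the global mean by one SD; clusters positive for both types are
#' "mixture", for neither "none"; cells inherit their cluster's label.
#'
#' @param ctm a \code{\link{cell_transcript_matrix}} (>= 2 cells).
#' @param resolution Leiden resolution (default 2.0).
#' @param k kNN graph degree (default 15; reduced with a warning when there
#'   are fewer cells).
#' @param canonical canonical gene lists per type.
#' @param seed integer seed (community detection is seeded).
#' @return data.frame: \code{cell_id}, \code{cluster}, \code{call} in
#'   \{cDC1, CD8, mixture, none\}; attribute \code{cluster_calls}.
#' @export
detect_cluster <- function(ctm, resolution = 2.0, k = 15L,
                           canonical = canonical_genes(), seed = 1L) {
  stopifnot(inherits(ctm, "cell_transcript_matrix"))
  n <- ncol(ctm$counts)
  if (n < 2L) stop_("clustering needs >= 2 cells")
  if (k >= n) {
    warning("k (", k, ") >= number of cells; reduced to ", n - 1L)
    k <- n - 1L
  }
  depth <- pmax(ctm$totals, 1)
  norm <- log1p(sweep(ctm$counts, 2, depth, "/") * median(depth))

  d <- as.matrix(dist(t(norm)))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[2:(k + 1L)]
    cbind(i, nb)
  }))
  edges <- unique(t(apply(edges, 1, sort)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  memb <- with_seed(substream_seed(seed, "cluster"),
                    igraph::membership(leiden_communities(g, resolution)))

  types <- names(canonical)
  sums <- vapply(types, function(t) log1p(canonical_sum(ctm, canonical[[t]])),
                 numeric(n))
  sums <- matrix(sums, ncol = length(types))
  cl_ids <- sort(unique(memb))
  cluster_pos <- sapply(types, function(ti) {
    j <- match(ti, types)
    cut <- mean(sums[, j]) + sd(sums[, j])
    vapply(cl_ids, function(cl) mean(sums[memb == cl, j]) > cut, logical(1))
  })
  cluster_pos <- matrix(cluster_pos, nrow = length(cl_ids),
                        dimnames = list(cl_ids, types))
  cluster_call <- apply(cluster_pos, 1, function(z) {
    if (all(z)) "mixture" else if (any(z)) types[z] else "none"
  })
  call <- cluster_call[match(memb, cl_ids)]
  structure(data.frame(cell_id = colnames(ctm$counts),
                       cluster = as.integer(memb), call = call,
                       row.names = NULL, stringsAsFactors = FALSE),
            cluster_calls = cluster_call)
}

#' Consensus of threshold and cluster candidate calls
#'
#' A cell becomes a consensus candidate of type t iff the threshold method
#' calls it t (cells called "both" first resolve to the type with the larger
#' canonical sum, ties to cDC1) and the cluster method places it in a
#' cluster labelled t or "mixture". Everything else is "none".
#'
#' @param thr_calls output of \code{\link{detect_threshold}}.
#' @param clu_calls output of \code{\link{detect_cluster}} (same cells, same
#'   order).
#' @return data.frame: \code{cell_id}, \code{threshold_call},
#'   \code{cluster_call}, \code{consensus} in \{cDC1, CD8, none\}.
#' @export
consensus_candidates <- function(thr_calls, clu_calls) {
  if (!identical(thr_calls$cell_id, clu_calls$cell_id))
    stop_("threshold and cluster calls are not aligned")
  sums <- attr(thr_calls, "sums")
  tcall <- thr_calls$call
  both <- tcall == "both"
  if (any(both)) {
    if (is.null(sums)) stop_("'both' calls need canonical sums to resolve")
    tcall[both] <- ifelse(sums[both, "CD8"] > sums[both, "cDC1"], "CD8", "cDC1")
  }
  agree <- clu_calls$call == tcall | clu_calls$call == "mixture"
  consensus <- ifelse(tcall %in% c("cDC1", "CD8") & agree, tcall, "none")
  data.frame(cell_id = thr_calls$cell_id, threshold_call = thr_calls$call,
             cluster_call = clu_calls$call, consensus = consensus,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build 10-micron niches (hubs) around candidate cells
#'
#' One hub per candidate cell: its members are all cells (of any type) whose
#' centroid lies within \code{radius_um} of the candidate centroid, the
#' center included, and the hub's expression is the sum of member counts.
#' Hubs may overlap and share members.
#'
#' @param ctm a \code{\link{cell_transcript_matrix}}.
#' @param candidates character vector of candidate cell ids (>= 1), or the
#'   data.frame from \code{\link{consensus_candidates}} (rows with consensus
#'   != "none" are used).
#' @param radius_um niche radius in microns (default 10, i.e. 20-micron
#'   diameter).
#' @return Object of class \code{hub_set}: list with \code{hubs}
#'   (data.frame: hub_id, center_cell, center_type, x_um, y_um, n_cells,
#'   class), \code{counts} (gene-by-hub aggregated matrix) and
#'   \code{members} (list of member cell ids).
#' @export
build_hubs <- function(ctm, candidates, radius_um = 10) {
  stopifnot(inherits(ctm, "cell_transcript_matrix"))
  check_number(radius_um, "radius_um", lower = 1e-12)
  if (is.data.frame(candidates)) {
    keep <- candidates$consensus != "none"
    ctype <- candidates$consensus[keep]
    cand <- candidates$cell_id[keep]
  } else {
    cand <- as.character(candidates)
    ctype <- rep(NA_character_, length(cand))
  }
  if (length(cand) == 0L) stop_("no candidate cells")
  idx <- match(cand, ctm$cells$cell_id)
  if (anyNA(idx)) stop_("candidate cell id(s) not in matrix: ",
                        paste(head(cand[is.na(idx)], 5), collapse = ", "))
  x <- ctm$cells$x_um; y <- ctm$cells$y_um
  r2 <- radius_um^2
  members <- lapply(idx, function(i) {
    which((x - x[i])^2 + (y - y[i])^2 <= r2)
  })
  agg <- vapply(members, function(m)
    if (length(m) == 1L) ctm$counts[, m] else rowSums(ctm$counts[, m, drop = FALSE]),
    numeric(nrow(ctm$counts)))
  agg <- matrix(agg, nrow = nrow(ctm$counts),
                dimnames = list(rownames(ctm$counts),
                                sprintf("HUB%05d", seq_along(idx))))
  hubs <- data.frame(hub_id = colnames(agg), center_cell = cand,
                     center_type = ctype, x_um = x[idx], y_um = y[idx],
                     n_cells = lengths(members), class = NA_character_,
                     row.names = NULL, stringsAsFactors = FALSE)
  structure(list(hubs = hubs, counts = agg,
                 members = lapply(members, function(m) ctm$cells$cell_id[m])),
            class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("hub_set: %d hubs, %d genes; median %d cells/hub\n",
              nrow(x$hubs), nrow(x$counts), as.integer(median(x$hubs$n_cells))))
  if (!all(is.na(x$hubs$class)))
    print(table(x$hubs$class))
  invisible(x)
}

#' Classify hubs as cDC1-rich or cDC1-devoid
#'
#' A hub is cDC1-rich iff its aggregated BATF3 + XCR1 + CLEC9A count is at
#' least one molecule; hubs without any cDC1-related molecule are
#' cDC1-devoid.
#'
#' @param hubset a \code{\link{build_hubs}} result.
#' @param cdc1_genes the cDC1-defining transcripts (default
#'   BATF3/XCR1/CLEC9A); genes absent from the panel count zero.
#' @return The \code{hub_set} with the \code{class} column filled in.
#' @export
classify_hubs <- function(hubset, cdc1_genes = c("BATF3", "XCR1", "CLEC9A")) {
  stopifnot(inherits(hubset, "hub_set"))
  present <- intersect(cdc1_genes, rownames(hubset$counts))
  tot <- if (length(present) == 0L) rep(0, ncol(hubset$counts))
         else colSums(hubset$counts[present, , drop = FALSE])
  hubset$hubs$class <- ifelse(tot >= 1, "cDC1-rich", "cDC1-devoid")
  hubset
}

#' Hub densities by class and clinical-benefit group
#'
#' Emits both per-area (hubs/mm^2) and per-cell (hubs per 1,000 cells)
#' normalizations, since either may be the natural denominator depending on
#' how much tissue each sample contributes.
#'
#' @param hub_tables named list (by sample) of classified hub data.frames
#'   (the \code{hubs} element of a \code{hub_set}).
#' @param areas_mm2 named per-sample tissue areas in mm^2 (> 0).
#' @param n_cells named per-sample total cell counts (optional, for the
#'   per-cell normalization).
#' @param labels named per-sample clinical-benefit labels.
#' @return data.frame: sample_id, label, class, n_hubs, density_mm2,
#'   density_per_1k_cells.
#' @export
hub_density_by_group <- function(hub_tables, areas_mm2, n_cells = NULL,
                                 labels = NULL) {
  if (is.null(names(hub_tables))) stop_("'hub_tables' must be named by sample")
  if (any(areas_mm2 <= 0)) stop_("areas must be positive")
  rows <- lapply(names(hub_tables), function(s) {
    h <- hub_tables[[s]]
    a <- areas_mm2[[s]]
    nc <- if (is.null(n_cells)) NA_real_ else n_cells[[s]]
    lab <- if (is.null(labels)) NA_character_ else as.character(labels[[s]])
    cls <- c("cDC1-rich", "cDC1-devoid")
    n <- vapply(cls, function(cl) sum(h$class == cl), numeric(1))
    data.frame(sample_id = s, label = lab, class = cls, n_hubs = unname(n),
               density_mm2 = unname(n) / a,
               density_per_1k_cells = unname(n) / nc * 1000,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
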