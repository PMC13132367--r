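# Nearest-neighbour and triad distance statistics between phenotypes.

# Per-from-cell Euclidean distance to the nearest to-cell (chunked O(n*m)).
nn_distances <- function(fx, fy, tx, ty) {
  sqrt(nearest_dist2(fx, fy, tx, ty))
}

#' Mean nearest-neighbour distance between phenotypes
#'
#' Mean over cells of type \code{from} of the Euclidean distance (microns)
#' to the nearest cell of type \code{to}. Directional: averaged over the
#' from-cells only. Samples lacking either phenotype are excluded from
#' analysis via the \code{\link{excluded_sample}} sentinel rather than an
#' error.
#'
#' @param table cell table with \code{x_um}, \code{y_um}, \code{phenotype}.
#' @param from,to phenotype labels (defaults cDC1 -> CD8T).
#' @return Mean distance in microns with attribute \code{per_cell} (the
#'   per-from-cell minima), or an \code{excluded_sample} sentinel.
#' @export
mean_min_distance <- function(table, from = "cDC1", to = "CD8T") {
  f <- table[table$phenotype == from, , drop = FALSE]
  t_ <- table[table$phenotype == to, , drop = FALSE]
  if (nrow(f) == 0L || nrow(t_) == 0L)
    return(excluded_sample(sprintf("no %s cells in sample",
                                   if (nrow(f) == 0L) from else to)))
  d <- nn_distances(f$x_um, f$y_um, t_$x_um, t_$y_um)
  structure(mean(d), per_cell = setNames(d, f$cell_id))
}

#' Triad radius per cDC1 cell
#'
#' For every cDC1 cell, the minimum radius at which it simultaneously
#' encounters both a CD4 and a CD8 T cell: the maximum of its two
#' nearest-neighbour distances (the nearest CD4 and CD8 partners are
#' necessarily distinct cells since phenotypes are exclusive).
#'
#' @param table cell table with \code{x_um}, \code{y_um}, \code{phenotype}
#'   (labels cDC1, CD8T, CD4T).
#' @return List with \code{radii} (named per-cDC1 vector, microns) and
#'   \code{mean}; or an \code{excluded_sample} sentinel when any of the
#'   three phenotypes is absent.
#' @export
triad_radius <- function(table) {
  f <- table[table$phenotype == "cDC1", , drop = FALSE]
  c8 <- table[table$phenotype == "CD8T", , drop = FALSE]
  c4 <- table[table$phenotype == "CD4T", , drop = FALSE]
  if (nrow(f) == 0L || nrow(c8) == 0L || nrow(c4) == 0L) {
    missing <- c("cDC1", "CD8T", "CD4T")[c(nrow(f), nrow(c8), nrow(c4)) == 0L]
    return(excluded_sample(paste("no", paste(missing, collapse = "/"),
                                 "cells in sample")))
  }
  d8 <- nn_distances(f$x_um, f$y_um, c8$x_um, c8$y_um)
  d4 <- nn_distances(f$x_um, f$y_um, c4$x_um, c4$y_um)
  radii <- pmax(d8, d4)
  list(radii = setNames(radii, f$cell_id), mean = mean(radii))
}

#' Summarize a sample's distance statistics
#'
#' @param table phenotyped cell table.
#' @param sample_id sample identifier copied into the output.
#' @return One-row data.frame: sample id, per-phenotype counts, mean minimum
#'   cDC1->CD8 and cDC1->CD4 distances, mean triad radius (NA where the
#'   sample is excluded for a missing phenotype).
#' @export
distance_summary <- function(table, sample_id = "sample") {
  ph <- function(x) sum(table$phenotype == x)
  d8 <- mean_min_distance(table, "cDC1", "CD8T")
  d4 <- mean_min_distance(table, "cDC1", "CD4T")
  tr <- triad_radius(table)
  data.frame(sample_id = sample_id,
             n_cdc1 = ph("cDC1"), n_cd8 = ph("CD8T"), n_cd4 = ph("CD4T"),
             n_other = ph("other"),
             mean_dist_cdc1_cd8 = if (is_excluded(d8)) NA_real_ else as.numeric(d8),
             mean_dist_cdc1_cd4 = if (is_excluded(d4)) NA_real_ else as.numeric(d4),
             mean_triad_radius = if (is_excluded(tr)) NA_real_ else tr$mean,
             stringsAsFactors = FALSE)
}

#' Compare per-sample distances between clinical-benefit groups
#'
#' Two-sided rank-sum comparison of a per-sample distance statistic between
#' two groups (e.g. responders vs non-responders); excluded (NA) samples are
#' dropped with a note.
#'
#' @param values named per-sample numeric vector (NA = excluded sample).
#' @param labels per-sample group labels aligned with \code{values} (exactly
#'   two non-empty groups after dropping NAs).
#' @return List: \code{statistic} (U), \code{p}, \code{groups}, \code{n},
#'   \code{n_excluded}.
#' @export
group_distance_compare <- function(values, labels) {
  labels <- as.character(labels)
  if (length(values) != length(labels)) stop_("values and labels must align")
  keep <- !is.na(values) & !is.na(labels)
  n_excl <- sum(!keep)
  values <- values[keep]; labels <- labels[keep]
  gs <- sort(unique(labels))
  if (length(gs) != 2L) stop_("need exactly two non-empty groups, got ",
                              length(gs))
  x <- values[labels == gs[1]]; y <- values[labels == gs[2]]
  mt <- mw_test(x, y)
  list(statistic = mt$U, p = mt$p, groups = gs,
       n = c(length(x), length(y)), n_excluded = n_excl)
}
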