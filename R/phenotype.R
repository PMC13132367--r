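# Cell phenotyping, border trimming, tissue area and densities.

#' Assign cell phenotypes from marker positivity
#'
#' Priority rule: BATF3-positive cells are cDC1 regardless of other markers;
#' among BATF3-negative cells, CD8-positive cells are cytotoxic T cells
#' (CD8T); remaining CD3-positive cells are T helper cells (CD4T); cells
#' negative for all three markers are "other". Positivity is strictly above
#' the marker threshold.
#'
#' @param table cell table with intensity columns \code{BATF3}, \code{CD3},
#'   \code{CD8}.
#' @param thr named thresholds for all three markers (see
#'   \code{\link{marker_thresholds}}).
#' @return The table with a \code{phenotype} column
#'   (cDC1 / CD8T / CD4T / other).
#' @export
assign_phenotypes <- function(table, thr) {
  markers <- c("BATF3", "CD3", "CD8")
  miss <- setdiff(markers, names(table))
  if (length(miss)) stop_("missing marker column(s): ", paste(miss, collapse = ", "))
  if (!all(markers %in% names(thr)))
    stop_("thresholds required for all of: ", paste(markers, collapse = ", "))
  batf3 <- table$BATF3 > thr[["BATF3"]]
  cd8 <- table$CD8 > thr[["CD8"]]
  cd3 <- table$CD3 > thr[["CD3"]]
  table$phenotype <- ifelse(batf3, "cDC1",
                     ifelse(cd8, "CD8T",
                     ifelse(cd3, "CD4T", "other")))
  table
}

#' Remove cells near the field border
#'
#' Drops cells within \code{margin_um} of any field edge, guarding against
#' staining and segmentation artifacts at image borders.
#'
#' @param table cell table with \code{x_um}, \code{y_um}.
#' @param bounds field bounds \code{c(xmin, xmax, ymin, ymax)}; defaults to
#'   the coordinate bounding box.
#' @param margin_um margin in microns (>= 0; must be below half the smaller
#'   field extent).
#' @return The trimmed table.
#' @export
trim_border <- function(table, bounds = NULL, margin_um = 20) {
  check_number(margin_um, "margin_um", lower = 0)
  if (is.null(bounds))
    bounds <- c(min(table$x_um), max(table$x_um), min(table$y_um), max(table$y_um))
  if (length(bounds) != 4L) stop_("'bounds' must be c(xmin, xmax, ymin, ymax)")
  ext <- min(bounds[2] - bounds[1], bounds[4] - bounds[3])
  if (margin_um >= ext / 2)
    stop_("margin (", margin_um, " um) is >= half the field extent")
  keep <- table$x_um >= bounds[1] + margin_um & table$x_um <= bounds[2] - margin_um &
          table$y_um >= bounds[3] + margin_um & table$y_um <= bounds[4] - margin_um
  table[keep, , drop = FALSE]
}

#' Estimate tissue area from cell coordinates
#'
#' Occupancy grid: the coordinate bounding box is tiled into
#' \code{bin_um}-square bins and the area is the number of occupied bins
#' times the bin area, converted to mm^2. The whole tissue (tumor plus
#' stroma) contributes; no masking is applied.
#'
#' @param table cell table with \code{x_um}, \code{y_um} (>= 1 cell).
#' @param bin_um bin side in microns (default 50).
#' @return Area in mm^2.
#' @export
estimate_tissue_area <- function(table, bin_um = 50) {
  if (nrow(table) == 0L) stop_("cannot estimate area from an empty cell table")
  check_number(bin_um, "bin_um", lower = 1e-8)
  ix <- floor((table$x_um - min(table$x_um)) / bin_um)
  iy <- floor((table$y_um - min(table$y_um)) / bin_um)
  n_occ <- nrow(unique(cbind(ix, iy)))
  n_occ * bin_um^2 / 1e6
}

#' Per-phenotype cell densities
#'
#' @param table cell table with a \code{phenotype} column.
#' @param area_mm2 tissue area in mm^2 (> 0), e.g. from
#'   \code{\link{estimate_tissue_area}}.
#' @param phenotypes phenotype levels to report (zero counts included).
#' @return data.frame: \code{phenotype}, \code{n}, \code{density_mm2}.
#' @export
densities <- function(table, area_mm2,
                      phenotypes = c("cDC1", "CD8T", "CD4T", "other")) {
  check_number(area_mm2, "area_mm2", lower = 1e-12)
  n <- vapply(phenotypes, function(ph) sum(table$phenotype == ph), numeric(1))
  data.frame(phenotype = phenotypes, n = unname(n),
             density_mm2 = unname(n) / area_mm2,
             row.names = NULL, stringsAsFactors = FALSE)
}
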