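# Synthetic imaging spatial-transcriptomic cell-by-gene counts.

#' Default gene panel for the spatial-transcriptome generator
#'
#' Canonical cell-type markers (BATF3/XCR1/CLEC9A for cDC1, CD8A/CD8B for
#' CD8 T cells), activation genes expected to rise near cDC1
#' (IFN-gamma-response and T-cell-activation transcripts), and unstructured
#' background genes standing in for the rest of a large imaging panel.
#'
#' @param n_background number of background genes (default 190, giving a
#'   200-gene desk-scale panel).
#' @return A list with elements \code{canonical} (list cDC1/CD8),
#'   \code{activation} and \code{background} (character vectors).
#' @export
default_st_panel <- function(n_background = 190L) {
  list(canonical = list(cDC1 = c("BATF3", "XCR1", "CLEC9A"),
                        CD8 = c("CD8A", "CD8B")),
       activation = c("IDO1", "CXCL9", "CXCL10", "IL2RA", "TNFRSF9"),
       background = sprintf("BG%03d", seq_len(n_background)))
}

#' Parameters for the spatial-transcriptome generator
#'
#' @param n_cells number of cells (>= 1).
#' @param panel gene panel as returned by \code{\link{default_st_panel}}.
#' @param proportions named simplex of true cell-type proportions over
#'   \code{c("cDC1","CD8","other")}; must sum to 1.
#' @param marker_fold fold-elevation (> 1) of canonical markers in the owning
#'   cell type; the default 100 reflects that cell-type markers are
#'   essentially exclusive to their type.
#' @param activation_fold fold-elevation (> 1) of activation genes in cells
#'   whose centroid lies within \code{activation_radius_um} of a true cDC1.
#' @param specificity relative base weight of canonical lineage markers
#'   outside their owning type (default 0.05): marker transcripts are
#'   near-absent in non-owning cells, which is exactly what makes them
#'   markers. \code{marker_fold} acts on top of this low base, so the
#'   owning-vs-background mean ratio is still exactly \code{marker_fold}.
#'   Activation genes keep base weight 1 (inducible, not lineage-restricted).
#' @param depth expected total molecules per cell (default 230, a realistic
#'   per-cell median for imaging panels).
#' @param nb_dispersion NB dispersion alpha; 0 (default) gives Poisson counts.
#' @param field_width,field_height field extent in microns; the default
#'   500 x 500 um at 3,000 cells gives ~0.012 cells/um^2, i.e. about 4 cells
#'   per 10-um niche.
#' @param activation_radius_um radius in microns defining "near a cDC1".
#' @param seed integer seed.
#' @return Validated list of class \code{st_sim_params}.
#' @export
st_sim_params <- function(n_cells = 3000L, panel = default_st_panel(),
                          proportions = c(cDC1 = 0.02, CD8 = 0.10, other = 0.88),
                          marker_fold = 100, activation_fold = 3, depth = 230,
                          nb_dispersion = 0, field_width = 500,
                          field_height = 500, activation_radius_um = 10,
                          specificity = 0.05, seed = 1L) {
  check_number(n_cells, "n_cells", lower = 1)
  genes <- c(unlist(panel$canonical, use.names = FALSE), panel$activation,
             panel$background)
  if (length(genes) == 0L) stop_("empty gene panel")
  if (anyDuplicated(genes)) stop_("duplicated genes in panel")
  if (is.null(names(proportions)) ||
      !setequal(names(proportions), c("cDC1", "CD8", "other")))
    stop_("'proportions' must be named over cDC1, CD8, other")
  if (abs(sum(proportions) - 1) > 1e-8) stop_("'proportions' must sum to 1")
  if (any(proportions < 0)) stop_("'proportions' must be non-negative")
  # fold = 1 is allowed as the explicit null case
  check_number(marker_fold, "marker_fold", lower = 1)
  check_number(activation_fold, "activation_fold", lower = 1)
  check_number(depth, "depth", lower = 1e-8)
  check_number(nb_dispersion, "nb_dispersion", lower = 0)
  check_number(field_width, "field_width", lower = 1e-8)
  check_number(field_height, "field_height", lower = 1e-8)
  check_number(activation_radius_um, "activation_radius_um", lower = 1e-8)
  check_number(specificity, "specificity", lower = 1e-12, upper = 1)
  check_number(seed, "seed")
  structure(list(n_cells = as.integer(n_cells), panel = panel,
                 proportions = proportions[c("cDC1", "CD8", "other")],
                 marker_fold = marker_fold, activation_fold = activation_fold,
                 depth = depth, nb_dispersion = nb_dispersion,
                 field_width = field_width, field_height = field_height,
                 activation_radius_um = activation_radius_um,
                 specificity = specificity, seed = as.integer(seed)),
            class = "st_sim_params")
}

#' Generate a synthetic spatial cell-by-gene transcript matrix
#'
#' Cells are uniform on the field with multinomial true types. Gene means are
#' \code{depth * w_g / sum(w) * fold}: background genes carry base weight 1,
#' canonical and activation genes the low \code{specificity} weight (marker
#' transcripts are near-absent outside their context). Canonical markers are
#' multiplied by \code{marker_fold} in their owning type, activation genes by
#' \code{activation_fold} in cells within \code{activation_radius_um} of any
#' true cDC1 (including the cDC1 itself). Counts are Poisson (or NB when
#' \code{nb_dispersion > 0}).
#'
#' @param params an \code{\link{st_sim_params}} object.
#' @return A \code{\link{cell_transcript_matrix}} whose \code{cells} table
#'   additionally carries the hidden truth columns \code{true_type} and
#'   \code{near_cdc1}.
#' @export
gen_spatial_transcriptome <- function(params) {
  stopifnot(inherits(params, "st_sim_params"))
  p <- params
  genes <- c(unlist(p$panel$canonical, use.names = FALSE), p$panel$activation,
             p$panel$background)
  with_seed(substream_seed(p$seed, "st"), {
    n <- p$n_cells
    x <- runif(n, 0, p$field_width)
    y <- runif(n, 0, p$field_height)
    type <- sample(names(p$proportions), n, replace = TRUE, prob = p$proportions)

    cdc1_idx <- which(type == "cDC1")
    near <- rep(FALSE, n)
    if (length(cdc1_idx)) {
      d2 <- nearest_dist2(x, y, x[cdc1_idx], y[cdc1_idx])
      near <- d2 <= p$activation_radius_um^2
    }

    # Only lineage markers are type-restricted; activation genes are
    # inducible but broadly expressed at baseline.
    w <- setNames(rep(1, length(genes)), genes)
    w[unlist(p$panel$canonical, use.names = FALSE)] <- p$specificity
    base <- p$depth * w / sum(w)
    mu <- matrix(base, length(genes), n, dimnames = list(genes, NULL))
    for (t in names(p$panel$canonical)) {
      mk <- p$panel$canonical[[t]]
      mu[mk, type == t] <- mu[mk, type == t] * p$marker_fold
    }
    mu[p$panel$activation, near] <- mu[p$panel$activation, near] * p$activation_fold

    counts <- if (p$nb_dispersion > 0)
      matrix(rnbinom(length(mu), mu = mu, size = 1 / p$nb_dispersion), nrow(mu))
    else matrix(rpois(length(mu), mu), nrow(mu))
    rownames(counts) <- genes

    cells <- data.frame(cell_id = sprintf("X%05d", seq_len(n)),
                        x_um = x, y_um = y, true_type = type,
                        near_cdc1 = near, stringsAsFactors = FALSE)
    cell_transcript_matrix(counts, cells)
  })
}

# Squared distance from each (x, y) to its nearest (tx, ty), chunked.
nearest_dist2 <- function(x, y, tx, ty, chunk = 1024L) {
  out <- numeric(length(x))
  for (i0 in seq(1L, length(x), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, length(x))
    d2 <- outer(x[idx], tx, "-")^2 + outer(y[idx], ty, "-")^2
    out[idx] <- row_mins(d2)
  }
  out
}
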