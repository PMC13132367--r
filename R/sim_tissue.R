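# Synthetic multiplex-immunofluorescence point patterns.

#' Parameters for the tissue point-pattern generator
#'
#' Emulates a segmented multiplex-immunofluorescence field: cDC1, CD8 T,
#' CD4 T and "other" cells on a rectangular field in microns. A tunable
#' fraction of T cells is displaced from a randomly chosen cDC1 position by
#' an isotropic Gaussian, creating the cDC1-T attraction whose strength the
#' distance statistics are designed to detect; all remaining cells are
#' uniform on the field.
#'
#' @param field_width,field_height field extent in microns.
#' @param n_cdc1,n_cd8,n_cd4,n_other cell counts per phenotype (>= 0).
#' @param attraction_fraction fraction of T cells (CD8 and CD4) placed near a
#'   cDC1, in [0, 1]. Ignored (all uniform) when \code{n_cdc1 = 0}.
#' @param displacement_sd SD in microns of the isotropic Gaussian displacement.
#' @param seed integer seed.
#' @return Validated list of class \code{tissue_sim_params}.
#' @export
tissue_sim_params <- function(field_width = 1000, field_height = 1000,
                              n_cdc1 = 30L, n_cd8 = 200L, n_cd4 = 200L,
                              n_other = 1000L, attraction_fraction = 0,
                              displacement_sd = 10, seed = 1L) {
  check_number(field_width, "field_width", lower = 1e-8)
  check_number(field_height, "field_height", lower = 1e-8)
  for (nm in c("n_cdc1", "n_cd8", "n_cd4", "n_other"))
    check_number(get(nm), nm, lower = 0)
  check_number(attraction_fraction, "attraction_fraction", lower = 0, upper = 1)
  check_number(displacement_sd, "displacement_sd", lower = 1e-12)
  check_number(seed, "seed")
  structure(list(field_width = field_width, field_height = field_height,
                 n_cdc1 = as.integer(n_cdc1), n_cd8 = as.integer(n_cd8),
                 n_cd4 = as.integer(n_cd4), n_other = as.integer(n_other),
                 attraction_fraction = attraction_fraction,
                 displacement_sd = displacement_sd, seed = as.integer(seed)),
            class = "tissue_sim_params")
}

# Marker intensity draws: clearly bimodal log-normal, positive vs negative.
intensity_draw <- function(n, positive) {
  ifelse(positive, rlnorm(n, log(25), 0.35), rlnorm(n, log(2), 0.5))
}

#' Generate a synthetic mIF cell table
#'
#' @param params a \code{\link{tissue_sim_params}} object.
#' @return data.frame (one row per cell): \code{cell_id}, \code{x_um},
#'   \code{y_um}, marker intensities \code{BATF3}, \code{CD3}, \code{CD8},
#'   and the hidden-truth \code{phenotype} label
#'   (cDC1 / CD8T / CD4T / other). Marker intensities are generated
#'   consistently with the phenotype (cDC1: BATF3+; CD8T: CD3+CD8+;
#'   CD4T: CD3+ only) so the thresholding/phenotyping stages can be run
#'   end-to-end on the output.
#' @details Attracted T cells whose displaced position falls outside the
#'   field are resampled (rejection), preserving the displacement
#'   distribution. Deterministic given \code{params$seed}.
#' @export
gen_tissue <- function(params) {
  stopifnot(inherits(params, "tissue_sim_params"))
  p <- params
  with_seed(substream_seed(p$seed, "tissue"), {
    w <- p$field_width; h <- p$field_height

    unif_xy <- function(n) cbind(runif(n, 0, w), runif(n, 0, h))

    cdc1 <- unif_xy(p$n_cdc1)

    place_t <- function(n) {
      if (n == 0L) return(cbind(numeric(0), numeric(0)))
      attracted <- p$n_cdc1 > 0L & runif(n) < p$attraction_fraction
      xy <- unif_xy(n)
      idx <- which(attracted)
      while (length(idx)) {
        anchor <- cdc1[sample.int(p$n_cdc1, length(idx), replace = TRUE), , drop = FALSE]
        prop <- anchor + matrix(rnorm(2 * length(idx), 0, p$displacement_sd),
                                ncol = 2)
        ok <- prop[, 1] >= 0 & prop[, 1] <= w & prop[, 2] >= 0 & prop[, 2] <= h
        xy[idx[ok], ] <- prop[ok, , drop = FALSE]
        idx <- idx[!ok]
      }
      xy
    }

    cd8 <- place_t(p$n_cd8)
    cd4 <- place_t(p$n_cd4)
    other <- unif_xy(p$n_other)

    xy <- rbind(cdc1, cd8, cd4, other)
    pheno <- rep(c("cDC1", "CD8T", "CD4T", "other"),
                 c(p$n_cdc1, p$n_cd8, p$n_cd4, p$n_other))
    n <- nrow(xy)
    data.frame(
      cell_id = sprintf("C%05d", seq_len(n)),
      x_um = xy[, 1], y_um = xy[, 2],
      BATF3 = intensity_draw(n, pheno == "cDC1"),
      CD3 = intensity_draw(n, pheno %in% c("CD8T", "CD4T")),
      CD8 = intensity_draw(n, pheno == "CD8T"),
      phenotype = pheno,
      stringsAsFactors = FALSE)
  })
}
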