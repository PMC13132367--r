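# Lightweight S3 containers shared across modules.

#' Construct a gene-by-sample count matrix
#'
#' @param counts numeric matrix of non-negative integer counts with unique
#'   gene symbols as rownames and sample ids as colnames.
#' @return An object of class \code{count_matrix}: a list with elements
#'   \code{counts} (integer matrix) and \code{lib_sizes} (column sums).
#' @export
count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop_("'counts' must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_("'counts' needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop_("duplicate gene ids: ",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (any(counts < 0)) stop_("negative counts")
  if (any(abs(counts - round(counts)) > 1e-8)) stop_("counts must be integers")
  storage.mode(counts) <- "double"
  structure(list(counts = counts, lib_sizes = colSums(counts)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples; median library size %s\n",
              nrow(x$counts), ncol(x$counts),
              format(median(x$lib_sizes), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# Accept either a count_matrix or a bare matrix in user-facing functions.
as_count_matrix <- function(x) {
  if (inherits(x, "count_matrix")) x else count_matrix(x)
}

#' Construct a gene signature
#'
#' A named, ordered set of gene symbols with per-gene provenance flags
#' recording how each gene entered the signature (candidate pool,
#' detectability filter, importance filter, or literature curation).
#'
#' @param name signature name (e.g. \code{"cDC1"}, \code{"CD8"}, \code{"NK"}).
#' @param genes character vector of gene symbols (non-empty, deduplicated
#'   preserving first occurrence).
#' @param provenance character vector recycled over genes; one of
#'   \code{"candidate"}, \code{"detectability-passed"}, \code{"importance-passed"},
#'   \code{"curated"}.
#' @return Object of class \code{gene_signature}.
#' @export
gene_signature <- function(name, genes, provenance = "curated") {
  if (length(genes) == 0L) stop_("a gene signature cannot be empty")
  genes <- as.character(genes[!duplicated(genes)])
  provenance <- rep_len(provenance, length(genes))
  ok <- c("candidate", "detectability-passed", "importance-passed", "curated")
  if (!all(provenance %in% ok))
    stop_("provenance must be one of: ", paste(ok, collapse = ", "))
  structure(list(name = name, genes = genes,
                 provenance = setNames(provenance, genes)),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d genes (%s%s)\n", x$name, length(x$genes),
              paste(head(x$genes, 5), collapse = ", "),
              if (length(x$genes) > 5) ", ..." else ""))
  invisible(x)
}

#' Default three-gene cDC1 signature (BATF3, XCR1, CLEC9A)
#' @return A \code{\link{gene_signature}} with the canonical cDC1 trio.
#' @export
cdc1_signature <- function() gene_signature("cDC1", c("BATF3", "XCR1", "CLEC9A"))

#' Construct a cell-by-gene spatial transcript matrix
#'
#' @param counts gene-by-cell matrix of non-negative integer counts.
#' @param cells data.frame with columns \code{cell_id}, \code{x_um},
#'   \code{y_um} (coordinates in microns), one row per column of
#'   \code{counts}, in the same order.
#' @return Object of class \code{cell_transcript_matrix} with elements
#'   \code{counts}, \code{cells} and \code{totals} (per-cell molecule totals).
#' @export
cell_transcript_matrix <- function(counts, cells) {
  if (!is.matrix(counts)) stop_("'counts' must be a matrix")
  req <- c("cell_id", "x_um", "y_um")
  miss <- setdiff(req, names(cells))
  if (length(miss)) stop_("cells table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(cells) != ncol(counts)) stop_("cells table and count columns disagree")
  if (!all(is.finite(cells$x_um)) || !all(is.finite(cells$y_um)))
    stop_("cell coordinates must be finite")
  if (any(counts < 0)) stop_("negative counts")
  colnames(counts) <- as.character(cells$cell_id)
  structure(list(counts = counts, cells = cells, totals = colSums(counts)),
            class = "cell_transcript_matrix")
}

#' @export
print.cell_transcript_matrix <- function(x, ...) {
  cat(sprintf("cell_transcript_matrix: %d genes x %d cells; median molecules/cell %.0f\n",
              nrow(x$counts), ncol(x$counts), median(x$totals)))
  invisible(x)
}

#' Excluded-sample sentinel
#'
#' Spatial distance statistics require at least one cell of each phenotype;
#' samples that fail this are excluded from analysis rather than raising an
#' error. The sentinel is distinct from both a numeric result and an error.
#'
#' @param reason character reason for exclusion.
#' @return Object of class \code{excluded_sample}.
#' @export
excluded_sample <- function(reason) {
  structure(list(reason = reason), class = "excluded_sample")
}

#' Test for the excluded-sample sentinel
#' @param x object to test.
#' @return TRUE if \code{x} is an \code{\link{excluded_sample}}.
#' @export
is_excluded <- function(x) inherits(x, "excluded_sample")

#' @export
print.excluded_sample <- function(x, ...) {
  cat("excluded sample:", x$reason, "\n")
  invisible(x)
}
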