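# Plain-text readers/writers: counts (gzip TSV, MTX trio), GMT gene sets,
# cell tables and clinical CSV, flat key-value configs.

#' Write a count matrix as gzip TSV
#'
#' Genes in rows (first column \code{gene}), one column per sample.
#'
#' @param cm a \code{\link{count_matrix}} (or gene-by-sample matrix).
#' @param path output path (written gzip-compressed when it ends in .gz).
#' @return \code{path}, invisibly.
#' @export
write_count_matrix_tsv <- function(cm, path) {
  cm <- as_count_matrix(cm)
  dt <- data.table::data.table(gene = rownames(cm$counts))
  dt <- cbind(dt, data.table::as.data.table(cm$counts))
  data.table::fwrite(dt, path, sep = "\t", compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Write a count matrix as an MTX triplet with sidecars
#'
#' \code{matrix.mtx} (MatrixMarket coordinate format), \code{genes.tsv} and
#' \code{barcodes.tsv} in \code{dir}.
#'
#' @param cm a \code{\link{count_matrix}} or matrix.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_count_matrix_mtx <- function(cm, dir) {
  cm <- as_count_matrix(cm)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(cm$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(cm$counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

read_expression_tsv <- function(path) {
  # read.delim via file() handles gzip transparently (fread would need R.utils)
  dt <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (names(dt)[1] != "gene")
    stop_("malformed header in ", path, ": first column must be 'gene'")
  genes <- as.character(dt[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) stop_("duplicated gene row(s): ", paste(dup, collapse = ", "))
  m <- as.matrix(dt[, -1])
  rownames(m) <- genes
  if (any(is.na(m))) stop_("missing values in expression matrix ", path)
  if (any(m < 0)) stop_("negative counts in ", path)
  m
}

read_expression_mtx <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  lines <- readLines(mtx)
  body <- which(!startsWith(lines, "%"))
  if (length(body) < 1L) stop_("malformed MTX file ", mtx)
  dims <- scan(text = lines[body[1]], quiet = TRUE)
  if (length(dims) != 3L) stop_("malformed MTX size line at line ", body[1])
  if (dims[1] != length(genes) || dims[2] != length(cells))
    stop_("MTX dimensions disagree with sidecars (",
          dims[1], "x", dims[2], " vs ", length(genes), " genes, ",
          length(cells), " barcodes)")
  m <- matrix(0, dims[1], dims[2], dimnames = list(genes, cells))
  for (ln in body[-1]) {
    trip <- scan(text = lines[ln], quiet = TRUE)
    if (length(trip) != 3L) stop_("malformed MTX triplet at line ", ln)
    if (trip[1] < 1 || trip[1] > dims[1] || trip[2] < 1 || trip[2] > dims[2])
      stop_("MTX index out of range at line ", ln, ": (",
            trip[1], ", ", trip[2], ")")
    m[trip[1], trip[2]] <- trip[3]
  }
  if (anyDuplicated(genes))
    stop_("duplicated gene row(s): ",
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m
}

#' Read an expression matrix (gzip TSV or MTX trio)
#'
#' @param path a \code{.tsv}/\code{.tsv.gz} file or a directory holding
#'   \code{matrix.mtx}, \code{genes.tsv}, \code{barcodes.tsv}.
#' @param as_counts validate and wrap as a \code{\link{count_matrix}}
#'   (default); set FALSE for already-normalized values.
#' @return A \code{count_matrix}, or a bare matrix when
#'   \code{as_counts = FALSE}.
#' @export
read_expression <- function(path, as_counts = TRUE) {
  if (!file.exists(path)) stop_("no such file or directory: ", path)
  m <- if (dir.exists(path)) read_expression_mtx(path) else read_expression_tsv(path)
  if (as_counts) count_matrix(m) else m
}

#' Read gene sets from a GMT file
#'
#' Each line: set name, description, tab-separated gene symbols. Genes are
#' deduplicated preserving first occurrence; duplicate set names and empty
#' sets are rejected with the offending line number.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop_("GMT line ", i, " has fewer than 3 fields")
    nm <- f[1]
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    genes <- genes[!duplicated(genes)]
    if (length(genes) == 0L) stop_("GMT line ", i, " has an empty gene set")
    if (nm %in% names(sets)) stop_("duplicate set name '", nm, "' at line ", i)
    sets[[nm]] <- genes
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-cell table from CSV
#'
#' @param path CSV with at least \code{cell_id}, \code{x_um}, \code{y_um}
#'   (coordinates in microns); extra columns are preserved untouched.
#' @param required required column names.
#' @return data.frame.
#' @export
read_cell_table <- function(path, required = c("cell_id", "x_um", "y_um")) {
  df <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) stop_("missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$x_um)) || any(!is.finite(df$y_um)))
    stop_("NA or non-finite coordinates in ", path)
  df
}

#' Write a per-cell table to CSV
#' @param table data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_cell_table <- function(table, path) {
  data.table::fwrite(table, path, sep = ",")
  invisible(path)
}

#' Read a clinical table from CSV
#'
#' @param path CSV with \code{sample_id} and \code{response}; optional
#'   \code{os_time}, \code{os_event}.
#' @return data.frame with a \code{response_group} factor added.
#' @export
read_clinical <- function(path) {
  df <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
  miss <- setdiff(c("sample_id", "response"), names(df))
  if (length(miss)) stop_("missing column(s): ", paste(miss, collapse = ", "))
  df$response_group <- group_response(df$response)
  df
}

#' Read a flat key-value configuration file
#'
#' One \code{key = value} pair per line; \code{#} comments and blank lines
#' ignored. Values are parsed as numbers or logicals when possible;
#' comma-separated values become vectors.
#'
#' @param path config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (i in seq_along(lines)) {
    kv <- regmatches(lines[i], regexec("^([^=]+)=(.*)$", lines[i]))[[1]]
    if (length(kv) != 3L) stop_("malformed config line: '", lines[i], "'")
    key <- trimws(kv[2]); val <- trimws(kv[3])
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    parsed <- suppressWarnings(as.numeric(parts))
    v <- if (!anyNA(parsed)) parsed
         else if (all(toupper(parts) %in% c("TRUE", "FALSE"))) as.logical(toupper(parts))
         else parts
    cfg[[key]] <- v
  }
  cfg
}
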