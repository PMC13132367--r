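# Independent oracles, deliberately written step-by-step (loops, no shared
# code with R/) so each checks its implementation by a second route.

# Clean-room kernel-CDF rank enrichment score: per gene Gaussian-kernel CDF
# (bandwidth sd/4), symmetric rank statistic |i - p/2| over the per-sample
# ordering, weighted KS walk, difference of extrema.
oracle_gsva <- function(expr, genes, tau = 1) {
  p <- nrow(expr); n <- ncol(expr)
  z <- matrix(0, p, n)
  for (i in seq_len(p)) {
    h <- sd(expr[i, ]) / 4
    for (j in seq_len(n)) {
      z[i, j] <- if (h == 0) 0.5 else mean(pnorm((expr[i, j] - expr[i, ]) / h))
    }
  }
  out <- numeric(n)
  for (j in seq_len(n)) {
    ord <- order(z[, j], decreasing = TRUE)
    inset <- rownames(expr)[ord] %in% genes
    rstat <- abs(seq_len(p) - p / 2)^tau
    den_in <- sum(rstat[inset]); den_out <- sum(!inset)
    cum_in <- 0; cum_out <- 0
    mx <- 0; mn <- 0
    for (i in seq_len(p)) {
      if (inset[i]) cum_in <- cum_in + rstat[i] else cum_out <- cum_out + 1
      w <- cum_in / den_in - cum_out / den_out
      if (w > mx) mx <- w
      if (w < mn) mn <- w
    }
    out[j] <- mx + mn
  }
  setNames(out, colnames(expr))
}

# Brute-force directional mean nearest-neighbour distance.
oracle_nn_mean <- function(table, from, to) {
  f <- table[table$phenotype == from, ]
  t_ <- table[table$phenotype == to, ]
  d <- numeric(nrow(f))
  for (i in seq_len(nrow(f)))
    d[i] <- min(sqrt((f$x_um[i] - t_$x_um)^2 + (f$y_um[i] - t_$y_um)^2))
  mean(d)
}

# Brute-force per-cDC1 triad radii.
oracle_triad <- function(table) {
  f <- table[table$phenotype == "cDC1", ]
  c8 <- table[table$phenotype == "CD8T", ]
  c4 <- table[table$phenotype == "CD4T", ]
  r <- numeric(nrow(f))
  for (i in seq_len(nrow(f))) {
    d8 <- min(sqrt((f$x_um[i] - c8$x_um)^2 + (f$y_um[i] - c8$y_um)^2))
    d4 <- min(sqrt((f$x_um[i] - c4$x_um)^2 + (f$y_um[i] - c4$y_um)^2))
    r[i] <- max(d8, d4)
  }
  r
}

# Brute-force Otsu: evaluate the between-class variance at every bin
# boundary of a 256-bin histogram; ties resolved at the middle candidate.
oracle_otsu <- function(values, n_bins = 256L) {
  edges <- seq(min(values), max(values), length.out = n_bins + 1L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  best <- -1; hits <- integer(0)
  for (k in seq_len(n_bins - 1L)) {
    thr <- edges[k + 1L]
    lo <- values[values <= thr]; hi <- values[values > thr]
    if (length(lo) == 0L || length(hi) == 0L) next
    # bin the class means as the histogram does
    blo <- pmin(findInterval(lo, edges, rightmost.closed = TRUE), n_bins)
    bhi <- pmin(findInterval(hi, edges, rightmost.closed = TRUE), n_bins)
    bcv <- length(lo) * length(hi) * (mean(mids[blo]) - mean(mids[bhi]))^2
    tol <- 1e-12 * max(1, best)
    if (bcv > best + tol) { best <- bcv; hits <- k }
    else if (bcv >= best - tol) hits <- c(hits, k)
  }
  edges[hits[ceiling(length(hits) / 2)] + 1L]
}

# Small deterministic cell table for geometry tests.
toy_cells <- function(xy, phenotype) {
  data.frame(cell_id = sprintf("c%02d", seq_len(nrow(xy))),
             x_um = xy[, 1], y_um = xy[, 2], phenotype = phenotype,
             stringsAsFactors = FALSE)
}

# Random phenotyped point pattern for oracle-equivalence sweeps.
random_pattern <- function(n_total, seed) {
  set.seed(seed)
  n1 <- sample.int(max(1, n_total %/% 10), 1)
  n2 <- sample.int(max(1, n_total %/% 2), 1)
  n3 <- max(1L, n_total - n1 - n2)
  toy_cells(cbind(runif(n1 + n2 + n3, 0, 1000), runif(n1 + n2 + n3, 0, 1000)),
            rep(c("cDC1", "CD8T", "CD4T"), c(n1, n2, n3)))
}

# Minimal in-memory cell_transcript_matrix from a dense count matrix.
toy_ctm <- function(counts, x = NULL, y = NULL) {
  n <- ncol(counts)
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("c%03d", seq_len(n))
  cells <- data.frame(cell_id = colnames(counts),
                      x_um = x %||% (seq_len(n) * 100),
                      y_um = y %||% rep(0, n), stringsAsFactors = FALSE)
  cell_transcript_matrix(counts, cells)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
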