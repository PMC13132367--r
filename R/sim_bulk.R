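# Synthetic bulk RNA-seq cohorts with latent cell-type abundance factors.

#' Parameters for the bulk cohort generator
#'
#' The generator emulates a checkpoint-inhibitor trial cohort: gene-by-sample
#' negative-binomial counts in which each immune cell type (cDC1, CD8, NK)
#' contributes a latent per-sample abundance factor. Signature genes of type
#' t have their mean multiplied by \code{exp(z_t)} where \code{z_t} is the
#' type's standard-normal latent; the cDC1 and CD8 latents are correlated
#' (the structure repeatedly observed across trial cohorts), and clinical
#' response is drawn through a logistic link on the cDC1 latent.
#'
#' @param n_samples number of samples (>= 4).
#' @param n_genes total number of genes (must exceed the summed signature sizes).
#' @param signature_sizes named integer vector of planted signature sizes per
#'   cell type; default \code{c(cDC1 = 20, CD8 = 20, NK = 15)}.
#' @param latent_corr correlation between the cDC1 and CD8 latents, in [-1, 1].
#' @param response_effect shift of the response log-odds per cDC1 latent SD.
#' @param nb_dispersion NB dispersion alpha (variance mu + alpha mu^2); 0 gives
#'   Poisson counts.
#' @param baseline_mean median baseline gene mean (gene means are log-normal
#'   around this value, sdlog 1).
#' @param os_effect log-hazard decrease per cDC1 latent SD in the optional
#'   survival fields (exponential survival, administrative censoring at 36
#'   months).
#' @param seed integer seed; all randomness derives from it.
#' @return A validated list of class \code{bulk_sim_params}.
#' @export
bulk_sim_params <- function(n_samples = 200L, n_genes = 2000L,
                            signature_sizes = c(cDC1 = 20L, CD8 = 20L, NK = 15L),
                            latent_corr = 0.6, response_effect = 1.0,
                            nb_dispersion = 0.3, baseline_mean = 50,
                            os_effect = 0.5, seed = 1L) {
  check_number(n_samples, "n_samples", lower = 4)
  check_number(n_genes, "n_genes", lower = 1)
  if (is.null(names(signature_sizes)) || any(names(signature_sizes) == ""))
    stop_("'signature_sizes' must be a named vector of cell types")
  if (any(signature_sizes < 1)) stop_("signature sizes must be >= 1")
  if (sum(signature_sizes) >= n_genes)
    stop_("n_genes must exceed the total number of signature genes")
  check_number(latent_corr, "latent_corr", lower = -1, upper = 1)
  check_number(response_effect, "response_effect")
  check_number(nb_dispersion, "nb_dispersion", lower = 0)
  check_number(baseline_mean, "baseline_mean", lower = 1e-8)
  check_number(os_effect, "os_effect")
  check_number(seed, "seed")
  structure(list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
                 signature_sizes = signature_sizes, latent_corr = latent_corr,
                 response_effect = response_effect, nb_dispersion = nb_dispersion,
                 baseline_mean = baseline_mean, os_effect = os_effect,
                 seed = as.integer(seed)),
            class = "bulk_sim_params")
}

# Latent factor covariance: unit variances, latent_corr between cDC1 and CD8
# (when both types are present), other pairs independent.
latent_sigma <- function(types, latent_corr) {
  k <- length(types)
  sigma <- diag(k)
  dimnames(sigma) <- list(types, types)
  if (all(c("cDC1", "CD8") %in% types)) {
    sigma["cDC1", "CD8"] <- latent_corr
    sigma["CD8", "cDC1"] <- latent_corr
  }
  sigma
}

#' Generate a synthetic bulk RNA-seq cohort
#'
#' @param params a \code{\link{bulk_sim_params}} object.
#' @return A list with elements \code{counts} (a \code{\link{count_matrix}}),
#'   \code{clinical} (data.frame: sample_id, response CR/PR/SD/PD,
#'   response_group CR/PR vs SD vs PD, os_time, os_event),
#'   \code{latents} (sample-by-type matrix of true latent factors) and
#'   \code{signature_genes} (list of planted genes per type).
#' @details Deterministic given \code{params$seed}. Signature gene symbols for
#'   cDC1 start with the canonical trio BATF3, XCR1, CLEC9A and for CD8 with
#'   CD8A, CD8B; remaining planted and background genes carry synthetic
#'   symbols.
#' @export
gen_bulk_cohort <- function(params) {
  stopifnot(inherits(params, "bulk_sim_params"))
  p <- params
  types <- names(p$signature_sizes)
  sigma <- latent_sigma(types, p$latent_corr)
  eig <- eigen(sigma, symmetric = TRUE)
  if (any(eig$values < -1e-8))
    stop_("latent covariance is not positive semi-definite (latent_corr = ",
          p$latent_corr, ")")
  # eigen factor rather than Cholesky: tolerates the singular |corr| = 1 case
  fac <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), length(eig$values)) %*%
    t(eig$vectors)

  with_seed(substream_seed(p$seed, "bulk"), {
    z <- matrix(rnorm(p$n_samples * length(types)), p$n_samples) %*% fac
    colnames(z) <- types

    sig_genes <- list()
    canon <- list(cDC1 = c("BATF3", "XCR1", "CLEC9A"), CD8 = c("CD8A", "CD8B"),
                  NK = c("NCR1", "KLRD1"))
    for (t in types) {
      k <- p$signature_sizes[[t]]
      base <- canon[[t]] %||% character(0)
      base <- head(base, k)
      extra <- if (k > length(base))
        sprintf("%s.SIG%02d", toupper(t), seq_len(k - length(base))) else character(0)
      sig_genes[[t]] <- c(base, extra)
    }
    n_bg <- p$n_genes - length(unlist(sig_genes))
    gene_ids <- c(unlist(sig_genes, use.names = FALSE),
                  sprintf("BG%05d", seq_len(n_bg)))

    base_mean <- rlnorm(p$n_genes, meanlog = log(p$baseline_mean), sdlog = 1)
    mu <- matrix(base_mean, p$n_genes, p$n_samples)
    offset <- 0L
    for (t in types) {
      idx <- offset + seq_len(p$signature_sizes[[t]])
      mu[idx, ] <- mu[idx, ] * rep(exp(z[, t]), each = length(idx))
      offset <- offset + p$signature_sizes[[t]]
    }

    counts <- if (p$nb_dispersion > 0)
      matrix(rnbinom(length(mu), mu = mu, size = 1 / p$nb_dispersion), nrow(mu))
    else matrix(rpois(length(mu), mu), nrow(mu))
    dimnames(counts) <- list(gene_ids, sprintf("S%03d", seq_len(p$n_samples)))

    benefit <- rbinom(p$n_samples, 1, plogis(p$response_effect * z[, "cDC1"]))
    response <- ifelse(benefit == 1,
                       ifelse(runif(p$n_samples) < 0.2, "CR", "PR"),
                       ifelse(runif(p$n_samples) < 0.5, "SD", "PD"))
    os_raw <- rexp(p$n_samples, rate = 0.08 * exp(-p$os_effect * z[, "cDC1"]))
    os_time <- pmin(os_raw, 36)
    clinical <- data.frame(
      sample_id = colnames(counts),
      response = factor(response, levels = c("CR", "PR", "SD", "PD")),
      response_group = group_response(response),
      os_time = round(os_time, 3),
      os_event = as.integer(os_raw <= 36),
      stringsAsFactors = FALSE)
    rownames(z) <- colnames(counts)

    list(counts = count_matrix(counts), clinical = clinical,
         latents = z, signature_genes = sig_genes)
  })
}

#' Collapse CR/PR into one clinical-benefit group
#'
#' CR and PR are merged (few complete responses); SD and PD stay separate.
#'
#' @param response character or factor vector with levels CR, PR, SD, PD.
#' @return Factor with levels \code{"CR/PR"}, \code{"SD"}, \code{"PD"}.
#' @export
group_response <- function(response) {
  response <- as.character(response)
  bad <- setdiff(unique(response), c("CR", "PR", "SD", "PD", NA))
  if (length(bad)) stop_("unknown response label(s): ", paste(bad, collapse = ", "))
  factor(ifelse(response %in% c("CR", "PR"), "CR/PR", response),
         levels = c("CR/PR", "SD", "PD"))
}
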