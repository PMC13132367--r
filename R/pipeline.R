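# Orchestrator: chains the analysis stages into reproducible arms and
# writes a manifest making every output regenerable from config + seed.

stage_keys <- list(
  "simulate-bulk" = c("stage", "out_dir", "seed", "n_samples", "n_genes",
                      "latent_corr", "response_effect", "nb_dispersion",
                      "baseline_mean", "os_effect"),
  "simulate-tissue" = c("stage", "out_dir", "seed", "field_width",
                        "field_height", "n_cdc1", "n_cd8", "n_cd4", "n_other",
                        "attraction_fraction", "displacement_sd"),
  "simulate-st" = c("stage", "out_dir", "seed", "n_cells", "marker_fold",
                    "activation_fold", "depth", "field_width", "field_height"),
  "signatures" = c("stage", "out_dir", "seed", "counts", "clinical",
                   "signatures_gmt", "candidates_gmt", "rho_min", "alpha",
                   "min_count", "min_frac"),
  "mif" = c("stage", "out_dir", "seed", "cells", "labels", "margin_um",
            "bin_um", "min_cells"),
  "hubs" = c("stage", "out_dir", "seed", "counts", "cells", "radius_um",
             "min_molecules", "n_perm", "resolution", "knn",
             "gene_sets_gmt"),
  "run" = c("stage", "out_dir", "seed"))

config_hash <- function(cfg) {
  cfg <- cfg[order(names(cfg))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(vapply(names(cfg), function(k)
    paste0(k, "=", paste(format(cfg[[k]], digits = 15), collapse = ",")),
    character(1)), tmp)
  unname(md5sum(tmp))
}

manifest_new <- function(cfg, inputs = character(0)) {
  # directory inputs (e.g. an MTX trio) are checksummed file by file
  inputs <- as.character(unlist(lapply(inputs, function(p) {
    if (dir.exists(p)) list.files(p, full.names = TRUE) else p
  })))
  inputs <- inputs[file.exists(inputs) & !dir.exists(inputs)]
  list(tool = "cdc1niche", version = as.character(packageVersion("cdc1niche")),
       stage = cfg$stage, seed = cfg$seed, config = cfg,
       config_hash = config_hash(cfg),
       input_checksums = if (length(inputs)) as.list(md5sum(inputs)) else list(),
       stages = list())
}

manifest_log <- function(man, stage, n_in, n_out) {
  man$stages[[length(man$stages) + 1L]] <-
    list(stage = stage, rows_in = n_in, rows_out = n_out)
  man
}

#' Run one pipeline stage from a configuration
#'
#' Stages: \code{simulate-bulk}, \code{simulate-tissue}, \code{simulate-st}
#' (synthetic-data generators); \code{signatures} (normalize, optionally
#' derive signatures from candidate pools across cohorts, score, rescale,
#' response-group tests and signature correlations); \code{mif} (threshold,
#' phenotype, trim, area, densities, distances, group tests); \code{hubs}
#' (QC, two-method consensus detection, hub construction, classification,
#' density, differential expression, optional preranked GSEA); \code{run}
#' (self-contained demo chaining simulation and all three arms). Unknown
#' configuration keys are rejected before anything runs; every run writes
#' \code{manifest.json} echoing the resolved parameters, seed and input
#' checksums so any reported number is regenerable.
#'
#' @param config path to a flat key-value config file (see
#'   \code{\link{read_config}}) or an equivalent named list; must contain
#'   \code{stage}.
#' @param out_dir output directory (overrides \code{out_dir} in the config).
#' @param seed seed override.
#' @return The run manifest (list), invisibly; all tabular outputs are
#'   written as CSV under \code{out_dir}.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- if (is.character(config) && length(config) == 1L) read_config(config)
         else config
  if (is.null(cfg$stage)) stop_("config must name a 'stage'")
  stage <- as.character(cfg$stage)
  if (!stage %in% names(stage_keys))
    stop_("unknown stage '", stage, "'; known: ",
          paste(names(stage_keys), collapse = ", "))
  unknown <- setdiff(names(cfg), stage_keys[[stage]])
  if (length(unknown))
    stop_("unknown config key(s) for stage '", stage, "': ",
          paste(unknown, collapse = ", "))
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(seed)) cfg$seed <- seed
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (is.null(cfg$out_dir)) stop_("an output directory is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  man <- switch(stage,
    "simulate-bulk" = stage_simulate_bulk(cfg),
    "simulate-tissue" = stage_simulate_tissue(cfg),
    "simulate-st" = stage_simulate_st(cfg),
    "signatures" = stage_signatures(cfg),
    "mif" = stage_mif(cfg),
    "hubs" = stage_hubs(cfg),
    "run" = stage_run_all(cfg))

  jsonlite::write_json(man, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}

stage_simulate_bulk <- function(cfg) {
  p <- bulk_sim_params(
    n_samples = cfg$n_samples %||% 200, n_genes = cfg$n_genes %||% 2000,
    latent_corr = cfg$latent_corr %||% 0.6,
    response_effect = cfg$response_effect %||% 1.0,
    nb_dispersion = cfg$nb_dispersion %||% 0.3,
    baseline_mean = cfg$baseline_mean %||% 50,
    os_effect = cfg$os_effect %||% 0.5, seed = cfg$seed)
  sim <- gen_bulk_cohort(p)
  man <- manifest_new(cfg)
  write_count_matrix_tsv(sim$counts, file.path(cfg$out_dir, "counts.tsv.gz"))
  write.csv(sim$clinical, file.path(cfg$out_dir, "clinical.csv"), row.names = FALSE)
  lat <- data.frame(sample_id = rownames(sim$latents), sim$latents)
  write.csv(lat, file.path(cfg$out_dir, "latents.csv"), row.names = FALSE)
  write_gmt(sim$signature_genes, file.path(cfg$out_dir, "signature_genes.gmt"))
  manifest_log(man, "simulate-bulk", 0L, ncol(sim$counts$counts))
}

stage_simulate_tissue <- function(cfg) {
  p <- tissue_sim_params(
    field_width = cfg$field_width %||% 1000,
    field_height = cfg$field_height %||% 1000,
    n_cdc1 = cfg$n_cdc1 %||% 30, n_cd8 = cfg$n_cd8 %||% 200,
    n_cd4 = cfg$n_cd4 %||% 200, n_other = cfg$n_other %||% 1000,
    attraction_fraction = cfg$attraction_fraction %||% 0,
    displacement_sd = cfg$displacement_sd %||% 10, seed = cfg$seed)
  cells <- gen_tissue(p)
  man <- manifest_new(cfg)
  write_cell_table(cells, file.path(cfg$out_dir, "cells.csv"))
  manifest_log(man, "simulate-tissue", 0L, nrow(cells))
}

stage_simulate_st <- function(cfg) {
  p <- st_sim_params(
    n_cells = cfg$n_cells %||% 3000, marker_fold = cfg$marker_fold %||% 20,
    activation_fold = cfg$activation_fold %||% 3, depth = cfg$depth %||% 230,
    field_width = cfg$field_width %||% 500,
    field_height = cfg$field_height %||% 500, seed = cfg$seed)
  ctm <- gen_spatial_transcriptome(p)
  man <- manifest_new(cfg)
  write_count_matrix_mtx(ctm$counts, file.path(cfg$out_dir, "st_counts"))
  write_cell_table(ctm$cells, file.path(cfg$out_dir, "st_cells.csv"))
  manifest_log(man, "simulate-st", 0L, ncol(ctm$counts))
}

stage_signatures <- function(cfg) {
  if (is.null(cfg$counts)) stop_("stage 'signatures' needs 'counts'")
  count_paths <- as.character(cfg$counts)
  clin_paths <- as.character(cfg$clinical %||% character(0))
  inputs <- c(count_paths, clin_paths, cfg$signatures_gmt, cfg$candidates_gmt)
  man <- manifest_new(cfg, unlist(inputs))

  cohorts <- lapply(count_paths, function(pth) {
    cm <- read_expression(pth)
    norm <- log2_cpm(cm, compute_tmm_factors(cm))
    list(counts = cm, norm = norm)
  })
  names(cohorts) <- paste0("cohort", seq_along(cohorts))
  man <- manifest_log(man, "normalize", length(cohorts),
                      sum(vapply(cohorts, function(co) ncol(co$norm), numeric(1))))

  signatures <- list()
  if (!is.null(cfg$signatures_gmt)) {
    sets <- read_gmt(cfg$signatures_gmt)
    signatures <- c(signatures, lapply(names(sets), function(nm)
      gene_signature(nm, sets[[nm]])))
    names(signatures) <- names(sets)
  }
  if (!is.null(cfg$candidates_gmt)) {
    pools <- read_gmt(cfg$candidates_gmt)
    for (nm in names(pools)) {
      sg <- derive_signature(cohorts, pools[[nm]], name = nm,
                             rho_min = cfg$rho_min %||% 0.4,
                             alpha = cfg$alpha %||% 0.05,
                             min_count = cfg$min_count %||% 5,
                             min_frac = cfg$min_frac %||% 0.5)
      if (!is.null(sg)) signatures[[nm]] <- sg
    }
    man <- manifest_log(man, "derive", length(pools), length(signatures))
  }
  if (length(signatures) == 0L) signatures <- list(cDC1 = cdc1_signature())

  all_scores <- list(); all_tests <- list(); all_cors <- list()
  for (ci in names(cohorts)) {
    sc <- score_signatures(cohorts[[ci]]$norm, signatures)
    sc$cohort <- ci
    all_scores[[ci]] <- sc
    if (length(clin_paths) >= match(ci, names(cohorts))) {
      clin <- read_clinical(clin_paths[[match(ci, names(cohorts))]])
      for (snm in unique(sc$signature)) {
        v <- setNames(sc$raw_score[sc$signature == snm],
                      sc$sample_id[sc$signature == snm])
        gc_ <- group_compare(v, clin)
        gc_$cohort <- ci; gc_$signature <- snm
        all_tests[[paste(ci, snm)]] <- gc_
      }
    }
    if (length(signatures) >= 2L) {
      vecs <- lapply(names(signatures), function(snm)
        sc$raw_score[sc$signature == snm])
      names(vecs) <- names(signatures)
      cp <- correlation_panel(vecs, "pearson")
      cp$cohort <- ci
      all_cors[[ci]] <- cp
    }
  }
  scores <- do.call(rbind, all_scores)
  write.csv(scores, file.path(cfg$out_dir, "scores.csv"), row.names = FALSE)
  if (length(all_tests))
    write.csv(do.call(rbind, all_tests), file.path(cfg$out_dir, "group_tests.csv"),
              row.names = FALSE)
  if (length(all_cors))
    write.csv(do.call(rbind, all_cors), file.path(cfg$out_dir, "correlations.csv"),
              row.names = FALSE)
  jsonlite::write_json(
    list(signatures = lapply(signatures, function(s)
      if (inherits(s, "gene_signature")) s$genes else s)),
    file.path(cfg$out_dir, "signatures.json"), auto_unbox = TRUE, pretty = TRUE)
  manifest_log(man, "score", length(signatures), nrow(scores))
}

stage_mif <- function(cfg) {
  if (is.null(cfg$cells)) stop_("stage 'mif' needs 'cells'")
  paths <- as.character(cfg$cells)
  man <- manifest_new(cfg, paths)
  ids <- sub("\\.csv$", "", basename(paths))
  min_cells <- cfg$min_cells %||% 10

  summaries <- list(); dens <- list(); thr_all <- list()
  for (i in seq_along(paths)) {
    tab <- read_cell_table(paths[i])
    n_in <- nrow(tab)
    thr <- marker_thresholds(tab)
    tab <- assign_phenotypes(tab, thr)
    tab <- trim_border(tab, margin_um = cfg$margin_um %||% 20)
    if (nrow(tab) < min_cells) next
    area <- estimate_tissue_area(tab, bin_um = cfg$bin_um %||% 50)
    d <- densities(tab, area)
    d$sample_id <- ids[i]
    dens[[ids[i]]] <- d
    summaries[[ids[i]]] <- distance_summary(tab, ids[i])
    thr_all[[ids[i]]] <- as.list(thr)
    man <- manifest_log(man, paste0("mif:", ids[i]), n_in, nrow(tab))
  }
  summary_df <- do.call(rbind, summaries)
  write.csv(summary_df, file.path(cfg$out_dir, "distance_summary.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, dens), file.path(cfg$out_dir, "densities.csv"),
            row.names = FALSE)
  jsonlite::write_json(thr_all, file.path(cfg$out_dir, "thresholds.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  if (!is.null(cfg$labels)) {
    lab <- read.csv(cfg$labels, stringsAsFactors = FALSE)
    v <- setNames(summary_df$mean_dist_cdc1_cd8, summary_df$sample_id)
    l <- setNames(lab$label, lab$sample_id)[names(v)]
    if (length(unique(na.omit(l))) == 2L) {
      res <- group_distance_compare(v, l)
      jsonlite::write_json(res, file.path(cfg$out_dir, "group_tests.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
  }
  man
}

stage_hubs <- function(cfg) {
  if (is.null(cfg$counts) || is.null(cfg$cells))
    stop_("stage 'hubs' needs 'counts' and 'cells'")
  man <- manifest_new(cfg, c(cfg$counts, cfg$cells, cfg$gene_sets_gmt))
  m <- read_expression(cfg$counts)
  cells <- read_cell_table(cfg$cells)
  ctm <- cell_transcript_matrix(m$counts[, cells$cell_id, drop = FALSE], cells)
  n0 <- ncol(ctm$counts)
  ctm <- qc_filter(ctm, cfg$min_molecules %||% 50)
  man <- manifest_log(man, "qc", n0, ncol(ctm$counts))

  thr <- detect_threshold(ctm)
  clu <- detect_cluster(ctm, resolution = cfg$resolution %||% 2.0,
                        k = cfg$knn %||% 15, seed = cfg$seed)
  cons <- consensus_candidates(thr, clu)
  man <- manifest_log(man, "consensus", ncol(ctm$counts),
                      sum(cons$consensus != "none"))
  if (!any(cons$consensus != "none"))
    stop_("stage 'hubs': no consensus candidate cells detected")

  hs <- build_hubs(ctm, cons, radius_um = cfg$radius_um %||% 10)
  hs <- classify_hubs(hs)
  write.csv(hs$hubs, file.path(cfg$out_dir, "hubs.csv"), row.names = FALSE)
  man <- manifest_log(man, "hubs", sum(cons$consensus != "none"), nrow(hs$hubs))

  de <- tryCatch(hub_de(hs), error = function(e) NULL)
  if (!is.null(de)) {
    write.csv(de, file.path(cfg$out_dir, "hub_de.csv"), row.names = FALSE)
    man <- manifest_log(man, "de", nrow(hs$hubs), nrow(de))
    if (!is.null(cfg$gene_sets_gmt)) {
      sets <- read_gmt(cfg$gene_sets_gmt)
      stats <- setNames(sign(de$log2fc) * -log10(pmax(de$p, 1e-300)), de$gene)
      gs <- preranked_gsea(stats, sets, n_perm = cfg$n_perm %||% 1000,
                           seed = cfg$seed)
      write.csv(gs, file.path(cfg$out_dir, "gsea.csv"), row.names = FALSE)
      man <- manifest_log(man, "gsea", length(sets), sum(!is.na(gs$es)))
    }
  }
  man
}

stage_run_all <- function(cfg) {
  man <- manifest_new(cfg)
  sub <- function(d) file.path(cfg$out_dir, d)
  m1 <- run_pipeline(list(stage = "simulate-bulk", out_dir = sub("bulk_sim"),
                          seed = cfg$seed, n_samples = 60, n_genes = 600))
  m2 <- run_pipeline(list(stage = "signatures", out_dir = sub("signatures"),
                          seed = cfg$seed,
                          counts = file.path(sub("bulk_sim"), "counts.tsv.gz"),
                          clinical = file.path(sub("bulk_sim"), "clinical.csv"),
                          signatures_gmt = file.path(sub("bulk_sim"),
                                                     "signature_genes.gmt")))
  m3 <- run_pipeline(list(stage = "simulate-tissue", out_dir = sub("tissue_sim"),
                          seed = cfg$seed, attraction_fraction = 0.5))
  m4 <- run_pipeline(list(stage = "mif", out_dir = sub("mif"),
                          cells = file.path(sub("tissue_sim"), "cells.csv"),
                          seed = cfg$seed))
  m5 <- run_pipeline(list(stage = "simulate-st", out_dir = sub("st_sim"),
                          seed = cfg$seed, n_cells = 1500))
  m6 <- run_pipeline(list(stage = "hubs", out_dir = sub("hubs"),
                          counts = file.path(sub("st_sim"), "st_counts"),
                          cells = file.path(sub("st_sim"), "st_cells.csv"),
                          seed = cfg$seed, n_perm = 200))
  man$stages <- do.call(c, lapply(list(m1, m2, m3, m4, m5, m6),
                                  function(m) m$stages))
  man
}
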