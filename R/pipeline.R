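#' End-to-end pipeline configuration
#'
#' Either real input paths (a compound library and peak table for the
#' annotation stage, and/or the two mapping tables for the network stage)
#' or a [generator_config()] must be supplied; a configuration with
#' neither is an error.
#'
#' @param library_path,peaks_path CSV paths for the annotation stage
#'   (`NULL` to skip).
#' @param itm_path,tpm_path CSV/TSV paths of the ingredient-target and
#'   target-pathway mapping tables (`NULL` to use the generator).
#' @param generator an `itp_generator_config`, used when mapping paths are
#'   absent; also drives a synthetic annotation stage when `library_path`
#'   is absent.
#' @param tol_ppm annotation mass tolerance (ppm).
#' @param ratio_threshold enrichment ratio cut-off for the screen.
#' @param k_min smallest degree in the power-law fit of the PPI clustering
#'   spectrum; `NULL` skips the fit.
#' @param prune_isolated drop degree-0 nodes after network construction.
#' @param out_dir output directory; `NULL` writes nothing.
#' @param seed integer seed for the synthetic stages.
#' @return a list of class `itp_pipeline_config`.
#' @export
pipeline_config <- function(library_path = NULL, peaks_path = NULL,
                            itm_path = NULL, tpm_path = NULL,
                            generator = NULL,
                            tol_ppm = 5, ratio_threshold = 1,
                            k_min = NULL, prune_isolated = FALSE,
                            out_dir = NULL, seed = 1L) {
  have_maps <- !is.null(itm_path) && !is.null(tpm_path)
  if (!have_maps && is.null(generator)) {
    stop(paste("pipeline needs either both mapping tables",
               "(itm_path, tpm_path) or a generator config"), call. = FALSE)
  }
  if (!is.null(generator) && !inherits(generator, "itp_generator_config")) {
    stop("'generator' must come from generator_config()", call. = FALSE)
  }
  structure(list(
    library_path = library_path, peaks_path = peaks_path,
    itm_path = itm_path, tpm_path = tpm_path,
    generator = generator,
    tol_ppm = tol_ppm, ratio_threshold = ratio_threshold,
    k_min = k_min, prune_isolated = prune_isolated,
    out_dir = out_dir, seed = as.integer(seed)
  ), class = "itp_pipeline_config")
}

#' Run the full annotation-to-key-elements pipeline
#'
#' Chains the stages of a network-pharmacology screen: (1) annotate the
#' peak table against the compound library at the ppm tolerance and screen
#' for sample-versus-control enrichment; (2) build the merged
#' ingredient-pathway interaction network and its three subnetworks from
#' the mapping tables; (3) compute the metrics suite for all four networks
#' (bipartite density for the IPB network, power-law fit on the PPI
#' clustering spectrum); (4) rank ingredients and pathways by centrality.
#' Every count a results section would report (compounds annotated,
#' compounds enriched, nodes and edges per network) is logged via
#' `message()` so a run is auditable.
#'
#' When an annotation stage ran and at least one screened compound name
#' matches an ingredient id of the mapping, the mapping is restricted to
#' the screened ingredients before network construction; if a screen was
#' run and returned no enriched compound, the network stages are skipped
#' with a warning.
#'
#' @param cfg an `itp_pipeline_config`.
#' @return list with elements `annotation` (all hits), `screened`
#'   (enriched hits), `networks` (list of `itp_network`: IPI, TTI, IPB,
#'   PPI), `metrics` (list of `itp_metrics`), `summary` (the side-by-side
#'   statistics table), `key_ingredients`, `key_pathways` (ranked tables),
#'   and `files` (paths written, if `out_dir` was set).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "itp_pipeline_config"))
  gen <- NULL

  # ---- annotation + screen ----
  annotation <- screened <- NULL
  if (!is.null(cfg$library_path) || !is.null(cfg$peaks_path)) {
    if (is.null(cfg$library_path) || is.null(cfg$peaks_path)) {
      stop("annotation stage needs both 'library_path' and 'peaks_path'",
           call. = FALSE)
    }
    lib <- compound_library(.read_delim_auto(cfg$library_path))
    peaks <- .read_delim_auto(cfg$peaks_path)
    if (!all(c("feature_id", "mz") %in% names(peaks))) {
      stop(sprintf("peak table '%s' needs columns 'feature_id' and 'mz'",
                   cfg$peaks_path), call. = FALSE)
    }
    annotation <- annotate_peaks(peaks, lib, tol_ppm = cfg$tol_ppm)
    screened <- screen_enriched(annotation, ratio_threshold = cfg$ratio_threshold)
  } else if (!is.null(cfg$generator)) {
    pk <- generate_peak_table(seed = cfg$seed)
    annotation <- annotate_peaks(pk$peaks, pk$library, tol_ppm = cfg$tol_ppm)
    screened <- screen_enriched(annotation, ratio_threshold = cfg$ratio_threshold)
  }
  if (!is.null(annotation)) {
    message(sprintf("annotation: %d peak(s) annotated, %d enriched in sample",
                    length(unique(annotation$feature_id)),
                    length(unique(screened$feature_id))))
  }

  # ---- mappings ----
  if (!is.null(cfg$itm_path)) {
    itm <- read_mapping_table(cfg$itm_path, "ingredient-target")
    tpm <- read_mapping_table(cfg$tpm_path, "target-pathway")
  } else {
    gen <- generate_mappings(cfg$generator)
    itm <- gen$itm
    tpm <- gen$tpm
  }

  if (!is.null(screened)) {
    if (nrow(screened) == 0L) {
      warning("no enriched compounds: network stages skipped", call. = FALSE)
      return(list(annotation = annotation, screened = screened,
                  networks = NULL, metrics = NULL, summary = NULL,
                  key_ingredients = NULL, key_pathways = NULL, files = NULL))
    }
    hit_ings <- intersect(unique(screened$compound_name), names(itm))
    if (length(hit_ings)) {
      message(sprintf("restricting mapping to %d screened ingredient(s)",
                      length(hit_ings)))
      itm <- itm[hit_ings]
    }
  }

  # ---- networks ----
  ipi <- build_ipi(itm, tpm, prune = cfg$prune_isolated)
  networks <- list(
    IPI = ipi,
    TTI = subnetwork(ipi, "TTI"),
    IPB = subnetwork(ipi, "IPB"),
    PPI = subnetwork(ipi, "PPI")
  )
  for (net in networks) {
    message(sprintf("%s network: %d nodes, %d edges",
                    net$name, n_nodes(net), n_edges(net)))
  }

  # ---- metrics ----
  metrics <- list(
    IPI = network_metrics(networks$IPI),
    TTI = network_metrics(networks$TTI),
    IPB = network_metrics(networks$IPB, density_mode = "bipartite"),
    PPI = network_metrics(networks$PPI, k_min = cfg$k_min)
  )
  summary_tab <- metrics_table(metrics)
  key_ingredients <- rank_key_nodes(metrics$IPB, by = "degree")
  key_ingredients <- key_ingredients[key_ingredients$type == "ingredient", ,
                                     drop = FALSE]
  key_ingredients$rank <- seq_len(nrow(key_ingredients))
  key_pathways <- rank_key_nodes(metrics$PPI, by = "composite")

  # ---- outputs ----
  files <- NULL
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character()
    if (!is.null(annotation)) {
      files <- c(files,
                 write_hits(annotation, file.path(cfg$out_dir, "annotation_hits.csv")),
                 write_hits(screened, file.path(cfg$out_dir, "screened_hits.csv")))
    }
    for (net in networks) {
      files <- c(files,
        write_pajek(net, file.path(cfg$out_dir, paste0(tolower(net$name), ".net"))),
        write_graphml(net, file.path(cfg$out_dir, paste0(tolower(net$name), ".graphml"))))
    }
    for (rep in metrics) files <- c(files, write_metrics_report(rep, cfg$out_dir))
    sm <- file.path(cfg$out_dir, "network_statistics.csv")
    utils::write.csv(summary_tab, sm, row.names = FALSE)
    ki <- file.path(cfg$out_dir, "key_ingredients.csv")
    kp <- file.path(cfg$out_dir, "key_pathways.csv")
    utils::write.csv(key_ingredients, ki, row.names = FALSE)
    utils::write.csv(key_pathways, kp, row.names = FALSE)
    files <- c(files, sm, ki, kp)
  }

  list(
    annotation = annotation, screened = screened,
    networks = networks, metrics = metrics, summary = summary_tab,
    key_ingredients = key_ingredients, key_pathways = key_pathways,
    files = files
  )
}
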