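#' Configuration for the synthetic mapping generator
#'
#' Describes a random ingredient-target-pathway annotation instance with
#' the size and sharing structure of an affinity-screened herbal-extract
#' study: a handful of screened ingredients, on the order of a hundred
#' predicted target proteins, and several dozen enriched pathways. Defaults
#' emulate a 6-ingredient / 160-target / 90-pathway study in which two
#' "hub" ingredients reach every pathway.
#'
#' Annotation is independent Bernoulli, with two realistic skews layered on
#' top: a fraction of *pleiotropic* targets annotated to many pathways
#' (pathway crosstalk is driven by shared multi-pathway proteins), and a few
#' *hub pathways* that most targets touch (large generic pathways collect
#' most targets). Defaults are calibrated once against the aggregate
#' structure such studies report — a few hundred ingredient-pathway edges
#' and a pathway-pathway density near 0.77 — not tuned per run.
#'
#' @param n_ingredients,n_targets,n_pathways counts (all >= 1).
#' @param p_ingredient_target probability an ingredient is predicted to hit
#'   a given target.
#' @param p_target_pathway baseline probability a target is annotated to a
#'   given (non-hub) pathway.
#' @param pleiotropic_fraction fraction of targets that are pleiotropic.
#' @param pleiotropic_p per-pathway annotation probability for pleiotropic
#'   targets.
#' @param n_hub_pathways number of hub pathways.
#' @param hub_pathway_p probability that any target is annotated to a hub
#'   pathway.
#' @param hub_fraction fraction of ingredients forced, after the random
#'   draw, to cover every pathway (the "main active ingredient" structure).
#' @param seed integer seed; identical configurations generate identical
#'   instances.
#' @return a list of class `itp_generator_config`.
#' @export
generator_config <- function(n_ingredients = 6L,
                             n_targets = 160L,
                             n_pathways = 90L,
                             p_ingredient_target = 0.25,
                             p_target_pathway = 0.06,
                             pleiotropic_fraction = 0.15,
                             pleiotropic_p = 0.20,
                             n_hub_pathways = 4L,
                             hub_pathway_p = 0.85,
                             hub_fraction = 2 / 6,
                             seed = 1L) {
  cfg <- list(
    n_ingredients = as.integer(n_ingredients),
    n_targets = as.integer(n_targets),
    n_pathways = as.integer(n_pathways),
    p_ingredient_target = p_ingredient_target,
    p_target_pathway = p_target_pathway,
    pleiotropic_fraction = pleiotropic_fraction,
    pleiotropic_p = pleiotropic_p,
    n_hub_pathways = as.integer(n_hub_pathways),
    hub_pathway_p = hub_pathway_p,
    hub_fraction = hub_fraction,
    seed = as.integer(seed)
  )
  counts <- c(cfg$n_ingredients, cfg$n_targets, cfg$n_pathways)
  if (any(is.na(counts)) || any(counts < 1L)) {
    stop("counts must be integers >= 1", call. = FALSE)
  }
  probs <- c(cfg$p_ingredient_target, cfg$p_target_pathway,
             cfg$pleiotropic_fraction, cfg$pleiotropic_p, cfg$hub_pathway_p,
             cfg$hub_fraction)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("probabilities and fractions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_hub_pathways < 0L || cfg$n_hub_pathways > cfg$n_pathways) {
    stop("'n_hub_pathways' must lie in [0, n_pathways]", call. = FALSE)
  }
  structure(cfg, class = "itp_generator_config")
}

#' Generate synthetic ingredient-target and target-pathway mappings
#'
#' Draws the two annotation relations under [generator_config()]. Hub
#' ingredients are post-processed so that their targets cover every
#' pathway (extra pathway annotations are added to randomly chosen targets
#' of the hub until coverage is complete). Targets whose pathway set comes
#' out empty are re-drawn once, then dropped with a message so the target
#' budget stays auditable. An ingredient whose target set comes out empty
#' is re-drawn once, then kept with no targets (an isolated ingredient
#' node); a hub ingredient is instead given one random target so full
#' coverage stays possible.
#'
#' @param cfg an `itp_generator_config`.
#' @return list with `itm` (ingredient-to-target named list), `tpm`
#'   (target-to-pathway named list), `hub_ingredients` (character), and
#'   `config`.
#' @export
generate_mappings <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "itp_generator_config"))
  set.seed(cfg$seed)
  ingredients <- sprintf("ing%02d", seq_len(cfg$n_ingredients))
  targets <- sprintf("P%05d", seq_len(cfg$n_targets))
  pathways <- sprintf("hsa%05d", 5200L + seq_len(cfg$n_pathways))

  draw_targets <- function() targets[stats::runif(cfg$n_targets) < cfg$p_ingredient_target]
  itm <- lapply(ingredients, function(i) draw_targets())
  names(itm) <- ingredients
  for (i in ingredients) {
    if (!length(itm[[i]])) itm[[i]] <- draw_targets()
  }

  pleio <- stats::runif(cfg$n_targets) < cfg$pleiotropic_fraction
  p_path <- rep(cfg$p_target_pathway, cfg$n_pathways)
  hub_pwys <- seq_len(cfg$n_hub_pathways)
  draw_pathways <- function(t_idx) {
    p <- if (pleio[t_idx]) rep(cfg$pleiotropic_p, cfg$n_pathways) else p_path
    p[hub_pwys] <- cfg$hub_pathway_p
    pathways[stats::runif(cfg$n_pathways) < p]
  }
  tpm <- lapply(seq_len(cfg$n_targets), draw_pathways)
  names(tpm) <- targets
  empty <- which(lengths(tpm) == 0L)
  for (t_idx in empty) tpm[[t_idx]] <- draw_pathways(t_idx)
  still_empty <- names(tpm)[lengths(tpm) == 0L]
  if (length(still_empty)) {
    message(sprintf("dropped %d target(s) with no pathway annotation: %s",
                    length(still_empty),
                    paste(utils::head(still_empty, 5L), collapse = ", ")))
    tpm <- tpm[lengths(tpm) > 0L]
  }

  n_hubs <- ceiling(cfg$hub_fraction * cfg$n_ingredients)
  hubs <- utils::head(ingredients, n_hubs)
  for (h in hubs) {
    mapped <- intersect(itm[[h]], names(tpm))
    if (!length(mapped)) {
      mapped <- sample(names(tpm), 1L)
      itm[[h]] <- c(itm[[h]], mapped)
    }
    covered <- unique(unlist(tpm[mapped], use.names = FALSE))
    for (j in setdiff(pathways, covered)) {
      t <- if (length(mapped) == 1L) mapped else sample(mapped, 1L)
      tpm[[t]] <- c(tpm[[t]], j)
    }
  }

  list(
    itm = lapply(itm, function(v) sort(unique(v))),
    tpm = lapply(tpm, function(v) sort(unique(v))),
    hub_ingredients = hubs,
    config = cfg
  )
}

# plausible phytochemical compositions (flavonoids, coumarins, phenolic
# acids, terpenoids, alkaloids); all pairwise [M+H]+ differences exceed
# 10 ppm so synthetic peaks annotate unambiguously at a 5 ppm tolerance
.phytochemical_formulas <- data.frame(
  formula = c(
    "C15H10O5", "C15H10O6", "C15H10O7", "C16H12O5", "C16H12O6", "C16H12O7",
    "C17H14O6", "C17H14O7", "C18H16O7", "C18H16O8", "C20H18O8", "C21H20O11",
    "C21H20O12", "C27H30O15", "C27H30O16", "C9H6O3", "C10H8O4", "C11H10O4",
    "C11H10O5", "C9H8O4", "C16H18O9", "C25H24O12", "C7H6O5", "C14H6O8",
    "C10H16", "C15H24", "C15H22O", "C15H22O2", "C20H28O2", "C30H48O3",
    "C6H6N2O", "C10H13N5O3", "C17H19NO3", "C20H17NO6", "C9H11NO2",
    "C8H11NO3", "C10H12O", "C12H16O3", "C12H18O2", "C18H30O2"
  ),
  category = c(
    rep("Flavone", 15L), rep("Coumarin", 4L), rep("Organic Acid", 5L),
    rep("Terpene", 6L), rep("Alkaloid", 6L), rep("Other", 4L)
  ),
  stringsAsFactors = FALSE
)

#' Generate a synthetic compound library and LC-MS peak table
#'
#' Emulates the annotation/screening input of an ultrafiltration
#' experiment: a library of plausible phytochemical compositions and one
#' measured \eqn{[M+H]^+} peak per compound, the measured m/z perturbed by
#' uniform noise within `noise_ppm`, with exactly `n_enriched` peaks given
#' a sample/control area ratio above 1 (planted binders) and the rest a
#' ratio below 1.
#'
#' @param n_compounds number of compounds (at most
#'   `nrow(itpnet:::.phytochemical_formulas)`, currently 40).
#' @param n_enriched number of planted enriched compounds
#'   (`<= n_compounds`).
#' @param noise_ppm half-width of the uniform measurement error, in ppm.
#' @param seed integer seed.
#' @return list with `library` (a [compound_library()] table), `peaks`
#'   (columns `feature_id`, `mz`, `rt_min`, `area_sample`, `area_control`),
#'   and `enriched` (the planted compound names).
#' @export
generate_peak_table <- function(n_compounds = 34L, n_enriched = 6L,
                                noise_ppm = 2, seed = 1L) {
  n_compounds <- as.integer(n_compounds)
  n_enriched <- as.integer(n_enriched)
  if (is.na(n_compounds) || n_compounds < 1L ||
      n_compounds > nrow(.phytochemical_formulas)) {
    stop(sprintf("'n_compounds' must be in [1, %d]",
                 nrow(.phytochemical_formulas)), call. = FALSE)
  }
  if (is.na(n_enriched) || n_enriched < 0L || n_enriched > n_compounds) {
    stop("'n_enriched' must lie in [0, n_compounds]", call. = FALSE)
  }
  if (!is.numeric(noise_ppm) || noise_ppm < 0) {
    stop("'noise_ppm' must be non-negative", call. = FALSE)
  }
  set.seed(as.integer(seed))
  rows <- sample(nrow(.phytochemical_formulas), n_compounds)
  lib <- data.frame(
    name = sprintf("cpd%02d", seq_len(n_compounds)),
    category = .phytochemical_formulas$category[rows],
    formula = .phytochemical_formulas$formula[rows],
    stringsAsFactors = FALSE
  )
  lib <- compound_library(lib)

  noise <- stats::runif(n_compounds, -noise_ppm, noise_ppm)
  enriched_idx <- if (n_enriched > 0L) sample(n_compounds, n_enriched) else integer()
  ratio <- stats::runif(n_compounds, 0.3, 0.9)
  ratio[enriched_idx] <- stats::runif(n_enriched, 1.5, 4)
  area_control <- stats::rlnorm(n_compounds, meanlog = 10, sdlog = 0.5)
  peaks <- data.frame(
    feature_id = sprintf("F%03d", seq_len(n_compounds)),
    mz = lib$mh_mz * (1 + noise * 1e-6),
    rt_min = round(stats::runif(n_compounds, 2, 11), 2),
    area_sample = area_control * ratio,
    area_control = area_control,
    stringsAsFactors = FALSE
  )
  list(library = lib, peaks = peaks, enriched = lib$name[sort(enriched_idx)])
}
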