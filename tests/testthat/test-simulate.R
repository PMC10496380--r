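test_that("generator configuration validates its domain", {
  expect_s3_class(generator_config(), "itp_generator_config")
  expect_error(generator_config(p_ingredient_target = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(n_ingredients = 0), ">= 1")
  expect_error(generator_config(n_hub_pathways = 200), "n_hub_pathways")
  expect_error(generate_peak_table(n_compounds = 4, n_enriched = 6),
               "n_enriched")
})

test_that("identical seeds reproduce identical instances", {
  cfg <- generator_config(seed = 424L)
  a <- generate_mappings(cfg)
  b <- generate_mappings(cfg)
  expect_identical(a$itm, b$itm)
  expect_identical(a$tpm, b$tpm)
  expect_false(identical(a$itm, generate_mappings(generator_config(seed = 425L))$itm))

  p1 <- generate_peak_table(20, 4, 2, seed = 9)
  p2 <- generate_peak_table(20, 4, 2, seed = 9)
  expect_identical(p1, p2)
})

test_that("degenerate probabilities give the extreme networks", {
  full <- generate_mappings(generator_config(
    p_ingredient_target = 1, p_target_pathway = 1,
    pleiotropic_fraction = 0, n_hub_pathways = 0, seed = 2))
  tti <- build_tti(full$itm)
  expect_equal(n_edges(tti), 15L)  # complete graph on 6 ingredients
  ipb <- build_ipb(full$itm, full$tpm)
  expect_equal(n_edges(ipb), 6L * 90L)  # complete bipartite

  none <- generate_mappings(generator_config(
    p_ingredient_target = 0, hub_fraction = 0, seed = 3))
  expect_equal(n_edges(build_tti(none$itm)), 0L)
  expect_equal(n_edges(suppressWarnings(build_ipb(none$itm, none$tpm))), 0L)
})

test_that("hub ingredients cover every pathway and top the degree ranking", {
  withr::with_seed(1, {
    for (seed in sample.int(10000, 5)) {
      gen <- generate_mappings(generator_config(seed = seed))
      ipb <- suppressWarnings(build_ipb(gen$itm, gen$tpm))
      rep <- network_metrics(ipb, density_mode = "bipartite")
      deg <- stats::setNames(rep$per_node$degree, rep$per_node$id)
      expect_true(all(deg[gen$hub_ingredients] == gen$config$n_pathways))
      ranked <- rank_key_nodes(rep, by = "degree")
      ranked <- ranked[ranked$type == "ingredient", ]
      expect_setequal(utils::head(ranked$id, length(gen$hub_ingredients)),
                      gen$hub_ingredients)
    }
  })
})

test_that("non-hub coverage matches the closed-form expectation", {
  # P(non-hub ingredient linked to a non-hub pathway) =
  #   1 - prod_t (1 - P(t in targets) * P(pathway in t's annotation))
  cfg <- generator_config(n_hub_pathways = 0)
  p_pair <- cfg$p_ingredient_target *
    (cfg$pleiotropic_fraction * cfg$pleiotropic_p +
       (1 - cfg$pleiotropic_fraction) * cfg$p_target_pathway)
  p_edge <- 1 - (1 - p_pair)^cfg$n_targets
  n_nonhub <- cfg$n_ingredients - ceiling(cfg$hub_fraction * cfg$n_ingredients)
  expected <- n_nonhub * cfg$n_pathways * p_edge

  degs <- vapply(1:50, function(seed) {
    gen <- generate_mappings(generator_config(n_hub_pathways = 0, seed = seed))
    ipb <- suppressWarnings(build_ipb(gen$itm, gen$tpm))
    deg <- degree_stats(ipb)$degree
    sum(deg[setdiff(names(gen$itm), gen$hub_ingredients)])
  }, numeric(1))
  se <- stats::sd(degs) / sqrt(length(degs))
  expect_lt(abs(mean(degs) - expected), 3 * se + 0.01 * expected)
})

test_that("synthetic peak tables screen back to the planted structure", {
  pk <- generate_peak_table(34, 6, 2.0, seed = 17)
  hits <- annotate_peaks(pk$peaks, pk$library, tol_ppm = 5)
  expect_equal(nrow(hits), 34L)  # every compound annotates, unambiguously
  expect_false(any(hits$ambiguous))
  kept <- screen_enriched(hits, ratio_threshold = 1)
  expect_equal(nrow(kept), 6L)
  expect_setequal(kept$compound_name, pk$enriched)

  exact <- generate_peak_table(10, 2, 0, seed = 4)
  expect_equal(annotate_peaks(exact$peaks, exact$library)$ppm_error,
               rep(0, 10))

  lone <- generate_peak_table(1, 0, 0, seed = 5)
  h <- annotate_peaks(lone$peaks, lone$library)
  expect_equal(nrow(screen_enriched(h)), 0L)
})

test_that("the built-in composition set annotates unambiguously at 5 ppm", {
  lib <- compound_library(itpnet:::.phytochemical_formulas[, "formula", drop = FALSE] |>
                            transform(name = sprintf("c%02d", 1:40)))
  mz <- sort(lib$mh_mz)
  gaps_ppm <- diff(mz) / mz[-1] * 1e6
  expect_true(all(gaps_ppm > 10))
})
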