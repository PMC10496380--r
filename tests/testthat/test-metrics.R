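k_complete <- function(n, type = "ingredient", name = "TTI") {
  ids <- sprintf("v%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2L))
  itp_network(data.frame(id = ids, type = type),
              data.frame(from = ids[pairs[, 1]], to = ids[pairs[, 2]]), name)
}

path_abc <- itp_network(
  data.frame(id = c("a", "b", "c"), type = "pathway"),
  data.frame(from = c("a", "b"), to = c("b", "c")), "PPI")

test_that("degree statistics satisfy the handshake identities", {
  k6 <- k_complete(6)
  ds <- degree_stats(k6)
  expect_true(all(ds$degree == 5L))
  expect_equal(ds$avg_degree, 5)
  expect_equal(sum(ds$distribution$p_k), 1)

  lone <- itp_network(data.frame(id = "x", type = "pathway"),
                      data.frame(from = character(), to = character()), "PPI")
  ds1 <- degree_stats(lone)
  expect_equal(unname(ds1$degree), 0L)
  expect_equal(ds1$distribution, data.frame(k = 0L, p_k = 1))

  withr::with_seed(3, {
    for (rep in 1:10) {
      g <- random_itp_graph(sample(4:15, 1), stats::runif(1, 0.2, 0.9))
      ds <- degree_stats(g)
      expect_equal(sum(ds$degree), 2L * n_edges(g))
      expect_equal(ds$avg_degree, 2 * n_edges(g) / n_nodes(g))
      expect_equal(sum(ds$distribution$p_k), 1)
    }
  })
})

test_that("density distinguishes simple and bipartite conventions", {
  expect_equal(net_density(k_complete(6)), 1)
  bip <- itp_network(
    data.frame(id = c("i1", "i2", "p1", "p2", "p3"),
               type = c("ingredient", "ingredient", rep("pathway", 3))),
    data.frame(from = c("i1", "i1", "i2"), to = c("p1", "p2", "p3")), "IPB")
  expect_equal(net_density(bip, "bipartite"), 3 / 6)
  expect_equal(net_density(bip, "simple"), 2 * 3 / (5 * 4))
  expect_error(net_density(k_complete(6), "bipartite"), "bipartite")
})

test_that("path metrics come out exactly on analysable graphs", {
  k6 <- distance_metrics(k_complete(6))
  expect_equal(k6$L, 1)
  expect_equal(k6$D, 1)

  p <- distance_metrics(path_abc)
  expect_equal(p$L, 4 / 3)  # ordered pairs: (1+1+2)*2 / 6
  expect_equal(p$D, 2)

  # in any diameter-2 graph, L = 2 - 2E/(N(N-1)) exactly
  withr::with_seed(13, {
    for (rep in 1:10) {
      n <- sample(8:20, 1)
      m <- sample((n - 1):(n * (n - 1) / 2 - 1), 1)
      g <- hub_graph(n, m)
      dm <- distance_metrics(g)
      if (dm$D == 2) {
        expect_equal(dm$L, 2 - 2 * n_edges(g) / (n * (n - 1)))
      }
      expect_gte(dm$L, 1)
      expect_lte(dm$L, dm$D)
    }
  })

  edgeless <- itp_network(data.frame(id = c("a", "b"), type = "pathway"),
                          data.frame(from = character(), to = character()), "PPI")
  expect_error(distance_metrics(edgeless), "no edges")
})

test_that("clustering coefficients match neighbour-pair counting", {
  tri <- k_complete(3)
  cl <- clustering_coefficients(tri)
  expect_true(all(cl$local == 1))
  expect_equal(cl$C, 1)

  expect_equal(unname(clustering_coefficients(path_abc)$local), c(0, 0, 0))

  withr::with_seed(31, {
    for (rep in 1:20) {
      g <- random_itp_graph(10, stats::runif(1, 0.2, 0.8))
      expect_equal(clustering_coefficients(g)$local, oracle_clustering(g))
    }
  })
})

test_that("centralities take their textbook values on canonical graphs", {
  # middle node of a 3-path carries the one geodesic between the ends
  cent <- centralities(path_abc)
  expect_equal(cent$C_b[cent$id == "b"], 1)
  expect_equal(cent$C_b_raw[cent$id == "b"], 1)
  expect_equal(cent$C_b[cent$id != "b"], c(0, 0))

  kn <- centralities(k_complete(8))
  expect_true(all(kn$C_d == 1))
  expect_true(all(kn$C_c == 1))
  expect_true(all(kn$C_b == 0))
})

test_that("centralities and clustering agree with the brute-force oracle", {
  withr::with_seed(77, {
    for (rep in 1:60) {
      n <- sample(4:12, 1)
      g <- random_itp_graph(n, stats::runif(1, 0.15, 0.95))
      got <- suppressWarnings(centralities(g))
      want <- suppressWarnings(oracle_centralities(g))
      expect_equal(got$degree, want$degree)
      expect_equal(got$C_d, want$C_d)
      expect_equal(got$C_b_raw, want$C_b_raw, tolerance = 1e-12)
      expect_equal(got$C_b, want$C_b, tolerance = 1e-12)
      expect_equal(got$C_c, want$C_c, tolerance = 1e-12)
    }
  })
})

test_that("centralities cross-check against igraph", {
  skip_if_not_installed("igraph")
  withr::with_seed(123, {
    for (rep in 1:10) {
      g <- random_itp_graph(10, 0.4)
      ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                          vertices = g$nodes$id)
      got <- suppressWarnings(centralities(g))
      ib <- igraph::betweenness(ig, directed = FALSE)
      expect_equal(got$C_b_raw, unname(ib[got$id]), tolerance = 1e-10)
      comp <- igraph::components(ig)
      if (comp$no == 1L) {
        ic <- igraph::closeness(ig, normalized = TRUE)
        expect_equal(got$C_c, unname(ic[got$id]), tolerance = 1e-10)
      }
    }
  })
})

test_that("log-log regression recovers planted power-law exponents", {
  k <- 72:90
  spec <- data.frame(k = k, c_k = k^(-0.95))
  expect_equal(powerlaw_gamma(spec, k_min = 72)$gamma, -0.95, tolerance = 1e-12)

  flat <- data.frame(k = 5:30, c_k = 0.4)
  expect_equal(powerlaw_gamma(flat)$gamma, 0, tolerance = 1e-12)

  expect_error(powerlaw_gamma(data.frame(k = 1, c_k = 1)), "at least 2")
  expect_error(powerlaw_gamma(data.frame(k = 70:90, c_k = 0), k_min = 70),
               "at least 2")

  # 5% multiplicative noise: recovered within +/- 0.05, averaged behaviour
  withr::with_seed(55, {
    errs <- replicate(50, {
      gamma <- stats::runif(1, -2, -0.5)
      k <- 20:90
      y <- k^gamma * exp(stats::rnorm(length(k), 0, 0.05))
      powerlaw_gamma(data.frame(k = k, c_k = y), k_min = 20)$gamma - gamma
    })
    expect_true(all(abs(errs) < 0.05))
  })
})

test_that("node ranking is deterministic and honours each index", {
  g <- hub_graph(8, 12)
  rep <- network_metrics(g)
  for (by in c("degree", "C_d", "C_b", "C_c")) {
    r <- rank_key_nodes(rep, by = by)
    expect_true(all(diff(r[[by]]) <= 0))
  }
  comp <- rank_key_nodes(rep, by = "composite")
  expect_true(all(diff(comp$composite) <= 0))
  expect_error(rank_key_nodes(rep, by = "pagerank"))

  # all-equal metrics fall back to lexicographic order
  k5 <- network_metrics(k_complete(5))
  expect_equal(rank_key_nodes(k5, by = "degree")$id, sort(k5$per_node$id))
  expect_equal(rank_key_nodes(k5, by = "composite")$id, sort(k5$per_node$id))
})

test_that("the metrics report is internally consistent", {
  withr::with_seed(9, {
    g <- random_itp_graph(12, 0.5)
    rep <- network_metrics(g)
    expect_s3_class(rep, "itp_metrics")
    expect_equal(rep$avg_degree, 2 * rep$E / rep$N)
    expect_equal(sum(rep$degree_distribution$p_k), 1)
    expect_equal(nrow(rep$per_node), rep$N)
    expect_true(all(rep$per_node$C_d >= 0 & rep$per_node$C_d <= 1))
    expect_true(all(rep$per_node$C_b >= 0 & rep$per_node$C_b <= 1))
    expect_true(all(rep$per_node$C_c >= 0 & rep$per_node$C_c <= 1))
    tab <- metrics_table(rep, network_metrics(k_complete(6)))
    expect_equal(dim(tab), c(10L, 3L))
    expect_equal(tab$TTI[tab$Characteristic == "Density"], 1)
  })
})
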