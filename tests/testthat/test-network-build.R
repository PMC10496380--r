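test_that("network constructor enforces simple-graph and type invariants", {
  nodes <- data.frame(id = c("a", "b", "p1"),
                      type = c("ingredient", "ingredient", "pathway"))
  net <- itp_network(nodes, data.frame(from = c("b", "a"), to = c("a", "b")), "IPI")
  expect_equal(n_edges(net), 1L)  # canonicalised + de-duplicated
  expect_error(itp_network(nodes, data.frame(from = "a", to = "a"), "IPI"),
               "self-loops")
  expect_error(itp_network(nodes, data.frame(from = "a", to = "zz"), "IPI"),
               "not declared")
  expect_error(itp_network(nodes, data.frame(from = "a", to = "p1"), "TTI"),
               "signature")
  expect_error(itp_network(nodes, data.frame(from = "a", to = "b"), "IPB"),
               "signature")
})

test_that("ingredients sharing targets form the expected TTI graphs", {
  # every pair shares a target: the complete graph on 6 ingredients
  itm <- lapply(1:6, function(i) c("t_common", sprintf("t%d", i)))
  names(itm) <- sprintf("ing%d", 1:6)
  k6 <- build_tti(itm)
  expect_equal(n_nodes(k6), 6L)
  expect_equal(n_edges(k6), 15L)
  expect_true(all(degree_stats(k6)$degree == 5L))

  disjoint <- build_tti(list(a = "t1", b = "t2"))
  expect_equal(n_nodes(disjoint), 2L)
  expect_equal(n_edges(disjoint), 0L)
})

test_that("TTI/IPB/PPI edge sets match brute-force enumeration", {
  withr::with_seed(99, {
    for (rep in 1:25) {
      maps <- random_mappings(5, 12, 8, p_it = stats::runif(1, 0.1, 0.6),
                              p_tp = stats::runif(1, 0.1, 0.6))
      itm <- maps$itm; tpm <- maps$tpm

      tti <- build_tti(itm)
      for (pair in utils::combn(names(itm), 2, simplify = FALSE)) {
        expected <- length(intersect(itm[[pair[1]]], itm[[pair[2]]])) > 0
        found <- any(tti$edges$from == pair[1] & tti$edges$to == pair[2])
        expect_equal(found, expected)
      }

      ipb <- suppressWarnings(build_ipb(itm, tpm))
      pwys <- sort(unique(unlist(tpm)))
      for (i in names(itm)) {
        for (j in pwys) {
          expected <- any(vapply(intersect(itm[[i]], names(tpm)),
                                 function(t) j %in% tpm[[t]], logical(1)))
          a <- min(i, j); b <- max(i, j)
          found <- any(ipb$edges$from == a & ipb$edges$to == b)
          expect_equal(found, expected)
        }
      }

      ppi <- build_ppi(tpm)
      for (pair in utils::combn(pwys, 2, simplify = FALSE)) {
        expected <- any(vapply(tpm, function(s) all(pair %in% s), logical(1)))
        found <- any(ppi$edges$from == pair[1] & ppi$edges$to == pair[2])
        expect_equal(found, expected)
      }
    }
  })
})

test_that("one multi-pathway target yields a clique; disjoint targets disjoint cliques", {
  tri <- build_ppi(list(t1 = c("a", "b", "c")))
  expect_equal(n_edges(tri), 3L)
  two <- build_ppi(list(t1 = c("a", "b"), t2 = c("c", "d")))
  expect_equal(n_edges(two), 2L)
  expect_false(any(two$edges$from == "a" & two$edges$to %in% c("c", "d")))
})

test_that("the merged IPI network is the disjoint union of its three edge classes", {
  withr::with_seed(7, {
    for (rep in 1:100) {
      maps <- random_mappings(sample(2:7, 1), sample(5:20, 1), sample(3:12, 1),
                              p_it = stats::runif(1, 0, 0.7),
                              p_tp = stats::runif(1, 0.05, 0.7))
      ipi <- suppressWarnings(build_ipi(maps$itm, maps$tpm))
      tti <- build_tti(maps$itm)
      ipb <- suppressWarnings(build_ipb(maps$itm, maps$tpm))
      ppi <- build_ppi(maps$tpm)
      expect_equal(n_edges(ipi), n_edges(tti) + n_edges(ipb) + n_edges(ppi))
      # subnetwork extraction restores each class exactly
      expect_equal(subnetwork(ipi, "TTI")$edges, tti$edges)
      expect_equal(subnetwork(ipi, "IPB")$edges, ipb$edges)
      expect_equal(subnetwork(ipi, "PPI")$edges, ppi$edges)
    }
  })
})

test_that("adding a target annotation never removes an edge", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      maps <- random_mappings(4, 10, 6, 0.3, 0.3)
      ipi1 <- suppressWarnings(build_ipi(maps$itm, maps$tpm))
      itm2 <- maps$itm
      tpm2 <- maps$tpm
      # add one ingredient-target and one target-pathway annotation
      i <- sample(names(itm2), 1)
      itm2[[i]] <- unique(c(itm2[[i]], sample(names(tpm2), 1)))
      t <- sample(names(tpm2), 1)
      tpm2[[t]] <- unique(c(tpm2[[t]], "p_new"))
      ipi2 <- suppressWarnings(build_ipi(itm2, tpm2))
      key <- function(net) paste(net$edges$from, net$edges$to)
      expect_true(all(key(ipi1) %in% key(ipi2)))
    }
  })
})

test_that("empty inputs degrade as documented", {
  itm <- list(a = c("t1", "t2"), b = c("t2"))
  # no pathway map: the IPI reduces to the TTI
  ipi <- build_ipi(itm, NULL)
  expect_equal(ipi$edges, build_tti(itm)$edges)
  # unmapped targets warn and contribute nothing
  expect_warning(build_ipb(itm, list(t2 = "p1")), "no pathway annotation")
  # ingredients with no predicted targets become isolated nodes
  tti <- build_tti(list(a = character(), b = character()))
  expect_equal(n_edges(tti), 0L)
  expect_error(build_tti(list()), "empty")
})

test_that("pruning removes exactly the isolated nodes", {
  itm <- list(a = c("t1"), b = c("t1"), c = c("t9"))
  tpm <- list(t1 = c("p1", "p2"))
  ipi <- suppressWarnings(build_ipi(itm, tpm))
  expect_equal(n_nodes(ipi), 5L)  # c is isolated (t9 unmapped)
  pruned <- suppressMessages(suppressWarnings(build_ipi(itm, tpm, prune = TRUE)))
  expect_setequal(pruned$nodes$id, c("a", "b", "p1", "p2"))
  expect_equal(pruned$edges, ipi$edges)
})
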