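# Independent oracles used to cross-check the graph machinery.
# They deliberately share no code with the package internals: distances come
# from Floyd-Warshall on the adjacency matrix, geodesic counts from the
# dynamic-programming recursion over the distance matrix, and betweenness
# from the pair-sum definition g_jk(i)/g_jk.

random_itp_graph <- function(n, p, name = "PPI") {
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  itp_network(
    nodes = data.frame(id = ids, type = "pathway"),
    edges = data.frame(from = ids[pairs[keep, 1L]], to = ids[pairs[keep, 2L]]),
    name = name
  )
}

adj_matrix <- function(net) {
  ids <- net$nodes$id
  A <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(net$edges)) {
    A[cbind(net$edges$from, net$edges$to)] <- 1L
    A[cbind(net$edges$to, net$edges$from)] <- 1L
  }
  A
}

floyd_warshall <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n, dimnames = dimnames(A))
  d[A == 1L] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  d
}

# number of geodesics between every ordered pair, from the distance matrix:
# g(s, t) = sum over neighbours m of t with d(s, m) = d(s, t) - 1 of g(s, m)
geodesic_counts <- function(A, d) {
  n <- nrow(A)
  g <- matrix(0, n, n, dimnames = dimnames(A))
  diag(g) <- 1
  finite <- sort(unique(d[is.finite(d) & d > 0]))
  for (len in finite) {
    for (s in seq_len(n)) {
      for (t in which(d[s, ] == len)) {
        pred <- which(A[, t] == 1L & d[s, ] == len - 1)
        g[s, t] <- sum(g[s, pred])
      }
    }
  }
  g
}

oracle_centralities <- function(net) {
  A <- adj_matrix(net)
  n <- nrow(A)
  d <- floyd_warshall(A)
  g <- geodesic_counts(A, d)
  deg <- rowSums(A)

  cb_raw <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n - 1L)) {
      for (k in (j + 1L):n) {
        if (j == i || k == i || !is.finite(d[j, k])) next
        # geodesics through i: g(j,i) * g(i,k) when i lies on a j-k geodesic
        if (is.finite(d[j, i]) && is.finite(d[i, k]) &&
            d[j, i] + d[i, k] == d[j, k]) {
          cb_raw[i] <- cb_raw[i] + g[j, i] * g[i, k] / g[j, k]
        }
      }
    }
  }

  cc <- numeric(n)
  for (i in seq_len(n)) {
    reach <- which(is.finite(d[i, ]) & d[i, ] > 0)
    if (length(reach)) {
      cc[i] <- (length(reach) / sum(d[i, reach])) * length(reach) / (n - 1)
    }
  }

  data.frame(
    id = rownames(A),
    degree = as.integer(deg),
    C_d = deg / (n - 1),
    C_b_raw = cb_raw,
    C_b = cb_raw / ((n - 1) * (n - 2) / 2),
    C_c = cc,
    stringsAsFactors = FALSE
  )
}

oracle_clustering <- function(net) {
  A <- adj_matrix(net)
  n <- nrow(A)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1L)
    if (length(nb) < 2L) next
    out[i] <- sum(A[nb, nb]) / (length(nb) * (length(nb) - 1L))
  }
  names(out) <- rownames(A)
  out
}

# hub-based construction of a connected diameter-2 graph with exactly
# n nodes and m edges: keep the star on node 1, fill/remove among the rest
hub_graph <- function(n, m, type = "pathway", name = "PPI") {
  stopifnot(m >= n - 1, m <= n * (n - 1) / 2)
  ids <- sprintf("v%03d", seq_len(n))
  star <- cbind(1L, 2L:n)
  rest <- t(utils::combn(2L:n, 2L))
  extra <- m - (n - 1L)
  edges <- rbind(star, rest[seq_len(extra), , drop = FALSE])
  itp_network(
    nodes = data.frame(id = ids, type = type),
    edges = data.frame(from = ids[edges[, 1L]], to = ids[edges[, 2L]]),
    name = name
  )
}

random_mappings <- function(n_ing, n_tar, n_pwy, p_it, p_tp) {
  ings <- sprintf("i%02d", seq_len(n_ing))
  tars <- sprintf("t%02d", seq_len(n_tar))
  pwys <- sprintf("p%02d", seq_len(n_pwy))
  itm <- lapply(ings, function(i) tars[stats::runif(n_tar) < p_it])
  names(itm) <- ings
  tpm <- lapply(tars, function(t) pwys[stats::runif(n_pwy) < p_tp])
  names(tpm) <- tars
  tpm <- tpm[lengths(tpm) > 0L]
  if (!length(tpm)) tpm <- stats::setNames(list(pwys[1L]), tars[1L])
  list(itm = itm, tpm = tpm)
}
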