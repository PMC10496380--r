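# adjacency list as integer indices into net$nodes$id (sorted order)
.adjacency <- function(net) {
  ids <- net$nodes$id
  adj <- vector("list", length(ids))
  if (nrow(net$edges)) {
    fi <- match(net$edges$from, ids)
    ti <- match(net$edges$to, ids)
    for (e in seq_along(fi)) {
      adj[[fi[e]]] <- c(adj[[fi[e]]], ti[e])
      adj[[ti[e]]] <- c(adj[[ti[e]]], fi[e])
    }
  }
  lapply(adj, function(v) if (is.null(v)) integer() else sort(v))
}

# single-source BFS; returns integer distances with NA for unreachable
.bfs_dist <- function(adj, s) {
  n <- length(adj)
  d <- rep(NA_integer_, n)
  d[s] <- 0L
  frontier <- s
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.na(d[nxt])]
    if (!length(nxt)) break
    d[nxt] <- d[frontier[1L]] + 1L
    frontier <- nxt
  }
  d
}

#' Per-node degrees, average degree and degree distribution
#'
#' @param net an `itp_network` with at least one node.
#' @return list with `degree` (named integer vector), `avg_degree`
#'   (\eqn{\langle k\rangle = 2E/N}), and `distribution`, a data frame of
#'   `k` and `p_k` (the fraction of nodes with degree `k`; probabilities
#'   sum to 1).
#' @export
degree_stats <- function(net) {
  stopifnot(inherits(net, "itp_network"))
  if (n_nodes(net) == 0L) stop("network has no nodes", call. = FALSE)
  deg <- lengths(.adjacency(net))
  names(deg) <- net$nodes$id
  tab <- table(deg)
  list(
    degree = deg,
    avg_degree = 2 * n_edges(net) / n_nodes(net),
    distribution = data.frame(
      k = as.integer(names(tab)),
      p_k = as.vector(tab) / length(deg)
    )
  )
}

#' Network density
#'
#' In `simple` mode, the fraction of realised node pairs,
#' \eqn{2E/(N(N-1))}. In `bipartite` mode — appropriate for the
#' ingredient-pathway bimodal network, where only cross-type pairs can ever
#' be linked — the fraction of realised ingredient x pathway pairs.
#'
#' @param net an `itp_network`.
#' @param mode `"simple"` or `"bipartite"`.
#' @return density in \[0, 1\].
#' @export
net_density <- function(net, mode = c("simple", "bipartite")) {
  stopifnot(inherits(net, "itp_network"))
  mode <- match.arg(mode)
  n <- n_nodes(net)
  if (mode == "simple") {
    if (n < 2L) stop("density needs at least 2 nodes", call. = FALSE)
    return(2 * n_edges(net) / (n * (n - 1)))
  }
  n_ing <- sum(net$nodes$type == "ingredient")
  n_pwy <- sum(net$nodes$type == "pathway")
  if (n_ing == 0L || n_pwy == 0L) {
    stop("bipartite density needs both ingredient and pathway nodes", call. = FALSE)
  }
  type_of <- stats::setNames(net$nodes$type, net$nodes$id)
  if (nrow(net$edges) &&
      any(type_of[net$edges$from] == type_of[net$edges$to])) {
    stop("bipartite density on a network with within-type edges", call. = FALSE)
  }
  n_edges(net) / (n_ing * n_pwy)
}

#' Average path length, diameter and all-pairs shortest distances
#'
#' Shortest-path lengths by breadth-first search.
#' \eqn{L = \frac{1}{N(N-1)}\sum_{i \ne j} d_{ij}} averaged over ordered
#' pairs; for a disconnected network the average runs over pairs within
#' connected components (the unreachable \eqn{d_{ij}} are undefined).
#' \eqn{D = \max d_{ij}} over finite distances.
#'
#' @param net an `itp_network` with at least one edge.
#' @return list with `L`, `D` and the integer distance matrix `d`
#'   (`NA` for unreachable pairs).
#' @export
distance_metrics <- function(net) {
  stopifnot(inherits(net, "itp_network"))
  if (n_nodes(net) < 2L) stop("need at least 2 nodes", call. = FALSE)
  if (n_edges(net) == 0L) {
    stop("network has no edges: no finite distances", call. = FALSE)
  }
  adj <- .adjacency(net)
  n <- length(adj)
  d <- matrix(NA_integer_, n, n, dimnames = list(net$nodes$id, net$nodes$id))
  for (s in seq_len(n)) d[s, ] <- .bfs_dist(adj, s)
  off <- d[row(d) != col(d)]
  list(
    L = mean(off, na.rm = TRUE),
    D = max(off, na.rm = TRUE),
    d = d
  )
}

#' Local clustering coefficients, network average, and clustering spectrum
#'
#' \eqn{C_i = 2 e_i / (k_i (k_i - 1))} for \eqn{k_i \ge 2}, where
#' \eqn{e_i} is the number of edges among the neighbours of node *i*;
#' nodes of degree < 2 take \eqn{C_i = 0}. `C` is the mean over all nodes,
#' and the spectrum `C(k)` is the mean \eqn{C_i} over nodes of degree `k`.
#'
#' @param net an `itp_network`.
#' @return list with `local` (named numeric), `C` (network average) and
#'   `spectrum` (data frame of `k`, `c_k`).
#' @export
clustering_coefficients <- function(net) {
  stopifnot(inherits(net, "itp_network"))
  adj <- .adjacency(net)
  n <- length(adj)
  local <- numeric(n)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    k <- length(nb)
    if (k < 2L) next
    e_i <- sum(vapply(nb, function(u) sum(adj[[u]] %in% nb), numeric(1L))) / 2
    local[i] <- 2 * e_i / (k * (k - 1))
  }
  names(local) <- net$nodes$id
  deg <- lengths(adj)
  spec <- vapply(split(local, deg), mean, numeric(1L))
  list(
    local = local,
    C = if (n) mean(local) else NaN,
    spectrum = data.frame(k = as.integer(names(spec)), c_k = as.vector(spec))
  )
}

#' Degree, betweenness and closeness centralities
#'
#' Degree centrality \eqn{C_d = k_i/(N-1)}. Betweenness
#' \eqn{C_b(i) = \sum_{j<k,\; j,k \ne i} g_{jk}(i)/g_{jk}} (the fraction of
#' geodesics between each pair passing through *i*), computed with Brandes'
#' accumulation algorithm and reported both raw and normalised by
#' \eqn{(N-1)(N-2)/2} so that it lies in \[0, 1\]. Closeness
#' \eqn{C_c = (N-1)/\sum_j d_{ij}}; on a disconnected network the sum runs
#' over reachable nodes and the value is scaled by
#' \eqn{(r-1)/(N-1)} where *r* is the size of the node's component
#' (Wasserman-Faust correction), unless `wf_correction = FALSE`, in which
#' case the reachable-only formula is used unscaled. Isolated nodes get
#' closeness 0 with a warning.
#'
#' @param net an `itp_network` with at least 3 nodes (betweenness is
#'   undefined below that).
#' @param wf_correction logical; apply the component-size scaling of
#'   closeness on disconnected networks.
#' @return data frame with columns `id`, `degree`, `C_d`, `C_b_raw`,
#'   `C_b`, `C_c`.
#' @export
centralities <- function(net, wf_correction = TRUE) {
  stopifnot(inherits(net, "itp_network"))
  n <- n_nodes(net)
  if (n < 3L) stop("centralities need at least 3 nodes", call. = FALSE)
  adj <- .adjacency(net)
  deg <- lengths(adj)

  # Brandes (2001) betweenness accumulation, undirected unweighted
  cb <- numeric(n)
  closeness <- numeric(n)
  isolated <- deg == 0L
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
    reach <- which(dist > 0L)
    if (length(reach)) {
      # reachable-only closeness; Wasserman-Faust scales by the fraction of
      # the network the node can actually reach, so full-graph closeness is
      # unchanged on connected networks
      cc <- length(reach) / sum(dist[reach])
      if (wf_correction) cc <- cc * length(reach) / (n - 1L)
      closeness[s] <- cc
    }
  }
  if (any(isolated)) {
    warning(sprintf("%d isolated node(s): closeness reported as 0",
                    sum(isolated)), call. = FALSE)
  }
  cb_raw <- cb / 2  # undirected: each pair accumulated from both endpoints
  norm <- (n - 1) * (n - 2) / 2
  data.frame(
    id = net$nodes$id,
    degree = as.integer(deg),
    C_d = deg / (n - 1),
    C_b_raw = cb_raw,
    C_b = cb_raw / norm,
    C_c = closeness,
    stringsAsFactors = FALSE
  )
}

#' Fit a power law to a clustering spectrum (or degree distribution)
#'
#' Ordinary least squares on the log-log points: the slope of
#' \eqn{\log y \sim \log k} restricted to \eqn{k \ge k_{min}} and
#' \eqn{y > 0} is the exponent \eqn{\gamma} of \eqn{y \propto k^\gamma}.
#' This is the conventional log-log regression of small-world analyses;
#' maximum-likelihood tail fitting is out of scope.
#'
#' @param spectrum data frame with columns `k` and a value column (`c_k` or
#'   `p_k`; the second column is used).
#' @param k_min smallest degree included in the fit.
#' @return list with `gamma`, `intercept` (on the log scale), `n_points`.
#' @export
powerlaw_gamma <- function(spectrum, k_min = 1) {
  stopifnot(is.data.frame(spectrum), "k" %in% names(spectrum), ncol(spectrum) >= 2L)
  y <- spectrum[[setdiff(names(spectrum), "k")[1L]]]
  use <- spectrum$k >= k_min & y > 0 & is.finite(y)
  if (sum(use) < 2L) {
    stop("power-law fit needs at least 2 points with k >= k_min and positive values",
         call. = FALSE)
  }
  fit <- stats::lm(log(y[use]) ~ log(spectrum$k[use]))
  list(
    gamma = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    n_points = sum(use)
  )
}

#' Full network-statistics report
#'
#' Computes the whole small-world/centrality suite for one network: node
#' and edge counts, average degree, density, average path length, diameter,
#' clustering coefficient, per-node degree/clustering/centralities, the
#' degree distribution, the clustering spectrum, and (optionally) the
#' power-law exponent of the clustering spectrum.
#'
#' @param net an `itp_network`.
#' @param density_mode `"simple"` or `"bipartite"` (see [net_density()]).
#' @param k_min if not `NULL`, fit \eqn{C(k) \propto k^\gamma} on spectrum
#'   points with \eqn{k \ge k_{min}}; the fit is skipped with a message if
#'   fewer than 2 usable points remain.
#' @param wf_correction passed to [centralities()].
#' @return an object of class `itp_metrics`: a list with `network_name`,
#'   `N`, `E`, `avg_degree`, `density`, `density_mode`, `L`, `D`, `C`,
#'   `per_node` (data frame: `id`, `type`, `degree`, `clustering`, `C_d`,
#'   `C_b_raw`, `C_b`, `C_c`), `degree_distribution`, `clustering_spectrum`,
#'   and `powerlaw` (list or `NULL`).
#' @export
network_metrics <- function(net, density_mode = c("simple", "bipartite"),
                            k_min = NULL, wf_correction = TRUE) {
  stopifnot(inherits(net, "itp_network"))
  density_mode <- match.arg(density_mode)
  ds <- degree_stats(net)
  cl <- clustering_coefficients(net)
  dist <- if (n_edges(net) > 0L && n_nodes(net) >= 2L) {
    distance_metrics(net)
  } else {
    list(L = NA_real_, D = NA_real_, d = NULL)
  }
  cent <- if (n_nodes(net) >= 3L) {
    centralities(net, wf_correction = wf_correction)
  } else {
    data.frame(id = net$nodes$id, degree = as.integer(ds$degree),
               C_d = NA_real_, C_b_raw = NA_real_, C_b = NA_real_,
               C_c = NA_real_, stringsAsFactors = FALSE)
  }
  per_node <- merge(net$nodes, cent, by = "id", sort = TRUE)
  per_node$clustering <- cl$local[per_node$id]
  per_node <- per_node[, c("id", "type", "degree", "clustering",
                           "C_d", "C_b_raw", "C_b", "C_c")]
  pl <- NULL
  if (!is.null(k_min)) {
    spec <- cl$spectrum
    usable <- sum(spec$k >= k_min & spec$c_k > 0)
    if (usable >= 2L) {
      pl <- c(powerlaw_gamma(spec, k_min = k_min), k_min = k_min)
    } else {
      message(sprintf(
        "power-law fit skipped for %s: %d usable spectrum point(s) at k >= %s",
        net$name, usable, format(k_min)))
    }
  }
  structure(list(
    network_name = net$name,
    N = n_nodes(net), E = n_edges(net),
    avg_degree = ds$avg_degree,
    density = net_density(net, mode = density_mode),
    density_mode = density_mode,
    L = dist$L, D = dist$D, C = cl$C,
    per_node = per_node,
    degree_distribution = ds$distribution,
    clustering_spectrum = cl$spectrum,
    powerlaw = pl
  ), class = "itp_metrics")
}

#' @export
print.itp_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("Network statistics: %s (N = %d, E = %d)\n",
              x$network_name, x$N, x$E))
  fm <- function(v) ifelse(is.na(v), "-", format(round(v, digits)))
  cat(sprintf("  Average degree <k>      %s\n", fm(x$avg_degree)))
  cat(sprintf("  Density (%s)      %s\n", x$density_mode, fm(x$density)))
  cat(sprintf("  Average path length L   %s\n", fm(x$L)))
  cat(sprintf("  Diameter D              %s\n", fm(x$D)))
  cat(sprintf("  Clustering coefficient  %s\n", fm(x$C)))
  cat(sprintf("  Mean degree centrality  %s\n", fm(mean(x$per_node$C_d))))
  cat(sprintf("  Mean betweenness        %s\n", fm(mean(x$per_node$C_b))))
  cat(sprintf("  Mean closeness          %s\n", fm(mean(x$per_node$C_c))))
  if (!is.null(x$powerlaw)) {
    cat(sprintf("  Power-law C(k) ~ k^gamma: gamma = %s (k >= %s, %d points)\n",
                fm(x$powerlaw$gamma), format(x$powerlaw$k_min),
                x$powerlaw$n_points))
  }
  invisible(x)
}

#' @export
summary.itp_metrics <- function(object, ...) {
  print(object, ...)
  cat("\nTop nodes by degree:\n")
  print(utils::head(rank_key_nodes(object, by = "degree"), 5L))
  invisible(object)
}

#' Rank nodes by a centrality index
#'
#' Orders the per-node table of a metrics report by the chosen index,
#' descending. `composite` is the mean of min-max-scaled degree,
#' betweenness and closeness centralities (an index that is constant across
#' nodes contributes 0 for every node). Ties are broken lexicographically
#' by node id so rankings are reproducible.
#'
#' @param report an `itp_metrics` object.
#' @param by `"degree"`, `"C_d"`, `"C_b"`, `"C_c"` or `"composite"`.
#' @return the per-node data frame, ordered, with a `rank` column and (for
#'   `composite`) a `composite` column.
#' @export
rank_key_nodes <- function(report, by = c("degree", "C_d", "C_b", "C_c", "composite")) {
  stopifnot(inherits(report, "itp_metrics"))
  by <- match.arg(by)
  pn <- report$per_node
  if (by == "composite") {
    scale01 <- function(v) {
      rng <- range(v, na.rm = TRUE)
      if (diff(rng) == 0) return(rep(0, length(v)))
      (v - rng[1L]) / diff(rng)
    }
    pn$composite <- rowMeans(cbind(scale01(pn$C_d), scale01(pn$C_b), scale01(pn$C_c)))
    key <- pn$composite
  } else {
    key <- pn[[by]]
  }
  out <- pn[order(-key, pn$id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Side-by-side summary table for several networks
#'
#' Arranges the headline statistics of several metrics reports as one row
#' per statistic and one column per network, the standard presentation of
#' multi-network studies. Centrality rows are means over nodes.
#'
#' @param ... `itp_metrics` objects (or a single list of them).
#' @return data frame with a `Characteristic` column and one numeric column
#'   per network.
#' @export
metrics_table <- function(...) {
  reports <- list(...)
  if (length(reports) == 1L && !inherits(reports[[1L]], "itp_metrics")) {
    reports <- reports[[1L]]
  }
  stopifnot(all(vapply(reports, inherits, logical(1L), "itp_metrics")))
  col <- function(r) c(
    `Nodes` = r$N,
    `Edges` = r$E,
    `Average degree` = r$avg_degree,
    `Density` = r$density,
    `Average path length` = r$L,
    `Diameter` = r$D,
    `Clustering coefficient` = r$C,
    `Degree centrality` = mean(r$per_node$C_d),
    `Betweenness centrality` = mean(r$per_node$C_b),
    `Closeness centrality` = mean(r$per_node$C_c)
  )
  vals <- vapply(reports, col, numeric(10L))
  colnames(vals) <- vapply(reports, `[[`, character(1L), "network_name")
  data.frame(Characteristic = rownames(vals), vals, row.names = NULL,
             check.names = FALSE)
}
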