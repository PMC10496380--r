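#' Construct an ingredient/pathway interaction network
#'
#' Internal constructor for the labelled, typed-node, undirected simple
#' graphs this package works with. Edges are stored canonically
#' (`from < to` in string order), de-duplicated, with self-loops rejected.
#'
#' @param nodes data frame with columns `id` (character, unique) and `type`
#'   (`"ingredient"` or `"pathway"`).
#' @param edges data frame with character columns `from`, `to`; may have
#'   zero rows.
#' @param name network name, one of `"IPI"`, `"TTI"`, `"IPB"`, `"PPI"`.
#' @return an object of class `itp_network`.
#' @export
itp_network <- function(nodes, edges, name) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  name <- match.arg(name, c("IPI", "TTI", "IPB", "PPI"))
  nodes <- data.frame(
    id = as.character(nodes$id),
    type = as.character(nodes$type),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  if (!all(nodes$type %in% c("ingredient", "pathway"))) {
    stop("node type must be 'ingredient' or 'pathway'", call. = FALSE)
  }
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL

  if (nrow(edges)) {
    from <- as.character(edges$from)
    to <- as.character(edges$to)
    if (any(from == to)) stop("self-loops are not allowed", call. = FALSE)
    swap <- from > to
    tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
    key <- paste(from, to, sep = "\r")
    keep <- !duplicated(key)
    edges <- data.frame(from = from[keep], to = to[keep], stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
    missing <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
    if (length(missing)) {
      stop("edge endpoints not declared as nodes: ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    }
  } else {
    edges <- data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  }

  type_of <- stats::setNames(nodes$type, nodes$id)
  if (nrow(edges)) {
    tf <- type_of[edges$from]; tt <- type_of[edges$to]
    ok <- switch(name,
      TTI = all(tf == "ingredient" & tt == "ingredient"),
      PPI = all(tf == "pathway" & tt == "pathway"),
      IPB = all(tf != tt),
      IPI = TRUE
    )
    if (!ok) stop(sprintf("edge node types violate the %s signature", name),
                  call. = FALSE)
  }
  structure(list(name = name, nodes = nodes, edges = edges),
            class = "itp_network")
}

#' @export
print.itp_network <- function(x, ...) {
  n_ing <- sum(x$nodes$type == "ingredient")
  n_pwy <- sum(x$nodes$type == "pathway")
  cat(sprintf("%s network: %d nodes (%d ingredients, %d pathways), %d edges\n",
              x$name, nrow(x$nodes), n_ing, n_pwy, nrow(x$edges)))
  invisible(x)
}

#' Number of nodes and edges
#' @param net an `itp_network`.
#' @return integer count.
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

# validate + normalize a mapping: named list of non-empty character vectors
.as_mapping <- function(mapping, what) {
  if (is.data.frame(mapping)) {
    if (ncol(mapping) != 2L) {
      stop(sprintf("%s table must have exactly two columns", what), call. = FALSE)
    }
    mapping <- split(as.character(mapping[[2L]]), as.character(mapping[[1L]]))
  }
  if (!is.list(mapping) || length(mapping) == 0L) {
    stop(sprintf("%s is empty or not a list", what), call. = FALSE)
  }
  if (is.null(names(mapping)) || !all(nzchar(names(mapping)))) {
    stop(sprintf("%s must be a named list or two-column data frame", what),
         call. = FALSE)
  }
  if (anyDuplicated(names(mapping))) {
    stop(sprintf("%s has duplicate ids", what), call. = FALSE)
  }
  # empty annotation sets are tolerated: the id becomes an isolated node
  mapping <- lapply(mapping, function(v) sort(unique(as.character(v))))
  mapping[order(names(mapping))]
}

.all_pairs <- function(ids) {
  n <- length(ids)
  if (n < 2L) {
    return(data.frame(from = character(), to = character(), stringsAsFactors = FALSE))
  }
  idx <- utils::combn(n, 2L)
  data.frame(from = ids[idx[1L, ]], to = ids[idx[2L, ]], stringsAsFactors = FALSE)
}

#' Ingredient-ingredient interaction (TTI) network
#'
#' Two ingredients are connected iff their predicted target sets share at
#' least one protein.
#'
#' @param itm ingredient-to-target mapping: named list (ingredient id to
#'   character vector of target ids) or a two-column data frame.
#' @return an `itp_network` with only ingredient nodes.
#' @export
build_tti <- function(itm) {
  itm <- .as_mapping(itm, "ingredient-target mapping")
  ids <- names(itm)
  pairs <- .all_pairs(ids)
  if (nrow(pairs)) {
    share <- mapply(function(a, b) length(intersect(itm[[a]], itm[[b]])) > 0L,
                    pairs$from, pairs$to)
    pairs <- pairs[share, , drop = FALSE]
  }
  itp_network(
    nodes = data.frame(id = ids, type = "ingredient"),
    edges = pairs, name = "TTI"
  )
}

#' Ingredient-pathway bimodal (IPB) network
#'
#' An ingredient is connected to a pathway iff at least one of its targets is
#' annotated to that pathway. Targets present in `itm` but missing from
#' `tpm` contribute nothing; a warning reports how many were unmapped.
#'
#' @param itm ingredient-to-target mapping (named list or two-column data
#'   frame).
#' @param tpm target-to-pathway mapping (same shapes).
#' @return a bipartite `itp_network`. Its node set is all ingredients plus
#'   all pathways appearing in `tpm`; degree-0 nodes can be removed
#'   afterwards with [prune_isolated()].
#' @export
build_ipb <- function(itm, tpm) {
  itm <- .as_mapping(itm, "ingredient-target mapping")
  tpm <- .as_mapping(tpm, "target-pathway mapping")
  unmapped <- setdiff(unique(unlist(itm)), names(tpm))
  if (length(unmapped)) {
    warning(sprintf("%d target(s) have no pathway annotation and are ignored",
                    length(unmapped)), call. = FALSE)
  }
  pathways <- sort(unique(unlist(tpm)))
  edges <- do.call(rbind, lapply(names(itm), function(i) {
    covered <- unique(unlist(tpm[intersect(itm[[i]], names(tpm))]))
    if (!length(covered)) return(NULL)
    data.frame(from = i, to = covered, stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  }
  itp_network(
    nodes = rbind(
      data.frame(id = names(itm), type = "ingredient"),
      data.frame(id = pathways, type = "pathway")
    ),
    edges = edges, name = "IPB"
  )
}

#' Pathway-pathway interaction (PPI) network
#'
#' Two pathways are connected iff at least one target is annotated to both,
#' i.e. the edge set is the union over targets of the clique on each
#' target's pathway set.
#'
#' @param tpm target-to-pathway mapping (named list or two-column data
#'   frame).
#' @return an `itp_network` with only pathway nodes.
#' @export
build_ppi <- function(tpm) {
  tpm <- .as_mapping(tpm, "target-pathway mapping")
  pathways <- sort(unique(unlist(tpm)))
  edges <- do.call(rbind, lapply(tpm, function(pwys) {
    .all_pairs(sort(pwys))
  }))
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  }
  itp_network(
    nodes = data.frame(id = pathways, type = "pathway"),
    edges = edges, name = "PPI"
  )
}

#' Merged ingredient-pathway interaction (IPI) network
#'
#' The full multiplex: ingredient and pathway nodes with all three edge
#' classes — ingredient-ingredient (shared target), ingredient-pathway
#' (target annotated to pathway), and pathway-pathway (shared target). The
#' three classes are disjoint by node-type signature, so the edge count of
#' the IPI network is always the sum of the TTI, IPB and PPI edge counts.
#'
#' @inheritParams build_ipb
#' @param prune drop degree-0 nodes from the result (the convention of
#'   removing isolated elements before reporting network sizes). Off by
#'   default so node budgets stay auditable.
#' @return an `itp_network` with name `"IPI"`.
#' @export
build_ipi <- function(itm, tpm = NULL, prune = FALSE) {
  itm <- .as_mapping(itm, "ingredient-target mapping")
  if (is.null(tpm) || (is.list(tpm) && !is.data.frame(tpm) && length(tpm) == 0L)) {
    tti <- build_tti(itm)
    net <- itp_network(tti$nodes, tti$edges, "IPI")
    return(if (prune) prune_isolated(net) else net)
  }
  tpm <- .as_mapping(tpm, "target-pathway mapping")
  tti <- build_tti(itm)
  ipb <- suppressWarnings(build_ipb(itm, tpm))
  ppi <- build_ppi(tpm)
  net <- itp_network(
    nodes = ipb$nodes,
    edges = rbind(tti$edges, ipb$edges, ppi$edges),
    name = "IPI"
  )
  if (prune) prune_isolated(net) else net
}

#' Remove isolated (degree-0) nodes from a network
#'
#' @param net an `itp_network`.
#' @return the network restricted to nodes with degree >= 1.
#' @export
prune_isolated <- function(net) {
  stopifnot(inherits(net, "itp_network"))
  connected <- unique(c(net$edges$from, net$edges$to))
  dropped <- setdiff(net$nodes$id, connected)
  if (length(dropped)) {
    message(sprintf("pruned %d isolated node(s) from %s", length(dropped), net$name))
  }
  itp_network(net$nodes[net$nodes$id %in% connected, , drop = FALSE],
              net$edges, net$name)
}

#' Restrict a merged IPI network to one edge-class signature
#'
#' Extracts the TTI, IPB or PPI subnetwork of an IPI network by node-type
#' signature of the edges.
#'
#' @param net an `itp_network`, normally with name `"IPI"`.
#' @param name which subnetwork to extract.
#' @return an `itp_network` of the requested class.
#' @export
subnetwork <- function(net, name = c("TTI", "IPB", "PPI")) {
  stopifnot(inherits(net, "itp_network"))
  name <- match.arg(name)
  type_of <- stats::setNames(net$nodes$type, net$nodes$id)
  tf <- type_of[net$edges$from]
  tt <- type_of[net$edges$to]
  keep <- switch(name,
    TTI = tf == "ingredient" & tt == "ingredient",
    PPI = tf == "pathway" & tt == "pathway",
    IPB = tf != tt
  )
  nodes <- switch(name,
    TTI = net$nodes[net$nodes$type == "ingredient", , drop = FALSE],
    PPI = net$nodes[net$nodes$type == "pathway", , drop = FALSE],
    IPB = net$nodes
  )
  itp_network(nodes, net$edges[keep, , drop = FALSE], name)
}
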