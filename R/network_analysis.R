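#' Number of unordered phenotype pairs
#'
#' @param P node count, at least 2.
#' @return `P * (P - 1) / 2`, e.g. 45 pairs for 10 phenotypes, 28 for 8.
#' @export
pair_count <- function(P) {
  if (length(P) != 1L || is.na(P) || P < 2 || P != round(P))
    stop("P must be a single integer >= 2", call. = FALSE)
  as.integer(P * (P - 1) / 2)
}

#' Network density (percent)
#'
#' The portion of all possible node pairs realized as edges, as a percentage
#' reported to two decimals (so 29 edges among 10 nodes give 64.44).
#'
#' @param n_edges number of edges.
#' @param P node count.
#' @return Density in percent, rounded to 2 decimals.
#' @export
network_density <- function(n_edges, P) {
  np <- pair_count(P)
  if (length(n_edges) != 1L || is.na(n_edges) || n_edges < 0 || n_edges > np)
    stop("n_edges must lie in [0, ", np, "]", call. = FALSE)
  round(100 * n_edges / np, 2)
}

# adjacency matrix (logical) of a phenotype_network
.adjacency <- function(network) {
  nms <- network$nodes
  A <- matrix(FALSE, length(nms), length(nms), dimnames = list(nms, nms))
  if (nrow(network$edges)) {
    i <- match(network$edges$node1, nms)
    j <- match(network$edges$node2, nms)
    A[cbind(i, j)] <- TRUE
    A[cbind(j, i)] <- TRUE
  }
  A
}

#' Degree ranking of network nodes
#'
#' @param network a [phenotype_network()].
#' @return Data frame with `node`, `degree` and `fully_connected` (is the node
#'   adjacent to every other node), sorted by degree descending with ties
#'   broken lexicographically by node name.
#' @export
degree_ranking <- function(network) {
  stopifnot(inherits(network, "phenotype_network"))
  A <- .adjacency(network)
  deg <- rowSums(A)
  out <- data.frame(node = names(deg), degree = as.integer(deg),
                    fully_connected = deg == length(network$nodes) - 1L,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Transitive-node analysis of non-adjacent pairs
#'
#' For every unordered pair of nodes without a direct edge, finds the set of
#' "transitive" nodes: intermediates m such that both (j, m) and (m, k) are
#' edges, i.e. the pair is connected by a shortest path of length 2 through m.
#' Pairs with no such intermediate are at graph distance greater than 2 (or
#' disconnected) and are reported separately. Per-node counts tally the number
#' of non-adjacent *pairs* (not paths) each node connects; when a pair has
#' several transitive nodes, every one of them is credited.
#'
#' @param network a [phenotype_network()].
#' @return List with `pairs` (data frame: `node1`, `node2`, `connectors`
#'   (comma-separated), `n_connectors`, `distance_gt_2`) and `node_counts`
#'   (named integer vector over all nodes).
#' @export
transitive_nodes <- function(network) {
  stopifnot(inherits(network, "phenotype_network"))
  A <- .adjacency(network)
  nms <- network$nodes
  P <- length(nms)
  rows <- list()
  counts <- stats::setNames(integer(P), nms)
  if (P >= 2) {
    for (j in seq_len(P - 1)) for (k in (j + 1):P) {
      if (A[j, k]) next
      mids <- nms[A[j, ] & A[k, ]]
      counts[mids] <- counts[mids] + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        node1 = nms[j], node2 = nms[k],
        connectors = paste(mids, collapse = ","),
        n_connectors = length(mids),
        distance_gt_2 = length(mids) == 0L,
        stringsAsFactors = FALSE
      )
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows)
           else data.frame(node1 = character(), node2 = character(),
                           connectors = character(), n_connectors = integer(),
                           distance_gt_2 = logical())
  list(pairs = pairs, node_counts = counts)
}

#' Summary statistics of a network
#'
#' @param network a [phenotype_network()].
#' @return Object of class `network_summary`: node/pair/edge counts, density
#'   percent, the degree ranking and transitive-node counts.
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "phenotype_network"))
  P <- length(network$nodes)
  ne <- nrow(network$edges)
  structure(
    list(n_nodes = P, n_possible_pairs = pair_count(P), n_edges = ne,
         density_percent = network_density(ne, P),
         degree = degree_ranking(network),
         transitive = transitive_nodes(network),
         alpha = network$alpha),
    class = "network_summary"
  )
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("nodes: %d  possible pairs: %d  edges: %d  density: %.2f%% (alpha = %g)\n",
              x$n_nodes, x$n_possible_pairs, x$n_edges, x$density_percent, x$alpha))
  cat("top degrees:\n")
  print(utils::head(x$degree, 5))
  tc <- sort(x$transitive$node_counts, decreasing = TRUE)
  tc <- tc[tc > 0]
  if (length(tc)) {
    cat("transitive-node pair counts:",
        paste(sprintf("%s=%d", names(tc), tc), collapse = ", "), "\n")
  }
  invisible(x)
}
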