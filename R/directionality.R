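#' Standardized partial variances
#'
#' The standardized partial variance (SPV) of phenotype j is the fraction of
#' its variance left unexplained by all other phenotypes,
#' \eqn{\mathrm{spv}_j = 1 - R^2_j = 1/q_{jj}}, where \eqn{q_{jj}} is the j-th
#' diagonal of the precision of the *correlation* matrix. Computing on the
#' correlation scale makes the quantity unit-free, so it is invariant to
#' affine rescaling of any phenotype.
#'
#' @param fit a `ggm_fit` from [fit_network()], or a positive definite
#'   correlation matrix.
#' @return Named vector of SPVs in `(0, 1]`.
#' @export
standardized_partial_variance <- function(fit) {
  R <- if (inherits(fit, "ggm_fit")) fit$correlation else as.matrix(fit)
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch))
    stop("correlation matrix is not positive definite", call. = FALSE)
  q <- chol2inv(ch)
  spv <- 1 / diag(q)
  names(spv) <- colnames(R)
  spv
}

#' Orient network edges by SPV log-ratios
#'
#' Produces a partially directed graph with the same topology as the
#' undirected significance network. For each edge (j, k) the log-ratio
#' \eqn{r_{jk} = \log(\mathrm{spv}_j / \mathrm{spv}_k)} is antisymmetric; the
#' edge is directed from the node with the larger SPV (the less-explained
#' variable) toward the node with the smaller SPV when
#' \eqn{|r_{jk}|} exceeds `min_abs_log_ratio`, and left undirected otherwise.
#' Hub-like sink nodes (well explained by their neighbors) therefore collect
#' incoming edges.
#'
#' @param fit a `ggm_fit`.
#' @param network the [phenotype_network()] to orient (its edges must be pairs
#'   of the fit's phenotypes).
#' @param min_abs_log_ratio non-negative orientation threshold. The default
#'   `log(1.25)` directs an edge only when one SPV exceeds the other by at
#'   least 25%; pass a smaller value to orient weakly coupled systems, or 0
#'   to direct every edge.
#' @return Object of class `directed_network`: `nodes`, `spv`, `edges` (data
#'   frame with `node1`, `node2`, `pcor`, `pvalue`, `log_ratio`, `source`,
#'   `sink`, `directed`), `in_degree` (named count of incoming directed
#'   edges), `min_abs_log_ratio`.
#' @export
orient_edges <- function(fit, network, min_abs_log_ratio = log(1.25)) {
  stopifnot(inherits(fit, "ggm_fit"), inherits(network, "phenotype_network"))
  if (length(min_abs_log_ratio) != 1L || is.na(min_abs_log_ratio) ||
      min_abs_log_ratio < 0)
    stop("min_abs_log_ratio must be a single non-negative number", call. = FALSE)
  if (!all(c(network$edges$node1, network$edges$node2) %in% fit$phenotype_names))
    stop("network edges must connect phenotypes of the fit", call. = FALSE)
  spv <- standardized_partial_variance(fit)
  e <- network$edges
  lr <- log(spv[e$node1] / spv[e$node2])
  directed <- abs(lr) > min_abs_log_ratio
  src <- ifelse(lr >= 0, e$node1, e$node2)
  snk <- ifelse(lr >= 0, e$node2, e$node1)
  edges <- data.frame(
    node1 = e$node1, node2 = e$node2,
    pcor = e$pcor, pvalue = e$pvalue,
    log_ratio = as.numeric(lr),
    source = ifelse(directed, src, NA_character_),
    sink = ifelse(directed, snk, NA_character_),
    directed = directed,
    stringsAsFactors = FALSE
  )
  rownames(edges) <- NULL
  in_degree <- stats::setNames(integer(length(network$nodes)), network$nodes)
  if (any(directed)) {
    tb <- table(edges$sink[edges$directed])
    in_degree[names(tb)] <- as.integer(tb)
  }
  structure(
    list(nodes = network$nodes, spv = spv, edges = edges,
         in_degree = in_degree, min_abs_log_ratio = min_abs_log_ratio,
         alpha = network$alpha),
    class = "directed_network"
  )
}

#' @export
print.directed_network <- function(x, ...) {
  nd <- sum(x$edges$directed)
  cat(sprintf("directed_network: %d nodes, %d edges (%d directed, %d undirected)\n",
              length(x$nodes), nrow(x$edges), nd, nrow(x$edges) - nd))
  top <- sort(x$in_degree, decreasing = TRUE)
  top <- top[top > 0]
  if (length(top))
    cat("in-degree:", paste(sprintf("%s=%d", names(top), top), collapse = ", "), "\n")
  invisible(x)
}
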