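# shared fixtures and independent oracles, all built in code

make_table <- function(x, group = NULL) {
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  phenotype_table(as.data.frame(x), colnames(x), group = group)
}

# random multivariate-normal draw with a valid random partial-correlation
# structure: precision = I + weak random symmetric off-diagonals
random_spec <- function(P, K, seed, max_omega = 0.3) {
  set.seed(seed)
  om <- diag(P)
  off <- matrix(stats::runif(P * P, -max_omega, max_omega), P)
  off <- (off + t(off)) / 2 / P * 2  # damp to keep the precision PD
  om[upper.tri(om)] <- off[upper.tri(off)]
  om[lower.tri(om)] <- t(om)[lower.tri(om)]
  diag(om) <- 1
  ggm_spec(paste0("v", seq_len(P)), om, K = K, seed = seed)
}

# oracle: partial correlation of columns j and k via explicit least-squares
# regression of each on all remaining columns (independent of the precision
# matrix route used by the package)
residual_pcor_oracle <- function(x, j, k) {
  others <- setdiff(seq_len(ncol(x)), c(j, k))
  if (length(others) == 0) return(stats::cor(x[, j], x[, k]))
  Z <- cbind(1, x[, others, drop = FALSE])
  rj <- stats::lm.fit(Z, x[, j])$residuals
  rk <- stats::lm.fit(Z, x[, k])$residuals
  stats::cor(rj, rk)
}

# oracle: O(P^3) triple scan for length-2 connectors of non-adjacent pairs
transitive_oracle <- function(adj) {
  P <- nrow(adj)
  nms <- rownames(adj)
  out <- list()
  for (j in seq_len(P - 1)) for (k in (j + 1):P) {
    if (adj[j, k]) next
    mids <- nms[vapply(seq_len(P), function(m) adj[j, m] && adj[m, k], logical(1))]
    out[[paste(nms[j], nms[k], sep = "|")]] <- mids
  }
  out
}

# build an arbitrary significance network over `nodes` from an index matrix
edges_network <- function(nodes, pairs, pcor = NULL, pvalue = NULL,
                          alpha = 0.05) {
  n <- nrow(pairs)
  phenotype_network(
    nodes,
    data.frame(node1 = nodes[pairs[, 1]], node2 = nodes[pairs[, 2]],
               pcor = pcor %||% rep(0.5, n),
               pvalue = pvalue %||% rep(1e-4, n),
               stringsAsFactors = FALSE),
    alpha = alpha
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
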