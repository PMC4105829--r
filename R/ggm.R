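#' Shrinkage estimate of the correlation matrix
#'
#' Standardizes each phenotype column and shrinks the sample correlation
#' matrix toward the identity, \eqn{R^* = \lambda I + (1-\lambda) R}. When
#' `lambda` is not supplied it is estimated analytically by the
#' variance-of-entries rule,
#' \eqn{\hat\lambda = \sum_{j<k} \widehat{\mathrm{Var}}(r_{jk}) /
#' \sum_{j<k} r_{jk}^2}, clipped to `[0, 1]`. This guarantees a positive
#' definite estimate even when \eqn{K} is close to \eqn{P}; with ample
#' subjects the estimated intensity is near zero and \eqn{R^*} is essentially
#' the sample correlation.
#'
#' @param table a [phenotype_table()] (complete cases) or a numeric K x P
#'   matrix.
#' @param lambda shrinkage intensity in `[0, 1]`, or `NULL` (default) to
#'   estimate it from the data.
#' @return List with `correlation` (P x P matrix) and `lambda` (the intensity
#'   used).
#' @export
estimate_correlation <- function(table, lambda = NULL) {
  x <- if (inherits(table, "phenotype_table")) pheno_values(table) else as.matrix(table)
  if (anyNA(x))
    stop("missing values present; apply complete_case_filter() first", call. = FALSE)
  K <- nrow(x); P <- ncol(x)
  degrees_of_freedom(K, P)  # validates K >= P + 2
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s) with zero variance: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  xs <- scale(x)
  r <- crossprod(xs) / (K - 1)
  diag(r) <- 1
  if (is.null(lambda)) {
    # variance-of-entries intensity: var-hat(r_jk) from the empirical variance
    # of the per-subject products of standardized scores
    wbar <- r * (K - 1) / K
    sum_w2 <- crossprod(xs^2)
    var_r <- K / (K - 1)^3 * (sum_w2 - K * wbar^2)
    off <- upper.tri(r)
    denom <- sum(r[off]^2)
    lambda <- if (denom > 0) min(1, max(0, sum(var_r[off]) / denom)) else 1
  } else {
    if (length(lambda) != 1L || is.na(lambda) || lambda < 0 || lambda > 1)
      stop("lambda must be a single value in [0, 1]", call. = FALSE)
  }
  rstar <- (1 - lambda) * r
  diag(rstar) <- 1
  list(correlation = rstar, lambda = lambda)
}

#' Partial correlations from a correlation matrix
#'
#' Inverts the (positive definite) correlation matrix to the precision matrix
#' \eqn{Q} and standardizes: \eqn{\omega_{jk} = -q_{jk}/\sqrt{q_{jj} q_{kk}}}
#' for \eqn{j \ne k}, with unit diagonal. \eqn{\omega_{jk}} is the correlation
#' of variables j and k conditional on all remaining variables, and is zero
#' exactly when they are conditionally independent under Gaussianity.
#'
#' @param correlation symmetric positive definite P x P matrix.
#' @return Symmetric P x P partial-correlation matrix with unit diagonal.
#' @export
partial_correlations <- function(correlation) {
  correlation <- as.matrix(correlation)
  if (nrow(correlation) != ncol(correlation) ||
      max(abs(correlation - t(correlation))) > 1e-8)
    stop("correlation matrix must be symmetric", call. = FALSE)
  ch <- tryCatch(chol(correlation), error = function(e) NULL)
  if (is.null(ch))
    stop("correlation matrix is singular or not positive definite; ",
         "re-estimate with shrinkage (lambda > 0)", call. = FALSE)
  q <- chol2inv(ch)
  d <- sqrt(diag(q))
  pcor <- -q / tcrossprod(d)
  diag(pcor) <- 1
  pcor <- (pcor + t(pcor)) / 2
  dimnames(pcor) <- dimnames(correlation)
  pcor
}

#' Fit a phenotypic GGM network
#'
#' Full pipeline: standardize the phenotype columns, estimate the (shrunk)
#' correlation matrix, invert to partial correlations, assign every pair a
#' two-sided p-value from the Hotelling null with \eqn{\kappa = K - P + 1}
#' degrees of freedom, and keep edges with `p < alpha`.
#'
#' @param table a [phenotype_table()] with complete cases.
#' @param alpha significance threshold for an edge (the conventional choices
#'   are 0.001 for a single-population network and 0.05 for group networks).
#' @param lambda shrinkage intensity; `NULL` (default) estimates it, `0`
#'   reproduces the plain sample-correlation fit under which the Hotelling
#'   null is exact.
#' @param bonferroni if `TRUE`, threshold at `alpha / pair_count(P)` instead.
#' @return List with components `fit` (a `ggm_fit`: mean, correlation,
#'   shrinkage_lambda, pcor, kappa, pvalues, log10_pvalues) and `network`
#'   (a [phenotype_network()] of significant edges).
#' @export
#' @examples
#' om <- diag(3)
#' om[1, 2] <- om[2, 1] <- 0.4
#' spec <- ggm_spec(c("a", "b", "c"), om, K = 200, seed = 1)
#' res <- fit_network(sample_ggm(spec), alpha = 0.05)
#' res$network
fit_network <- function(table, alpha = 0.001, lambda = NULL, bonferroni = FALSE) {
  stopifnot(inherits(table, "phenotype_table"))
  x <- pheno_values(table)
  est <- estimate_correlation(x, lambda = lambda)
  pcor <- partial_correlations(est$correlation)
  K <- nrow(x); P <- ncol(x)
  kappa <- degrees_of_freedom(K, P)
  lp10 <- matrix(0, P, P, dimnames = dimnames(pcor))
  off <- upper.tri(lp10)
  lp10[off] <- hotelling_pvalue(pcor[off], kappa, log10 = TRUE)
  lp10 <- lp10 + t(lp10)
  pv <- 10^lp10
  diag(pv) <- NA_real_
  diag(lp10) <- NA_real_
  fit <- structure(
    list(mean = colMeans(x), correlation = est$correlation,
         shrinkage_lambda = est$lambda, pcor = pcor, kappa = kappa,
         pvalues = pv, log10_pvalues = lp10,
         K = K, P = P, phenotype_names = colnames(x), group = table$group),
    class = "ggm_fit"
  )
  thr <- if (bonferroni) alpha / pair_count(P) else alpha
  list(fit = fit, network = network_from_fit(fit, alpha = thr))
}

#' @export
print.ggm_fit <- function(x, ...) {
  cat(sprintf("ggm_fit: P=%d phenotypes, K=%d subjects (kappa=%d), lambda=%.4g\n",
              x$P, x$K, x$kappa, x$shrinkage_lambda))
  invisible(x)
}

#' Significance network of a fitted GGM
#'
#' Extracts the edges of a `ggm_fit` with p-value below `alpha`, ordered by
#' ascending p-value (ties broken by descending `|pcor|`, then by node pair).
#'
#' @param fit a `ggm_fit` from [fit_network()].
#' @param alpha significance threshold.
#' @return A [phenotype_network()].
#' @export
network_from_fit <- function(fit, alpha = 0.001) {
  stopifnot(inherits(fit, "ggm_fit"))
  nms <- fit$phenotype_names
  P <- fit$P
  idx <- which(upper.tri(fit$pcor), arr.ind = TRUE)
  edges <- data.frame(
    node1 = nms[idx[, 1]], node2 = nms[idx[, 2]],
    pcor = fit$pcor[idx],
    pvalue = fit$pvalues[idx],
    log10_pvalue = fit$log10_pvalues[idx],
    stringsAsFactors = FALSE
  )
  edges <- edges[edges$pvalue < alpha, , drop = FALSE]
  phenotype_network(nodes = nms, edges = edges, alpha = alpha)
}

#' Phenotype significance network
#'
#' An undirected graph whose nodes are phenotypes and whose edges are the
#' pairs with significant partial correlation. Edge rows carry `node1`,
#' `node2`, `pcor`, `pvalue` (and optionally `log10_pvalue`). Edges are
#' stored with a deterministic order: ascending p-value, ties broken by
#' descending `|pcor|`, then lexicographic node pair.
#'
#' @param nodes character vector of phenotype names.
#' @param edges data frame with at least `node1`, `node2`, `pcor`, `pvalue`;
#'   may be empty.
#' @param alpha the significance threshold the edges satisfy.
#' @return Object of class `phenotype_network`.
#' @export
phenotype_network <- function(nodes, edges, alpha = 0.001) {
  if (missing(edges) || is.null(edges))
    edges <- data.frame(node1 = character(), node2 = character(),
                        pcor = numeric(), pvalue = numeric())
  stopifnot(all(c("node1", "node2", "pcor", "pvalue") %in% names(edges)))
  if (nrow(edges)) {
    if (any(edges$node1 == edges$node2))
      stop("self-loop edges are not allowed", call. = FALSE)
    if (!all(c(edges$node1, edges$node2) %in% nodes))
      stop("edge endpoints must be listed in nodes", call. = FALSE)
    # canonical endpoint order within each edge, then sort
    swap <- edges$node1 > edges$node2
    tmp <- edges$node1[swap]; edges$node1[swap] <- edges$node2[swap]
    edges$node2[swap] <- tmp
    if (anyDuplicated(edges[c("node1", "node2")]))
      stop("duplicate edges are not allowed", call. = FALSE)
    key <- if ("log10_pvalue" %in% names(edges)) edges$log10_pvalue
           else log10(edges$pvalue)
    edges <- edges[order(key, -abs(edges$pcor), edges$node1, edges$node2), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, alpha = alpha),
            class = "phenotype_network")
}

#' @export
print.phenotype_network <- function(x, ...) {
  cat(sprintf("phenotype_network: %d nodes, %d edges (alpha = %g, density = %.2f%%)\n",
              length(x$nodes), nrow(x$edges), x$alpha,
              network_density(nrow(x$edges), length(x$nodes))))
  if (nrow(x$edges)) print(utils::head(x$edges, 10))
  invisible(x)
}
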