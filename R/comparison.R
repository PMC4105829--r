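# fast internal pcor for permutation loops: standardize -> (optionally shrunk)
# correlation -> precision -> standardized negative off-diagonals
.pcor_of <- function(x, lambda) {
  K <- nrow(x)
  xs <- scale(x)
  r <- crossprod(xs) / (K - 1)
  diag(r) <- 1
  if (is.null(lambda)) {
    wbar <- r * (K - 1) / K
    var_r <- K / (K - 1)^3 * (crossprod(xs^2) - K * wbar^2)
    off <- upper.tri(r)
    denom <- sum(r[off]^2)
    lambda <- if (denom > 0) min(1, max(0, sum(var_r[off]) / denom)) else 1
  }
  r <- (1 - lambda) * r
  diag(r) <- 1
  q <- chol2inv(chol(r))
  d <- sqrt(diag(q))
  pc <- -q / tcrossprod(d)
  diag(pc) <- 1
  pc
}

#' Permutation test for differential network connectivity
#'
#' Tests, for every phenotype pair, whether the partial correlation differs
#' between two subject groups. The observed statistic is the signed difference
#' \eqn{\Delta_{jk} = \omega^A_{jk} - \omega^B_{jk}}. Group labels are
#' reshuffled over the pooled subjects (group sizes held fixed), the partial
#' correlations are recomputed in each shuffled group with the same shrinkage
#' policy, and the two-sided empirical p-value is
#' \eqn{(1 + \#\{|\Delta^{perm}| \ge |\Delta^{obs}|\}) / (B + 1)},
#' bounded below by the resolution floor \eqn{1/(B+1)}.
#'
#' @param tableA,tableB [phenotype_table()] objects with identical phenotype
#'   columns; each group needs `K >= P + 2`.
#' @param B number of label permutations (10,000 is the conventional choice;
#'   values below 100 trigger a resolution warning).
#' @param seed integer seed for reproducible shuffles.
#' @param lambda shrinkage policy applied to the observed and every permuted
#'   fit: `NULL` re-estimates per fit, a number pins it.
#' @param alpha significance threshold used for the [classify_edges()] column.
#' @return A `comparison_result` data frame with one row per pair: `node1`,
#'   `node2`, `pcor_A`, `pcor_B`, `pvalue_A`, `pvalue_B` (Hotelling), `delta`,
#'   `perm_pvalue`, `edge_class`.
#' @export
permutation_diff_test <- function(tableA, tableB, B = 10000, seed = NULL,
                                  lambda = NULL, alpha = 0.05) {
  stopifnot(inherits(tableA, "phenotype_table"),
            inherits(tableB, "phenotype_table"))
  if (!identical(tableA$phenotypes, tableB$phenotypes))
    stop("the two groups must share the same phenotype columns", call. = FALSE)
  if (B < 100)
    warning("B < 100 gives a permutation p-value floor above 0.01", call. = FALSE)
  xA <- pheno_values(tableA); xB <- pheno_values(tableB)
  KA <- nrow(xA); KB <- nrow(xB); P <- ncol(xA)
  kapA <- degrees_of_freedom(KA, P); kapB <- degrees_of_freedom(KB, P)
  pcA <- .pcor_of(xA, lambda); pcB <- .pcor_of(xB, lambda)
  delta_obs <- pcA - pcB
  off <- which(upper.tri(delta_obs))
  pooled <- rbind(xA, xB)
  count <- numeric(length(off))
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(KA + KB)
      d <- .pcor_of(pooled[idx[seq_len(KA)], , drop = FALSE], lambda) -
           .pcor_of(pooled[idx[(KA + 1):(KA + KB)], , drop = FALSE], lambda)
      count <- count + (abs(d[off]) >= abs(delta_obs[off]))
    }
  })
  idx2 <- which(upper.tri(pcA), arr.ind = TRUE)
  nms <- tableA$phenotypes
  out <- data.frame(
    node1 = nms[idx2[, 1]], node2 = nms[idx2[, 2]],
    pcor_A = pcA[off], pcor_B = pcB[off],
    pvalue_A = hotelling_pvalue(pcA[off], kapA),
    pvalue_B = hotelling_pvalue(pcB[off], kapB),
    delta = delta_obs[off],
    perm_pvalue = (1 + count) / (B + 1),
    stringsAsFactors = FALSE
  )
  out$edge_class <- .classify(out$pvalue_A, out$pvalue_B,
                              out$pcor_A, out$pcor_B, alpha)
  class(out) <- c("comparison_result", class(out))
  attr(out, "B") <- B
  attr(out, "alpha") <- alpha
  attr(out, "groups") <- c(A = tableA$group %||% "A", B = tableB$group %||% "B")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.classify <- function(pA, pB, wA, wB, alpha) {
  sigA <- pA < alpha
  sigB <- pB < alpha
  ifelse(sigA & sigB & sign(wA) == sign(wB), "concordant",
  ifelse(sigA & sigB, "sign_discordant",
  ifelse(sigA, "A_only",
  ifelse(sigB, "B_only", "absent"))))
}

#' Classify edges by concordance between two group fits
#'
#' Mirrors the green/red/black edge classes of two-group network figures:
#' `concordant` when the pair is significant in both groups with the same
#' sign of partial correlation, `sign_discordant` when significant in both
#' with opposite signs, `A_only`/`B_only` when significant in exactly one
#' group, `absent` otherwise.
#'
#' @param fitA,fitB `ggm_fit` objects over the same phenotypes.
#' @param alpha per-group significance threshold (0.05 is conventional for
#'   group comparisons).
#' @return Data frame with `node1`, `node2`, `pcor_A`, `pcor_B`, `pvalue_A`,
#'   `pvalue_B`, `edge_class`.
#' @export
classify_edges <- function(fitA, fitB, alpha = 0.05) {
  stopifnot(inherits(fitA, "ggm_fit"), inherits(fitB, "ggm_fit"))
  if (!identical(fitA$phenotype_names, fitB$phenotype_names))
    stop("fits must cover the same phenotypes", call. = FALSE)
  idx <- which(upper.tri(fitA$pcor), arr.ind = TRUE)
  off <- which(upper.tri(fitA$pcor))
  nms <- fitA$phenotype_names
  out <- data.frame(
    node1 = nms[idx[, 1]], node2 = nms[idx[, 2]],
    pcor_A = fitA$pcor[off], pcor_B = fitB$pcor[off],
    pvalue_A = fitA$pvalues[off], pvalue_B = fitB$pvalues[off],
    stringsAsFactors = FALSE
  )
  out$edge_class <- .classify(out$pvalue_A, out$pvalue_B,
                              out$pcor_A, out$pcor_B, alpha)
  out
}

#' Partial residuals for a focal phenotype pair
#'
#' Residuals of the two focal variables after least-squares regression (with
#' intercept) on the remaining P - 2 phenotypes — the scatter underlying a
#' partial-correlation estimate. The Pearson correlation of the two residual
#' vectors equals the lambda = 0 GGM partial correlation of the pair.
#'
#' @param table a [phenotype_table()] with complete cases and P >= 3.
#' @param x,y names of the two focal phenotypes.
#' @return Data frame with per-subject `residual_x`, `residual_y` and a
#'   `group` column (the table's group label, if any); attribute
#'   `residual_cor` holds their Pearson correlation.
#' @export
partial_residuals <- function(table, x, y) {
  stopifnot(inherits(table, "phenotype_table"))
  v <- pheno_values(table)
  if (!all(c(x, y) %in% colnames(v)))
    stop("focal variables must be phenotype columns", call. = FALSE)
  if (ncol(v) < 3) stop("need at least 3 phenotypes", call. = FALSE)
  if (anyNA(v))
    stop("missing values present; apply complete_case_filter() first", call. = FALSE)
  others <- setdiff(colnames(v), c(x, y))
  X <- cbind(1, v[, others, drop = FALSE])
  if (qr(X)$rank < ncol(X))
    stop("conditioning phenotypes are collinear", call. = FALSE)
  res <- stats::lm.fit(X, v[, c(x, y)])$residuals
  if (any(apply(res, 2, stats::sd) < 1e-12))
    stop("zero residual variance for a focal variable", call. = FALSE)
  out <- data.frame(residual_x = res[, 1], residual_y = res[, 2],
                    group = table$group %||% NA_character_,
                    stringsAsFactors = FALSE)
  attr(out, "residual_cor") <- stats::cor(res[, 1], res[, 2])
  attr(out, "focal") <- c(x = x, y = y)
  out
}

#' Marginal and partial correlations of focal pairs across groups
#'
#' For each group and each focal pair, reports the marginal Pearson
#' correlation side by side with the GGM partial correlation (lambda = 0) and
#' its Hotelling p-value — the layout that exposes partial-vs-marginal sign
#' divergence across severity groups.
#'
#' @param tables named list of [phenotype_table()] objects (>= 2 groups) with
#'   identical phenotype columns.
#' @param pairs a 2-column character matrix, or a list of length-2 character
#'   vectors, of focal pairs.
#' @param lambda shrinkage policy for the GGM fits (default 0 so the partial
#'   correlation equals the residual-regression correlation).
#' @return Data frame with `group`, `node1`, `node2`, `pearson_r`, `pcor`,
#'   `pvalue`.
#' @export
multi_group_compare <- function(tables, pairs, lambda = 0) {
  stopifnot(is.list(tables), length(tables) >= 2)
  if (is.list(pairs) && !is.matrix(pairs))
    pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.character(pairs), ncol = 2)
  ph <- tables[[1]]$phenotypes
  rows <- list()
  for (g in names(tables)) {
    tab <- tables[[g]]
    if (!identical(tab$phenotypes, ph))
      stop("all groups must share the same phenotype columns", call. = FALSE)
    v <- pheno_values(tab)
    kappa <- degrees_of_freedom(nrow(v), ncol(v))
    pc <- partial_correlations(estimate_correlation(v, lambda = lambda)$correlation)
    for (i in seq_len(nrow(pairs))) {
      a <- pairs[i, 1]; b <- pairs[i, 2]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, node1 = a, node2 = b,
        pearson_r = stats::cor(v[, a], v[, b]),
        pcor = pc[a, b],
        pvalue = hotelling_pvalue(pc[a, b], kappa),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
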