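#' Specification of a synthetic cohort with known partial correlations
#'
#' Defines a P-variate Gaussian sampling model by its target partial
#' correlation matrix. The implied precision matrix has unit diagonal and
#' off-diagonals \eqn{q_{jk} = -\omega_{jk}}; it must be positive definite
#' (the minimum eigenvalue is validated and stored), and the sampling
#' covariance is its inverse. Fitted partial correlations converge to the
#' targets as K grows.
#'
#' @param phenotype_names character vector of P unique names.
#' @param target_pcor symmetric P x P matrix with unit diagonal and
#'   off-diagonal entries in `(-1, 1)`.
#' @param K number of subjects to draw.
#' @param seed integer seed making [sample_ggm()] deterministic.
#' @return Object of class `ggm_spec` with elements `phenotype_names`,
#'   `target_pcor`, `K`, `seed`, `min_eigenvalue`.
#' @export
#' @examples
#' om <- diag(3); om[1, 2] <- om[2, 1] <- 0.5
#' spec <- ggm_spec(c("x", "y", "z"), om, K = 500, seed = 7)
ggm_spec <- function(phenotype_names, target_pcor, K, seed = NULL) {
  P <- length(phenotype_names)
  if (P < 2 || anyDuplicated(phenotype_names))
    stop("need at least two unique phenotype names", call. = FALSE)
  target_pcor <- as.matrix(target_pcor)
  if (!all(dim(target_pcor) == P))
    stop("target_pcor must be P x P", call. = FALSE)
  if (max(abs(target_pcor - t(target_pcor))) > 1e-10)
    stop("target_pcor must be symmetric", call. = FALSE)
  if (any(abs(diag(target_pcor) - 1) > 1e-10))
    stop("target_pcor must have unit diagonal", call. = FALSE)
  off <- target_pcor[upper.tri(target_pcor)]
  if (any(abs(off) >= 1))
    stop("off-diagonal partial correlations must lie in (-1, 1)", call. = FALSE)
  if (length(K) != 1L || is.na(K) || K < 1)
    stop("K must be a positive subject count", call. = FALSE)
  Q <- -target_pcor
  diag(Q) <- 1
  mineig <- min(eigen(Q, symmetric = TRUE, only.values = TRUE)$values)
  if (mineig <= 1e-10)
    stop(sprintf(paste0("implied precision matrix is not positive definite ",
                        "(minimum eigenvalue %.4g); weaken the requested ",
                        "partial correlations"), mineig), call. = FALSE)
  dimnames(target_pcor) <- list(phenotype_names, phenotype_names)
  structure(
    list(phenotype_names = phenotype_names, target_pcor = target_pcor,
         K = as.integer(K), seed = seed, min_eigenvalue = mineig),
    class = "ggm_spec"
  )
}

#' @export
print.ggm_spec <- function(x, ...) {
  ne <- sum(abs(x$target_pcor[upper.tri(x$target_pcor)]) > 0)
  cat(sprintf("ggm_spec: P=%d, K=%d, %d nonzero target edges, min precision eigenvalue %.3g\n",
              length(x$phenotype_names), x$K, ne, x$min_eigenvalue))
  invisible(x)
}

#' Draw a synthetic cohort from a GGM specification
#'
#' Draws K independent P-variate Gaussian subjects whose covariance is the
#' inverse of the precision implied by the spec's target partial correlation
#' matrix. Deterministic given `spec$seed` (or the `seed` argument, which
#' takes precedence).
#'
#' @param spec a [ggm_spec()].
#' @param seed optional seed overriding `spec$seed`.
#' @return A [phenotype_table()] with the spec's phenotype names.
#' @export
sample_ggm <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "ggm_spec"))
  seed <- seed %||% spec$seed
  Q <- -spec$target_pcor
  diag(Q) <- 1
  Sigma <- chol2inv(chol(Q))
  L <- chol(Sigma)
  P <- length(spec$phenotype_names)
  z <- with_seed(seed, matrix(stats::rnorm(spec$K * P), spec$K, P))
  x <- z %*% L
  colnames(x) <- spec$phenotype_names
  phenotype_table(as.data.frame(x), spec$phenotype_names)
}

#' Two-group specification with selected differential edges
#'
#' Builds a pair of group-specific [ggm_spec()]s from a shared base by
#' overriding selected partial correlations per group — including sign-flip
#' scenarios in which one pair has opposite conditional association in the
#' two groups while the shared structure is untouched.
#'
#' @param base a [ggm_spec()] providing the shared target matrix.
#' @param overrides_A,overrides_B data frames (or NULL) with columns `node1`,
#'   `node2`, `omega` giving the group-specific edge values.
#' @param K_A,K_B per-group subject counts (both must be positive).
#' @param seed master seed; per-group sampling seeds are derived from it.
#' @return Object of class `two_group_spec` with elements `A` and `B`
#'   (validated `ggm_spec`s) and `seed`.
#' @export
two_group_spec <- function(base, overrides_A = NULL, overrides_B = NULL,
                           K_A, K_B, seed = NULL) {
  stopifnot(inherits(base, "ggm_spec"))
  if (length(K_A) != 1L || length(K_B) != 1L || is.na(K_A) || is.na(K_B) ||
      K_A < 1 || K_B < 1)
    stop("both group sizes must be positive", call. = FALSE)
  apply_overrides <- function(om, ov) {
    if (is.null(ov) || nrow(ov) == 0L) return(om)
    stopifnot(all(c("node1", "node2", "omega") %in% names(ov)))
    for (i in seq_len(nrow(ov))) {
      a <- as.character(ov$node1[i]); b <- as.character(ov$node2[i])
      if (!all(c(a, b) %in% rownames(om)))
        stop("override names unknown: ", a, ", ", b, call. = FALSE)
      om[a, b] <- om[b, a] <- ov$omega[i]
    }
    om
  }
  specA <- ggm_spec(base$phenotype_names,
                    apply_overrides(base$target_pcor, overrides_A), K = K_A)
  specB <- ggm_spec(base$phenotype_names,
                    apply_overrides(base$target_pcor, overrides_B), K = K_B)
  structure(list(A = specA, B = specB, seed = seed), class = "two_group_spec")
}

#' Draw the two group cohorts
#'
#' Independent draws per group from the group-specific models, with per-group
#' seeds derived deterministically from the master seed.
#'
#' @param spec a [two_group_spec()].
#' @param seed optional master seed overriding `spec$seed`.
#' @return Named list of two [phenotype_table()]s (`A`, `B`) with their
#'   `group` fields set.
#' @export
sample_two_groups <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "two_group_spec"))
  seed <- seed %||% spec$seed
  seeds <- if (is.null(seed)) list(NULL, NULL) else as.list(derive_seeds(seed, 2))
  tabA <- sample_ggm(spec$A, seed = seeds[[1]])
  tabB <- sample_ggm(spec$B, seed = seeds[[2]])
  tabA$group <- "A"; tabB$group <- "B"
  list(A = tabA, B = tabB)
}

#' Append standard-Gaussian noise phenotypes
#'
#' Adds n independent standard-normal columns to a table — the
#' variable-selection robustness experiment: at moderate K and a strict edge
#' threshold the appended columns should acquire no significant edges.
#'
#' @param table a [phenotype_table()].
#' @param n number of noise columns (>= 1).
#' @param seed integer seed.
#' @param prefix name prefix for the new columns (`noise1`, `noise2`, ...).
#' @return A [phenotype_table()] with P + n phenotype columns.
#' @export
add_noise_variables <- function(table, n, seed = NULL, prefix = "noise") {
  stopifnot(inherits(table, "phenotype_table"))
  if (length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    stop("n must be a positive integer", call. = FALSE)
  K <- n_subjects(table)
  z <- with_seed(seed, matrix(stats::rnorm(K * n), K, n))
  nms <- paste0(prefix, seq_len(n))
  clash <- nms %in% names(table$data)
  if (any(clash)) {
    warning("renaming colliding noise column(s): ",
            paste(nms[clash], collapse = ", "), call. = FALSE)
    while (any(nms %in% names(table$data))) nms <- paste0(nms, "_n")
  }
  colnames(z) <- nms
  out <- table
  out$data <- cbind(table$data, as.data.frame(z))
  out$phenotypes <- c(table$phenotypes, nms)
  out
}

#' A COPD-like hub network preset
#'
#' A fixed, purely synthetic 10-phenotype specification whose nonzero partial
#' correlations form a hub-and-spoke pattern: one designated hub (`GasTrap`)
#' is connected to all nine other phenotypes, plus seven secondary edges
#' among the spokes. Magnitudes span 0.043 to 0.654 — the range reported for
#' strong clinical phenotype networks. The implied precision is positive
#' definite. Useful as a realistic recovery benchmark; it is a synthetic
#' stand-in, not an estimate from any study data.
#'
#' @param K subject count attached to the spec (default 8141, a realistic
#'   large-cohort complete-case size).
#' @param seed seed attached to the spec.
#' @return A validated [ggm_spec()]; repeated calls return identical specs.
#' @export
copd_like_preset <- function(K = 8141, seed = NULL) {
  nm <- c("FEV1pp", "Emph", "EmphDist", "GasTrap", "Pi10",
          "ExacerFreq", "SixMWD", "BMI", "Age", "PackYear")
  om <- diag(10)
  dimnames(om) <- list(nm, nm)
  set_edge <- function(a, b, v) om[a, b] <<- om[b, a] <<- v
  # hub: GasTrap connected to every other phenotype
  set_edge("Emph", "GasTrap", 0.654)
  set_edge("FEV1pp", "GasTrap", -0.353)
  set_edge("GasTrap", "Age", 0.234)
  set_edge("GasTrap", "BMI", -0.228)
  set_edge("GasTrap", "SixMWD", -0.075)
  set_edge("EmphDist", "GasTrap", -0.054)
  set_edge("GasTrap", "ExacerFreq", 0.049)
  set_edge("GasTrap", "Pi10", -0.046)
  set_edge("GasTrap", "PackYear", 0.043)
  # secondary structure among the spokes
  set_edge("FEV1pp", "Pi10", -0.320)
  set_edge("SixMWD", "BMI", -0.198)
  set_edge("Pi10", "SixMWD", -0.185)
  set_edge("Age", "PackYear", 0.183)
  set_edge("FEV1pp", "SixMWD", 0.179)
  set_edge("FEV1pp", "ExacerFreq", -0.140)
  set_edge("FEV1pp", "Emph", -0.140)
  ggm_spec(nm, om, K = K, seed = seed)
}

#' Read a GGM specification from YAML
#'
#' Schema: `phenotypes` (list of names), `K`, optional `seed`, and `edges` —
#' a list of mappings with keys `node1`, `node2`, `omega`.
#'
#' @param path path to a YAML file.
#' @return A [ggm_spec()].
#' @export
read_ggm_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$phenotypes) || is.null(cfg$K))
    stop("YAML spec needs 'phenotypes' and 'K'", call. = FALSE)
  nm <- as.character(cfg$phenotypes)
  om <- diag(length(nm))
  dimnames(om) <- list(nm, nm)
  for (e in cfg$edges) {
    a <- as.character(e$node1); b <- as.character(e$node2)
    if (!all(c(a, b) %in% nm))
      stop("edge names unknown: ", a, ", ", b, call. = FALSE)
    om[a, b] <- om[b, a] <- as.numeric(e$omega)
  }
  ggm_spec(nm, om, K = as.integer(cfg$K),
           seed = if (is.null(cfg$seed)) NULL else as.integer(cfg$seed))
}
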