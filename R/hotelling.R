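#' Hotelling null density of a sample partial correlation
#'
#' Under the null of conditional independence, a sample partial correlation
#' \eqn{\omega} estimated from \eqn{K} subjects and \eqn{P} variables follows
#' the density
#' \deqn{p(\omega \mid \kappa) = (1-\omega^2)^{(\kappa-3)/2}
#'   \frac{\Gamma(\kappa/2)}{\pi^{1/2}\,\Gamma((\kappa-1)/2)},}
#' with \eqn{\kappa = K - P + 1} degrees of freedom. Equivalently
#' \eqn{\omega^2 \sim \mathrm{Beta}(1/2, (\kappa-1)/2)}.
#'
#' @param omega numeric vector of partial correlations in `(-1, 1)`.
#' @param kappa degrees of freedom, at least 3.
#' @return Density values.
#' @seealso [hotelling_pvalue()], [degrees_of_freedom()]
#' @export
hotelling_density <- function(omega, kappa) {
  .check_kappa(kappa)
  ifelse(abs(omega) < 1,
         exp((kappa - 3) / 2 * log1p(-omega^2) +
               lgamma(kappa / 2) - 0.5 * log(pi) - lgamma((kappa - 1) / 2)),
         0)
}

.check_kappa <- function(kappa) {
  if (length(kappa) != 1L || !is.finite(kappa) || kappa < 3)
    stop("kappa must be a single value >= 3 (need K >= P + 2)", call. = FALSE)
}

#' Two-sided tail p-value under the Hotelling null
#'
#' Computes \eqn{P(|W| \ge |\omega|)} for the null density of
#' [hotelling_density()], in closed form through the regularized incomplete
#' beta function (\eqn{W^2 \sim \mathrm{Beta}(1/2,(\kappa-1)/2)}). The
#' computation is carried out on the log scale, so p-values far below the
#' double-precision underflow limit are representable via `log10 = TRUE`
#' (large cohorts yield log10 p-values of several hundred in magnitude for
#' strong edges).
#'
#' @param omega numeric vector of partial correlations; entries with
#'   `|omega| >= 1` yield p = 0 with a warning.
#' @param kappa degrees of freedom \eqn{\kappa = K - P + 1 \ge 3}.
#' @param log10 if `TRUE`, return log10 of the p-value instead.
#' @return p-values in `(0, 1]` (or their log10).
#' @export
#' @examples
#' hotelling_pvalue(0.5, kappa = 10)
#' hotelling_pvalue(0.654, kappa = 8132, log10 = TRUE)
hotelling_pvalue <- function(omega, kappa, log10 = FALSE) {
  .check_kappa(kappa)
  if (any(abs(omega) >= 1, na.rm = TRUE))
    warning("|omega| >= 1: p-value is exactly 0", call. = FALSE)
  lp <- stats::pbeta(omega^2, shape1 = 0.5, shape2 = (kappa - 1) / 2,
                     lower.tail = FALSE, log.p = TRUE)
  lp[abs(omega) >= 1] <- -Inf
  if (log10) lp / log(10) else exp(lp)
}

#' Degrees of freedom of the partial-correlation null
#'
#' @param K number of subjects.
#' @param P number of phenotype variables.
#' @return \eqn{\kappa = K - P + 1}; errors unless `K >= P + 2` (so that
#'   \eqn{\kappa \ge 3} and the null density is proper).
#' @export
#' @examples
#' degrees_of_freedom(8141, 10)  # 8132
degrees_of_freedom <- function(K, P) {
  if (K <= P + 1)
    stop("need K >= P + 2 subjects to fit a network (K = ", K, ", P = ", P, ")",
         call. = FALSE)
  as.integer(K - P + 1)
}
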