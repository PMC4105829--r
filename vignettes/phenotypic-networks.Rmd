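---
title: "Partial-correlation networks of quantitative phenotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial-correlation networks of quantitative phenotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenonet)
```

## The model

Complex diseases are characterized by panels of quantitative phenotypes —
lung function, imaging measures, exercise capacity, body composition,
exposure history — that are correlated with one another in ways that
pairwise analyses cannot disentangle. phenonet models a panel of $P$
phenotypes measured on $K$ subjects as a multivariate Gaussian vector
$Y_i \sim N_P(\mu, \Sigma)$ and summarizes its conditional dependence
structure by the partial correlation matrix $\Omega$. With
$Q = R^{-1}$ the precision of the correlation matrix $R$,

$$\omega_{jk} = -\,\frac{q_{jk}}{\sqrt{q_{jj}\,q_{kk}}},$$

the correlation between phenotypes $j$ and $k$ *given all other
phenotypes*. Under Gaussianity $\omega_{jk} = 0$ exactly when $j$ and $k$
are conditionally independent, so the graph with an edge for every nonzero
$\omega_{jk}$ is a Gaussian graphical model: a map of direct phenotype
relationships with the indirect, pathway-mediated correlation stripped out.
Marginal and partial correlations can disagree in sign — a phenomenon the
package is specifically designed to expose (see the multi-group comparison
below).

## Estimation

Columns are standardized and the sample correlation matrix is shrunk toward
the identity,

$$R^\* = \lambda I + (1-\lambda) R,$$

with intensity chosen analytically by the variance-of-entries rule
$\hat\lambda = \sum_{j<k}\widehat{\mathrm{Var}}(r_{jk}) \big/ \sum_{j<k}
r_{jk}^2$, clipped to $[0,1]$. The entry variances are estimated from the
per-subject products of standardized scores. This guarantees a positive
definite estimate for any $K \ge P+2$; with thousands of subjects and a
well-connected panel $\hat\lambda$ is a fraction of a percent and $R^\*$
is essentially the sample correlation.

Two properties of the rule are worth knowing:

* When the data carry no correlation signal relative to sampling noise
  (small $K$, weak structure), $\hat\lambda$ can reach 1, in which case
  $\Omega = I$: the estimator is declaring the panel indistinguishable from
  independence. This is a feature, not a failure mode.
* `lambda = 0` reproduces the plain sample-correlation fit, under which the
  edge test below is exact. All calibration checks in the test suite pin
  `lambda = 0` for this reason; the default `lambda = NULL` (auto) is the
  practical choice for real panels.

## Edge significance

Under the null of conditional independence a sample partial correlation
estimated with $\kappa = K - P + 1$ degrees of freedom follows the density

$$p(\omega \mid \kappa) = (1-\omega^2)^{(\kappa-3)/2}\,
\frac{\Gamma(\kappa/2)}{\pi^{1/2}\,\Gamma\!\big((\kappa-1)/2\big)},$$

equivalently $\omega^2 \sim \mathrm{Beta}\!\big(\tfrac12,
\tfrac{\kappa-1}{2}\big)$. `hotelling_pvalue()` computes the two-sided tail
mass in closed form through the regularized incomplete beta function, on
the log scale, so that the astronomically small p-values produced by strong
edges in large cohorts (log10 p-values of −200 and beyond) remain exactly
representable; edge tables carry a `log10_pvalue` column alongside the
(possibly underflowed) `pvalue`. The test suite verifies the closed form
against adaptive quadrature of the density to $10^{-10}$ and checks that
null edge p-values are uniform by simulation.

Significance thresholds are raw by convention — $\alpha = 0.001$ for a
single-population network, $\alpha = 0.05$ for group-specific networks —
with an optional Bonferroni flag in `fit_network()`. $\kappa \ge 3$
(equivalently $K \ge P + 2$) is enforced everywhere so the null density is
proper. The null is applied to the shrunk estimate exactly as fitted; since
shrinkage biases $|\omega|$ downward, auto-shrinkage makes the test mildly
conservative, and `lambda = 0` is available when exactness matters.

## Network summaries

Density is the percentage of the $P(P-1)/2$ possible pairs realized as
edges, printed to two decimals (29 of 45 pairs is 64.44%). Degree ranking
flags hub phenotypes (ties broken lexicographically). For every pair
*without* an edge, `transitive_nodes()` reports the set of intermediates
completing a length-2 shortest path; per-node tallies count pairs, and a
pair with several connectors credits each of them (a documented choice —
users wanting unique-connector counts can filter on `n_connectors == 1`).
Pairs at distance greater than 2 are reported separately rather than folded
into hub counts.

## Comparing group networks

Subject groups are defined by first-match-wins predicate rules
(`group_spec()`), which directly encodes designs that drop subjects
matching no definition — e.g. genotype analyses restricted to the two
homozygous classes, or case/control definitions that exclude intermediate
spirometry. `permutation_diff_test()` then tests each pair for differential
connectivity:

* the statistic is the signed difference
  $\Delta_{jk} = \omega^A_{jk} - \omega^B_{jk}$, two-sided, so both
  magnitude changes and sign flips register;
* group labels are reshuffled over the pooled subjects with group sizes
  held fixed, and the partial correlations are recomputed per shuffled
  group under the same shrinkage policy as the observed fit (statistic and
  null must match);
* the empirical p-value carries the +1 correction,
  $p = (1 + \#\{|\Delta^{perm}| \ge |\Delta^{obs}|\})/(B+1)$, so it is
  valid and bounded below by the resolution floor $1/(B+1)$. The default
  $B = 10{,}000$ resolves $10^{-4}$; desk-scale checks use smaller $B$.

Each pair is also classified against per-group Hotelling significance at a
chosen $\alpha$: `concordant` (significant in both groups, same sign),
`sign_discordant` (both, opposite signs), `A_only`/`B_only`, `absent` —
the green/red/black classes of two-group network figures.
`partial_residuals()` exposes the per-subject scatter behind any single
partial correlation (its correlation equals the `lambda = 0` estimate, an
identity the tests verify to $10^{-8}$), and `multi_group_compare()` prints
marginal Pearson and partial correlations side by side across ordered
groups, the layout in which partial-vs-marginal sign divergence becomes
visible.

## Edge directionality

The standardized partial variance of a node,
$\mathrm{spv}_j = 1 - R^2_j = 1/q_{jj}$, is the fraction of its variance
unexplained by all other phenotypes; it is unit-free because it is computed
on the correlation scale. For each significant edge the antisymmetric
log-ratio $r_{jk} = \log(\mathrm{spv}_j/\mathrm{spv}_k)$ orients the edge
from the less-explained node toward the better-explained node when
$|r_{jk}|$ exceeds a threshold; otherwise the edge stays undirected, so the
partially directed graph always has the topology of the undirected network.

No principled universal threshold exists, so the rule is deliberately
transparent and tunable: the default `log(1.25)` (≈0.223) requires one SPV
to exceed the other by 25%, appropriate for strongly coupled panels;
weakly coupled systems produce genuine orientation signal at much smaller
log-ratios (the collider demonstration below uses 0.03), and the threshold
is exposed everywhere, including the CLI.

What the heuristic can and cannot do:

* it reliably identifies *sink* patterns — a node well explained by many
  neighbors, such as a hub phenotype or the child of a collider
  ($Z = \sum_i X_i + \varepsilon$), collects incoming edges — and *source*
  patterns — an exogenous root retains SPV near 1;
* it does **not** recover chain order. For a causal chain
  $X_1 \to X_2 \to X_3$ the interior node is explained by both neighbors
  and provably has the *smallest* SPV of the three
  ($\mathrm{spv}_2 = (1-\rho_1^2)(1-\rho_2^2)/(1-\rho_1^2\rho_2^2)$), so
  the downstream edge orients back into the middle. Orientation output
  should be read as "direct influence flows toward well-explained
  phenotypes", not as causal discovery; the package deliberately does not
  implement constraint-based causal search, and the partially directed
  graph is not constrained to be acyclic.

A related structural fact governs collider simulations: conditioning on a
common child induces a partial correlation of $-1/(1+\sigma^2)$ between
independent parents (noise variance $\sigma^2$). A strong three-node
collider therefore *must* show a parent–parent edge; only a weakly coupled,
many-parent design keeps parent pairs below an $\alpha = 0.001$ edge
threshold while preserving a clean orientation margin. The package's
collider benchmark uses 8 parents, $\sigma^2 = 120$ and $K = 5000$, chosen
from this closed-form analysis.

## Synthetic cohorts

The generators exist so that every statistical claim above is testable
without subject-level study data (which, for the motivating cohorts, is not
public).

* `ggm_spec()` maps a target $\Omega$ to a precision matrix with unit
  diagonal and $q_{jk} = -\omega_{jk}$, validates positive definiteness
  (reporting the offending eigenvalue otherwise — specs are rejected, never
  silently repaired), and `sample_ggm()` draws $K$ subjects with covariance
  $Q^{-1}$ via its Cholesky factor. Fitted partial correlations converge to
  the targets (max error < 0.03 at $K = 20{,}000$ in the tests).
* Marginals are standard Gaussian; since $\Omega$ is invariant to affine
  rescaling of columns, realistic units can be layered on without touching
  the dependence structure.
* Seeding: one master seed; per-group seeds are derived from it. Seeded
  helpers restore the caller's RNG stream. Use *different* seeds for a
  cohort and for `add_noise_variables()` on that cohort — reusing one seed
  replays the same normal deviates and the "noise" duplicates the data.
* `copd_like_preset()` is a fixed synthetic 10-phenotype benchmark: a hub
  (`GasTrap`) connected to all nine other nodes plus seven secondary
  edges, magnitudes 0.043–0.654 — the range observed in strong clinical
  phenotype networks, with realistic clinical variable names. At
  $K = 8141$ the hub is recovered as the top-degree node and every planted
  edge with $|\omega| \ge 0.15$ is significant at $p < 0.001$.
* The three-group sign-flip scenario plants $\omega_{xy} \in
  \{+0.07, 0.008, -0.07\}$ on top of a shared driver ($\omega_{xz} = +0.5$,
  $\omega_{yz} = -0.5$), which keeps the *marginal* correlation of $(x,y)$
  negative (about $-0.24$, $-0.32$, $-0.43$) while the partial correlation
  crosses zero — the canonical demonstration that conditioning can reverse
  an epidemiological association.

## Numerical choices and problem sizes

Inversions go through Cholesky factorization (`chol`/`chol2inv`), with
non-positive-definite input reported as an instruction to shrink. Edge
tables are ordered by ascending p-value with ties broken by descending
$|\omega|$ then node pair, using `log10_pvalue` so underflowed ties order
correctly. Missing-value tokens in delimited input: empty string, `NA`,
`NaN`, `N/A`, `NULL`, `.` (case-insensitive); unparsable cells become
missing with a logged count. Complete-case filtering is the only missing
data policy — imputation is out of scope by design.

The simulation sizes used by the test suite and the acceptance script were
chosen to make each check decisive at desk scale: 200 independent cohorts
($K = 500$, $P = 10$) for p-value uniformity; 20 two-group studies with
$B = 1000$ permutations for the level of the permutation test; $K = 8141$
for preset recovery; 100 runs of the noise-variable experiment at
$K = 2000$; 100 random instances for the regression-residual oracle
identity.

## Limitations

The model assumes approximately Gaussian quantitative phenotypes; heavily
skewed variables should be transformed upstream (no transformation is
applied by default, since several standard clinical variables are already
ratios or log-ratios by construction). Edges are thresholded, not weighted;
the choice of $\alpha$ is conventional. The Hotelling null applied to
auto-shrunk estimates is mildly conservative. The directionality heuristic
is a screening device, not causal inference. Categorical phenotypes are
supported only as grouping variables, not as network nodes.
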