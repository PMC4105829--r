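write_csv_fixture <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

test_that("delimited input is parsed with missing-token handling", {
  f <- write_csv_fixture(c("id,a,b,c,status",
                           "s1,1,2.5,3,case",
                           "s2,2,3.5,4,control",
                           "s3,3,4.5,5,case",
                           "s4,4,5.5,6,control",
                           "s5,5,6.5,7,case"))
  pt <- read_phenotype_table(f, c("a", "b", "c"), quiet = TRUE)
  expect_s3_class(pt, "phenotype_table")
  expect_equal(n_subjects(pt), 5)
  expect_equal(n_phenotypes(pt), 3)
  expect_equal(pheno_values(pt)[, "b"], c(2.5, 3.5, 4.5, 5.5, 6.5))

  f2 <- write_csv_fixture(c("a,b", "1,NA", "2,nan", "3,", "4,5", "x,6"))
  suppressMessages(pt2 <- read_phenotype_table(f2, c("a", "b")))
  expect_equal(n_subjects(pt2), 5)  # K unchanged before filtering
  expect_equal(sum(is.na(pheno_values(pt2))), 4)  # 3 tokens + 1 unparsable "x"

  expect_error(read_phenotype_table(f, c("a", "zzz"), quiet = TRUE),
               "absent from header")
  f3 <- write_csv_fixture("a,b")
  expect_error(read_phenotype_table(f3, c("a"), quiet = TRUE), "zero data rows")
})

test_that("complete-case filtering drops exactly the incomplete subjects", {
  x <- matrix(rnorm(30), 10, 3)
  x[2, 1] <- NA; x[7, 3] <- NA
  pt <- make_table(x)
  flt <- complete_case_filter(pt, quiet = TRUE)
  expect_equal(n_subjects(flt), 8)
  expect_equal(attr(flt, "n_excluded"), 2)
  # order preserved
  expect_equal(pheno_values(flt)[, 1], x[-c(2, 7), 1])

  clean <- make_table(matrix(rnorm(30), 10, 3))
  expect_identical(pheno_values(complete_case_filter(clean, quiet = TRUE)),
                   pheno_values(clean))
  # idempotent
  expect_identical(pheno_values(complete_case_filter(flt, quiet = TRUE)),
                   pheno_values(flt))

  allna <- make_table(matrix(NA_real_, 4, 2))
  expect_error(complete_case_filter(allna, quiet = TRUE), "all subjects")
})

test_that("filtering a large table matches a brute-force row scan", {
  set.seed(42)
  K <- 1500
  x <- matrix(rnorm(K * 10), K, 10)
  miss <- cbind(sample.int(K, 120), sample.int(10, 120, replace = TRUE))
  x[miss] <- NA
  expected <- sum(apply(x, 1, function(r) !anyNA(r)))  # independent scan
  flt <- complete_case_filter(make_table(x), quiet = TRUE)
  expect_equal(n_subjects(flt), expected)
  expect_false(anyNA(pheno_values(flt)))
})

test_that("stratification is first-match-wins and partitions matched subjects", {
  set.seed(7)
  df <- data.frame(a = rnorm(60), b = rnorm(60),
                   genotype = sample(0:2, 60, replace = TRUE))
  pt <- phenotype_table(df, c("a", "b"))
  gs <- group_spec(c(risk = "genotype == 2", nonrisk = "genotype == 0"))
  grp <- suppressMessages(stratify(pt, gs))
  expect_named(grp, c("risk", "nonrisk"))
  expect_equal(n_subjects(grp$risk), sum(df$genotype == 2))
  expect_equal(n_subjects(grp$nonrisk), sum(df$genotype == 0))
  # heterozygotes dropped; groups disjoint and sizes sum to matched count
  expect_equal(n_subjects(grp$risk) + n_subjects(grp$nonrisk),
               sum(df$genotype != 1))
  expect_equal(grp$risk$group, "risk")

  all_rule <- group_spec(c(everyone = "a > -Inf"))
  expect_equal(n_subjects(suppressMessages(stratify(pt, all_rule))$everyone), 60)

  # first-match-wins: overlapping rules never double-assign
  overlap <- group_spec(c(g1 = "genotype >= 1", g2 = "genotype == 2"))
  grp2 <- suppressWarnings(suppressMessages(stratify(pt, overlap)))
  expect_equal(n_subjects(grp2$g1), sum(df$genotype >= 1))
  expect_false("g2" %in% names(grp2))
})

test_that("spirometry-style threshold rules match brute-force predicate counts", {
  set.seed(11)
  df <- data.frame(FEV1pp = runif(100, 20, 130), ratio = runif(100, 0.3, 0.95),
                   x = rnorm(100))
  pt <- phenotype_table(df, "x")
  gs <- group_spec(c(case = "FEV1pp < 80 & ratio < 0.7",
                     control = "FEV1pp >= 80 & ratio >= 0.7"))
  grp <- suppressMessages(stratify(pt, gs))
  expect_equal(n_subjects(grp$case), sum(df$FEV1pp < 80 & df$ratio < 0.7))
  expect_equal(n_subjects(grp$control), sum(df$FEV1pp >= 80 & df$ratio >= 0.7))

  empty <- group_spec(c(none = "FEV1pp > 1000", rest = "TRUE"))
  expect_warning(suppressMessages(stratify(pt, empty)), "matched no subjects")
})

test_that("edge tables round-trip through TSV", {
  net <- edges_network(letters[1:5],
                       cbind(c(1, 1, 2), c(2, 3, 4)),
                       pcor = c(0.61234, -0.25431, 0.11111),
                       pvalue = c(1e-8, 2e-4, 9e-3))
  f <- tempfile(fileext = ".tsv")
  write_edge_table(net, f)
  back <- read_edge_table(f)
  expect_equal(nrow(back), 3)
  expect_equal(back$pcor, net$edges$pcor, tolerance = 1e-12)
  expect_equal(back$pvalue, sort(back$pvalue))  # sorted ascending

  empty <- phenotype_network(letters[1:3], NULL)
  f2 <- tempfile(fileext = ".tsv")
  write_edge_table(empty, f2)
  expect_length(readLines(f2), 1)  # header only
})

test_that("graph export produces valid GraphML and DOT", {
  set.seed(3)
  nodes <- paste0("p", 1:10)
  pairs <- t(combn(10, 2))[sample(45, 29), ]
  net <- edges_network(nodes, pairs)
  f <- tempfile(fileext = ".graphml")
  export_graph(net, f, "graphml")
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), 10)
  expect_equal(igraph::ecount(g), 29)
  # attribute round trip
  expect_setequal(round(igraph::E(g)$pcor, 10), round(net$edges$pcor, 10))

  # partially directed export distinguishes edge styles
  tab <- sample_ggm(random_spec(5, 400, seed = 5))
  res <- fit_network(tab, alpha = 0.9)
  dn <- orient_edges(res$fit, res$network, min_abs_log_ratio = 0)
  f2 <- tempfile(fileext = ".dot")
  export_graph(dn, f2, "dot")
  expect_true(any(grepl("->", readLines(f2), fixed = TRUE)))

  empty <- phenotype_network(c("a", "b"), NULL)
  f3 <- tempfile(fileext = ".graphml")
  export_graph(empty, f3, "graphml")
  g3 <- igraph::read_graph(f3, format = "graphml")
  expect_equal(igraph::vcount(g3), 2)
  expect_equal(igraph::ecount(g3), 0)

  expect_error(export_graph(net, tempfile(), "gexf"), "unknown graph format")
})

test_that("YAML group and cohort specifications load from shipped examples", {
  gs <- read_group_spec(system.file("extdata", "copd_groups.yaml",
                                    package = "phenonet"))
  expect_named(gs$rules, c("case", "control"))
  expect_true(gs$drop_unmatched)
  set.seed(21)
  df <- data.frame(FEV1pp = runif(50, 30, 120), fev1_fvc = runif(50, 0.4, 0.9),
                   x = rnorm(50), y = rnorm(50))
  grp <- suppressMessages(suppressWarnings(
    stratify(phenotype_table(df, c("x", "y")), gs)))
  expect_equal(n_subjects(grp$case), sum(df$FEV1pp < 80 & df$fev1_fvc < 0.7))

  spec <- read_ggm_spec(system.file("extdata", "example_spec.yaml",
                                    package = "phenonet"))
  expect_s3_class(spec, "ggm_spec")
  expect_equal(spec$target_pcor["hub", "s1"], 0.45)
  expect_equal(spec$K, 2000L)
  expect_equal(n_subjects(sample_ggm(spec)), 2000)
})

test_that("the command-line interface runs simulate and build end to end", {
  cli <- system.file("cli", "phenonet.R", package = "phenonet")
  rscript <- file.path(R.home("bin"), "Rscript")
  libs <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  csv <- tempfile(fileext = ".csv")
  edges <- tempfile(fileext = ".tsv")
  spec <- system.file("extdata", "example_spec.yaml", package = "phenonet")
  o1 <- suppressWarnings(system2(rscript, c(cli, "simulate", "--spec", spec,
                                            "--out", csv, "--seed", "3"),
                                 stdout = TRUE, stderr = TRUE, env = libs))
  expect_true(file.exists(csv))
  o2 <- suppressWarnings(system2(rscript, c(cli, "build", "--input", csv,
                                            "--phenotypes", "hub,s1,s2,s3",
                                            "--alpha", "0.001",
                                            "--out-edges", edges),
                                 stdout = TRUE, stderr = TRUE, env = libs))
  expect_true(file.exists(edges))
  e <- read_edge_table(edges)
  expect_gte(nrow(e), 4)  # the four planted edges are all strong
  expect_true(all(c("node1", "node2", "pcor", "pvalue") %in% names(e)))
})
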