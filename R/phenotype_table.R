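#' Phenotype table
#'
#' Container for a subjects-by-phenotypes data set: a data frame holding the
#' quantitative phenotype columns (plus any auxiliary columns such as subject
#' identifiers, case/control status or genotypes used for grouping) together
#' with the names of the phenotype columns entering network analysis.
#'
#' @param data data frame; phenotype columns are coerced to numeric.
#' @param phenotypes character vector of phenotype column names (unique, all
#'   present in `data`).
#' @param subject_col optional name of a subject-identifier column.
#' @param group optional single label recording which subject group this table
#'   represents (set by [stratify()]).
#'
#' @return An object of class `phenotype_table` with elements `data`,
#'   `phenotypes`, `subject_col`, `group`.
#' @seealso [read_phenotype_table()], [complete_case_filter()], [stratify()]
#' @export
#' @examples
#' pt <- phenotype_table(data.frame(a = rnorm(20), b = rnorm(20)), c("a", "b"))
#' n_subjects(pt)
phenotype_table <- function(data, phenotypes, subject_col = NULL, group = NULL) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) stop("phenotype table has zero data rows", call. = FALSE)
  if (anyDuplicated(phenotypes))
    stop("phenotype names must be unique", call. = FALSE)
  missing_cols <- setdiff(phenotypes, names(data))
  if (length(missing_cols))
    stop("phenotype column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!is.null(subject_col) && !subject_col %in% names(data))
    stop("subject column not found: ", subject_col, call. = FALSE)
  for (p in phenotypes) data[[p]] <- as.numeric(data[[p]])
  structure(
    list(data = data, phenotypes = phenotypes,
         subject_col = subject_col, group = group),
    class = "phenotype_table"
  )
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d subjects x %d phenotypes\n",
              n_subjects(x), n_phenotypes(x)))
  cat("  phenotypes:", paste(x$phenotypes, collapse = ", "), "\n")
  if (!is.null(x$group)) cat("  group:", x$group, "\n")
  nmiss <- sum(is.na(pheno_values(x)))
  if (nmiss > 0) cat("  missing phenotype cells:", nmiss, "\n")
  invisible(x)
}

#' @rdname phenotype_table
#' @param x a `phenotype_table`.
#' @export
n_subjects <- function(x) nrow(x$data)

#' @rdname phenotype_table
#' @export
n_phenotypes <- function(x) length(x$phenotypes)

#' Extract the numeric K x P phenotype matrix
#' @param x a `phenotype_table`.
#' @return numeric matrix with phenotype names as columns.
#' @export
pheno_values <- function(x) {
  m <- as.matrix(x$data[x$phenotypes])
  storage.mode(m) <- "double"
  m
}

# Missing-value tokens recognized in delimited input (case-insensitive),
# matching common dialects of clinical CSV exports.
.missing_tokens <- c("", "na", "nan", "n/a", "null", ".")

#' Read a phenotype table from delimited text
#'
#' Reads a CSV/TSV file with a header row, parses the named phenotype columns
#' as numeric (non-parsable cells and the tokens `""`, `"NA"`, `"NaN"`,
#' `"N/A"`, `"NULL"`, `"."` — case-insensitive — become missing) and reports
#' row and per-column missingness counts.
#'
#' @param path path to a delimited text file with a header row.
#' @param phenotype_columns character vector of phenotype column names.
#' @param group_columns optional character vector of additional columns that
#'   must be present (grouping variables such as status or genotype).
#' @param sep field separator; defaults to `"\t"` for `.tsv`/`.txt` files and
#'   `","` otherwise.
#' @param quiet suppress the parsing log.
#' @return A [phenotype_table()].
#' @export
read_phenotype_table <- function(path, phenotype_columns, group_columns = NULL,
                                 sep = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"")
  if (nrow(raw) == 0L) stop("input file has zero data rows: ", path, call. = FALSE)
  need <- c(phenotype_columns, group_columns)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("requested column(s) absent from header: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (p in phenotype_columns) {
    cell <- trimws(raw[[p]])
    cell[tolower(cell) %in% .missing_tokens] <- NA_character_
    num <- suppressWarnings(as.numeric(cell))
    n_bad <- sum(!is.na(cell) & is.na(num))
    if (n_bad > 0 && !quiet)
      message(sprintf("column '%s': %d non-numeric cell(s) set to missing", p, n_bad))
    raw[[p]] <- num
  }
  pt <- phenotype_table(raw, phenotype_columns)
  if (!quiet) {
    nmiss <- colSums(is.na(pheno_values(pt)))
    message(sprintf("read %d subjects, %d phenotypes (%d cells missing)",
                    n_subjects(pt), n_phenotypes(pt), sum(nmiss)))
  }
  pt
}

#' Complete-case filtering
#'
#' Drops every subject with a missing value in any phenotype column, keeping
#' subject order. The number of excluded subjects is recorded in the
#' `n_excluded` attribute and reported.
#'
#' @param table a [phenotype_table()].
#' @param quiet suppress the exclusion report.
#' @return The filtered `phenotype_table` (idempotent).
#' @export
complete_case_filter <- function(table, quiet = FALSE) {
  stopifnot(inherits(table, "phenotype_table"))
  keep <- stats::complete.cases(pheno_values(table))
  n_excluded <- sum(!keep)
  if (all(!keep))
    stop("complete-case filtering excluded all subjects", call. = FALSE)
  out <- table
  out$data <- table$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  attr(out, "n_excluded") <- n_excluded
  if (!quiet && n_excluded > 0)
    message(sprintf("excluded %d subject(s) with missing phenotypes; %d retained",
                    n_excluded, sum(keep)))
  out
}

#' Group specification
#'
#' An ordered set of named rules partitioning subjects into groups. Each rule
#' is an R expression (given as a string) over columns of the table, e.g.
#' `"FEV1pp < 80 & ratio < 0.7"` or `"genotype == 2"`. Rules are applied
#' first-match-wins: a subject belongs to the first group whose predicate is
#' `TRUE`. Subjects matching no rule are dropped when `drop_unmatched` (the
#' default, mirroring designs that exclude heterozygotes or subjects meeting
#' neither the case nor the control definition).
#'
#' @param rules named list or named character vector of predicate expressions;
#'   names are the group names (unique).
#' @param drop_unmatched drop subjects matching no rule (`TRUE`) or collect
#'   them in a group `"unmatched"` (`FALSE`).
#' @return An object of class `group_spec`.
#' @export
#' @examples
#' gs <- group_spec(c(risk = "genotype == 2", nonrisk = "genotype == 0"))
group_spec <- function(rules, drop_unmatched = TRUE) {
  rules <- as.list(rules)
  if (length(rules) == 0L) stop("group_spec needs at least one rule", call. = FALSE)
  if (is.null(names(rules)) || any(names(rules) == "") ||
      anyDuplicated(names(rules)))
    stop("group rules must have unique non-empty names", call. = FALSE)
  if (!all(vapply(rules, is.character, logical(1))))
    stop("each rule must be a character predicate expression", call. = FALSE)
  structure(list(rules = rules, drop_unmatched = isTRUE(drop_unmatched)),
            class = "group_spec")
}

#' Read a group specification from YAML
#'
#' Expects a mapping with a `groups` key (mapping of group name to predicate
#' string) and an optional logical `drop_unmatched` key.
#'
#' @param path path to a YAML file.
#' @return A [group_spec()].
#' @export
read_group_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$groups)) stop("YAML group spec needs a 'groups' mapping", call. = FALSE)
  group_spec(lapply(cfg$groups, as.character),
             drop_unmatched = if (is.null(cfg$drop_unmatched)) TRUE
                              else isTRUE(cfg$drop_unmatched))
}

#' Stratify subjects into groups
#'
#' Partitions a phenotype table by the first-matching rule of a
#' [group_spec()]. Predicates evaluating to `NA` count as non-matching. Empty
#' groups are omitted with a warning.
#'
#' @param table a [phenotype_table()].
#' @param spec a [group_spec()].
#' @param quiet suppress the per-group size report.
#' @return Named list of `phenotype_table` objects, one per non-empty group,
#'   each with its `group` field set.
#' @export
stratify <- function(table, spec, quiet = FALSE) {
  stopifnot(inherits(table, "phenotype_table"), inherits(spec, "group_spec"))
  K <- n_subjects(table)
  assigned <- rep(NA_character_, K)
  for (g in names(spec$rules)) {
    hit <- eval(parse(text = spec$rules[[g]]), envir = table$data,
                enclos = baseenv())
    if (!is.logical(hit) || !(length(hit) %in% c(1L, K)))
      stop("rule '", g, "' did not evaluate to a per-subject logical", call. = FALSE)
    hit <- rep_len(hit, K)
    hit[is.na(hit)] <- FALSE
    assigned[is.na(assigned) & hit] <- g
  }
  if (!spec$drop_unmatched) assigned[is.na(assigned)] <- "unmatched"
  out <- list()
  for (g in unique(stats::na.omit(c(names(spec$rules),
                                    if (!spec$drop_unmatched) "unmatched")))) {
    idx <- which(!is.na(assigned) & assigned == g)
    if (length(idx) == 0L) {
      warning("group '", g, "' matched no subjects; omitted", call. = FALSE)
      next
    }
    sub <- table
    sub$data <- table$data[idx, , drop = FALSE]
    rownames(sub$data) <- NULL
    sub$group <- g
    out[[g]] <- sub
  }
  if (!quiet)
    message(paste(sprintf("group %s: K=%d", names(out),
                          vapply(out, n_subjects, integer(1))),
                  collapse = "; "))
  out
}
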