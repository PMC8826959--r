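#' Construct a gene-by-population mutation count matrix
#'
#' The central data container: nonnegative integer counts of (typically
#' nonsynonymous) de novo mutations, one row per gene and one column per
#' replicate population, together with a population-to-treatment map.
#'
#' @param counts integer matrix, genes in rows and populations in columns.
#'   Must carry unique row and column names (gene and population ids) or they
#'   may be supplied via `gene_ids` / `population_ids`.
#' @param treatments named character vector mapping population id to treatment
#'   label; populations absent from the map get treatment `"default"`.
#' @param gene_ids,population_ids optional label vectors overriding dimnames.
#'
#' @return an object of class `count_matrix`: a list with elements `counts`
#'   (named integer matrix), `treatments` (named character vector, one entry
#'   per population).
#' @export
mutation_count_matrix <- function(counts, treatments = NULL,
                                  gene_ids = NULL, population_ids = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(gene_ids)) rownames(counts) <- gene_ids
  if (!is.null(population_ids)) colnames(counts) <- population_ids
  if (nrow(counts) == 0L) {
    stop_pardiv("no genes: count matrix has zero rows", class = "pardiv_validation")
  }
  if (ncol(counts) == 0L) {
    stop_pardiv("no populations: count matrix has zero columns",
                class = "pardiv_validation")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_pardiv("count matrix needs gene and population ids",
                class = "pardiv_validation")
  }
  if (anyDuplicated(rownames(counts))) {
    stop_pardiv("duplicate gene id: %s",
                paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                      collapse = ", "),
                class = "pardiv_validation")
  }
  if (anyDuplicated(colnames(counts))) {
    stop_pardiv("duplicate population id: %s",
                paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                      collapse = ", "),
                class = "pardiv_validation")
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
                 arr.ind = TRUE)[1, , drop = TRUE]
    stop_pardiv("invalid count at gene '%s', population '%s': must be a nonnegative integer",
                rownames(counts)[bad[1]], colnames(counts)[bad[2]],
                class = "pardiv_parse")
  }
  storage.mode(counts) <- "integer"
  tr <- rep("default", ncol(counts))
  names(tr) <- colnames(counts)
  if (!is.null(treatments)) {
    treatments <- vapply(treatments, as.character, character(1))
    hit <- intersect(names(treatments), names(tr))
    tr[hit] <- treatments[hit]
  }
  structure(list(counts = counts, treatments = tr), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("Mutation count matrix: %d genes x %d populations\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("Treatments: %s\n",
              paste(sprintf("%s (n=%d)", names(table(x$treatments)),
                            as.integer(table(x$treatments))), collapse = ", ")))
  cat(sprintf("Total mutations: %d; nonzero entries: %.1f%%\n",
              sum(x$counts), 100 * mean(x$counts > 0)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Per-population total mutation counts
#' @param x a `count_matrix`
#' @return named integer vector of column sums
#' @export
population_totals <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  cs <- colSums(x$counts)
  structure(as.integer(cs), names = names(cs))
}

#' Read a gene-by-population count matrix from TSV
#'
#' Expects a UTF-8 TSV with header row of population ids, first column of gene
#' ids (header cell `gene_id`), and nonnegative integer cells. Lines starting
#' with `#` are metadata and skipped.
#'
#' @param path path to the count TSV
#' @param treatment_map_path optional two-column TSV (population_id, treatment)
#' @return a [mutation_count_matrix()] object
#' @export
read_count_matrix <- function(path, treatment_map_path = NULL) {
  df <- read_tsv_plain(path, colClasses = "character")
  if (ncol(df) < 2L) {
    stop_pardiv("count matrix needs a gene_id column plus at least one population",
                class = "pardiv_parse")
  }
  if (nrow(df) == 0L) {
    stop_pardiv("no genes: count matrix '%s' has a header but no rows", path,
                class = "pardiv_validation")
  }
  gene_ids <- df[[1]]
  pops <- colnames(df)[-1]
  cells <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_pardiv("malformed count '%s' at gene '%s', population '%s'",
                cells[bad[1, 1], bad[1, 2]], gene_ids[bad[1, 1]], pops[bad[1, 2]],
                class = "pardiv_parse")
  }
  treatments <- NULL
  if (!is.null(treatment_map_path)) {
    treatments <- read_treatment_map(treatment_map_path)
  }
  mutation_count_matrix(num, treatments = treatments,
                        gene_ids = gene_ids, population_ids = pops)
}

#' Read a population-to-treatment map from TSV
#' @param path two-column TSV with columns population_id, treatment
#' @return named character vector (treatment labels named by population id)
#' @export
read_treatment_map <- function(path) {
  df <- read_tsv_plain(path, colClasses = "character")
  need <- c("population_id", "treatment")
  if (!all(need %in% colnames(df))) {
    stop_pardiv("treatment map must have columns: %s", paste(need, collapse = ", "),
                class = "pardiv_schema")
  }
  if (anyDuplicated(df$population_id)) {
    stop_pardiv("duplicate population id in treatment map",
                class = "pardiv_validation")
  }
  stats::setNames(df$treatment, df$population_id)
}

#' Write a count matrix (and optionally its treatment map) to TSV
#' @param x a `count_matrix`
#' @param path output TSV path
#' @param treatment_map_path optional path for the population/treatment TSV
#' @param params named list folded into the commented metadata header
#' @return `path`, invisibly
#' @export
write_count_matrix <- function(x, path, treatment_map_path = NULL,
                               params = list()) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, params)
  if (!is.null(treatment_map_path)) {
    tm <- data.frame(population_id = names(x$treatments),
                     treatment = unname(x$treatments))
    write_tsv_with_header(tm, treatment_map_path, params)
  }
  invisible(path)
}

#' Collapse replicate populations into per-treatment totals, one pair at a time
#'
#' The degree of parallel evolution within each environment is quantified by
#' summing mutation counts across that environment's replicate populations;
#' divergence statistics then compare these per-gene treatment totals pairwise.
#'
#' @param x a `count_matrix` with at least two distinct treatment labels
#' @return a named list of `treatment_pair` objects, one per unordered pair of
#'   treatments, each holding per-gene summed counts (`n_1`, `n_2`), the
#'   treatment-wide totals, and the two labels. Names are `"A|B"`.
#' @export
collapse_by_treatment <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  labs <- sort(unique(x$treatments))
  if (length(labs) < 2L) {
    stop_pardiv(paste0("only one treatment label ('%s'): between-environment ",
                       "divergence needs >= 2 treatments; use the occupancy/",
                       "parallelism functions for single-environment data"),
                labs[1], class = "pardiv_validation")
  }
  sums <- vapply(labs, function(l) {
    cols <- names(x$treatments)[x$treatments == l]
    rowSums(x$counts[, cols, drop = FALSE])
  }, numeric(nrow(x$counts)))
  if (is.null(dim(sums))) sums <- matrix(sums, nrow = 1, dimnames = list(rownames(x$counts), labs))
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  out <- lapply(pairs, function(p) {
    treatment_pair(label_1 = p[1], label_2 = p[2],
                   n_1 = stats::setNames(sums[, p[1]], rownames(sums)),
                   n_2 = stats::setNames(sums[, p[2]], rownames(sums)))
  })
  names(out) <- vapply(pairs, paste, character(1), collapse = "|")
  out
}

#' Construct a treatment pair (per-gene counts summed within two environments)
#' @param label_1,label_2 treatment labels
#' @param n_1,n_2 named per-gene integer count vectors (same gene universe)
#' @return a `treatment_pair` object
#' @export
treatment_pair <- function(label_1, label_2, n_1, n_2) {
  stopifnot(length(n_1) == length(n_2), all(n_1 >= 0), all(n_2 >= 0))
  if (!identical(names(n_1), names(n_2))) {
    stop_pardiv("treatment pair gene universes differ", class = "pardiv_validation")
  }
  structure(list(label_1 = label_1, label_2 = label_2,
                 n_1 = n_1, n_2 = n_2,
                 n_tot_1 = sum(n_1), n_tot_2 = sum(n_2)),
            class = "treatment_pair")
}

#' @export
print.treatment_pair <- function(x, ...) {
  cat(sprintf("Treatment pair %s vs %s: %d genes; totals %d vs %d\n",
              x$label_1, x$label_2, length(x$n_1),
              as.integer(x$n_tot_1), as.integer(x$n_tot_2)))
  invisible(x)
}
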