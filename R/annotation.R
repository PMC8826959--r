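#' Read a gene annotation table (per-gene nonsynonymous site counts)
#'
#' The multiplicity correction rescales counts by gene target size, so every
#' gene used in covariance analysis must be annotated with its number of
#' nonsynonymous sites `L`. The genome-wide mean target size is taken over all
#' rows of this table, not just mutated genes.
#'
#' @param path TSV with columns `gene_id`, `L` (a `description` column is
#'   carried through if present)
#' @return a data.frame of class `gene_annotation` with columns `gene_id`, `L`
#' @export
read_gene_annotation <- function(path) {
  df <- read_tsv_plain(path)
  if (!all(c("gene_id", "L") %in% colnames(df))) {
    stop_pardiv("annotation must have columns gene_id and L",
                class = "pardiv_schema")
  }
  gene_annotation(df$gene_id, df$L,
                  description = if ("description" %in% colnames(df)) df$description)
}

#' Construct a validated gene annotation
#' @param gene_id character vector of unique gene ids
#' @param L positive numeric vector of nonsynonymous site counts per gene
#' @param description optional character vector
#' @return data.frame of class `gene_annotation`
#' @export
gene_annotation <- function(gene_id, L, description = NULL) {
  gene_id <- as.character(gene_id)
  L <- as.numeric(L)
  if (anyDuplicated(gene_id)) {
    stop_pardiv("duplicate gene_id in annotation: %s",
                paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "),
                class = "pardiv_validation")
  }
  if (anyNA(L) || any(L <= 0)) {
    stop_pardiv("annotation L must be > 0 for every gene (offending gene: %s)",
                gene_id[which(is.na(L) | L <= 0)[1]],
                class = "pardiv_validation")
  }
  df <- data.frame(gene_id = gene_id, L = L, stringsAsFactors = FALSE)
  if (!is.null(description)) df$description <- as.character(description)
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Genome-wide mean nonsynonymous target size
#' @param annotation a `gene_annotation`
#' @return mean of `L` over all annotated genes
#' @export
mean_target_size <- function(annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  mean(annotation$L)
}

#' Write a gene annotation to TSV
#' @param annotation a `gene_annotation`
#' @param path output path
#' @param params metadata for the commented header
#' @return `path`, invisibly
#' @export
write_gene_annotation <- function(annotation, path, params = list()) {
  stopifnot(inherits(annotation, "gene_annotation"))
  write_tsv_with_header(as.data.frame(annotation), path, params)
}

# L lookup for a set of genes, erroring with the missing gene named
lookup_target_sizes <- function(annotation, gene_ids) {
  stopifnot(inherits(annotation, "gene_annotation"))
  idx <- match(gene_ids, annotation$gene_id)
  if (anyNA(idx)) {
    stop_pardiv("gene '%s' has no annotation entry (required for multiplicity)",
                gene_ids[which(is.na(idx))[1]], class = "pardiv_lookup")
  }
  stats::setNames(annotation$L[idx], gene_ids)
}
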