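#' Read an OrthoFinder-style orthogroup assignment table
#'
#' Parses the tab-separated `Orthogroups.tsv` dialect: first column holds the
#' orthogroup (OG) identifier, each remaining column one species, cells are
#' comma-separated gene lists (possibly empty). Whitespace around commas is
#' trimmed, matching OrthoFinder's `", "`-separated output.
#'
#' @param path Path to the tab-separated orthogroup table.
#' @param species_names Character vector of species columns to keep, in the
#'   requested order. `NULL` keeps every column after the first.
#' @return An `orthogroup_table`: a list with `og_ids` (ordered character),
#'   `species` (ordered character), and `membership` (list indexed
#'   `[[og]][[species]]` holding character vectors of member gene ids).
#' @details A gene may belong to at most one OG within a species; a duplicate
#'   assignment is a validation error naming the gene and both OGs.
#' @export
read_orthogroups <- function(path, species_names = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", na.strings = NULL)
  if (ncol(raw) < 2L)
    stop("orthogroup table needs an OG column plus at least one species column")
  all_species <- colnames(raw)[-1L]
  if (is.null(species_names)) species_names <- all_species
  missing <- setdiff(species_names, all_species)
  if (length(missing))
    stop("species column(s) not found in orthogroup table: ",
         paste(missing, collapse = ", "))
  og_ids <- raw[[1L]]
  if (anyDuplicated(og_ids))
    stop("duplicated orthogroup ids in table: ",
         paste(unique(og_ids[duplicated(og_ids)]), collapse = ", "))
  membership <- lapply(seq_along(og_ids), function(i) {
    row <- lapply(species_names, function(sp) parse_gene_list(raw[[sp]][i]))
    names(row) <- species_names
    row
  })
  names(membership) <- og_ids
  tab <- structure(list(og_ids = og_ids, species = species_names,
                        membership = membership),
                   class = "orthogroup_table")
  validate_orthogroup_table(tab)
  tab
}

parse_gene_list <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  out <- trimws(strsplit(x, ",", fixed = TRUE)[[1L]])
  out[nzchar(out)]
}

validate_orthogroup_table <- function(tab) {
  for (sp in tab$species) {
    genes <- lapply(tab$membership, `[[`, sp)
    if (any(vapply(genes, anyDuplicated, 0L) > 0L)) {
      bad <- tab$og_ids[vapply(genes, anyDuplicated, 0L) > 0L][1L]
      stop("duplicate gene within OG ", bad, " for species ", sp)
    }
    flat <- unlist(genes, use.names = FALSE)
    if (anyDuplicated(flat)) {
      g <- flat[duplicated(flat)][1L]
      ogs <- tab$og_ids[vapply(genes, function(v) g %in% v, NA)]
      stop("gene ", g, " assigned to multiple OGs for species ", sp, ": ",
           paste(ogs, collapse = ", "))
    }
  }
  invisible(tab)
}

#' @export
print.orthogroup_table <- function(x, ...) {
  cat("orthogroup_table:", length(x$og_ids), "OGs x",
      length(x$species), "species (", paste(x$species, collapse = ", "), ")\n")
  invisible(x)
}

#' Keep orthogroups present in every required species
#'
#' Retains exactly the OGs with at least one member gene in each of
#' `required_species`, preserving order. This is the "universal OG" filter
#' that defines the cross-species comparison universe; genes outside it are
#' ignored downstream.
#'
#' @param table An `orthogroup_table`.
#' @param required_species Species that must each contribute >= `min_copies`
#'   genes. Defaults to all species in the table; an empty vector retains
#'   every OG.
#' @param min_copies,max_copies Optional per-species copy-number bounds
#'   (defaults: presence-based, i.e. >= 1 with no upper bound). Set both to 1
#'   for single-copy OGs.
#' @return A filtered `orthogroup_table`.
#' @export
filter_universal_orthogroups <- function(table, required_species = table$species,
                                         min_copies = 1L, max_copies = Inf) {
  stopifnot(inherits(table, "orthogroup_table"))
  missing <- setdiff(required_species, table$species)
  if (length(missing))
    stop("required species not in table: ", paste(missing, collapse = ", "))
  keep <- vapply(table$membership, function(row) {
    all(vapply(required_species, function(sp) {
      n <- length(row[[sp]])
      n >= min_copies && n <= max_copies
    }, NA))
  }, NA)
  if (!any(keep)) warning("no orthogroup passes the universal filter")
  structure(list(og_ids = table$og_ids[keep], species = table$species,
                 membership = table$membership[keep]),
            class = "orthogroup_table")
}

#' Collapse a gene-level expression matrix onto orthogroups
#'
#' For one species, sums the raw counts of all member genes of each OG in
#' each cell, yielding the composite "ortho-gene" matrix. Genes listed in the
#' orthogroup table but absent from the expression matrix are dropped (a
#' tally is reported via `message()`); OGs with no present gene are kept as
#' all-zero rows and flagged, so matrices from different species stay aligned
#' on one OG universe.
#'
#' @param counts Gene x cell matrix of non-negative counts (dense or
#'   `Matrix` sparse), with gene ids as rownames and cell ids as colnames.
#' @param cell_types Named character vector mapping every cell id to its
#'   cell-type label.
#' @param table An `orthogroup_table` containing `species`.
#' @param species The species whose column of `table` applies to `counts`.
#' @return An `ortho_gene_matrix`: list with `counts` (sparse OG x cell
#'   matrix), `cell_types` (named character, aligned to columns), `species`,
#'   and `empty_ogs` (OG ids with no gene present in `counts`).
#' @export
aggregate_to_orthogenes <- function(counts, cell_types, table, species) {
  stopifnot(inherits(table, "orthogroup_table"))
  if (!species %in% table$species)
    stop("species '", species, "' not in orthogroup table")
  counts <- as_sparse_counts(counts)
  validate_cell_types(counts, cell_types)

  og_ids <- table$og_ids
  members <- lapply(table$membership, `[[`, species)
  gene <- unlist(members, use.names = FALSE)
  og_of_gene <- rep(og_ids, lengths(members))
  present <- gene %in% rownames(counts)
  n_missing <- sum(!present)
  if (n_missing > 0L)
    message(n_missing, " of ", length(gene), " ", species,
            " genes in the orthogroup table are absent from the expression matrix and were dropped")
  gene <- gene[present]
  og_of_gene <- og_of_gene[present]

  # OG x gene indicator, then one sparse product does the per-OG summation
  ind <- Matrix::sparseMatrix(
    i = match(og_of_gene, og_ids),
    j = match(gene, rownames(counts)),
    x = 1,
    dims = c(length(og_ids), nrow(counts)),
    dimnames = list(og_ids, rownames(counts)))
  og_counts <- methods::as(ind %*% counts, "CsparseMatrix")
  empty <- og_ids[!og_ids %in% unique(og_of_gene)]
  if (length(empty))
    message(length(empty), " OG(s) have no ", species,
            " gene present; kept as zero rows")
  new_ortho_gene_matrix(og_counts, cell_types[colnames(og_counts)], species,
                        empty_ogs = empty)
}

new_ortho_gene_matrix <- function(counts, cell_types, species,
                                  empty_ogs = character(0)) {
  structure(list(counts = counts, cell_types = cell_types,
                 species = species, empty_ogs = empty_ogs),
            class = "ortho_gene_matrix")
}

as_sparse_counts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and cell colnames")
  if (min(counts) < 0) stop("counts must be non-negative")
  if (anyDuplicated(rownames(counts))) stop("duplicated gene ids in counts")
  methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
              "CsparseMatrix")
}

validate_cell_types <- function(counts, cell_types) {
  if (is.null(names(cell_types)))
    stop("cell_types must be a named vector (names = cell ids)")
  missing <- setdiff(colnames(counts), names(cell_types))
  if (length(missing))
    stop("cells without a cell-type label: ", paste(utils::head(missing, 5), collapse = ", "))
  invisible(TRUE)
}

#' @export
print.ortho_gene_matrix <- function(x, ...) {
  cat("ortho_gene_matrix [", x$species, "]: ", nrow(x$counts), " OGs x ",
      ncol(x$counts), " cells, ", length(unique(x$cell_types)),
      " cell types\n", sep = "")
  invisible(x)
}

#' Read a gene x cell expression matrix
#'
#' Accepts either MatrixMarket sparse triplet input with sidecar gene and
#' cell id files (one id per line) or a dense tab-separated matrix with gene
#' rownames and cell ids in the header.
#'
#' @param path Matrix file (`.mtx` or dense TSV).
#' @param genes_path,cells_path Sidecar id files; required for MTX input.
#' @return Sparse gene x cell matrix with dimnames.
#' @export
read_expression <- function(path, genes_path = NULL, cells_path = NULL) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(genes_path) || is.null(cells_path))
      stop("MTX input needs genes_path and cells_path sidecar files")
    m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    rownames(m) <- readLines(genes_path)
    colnames(m) <- readLines(cells_path)
    m
  } else {
    as_sparse_counts(as.matrix(utils::read.delim(path, row.names = 1L,
                                                 check.names = FALSE)))
  }
}

#' Read a cell annotation table
#'
#' @param path TSV with columns `cell_id` and `cell_type`.
#' @return Named character vector mapping cell id to cell-type label.
#' @export
read_cell_annotations <- function(path) {
  ann <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (!all(c("cell_id", "cell_type") %in% colnames(ann)))
    stop("annotation file must have columns cell_id and cell_type")
  stats::setNames(ann$cell_type, ann$cell_id)
}

#' Write an ortho-gene matrix as MTX plus sidecar files
#'
#' @param ogm An `ortho_gene_matrix`.
#' @param dir Output directory (created if needed). Emits `matrix.mtx`,
#'   `ogs.tsv` and `cells.tsv` (one id per line), and `annotations.tsv`
#'   (columns cell_id, cell_type).
#' @return `dir`, invisibly.
#' @export
write_orthogene_matrix <- function(ogm, dir) {
  stopifnot(inherits(ogm, "ortho_gene_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(ogm$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(ogm$counts), file.path(dir, "ogs.tsv"))
  writeLines(colnames(ogm$counts), file.path(dir, "cells.tsv"))
  utils::write.table(
    data.frame(cell_id = colnames(ogm$counts),
               cell_type = unname(ogm$cell_types[colnames(ogm$counts)])),
    file.path(dir, "annotations.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
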