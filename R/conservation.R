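#' Rank-sum test of an OG between ingroup and outgroup cells
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test comparing the OG's
#' per-cell expression in the ingroup cell types against all remaining
#' cells. The exact null distribution is used when `n * m <= 400` and the
#' data are tie-free; otherwise the normal approximation with tie correction
#' and continuity correction applies.
#'
#' @param ogm An `ortho_gene_matrix`.
#' @param og OG id (must be a row of `ogm$counts`).
#' @param ingroup_types Cell-type labels forming the ingroup.
#' @return Two-sided p-value.
#' @export
ingroup_outgroup_test <- function(ogm, og, ingroup_types) {
  stopifnot(inherits(ogm, "ortho_gene_matrix"))
  if (!og %in% rownames(ogm$counts)) stop("unknown OG: ", og)
  types <- ogm$cell_types[colnames(ogm$counts)]
  x <- as.numeric(ogm$counts[og, types %in% ingroup_types])
  y <- as.numeric(ogm$counts[og, !types %in% ingroup_types])
  rank_sum_p(x, y)
}

rank_sum_p <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("ingroup and outgroup each need >= 2 observations")
  exact <- length(x) * length(y) <= 400 && !anyDuplicated(c(x, y))
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value)
  if (is.nan(p)) 1 else p   # fully tied data carry no evidence
}

# Vectorized rank-sum p-values for every OG of a matrix at once: the normal
# approximation with tie correction, matching wilcox.test(correct = TRUE).
# Used by shared_markers where thousands of OGs are tested on many cells.
rank_sum_p_rows <- function(counts, in_cols) {
  m <- as.matrix(counts)
  n1 <- sum(in_cols); n2 <- ncol(m) - n1
  stopifnot(n1 >= 2L, n2 >= 2L)
  n <- n1 + n2
  ranks <- t(apply(m, 1L, rank))
  W <- rowSums(ranks[, in_cols, drop = FALSE]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tie_term <- apply(m, 1L, function(v) {
    tt <- table(v); sum(tt^3 - tt)
  })
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- W - mu
  z <- sign(z) * pmax(abs(z) - 0.5, 0)  # continuity correction
  p <- ifelse(sigma2 <= 0, 1, 2 * stats::pnorm(-abs(z) / sqrt(pmax(sigma2, .Machine$double.eps))))
  unname(pmin(p, 1))
}

#' Per-species focal-type marker set
#'
#' OGs up-regulated in the focal cell type(s) of one species: fold change
#' strictly above `fc_min` in at least one focal type and BH-adjusted
#' ingroup/outgroup rank-sum p-value below `fdr` (BH applied within the
#' species across all tested OGs).
#'
#' @param fc Fold-change matrix of the species.
#' @param ogm The species' `ortho_gene_matrix` (cells or metacells) used for
#'   the rank-sum tests.
#' @param focal_types Focal (e.g. phagocyte-like) cell-type labels.
#' @param fc_min Fold-change cutoff, strict `>` (default 1.1).
#' @param fdr BH false-discovery-rate cutoff (default 0.05).
#' @return data.frame with columns `og`, `fc` (max over focal types),
#'   `p_value`, `q_value`, `marker` (logical).
#' @export
species_markers <- function(fc, ogm, focal_types, fc_min = 1.1, fdr = 0.05) {
  stopifnot(inherits(ogm, "ortho_gene_matrix"))
  unknown <- setdiff(focal_types, colnames(fc))
  if (length(unknown))
    stop("focal type(s) not in fold-change matrix: ", paste(unknown, collapse = ", "))
  ogs <- intersect(rownames(fc), rownames(ogm$counts))
  types <- ogm$cell_types[colnames(ogm$counts)]
  p <- rank_sum_p_rows(ogm$counts[ogs, , drop = FALSE], types %in% focal_types)
  q <- stats::p.adjust(p, method = "BH")
  fc_max <- apply(fc[ogs, focal_types, drop = FALSE], 1L, max)
  data.frame(og = ogs, fc = fc_max, p_value = p, q_value = q,
             marker = fc_max > fc_min & q < fdr, row.names = NULL)
}

#' Shared orthologous markers for a linked cell-type pair
#'
#' For a retained cross-species cell-type link, calls an OG a shared marker
#' when it maintains a fold change strictly above `fc_min` in the linked
#' type in both species and its BH-adjusted ingroup/outgroup rank-sum
#' p-value is below `fdr` in both species.
#'
#' @param fc_a,fc_b Fold-change matrices of the two species.
#' @param type_a,type_b The linked cell-type labels.
#' @param ogm_a,ogm_b The species' ortho-gene matrices for testing.
#' @param fc_min,fdr Cutoffs as in [species_markers()].
#' @return data.frame with columns `og`, `fc_a`, `p_value_a`, `q_value_a`,
#'   `fc_b`, `p_value_b`, `q_value_b`, `shared`.
#' @export
shared_markers <- function(fc_a, fc_b, type_a, type_b, ogm_a, ogm_b,
                           fc_min = 1.1, fdr = 0.05) {
  ma <- species_markers(fc_a, ogm_a, type_a, fc_min, fdr)
  mb <- species_markers(fc_b, ogm_b, type_b, fc_min, fdr)
  shared_ogs <- intersect(ma$og, mb$og)
  ia <- match(shared_ogs, ma$og); ib <- match(shared_ogs, mb$og)
  data.frame(og = shared_ogs,
             fc_a = ma$fc[ia], p_value_a = ma$p_value[ia], q_value_a = ma$q_value[ia],
             fc_b = mb$fc[ib], p_value_b = mb$p_value[ib], q_value_b = mb$q_value[ib],
             shared = ma$marker[ia] & mb$marker[ib],
             row.names = NULL)
}

#' Exact multi-set intersections of marker sets (UpSet semantics)
#'
#' Each OG is counted in exactly the combination of species sets that
#' contain it, generalizing a Venn diagram; the core set holds the OGs
#' present in every species' set.
#'
#' @param marker_sets Named list: species -> character vector of OG ids.
#' @return List with `combinations` (data.frame: `combination`
#'   (`+`-separated species), `degree`, `size`), `members` (list of OG
#'   vectors per combination), and `core_set` (OGs in all species).
#' @export
marker_intersections <- function(marker_sets) {
  stopifnot(is.list(marker_sets), length(marker_sets) >= 2L,
            !is.null(names(marker_sets)))
  marker_sets <- lapply(marker_sets, unique)
  universe <- unique(unlist(marker_sets, use.names = FALSE))
  if (!length(universe)) {
    return(list(combinations = data.frame(combination = character(0),
                                          degree = integer(0), size = integer(0)),
                members = list(), core_set = character(0)))
  }
  pattern <- vapply(marker_sets, function(s) universe %in% s,
                    logical(length(universe)))
  pattern <- matrix(pattern, nrow = length(universe),
                    dimnames = list(universe, names(marker_sets)))
  key <- apply(pattern, 1L, function(row)
    paste(names(marker_sets)[row], collapse = "+"))
  members <- split(universe, key)
  combos <- data.frame(combination = names(members),
                       degree = lengths(strsplit(names(members), "+", fixed = TRUE)),
                       size = lengths(members), row.names = NULL)
  combos <- combos[order(-combos$degree, -combos$size), , drop = FALSE]
  core <- universe[rowSums(pattern) == length(marker_sets)]
  list(combinations = combos, members = members, core_set = sort(core))
}

#' Orthogroups with conserved differentially expressed genes
#'
#' Maps per-species DEG lists onto orthogroups and returns the OGs whose
#' member genes include at least one DEG in at least `min_species` species.
#' Genes that map to no OG are tallied via `message()`.
#'
#' @param deg_lists Named list: species -> character vector of DEG gene ids
#'   (any cell type).
#' @param table An `orthogroup_table` covering those species.
#' @param min_species Minimum number of species with a DEG in the OG.
#' @return Character vector of OG ids (in table order).
#' @export
conserved_deg_orthogroups <- function(deg_lists, table, min_species) {
  stopifnot(inherits(table, "orthogroup_table"), min_species >= 1L)
  unknown <- setdiff(names(deg_lists), table$species)
  if (length(unknown))
    stop("DEG list species not in orthogroup table: ", paste(unknown, collapse = ", "))
  hits <- matrix(FALSE, nrow = length(table$og_ids), ncol = length(deg_lists),
                 dimnames = list(table$og_ids, names(deg_lists)))
  for (sp in names(deg_lists)) {
    members <- lapply(table$membership, `[[`, sp)
    gene2og <- stats::setNames(rep(table$og_ids, lengths(members)),
                               unlist(members, use.names = FALSE))
    degs <- unique(deg_lists[[sp]])
    mapped <- gene2og[degs[degs %in% names(gene2og)]]
    n_unmapped <- sum(!degs %in% names(gene2og))
    if (n_unmapped > 0L)
      message(n_unmapped, " ", sp, " DEG(s) map to no orthogroup")
    hits[unique(mapped), sp] <- TRUE
  }
  table$og_ids[rowSums(hits) >= min_species]
}

#' Read per-species DEG lists from a TSV
#'
#' @param path TSV with columns `species`, `cell_type`, `gene`.
#' @param cell_types Optional cell-type filter; default keeps all rows.
#' @return Named list species -> character vector of genes.
#' @export
read_deg_lists <- function(path, cell_types = NULL) {
  deg <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("species", "cell_type", "gene")
  if (!all(need %in% colnames(deg)))
    stop("DEG file must have columns: ", paste(need, collapse = ", "))
  if (!is.null(cell_types)) deg <- deg[deg$cell_type %in% cell_types, , drop = FALSE]
  lapply(split(deg$gene, deg$species), unique)
}
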