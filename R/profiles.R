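#' Aggregate same-type cells into metacells
#'
#' Cells of each type are shuffled (seeded via the caller's RNG state) and
#' partitioned into consecutive groups of exactly `group_size`; each
#' metacell is the element-wise sum of its members and inherits the type
#' label. Leftover cells that cannot fill a complete group are dropped.
#' Summing a fixed number of cells reduces dropout sparsity before profile
#' computation; the default of 10 matches common pseudo-metacell practice.
#'
#' @param ogm An `ortho_gene_matrix`.
#' @param group_size Cells per metacell (>= 1). `1` returns the input cells
#'   (in shuffled order).
#' @return An `ortho_gene_matrix` of metacells, ids `<type>.mc<k>`.
#' @export
make_metacells <- function(ogm, group_size = 10L) {
  stopifnot(inherits(ogm, "ortho_gene_matrix"), group_size >= 1L)
  types <- split(colnames(ogm$counts), ogm$cell_types[colnames(ogm$counts)])
  blocks <- list(); labels <- character(0); ids <- character(0)
  dropped <- 0L
  for (ty in names(types)) {
    cells <- sample(types[[ty]])
    n_groups <- length(cells) %/% group_size
    dropped <- dropped + length(cells) - n_groups * group_size
    if (n_groups == 0L) {
      warning("cell type '", ty, "' has fewer than ", group_size,
              " cells; no metacells produced")
      next
    }
    grp <- rep(seq_len(n_groups), each = group_size)
    used <- cells[seq_len(n_groups * group_size)]
    # metacell x cell indicator; sparse product sums each group
    ind <- Matrix::sparseMatrix(i = grp, j = match(used, colnames(ogm$counts)),
                                x = 1,
                                dims = c(n_groups, ncol(ogm$counts)))
    blocks[[ty]] <- methods::as(ogm$counts %*% Matrix::t(ind), "CsparseMatrix")
    ids <- c(ids, paste0(ty, ".mc", seq_len(n_groups)))
    labels <- c(labels, rep(ty, n_groups))
  }
  if (!length(blocks)) stop("no cell type had enough cells for a metacell")
  counts <- do.call(cbind, unname(blocks))
  colnames(counts) <- ids
  if (dropped > 0L) message(dropped, " leftover cell(s) dropped during metacell grouping")
  new_ortho_gene_matrix(counts, stats::setNames(labels, ids), ogm$species,
                        empty_ogs = ogm$empty_ogs)
}

#' Per-cell-type geometric-mean expression profile
#'
#' Each cell's counts are first depth-scaled by
#' `median(total counts over cells) / (that cell's total)`, i.e. normalized
#' by the median cell size. Then, per (OG, cell type), the geometric mean of
#' the scaled values is taken on a log-offset scale:
#' `exp(mean(log(scaled + epsilon))) - epsilon`, floored at 0. The offset
#' makes the geometric mean defined in the presence of zeros, which dominate
#' single-cell counts; as `epsilon -> 0` it converges to the plain geometric
#' mean for positive data.
#'
#' @param ogm An `ortho_gene_matrix` (cells or metacells).
#' @param epsilon Log-offset constant (> 0). Default 0.05, matching the
#'   fold-change pseudocount.
#' @return OG x cell-type matrix of mean expression (dimnames set).
#' @export
celltype_geometric_mean <- function(ogm, epsilon = 0.05) {
  stopifnot(inherits(ogm, "ortho_gene_matrix"), epsilon > 0)
  depth <- Matrix::colSums(ogm$counts)
  zero <- depth == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total counts excluded")
    ogm$counts <- ogm$counts[, !zero, drop = FALSE]
    depth <- depth[!zero]
  }
  if (!ncol(ogm$counts)) stop("no cells left after excluding empty cells")
  scale <- stats::median(depth) / depth
  scaled <- ogm$counts %*% Matrix::Diagonal(x = scale)
  types <- ogm$cell_types[colnames(ogm$counts)]
  type_levels <- sort(unique(types))
  prof <- vapply(type_levels, function(ty) {
    sub <- scaled[, types == ty, drop = FALSE]
    # dense log is fine: profiles are computed per type on modest matrices
    m <- rowMeans(log(as.matrix(sub) + epsilon))
    pmax(exp(m) - epsilon, 0)
  }, numeric(nrow(scaled)))
  dimnames(prof) <- list(rownames(ogm$counts), type_levels)
  prof
}

#' Regularized fold-change matrix
#'
#' Converts a cell-type profile into the species' fold-change (FC) matrix:
#' `fc(o, t) = (mean(o, t) + p) / (median over types of mean(o, .) + p)`,
#' with pseudocount `p` guarding against zero medians and damping
#' fold-changes of weakly expressed OGs. Entries are strictly positive.
#'
#' @param profile OG x cell-type matrix from [celltype_geometric_mean()].
#' @param pseudocount Regularization constant `p` (> 0), default 0.05.
#' @return OG x cell-type matrix of fold changes, attribute `pseudocount`.
#' @export
fold_change <- function(profile, pseudocount = 0.05) {
  stopifnot(is.matrix(profile), pseudocount > 0, min(profile) >= 0)
  med <- apply(profile, 1L, stats::median)
  fc <- (profile + pseudocount) / (med + pseudocount)
  attr(fc, "pseudocount") <- pseudocount
  fc
}

#' Binary OG activity calls from fold changes
#'
#' An OG is called active (state 1) when its fold change strictly exceeds
#' `threshold` in at least one of the focal cell types (e.g. a species'
#' phagocyte-like subclusters); otherwise inactive (0).
#'
#' @param fc Fold-change matrix from [fold_change()].
#' @param focal_cell_types Non-empty labels, all present in `colnames(fc)`.
#' @param threshold Activity cutoff, strict `>`. Default 1.1.
#' @return Named integer vector (OG -> 0/1).
#' @export
binarize_activity <- function(fc, focal_cell_types, threshold = 1.1) {
  stopifnot(is.matrix(fc), length(focal_cell_types) >= 1L)
  unknown <- setdiff(focal_cell_types, colnames(fc))
  if (length(unknown))
    stop("focal cell type(s) not in fold-change matrix: ",
         paste(unknown, collapse = ", "))
  sub <- fc[, focal_cell_types, drop = FALSE]
  state <- as.integer(apply(sub, 1L, max) > threshold)
  names(state) <- rownames(fc)
  state
}
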