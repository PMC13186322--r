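# Shared fixture builders and independent oracles.

# Wrap a dense gene x cell matrix as an ortho_gene_matrix without going
# through aggregation (for profile/marker unit tests).
toy_ogm <- function(counts, cell_types, species = "toy") {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  orthocellmap:::new_ortho_gene_matrix(
    methods::as(counts, "CsparseMatrix"),
    cell_types, species)
}

# Random orthogroup table: n_og OGs over the given species, each species
# contributing 0..max_copies genes per OG (0 with prob p_absent).
random_orthogroup_table <- function(n_og, species, p_absent = 0.3,
                                    max_copies = 3) {
  og_ids <- sprintf("OG%03d", seq_len(n_og))
  counter <- stats::setNames(rep(0L, length(species)), species)
  membership <- lapply(og_ids, function(og) {
    row <- lapply(species, function(sp) {
      n <- if (stats::runif(1) < p_absent) 0L else sample.int(max_copies, 1L)
      if (n == 0L) return(character(0))
      idx <- counter[[sp]] + seq_len(n)
      counter[[sp]] <<- counter[[sp]] + n
      paste0(sp, "_g", idx)
    })
    names(row) <- species
    row
  })
  names(membership) <- og_ids
  structure(list(og_ids = og_ids, species = species, membership = membership),
            class = "orthogroup_table")
}

# Write an orthogroup table to a temp Orthogroups.tsv and return the path.
write_og_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Exhaustive parsimony oracle: minimum change count over all 2^Nnode
# internal assignments, independent of the Sankoff implementation.
brute_force_parsimony <- function(tree, tip_states) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  tip_vec <- as.integer(tip_states[tree$tip.label])
  assign <- as.matrix(expand.grid(rep(list(0:1), n_int)))
  full <- cbind(matrix(tip_vec, nrow(assign), n_tip, byrow = TRUE), assign)
  min(rowSums(full[, tree$edge[, 1L], drop = FALSE] !=
                full[, tree$edge[, 2L], drop = FALSE]))
}

# Recount state changes of a full node-state assignment on the tree.
recount_changes <- function(tree, states) {
  sum(states[tree$edge[, 1L]] != states[tree$edge[, 2L]])
}

# Small simulated panel for pipeline-level tests (fast: ~1 s).
small_panel <- function(seed = 42L, ...) {
  simulate_panel(simulation_config(
    cells_per_type = 60L, n_ogs = 120L, planted_module_size = 10L,
    seed = seed, ...))
}

panel_pipeline_config <- function(panel, seed = 42L, ...) {
  pipeline_config(panel$orthogroups,
                  expr = lapply(panel$species, `[[`, "counts"),
                  cell_annotations = lapply(panel$species, `[[`, "cell_types"),
                  tree = panel$tree,
                  focal_cell_types = as.list(panel$truth$homolog_map),
                  seed = seed, ...)
}
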