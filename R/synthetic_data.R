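#' Configuration for the multi-species single-cell simulator
#'
#' Bundles and validates the generative settings for [simulate_panel()].
#' Defaults describe a compact three-species panel with four cell types per
#' species, 200 cells per type and 300 orthogroups, of which a 20-OG
#' conserved module is up-regulated fourfold in each species'
#' phagocyte-like type.
#'
#' @param n_species Number of species (>= 2).
#' @param cell_types_per_species Cell types per species (>= 2).
#' @param cells_per_type Cells per cell type.
#' @param n_ogs Number of orthogroups.
#' @param planted_module_size Size of the planted conserved module (and of
#'   each lineage-specific identity module).
#' @param planted_fold Multiplier applied to module-OG means in the
#'   phagocyte-like type (> 1 plants signal; 1 is the null).
#' @param paralog_rate Mean number of extra gene copies per OG per species
#'   (Poisson); each OG yields `1 + Poisson(paralog_rate)` genes.
#' @param nb_mean Central baseline mean count per OG per cell; per-OG
#'   baselines are drawn once (shared across species) from a log-normal
#'   around this value to emulate expression heterogeneity.
#' @param nb_dispersion Negative-binomial size parameter (> 0; smaller =
#'   more overdispersed).
#' @param depth_variation Log-normal sdlog of per-cell size factors.
#' @param tree Newick string with branch lengths in Myr; defaults to a
#'   dated tree over `sp1..spN` (caterpillar topology, 100-Myr steps).
#' @param trait_change_prob Per-branch flip probability for the planted
#'   binary trait history (in `[0, 0.5)`).
#' @param seed Integer seed; all randomness in [simulate_panel()] flows
#'   from it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_species = 3L, cell_types_per_species = 4L,
                              cells_per_type = 200L, n_ogs = 300L,
                              planted_module_size = 20L, planted_fold = 4,
                              paralog_rate = 0.5, nb_mean = 2,
                              nb_dispersion = 2, depth_variation = 0.3,
                              tree = NULL, trait_change_prob = 0.05,
                              seed = 1L) {
  if (is.null(tree)) tree <- default_panel_tree(n_species)
  cfg <- list(n_species = as.integer(n_species),
              cell_types_per_species = as.integer(cell_types_per_species),
              cells_per_type = as.integer(cells_per_type),
              n_ogs = as.integer(n_ogs),
              planted_module_size = as.integer(planted_module_size),
              planted_fold = planted_fold, paralog_rate = paralog_rate,
              nb_mean = nb_mean, nb_dispersion = nb_dispersion,
              depth_variation = depth_variation, tree = tree,
              trait_change_prob = trait_change_prob, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_species >= 2L, cell_types_per_species >= 2L,
              cells_per_type >= 1L, n_ogs >= 1L, planted_fold >= 1,
              paralog_rate >= 0, nb_mean > 0, nb_dispersion > 0,
              depth_variation >= 0, trait_change_prob >= 0,
              trait_change_prob < 0.5)
    if (2L * planted_module_size > n_ogs)
      stop("planted module plus lineage modules exceed n_ogs")
  })
  structure(cfg, class = "simulation_config")
}

default_panel_tree <- function(n_species) {
  tips <- paste0("sp", seq_len(n_species), ":100")
  nwk <- tips[1L]
  for (i in seq_len(n_species - 1L))
    nwk <- paste0("(", nwk, ",", tips[i + 1L], "):100")
  paste0(sub(":100$", "", nwk), ";")
}

#' Simulate a multi-species single-cell panel with planted ground truth
#'
#' For each species, every OG expands into `1 + Poisson(paralog_rate)`
#' paralogous genes whose expected expression splits the OG total by a
#' symmetric Dirichlet (so OG-level sums recover the OG signal in
#' expectation). Counts are negative binomial with log-normal per-cell size
#' factors. The planted conserved module is up-regulated `planted_fold`-fold
#' in each species' randomly designated phagocyte-like cell type. Every
#' other cell type carries its own disjoint-from-the-module,
#' lineage-specific identity module of the same size and fold, drawn
#' independently per species from the non-conserved OG pool — mirroring
#' real tissues, where each cell type expresses a distinct marker program
#' but only the phagocyte program is shared across species. A binary trait
#' history (root states Bernoulli(0.5), per-edge flips) is planted on the
#' species tree.
#'
#' @param config A [simulation_config()].
#' @return List with `species` (per-species list of `counts` gene x cell
#'   sparse matrix and `cell_types` named vector), `orthogroups` (an
#'   `orthogroup_table`), `tree` ([ape::phylo]), and `truth` (module OGs,
#'   per-species phagocyte-like label `homolog_map`, per-species/type
#'   `lineage_modules`, gene to OG maps, and the planted trait history).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  species <- paste0("sp", seq_len(config$n_species))
  types <- paste0("ct", seq_len(config$cell_types_per_species))
  og_ids <- sprintf("OG%04d", seq_len(config$n_ogs))

  module_ogs <- og_ids[seq_len(config$planted_module_size)]
  nonmodule_pool <- setdiff(og_ids, module_ogs)
  # per-OG baseline means, conserved across species
  og_mean <- stats::rlnorm(config$n_ogs, log(config$nb_mean), 0.5)
  names(og_mean) <- og_ids
  homolog_map <- stats::setNames(sample(types, config$n_species, replace = TRUE),
                                 species)
  # one identity module per non-phagocyte type per species, drawn
  # independently per species so the programs do not align across species
  lineage_modules <- lapply(species, function(sp) {
    other <- setdiff(types, homolog_map[sp])
    stats::setNames(lapply(other, function(ty)
      sample(nonmodule_pool, config$planted_module_size)), other)
  })
  names(lineage_modules) <- species

  membership <- lapply(og_ids, function(og) stats::setNames(
    vector("list", length(species)), species))
  names(membership) <- og_ids
  panel <- list()
  gene_to_og <- list()
  for (sp in species) {
    n_genes_per_og <- 1L + stats::rpois(config$n_ogs, config$paralog_rate)
    og_of_gene <- rep(og_ids, n_genes_per_og)
    genes <- paste0(sp, "_g", sprintf("%05d", seq_along(og_of_gene)))
    # symmetric Dirichlet split of each OG's mean over its paralogs
    w <- stats::rgamma(length(genes), shape = 5)
    w <- w / stats::ave(w, og_of_gene, FUN = sum)
    gene_mean <- og_mean[og_of_gene] * w

    cells <- paste0(sp, "_c", sprintf("%05d",
                    seq_len(config$cells_per_type * length(types))))
    cell_type <- stats::setNames(rep(types, each = config$cells_per_type), cells)
    size_factor <- stats::rlnorm(length(cells), 0, config$depth_variation)

    fold <- matrix(1, nrow = config$n_ogs, ncol = length(types),
                   dimnames = list(og_ids, types))
    fold[module_ogs, homolog_map[sp]] <- config$planted_fold
    for (ty in names(lineage_modules[[sp]]))
      fold[lineage_modules[[sp]][[ty]], ty] <- config$planted_fold

    mu <- outer(gene_mean, size_factor) * fold[og_of_gene, cell_type[cells]]
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = config$nb_dispersion),
                     nrow = length(genes), dimnames = list(genes, cells))
    panel[[sp]] <- list(counts = as_sparse_counts(counts),
                        cell_types = cell_type)
    gene_to_og[[sp]] <- stats::setNames(og_of_gene, genes)
    for (i in seq_along(og_ids))
      membership[[i]][[sp]] <- genes[og_of_gene == og_ids[i]]
  }
  table <- structure(list(og_ids = og_ids, species = species,
                          membership = membership),
                     class = "orthogroup_table")
  tree <- ape::read.tree(text = config$tree)
  history <- plant_trait_history(tree, config$n_ogs, config$trait_change_prob)
  list(species = panel, orthogroups = table, tree = tree,
       truth = list(module_ogs = module_ogs, homolog_map = homolog_map,
                    lineage_modules = lineage_modules,
                    gene_to_og = gene_to_og, og_mean = og_mean,
                    trait_history = history))
}

plant_trait_history <- function(tree, n_ogs, trait_change_prob) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  states <- matrix(NA_integer_, n_all, n_ogs)
  root <- n_tip + 1L
  states[root, ] <- stats::rbinom(n_ogs, 1L, 0.5)
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  flips <- matrix(NA, nrow(tree$edge), n_ogs)
  for (e in rev(seq_len(nrow(edges)))) {        # preorder: parents first
    par <- edges[e, 1L]; chl <- edges[e, 2L]
    flip <- stats::rbinom(n_ogs, 1L, trait_change_prob) == 1L
    states[chl, ] <- ifelse(flip, 1L - states[par, ], states[par, ])
    row <- which(tree$edge[, 1L] == par & tree$edge[, 2L] == chl)
    flips[row, ] <- flip
  }
  rownames(states) <- node_names(tree)
  list(node_states = states,
       tip_states = states[seq_len(n_tip), , drop = FALSE],
       n_changes_per_og = colSums(flips),
       flips_per_edge = rowSums(flips))
}

#' Simulate a binary trait history on a tree
#'
#' Root states are Bernoulli(0.5); along each edge every trait flips
#' independently with probability `trait_change_prob`. Returns tip states
#' plus the full internal truth, the planted ground truth for ancestral
#' state reconstruction.
#'
#' @param tree A rooted [ape::phylo] tree.
#' @param n_ogs Number of traits.
#' @param trait_change_prob Per-edge flip probability (in `[0, 0.5)`).
#' @param seed Integer seed.
#' @return List with `tip_states` (tips x trait 0/1 matrix), `node_states`
#'   (all nodes x trait), `n_changes_per_og`, `flips_per_edge`.
#' @export
simulate_trait_history <- function(tree, n_ogs, trait_change_prob, seed = 1L) {
  stopifnot(trait_change_prob >= 0, trait_change_prob < 0.5)
  set.seed(seed)
  plant_trait_history(tree, n_ogs, trait_change_prob)
}

#' Write an orthogroup table in the Orthogroups.tsv dialect
#'
#' @param table An `orthogroup_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(table, path) {
  stopifnot(inherits(table, "orthogroup_table"))
  rows <- vapply(table$og_ids, function(og) {
    paste(c(og, vapply(table$species, function(sp)
      paste(table$membership[[og]][[sp]], collapse = ", "), "")),
      collapse = "\t")
  }, "")
  writeLines(c(paste(c("Orthogroup", table$species), collapse = "\t"), rows),
             path)
  invisible(path)
}

#' Write a simulated panel as a plain-text fixture tree
#'
#' Emits, per species, MTX counts with gene/cell sidecars and a cell
#' annotation TSV; plus `Orthogroups.tsv`, the Newick tree, a ground-truth
#' JSON and a `manifest.tsv` listing every file with its md5 checksum.
#'
#' @param panel Result of [simulate_panel()].
#' @param dir Output directory.
#' @param force Overwrite a non-empty directory (default errors).
#' @return `dir`, invisibly.
#' @export
write_fixture_set <- function(panel, dir, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir, all.files = TRUE, no.. = TRUE)) && !force)
    stop("directory ", dir, " is not empty; use force = TRUE to overwrite")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(panel$species)) {
    d <- file.path(dir, sp)
    dir.create(d, showWarnings = FALSE)
    x <- panel$species[[sp]]
    Matrix::writeMM(x$counts, file.path(d, "matrix.mtx"))
    writeLines(rownames(x$counts), file.path(d, "genes.tsv"))
    writeLines(colnames(x$counts), file.path(d, "cells.tsv"))
    utils::write.table(data.frame(cell_id = names(x$cell_types),
                                  cell_type = unname(x$cell_types)),
                       file.path(d, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_orthogroups(panel$orthogroups, file.path(dir, "Orthogroups.tsv"))
  ape::write.tree(panel$tree, file.path(dir, "tree.nwk"))
  truth <- panel$truth
  truth$trait_history$node_states <- as.data.frame(truth$trait_history$node_states)
  truth$trait_history$tip_states <- as.data.frame(truth$trait_history$tip_states)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.tsv")
  utils::write.table(data.frame(file = files,
                                md5 = unname(tools::md5sum(file.path(dir, files)))),
                     file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
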