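#' Configuration for the end-to-end pipeline
#'
#' Collects inputs and the analysis parameters at their canonical defaults:
#' pseudocount 0.05, fold-change threshold 1.1, similarity percentile 88,
#' metacells of 10 cells, BH FDR 0.05.
#'
#' @param orthogroups An `orthogroup_table` or path to an Orthogroups.tsv.
#' @param expr Named list (species -> gene x cell count matrix, or path to a
#'   matrix file readable by [read_expression()]; for MTX give
#'   `list(matrix=, genes=, cells=)` paths).
#' @param cell_annotations Named list (species -> named cell-type vector or
#'   annotation TSV path).
#' @param tree [ape::phylo], Newick path, or `NULL` to skip trait evolution.
#' @param focal_cell_types Named list (species -> focal, e.g.
#'   phagocyte-like, cell-type labels); `NULL` skips marker and trait
#'   stages.
#' @param deg_lists Optional named list (species -> DEG gene ids) or TSV
#'   path for [conserved_deg_orthogroups()].
#' @param pseudocount,fc_threshold,percentile,metacell_size,fdr Analysis
#'   parameters (see the stage functions).
#' @param min_species Minimum species count for conserved-DEG OGs
#'   (default: all species).
#' @param symmetric Symmetrized KLD (default) or directed.
#' @param global_percentile Pool species pairs for the link threshold.
#' @param seed Integer seed (metacell grouping).
#' @param out Output directory (`NULL`: no files written).
#' @param force Overwrite a non-empty output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(orthogroups, expr, cell_annotations, tree = NULL,
                            focal_cell_types = NULL, deg_lists = NULL,
                            pseudocount = 0.05, fc_threshold = 1.1,
                            percentile = 88, metacell_size = 10L, fdr = 0.05,
                            min_species = NULL, symmetric = TRUE,
                            global_percentile = FALSE, seed = 1L,
                            out = NULL, force = FALSE) {
  stopifnot(pseudocount > 0, fc_threshold > 0, percentile >= 0,
            percentile <= 100, metacell_size >= 1, fdr > 0, fdr <= 1)
  if (is.null(names(expr)) || !setequal(names(expr), names(cell_annotations)))
    stop("expr and cell_annotations must be named lists over the same species")
  structure(list(orthogroups = orthogroups, expr = expr,
                 cell_annotations = cell_annotations, tree = tree,
                 focal_cell_types = focal_cell_types, deg_lists = deg_lists,
                 pseudocount = pseudocount, fc_threshold = fc_threshold,
                 percentile = percentile, metacell_size = as.integer(metacell_size),
                 fdr = fdr, min_species = min_species, symmetric = symmetric,
                 global_percentile = global_percentile, seed = as.integer(seed),
                 out = out, force = force),
            class = "pipeline_config")
}

#' Run the full cross-species comparison pipeline
#'
#' Executes, in order: orthogroup filtering to the universal set, ortho-gene
#' aggregation per species, metacell grouping, geometric-mean profiles and
#' fold-change matrices, cross-species KLD similarity with percentile link
#' thresholding, shared-marker calling and multi-species intersection for
#' the focal cell types, conserved-DEG orthogroups (when DEG lists are
#' given), and parsimony trait evolution (when a tree is given). Omitting
#' the tree or the focal types skips the dependent stages, which is noted
#' in the log.
#'
#' @param config A [pipeline_config()].
#' @return Result bundle: `orthogroups`, per-species `orthogenes` and
#'   `metacells`, `profiles`, `fold_changes`, `links`, `markers` (per
#'   retained focal link), `marker_sets`, `intersections`, `activity`,
#'   `trait_evolution`, `conserved_deg_ogs`, `log` (character vector).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  note <- function(...) {
    line <- paste0(...)
    message(line)
    log <<- c(log, line)
  }
  set.seed(config$seed)
  note("orthocellmap ", as.character(utils::packageVersion("orthocellmap")),
       " | seed=", config$seed,
       " | pseudocount=", config$pseudocount,
       " fc_threshold=", config$fc_threshold,
       " percentile=", config$percentile,
       " metacell_size=", config$metacell_size,
       " fdr=", config$fdr,
       " symmetric=", config$symmetric,
       " global_percentile=", config$global_percentile)

  species <- names(config$expr)
  tab <- config$orthogroups
  if (is.character(tab)) tab <- read_orthogroups(tab, species)
  tab <- filter_universal_orthogroups(tab, species)
  note("stage orthomap: ", length(tab$og_ids), " universal OGs across ",
       length(species), " species")

  metacells <- profiles <- fold_changes <- list()
  for (sp in species) {
    e <- config$expr[[sp]]
    if (is.character(e)) e <- read_expression(e)
    else if (is.list(e) && !is.null(e$matrix))
      e <- read_expression(e$matrix, e$genes, e$cells)
    ann <- config$cell_annotations[[sp]]
    if (is.character(ann) && is.null(names(ann)) && length(ann) == 1L)
      ann <- read_cell_annotations(ann)
    ogm <- aggregate_to_orthogenes(e, ann, tab, sp)
    mc <- if (config$metacell_size > 1L)
      make_metacells(ogm, config$metacell_size) else ogm
    metacells[[sp]] <- mc
    profiles[[sp]] <- celltype_geometric_mean(mc, epsilon = config$pseudocount)
    fold_changes[[sp]] <- fold_change(profiles[[sp]], config$pseudocount)
    note("stage profiles [", sp, "]: ", ncol(mc$counts), " metacells, ",
         ncol(profiles[[sp]]), " cell types")
  }

  pairs <- utils::combn(species, 2L)
  links <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    celltype_kld(fold_changes[[a]], fold_changes[[b]], a, b,
                 symmetric = config$symmetric)
  }))
  links <- threshold_links(similarity_scores(links),
                           percentile = config$percentile,
                           global = config$global_percentile)
  note("stage similarity: ", nrow(links), " cell-type pairs, ",
       sum(links$retained), " links retained at percentile ", config$percentile)

  markers <- NULL; marker_sets <- NULL; intersections <- NULL
  activity <- NULL; trait <- NULL
  if (is.null(config$focal_cell_types)) {
    note("stage markers: skipped (no focal cell types given)")
  } else {
    focal <- config$focal_cell_types
    missing_sp <- setdiff(species, names(focal))
    if (length(missing_sp))
      stop("focal_cell_types lacks species: ", paste(missing_sp, collapse = ", "))
    focal_links <- links[links$retained &
                           mapply(function(sa, ta) ta %in% focal[[sa]],
                                  links$species_a, links$type_a) &
                           mapply(function(sb, tb) tb %in% focal[[sb]],
                                  links$species_b, links$type_b), , drop = FALSE]
    markers <- lapply(seq_len(nrow(focal_links)), function(i) {
      l <- focal_links[i, ]
      cbind(l[, c("species_a", "type_a", "species_b", "type_b")],
            shared_markers(fold_changes[[l$species_a]], fold_changes[[l$species_b]],
                           l$type_a, l$type_b,
                           metacells[[l$species_a]], metacells[[l$species_b]],
                           fc_min = config$fc_threshold, fdr = config$fdr),
            row.names = NULL)
    })
    markers <- if (length(markers)) do.call(rbind, markers) else NULL
    marker_sets <- lapply(species, function(sp) {
      m <- species_markers(fold_changes[[sp]], metacells[[sp]], focal[[sp]],
                           fc_min = config$fc_threshold, fdr = config$fdr)
      m$og[m$marker]
    })
    names(marker_sets) <- species
    intersections <- marker_intersections(marker_sets)
    note("stage conservation: ", nrow(focal_links), " retained focal links, core set of ",
         length(intersections$core_set), " OGs across all species")

    activity <- vapply(species, function(sp)
      binarize_activity(fold_changes[[sp]], focal[[sp]], config$fc_threshold),
      integer(length(tab$og_ids)))
    rownames(activity) <- tab$og_ids
    if (is.null(config$tree)) {
      note("stage trait_evolution: skipped (no tree given)")
    } else {
      tree <- config$tree
      if (is.character(tree)) tree <- read_newick(tree)
      trait <- reconstruct_trait_evolution(activity, tree)
      note("stage trait_evolution: ", sum(trait$scores),
           " total state changes over ", nrow(activity), " OGs")
    }
  }

  conserved_deg <- NULL
  if (!is.null(config$deg_lists)) {
    dl <- config$deg_lists
    if (is.character(dl)) dl <- read_deg_lists(dl)
    min_sp <- if (is.null(config$min_species)) length(species) else config$min_species
    conserved_deg <- conserved_deg_orthogroups(dl, tab, min_sp)
    note("stage conservation: ", length(conserved_deg),
         " OGs with DEGs in >= ", min_sp, " species")
  }

  res <- list(orthogroups = tab, metacells = metacells, profiles = profiles,
              fold_changes = fold_changes, links = links, markers = markers,
              marker_sets = marker_sets, intersections = intersections,
              activity = activity, trait_evolution = trait,
              conserved_deg_ogs = conserved_deg, log = log)
  if (!is.null(config$out)) write_pipeline_outputs(res, config)
  res
}

pipeline_header <- function(config, what) {
  c(paste0("# orthocellmap::run_pipeline | ", what),
    paste0("# pseudocount=", config$pseudocount,
           " fc_threshold=", config$fc_threshold,
           " percentile=", config$percentile,
           " metacell_size=", config$metacell_size,
           " fdr=", config$fdr, " seed=", config$seed))
}

write_commented_tsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_outputs <- function(res, config) {
  dir <- config$out
  if (dir.exists(dir) && length(dir(dir, all.files = TRUE, no.. = TRUE)) &&
      !config$force)
    stop("output directory ", dir, " is not empty; set force = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_commented_tsv(res$links, file.path(dir, "links.tsv"),
                      pipeline_header(config, "cross-species cell-type links"))
  if (!is.null(res$markers))
    write_commented_tsv(res$markers, file.path(dir, "markers.tsv"),
                        pipeline_header(config, "shared orthologous markers"))
  if (!is.null(res$intersections)) {
    write_commented_tsv(res$intersections$combinations,
                        file.path(dir, "intersections.tsv"),
                        pipeline_header(config, "marker-set intersections (UpSet)"))
    jsonlite::write_json(
      list(core_set = res$intersections$core_set,
           members = res$intersections$members),
      file.path(dir, "intersections.json"))
  }
  if (!is.null(res$activity))
    write_commented_tsv(data.frame(og = rownames(res$activity), res$activity,
                                   check.names = FALSE),
                        file.path(dir, "activity.tsv"),
                        pipeline_header(config, "binary OG activity per species"))
  if (!is.null(res$trait_evolution)) {
    write_trait_evolution(res$trait_evolution, dir)
  }
  if (!is.null(res$conserved_deg_ogs))
    write_commented_tsv(data.frame(og = res$conserved_deg_ogs),
                        file.path(dir, "conserved_deg_ogs.tsv"),
                        pipeline_header(config, "conserved-DEG orthogroups"))
  writeLines(res$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
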