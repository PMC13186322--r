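#' Align two fold-change profiles on their shared orthogroups
#'
#' Restricts both matrices to the intersection of their OG sets, in one
#' shared row order (the order of appearance in `fc_a`).
#'
#' @param fc_a,fc_b Fold-change matrices with OG rownames.
#' @return List with elements `a` and `b`, row-aligned.
#' @export
joint_profiles <- function(fc_a, fc_b) {
  shared <- intersect(rownames(fc_a), rownames(fc_b))
  if (!length(shared)) stop("no orthogroup shared between the two profiles")
  list(a = fc_a[shared, , drop = FALSE], b = fc_b[shared, , drop = FALSE])
}

#' Kullback-Leibler divergence between two positive vectors
#'
#' Both vectors are normalized to probability distributions P, Q (divide by
#' their sums); returns `sum(P * log(P / Q))` in nats. Strictly positive
#' input is required — the fold-change pseudocount guarantees it upstream.
#'
#' @param p_vec,q_vec Positive numeric vectors of equal length (>= 2).
#' @return Non-negative divergence in nats (0 iff P == Q).
#' @export
kl_divergence <- function(p_vec, q_vec) {
  if (length(p_vec) != length(q_vec) || length(p_vec) < 2L)
    stop("vectors must have equal length >= 2")
  if (min(p_vec) <= 0 || min(q_vec) <= 0)
    stop("KLD requires strictly positive entries (pseudocount contract)")
  p <- p_vec / sum(p_vec)
  q <- q_vec / sum(q_vec)
  sum(p * log(p / q))
}

#' Symmetrized Kullback-Leibler divergence
#'
#' Arithmetic mean of the two directed divergences; symmetric by
#' construction, suited to undirected cell-type links.
#'
#' @inheritParams kl_divergence
#' @return Non-negative divergence in nats.
#' @export
symmetric_divergence <- function(p_vec, q_vec) {
  (kl_divergence(p_vec, q_vec) + kl_divergence(q_vec, p_vec)) / 2
}

#' Cross-species cell-type divergence table
#'
#' Computes the (symmetrized) KLD between every cell type of species A and
#' every cell type of species B over their joint fold-change profiles.
#'
#' @param fc_a,fc_b Fold-change matrices of the two species.
#' @param species_a,species_b Species names recorded in the output.
#' @param symmetric Use [symmetric_divergence()] (default); `FALSE` computes
#'   directed KLD(A-type || B-type).
#' @return data.frame with columns `species_a`, `type_a`, `species_b`,
#'   `type_b`, `kld`.
#' @export
celltype_kld <- function(fc_a, fc_b, species_a, species_b, symmetric = TRUE) {
  j <- joint_profiles(fc_a, fc_b)
  grid <- expand.grid(type_a = colnames(j$a), type_b = colnames(j$b),
                      stringsAsFactors = FALSE)
  div <- if (symmetric) symmetric_divergence else kl_divergence
  grid$kld <- mapply(function(ta, tb) div(j$a[, ta], j$b[, tb]),
                     grid$type_a, grid$type_b)
  data.frame(species_a = species_a, type_a = grid$type_a,
             species_b = species_b, type_b = grid$type_b,
             kld = grid$kld, row.names = NULL)
}

species_pair_key <- function(graph) paste(graph$species_a, graph$species_b, sep = "\r")

#' Invert divergences into similarity scores
#'
#' Within each species pair, divergences are min-max inverted:
#' `similarity = 1 - kld / max(kld)` (all-equal divergences map to 1). Any
#' strictly decreasing inversion yields the same percentile link sets, so
#' the choice is presentational; min-max puts scores on [0, 1].
#'
#' @param graph data.frame from [celltype_kld()] (rows may cover several
#'   species pairs).
#' @return The input with a `similarity` column added.
#' @export
similarity_scores <- function(graph) {
  stopifnot(all(c("species_a", "species_b", "kld") %in% colnames(graph)),
            all(graph$kld >= 0))
  graph$similarity <- stats::ave(graph$kld, species_pair_key(graph),
                                 FUN = function(k) {
                                   if (max(k) == 0) rep(1, length(k))
                                   else 1 - k / max(k)
                                 })
  graph
}

#' Retain the most similar cross-species links by percentile threshold
#'
#' Within each species pair (or globally), a link is retained when its
#' similarity is at or above the empirical `percentile` of that pair's
#' similarity scores (linear-interpolation percentile; ties at the cutoff
#' are kept). The default 88 keeps the top 12% most similar connections.
#'
#' @param graph data.frame with a `similarity` column
#'   (from [similarity_scores()]).
#' @param percentile Threshold in \[0, 100\].
#' @param global Pool all species pairs into one percentile (default
#'   `FALSE`: per species pair).
#' @return The input with logical `retained` and numeric `cutoff` columns.
#' @export
threshold_links <- function(graph, percentile = 88, global = FALSE) {
  stopifnot("similarity" %in% colnames(graph),
            percentile >= 0, percentile <= 100)
  cut_fun <- function(s) rep(stats::quantile(s, percentile / 100, names = FALSE),
                             length(s))
  graph$cutoff <- if (global) cut_fun(graph$similarity)
                  else stats::ave(graph$similarity, species_pair_key(graph),
                                  FUN = cut_fun)
  graph$retained <- graph$similarity >= graph$cutoff
  attr(graph, "percentile") <- percentile
  graph
}
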