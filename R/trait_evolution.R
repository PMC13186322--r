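#' Read a rooted, dated species tree from Newick
#'
#' Thin validating wrapper around [ape::read.tree()]. Tips must be uniquely
#' named. Branch lengths are interpreted as millions of years (Myr); their
#' absence is tolerated here but is an error when change rates are
#' requested. An unrooted (basal-trifurcation) tree is accepted as a
#' multifurcation at the root and flagged via `message()`.
#'
#' @param path Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("tree has unnamed tips")
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length))
    message("tree has no branch lengths; change rates will be unavailable")
  if (!ape::is.rooted(tree))
    message("tree is unrooted; treating the basal trifurcation as a root multifurcation")
  tree
}

n_nodes_total <- function(tree) length(tree$tip.label) + tree$Nnode

#' Node names for tips and internal nodes
#'
#' Tips keep their labels; internal nodes use Newick node labels where
#' present and non-empty, else `Node<k>` by ape node number. The root also
#' answers to `"root"` and any node to `"MRCA(tipA,tipB,...)"` in
#' [match_node()].
#'
#' @param tree An [ape::phylo] tree.
#' @return Character vector of length `Ntip + Nnode`, indexed by ape node
#'   number.
#' @export
node_names <- function(tree) {
  n_tip <- length(tree$tip.label)
  internal <- paste0("Node", seq_len(tree$Nnode) + n_tip)
  if (!is.null(tree$node.label)) {
    has <- nzchar(tree$node.label) & !is.na(tree$node.label)
    internal[has] <- tree$node.label[has]
  }
  c(tree$tip.label, internal)
}

#' Resolve a node reference to an ape node number
#'
#' @param tree An [ape::phylo] tree.
#' @param node `"root"`, a tip or internal node label, a `Node<k>` id, or
#'   `"MRCA(tip1,tip2,...)"`.
#' @return Integer node number.
#' @export
match_node <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (identical(node, "root")) return(n_tip + 1L)
  nm <- node_names(tree)
  hit <- which(nm == node)
  if (length(hit) == 1L) return(hit)
  if (grepl("^MRCA\\(.+\\)$", node)) {
    tips <- trimws(strsplit(sub("^MRCA\\((.+)\\)$", "\\1", node), ",")[[1L]])
    bad <- setdiff(tips, tree$tip.label)
    if (length(bad)) stop("unknown tip(s) in MRCA reference: ", paste(bad, collapse = ", "))
    if (length(tips) == 1L) return(which(tree$tip.label == tips))
    return(ape::getMRCA(tree, tips))
  }
  stop("unknown node: ", node)
}

# Unit-cost Sankoff bottom-up pass, vectorized across traits.
# tip_states: n_tip x n_trait matrix of 0/1, rows in tree$tip.label order.
# Returns cost0/cost1 ((Ntip+Nnode) x n_trait) and per-trait minimal scores.
sankoff_costs <- function(tree, tip_states) {
  n_tip <- length(tree$tip.label)
  n_all <- n_nodes_total(tree)
  n_trait <- ncol(tip_states)
  cost0 <- matrix(0, n_all, n_trait)
  cost1 <- matrix(0, n_all, n_trait)
  cost0[seq_len(n_tip), ] <- ifelse(tip_states == 0, 0, Inf)
  cost1[seq_len(n_tip), ] <- ifelse(tip_states == 1, 0, Inf)
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1L]; chl <- edges[e, 2L]
    cost0[par, ] <- cost0[par, ] + pmin(cost0[chl, ], cost1[chl, ] + 1)
    cost1[par, ] <- cost1[par, ] + pmin(cost1[chl, ], cost0[chl, ] + 1)
  }
  root <- n_tip + 1L
  list(cost0 = cost0, cost1 = cost1,
       score = pmin(cost0[root, ], cost1[root, ]))
}

as_tip_state_matrix <- function(tree, tip_states) {
  if (is.null(dim(tip_states)))
    tip_states <- matrix(tip_states, ncol = 1L,
                         dimnames = list(names(tip_states), "trait"))
  missing <- setdiff(tree$tip.label, rownames(tip_states))
  if (length(missing))
    stop("missing tip state(s) for: ", paste(missing, collapse = ", "))
  m <- tip_states[tree$tip.label, , drop = FALSE]
  if (!all(m %in% c(0, 1))) stop("tip states must be 0 or 1")
  m
}

#' Fitch/Sankoff parsimony pass for one binary trait
#'
#' Bottom-up unit-cost parsimony (Fitch on bifurcating trees, generalized to
#' multifurcations via Sankoff with unit transition costs). Returns, per
#' node, the set of states attaining the minimal subtree cost, and the
#' minimum number of state changes on the whole tree.
#'
#' @param tree A rooted [ape::phylo] tree (bifurcating or multifurcating).
#' @param tip_states Named 0/1 vector covering every tip label.
#' @return List with `state_sets` (nodes x 2 logical matrix, columns
#'   `"0"`/`"1"`, rownames from [node_names()]) and `score` (minimal change
#'   count).
#' @export
fitch_states <- function(tree, tip_states) {
  m <- as_tip_state_matrix(tree, tip_states)
  sk <- sankoff_costs(tree, m)
  mins <- pmin(sk$cost0[, 1L], sk$cost1[, 1L])
  sets <- cbind("0" = sk$cost0[, 1L] == mins, "1" = sk$cost1[, 1L] == mins)
  rownames(sets) <- node_names(tree)
  list(state_sets = sets, score = sk$score[1L], costs = sk)
}

# Top-down resolution shared by the single- and multi-trait paths.
# Assign each node the parent's state when it attains the node's minimal
# cost, else the node's unique minimal-cost state; root ties go to 1.
resolve_topdown <- function(tree, sk) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  n_trait <- ncol(sk$cost0)
  states <- matrix(NA_integer_, n_nodes_total(tree), n_trait)
  root_tie <- sk$cost0[root, ] == sk$cost1[root, ]
  if (any(root_tie))
    message(sum(root_tie), " trait(s) with a root-state tie resolved toward state 1 (active)")
  states[root, ] <- ifelse(sk$cost1[root, ] <= sk$cost0[root, ], 1L, 0L)
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in rev(seq_len(nrow(edges)))) {        # reverse postorder = preorder
    par <- edges[e, 1L]; chl <- edges[e, 2L]
    minc <- pmin(sk$cost0[chl, ], sk$cost1[chl, ])
    p <- states[par, ]
    parent_cost <- ifelse(p == 1L, sk$cost1[chl, ], sk$cost0[chl, ])
    states[chl, ] <- ifelse(parent_cost == minc, p, 1L - p)
  }
  rownames(states) <- node_names(tree)
  states
}

#' Resolve parsimony ambiguity into a single state per node
#'
#' Top-down pass over the result of [fitch_states()]: each node takes its
#' parent's state when that state lies in the node's minimal-cost set, else
#' its unique minimal-cost state; the root's tie (both states optimal) is
#' broken toward state 1 (active) and flagged. The resolved assignment
#' attains the parsimony score and places changes as close to the root as
#' the minimal-cost sets allow (ACCTRAN-style).
#'
#' @param tree A rooted [ape::phylo] tree.
#' @param fitch Result of [fitch_states()] on the same tree.
#' @return Named integer vector (0/1) over all nodes, names from
#'   [node_names()].
#' @export
resolve_states_acctran <- function(tree, fitch) {
  states <- resolve_topdown(tree, fitch$costs)
  stats::setNames(as.integer(states[, 1L]), rownames(states))
}

#' Count per-branch gains and losses over all traits
#'
#' For each edge, a gain is a parent-0 to child-1 transition of a trait's
#' resolved state, a loss the reverse.
#'
#' @param tree A rooted [ape::phylo] tree.
#' @param node_states (Ntip + Nnode) x n_trait matrix of resolved 0/1
#'   states, rows in ape node-number order (as returned by
#'   [reconstruct_trait_evolution()]).
#' @return data.frame, one row per edge: `parent`, `child` (node names),
#'   `gains`, `losses`.
#' @export
count_transitions <- function(tree, node_states) {
  if (is.null(dim(node_states))) node_states <- matrix(node_states, ncol = 1L)
  stopifnot(nrow(node_states) == n_nodes_total(tree))
  nm <- node_names(tree)
  P <- node_states[tree$edge[, 1L], , drop = FALSE]
  C <- node_states[tree$edge[, 2L], , drop = FALSE]
  data.frame(parent = nm[tree$edge[, 1L]], child = nm[tree$edge[, 2L]],
             gains = rowSums(P == 0L & C == 1L),
             losses = rowSums(P == 1L & C == 0L),
             row.names = NULL)
}

#' Per-branch state-change rates in changes per Myr
#'
#' `rate = (gains + losses) / branch length`; zero-length branches get `NA`
#' with a warning since the rate is undefined there.
#'
#' @param tree A rooted [ape::phylo] tree with branch lengths in Myr.
#' @param counts data.frame from [count_transitions()] (edge order must
#'   match `tree$edge`).
#' @return `counts` with `length_myr` and `rate` columns added.
#' @export
branch_change_rates <- function(tree, counts) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; cannot compute rates")
  stopifnot(nrow(counts) == nrow(tree$edge))
  counts$length_myr <- tree$edge.length
  counts$rate <- (counts$gains + counts$losses) / counts$length_myr
  if (any(tree$edge.length == 0)) {
    warning("zero-length branch(es): rate undefined, reported as NA")
    counts$rate[tree$edge.length == 0] <- NA_real_
  }
  counts
}

#' Parsimony reconstruction of binary OG activity across a species tree
#'
#' Runs the unit-cost parsimony pass and ACCTRAN-style resolution for every
#' OG of a tip activity matrix, then tallies per-branch gains, losses and
#' (when branch lengths exist) change rates per Myr.
#'
#' @param activity OG x species matrix of 0/1 tip states; column names must
#'   match the tree's tip labels.
#' @param tree A rooted [ape::phylo] tree, branch lengths in Myr.
#' @return List with `node_states` ((Ntip+Nnode) x OG matrix, rownames from
#'   [node_names()]), `scores` (per-OG parsimony score), `edges` (per-edge
#'   gains/losses and, if lengths exist, `length_myr` and `rate`), and
#'   `tree`.
#' @export
reconstruct_trait_evolution <- function(activity, tree) {
  stopifnot(is.matrix(activity))
  missing <- setdiff(tree$tip.label, colnames(activity))
  if (length(missing))
    stop("activity matrix lacks species: ", paste(missing, collapse = ", "))
  tips <- t(activity[, tree$tip.label, drop = FALSE])   # tips x OGs
  sk <- sankoff_costs(tree, tips)
  states <- resolve_topdown(tree, sk)
  colnames(states) <- rownames(activity)
  edges <- count_transitions(tree, states)
  if (!is.null(tree$edge.length)) edges <- branch_change_rates(tree, edges)
  list(node_states = states,
       scores = stats::setNames(sk$score, rownames(activity)),
       edges = edges, tree = tree)
}

#' OGs reconstructed as active at a given ancestral node
#'
#' @param activity OG x species 0/1 matrix (tips).
#' @param tree A rooted [ape::phylo] tree.
#' @param node Node reference accepted by [match_node()] (e.g. `"root"` or
#'   `"MRCA(oyster,human)"`).
#' @return Character vector of OG ids with resolved state 1 at the node.
#' @export
ancestral_active_set <- function(activity, tree, node) {
  idx <- match_node(tree, node)
  rec <- reconstruct_trait_evolution(activity, tree)
  rownames(activity)[rec$node_states[idx, ] == 1L]
}

#' Write trait-evolution outputs as plain-text tables
#'
#' Emits `node_states.tsv` (nodes x OGs), `edge_rates.tsv` (per-edge
#' gains/losses/rates) and `tree_rates.nwk` (input topology with rate labels
#' on internal nodes via [ape::write.tree()]).
#'
#' @param rec Result of [reconstruct_trait_evolution()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_trait_evolution <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(data.frame(node = rownames(rec$node_states),
                                rec$node_states, check.names = FALSE),
                     file.path(dir, "node_states.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rec$edges, file.path(dir, "edge_rates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- rec$tree
  if ("rate" %in% colnames(rec$edges)) {
    n_tip <- length(tr$tip.label)
    lab <- rep("", tr$Nnode)
    internal_children <- rec$tree$edge[, 2L] > n_tip
    lab[rec$tree$edge[internal_children, 2L] - n_tip] <-
      sprintf("rate=%.4g", rec$edges$rate[internal_children])
    tr$node.label <- lab
  }
  ape::write.tree(tr, file.path(dir, "tree_rates.nwk"))
  invisible(dir)
}
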