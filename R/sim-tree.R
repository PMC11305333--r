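# Random phylogenies with a planted number of independent, irreversible
# trait losses. The trait starts in state 1 (present) at the root; each
# loss event flips one edge 1 -> 0 and the whole clade below it; losses
# are placed so that no two loss clades are nested or jointly exhaust a
# larger clade, which makes the planted count exactly recoverable by
# Dollo parsimony.

# Leaf (tip) index sets below every node of an ape phylo, by postorder.
#' @noRd
node_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(po))) {
    parent <- po[k, 1]
    child <- po[k, 2]
    sets[[parent]] <- c(sets[[parent]], sets[[child]])
  }
  sets
}

#' Generate a random tree with a planted number of trait losses
#'
#' @param n_taxa number of tips (>= 3).
#' @param n_loss_events number of independent 1 -> 0 loss edges to plant.
#' @param seed integer seed.
#' @return list: `tree` (rooted binary `phylo`), `traits` (named 0/1
#'   vector over tip labels, 1 = trait present), `loss_edges` (edge
#'   indices carrying a loss).
#' @export
gen_tree_with_losses <- function(n_taxa, n_loss_events, seed = 1L) {
  if (n_taxa < 3L) stop("n_taxa must be >= 3")
  if (n_loss_events < 0L) stop("n_loss_events must be >= 0")
  with_seed(seed, {
    tree <- ape::rtree(n_taxa)
    tips <- node_tip_sets(tree)
    n_tip <- n_taxa
    edge_child <- tree$edge[, 2]
    # sibling edge of each edge (shares a parent)
    sibling_of <- vapply(seq_len(nrow(tree$edge)), function(e) {
      sib <- which(tree$edge[, 1] == tree$edge[e, 1])
      setdiff(sib, e)[1]
    }, numeric(1))
    zero <- integer(0)
    chosen <- integer(0)
    # greedy placement over a shuffled edge order can dead-end; retry
    # with fresh orders before declaring the request infeasible
    for (try in 1:200) {
      zero <- integer(0)
      chosen <- integer(0)
      for (e in sample.int(nrow(tree$edge))) {
        if (length(chosen) == n_loss_events) break
        leaves <- tips[[edge_child[e]]]
        if (length(intersect(leaves, zero)) > 0L) next
        sib_leaves <- tips[[edge_child[sibling_of[e]]]]
        if (all(sib_leaves %in% zero)) next
        chosen <- c(chosen, e)
        zero <- c(zero, leaves)
      }
      if (length(chosen) == n_loss_events) break
    }
    if (length(chosen) < n_loss_events) {
      stop("cannot place ", n_loss_events,
           " independent losses on this tree; use more taxa")
    }
    traits <- stats::setNames(rep(1L, n_tip), tree$tip.label)
    traits[tree$tip.label[zero]] <- 0L
    list(tree = tree, traits = traits, loss_edges = chosen)
  })
}
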