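# Comparative analyses: parsimony counts of independent trait losses on a
# phylogeny, distinct-allele lower bounds on independent origins, and
# collinear synteny chaining at a locus.

#' Minimum number of independent trait changes on a phylogeny
#'
#' `fitch` runs the standard two-pass small-parsimony count of state
#' changes for a binary character (changes in both directions allowed).
#' `dollo_loss` fixes the root in state 1 (trait present) and forbids
#' regain, so the minimum number of 1 -> 0 transitions equals the number
#' of maximal all-0 clades. Polytomies are resolved deterministically
#' (left-branching, by input order) before counting, so counts on
#' non-binary trees are lower bounds.
#'
#' @param tree a rooted `phylo`.
#' @param traits named 0/1 vector over all tip labels.
#' @param mode `"fitch"` or `"dollo_loss"`.
#' @return integer change count.
#' @export
min_independent_origins <- function(tree, traits,
                                    mode = c("fitch", "dollo_loss")) {
  mode <- match.arg(mode)
  if (!all(tree$tip.label %in% names(traits)))
    stop("missing trait state for: ",
         paste(setdiff(tree$tip.label, names(traits)), collapse = ", "))
  states <- traits[tree$tip.label]
  if (any(is.na(states)) || !all(states %in% c(0L, 1L)))
    stop("trait states must be 0 or 1 for every leaf")
  if (!ape::is.binary.phylo(tree)) tree <- ape::multi2di(tree, random = FALSE)
  n_tip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  if (mode == "fitch") {
    # state sets as 2-bit masks: bit 1 = state 0, bit 2 = state 1
    set <- integer(n_tip + tree$Nnode)
    set[seq_len(n_tip)] <- ifelse(states == 0L, 1L, 2L)
    changes <- 0L
    for (parent in unique(po[, 1])) {
      kids <- po[po[, 1] == parent, 2]
      s <- set[kids[1]]
      for (k in kids[-1]) {
        inter <- bitwAnd(s, set[k])
        if (inter == 0L) {
          s <- bitwOr(s, set[k])
          changes <- changes + 1L
        } else {
          s <- inter
        }
      }
      set[parent] <- s
    }
    changes
  } else {
    all0 <- logical(n_tip + tree$Nnode)
    all0[seq_len(n_tip)] <- states == 0L
    all0[(n_tip + 1L):(n_tip + tree$Nnode)] <- TRUE
    for (k in seq_len(nrow(po))) { # postorder: children final first
      all0[po[k, 1]] <- all0[po[k, 1]] && all0[po[k, 2]]
    }
    root <- n_tip + 1L
    parent_of <- integer(n_tip + tree$Nnode)
    parent_of[tree$edge[, 2]] <- tree$edge[, 1]
    sum(vapply(seq_len(n_tip + tree$Nnode), function(v) {
      all0[v] && (v == root || !all0[parent_of[v]])
    }, logical(1)))
  }
}

#' Count distinct loss alleles
#'
#' Allele descriptors are canonicalized as
#' `gene | effect_class | position`; with `collapse_shared = TRUE` an
#' identical descriptor observed in several species counts once (a
#' conservative lower bound on independent origins), otherwise each
#' (species, descriptor) observation counts.
#'
#' @param table data.frame with columns `species`, `gene`,
#'   `effect_class`, `position` (and optionally `shared_group`).
#' @param collapse_shared collapse identical descriptors across species.
#' @return integer allele count.
#' @export
count_distinct_alleles <- function(table, collapse_shared = TRUE) {
  need <- c("species", "gene", "effect_class", "position")
  if (!all(need %in% names(table)))
    stop("allele table needs columns: ", paste(need, collapse = ", "))
  tab <- table[need]
  if (nrow(tab) == 0L) stop("empty allele table")
  if (any(!stats::complete.cases(tab)))
    stop("malformed allele descriptor (missing fields)")
  desc <- paste(trimws(tab$gene), trimws(tab$effect_class),
                trimws(as.character(tab$position)), sep = "|")
  if (collapse_shared) {
    length(unique(desc))
  } else {
    nrow(unique(data.frame(species = tab$species, desc = desc)))
  }
}

# Longest strictly monotone subsequence (indices), O(n^2) DP; loci hold
# tens of anchors so quadratic is ample.
#' @noRd
longest_monotone_run <- function(x, decreasing = FALSE) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  if (decreasing) x <- -x
  len <- rep(1L, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (x[j] < x[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  at <- which.max(len)
  out <- integer(0)
  while (!is.na(at)) {
    out <- c(at, out)
    at <- prev[at]
  }
  out
}

#' Chain collinear anchors between two loci
#'
#' Maps anchor gene pairs to (index, index) positions in the two ordered
#' gene lists and extracts the maximal strictly collinear chain in each
#' orientation (longest increasing subsequence for `+`, decreasing for
#' `-`). Chains with at least `min_block` anchors are reported as blocks;
#' retention is the fraction of anchors captured in reported blocks.
#'
#' @param genes_a,genes_b character vectors of gene ids in coordinate
#'   order for each locus.
#' @param anchors data.frame with columns `gene_a`, `gene_b` (>= 1 row).
#' @param min_block minimum anchors per reported block (default 3).
#' @return list: `blocks` (data.frame `orientation`, `n_anchors`,
#'   `a_start`, `a_end`, `b_start`, `b_end`), `retention`,
#'   `n_anchors_total`, `chain_plus`, `chain_minus` (anchor row indices).
#' @export
synteny_chain <- function(genes_a, genes_b, anchors, min_block = 3L) {
  if (nrow(anchors) == 0L) stop("need at least one anchor pair")
  ia <- match(anchors$gene_a, genes_a)
  ib <- match(anchors$gene_b, genes_b)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(anchors$gene_a[is.na(ia)], anchors$gene_b[is.na(ib)]))
    stop("anchor references unknown gene(s): ",
         paste(bad, collapse = ", "))
  }
  ord <- order(ia)
  runs <- list(`+` = ord[longest_monotone_run(ib[ord])],
               `-` = ord[longest_monotone_run(ib[ord], decreasing = TRUE)])
  blocks <- do.call(rbind, lapply(names(runs), function(o) {
    run <- runs[[o]]
    if (length(run) < min_block) return(NULL)
    data.frame(orientation = o, n_anchors = length(run),
               a_start = min(ia[run]), a_end = max(ia[run]),
               b_start = min(ib[run]), b_end = max(ib[run]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(blocks)) {
    blocks <- data.frame(orientation = character(0),
                         n_anchors = integer(0), a_start = integer(0),
                         a_end = integer(0), b_start = integer(0),
                         b_end = integer(0))
  }
  chained <- unique(unlist(runs[vapply(runs, length, integer(1)) >=
                                  min_block]))
  list(blocks = blocks,
       retention = length(chained) / nrow(anchors),
       n_anchors_total = nrow(anchors),
       chain_plus = runs[["+"]], chain_minus = runs[["-"]])
}
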