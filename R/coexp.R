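# Cross-species co-expression conservation. Within each species a
# rank-standardized Spearman co-expression network is built; conservation
# of a gene pair across species is scored as the neighbor-voting AUROC:
# how well gene B's co-expression ranking in species B recovers the
# orthologs of gene A's top co-expression partners in species A.

#' Build a rank-standardized co-expression network
#'
#' Spearman correlation between all gene pairs, then each gene's row is
#' rank-standardized to (0, 1] (mid-rank ties), so network values are
#' comparable across genes and invariant to monotone transforms of
#' expression. Self-similarity is set to the row maximum. Genes with
#' constant expression are flagged and excluded from neighbor sets.
#'
#' @param expr numeric matrix, genes x samples, with gene ids as rownames
#'   (>= 3 samples).
#' @return gene x gene matrix in (0, 1] of class `coexp_network`;
#'   `attr(, "constant_genes")` lists excluded genes.
#' @export
build_network <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("need >= 3 samples")
  if (is.null(rownames(expr))) stop("expr must have gene ids as rownames")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids")
  const <- apply(expr, 1L, function(x) anyNA(x) ||
                   stats::var(x) == 0)
  n <- nrow(expr)
  rho <- matrix(NA_real_, n, n,
                dimnames = list(rownames(expr), rownames(expr)))
  if (any(!const)) {
    rho[!const, !const] <- stats::cor(t(expr[!const, , drop = FALSE]),
                                      method = "spearman")
  }
  net <- t(apply(rho, 1L, function(x) {
    if (all(is.na(x))) return(x)
    r <- rank(x, ties.method = "average", na.last = "keep")
    r / max(r, na.rm = TRUE)
  }))
  row_max <- apply(net, 1L, function(x) {
    if (all(is.na(x))) 0 else max(x, na.rm = TRUE)
  })
  diag(net) <- row_max
  net[is.na(net)] <- 0
  dimnames(net) <- dimnames(rho)
  structure(net, class = c("coexp_network", "matrix"),
            constant_genes = rownames(expr)[const])
}

#' @noRd
top_neighbors <- function(net, gene, k) {
  row <- net[gene, ]
  row <- row[names(row) != gene]
  excl <- attr(net, "constant_genes")
  if (length(excl) > 0L) row <- row[!names(row) %in% excl]
  # deterministic tie-break: value descending, then gene id
  ord <- order(-row, names(row))
  names(row)[ord[seq_len(min(k, length(row)))]]
}

#' Rank-sum (Mann-Whitney) AUROC
#'
#' AUROC of a score vector against a positive-label mask, computed from
#' mid-rank sums; ties contribute 1/2.
#'
#' @param scores numeric scores (higher = predicted positive).
#' @param positive logical mask, same length.
#' @return AUROC in `[0, 1]`, or `NA` if either class is empty.
#' @export
rank_sum_auroc <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Cross-species co-expression conservation AUROC for one gene pair
#'
#' Positives are the species-B orthologs of `geneA`'s top-`k`
#' co-expression neighbors in species A (`geneA` itself excluded;
#' neighbors without B-orthologs dropped; all B-orthologs of a neighbor
#' count). The candidate universe is every species-B gene with at least
#' one A-ortholog, minus `geneB`; candidates are ranked by `geneB`'s
#' network row and scored by rank-sum AUROC.
#'
#' @param netA,netB `coexp_network` matrices for species A and B.
#' @param orthology data.frame with columns `gene_a`, `gene_b`
#'   (many-to-many allowed).
#' @param geneA,geneB focal genes in species A and B.
#' @param k neighbor count (default 10).
#' @return list of class `conservation_score`: `gene_a`, `gene_b`,
#'   `auroc` (`NA` with a `reason` when undefined), `n_positives`,
#'   `n_candidates`, `k_used`.
#' @export
cross_species_auroc <- function(netA, netB, orthology, geneA, geneB,
                                k = 10L) {
  if (!geneA %in% rownames(netA)) stop("geneA not in netA: ", geneA)
  if (!geneB %in% rownames(netB)) stop("geneB not in netB: ", geneB)
  if (k < 1L) stop("k must be >= 1")
  res <- function(auroc, n_pos, n_cand, reason = NA_character_) {
    structure(list(gene_a = geneA, gene_b = geneB, auroc = auroc,
                   n_positives = n_pos, n_candidates = n_cand,
                   k_used = as.integer(k), reason = reason),
              class = "conservation_score")
  }
  candidates <- setdiff(intersect(unique(orthology$gene_b),
                                  rownames(netB)), geneB)
  if (length(candidates) == 0L)
    return(res(NA_real_, 0L, 0L, "no candidate genes with orthologs"))
  nb <- top_neighbors(netA, geneA, k)
  positives <- unique(orthology$gene_b[orthology$gene_a %in% nb])
  positives <- intersect(positives, candidates)
  if (length(positives) == 0L)
    return(res(NA_real_, 0L, length(candidates),
               "no neighbor has an ortholog among candidates"))
  scores <- netB[geneB, candidates]
  res(rank_sum_auroc(scores, candidates %in% positives),
      length(positives), length(candidates))
}

#' @export
print.conservation_score <- function(x, ...) {
  cat(sprintf("<conservation %s ~ %s: AUROC = %s (pos %d / cand %d, k=%d)%s>\n",
              x$gene_a, x$gene_b,
              ifelse(is.na(x$auroc), "NA", sprintf("%.3f", x$auroc)),
              x$n_positives, x$n_candidates, x$k_used,
              if (!is.na(x$reason)) paste0(" ", x$reason) else ""))
  invisible(x)
}

#' Conservation AUROC matrix for two gene families
#'
#' One [cross_species_auroc()] score per (family-A member, family-B
#' member) pair; undefined scores are `NA`.
#'
#' @inheritParams cross_species_auroc
#' @param familyA,familyB gene id vectors (non-empty).
#' @return numeric |familyA| x |familyB| matrix of AUROCs with the per-cell
#'   score objects in `attr(, "scores")`.
#' @export
family_auroc_matrix <- function(netA, netB, orthology, familyA, familyB,
                                k = 10L) {
  if (length(familyA) == 0L || length(familyB) == 0L)
    stop("families must be non-empty")
  scores <- list()
  m <- matrix(NA_real_, length(familyA), length(familyB),
              dimnames = list(familyA, familyB))
  for (a in familyA) {
    for (b in familyB) {
      s <- cross_species_auroc(netA, netB, orthology, a, b, k)
      m[a, b] <- s$auroc
      scores[[paste(a, b, sep = "~")]] <- s
    }
  }
  attr(m, "scores") <- scores
  m
}

#' Tissue-specificity (tau) scores
#'
#' Per-tissue mean expression is computed, log2(x + 1)-scaled, and scored
#' with the tau index: tau = sum(1 - x_i / max(x)) / (N - 1). tau is 0 for
#' uniform expression and 1 for single-tissue expression; all-zero genes
#' get `NA`.
#'
#' @param expr genes x samples matrix with rownames.
#' @param tissues character vector of tissue labels per sample (>= 2
#'   tissues, each >= 1 sample).
#' @return data.frame (`gene_id`, `tau`) with the per-tissue log-scaled
#'   mean matrix in `attr(, "tissue_means")`.
#' @export
tissue_specificity <- function(expr, tissues) {
  expr <- as.matrix(expr)
  if (length(tissues) != ncol(expr))
    stop("one tissue label per sample required")
  if (length(unique(tissues)) < 2L) stop("need >= 2 tissues")
  means <- sapply(unique(tissues), function(t) {
    rowMeans(expr[, tissues == t, drop = FALSE])
  })
  lm2 <- log2(means + 1)
  tau <- apply(lm2, 1L, function(x) {
    mx <- max(x)
    if (mx == 0) return(NA_real_)
    sum(1 - x / mx) / (length(x) - 1L)
  })
  out <- data.frame(gene_id = rownames(expr), tau = unname(tau),
                    stringsAsFactors = FALSE)
  attr(out, "tissue_means") <- lm2
  out
}
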