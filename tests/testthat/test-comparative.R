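test_that("parsimony counts are zero on an invariant trait", {
  tl <- gen_tree_with_losses(12, 0, seed = 301)
  expect_true(all(tl$traits == 1))
  expect_identical(min_independent_origins(tl$tree, tl$traits, "fitch"), 0L)
  expect_identical(min_independent_origins(tl$tree, tl$traits,
                                           "dollo_loss"), 0L)
})

test_that("fitch equals exhaustive ancestral-labeling minimization", {
  withr::local_seed(302)
  for (i in 1:30) {
    tree <- ape::rtree(8)
    traits <- stats::setNames(sample(0:1, 8, replace = TRUE),
                              tree$tip.label)
    expect_identical(min_independent_origins(tree, traits, "fitch"),
                     as.integer(brute_fitch(tree, traits)))
  }
})

test_that("dollo recovers planted loss counts exactly", {
  for (k in 0:6) {
    tl <- gen_tree_with_losses(24, k, seed = 310 + k)
    expect_identical(min_independent_origins(tl$tree, tl$traits,
                                             "dollo_loss"), k)
  }
  res <- dollo_recovery_experiment(n_trees = 20, seed = 311)
  expect_equal(res$exact_rate, 1)
  # infeasible event count
  expect_error(gen_tree_with_losses(4, 10, seed = 1), "cannot place")
})

test_that("dollo and fitch obey their parsimony inequalities", {
  withr::local_seed(303)
  for (i in 1:300) {
    tree <- ape::rtree(10)
    traits <- stats::setNames(sample(0:1, 10, replace = TRUE,
                                     prob = c(0.4, 0.6)), tree$tip.label)
    f <- min_independent_origins(tree, traits, "fitch")
    d <- min_independent_origins(tree, traits, "dollo_loss")
    expect_gte(d, f - 1L)
    expect_lte(d, sum(traits == 0))
    expect_lte(f, max(1L, sum(traits == 0)))
  }
})

test_that("trees and traits survive a Newick round trip", {
  tl <- gen_tree_with_losses(16, 3, seed = 321)
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tl$tree, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, tl$tree$tip.label)
  expect_identical(min_independent_origins(back, tl$traits, "dollo_loss"),
                   3L)
})

test_that("polytomies are resolved deterministically before counting", {
  tree <- ape::read.tree(text = "((a,b,c,d),(e,f));")
  traits <- c(a = 0, b = 0, c = 1, d = 1, e = 1, f = 1)
  expect_identical(min_independent_origins(tree, traits, "dollo_loss"),
                   min_independent_origins(tree, traits, "dollo_loss"))
  expect_error(min_independent_origins(tree, traits[-1], "fitch"),
               "missing trait state")
})

test_that("the packaged allele table lower-bounds independent losses at 16", {
  tab <- pl_allele_table()
  expect_identical(count_distinct_alleles(tab, collapse_shared = TRUE), 16L)
  expect_gt(count_distinct_alleles(tab, collapse_shared = FALSE), 16L)
  # the three shared-allele species pairs account for the difference
  expect_identical(count_distinct_alleles(tab, collapse_shared = FALSE),
                   19L)
})

test_that("allele counting collapses identical descriptors", {
  tab <- data.frame(species = c("sp1", "sp2", "sp3"), gene = "PL",
                    effect_class = "splice_donor", position = "i1+1G>A")
  expect_identical(count_distinct_alleles(tab, TRUE), 1L)
  expect_identical(count_distinct_alleles(tab, FALSE), 3L)
  expect_error(count_distinct_alleles(tab[0, ]), "empty")
  tab$position[2] <- NA
  expect_error(count_distinct_alleles(tab), "malformed")
})

test_that("synteny chains match brute-force monotone subsequences", {
  genes <- sprintf("g%02d", 1:10)
  anchors <- data.frame(gene_a = genes, gene_b = genes)
  ident <- synteny_chain(genes, genes, anchors)
  expect_identical(ident$blocks$orientation[1], "+")
  expect_identical(ident$blocks$n_anchors[1], 10L)
  expect_equal(ident$retention, 1)
  revd <- synteny_chain(genes, rev(genes), anchors)
  expect_identical(revd$blocks$orientation[which.max(revd$blocks$n_anchors)],
                   "-")
  expect_equal(revd$retention, 1)
  withr::local_seed(331)
  for (i in 1:15) {
    perm <- sample(genes)
    res <- synteny_chain(genes, perm, anchors, min_block = 1)
    ib <- match(anchors$gene_b, perm)
    expect_identical(length(res$chain_plus),
                     as.integer(brute_lis_len(ib)))
    expect_identical(length(res$chain_minus),
                     as.integer(brute_lis_len(ib, decreasing = TRUE)))
  }
  expect_error(synteny_chain(genes, genes,
                             data.frame(gene_a = "gX", gene_b = "g01")),
               "unknown gene")
})

test_that("synteny retention is invariant under joint relabeling", {
  genes <- sprintf("g%02d", 1:12)
  withr::local_seed(332)
  perm_b <- sample(genes)
  anchors <- data.frame(gene_a = genes, gene_b = genes)
  r1 <- synteny_chain(genes, perm_b, anchors)
  relabel <- stats::setNames(sprintf("x%02d", 1:12), genes)
  r2 <- synteny_chain(unname(relabel[genes]), unname(relabel[perm_b]),
                      data.frame(gene_a = unname(relabel[genes]),
                                 gene_b = unname(relabel[genes])))
  expect_equal(r2$retention, r1$retention)
})
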