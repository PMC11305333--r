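test_that("network values are rank-standardized and monotone-invariant", {
  withr::local_seed(201)
  expr <- matrix(rnorm(30 * 50), 30, 50,
                 dimnames = list(sprintf("g%02d", 1:30), NULL))
  net <- build_network(expr)
  expect_true(all(net >= 0 & net <= 1))
  # duplicated gene rows achieve the row maximum for each other
  expr2 <- rbind(expr, gdup = expr[1, ])
  net2 <- build_network(expr2)
  expect_equal(net2["g01", "gdup"], max(net2["g01", ]))
  # invariance to a monotone transform of expression
  net3 <- build_network(exp(expr))
  expect_equal(unclass(net3), unclass(net), ignore_attr = TRUE)
  # constant genes are flagged and never scored as neighbors
  expr3 <- rbind(expr, flat = rep(1, 50))
  net4 <- build_network(expr3)
  expect_identical(attr(net4, "constant_genes"), "flat")
  expect_error(build_network(expr[, 1:2]), "samples")
})

test_that("independent genes give uniform standardized values", {
  withr::local_seed(202)
  expr <- matrix(rnorm(40 * 1000), 40, 1000,
                 dimnames = list(sprintf("g%02d", 1:40), NULL))
  net <- build_network(expr)
  vals <- net[upper.tri(net)]
  ks <- suppressWarnings(stats::ks.test(vals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("rank-sum AUROC equals exhaustive pairwise counting", {
  withr::local_seed(203)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    scores <- sample(seq_len(40), n, replace = TRUE) # many ties
    positive <- seq_len(n) %in% sample.int(n, sample(1:10, 1))
    expect_equal(rank_sum_auroc(scores, positive),
                 brute_auroc(scores, positive))
  }
  expect_true(is.na(rank_sum_auroc(1:5, rep(TRUE, 5))))
})

test_that("identical species with identity orthology score AUROC 1", {
  withr::local_seed(204)
  expr <- matrix(rnorm(40 * 60), 40, 60,
                 dimnames = list(sprintf("g%02d", 1:40), NULL))
  net <- build_network(expr)
  orth <- data.frame(gene_a = rownames(expr), gene_b = rownames(expr))
  for (k in c(3, 10)) {
    s <- cross_species_auroc(net, net, orth, "g05", "g05", k = k)
    expect_equal(s$auroc, 1)
  }
})

test_that("conserved modules are recovered and permutation nulls are flat", {
  res <- coexp_conservation_experiment(
    seed = 211, n_pairs = 10, n_permutations = 30,
    config = expression_sim_config(n_genes_per_species = 100,
                                   n_samples = 200, n_modules = 8,
                                   rho = 1, noise_sd = 0.1,
                                   paralog_rate = 0, seed = 211))
  expect_gte(res$mean_conserved_auroc, 0.9)
  expect_lt(abs(res$perm_mean_auroc - 0.5), 0.06)
})

test_that("rho = 0 ortholog module agreement sits at chance", {
  sim <- gen_expression_pair(expression_sim_config(
    n_genes_per_species = 400, n_samples = 10, n_modules = 10, rho = 0,
    noise_sd = 0.5, paralog_rate = 0, seed = 221))
  agree <- mean(sim$truth$conserved)
  expect_lt(abs(agree - 0.1), 3 * sqrt(0.1 * 0.9 / 400))
  # rho = 1, no noise: within-module pairs correlate perfectly
  sim2 <- gen_expression_pair(expression_sim_config(
    n_genes_per_species = 20, n_samples = 30, n_modules = 4, rho = 1,
    noise_sd = 0, paralog_rate = 0, seed = 222))
  mods <- sim2$truth$module_a
  pair <- which(mods == mods[1])[1:2]
  rho_pair <- stats::cor(sim2$expr_a[pair[1], ], sim2$expr_a[pair[2], ],
                         method = "spearman")
  expect_equal(abs(rho_pair), 1)
  expect_false(anyNA(sim2$expr_a))
  expect_identical(dim(sim2$expr_a), c(20L, 30L))
  expect_error(expression_sim_config(n_modules = 0, rho = 0.5), "rho")
})

test_that("conservation AUROC rises monotonically with rho", {
  grid <- expand.grid(rho = c(0, 0.25, 0.5, 0.75, 1), seed = 1:4)
  aurocs <- mapply(function(rho, seed) {
    res <- coexp_conservation_experiment(
      seed = 230 + seed, n_pairs = 8, n_permutations = 0,
      config = expression_sim_config(n_genes_per_species = 60,
                                     n_samples = 120, n_modules = 6,
                                     rho = rho, noise_sd = 0.5,
                                     paralog_rate = 0, seed = 230 + seed))
    res$mean_conserved_auroc
  }, grid$rho, grid$seed)
  tr <- suppressWarnings(stats::cor.test(grid$rho, aurocs,
                                         method = "spearman",
                                         alternative = "greater"))
  expect_gt(tr$estimate, 0)
  expect_lt(tr$p.value, 0.01)
})

test_that("family matrices have the right shape and structure", {
  sim <- gen_expression_pair(expression_sim_config(
    n_genes_per_species = 60, n_samples = 150, n_modules = 6, rho = 1,
    noise_sd = 0.2, paralog_rate = 0, seed = 241))
  netA <- build_network(sim$expr_a)
  netB <- build_network(sim$expr_b)
  # pick three family members from distinct modules
  fam_idx <- match(1:3, sim$truth$module_a)
  famA <- sim$truth$gene_a[fam_idx]
  famB <- sim$truth$gene_b[fam_idx]
  m <- family_auroc_matrix(netA, netB, sim$orthology, famA, famB, k = 10)
  expect_identical(dim(m), c(3L, 3L))
  # each member's conserved partner is its row maximum
  for (i in 1:3) expect_identical(which.max(m[i, ]), c(i)[1] * 1L,
                                  ignore_attr = TRUE)
  # 1x1 family reduces to the single-pair score
  m1 <- family_auroc_matrix(netA, netB, sim$orthology, famA[1], famB[1])
  expect_equal(m1[1, 1],
               cross_species_auroc(netA, netB, sim$orthology, famA[1],
                                   famB[1])$auroc)
  expect_error(family_auroc_matrix(netA, netB, sim$orthology,
                                   character(0), famB), "non-empty")
})

test_that("scores are invariant to gene and sample permutations", {
  sim <- gen_expression_pair(expression_sim_config(
    n_genes_per_species = 50, n_samples = 80, n_modules = 5, rho = 1,
    noise_sd = 0.3, paralog_rate = 0, seed = 251))
  base <- cross_species_auroc(build_network(sim$expr_a),
                              build_network(sim$expr_b), sim$orthology,
                              "ga0001", "gb0001", k = 10)$auroc
  withr::local_seed(252)
  pa <- sim$expr_a[sample.int(50), sample.int(80)]
  pb <- sim$expr_b[sample.int(50), sample.int(80)]
  perm <- cross_species_auroc(build_network(pa), build_network(pb),
                              sim$orthology, "ga0001", "gb0001",
                              k = 10)$auroc
  expect_equal(perm, base)
})

test_that("tau matches its closed-form values", {
  expr <- rbind(flat = rep(5, 8),
                solo = c(9, 9, rep(0, 6)),
                half = c(7, 7, 7, 7, 0, 0, 0, 0),
                zero = rep(0, 8))
  tissues <- rep(c("root", "leaf", "flower", "fruit"), each = 2)
  ts <- tissue_specificity(expr, tissues)
  expect_equal(ts$tau[ts$gene_id == "flat"], 0)
  expect_equal(ts$tau[ts$gene_id == "solo"], 1)
  expect_equal(ts$tau[ts$gene_id == "half"], 2 / 3)
  expect_true(is.na(ts$tau[ts$gene_id == "zero"]))
  expect_error(tissue_specificity(expr, tissues[1:3]), "label")
  expect_error(tissue_specificity(expr, rep("root", 8)), "tissues")
})
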