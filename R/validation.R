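# Self-validation experiments: each function runs one of the package's
# generator -> method -> measure loops at a stated problem size and
# returns the measured operating characteristic (agreement rate, recovery
# rate, AUROC, model-selection rate). They are the backbone of the test
# suite and of scripts/acceptance.R.

#' Agreement between rule-based LOF calls and the translation oracle
#'
#' Generates a genome with gene models, injects `n_per_class` variants of
#' every effect class, classifies them, and compares the classifier's LOF
#' flag with [translation_lof_oracle()] (splice-site variants evaluated
#' through intron retention). Mismatches are returned, never silently
#' dropped.
#'
#' @param n_per_class variants per effect class (10 classes).
#' @param seed integer seed.
#' @param n_genes,chrom_len genome scale used for the experiment.
#' @return list: `agreement` (fraction), `n` (variants compared),
#'   `mismatches` (data.frame of disagreeing variants),
#'   `class_agreement` (fraction whose class matches the generator
#'   intent).
#' @export
lof_oracle_agreement <- function(n_per_class = 100L, seed = 1L,
                                 n_genes = 100L, chrom_len = 600000L) {
  genome <- gen_genome(2L, chrom_len, seed = seed)
  gg <- gen_gene_models(genome, n_genes, exon_count_range = c(4L, 7L),
                        exon_len_range = c(150L, 700L), seed = seed + 1L)
  spec <- stats::setNames(rep(n_per_class, length(variant_classes())),
                          variant_classes())
  iv <- inject_variants(gg$genome, gg$annotation, spec, seed = seed + 2L)
  eff <- classify_variants(gg$annotation, iv$variants, gg$genome)
  m <- merge(eff, iv$truth, by = "variant_id")
  oracle <- vapply(seq_len(nrow(m)), function(i) {
    v <- iv$variants[iv$variants$id == m$variant_id[i], , drop = FALSE]
    gid <- m$gene_id.y[i]
    if (is.na(gid)) return(FALSE) # intergenic: no gene, no protein effect
    translation_lof_oracle(gg$annotation[[gid]], gg$genome, v,
                           splice_intron = m$intron_index[i])
  }, logical(1))
  agree <- m$lof_flag == oracle
  intended <- sub("frameshift_indel", "frameshift", m$intended_class)
  list(agreement = mean(agree), n = nrow(m),
       mismatches = m[!agree, c("variant_id", "effect_class",
                                "intended_class", "lof_flag")],
       class_agreement = mean(intended == m$effect_class))
}

#' QTL recovery rate of the delta SNP-index mapper
#'
#' Repeatedly simulates an F2 bulked-segregant experiment with a
#' uniform-random causal position, maps it, and checks whether the
#' top-called interval covers the truth.
#'
#' @param n_runs simulation replicates.
#' @param seed integer seed.
#' @param chrom_len chromosome length (default 50 Mb).
#' @param n_high,n_low bulk sizes.
#' @param depth read depth per marker.
#' @param n_snps markers per chromosome.
#' @param alpha,min_run,merge_gap interval-calling parameters.
#' @return list: `recovery` (fraction of runs whose top interval covers
#'   the truth), `n_runs`, `median_width_mb` (median top-interval width),
#'   `runs` (per-run data.frame).
#' @export
bsa_recovery_experiment <- function(n_runs = 50L, seed = 1L,
                                    chrom_len = 5e7, n_high = 20L,
                                    n_low = 20L, depth = 50L,
                                    n_snps = 2000L, alpha = 0.01,
                                    min_run = 5L, merge_gap = 2L) {
  ci <- null_ci(depths = c(10, 20, 50, 100, 200), n_high = n_high,
                n_low = n_low, n_sim = 10000L, alpha = alpha,
                seed = seed)
  runs <- lapply(seq_len(n_runs), function(i) {
    s <- seed + 131L * i
    qtl <- with_seed(s, stats::runif(1, 0.02, 0.98)) * chrom_len
    counts <- gen_bsa_counts(chrom_len, qtl, n_high, n_low, depth,
                             n_snps, seed = s + 1L)
    snp <- compute_delta_index(counts)
    prof <- smooth_profile(snp)
    iv <- call_intervals(prof, ci, min_run, merge_gap)
    hit <- nrow(iv) > 0L && iv$start[1] <= qtl && iv$end[1] >= qtl
    data.frame(run = i, qtl = qtl, hit = hit,
               width = if (nrow(iv) > 0L) iv$end[1] - iv$start[1] else NA)
  })
  runs <- do.call(rbind, runs)
  list(recovery = mean(runs$hit), n_runs = n_runs,
       median_width_mb = stats::median(runs$width, na.rm = TRUE) / 1e6,
       runs = runs)
}

#' Co-expression conservation recovery and permutation null
#'
#' Simulates a fully conserved ortholog compendium (`rho = 1`), scores
#' ortholog pairs by cross-species neighbor-voting AUROC, and estimates
#' the null by permuting the orthology mapping.
#'
#' @param seed integer seed.
#' @param n_pairs ortholog pairs scored.
#' @param n_permutations orthology permutations for the null.
#' @param config an [expression_sim_config()]; default mirrors a strongly
#'   conserved compendium (rho = 1, noise_sd = 0.1, 500 samples).
#' @param k neighbor count.
#' @return list: `mean_conserved_auroc`, `conserved_aurocs`,
#'   `perm_mean_auroc`, `perm_aurocs`.
#' @export
coexp_conservation_experiment <- function(seed = 1L, n_pairs = 20L,
                                          n_permutations = 100L,
                                          config = NULL, k = 10L) {
  if (is.null(config)) {
    config <- expression_sim_config(n_genes_per_species = 200L,
                                    n_samples = 500L, n_modules = 10L,
                                    rho = 1, noise_sd = 0.1,
                                    paralog_rate = 0, seed = seed)
  }
  sim <- gen_expression_pair(config)
  netA <- build_network(sim$expr_a)
  netB <- build_network(sim$expr_b)
  pairs <- sim$truth[sim$truth$conserved & !sim$truth$is_paralog, ]
  pairs <- pairs[seq_len(min(n_pairs, nrow(pairs))), ]
  aurocs <- vapply(seq_len(nrow(pairs)), function(i) {
    cross_species_auroc(netA, netB, sim$orthology, pairs$gene_a[i],
                        pairs$gene_b[i], k = k)$auroc
  }, numeric(1))
  perm <- with_seed(seed + 1L, {
    vapply(seq_len(n_permutations), function(i) {
      orth <- sim$orthology
      orth$gene_b <- sample(orth$gene_b)
      cross_species_auroc(netA, netB, orth, pairs$gene_a[1],
                          pairs$gene_b[1], k = k)$auroc
    }, numeric(1))
  })
  list(mean_conserved_auroc = mean(aurocs, na.rm = TRUE),
       conserved_aurocs = aurocs,
       perm_mean_auroc = mean(perm, na.rm = TRUE), perm_aurocs = perm)
}

#' Phenotype-ratio model selection rate under duplicate-recessive truth
#'
#' Simulates F2 phenotype counts under a chosen true ratio and reports
#' how often [fit_segregation_model()] ranks the matching model first.
#'
#' @param n_seeds replicates.
#' @param n F2 individuals per replicate.
#' @param true_ratio length-2 ratio (default 9:7 duplicate recessive).
#' @param seed integer seed.
#' @return list: `selection_rate`, `n_seeds`, `selected` (labels).
#' @export
ratio_model_selection_experiment <- function(n_seeds = 100L, n = 10000L,
                                             true_ratio = c(9, 7),
                                             seed = 1L) {
  truth_label <- paste(true_ratio, collapse = ":")
  selected <- vapply(seq_len(n_seeds), function(i) {
    with_seed(seed + i, {
      absent <- stats::rbinom(1L, n, true_ratio[2] / sum(true_ratio))
      attr(fit_segregation_model(c(n - absent, absent)), "best")
    })
  }, character(1))
  list(selection_rate = mean(selected == truth_label), n_seeds = n_seeds,
       selected = selected)
}

#' Dollo loss-count recovery on planted trees
#'
#' Plants a known number of independent losses on random trees and checks
#' that Dollo parsimony returns the planted count exactly.
#'
#' @param n_trees replicates.
#' @param n_taxa tips per tree.
#' @param losses vector of planted loss counts cycled over replicates.
#' @param seed integer seed.
#' @return list: `exact_rate` (fraction recovered exactly), `n_trees`,
#'   `results` (data.frame planted vs recovered).
#' @export
dollo_recovery_experiment <- function(n_trees = 50L, n_taxa = 24L,
                                      losses = 1:6, seed = 1L) {
  res <- lapply(seq_len(n_trees), function(i) {
    k <- losses[((i - 1L) %% length(losses)) + 1L]
    tl <- gen_tree_with_losses(n_taxa, k, seed = seed + i)
    data.frame(planted = k,
               recovered = min_independent_origins(tl$tree, tl$traits,
                                                   "dollo_loss"))
  })
  res <- do.call(rbind, res)
  list(exact_rate = mean(res$planted == res$recovered),
       n_trees = n_trees, results = res)
}
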