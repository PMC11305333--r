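# Config-driven orchestration: simulate -> classify -> segregate -> map ->
# score conservation -> count losses, with every stage writing its outputs
# (and a small JSON summary) into a run directory. A single global seed
# fans out to per-stage child seeds by a fixed derivation
# (seed + 7919 * stage_index), so each stage is individually reproducible.

#' Default pipeline configuration
#'
#' Problem sizes are modest so a full run completes in seconds; every
#' value can be overridden via the `config` argument of [run_pipeline()]
#' or a YAML file with the same structure.
#'
#' @return nested named list of per-stage parameter blocks.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    genome = list(n_chrom = 2L, chrom_len = 300000L),
    genes = list(n_genes = 12L, exon_count_range = c(3L, 7L),
                 exon_len_range = c(150L, 600L),
                 intron_len_range = c(60L, 200L)),
    variants = list(spec = c(splice_donor = 3L, splice_acceptor = 3L,
                             frameshift_indel = 3L, stop_gained = 3L,
                             large_exonic_deletion = 2L,
                             inframe_indel = 3L, missense = 3L,
                             synonymous = 3L, intronic = 3L,
                             intergenic = 3L),
                    del_len = 474L, large_del_threshold = 50L),
    f2 = list(model = "single_recessive", n = 400L, distortion = 0,
              penetrance = 1),
    bsa = list(chrom_len = 5e7, qtl_position = 2.5e7, n_high_bulk = 20L,
               n_low_bulk = 20L, depth = 50L, n_snps = 2000L,
               map_rate = 2.5, min_depth = 10L, window = 2e6,
               step = 5e4, alpha = 0.01, n_sim = 2000L, min_run = 5L,
               merge_gap = 2L),
    coexp = list(n_genes_per_species = 150L, n_samples = 150L,
                 n_modules = 10L, rho = 1, noise_sd = 0.5,
                 paralog_rate = 0.05, k = 10L, n_pairs_scored = 5L),
    tree = list(n_taxa = 30L, n_loss_events = 5L)
  )
}

#' @noRd
merge_config <- function(user, defaults, path = "config") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown ", path, " key(s): ", paste(unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      merge_config(user[[k]], defaults[[k]], paste0(path, "$", k))
    } else user[[k]]
  }
  defaults
}

#' @noRd
stage_seed <- function(seed, stage_index) {
  as.integer(seed) + 7919L * as.integer(stage_index)
}

#' Run the full synthetic study end to end
#'
#' Stages, in dependency order: (1) simulate a genome, gene models and
#' truth-labelled variants; (2) classify the variants and measure
#' agreement with the generator truth; (3) simulate an F2 and run
#' co-segregation and phenotype-ratio model selection; (4) simulate bulk
#' counts and map the causal locus by delta SNP-index; (5) simulate a
#' paired expression compendium and score ortholog co-expression
#' conservation; (6) simulate a trait-mapped phylogeny and count losses
#' by Dollo and Fitch parsimony. Each stage writes its outputs and a
#' JSON summary under `out_dir`; a failure halts downstream stages. With
#' `resume = TRUE`, stages whose outputs already match the run MANIFEST
#' checksums are skipped.
#'
#' @param config nested list (see [default_config()]) or path to a YAML
#'   file; unknown keys are rejected.
#' @param out_dir run directory (created if needed).
#' @param resume skip stages whose outputs are already valid.
#' @return invisibly, the run report: list with `config`, `stages` (per
#'   stage summaries) and `out_dir`; also written to `summary.json`.
#' @export
run_pipeline <- function(config = NULL, out_dir, resume = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(config, default_config())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(out_dir, "config_resolved.yaml"))
  manifest_path <- file.path(out_dir, "MANIFEST.tsv")
  manifest <- if (file.exists(manifest_path)) {
    utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  } else data.frame(file = character(0), md5 = character(0))
  stage_done <- function(files) {
    resume && all(file.exists(file.path(out_dir, files))) &&
      all(vapply(files, function(f) {
        rec <- manifest$md5[manifest$file == f]
        length(rec) == 1L &&
          rec == unname(tools::md5sum(file.path(out_dir, f)))
      }, logical(1)))
  }
  stages <- list()
  run_stage <- function(name, files, fun) {
    if (stage_done(c(files, paste0("stage_", name, ".json")))) {
      message("stage ", name, ": outputs up to date, skipped")
      return(jsonlite::read_json(
        file.path(out_dir, paste0("stage_", name, ".json")),
        simplifyVector = TRUE))
    }
    summary <- tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    jsonlite::write_json(summary,
                         file.path(out_dir, paste0("stage_", name, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summary
  }
  path <- function(f) file.path(out_dir, f)

  stages$simulate <- run_stage("simulate",
    c("genome.fa", "genes.gff3", "variants.vcf", "variant_truth.tsv"),
    function() {
      s <- stage_seed(cfg$seed, 1L)
      genome <- gen_genome(cfg$genome$n_chrom, cfg$genome$chrom_len,
                           seed = s)
      gg <- gen_gene_models(genome, cfg$genes$n_genes,
                            cfg$genes$exon_count_range,
                            cfg$genes$exon_len_range,
                            cfg$genes$intron_len_range, seed = s + 1L)
      iv <- inject_variants(gg$genome, gg$annotation,
                            unlist(cfg$variants$spec), seed = s + 2L,
                            del_len = cfg$variants$del_len)
      write_fasta(gg$genome, path("genome.fa"))
      write_gff3(gg$annotation, path("genes.gff3"), seed = s)
      write_vcf(iv$variants, path("variants.vcf"), seed = s)
      write_tsv(iv$truth, path("variant_truth.tsv"), seed = s)
      list(n_genes = length(gg$annotation), n_variants = nrow(iv$variants),
           seed = s)
    })

  stages$classify <- run_stage("classify", c("effects.tsv"), function() {
    genome <- read_fasta(path("genome.fa"))
    annotation <- read_gff3(path("genes.gff3"))
    variants <- read_vcf(path("variants.vcf"))
    truth <- read_tsv(path("variant_truth.tsv"))
    eff <- classify_variants(annotation, variants, genome,
                             cfg$variants$large_del_threshold)
    write_tsv(eff, path("effects.tsv"))
    write_vcf(variants, path("variants_annotated.vcf"), effects = eff)
    m <- merge(eff, truth, by = "variant_id")
    intended <- sub("frameshift_indel", "frameshift", m$intended_class)
    list(n_classified = nrow(eff),
         class_agreement = mean(intended == m$effect_class),
         lof_agreement = mean(m$lof_flag == m$intended_lof))
  })

  stages$segregation <- run_stage("segregation", c("f2.tsv"), function() {
    s <- stage_seed(cfg$seed, 3L)
    pop <- gen_f2_population(cfg$f2$model, cfg$f2$n, cfg$f2$distortion,
                             cfg$f2$penetrance, seed = s)
    write_population(pop, path("f2.tsv"), seed = s)
    pop <- read_population(path("f2.tsv"))
    cs <- test_cosegregation(pop, "plA",
                             max_violations = if (cfg$f2$model ==
                               "duplicate_recessive") nrow(pop) else 0L)
    fit <- fit_segregation_model(pop)
    list(model = cfg$f2$model, n = nrow(pop),
         recessive_consistent = cs$recessive_consistent,
         n_violations = length(cs$violations),
         distortion_p = cs$distortion_result$p,
         best_ratio_model = attr(fit, "best"), seed = s)
  })

  stages$bsa <- run_stage("bsa",
    c("bsa_counts.tsv", "bsa_profile.tsv", "bsa_intervals.tsv"),
    function() {
      s <- stage_seed(cfg$seed, 4L)
      b <- cfg$bsa
      counts <- gen_bsa_counts(b$chrom_len, b$qtl_position, b$n_high_bulk,
                               b$n_low_bulk, b$depth, b$n_snps,
                               b$map_rate, seed = s)
      write_bsa_counts(counts, path("bsa_counts.tsv"), seed = s)
      counts <- read_bsa_counts(path("bsa_counts.tsv"))
      snp <- compute_delta_index(counts, b$min_depth)
      prof <- smooth_profile(snp, b$window, b$step)
      ci <- null_ci(depths = c(10, 20, 50, 100, 200),
                    n_high = b$n_high_bulk, n_low = b$n_low_bulk,
                    n_sim = b$n_sim, alpha = b$alpha, seed = s + 1L)
      band <- ci_at_depth(ci, prof$mean_depth)
      prof$ci_low <- band$ci_low
      prof$ci_high <- band$ci_high
      write_tsv(prof, path("bsa_profile.tsv"), seed = s)
      iv <- call_intervals(prof, ci, b$min_run, b$merge_gap)
      write_tsv(iv, path("bsa_intervals.tsv"), seed = s)
      recovered <- nrow(iv) > 0L && iv$start[1] <= b$qtl_position &&
        iv$end[1] >= b$qtl_position
      list(n_snps_used = nrow(snp), n_intervals = nrow(iv),
           qtl_position = b$qtl_position,
           top_interval = if (nrow(iv) > 0L)
             c(start = iv$start[1], end = iv$end[1]) else NULL,
           qtl_recovered = recovered, seed = s)
    })

  stages$coexp <- run_stage("coexp",
    c("expr_a.tsv", "expr_b.tsv", "orthology.tsv"), function() {
      s <- stage_seed(cfg$seed, 5L)
      cc <- cfg$coexp
      sim <- gen_expression_pair(expression_sim_config(
        cc$n_genes_per_species, cc$n_samples, cc$n_modules, cc$rho,
        cc$noise_sd, cc$paralog_rate, seed = s))
      write_expression(sim$expr_a, path("expr_a.tsv"), seed = s)
      write_expression(sim$expr_b, path("expr_b.tsv"), seed = s)
      write_tsv(sim$orthology, path("orthology.tsv"), seed = s)
      netA <- build_network(read_expression(path("expr_a.tsv")))
      netB <- build_network(read_expression(path("expr_b.tsv")))
      pairs <- sim$truth[sim$truth$conserved & !sim$truth$is_paralog, ]
      pairs <- utils::head(pairs, cc$n_pairs_scored)
      aurocs <- vapply(seq_len(nrow(pairs)), function(i) {
        cross_species_auroc(netA, netB, sim$orthology, pairs$gene_a[i],
                            pairs$gene_b[i], k = cc$k)$auroc
      }, numeric(1))
      list(n_pairs_scored = length(aurocs),
           mean_conserved_auroc = mean(aurocs, na.rm = TRUE), seed = s)
    })

  stages$losses <- run_stage("losses", c("tree.nwk", "traits.tsv"),
    function() {
      s <- stage_seed(cfg$seed, 6L)
      tl <- gen_tree_with_losses(cfg$tree$n_taxa, cfg$tree$n_loss_events,
                                 seed = s)
      ape::write.tree(tl$tree, path("tree.nwk"))
      write_tsv(data.frame(taxon = names(tl$traits),
                           state = unname(tl$traits)),
                path("traits.tsv"), seed = s)
      tree <- ape::read.tree(path("tree.nwk"))
      traits <- read_tsv(path("traits.tsv"))
      tr <- stats::setNames(traits$state, traits$taxon)
      list(n_taxa = cfg$tree$n_taxa,
           planted_losses = cfg$tree$n_loss_events,
           dollo_losses = min_independent_origins(tree, tr, "dollo_loss"),
           fitch_changes = min_independent_origins(tree, tr, "fitch"),
           seed = s)
    })

  report <- list(config = cfg, stages = stages, out_dir = out_dir)
  jsonlite::write_json(list(config = cfg, stages = stages),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- setdiff(list.files(out_dir), "MANIFEST.tsv")
  utils::write.table(
    data.frame(file = files,
               md5 = unname(tools::md5sum(file.path(out_dir, files)))),
    manifest_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}
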