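# Paired-species expression simulator with tunable co-expression
# conservation. A latent-factor model: genes belong to modules, samples
# draw one factor per module, and a gene's (log) expression is its
# loading times its module factor plus independent noise. Orthologs keep
# their module across species with probability rho; otherwise the
# species-2 member's module is redrawn uniformly, so module agreement
# falls to chance (1/n_modules) at rho = 0 and rises to 1 at rho = 1.

#' Configuration for the paired-expression simulator
#'
#' @param n_genes_per_species genes per species (before paralogs).
#' @param n_samples samples per species.
#' @param n_modules co-expression modules (<= n_genes; > 0 when rho > 0).
#' @param rho module-conservation probability in `[0, 1]`.
#' @param noise_sd independent noise standard deviation (>= 0) on the
#'   latent (log) scale.
#' @param paralog_rate probability that a species-2 gene is duplicated
#'   (the duplicate gets an independently drawn module).
#' @param seed integer seed.
#' @return validated config list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes_per_species = 200L,
                                  n_samples = 200L, n_modules = 10L,
                                  rho = 0.75, noise_sd = 0.5,
                                  paralog_rate = 0.05, seed = 1L) {
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_modules > n_genes_per_species)
    stop("n_modules must be <= n_genes_per_species")
  if (n_modules == 0L && rho > 0) stop("n_modules = 0 requires rho = 0")
  if (paralog_rate < 0 || paralog_rate > 1)
    stop("paralog_rate must be in [0, 1]")
  structure(list(n_genes_per_species = as.integer(n_genes_per_species),
                 n_samples = as.integer(n_samples),
                 n_modules = as.integer(n_modules), rho = rho,
                 noise_sd = noise_sd, paralog_rate = paralog_rate,
                 seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Generate a paired-species expression compendium with known conservation
#'
#' See [expression_sim_config()] for the model. Expression values are
#' exp(latent), hence nonnegative with rank structure identical to the
#' latent factors (the conservation machinery is Spearman-based, so only
#' ranks matter).
#'
#' @param config an `expression_sim_config`.
#' @return list: `expr_a`, `expr_b` (genes x samples matrices),
#'   `orthology` (data.frame `gene_a`, `gene_b`), `truth` (data.frame
#'   `gene_a`, `gene_b`, `module_a`, `module_b`, `conserved`,
#'   `is_paralog`).
#' @export
gen_expression_pair <- function(config = expression_sim_config()) {
  stopifnot(inherits(config, "expression_sim_config"))
  with_seed(config$seed, {
    n <- config$n_genes_per_species
    ns <- config$n_samples
    nm <- config$n_modules
    latent_expr <- function(fac, modules, loadings, ids) {
      latent <- loadings * fac[modules, , drop = FALSE] +
        matrix(stats::rnorm(length(modules) * ns, sd = config$noise_sd),
               length(modules), ns)
      expr <- exp(latent)
      rownames(expr) <- ids
      colnames(expr) <- colnames(fac)
      expr
    }
    fac_a <- matrix(stats::rnorm(nm * ns), nm, ns,
                    dimnames = list(NULL, sprintf("ga_s%04d", seq_len(ns))))
    fac_b <- matrix(stats::rnorm(nm * ns), nm, ns,
                    dimnames = list(NULL, sprintf("gb_s%04d", seq_len(ns))))
    mod_a <- rep_len(seq_len(nm), n)[sample.int(n)]
    load_a <- stats::runif(n, 0.6, 1.4)
    expr_a <- latent_expr(fac_a, mod_a, load_a,
                          sprintf("ga%04d", seq_len(n)))
    keep <- stats::runif(n) <= config$rho
    mod_b <- ifelse(keep, mod_a, sample.int(nm, n, replace = TRUE))
    load_b <- stats::runif(n, 0.6, 1.4)
    expr_b <- latent_expr(fac_b, mod_b, load_b,
                          sprintf("gb%04d", seq_len(n)))
    orthology <- data.frame(gene_a = rownames(expr_a),
                            gene_b = rownames(expr_b),
                            stringsAsFactors = FALSE)
    truth <- data.frame(orthology, module_a = mod_a, module_b = mod_b,
                        conserved = mod_a == mod_b, is_paralog = FALSE)
    # paralogs: duplicated species-2 genes with independent modules
    dup <- which(stats::runif(n) <= config$paralog_rate)
    if (length(dup) > 0L) {
      mod_p <- sample.int(nm, length(dup), replace = TRUE)
      load_p <- stats::runif(length(dup), 0.6, 1.4)
      # paralogs share species B's samples, hence its factor realizations
      expr_p <- latent_expr(fac_b, mod_p, load_p,
                            sprintf("gb%04d_p", dup))
      expr_b <- rbind(expr_b, expr_p)
      orthology <- rbind(orthology, data.frame(
        gene_a = sprintf("ga%04d", dup), gene_b = rownames(expr_p),
        stringsAsFactors = FALSE))
      truth <- rbind(truth, data.frame(
        gene_a = sprintf("ga%04d", dup), gene_b = rownames(expr_p),
        module_a = mod_a[dup], module_b = mod_p,
        conserved = mod_a[dup] == mod_p, is_paralog = TRUE))
    }
    list(expr_a = expr_a, expr_b = expr_b, orthology = orthology,
         truth = truth)
  })
}
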