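# Mendelian segregation statistics for F2 populations: goodness-of-fit to
# integer phenotype ratios, genotype-phenotype co-segregation under a
# recessive model, two-locus model selection, and segregation-distortion
# tests. All chi-square statistics are uncorrected Pearson statistics (no
# Yates continuity correction).

#' Upper-tail chi-square probability
#'
#' @param stat chi-square statistic (>= 0).
#' @param df degrees of freedom (>= 1).
#' @return upper-tail probability P(X2 >= stat).
#' @export
chisq_pvalue <- function(stat, df) {
  if (any(stat < 0)) stop("stat must be >= 0")
  if (any(df < 1)) stop("df must be >= 1")
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Chi-square goodness of fit to an integer ratio
#'
#' Pearson statistic against expected counts from an integer ratio (e.g.
#' `c(3, 1)` or `c(9, 7)`), without continuity correction.
#'
#' @param observed integer count vector.
#' @param expected_ratio positive ratio parts, same length as `observed`.
#' @param model_label optional label carried in the result.
#' @return list of class `segregation_test` with `statistic`, `df`, `p`,
#'   `observed`, `expected`, `model_label`.
#' @export
chisq_gof <- function(observed, expected_ratio, model_label = NULL) {
  if (length(observed) != length(expected_ratio))
    stop("observed and expected_ratio lengths differ")
  if (any(expected_ratio <= 0)) stop("ratio parts must be > 0")
  n <- sum(observed)
  if (n <= 0) stop("sum of observed counts must be > 0")
  expected <- n * expected_ratio / sum(expected_ratio)
  if (any(expected < 1))
    stop("expected count < 1 in some cell; pool categories before testing")
  statistic <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(statistic = statistic, df = df,
                 p = chisq_pvalue(statistic, df), observed = observed,
                 expected = expected,
                 model_label = model_label %||%
                   paste(expected_ratio, collapse = ":")),
            class = "segregation_test")
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(sprintf("<segregation test vs %s: X2 = %.3g, df = %d, p = %.3g>\n",
              x$model_label, x$statistic, x$df, x$p))
  invisible(x)
}

#' Genotype-phenotype co-segregation under a recessive model
#'
#' Checks that every trait-absent (mutant) individual is homozygous for
#' the mutant allele at the locus and every trait-present individual is
#' not, allowing up to `max_violations` exceptions (incomplete penetrance
#' or a second segregating locus). Also reports a 3:1 phenotype
#' goodness-of-fit and a 1:2:1 genotype segregation-distortion test.
#' Missing genotypes are excluded and counted.
#'
#' @param pop population data.frame as from [gen_f2_population()] or
#'   [read_population()].
#' @param locus locus name; genotypes are read from column
#'   `paste0("geno_", locus)`.
#' @param max_violations violation tolerance for the consistency verdict.
#' @return list: `recessive_consistent`, `violations` (ids), `n_missing`,
#'   `chi2_result` (phenotype vs 3:1), `distortion_result` (genotype vs
#'   1:2:1).
#' @export
test_cosegregation <- function(pop, locus, max_violations = 0L) {
  col <- paste0("geno_", locus)
  if (!col %in% names(pop)) stop("locus not present: ", locus)
  g <- pop[[col]]
  keep <- !is.na(g) & g != "missing"
  if (!any(keep)) stop("all genotypes missing at locus ", locus)
  n_missing <- sum(!keep)
  g <- g[keep]
  ph <- pop$phenotype[keep]
  bad <- (ph == "trait_absent" & g != "hom_alt") |
    (ph == "trait_present" & g == "hom_alt")
  counts <- c(sum(g == "hom_ref"), sum(g == "het"), sum(g == "hom_alt"))
  ph_counts <- c(sum(ph == "trait_present"), sum(ph == "trait_absent"))
  list(recessive_consistent = sum(bad) <= max_violations,
       violations = pop$id[keep][bad],
       n_missing = n_missing,
       chi2_result = chisq_gof(ph_counts, c(3, 1),
                               model_label = "3:1 phenotype"),
       distortion_result = chisq_gof(counts, c(1, 2, 1),
                                     model_label = "1:2:1 genotype"))
}

# Candidate F2 phenotype-ratio models (trait_present : trait_absent) and
# the number of loci each implies.
#' @noRd
segregation_models <- function() {
  list(`3:1` = list(ratio = c(3, 1), loci = 1L),
       `9:7` = list(ratio = c(9, 7), loci = 2L),
       `13:3` = list(ratio = c(13, 3), loci = 2L),
       `15:1` = list(ratio = c(15, 1), loci = 2L))
}

#' Rank Mendelian phenotype-ratio models for an F2
#'
#' Fits the phenotype counts against the classical one- and two-locus F2
#' ratios (3:1 single recessive; 9:7 duplicate recessive; 13:3; 15:1) and
#' ranks them by goodness-of-fit p-value, ties broken toward fewer loci.
#'
#' @param pop population data.frame with a `phenotype` column, or a
#'   length-2 count vector `c(trait_present, trait_absent)`.
#' @return data.frame (one row per model, best first) with `model`,
#'   `statistic`, `df`, `p`, `loci`; the best model label is in
#'   `attr(, "best")`.
#' @export
fit_segregation_model <- function(pop) {
  counts <- if (is.data.frame(pop)) {
    c(sum(pop$phenotype == "trait_present"),
      sum(pop$phenotype == "trait_absent"))
  } else as.numeric(pop)
  if (sum(counts) < 16) stop("need at least 16 individuals")
  models <- segregation_models()
  rows <- lapply(names(models), function(m) {
    fit <- chisq_gof(counts, models[[m]]$ratio, model_label = m)
    data.frame(model = m, statistic = fit$statistic, df = fit$df,
               p = fit$p, loci = models[[m]]$loci,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$p, out$loci, seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "best") <- out$model[1]
  out
}
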