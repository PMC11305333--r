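# F2 population and bulked-segregant count simulators. Genetics: a
# recessive trait-loss allele at one locus (single_recessive) or at either
# of two unlinked loci (duplicate_recessive, the 9:7 epistasis model).

#' @noRd
haldane_r <- function(d_cM) {
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' Simulate an F2 population for a recessive trait loss
#'
#' Genotypes are drawn 1:2:1 per locus (before distortion); the phenotype
#' is `trait_absent` (mutant) iff the individual is homozygous mutant at
#' the causal locus (`single_recessive`) or at either of two unlinked loci
#' (`duplicate_recessive`), thinned by `penetrance`. Segregation
#' distortion is modelled as additive selection against the mutant allele:
#' genotype weights (1, 1 - s/2, 1 - s) for (hom_ref, het, hom_alt).
#'
#' @param model `"single_recessive"` or `"duplicate_recessive"`.
#' @param n number of F2 individuals.
#' @param distortion selection coefficient s in `[0, 1)` per locus.
#' @param penetrance probability in `(0, 1]` that a genetically mutant
#'   individual expresses the mutant phenotype.
#' @param seed integer seed.
#' @return data.frame (`id`, `geno_plA` [, `geno_plB`], `phenotype`), the
#'   genotype columns in `{hom_ref, het, hom_alt}` and phenotype in
#'   `{trait_present, trait_absent}`.
#' @export
gen_f2_population <- function(model = c("single_recessive",
                                        "duplicate_recessive"),
                              n, distortion = 0, penetrance = 1,
                              seed = 1L) {
  model <- match.arg(model)
  if (n < 1L) stop("n must be >= 1")
  if (penetrance <= 0 || penetrance > 1)
    stop("penetrance must be in (0, 1]")
  if (distortion < 0 || distortion >= 1)
    stop("distortion must be in [0, 1)")
  with_seed(seed, {
    geno_levels <- c("hom_ref", "het", "hom_alt")
    w <- c(1, 2, 1) * c(1, 1 - distortion / 2, 1 - distortion)
    draw <- function() {
      sample(geno_levels, n, replace = TRUE, prob = w / sum(w))
    }
    gA <- draw()
    pop <- data.frame(id = sprintf("F2_%05d", seq_len(n)), geno_plA = gA,
                      stringsAsFactors = FALSE)
    mutant <- gA == "hom_alt"
    if (model == "duplicate_recessive") {
      gB <- draw()
      pop$geno_plB <- gB
      mutant <- mutant | gB == "hom_alt"
    }
    expressed <- mutant & stats::runif(n) <= penetrance
    pop$phenotype <- ifelse(expressed, "trait_absent", "trait_present")
    pop
  })
}

#' Simulate bulk allele-depth counts around a causal locus
#'
#' Emulates a QTL-seq (mapping-by-sequencing) experiment on an F2: the
#' high bulk pools phenotype-mutant individuals (homozygous mutant at the
#' QTL), the low bulk pools wild-phenotype individuals (drawn 1/3 AA : 2/3
#' Aa at the QTL). At a marker with recombination fraction r from the QTL
#' (Haldane transform of the map distance), each gamete carries the
#' mutant-parent allele with probability 1 - r when the gamete's QTL
#' allele is mutant, and r otherwise. Read counts are binomial draws at
#' the realized bulk allele frequency. Markers are sampled independently
#' given the QTL genotypes (no marker-marker linkage beyond the QTL).
#'
#' @param chrom_len chromosome length (bp).
#' @param qtl_position causal position (bp), or `NA` for a null simulation
#'   with no causal locus (all markers unlinked, r = 1/2).
#' @param n_high_bulk,n_low_bulk individuals per bulk.
#' @param depth mean read depth per marker per bulk.
#' @param n_snps number of markers (uniform random positions).
#' @param map_rate recombination map rate in cM/Mb.
#' @param seed integer seed.
#' @param chrom chromosome name for the output table.
#' @return data.frame (`chrom`, `pos`, `ref_depth_high`, `alt_depth_high`,
#'   `ref_depth_low`, `alt_depth_low`), alt = mutant-parent allele, sorted
#'   by position.
#' @export
gen_bsa_counts <- function(chrom_len, qtl_position, n_high_bulk = 20L,
                           n_low_bulk = 20L, depth = 50L, n_snps = 2000L,
                           map_rate = 2.5, seed = 1L, chrom = "chr1") {
  if (!is.na(qtl_position) &&
      (qtl_position < 1 || qtl_position > chrom_len))
    stop("qtl_position outside chromosome")
  if (depth < 1L) stop("depth must be >= 1")
  with_seed(seed, {
    pos <- sort(sample.int(chrom_len, n_snps))
    r <- if (is.na(qtl_position)) rep(0.5, n_snps)
      else haldane_r(abs(pos - qtl_position) / 1e6 * map_rate)
    nh2 <- 2L * n_high_bulk
    # high bulk: all gametes carry the mutant QTL allele
    alt_h <- stats::rbinom(n_snps, nh2, 1 - r)
    p_high <- alt_h / nh2
    # low bulk: individuals AA w.p. 1/3, Aa w.p. 2/3; count mutant (a-)
    # gametes: an A gamete transmits the mutant-parent marker w.p. r, an
    # a gamete w.p. 1 - r
    n_het <- stats::rbinom(1L, n_low_bulk, 2 / 3)
    n_AA <- n_low_bulk - n_het
    alt_l <- stats::rbinom(n_snps, 2L * n_AA, r) +          # AA gametes
      stats::rbinom(n_snps, n_het, r) +                      # Aa: A gamete
      stats::rbinom(n_snps, n_het, 1 - r)                    # Aa: a gamete
    p_low <- alt_l / (2L * n_low_bulk)
    alt_dh <- stats::rbinom(n_snps, depth, p_high)
    alt_dl <- stats::rbinom(n_snps, depth, p_low)
    data.frame(chrom = chrom, pos = pos,
               ref_depth_high = depth - alt_dh, alt_depth_high = alt_dh,
               ref_depth_low = depth - alt_dl, alt_depth_low = alt_dl,
               stringsAsFactors = FALSE)
  })
}
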