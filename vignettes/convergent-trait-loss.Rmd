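---
title: "Methods: dissecting convergent trait loss with convloss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting convergent trait loss with convloss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convloss)
```

# The problem

A binary morphological trait — the motivating case is plant prickles,
sharp epidermal outgrowths lost repeatedly in cultivated and wild
nightshades — can be abolished by independent loss-of-function (LOF)
mutations in a single co-opted gene. Dissecting such a system requires a
chain of analyses: classifying candidate variants against gene models,
testing genotype–phenotype co-segregation in crosses, mapping additional
loci by bulked-segregant sequencing, asking whether the gene's
co-expression context is conserved between species, and counting how many
times the trait was lost on a phylogeny. `convloss` implements this chain
and, because the real data behind any particular study are large and
partly inaccessible, pairs every analysis with a generator that simulates
its inputs with known ground truth. The test suite and the acceptance
script run the methods against that truth.

# Coordinates and file formats

All intervals are stored 1-based and closed, the native convention of R
and Bioconductor (IRanges, GFF3, VCF), so coordinates written to GFF3 and
VCF are emitted unchanged; VCF indels use the anchored-base convention and
are left-aligned before classification (`left_align_variant()`), the
standard normalization that removes representational ambiguity in
repetitive sequence. FASTA I/O goes through Biostrings, GFF3 parsing
through rtracklayer, VCF parsing through vcfR, and trees through ape.

# Variant-effect classification and its oracle

`classify_variant()` is a first-match-wins cascade:

1. an SNV or indel altering the first two (donor, GT) or last two
   (acceptor, AG) bases of an intron is a splice-site LOF — canonical
   sites only; a hit on a non-canonical annotated site is flagged
   `noncanonical_site` and is never automatically LOF, since splice
   disruption cannot be asserted for a site that was not spliceable to
   begin with;
2. a deletion removing at least `large_del_threshold` coding bp (default
   50) or a complete coding exon is a `large_exonic_deletion`, LOF
   regardless of frame — an in-frame deletion of dozens of codons is
   still expected to destroy the protein, which is why frame logic alone
   is insufficient;
3. remaining CDS indels are `frameshift` (net coding change not divisible
   by 3; LOF) or `inframe_indel` (divisible; not LOF);
4. CDS substitutions are resolved by codon comparison: `stop_gained` is
   LOF only when at least 10% of the protein is truncated (a declared,
   test-visible threshold; no nonsense-mediated-decay rule is attempted),
   `start_lost` is LOF, `stop_lost`, `missense` and `synonymous` are not;
5. anything else is `utr`, `intronic`, or `intergenic`.

The classifier is validated against an independent functional oracle:
apply the variant to the genome, re-splice the exons (coordinates mapped
through indels), translate from the annotated start, and call the variant
deleterious when the mutant protein is shorter than 90% of wild type or
its first residue is destroyed. Splice-site variants are evaluated by
retaining the affected intron (`simulate_missplice()`), because a broken
canonical site prevents that splicing event; the retained intron either
shifts the frame or inserts residues until an in-frame stop. The
acceptance suite requires ≥ 99% LOF agreement between cascade and oracle
over 1,000 generated variants spanning all ten effect classes.

# What the genome generator emulates — and what it does not

`gen_genome()` draws uniform A/C/G/T sequence; `gen_gene_models()` writes
multi-exon genes into it whose CDS begins with ATG, ends with a stop,
contains no internal in-frame stop, and whose introns are canonical
GT..AG on the transcription strand, on both strands. Two deliberate
design choices keep generator truth and oracle verdicts coherent:

* **Introns carry an early stop cassette.** Immediately after the GT
  donor each intron contains an 11-mer with a stop codon in all three
  frames. Real introns almost always contain stops near the donor; making
  it certain means intron retention always truncates, so a splice-site
  variant's intended LOF label is unambiguous.
* **Truncating variants are placed 5′.** Splice, frameshift and
  stop-gained variants are injected within the first 70% of the CDS
  (stop-gained within the first 85% of codons), and large exonic
  deletions only into genes where the deletion removes ≥ 12% of the CDS.
  A frameshift in the last few codons of a gene is biologically ambiguous
  (the oracle would call it benign); the generator does not manufacture
  such borderline cases, it manufactures clear instances of each intended
  class. Consequently the measured cascade/oracle agreement demonstrates
  that both machineries implement the same biology on unambiguous
  variants; it does not measure how often real 3′-terminal variants are
  benign.

The generator does not model repeats, GC heterogeneity, UTRs (the
classifier supports them; generated genes are fully coding), alternative
transcripts, or sequencing reads.

# Segregation statistics

All χ² statistics are uncorrected Pearson goodness-of-fit statistics
(`chisq_gof()`), with tail probabilities from the exact χ² distribution
(`chisq_pvalue()`, equal to `erfc(sqrt(x/2))` at 1 df); no Yates
correction is applied anywhere, matching how such F2 counts are normally
tested. Expected cells below 1 are an error advising pooling.
`fit_segregation_model()` scans the classical one- and two-locus F2
phenotype ratios (3:1, 9:7, 13:3, 15:1) and ranks by p-value, breaking
ties toward fewer loci. The duplicate-recessive (9:7) model — homozygous
mutant at either of two unlinked loci abolishes the trait — is the
minimal two-locus epistasis consistent with a second unlinked recessive
locus producing the same phenotype. `gen_f2_population()` draws 1:2:1
genotypes, models segregation distortion as additive selection against
the mutant allele (weights 1, 1−s/2, 1−s), and thins mutant phenotypes by
a penetrance parameter. Missing genotypes are excluded pairwise and
counted, never imputed.

# Bulked-segregant Δ SNP-index mapping

The high bulk pools phenotype-mutant F2 individuals (homozygous mutant at
the causal locus), the low bulk pools wild-phenotype individuals (1/3 AA
: 2/3 Aa). At a marker with recombination fraction *r* from the locus —
Haldane map function, r = (1 − e^(−2d/100))/2 with d in cM at a default
2.5 cM/Mb — each gamete transmits the mutant-parent allele with
probability 1−r (mutant gamete) or r (wild gamete); reads are binomial at
the realized bulk frequency. The expected Δ SNP-index at the locus is
1 − 1/3 = 2/3, decaying as (2/3)(1 − 2r). Markers are sampled
independently given the QTL genotypes; marker–marker linkage beyond the
shared QTL is not modelled, which leaves window-to-window noise slightly
less correlated than in real data.

Analysis defaults: minimum per-bulk depth 10, 2 Mb windows stepped by
50 kb (unweighted SNP means — depth already gates inclusion), α = 0.01
simulation null band tabulated against depth (unselected 1:2:1 bulks,
≥ 1,000 replicates, band symmetric about 0), intervals called from runs
of ≥ 5 consecutive windows above the upper band with gaps ≤ 2 windows
merged. The run-length requirement provides the family-wise control that
a per-SNP band alone would not; on null simulations, 100 seeded runs call
zero intervals ≥ 95% of the time. These defaults are configurable; no
attempt is made to reproduce any particular study's interval boundaries,
whose bulk sizes and depths are unstated. The fixture choice of 20+20
individuals and depth 50 is a realistic desk-scale experiment, and at
that scale the top called interval covers the true locus in ≥ 90% of 50
seeded 50 Mb simulations (median width ≈ 20 Mb — wide, as expected for
small bulks at moderate depth).

# Co-expression conservation

Within each species, `build_network()` computes Spearman correlations
between all gene pairs — rank-based, hence invariant to monotone
transforms and robust across heterogeneous meta-analysis samples — and
rank-standardizes each gene's row to (0, 1] with mid-rank ties; self
similarity is the row maximum and constant genes are excluded from
neighbor sets. `cross_species_auroc()` then asks: taking gene A's top-k
co-expression partners in species A (k = 10 by default; ties broken by
value then gene id, deterministically), mapping them through the ortholog
table (many-to-many pairs expand the positive set), how highly does gene
B's own network row rank them among all species-B genes that have
orthologs? The restriction of the candidate universe to genes with
orthologs keeps the comparison like-with-like. The score is the
Mann–Whitney rank-sum AUROC with mid-rank ties; an empty positive set
yields an explicit `NA` with a reason, never a silent 0.5.

The paired-expression generator is a latent-factor model: each gene
belongs to one module, samples draw one factor per module, and log
expression is loading × factor + N(0, noise_sd²). An ortholog keeps its
module across species with probability ρ; otherwise its species-2 module
is redrawn **uniformly over all modules**, so module agreement is
ρ + (1−ρ)/n_modules — chance level 1/n_modules at ρ = 0 and 1 at ρ = 1.
(Redrawing from the *other* modules only would drive agreement to zero at
ρ = 0 rather than to chance; the uniform redraw is the declared choice.)
Paralogs are duplicated species-2 genes sharing the species' factor
realizations with an independently drawn module. A single pooled network
per species is built; per-study aggregation across heterogeneous
compendia is a documented alternative this package does not implement.
At ρ = 1 with 200 genes, 10 modules, 500 samples and noise 0.1, conserved
ortholog pairs score mean AUROC ≈ 0.97, and permuting the orthology
collapses scores to 0.5 — the synthetic analogue of a strongly conserved
co-expression signal.

Tissue specificity uses the standard τ index on log2(x+1)-scaled
per-tissue means: τ = Σ(1 − x_i/max x)/(N−1), 0 for uniform and 1 for
single-tissue expression; all-zero genes are `NA` with a reason.

# Parsimony loss counting and synteny

`min_independent_origins()` implements Fitch small parsimony (two-pass
set operations; both change directions allowed) and a Dollo loss count:
with the root fixed in the ancestral trait-present state and regain
forbidden, the minimum number of losses is the number of maximal all-loss
clades. Polytomies are resolved deterministically (left-branching by
input order) before counting, so counts on non-binary trees are lower
bounds. The tree generator plants losses on edges chosen so that no two
loss clades are nested and no two jointly exhaust a larger clade — the
condition under which Dollo counting recovers the planted number exactly,
which the tests assert, alongside brute-force enumeration of all
ancestral labelings as the Fitch oracle on 8-taxon trees.

`count_distinct_alleles()` canonicalizes allele descriptors as
(gene, effect class, position key); collapsing identical descriptors
across species gives a conservative lower bound on independent origins
(identical alleles may be identical by descent or by recurrent mutation —
the bound does not need to decide). The packaged survey table
(`pl_allele_table()`) is a synthetic reconstruction encoding 16 distinct
deleterious alleles observed 19 times across species, three alleles
shared by species pairs; collapsed counting yields 16. Positions and most
species names in it are placeholders — the counts and sharing structure
are the data.

`synteny_chain()` maps anchor gene pairs to index pairs in two ordered
loci and extracts the maximal strictly collinear chain per orientation by
longest increasing (or decreasing) subsequence; blocks need ≥ 3 anchors
by default, and retention is the fraction of anchors chained.

# Orchestration and reproducibility

`run_pipeline()` runs simulate → classify → segregate → map → score
conservation → count losses from a nested config (YAML or list; unknown
keys rejected), writing per-stage outputs, a resolved config, a
checksummed MANIFEST, and a `summary.json` that is byte-identical across
runs with the same seed. A single global seed fans out to stage seeds by
a fixed derivation (seed + 7919 × stage index). Every generator restores
the caller's RNG state, so generators are pure functions of their seeds.
Stage failures halt downstream stages with the failing stage named;
`resume = TRUE` skips stages whose outputs still match the manifest.

# Problem sizes used in validation

The shipped validation experiments (`lof_oracle_agreement()`,
`bsa_recovery_experiment()`, `coexp_conservation_experiment()`,
`ratio_model_selection_experiment()`, `dollo_recovery_experiment()`) use:
1,000 variants (100 per class) on a 2 × 600 kb genome with 100 genes; 50
bulked-segregant simulations on 50 Mb chromosomes (bulks 20+20, depth 50,
2,000 markers); 200-gene × 500-sample expression pairs with 100 orthology
permutations; 100 simulated F2s of n = 10,000 for model selection; and 50
planted-loss trees of 24 taxa. These sizes give the operating
characteristics stable second digits while keeping a full validation run
in the tens of seconds; all are arguments, not constants.

# Known limitations

* One transcript per gene; no UTR-aware splice variants in generated
  data; no splice-strength or NMD modelling.
* The BSA simulator has no marker–marker linkage beyond the causal locus
  and a single population type (F2); no G′-type alternatives or
  depth-weighted smoothing.
* Conservation scores use a single pooled network per species and one
  neighbor count k; aggregation over many studies is out of scope.
* Dollo counting assumes the trait was ancestrally present and
  irreversibly lost; where regain is plausible, use the Fitch mode and
  read both as lower bounds.
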