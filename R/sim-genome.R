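# Synthetic genome and gene-model generation. These generators produce the
# coordinate frame that the variant classifier and the bulked-segregant
# simulators operate on, with ground truth known by construction.

#' Generate a random genome
#'
#' Chromosome sequences are uniform random draws over A/C/G/T, so base
#' composition is ~25% each and there is no repeat structure. Deterministic
#' for a fixed seed.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length in bp (>= 10 kb).
#' @param seed integer seed.
#' @return named character vector of class `sim_genome`
#'   (`chr1`, `chr2`, ...).
#' @export
gen_genome <- function(n_chrom, chrom_len, seed) {
  if (n_chrom < 1L) stop("n_chrom must be >= 1")
  if (chrom_len < 10000L) stop("chrom_len must be >= 10 kb")
  with_seed(seed, {
    g <- vapply(seq_len(n_chrom), function(i) rand_dna(chrom_len),
                character(1))
    names(g) <- paste0("chr", seq_len(n_chrom))
    structure(g, class = "sim_genome", seed = as.integer(seed))
  })
}

# Intron body: canonical GT..AG with an early stop-in-all-frames cassette.
# Real introns almost always contain stop codons close to the splice donor
# in every frame; planting one guarantees that intron retention truncates
# the protein, which keeps the intent of splice-site variants unambiguous.
.INTRON_STOP_CASSETTE <- "TAGCTAGCTAG"

#' @noRd
rand_intron <- function(len) {
  fixed <- 4L + nchar(.INTRON_STOP_CASSETTE)
  if (len < fixed + 5L) stop("intron length must be >= ", fixed + 5L)
  paste0("GT", .INTRON_STOP_CASSETTE, rand_dna(len - fixed), "AG")
}

#' Generate gene models and write them into a genome
#'
#' Builds multi-exon protein-coding genes: each CDS starts with ATG, ends
#' with a stop codon, contains no internal in-frame stop, and every intron
#' is canonical GT..AG on the transcription strand. Gene sequences are
#' written into the supplied genome (reverse-complemented for minus-strand
#' genes) without overlap; both strands are represented. The whole
#' transcript is coding (no UTRs).
#'
#' @param genome a `sim_genome` from [gen_genome()].
#' @param n_genes number of genes to place.
#' @param exon_count_range length-2 integer range of exons per gene.
#' @param exon_len_range length-2 range of exon lengths (bp).
#' @param intron_len_range length-2 range of intron lengths (bp, >= 20).
#' @param seed integer seed.
#' @return list with `annotation` (an `annotation_set`) and `genome`
#'   (the modified `sim_genome`).
#' @export
gen_gene_models <- function(genome, n_genes,
                            exon_count_range = c(3L, 7L),
                            exon_len_range = c(120L, 600L),
                            intron_len_range = c(60L, 200L),
                            seed = 1L) {
  stopifnot(inherits(genome, "sim_genome") || is.character(genome))
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (min(intron_len_range) < 20L) stop("intron length must be >= 20")
  with_seed(seed, {
    genes <- vector("list", n_genes)
    chroms <- names(genome)
    cursor <- stats::setNames(rep(3000L, length(chroms)), chroms)
    margin <- 3000L
    for (i in seq_len(n_genes)) {
      n_ex <- samp_range(exon_count_range[1], exon_count_range[2])
      ex_len <- samp_range(exon_len_range[1], exon_len_range[2], n_ex)
      rem <- sum(ex_len) %% 3L
      if (rem != 0L) ex_len[n_ex] <- ex_len[n_ex] + (3L - rem)
      n_codons <- sum(ex_len) %/% 3L
      codons <- c("ATG",
                  sample(sense_codons(), n_codons - 2L, replace = TRUE),
                  sample(stop_codons(), 1L))
      cds_seq <- paste(codons, collapse = "")
      in_len <- if (n_ex > 1L) {
        samp_range(intron_len_range[1], intron_len_range[2], n_ex - 1L)
      } else integer(0)
      # interleave exon chunks and introns (transcription orientation)
      bounds <- c(0L, cumsum(ex_len))
      chunks <- substring(cds_seq, bounds[-length(bounds)] + 1L,
                          bounds[-1L])
      parts <- character(0)
      ex_off <- integer(n_ex) # 1-based offsets of exon chunks in gene_seq
      at <- 0L
      for (j in seq_len(n_ex)) {
        ex_off[j] <- at + 1L
        parts <- c(parts, chunks[j])
        at <- at + ex_len[j]
        if (j < n_ex) {
          parts <- c(parts, rand_intron(in_len[j]))
          at <- at + in_len[j]
        }
      }
      gene_seq <- paste(parts, collapse = "")
      glen <- nchar(gene_seq)
      # strand: force both strands to appear
      strand <- if (i == 1L) "+" else if (i == 2L) "-"
        else sample(c("+", "-"), 1L)
      # placement: round-robin over chromosomes with intergenic gaps wide
      # enough that the 2 kb gene flanks never touch
      placed <- FALSE
      ord <- ((i - 1L) %% length(chroms)) + 1L
      for (ci in c(ord, setdiff(seq_along(chroms), ord))) {
        chrom <- chroms[ci]
        start <- cursor[chrom] + sample(4500:6500, 1L)
        if (start + glen - 1L <= nchar(genome[[chrom]]) - margin) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("cannot place gene ", i, " of ", n_genes,
             ": genome capacity exhausted; use fewer/shorter genes ",
             "or longer chromosomes")
      }
      cursor[chrom] <- start + glen - 1L
      written <- if (strand == "+") gene_seq else revcomp(gene_seq)
      substr(genome[[chrom]], start, start + glen - 1L) <- written
      exons <- if (strand == "+") {
        data.frame(start = start + ex_off - 1L,
                   end = start + ex_off + ex_len - 2L)
      } else {
        # transcript coordinate t maps to genomic start + glen - t
        data.frame(start = start + glen - (ex_off + ex_len - 1L),
                   end = start + glen - ex_off)
      }
      genes[[i]] <- gene_model(sprintf("gene%03d", i), chrom, strand,
                               exons = exons)
    }
    list(annotation = annotation_set(genes), genome = genome)
  })
}
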