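# Independent brute-force oracles and hand-built fixtures. These must not
# share code paths with the implementation they check.

# Minimum state changes for a binary character by exhaustive enumeration
# of all internal-node labelings.
brute_fitch <- function(tree, traits) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  states <- traits[tree$tip.label]
  best <- Inf
  for (mask in 0:(2^n_int - 1)) {
    lab <- c(states, as.integer(intToBits(mask))[seq_len(n_int)])
    changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# Longest strictly monotone subsequence length by enumerating all index
# subsets (n <= 15).
brute_lis_len <- function(x, decreasing = FALSE) {
  if (decreasing) x <- -x
  n <- length(x)
  best <- 0L
  for (mask in 1:(2^n - 1)) {
    idx <- which(as.logical(intToBits(mask))[seq_len(n)])
    if (all(diff(x[idx]) > 0)) best <- max(best, length(idx))
  }
  best
}

# AUROC by exhaustive pairwise comparison; ties weight 1/2.
brute_auroc <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  tot <- 0
  for (p in sp) tot <- tot + sum(p > sn) + 0.5 * sum(p == sn)
  tot / (length(sp) * length(sn))
}

# Hand-built two-exon toy gene: 40 codons (ATG, GCT x 36 with TGG at
# codons 5 and 39, TAA), exon1 = codons 1-20, a 62 bp intron, exon2 =
# codons 21-40. Known coordinates for precision tests.
toy_codons <- function() {
  cods <- c("ATG", rep("GCT", 38), "TAA")
  cods[5] <- "TGG"
  cods[39] <- "TGG"
  cods
}

make_toy_gene <- function(strand = "+", intron_seq = NULL) {
  cds <- paste(toy_codons(), collapse = "")
  if (is.null(intron_seq)) {
    intron_seq <- paste0("GT", "TAGCTAGCTAG", strrep("C", 47), "AG")
  }
  prefix <- strrep("ACGT", 25)                       # 100 bp
  suffix <- strrep("CA", 1600)                       # 3200 bp
  ex1 <- substr(cds, 1, 60)
  ex2 <- substr(cds, 61, 120)
  chrom <- paste0(prefix, ex1, intron_seq, ex2, suffix)
  iL <- nchar(intron_seq)
  exons <- data.frame(start = c(101L, 161L + iL),
                      end = c(160L, 220L + iL))
  if (strand == "+") {
    genome <- structure(c(chr1 = chrom), class = "sim_genome")
    gene <- gene_model("toy", "chr1", "+", exons)
  } else {
    L <- nchar(chrom)
    genome <- structure(
      c(chr1 = as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(chrom)))), class = "sim_genome")
    exons_m <- data.frame(start = L - exons$end + 1L,
                          end = L - exons$start + 1L)
    gene <- gene_model("toy", "chr1", "-", exons_m)
  }
  list(genome = genome, gene = gene, intron_len = iL,
       chrom_len = nchar(chrom))
}

# Toy gene with 5' and 3' UTR: exon1 holds 12 bp UTR + 16 codons, exon2
# holds 16 codons (last = TAA) + 12 bp UTR.
make_utr_gene <- function() {
  cods1 <- c("ATG", rep("GCT", 15))
  cods2 <- c(rep("GCT", 15), "TAA")
  intron <- paste0("GT", "TAGCTAGCTAG", strrep("C", 47), "AG")
  chrom <- paste0(strrep("ACGT", 25), strrep("C", 12),
                  paste(cods1, collapse = ""), intron,
                  paste(cods2, collapse = ""), strrep("C", 12),
                  strrep("CA", 1600))
  exons <- data.frame(start = c(101L, 223L), end = c(160L, 282L))
  cds <- data.frame(start = c(113L, 223L), end = c(160L, 270L))
  list(genome = structure(c(chr1 = chrom), class = "sim_genome"),
       gene = gene_model("toyutr", "chr1", "+", exons, cds))
}

snv_at <- function(pos, alt, genome, chrom = "chr1", id = "v1") {
  data.frame(chrom = chrom, pos = as.integer(pos),
             id = id, ref = substr(genome[[chrom]], pos, pos), alt = alt,
             stringsAsFactors = FALSE)
}
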