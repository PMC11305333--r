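# Translate-the-mutant machinery: applies variants to the genome, rebuilds
# the spliced transcript with coordinate mapping through indels, and
# translates. This is the functional oracle against which the rule-based
# classifier is validated: a mutation is deleterious if the mutant protein
# is substantially shortened or its start is destroyed.

#' @noRd
validate_refs <- function(seq, variants, chrom) {
  for (i in seq_len(nrow(variants))) {
    p <- variants$pos[i]
    ref <- variants$ref[i]
    obs <- substr(seq, p, p + nchar(ref) - 1L)
    if (obs != ref) {
      stop(sprintf("variant REF mismatch at %s:%d (VCF says %s, genome has %s)",
                   chrom, p, ref, obs))
    }
  }
  invisible(TRUE)
}

# Replace each block [pos, pos+nchar(ref)-1] with alt, right to left.
#' @noRd
mutate_seq <- function(seq, variants) {
  if (nrow(variants) == 0L) return(seq)
  ord <- order(variants$pos, decreasing = TRUE)
  for (i in ord) {
    p <- variants$pos[i]
    nr <- nchar(variants$ref[i])
    seq <- paste0(substr(seq, 1L, p - 1L), variants$alt[i],
                  substr(seq, p + nr, nchar(seq)))
  }
  seq
}

# Map an original genomic coordinate onto the mutated sequence. Positions
# inside a replaced block map into the replacement (clamped to its end).
#' @noRd
map_pos <- function(x, variants) {
  if (nrow(variants) == 0L) return(x)
  ord <- order(variants$pos)
  delta <- 0L
  for (i in ord) {
    p <- variants$pos[i]
    nr <- nchar(variants$ref[i])
    na <- nchar(variants$alt[i])
    if (x < p) break
    if (x <= p + nr - 1L) return(p + delta + min(x - p, na - 1L))
    delta <- delta + na - nr
  }
  x + delta
}

# Transcript offset (0-based, 5'->3') of a mutated genomic position given
# mutated exon intervals.
#' @noRd
transcript_offset <- function(exons, strand, m0) {
  ci <- which(exons$start <= m0 & exons$end >= m0)
  if (length(ci) != 1L) stop("CDS anchor fell outside exons after mutation")
  lens <- exons$end - exons$start + 1L
  if (strand == "+") {
    before <- if (ci > 1L) sum(lens[seq_len(ci - 1L)]) else 0L
    before + (m0 - exons$start[ci])
  } else {
    after <- if (ci < nrow(exons)) sum(lens[seq.int(ci + 1L, nrow(exons))])
      else 0L
    after + (exons$end[ci] - m0)
  }
}

#' @noRd
build_transcript <- function(gene, seq, exons = gene$exons) {
  extract_transcript(seq, exons, gene$strand)
}

#' Apply variants to a gene and translate the mutant transcript
#'
#' Applies the variants to the chromosome sequence, re-extracts the exons
#' on the transcription strand (mapping exon boundaries through indels),
#' and translates from the annotated start codon to the first stop.
#'
#' @param gene a `gene_model`.
#' @param genome a `sim_genome` / named character vector.
#' @param variants data.frame with `pos`, `ref`, `alt` (and optionally
#'   `chrom`); may be `NULL` or empty for the wild type. All variants must
#'   lie within the gene span +/- 2 kb and must not overlap one another.
#' @return list with `transcript` (spliced mutant transcript, coding
#'   strand) and `protein` (mutant peptide up to the first stop).
#' @export
splice_and_translate <- function(gene, genome, variants = NULL) {
  seq <- chrom_seq(genome, gene$chrom)
  if (is.null(variants) || nrow(variants) == 0L) {
    variants <- data.frame(pos = integer(0), ref = character(0),
                           alt = character(0))
  } else {
    variants <- variants[order(variants$pos), , drop = FALSE]
    sp <- gene_span(gene)
    if (any(variants$pos < sp[1] - 2000L | variants$pos > sp[2] + 2000L))
      stop("variant outside gene span +/- 2 kb")
    ends <- variants$pos + nchar(variants$ref) - 1L
    if (nrow(variants) > 1L &&
        any(variants$pos[-1L] <= ends[-nrow(variants)]))
      stop("overlapping variants are not supported")
    validate_refs(seq, variants, gene$chrom)
  }
  mut <- mutate_seq(seq, variants)
  ex <- gene$exons
  ex_m <- data.frame(
    start = vapply(ex$start, map_pos, numeric(1), variants = variants),
    end = vapply(ex$end, map_pos, numeric(1), variants = variants))
  ex_m <- ex_m[ex_m$end >= ex_m$start, , drop = FALSE]
  transcript <- extract_transcript(mut, ex_m, gene$strand)
  c0 <- if (gene$strand == "+") min(gene$cds$start) else max(gene$cds$end)
  m0 <- map_pos(c0, variants)
  t_off <- transcript_offset(ex_m, gene$strand, m0)
  cds_part <- substring(transcript, t_off + 1L)
  list(transcript = transcript,
       protein = translate_cds(cds_part, to_first_stop = TRUE))
}

#' Simulate intron retention (mis-splicing)
#'
#' Builds the transcript in which one intron is retained, translates it,
#' and classifies the downstream consequence: a retained intron whose
#' length is not a multiple of 3 disrupts the frame; one that is a
#' multiple of 3 inserts residues and, when it carries an in-frame stop,
#' prematurely terminates the protein.
#'
#' @param gene a `gene_model` with at least one intron.
#' @param genome genome sequences.
#' @param disrupted_intron_index intron index in transcript (5'->3') order.
#' @return list with `transcript` (retained-intron transcript) and
#'   `effect` (list: `effect_class`, `lof_flag`, `protein`,
#'   `wt_protein`).
#' @export
simulate_missplice <- function(gene, genome, disrupted_intron_index) {
  introns <- gene_introns(gene)
  n_in <- nrow(introns)
  if (n_in == 0L) stop("gene ", gene$gene_id, " has no introns")
  if (disrupted_intron_index < 1L || disrupted_intron_index > n_in)
    stop("intron index out of range (gene has ", n_in, " introns)")
  gj <- if (gene$strand == "+") disrupted_intron_index
    else n_in - disrupted_intron_index + 1L
  ex <- gene$exons
  ex_new <- ex
  ex_new$end[gj] <- ex$end[gj + 1L]
  ex_new <- ex_new[-(gj + 1L), , drop = FALSE]
  seq <- chrom_seq(genome, gene$chrom)
  transcript <- extract_transcript(seq, ex_new, gene$strand)
  c0 <- if (gene$strand == "+") min(gene$cds$start) else max(gene$cds$end)
  t_off <- transcript_offset(ex_new, gene$strand, c0)
  protein <- translate_cds(substring(transcript, t_off + 1L),
                           to_first_stop = TRUE)
  wt <- gene_protein(gene, genome)
  intron_len <- introns$end[gj] - introns$start[gj] + 1L
  cls <- if (nchar(protein) < nchar(wt)) {
    if (intron_len %% 3L != 0L) "frameshift" else "stop_gained"
  } else "inframe_indel"
  list(transcript = transcript,
       effect = list(effect_class = cls,
                     lof_flag = nchar(protein) < 0.9 * nchar(wt),
                     protein = protein, wt_protein = wt))
}

#' Functional loss-of-function oracle for a single variant
#'
#' Declares a variant loss-of-function when the mutant protein is shorter
#' than 90% of the wild type, empty, or altered at its first residue
#' (start destroyed). Splice-site variants are evaluated through intron
#' retention ([simulate_missplice()]) rather than through the spliced
#' transcript, since disrupting a canonical site prevents splicing of that
#' intron.
#'
#' @param gene a `gene_model`.
#' @param genome genome sequences.
#' @param variant one-row data.frame (`pos`, `ref`, `alt`).
#' @param splice_intron intron index (transcript order) to retain for
#'   splice-site variants; `NA` for all other variants.
#' @return logical LOF verdict.
#' @export
translation_lof_oracle <- function(gene, genome, variant,
                                   splice_intron = NA) {
  wt <- gene_protein(gene, genome)
  mut <- if (!is.na(splice_intron)) {
    simulate_missplice(gene, genome, splice_intron)$effect$protein
  } else {
    splice_and_translate(gene, genome, variant)$protein
  }
  nchar(mut) == 0L || nchar(mut) < 0.9 * nchar(wt) ||
    substr(mut, 1L, 1L) != substr(wt, 1L, 1L)
}
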