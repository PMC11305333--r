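# File formats. FASTA goes through Biostrings, GFF3 reading through
# rtracklayer, VCF reading through vcfR, trees through ape; tabular data
# are plain TSVs with '#' provenance comments. GFF3 and VCF are written
# 1-based per their standards; VCF indels use the anchored-base
# convention.

#' @noRd
provenance_line <- function(prefix = "#") {
  paste0(prefix, "convloss ",
         as.character(utils::packageVersion("convloss")))
}

#' Write genome sequences to FASTA
#' @param genome named character vector / `sim_genome`.
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(unclass(genome)[seq_along(genome)])
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read genome sequences from FASTA
#' @param path FASTA file.
#' @return `sim_genome` named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  structure(stats::setNames(as.character(x), sub("\\s.*$", "", names(x))),
            class = "sim_genome")
}

#' Write an annotation set to GFF3
#'
#' Emits gene / mRNA / exon / CDS features with correct CDS phase, 1-based
#' inclusive coordinates.
#'
#' @param annotation an `annotation_set`.
#' @param path output file.
#' @param seed optional seed recorded in the header.
#' @export
write_gff3 <- function(annotation, path, seed = NULL) {
  lines <- c("##gff-version 3", provenance_line("#!"),
             if (!is.null(seed)) paste0("#!seed ", seed))
  for (g in annotation) {
    sp <- gene_span(g)
    gid <- g$gene_id
    mid <- paste0(gid, ".t1")
    f <- function(type, s, e, phase, attrs) {
      sprintf("%s\tconvloss\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              g$chrom, type, as.integer(s), as.integer(e), g$strand,
              phase, attrs)
    }
    lines <- c(lines,
               f("gene", sp[1], sp[2], ".", paste0("ID=", gid)),
               f("mRNA", sp[1], sp[2], ".",
                 paste0("ID=", mid, ";Parent=", gid)))
    for (i in seq_len(nrow(g$exons))) {
      lines <- c(lines, f("exon", g$exons$start[i], g$exons$end[i], ".",
                          paste0("ID=", mid, ".exon", i, ";Parent=", mid)))
    }
    # phase: bases to skip to reach a codon boundary, in transcript order
    cds <- g$cds
    tr_order <- if (g$strand == "+") seq_len(nrow(cds))
      else rev(seq_len(nrow(cds)))
    lens <- (cds$end - cds$start + 1L)[tr_order]
    phases <- (3L - (c(0L, cumsum(lens))[seq_along(lens)] %% 3L)) %% 3L
    for (j in seq_along(tr_order)) {
      i <- tr_order[j]
      lines <- c(lines, f("CDS", cds$start[i], cds$end[i], phases[j],
                          paste0("ID=", mid, ".cds;Parent=", mid)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses via rtracklayer and assembles one `gene_model` per mRNA (one
#' transcript per gene).
#'
#' @param path GFF3 file.
#' @return an `annotation_set`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1]])
  }, character(1))
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  genes <- lapply(seq_len(nrow(mrna)), function(i) {
    mid <- mrna$ID[i]
    ex <- df[df$type == "exon" & df$Parent == mid, , drop = FALSE]
    cd <- df[df$type == "CDS" & df$Parent == mid, , drop = FALSE]
    gene_model(gene_id = mrna$Parent[i], chrom = as.character(mrna$seqnames[i]),
               strand = as.character(mrna$strand[i]),
               exons = data.frame(start = ex$start, end = ex$end),
               cds = data.frame(start = cd$start, end = cd$end))
  })
  annotation_set(genes)
}

#' Write variants to VCF v4.2
#'
#' @param variants data.frame (`chrom`, `pos`, `id`, `ref`, `alt`).
#' @param path output file.
#' @param effects optional data.frame from [classify_variants()]; when
#'   given, each record gets `CLE` (effect class) and `LOF` (0/1) INFO
#'   tags.
#' @param seed optional seed recorded in the header.
#' @export
write_vcf <- function(variants, path, effects = NULL, seed = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=convloss_",
                  as.character(utils::packageVersion("convloss"))),
           if (!is.null(seed)) paste0("##seed=", seed),
           "##INFO=<ID=CLE,Number=1,Type=String,Description=\"Effect class\">",
           "##INFO=<ID=LOF,Number=1,Type=Integer,Description=\"Loss of function flag\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- rep(".", nrow(variants))
  if (!is.null(effects)) {
    m <- match(variants$id, effects$variant_id)
    info <- ifelse(is.na(m), ".",
                   sprintf("CLE=%s;LOF=%d", effects$effect_class[m],
                           as.integer(effects$lof_flag[m])))
  }
  ord <- order(variants$chrom, variants$pos)
  rows <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                  variants$chrom[ord], variants$pos[ord],
                  variants$id[ord], variants$ref[ord], variants$alt[ord],
                  info[ord])
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read variants from VCF
#'
#' Multi-allelic records are rejected (split them upstream).
#'
#' @param path VCF file.
#' @return data.frame (`chrom`, `pos`, `id`, `ref`, `alt`).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    stop("multi-allelic VCF records are unsupported; split them first")
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
             id = fix$ID, ref = fix$REF, alt = fix$ALT,
             stringsAsFactors = FALSE)
}

#' @noRd
write_tsv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(provenance_line("# "),
               if (!is.null(seed)) paste0("# seed=", seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @noRd
read_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    ...)
}

#' Write / read an F2 population table
#' @param pop population data.frame.
#' @param path TSV file.
#' @param seed optional seed recorded in the header.
#' @export
write_population <- function(pop, path, seed = NULL) {
  write_tsv(pop, path, seed)
}

#' @rdname write_population
#' @export
read_population <- function(path) read_tsv(path)

#' Write / read a bulk allele-depth count table
#' @param counts counts data.frame from [gen_bsa_counts()].
#' @inheritParams write_population
#' @export
write_bsa_counts <- function(counts, path, seed = NULL) {
  write_tsv(counts, path, seed)
}

#' @rdname write_bsa_counts
#' @export
read_bsa_counts <- function(path) read_tsv(path)

#' Write / read an expression matrix (genes x samples)
#' @param expr numeric matrix with gene ids as rownames.
#' @inheritParams write_population
#' @export
write_expression <- function(expr, path, seed = NULL) {
  df <- data.frame(gene_id = rownames(expr), as.data.frame(expr),
                   check.names = FALSE)
  write_tsv(df, path, seed)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}

#' Read an allele table
#'
#' @param path TSV with columns `species`, `gene`, `effect_class`,
#'   `position` (and optionally `shared_group`, `source`).
#' @return data.frame for [count_distinct_alleles()].
#' @export
read_allele_table <- function(path) read_tsv(path)

#' Packaged allele survey table
#'
#' A synthetic reconstruction of a pan-genus survey of independent
#' loss-of-function alleles in the prickle-loss gene *PL*: 16 distinct
#' deleterious alleles, three of which were each observed in two species
#' (identical but not necessarily ancestral mutations, marked by
#' `shared_group`). Species names outside the mapped crop species and the
#' documented shared-allele pairs, and all positions, are synthetic
#' placeholders; the allele counts and sharing structure are what the
#' table encodes.
#'
#' @return data.frame with one row per (species, allele) observation.
#' @export
pl_allele_table <- function() {
  read_allele_table(system.file("extdata", "pl_alleles_synthetic.tsv",
                                package = "convloss", mustWork = TRUE))
}
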