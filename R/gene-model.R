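# Gene models: one transcript per gene, exons and CDS as 1-based closed
# genomic intervals (the R/Bioconductor convention; GFF3 I/O is 1-based
# inclusive so coordinates round-trip unchanged).

#' Construct a gene model
#'
#' A gene model holds one transcript: ordered exon intervals and the coding
#' segments within them, on a named chromosome and strand. Intervals are
#' 1-based, closed, and stored in ascending genomic order.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with `start`, `end` columns (1-based closed).
#' @param cds data.frame with `start`, `end` columns; must lie within exons
#'   and total a multiple of 3.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds = exons) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.data.frame(exons)[, c("start", "end")]
  cds <- as.data.frame(cds)[, c("start", "end")]
  exons <- exons[order(exons$start), , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  rownames(exons) <- rownames(cds) <- NULL
  if (any(exons$end < exons$start) || any(cds$end < cds$start))
    stop("malformed intervals in gene model ", gene_id)
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop("overlapping exons in gene model ", gene_id)
  for (i in seq_len(nrow(cds))) {
    if (!any(exons$start <= cds$start[i] & exons$end >= cds$end[i]))
      stop("CDS segment outside exons in gene model ", gene_id)
  }
  if (sum(cds$end - cds$start + 1L) %% 3L != 0L)
    stop("CDS length not a multiple of 3 in gene model ", gene_id)
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         exons = exons, cds = cds),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s %s:%d-%d (%s) %d exon(s), CDS %d bp>\n",
              x$gene_id, x$chrom, gene_span(x)[1], gene_span(x)[2],
              x$strand, nrow(x$exons), cds_length(x)))
  invisible(x)
}

#' Genomic span of a gene model
#' @param gene a `gene_model`.
#' @return length-2 integer vector (first, last genomic base).
#' @export
gene_span <- function(gene) {
  c(min(gene$exons$start), max(gene$exons$end))
}

#' Intron intervals of a gene model
#' @param gene a `gene_model`.
#' @return data.frame of `start`, `end` intron intervals in ascending
#'   genomic order (0 rows for intronless genes).
#' @export
gene_introns <- function(gene) {
  ex <- gene$exons
  if (nrow(ex) < 2L)
    return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1L] - 1L)
}

#' @noRd
cds_length <- function(gene) {
  sum(gene$cds$end - gene$cds$start + 1L)
}

# Genomic positions of the CDS in transcript (5'->3') order.
#' @noRd
cds_genomic_positions <- function(gene) {
  pos <- unlist(lapply(seq_len(nrow(gene$cds)),
                       function(i) gene$cds$start[i]:gene$cds$end[i]))
  if (gene$strand == "-") pos <- rev(pos)
  pos
}

#' @noRd
chrom_seq <- function(genome, chrom) {
  s <- genome[[chrom]]
  if (is.null(s)) stop("chromosome not in genome: ", chrom)
  s
}

# Concatenate intervals of a chromosome on the transcription strand.
#' @noRd
extract_transcript <- function(seq, intervals, strand) {
  if (nrow(intervals) == 0L) return("")
  parts <- substring(seq, intervals$start, intervals$end)
  out <- paste(parts, collapse = "")
  if (strand == "-") out <- revcomp(out)
  out
}

#' Spliced CDS sequence of a gene model
#' @param gene a `gene_model`.
#' @param genome named character vector of chromosome sequences (or a
#'   `sim_genome`).
#' @return coding-strand DNA string.
#' @export
spliced_cds <- function(gene, genome) {
  extract_transcript(chrom_seq(genome, gene$chrom), gene$cds, gene$strand)
}

#' Wild-type protein of a gene model
#' @inheritParams spliced_cds
#' @return amino-acid string up to (excluding) the first stop.
#' @export
gene_protein <- function(gene, genome) {
  translate_cds(spliced_cds(gene, genome), to_first_stop = TRUE)
}

#' Construct an annotation set
#'
#' @param genes list of `gene_model` objects.
#' @return object of class `annotation_set` (a named list of gene models).
#' @export
annotation_set <- function(genes) {
  stopifnot(all(vapply(genes, inherits, logical(1), "gene_model")))
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  structure(genes, class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set of %d gene model(s)>\n", length(x)))
  invisible(x)
}

#' @export
`[.annotation_set` <- function(x, i) {
  annotation_set(unclass(x)[i])
}

# Find the gene model whose span (+/- flank) contains a position; NULL if
# none. Ties broken toward the closest span.
#' @noRd
find_gene_at <- function(annotation, chrom, pos, flank = 2000L) {
  best <- NULL
  best_d <- Inf
  for (g in annotation) {
    if (g$chrom != chrom) next
    sp <- gene_span(g)
    if (pos >= sp[1] - flank && pos <= sp[2] + flank) {
      d <- max(0L, sp[1] - pos, pos - sp[2])
      if (d < best_d) {
        best <- g
        best_d <- d
      }
    }
  }
  best
}
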