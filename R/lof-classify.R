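# Rule-based variant-effect classification against gene models: a
# first-match-wins cascade over splice sites, large exonic deletions,
# frame-disrupting indels, and codon-level SNV consequences, with an
# explicit loss-of-function flag.
#
# LOF classes: splice_donor, splice_acceptor, frameshift, start_lost,
# large_exonic_deletion, and stop_gained when at least 10% of the protein
# is truncated. Canonical GT/AG sites only: a variant hitting an annotated
# splice site that is not canonical in the reference is noted
# "noncanonical_site" and never automatically LOF.

#' Effect classes emitted by the classifier
#' @return character vector of class labels.
#' @export
effect_classes <- function() {
  c("splice_donor", "splice_acceptor", "frameshift", "stop_gained",
    "start_lost", "stop_lost", "large_exonic_deletion", "inframe_indel",
    "missense", "synonymous", "intronic", "intergenic", "utr")
}

#' @noRd
effect_call <- function(variant_id, gene_id, effect_class, lof_flag,
                        protein_change = NA_character_,
                        truncation_fraction = NA_real_,
                        note = NA_character_) {
  structure(list(variant_id = variant_id, gene_id = gene_id,
                 effect_class = effect_class, lof_flag = lof_flag,
                 protein_change = protein_change,
                 truncation_fraction = truncation_fraction, note = note),
            class = "effect_call")
}

#' @export
print.effect_call <- function(x, ...) {
  cat(sprintf("<effect_call %s: %s%s gene=%s%s>\n",
              x$variant_id %||% "?", x$effect_class,
              if (isTRUE(x$lof_flag)) " [LOF]" else "",
              x$gene_id %||% "NA",
              if (!is.na(x$note)) paste0(" note=", x$note) else ""))
  invisible(x)
}

#' Left-align an indel against the reference sequence
#'
#' Shifts a VCF anchored indel to its left-most equivalent representation
#' (the standard normalization that removes positional ambiguity in
#' repetitive sequence). Non-indels are returned unchanged.
#'
#' @param var one-row data.frame (`pos`, `ref`, `alt`).
#' @param seq chromosome sequence string.
#' @return the variant, possibly with updated `pos`, `ref`, `alt`.
#' @export
left_align_variant <- function(var, seq) {
  ref <- var$ref
  alt <- var$alt
  pos <- var$pos
  if (nchar(ref) == nchar(alt)) return(var)
  repeat {
    nr <- nchar(ref)
    na <- nchar(alt)
    if (pos <= 1L || nr < 1L || na < 1L) break
    if (substr(ref, nr, nr) != substr(alt, na, na)) break
    prev <- substr(seq, pos - 1L, pos - 1L)
    ref <- paste0(prev, substr(ref, 1L, nr - 1L))
    alt <- paste0(prev, substr(alt, 1L, na - 1L))
    pos <- pos - 1L
  }
  var$pos <- pos
  var$ref <- ref
  var$alt <- alt
  var
}

#' Classify a variant against a gene model
#'
#' First-match-wins cascade: (1) canonical splice-site disruption (first or
#' last 2 intron bases); (2) deletion removing at least
#' `large_del_threshold` coding bp or a complete coding exon; (3) CDS indel
#' with net coding length change not divisible by 3 (frameshift) or
#' divisible (in-frame); (4) CDS SNV by codon comparison (stop_gained,
#' start_lost, stop_lost, missense, synonymous); (5) exonic non-coding
#' (utr), intronic, intergenic. Indels are left-aligned first.
#'
#' @param gene a `gene_model`, or `NULL` for a variant with no nearby gene.
#' @param var one-row data.frame (`chrom`, `pos`, `ref`, `alt`, and
#'   optionally `id`).
#' @param genome genome sequences.
#' @param large_del_threshold minimum coding bp removed for a deletion to
#'   be called `large_exonic_deletion` (default 50).
#' @return an `effect_call`.
#' @export
classify_variant <- function(gene, var, genome, large_del_threshold = 50L) {
  vid <- if ("id" %in% names(var)) var$id else NA_character_
  if (is.null(gene)) {
    return(effect_call(vid, NA_character_, "intergenic", FALSE))
  }
  seq <- chrom_seq(genome, gene$chrom)
  if (var$ref == var$alt) stop("ref and alt are identical at ", var$pos)
  validate_refs(seq, var, gene$chrom)
  if (grepl("[^ACGT]", var$ref) || grepl("[^ACGT]", var$alt))
    stop("symbolic or non-ACGT alleles are unsupported: ", var$id %||% var$pos)
  var <- left_align_variant(var, seq)
  pos <- var$pos
  nr <- nchar(var$ref)
  na <- nchar(var$alt)
  is_ins <- na > nr && nr == 1L && substr(var$alt, 1L, 1L) == var$ref
  is_del <- nr > na && na == 1L && substr(var$ref, 1L, 1L) == var$alt
  # altered reference bases (empty interval for a pure insertion)
  fp <- if (is_del) c(pos + 1L, pos + nr - 1L)
    else if (is_ins) c(NA_integer_, NA_integer_)
    else c(pos, pos + nr - 1L)
  hits_window <- function(w) { # w = sorted 2-bp genomic window
    if (is_ins) pos >= w[1] && pos < w[2]
    else fp[1] <= w[2] && fp[2] >= w[1]
  }
  # (1) splice sites
  introns <- gene_introns(gene)
  note <- NA_character_
  for (k in seq_len(nrow(introns))) {
    gs <- introns$start[k]
    ge <- introns$end[k]
    if (gene$strand == "+") {
      donor_w <- c(gs, gs + 1L)
      accept_w <- c(ge - 1L, ge)
      donor_ok <- substr(seq, gs, gs + 1L) == "GT"
      accept_ok <- substr(seq, ge - 1L, ge) == "AG"
    } else {
      donor_w <- c(ge - 1L, ge)
      accept_w <- c(gs, gs + 1L)
      donor_ok <- substr(seq, ge - 1L, ge) == "AC"
      accept_ok <- substr(seq, gs, gs + 1L) == "CT"
    }
    if (hits_window(donor_w)) {
      if (donor_ok) {
        return(effect_call(vid, gene$gene_id, "splice_donor", TRUE))
      }
      note <- "noncanonical_site"
    }
    if (hits_window(accept_w)) {
      if (accept_ok) {
        return(effect_call(vid, gene$gene_id, "splice_acceptor", TRUE))
      }
      note <- "noncanonical_site"
    }
  }
  cds <- gene$cds
  cds_tot <- cds_length(gene)
  overlap_bp <- function(a, b) { # total cds bp inside [a, b]
    sum(pmax(0L, pmin(cds$end, b) - pmax(cds$start, a) + 1L))
  }
  # (2) large exonic deletion
  if (is_del) {
    removed <- overlap_bp(fp[1], fp[2])
    whole_exon <- any(cds$start >= fp[1] & cds$end <= fp[2])
    if (removed >= large_del_threshold || whole_exon) {
      return(effect_call(vid, gene$gene_id, "large_exonic_deletion", TRUE,
                         truncation_fraction = removed / cds_tot,
                         note = note))
    }
  }
  # (3) CDS indels
  if (is_ins || is_del || nr != na) {
    coding_change <- if (is_ins) {
      in_cds <- any(cds$start <= pos & cds$end >= pos + 1L)
      if (in_cds) na - 1L else 0L
    } else {
      -overlap_bp(fp[1], fp[2])
    }
    if (coding_change != 0L) {
      if (abs(coding_change) %% 3L != 0L) {
        return(effect_call(vid, gene$gene_id, "frameshift", TRUE,
                           note = note))
      }
      return(effect_call(vid, gene$gene_id, "inframe_indel", FALSE,
                         note = note))
    }
  } else {
    # (4) substitution inside the CDS: codon comparison
    gpos <- pos:(pos + nr - 1L)
    cgp <- cds_genomic_positions(gene)
    idx <- match(gpos, cgp)
    if (all(!is.na(idx))) {
      wt_cds <- spliced_cds(gene, genome)
      mut_cds <- wt_cds
      for (i in seq_along(gpos)) {
        b <- substr(var$alt, i, i)
        if (gene$strand == "-") b <- comp_base(b)
        substr(mut_cds, idx[i], idx[i]) <- b
      }
      wt_p <- translate_cds(wt_cds)
      mut_p <- translate_cds(mut_cds)
      n_codons <- nchar(wt_p)
      n_aa <- n_codons - 1L
      if (wt_p == mut_p) {
        return(effect_call(vid, gene$gene_id, "synonymous", FALSE,
                           note = note))
      }
      d <- which(strsplit(wt_p, "")[[1]] != strsplit(mut_p, "")[[1]])[1]
      wt_aa <- substr(wt_p, d, d)
      mut_aa <- substr(mut_p, d, d)
      chg <- paste0(wt_aa, d, mut_aa)
      if (d == 1L) {
        return(effect_call(vid, gene$gene_id, "start_lost", TRUE,
                           protein_change = chg, note = note))
      }
      if (mut_aa == "*" && d <= n_aa) {
        trunc <- (n_aa - d + 1L) / n_aa
        return(effect_call(vid, gene$gene_id, "stop_gained",
                           trunc >= 0.1, protein_change = chg,
                           truncation_fraction = trunc, note = note))
      }
      if (wt_aa == "*") {
        return(effect_call(vid, gene$gene_id, "stop_lost", FALSE,
                           protein_change = chg, note = note))
      }
      return(effect_call(vid, gene$gene_id, "missense", FALSE,
                         protein_change = chg, note = note))
    }
  }
  # (5) exonic non-coding, intronic, intergenic
  probe <- if (is_ins) c(pos, pos + 1L) else fp[1]:fp[2]
  in_exon <- any(vapply(probe, function(p) {
    any(gene$exons$start <= p & gene$exons$end >= p)
  }, logical(1)))
  if (in_exon) {
    in_cds_any <- any(vapply(probe, function(p) {
      any(cds$start <= p & cds$end >= p)
    }, logical(1)))
    if (!in_cds_any) {
      return(effect_call(vid, gene$gene_id, "utr", FALSE, note = note))
    }
  }
  sp <- gene_span(gene)
  if (any(probe >= sp[1] & probe <= sp[2])) {
    if (in_exon) {
      # substitution straddling a CDS boundary without hitting a splice
      # window: conservatively exonic, reported as utr-adjacent
      return(effect_call(vid, gene$gene_id, "utr", FALSE, note = note))
    }
    return(effect_call(vid, gene$gene_id, "intronic", FALSE, note = note))
  }
  effect_call(vid, gene$gene_id, "intergenic", FALSE, note = note)
}

#' Classify a set of variants against an annotation set
#'
#' Assigns each variant to the gene whose span (+/- 2 kb) contains it
#' (nearest gene on ties) and runs [classify_variant()].
#'
#' @param annotation an `annotation_set`.
#' @param variants data.frame (`chrom`, `pos`, `id`, `ref`, `alt`).
#' @param genome genome sequences.
#' @param large_del_threshold passed to [classify_variant()].
#' @return data.frame with one row per variant: `variant_id`, `chrom`,
#'   `pos`, `gene_id`, `effect_class`, `lof_flag`, `protein_change`,
#'   `truncation_fraction`, `note`.
#' @export
classify_variants <- function(annotation, variants, genome,
                              large_del_threshold = 50L) {
  calls <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, , drop = FALSE]
    gene <- find_gene_at(annotation, v$chrom, v$pos)
    classify_variant(gene, v, genome,
                     large_del_threshold = large_del_threshold)
  })
  data.frame(
    variant_id = vapply(calls, function(x) x$variant_id %||% NA_character_,
                        character(1)),
    chrom = variants$chrom,
    pos = variants$pos,
    gene_id = vapply(calls, function(x) x$gene_id %||% NA_character_,
                     character(1)),
    effect_class = vapply(calls, `[[`, character(1), "effect_class"),
    lof_flag = vapply(calls, `[[`, logical(1), "lof_flag"),
    protein_change = vapply(calls, `[[`, character(1), "protein_change"),
    truncation_fraction = vapply(calls, `[[`, numeric(1),
                                 "truncation_fraction"),
    note = vapply(calls, `[[`, character(1), "note"),
    stringsAsFactors = FALSE)
}
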