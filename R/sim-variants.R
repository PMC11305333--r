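# Variant injection with ground truth. Each requested effect class is
# constructed so that classification against the gene models recovers the
# intended class, and so that the intended loss-of-function status agrees
# with the translate-the-mutant oracle. Severe (truncating) classes are
# placed in the 5' portion of the CDS so the intended effect is
# unambiguous; see the package vignette for the rationale.

# Fraction of the CDS (5'->3') within which truncating variants are placed.
.LOF_PLACEMENT_MAX_FRAC <- 0.7

#' @noRd
variant_classes <- function() {
  c("splice_donor", "splice_acceptor", "frameshift_indel", "stop_gained",
    "large_exonic_deletion", "inframe_indel", "missense", "synonymous",
    "intronic", "intergenic")
}

# Per-gene cache of CDS layout used repeatedly during injection.
#' @noRd
gene_layout <- function(gene, genome) {
  cgp <- cds_genomic_positions(gene)
  cds <- spliced_cds(gene, genome)
  n_codons <- nchar(cds) %/% 3L
  introns <- gene_introns(gene)
  # introns in transcript order, with fraction of CDS upstream of each
  tr_introns <- introns
  if (nrow(introns) > 0L) {
    if (gene$strand == "-")
      tr_introns <- introns[rev(seq_len(nrow(introns))), , drop = FALSE]
    ex_len <- gene$exons$end - gene$exons$start + 1L
    if (gene$strand == "-") ex_len <- rev(ex_len)
    tr_introns$upstream_frac <- cumsum(ex_len)[-length(ex_len)] /
      sum(ex_len)
  } else {
    tr_introns$upstream_frac <- numeric(0)
  }
  list(cgp = cgp, cds = cds, n_codons = n_codons,
       n_aa = n_codons - 1L, introns = introns, tr_introns = tr_introns)
}

#' Inject variants of requested effect classes into a genome
#'
#' Constructs SNVs and indels whose classification by [classify_variant()]
#' is intended to recover the requested class, together with a truth table.
#' Indels follow the VCF anchored-base convention. Variants are placed so
#' that footprints never overlap; a class that cannot be placed (e.g. a
#' large exonic deletion when no exon is long enough) is skipped with a
#' warning and recorded in the truth table attributes.
#'
#' @param genome a `sim_genome` carrying the gene sequences.
#' @param annotation an `annotation_set` from [gen_gene_models()].
#' @param spec named integer vector of requested counts, names among
#'   `variant_classes()`; or a data.frame with `class` and `count` columns.
#' @param seed integer seed.
#' @param del_len length (bp) of large exonic deletions.
#' @return list with `variants` (data.frame `chrom`, `pos`, `id`, `ref`,
#'   `alt`) and `truth` (data.frame with intended class, intended LOF flag,
#'   gene and intron bookkeeping). `attr(truth, "skipped")` records
#'   requests that could not be placed.
#' @export
inject_variants <- function(genome, annotation, spec, seed,
                            del_len = 474L) {
  if (is.data.frame(spec)) {
    spec <- stats::setNames(as.integer(spec$count), as.character(spec$class))
  }
  bad <- setdiff(names(spec), variant_classes())
  if (length(bad) > 0L)
    stop("unknown effect class(es): ", paste(bad, collapse = ", "))
  with_seed(seed, {
    layouts <- lapply(annotation, gene_layout, genome = genome)
    used <- data.frame(chrom = character(0), lo = integer(0),
                       hi = integer(0))
    out <- list()
    skipped <- list()
    counter <- 0L
    lof_classes <- c("splice_donor", "splice_acceptor", "frameshift_indel",
                     "stop_gained", "large_exonic_deletion")
    for (cls in names(spec)) {
      for (rep_i in seq_len(spec[[cls]])) {
        v <- NULL
        for (attempt in 1:150) {
          v <- try_place_variant(cls, genome, annotation, layouts, del_len)
          if (is.null(v)) next
          buf <- 12L
          clash <- any(used$chrom == v$chrom &
                         used$lo <= v$hi + buf & used$hi >= v$lo - buf)
          if (!clash) break
          v <- NULL
        }
        if (is.null(v)) {
          warning("could not place a ", cls,
                  " variant; request skipped", call. = FALSE)
          skipped[[length(skipped) + 1L]] <- cls
          next
        }
        counter <- counter + 1L
        v$id <- sprintf("var%04d", counter)
        v$class <- cls
        v$lof <- cls %in% lof_classes
        used <- rbind(used, data.frame(chrom = v$chrom, lo = v$lo,
                                       hi = v$hi))
        out[[counter]] <- v
      }
    }
    if (length(out) == 0L) stop("no variants could be placed")
    variants <- data.frame(
      chrom = vapply(out, `[[`, character(1), "chrom"),
      pos = vapply(out, `[[`, integer(1), "pos"),
      id = vapply(out, `[[`, character(1), "id"),
      ref = vapply(out, `[[`, character(1), "ref"),
      alt = vapply(out, `[[`, character(1), "alt"),
      stringsAsFactors = FALSE)
    truth <- data.frame(
      variant_id = variants$id,
      gene_id = vapply(out, function(v) v$gene_id %||% NA_character_,
                       character(1)),
      intended_class = vapply(out, `[[`, character(1), "class"),
      intended_lof = vapply(out, `[[`, logical(1), "lof"),
      intron_index = vapply(out, function(v) v$intron_index %||%
                              NA_integer_, integer(1)),
      stringsAsFactors = FALSE)
    ord <- order(variants$chrom, variants$pos)
    variants <- variants[ord, , drop = FALSE]
    truth <- truth[ord, , drop = FALSE]
    rownames(variants) <- rownames(truth) <- NULL
    if (length(skipped) > 0L)
      attr(truth, "skipped") <- table(unlist(skipped))
    list(variants = variants, truth = truth)
  })
}

# One placement attempt for a single class; returns NULL when the sampled
# gene cannot host the class.
#' @noRd
try_place_variant <- function(cls, genome, annotation, layouts, del_len) {
  gi <- samp_one(seq_along(annotation))
  gene <- annotation[[gi]]
  lay <- layouts[[gi]]
  seq <- chrom_seq(genome, gene$chrom)
  base_at <- function(p) substr(seq, p, p)
  snv <- function(p, alt_base, ...) {
    list(chrom = gene$chrom, pos = as.integer(p), ref = base_at(p),
         alt = alt_base, lo = as.integer(p), hi = as.integer(p),
         gene_id = gene$gene_id, ...)
  }
  switch(cls,
    splice_donor = ,
    splice_acceptor = {
      ti <- lay$tr_introns
      ok <- which(ti$upstream_frac <= .LOF_PLACEMENT_MAX_FRAC)
      if (length(ok) == 0L) return(NULL)
      k <- samp_one(ok)
      gs <- ti$start[k]; ge <- ti$end[k]
      donor <- cls == "splice_donor"
      pos2 <- if (gene$strand == "+") {
        if (donor) c(gs, gs + 1L) else c(ge - 1L, ge)
      } else {
        if (donor) c(ge - 1L, ge) else c(gs, gs + 1L)
      }
      p <- samp_one(pos2)
      ref <- base_at(p)
      # transcript-order intron index for the mis-splicing oracle
      idx <- if (gene$strand == "+") which(lay$introns$start == gs)
        else nrow(lay$introns) - which(lay$introns$start == gs) + 1L
      snv(p, samp_one(setdiff(DNA_BASES, ref)),
          intron_index = as.integer(idx))
    },
    frameshift_indel = {
      n <- length(lay$cgp)
      lo_i <- max(15L, ceiling(0.05 * n))
      hi_i <- floor(.LOF_PLACEMENT_MAX_FRAC * n)
      if (hi_i <= lo_i) return(NULL)
      idx <- samp_range(lo_i, hi_i)
      p <- lay$cgp[idx]
      seg <- which(gene$cds$start <= p - 12L & gene$cds$end >= p + 12L)
      if (length(seg) == 0L) return(NULL)
      l <- samp_one(1:2)
      if (stats::runif(1) < 0.5) { # deletion of l bases
        anchor <- p - 1L
        list(chrom = gene$chrom, pos = anchor,
             ref = substr(seq, anchor, anchor + l),
             alt = base_at(anchor), lo = anchor, hi = anchor + l,
             gene_id = gene$gene_id)
      } else { # insertion of l bases
        list(chrom = gene$chrom, pos = as.integer(p),
             ref = base_at(p), alt = paste0(base_at(p), rand_dna(l)),
             lo = as.integer(p), hi = as.integer(p + 1L),
             gene_id = gene$gene_id)
      }
    },
    stop_gained = {
      subs <- codon_sub_table()
      hi_ci <- floor(0.85 * lay$n_aa)
      if (hi_ci < 2L) return(NULL)
      cis <- samp_range(2L, hi_ci, n = 8L)
      for (ci in cis) {
        cod <- substr(lay$cds, 3L * ci - 2L, 3L * ci)
        cand <- subs[[cod]]
        cand <- cand[cand$kind == "nonsense", , drop = FALSE]
        if (nrow(cand) == 0L) next
        r <- cand[samp_one(seq_len(nrow(cand))), ]
        p <- lay$cgp[3L * (ci - 1L) + r$pos]
        alt <- if (gene$strand == "+") r$base else comp_base(r$base)
        return(snv(p, alt))
      }
      NULL
    },
    large_exonic_deletion = {
      # require the deletion to remove a clearly deleterious share of the
      # CDS (>= 12%), so the intended LOF label is unambiguous
      if (del_len < 0.12 * nchar(lay$cds)) return(NULL)
      segs <- which(gene$cds$end - gene$cds$start + 1L >= del_len + 24L)
      if (length(segs) == 0L) return(NULL)
      s <- samp_one(segs)
      delstart <- samp_range(gene$cds$start[s] + 12L,
                             gene$cds$end[s] - del_len - 11L)
      anchor <- delstart - 1L
      list(chrom = gene$chrom, pos = anchor,
           ref = substr(seq, anchor, anchor + del_len),
           alt = base_at(anchor), lo = anchor, hi = anchor + del_len,
           gene_id = gene$gene_id)
    },
    inframe_indel = {
      if (lay$n_codons < 4L) return(NULL)
      cis <- samp_range(2L, lay$n_codons - 1L, n = 8L)
      for (ci in cis) {
        g <- lay$cgp[(3L * ci - 2L):(3L * ci)]
        if (max(g) - min(g) != 2L) next # codon split across exons
        seg <- which(gene$cds$start <= min(g) - 12L &
                       gene$cds$end >= max(g) + 12L)
        if (length(seg) == 0L) next
        if (stats::runif(1) < 0.5) { # delete the whole codon
          anchor <- min(g) - 1L
          return(list(chrom = gene$chrom, pos = anchor,
                      ref = substr(seq, anchor, anchor + 3L),
                      alt = base_at(anchor), lo = anchor,
                      hi = anchor + 3L, gene_id = gene$gene_id))
        } else { # insert a sense codon at the codon boundary
          ins <- samp_one(sense_codons())
          anchor <- if (gene$strand == "+") max(g) else min(g) - 1L
          ins_seq <- if (gene$strand == "+") ins else revcomp(ins)
          return(list(chrom = gene$chrom, pos = as.integer(anchor),
                      ref = base_at(anchor),
                      alt = paste0(base_at(anchor), ins_seq),
                      lo = as.integer(anchor), hi = as.integer(anchor + 1L),
                      gene_id = gene$gene_id))
        }
      }
      NULL
    },
    missense = ,
    synonymous = {
      subs <- codon_sub_table()
      want <- if (cls == "missense") "missense" else "synonymous"
      if (lay$n_codons < 4L) return(NULL)
      cis <- samp_range(2L, lay$n_codons - 1L, n = 12L)
      for (ci in cis) {
        cod <- substr(lay$cds, 3L * ci - 2L, 3L * ci)
        cand <- subs[[cod]]
        cand <- cand[cand$kind == want, , drop = FALSE]
        if (nrow(cand) == 0L) next
        r <- cand[samp_one(seq_len(nrow(cand))), ]
        p <- lay$cgp[3L * (ci - 1L) + r$pos]
        alt <- if (gene$strand == "+") r$base else comp_base(r$base)
        return(snv(p, alt))
      }
      NULL
    },
    intronic = {
      if (nrow(lay$introns) == 0L) return(NULL)
      k <- samp_one(seq_len(nrow(lay$introns)))
      gs <- lay$introns$start[k]; ge <- lay$introns$end[k]
      if (ge - 13L < gs + 13L) return(NULL)
      p <- samp_range(gs + 13L, ge - 13L)
      ref <- base_at(p)
      snv(p, samp_one(setdiff(DNA_BASES, ref)))
    },
    intergenic = {
      chrom <- samp_one(names(genome))
      len <- nchar(genome[[chrom]])
      spans <- lapply(annotation, function(g) {
        if (g$chrom == chrom) gene_span(g) else NULL
      })
      spans <- spans[!vapply(spans, is.null, logical(1))]
      for (attempt in 1:30) {
        p <- samp_range(50L, len - 50L)
        clear <- all(vapply(spans, function(sp) {
          p < sp[1] - 2050L || p > sp[2] + 2050L
        }, logical(1)))
        if (clear) {
          ref <- substr(genome[[chrom]], p, p)
          return(list(chrom = chrom, pos = as.integer(p), ref = ref,
                      alt = samp_one(setdiff(DNA_BASES, ref)),
                      lo = as.integer(p), hi = as.integer(p),
                      gene_id = NULL))
        }
      }
      NULL
    },
    stop("unknown class: ", cls)
  )
}
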