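# Precision tests of the effect-classification cascade and the
# translate-the-mutant machinery on a hand-built two-exon gene with known
# codon coordinates (see helper-oracles.R).

toy <- make_toy_gene("+")
toy_wt_protein <- paste0("M", "AAA", "W", strrep("A", 33), "W") # 39 aa

test_that("wild-type translation matches the hand-computed protein", {
  st <- splice_and_translate(toy$gene, toy$genome)
  expect_identical(st$protein, toy_wt_protein)
  expect_identical(nchar(st$transcript), 120L)
  expect_identical(gene_protein(toy$gene, toy$genome), toy_wt_protein)
})

test_that("reverse-strand mirror construction translates identically", {
  toy_m <- make_toy_gene("-")
  expect_identical(splice_and_translate(toy_m$gene, toy_m$genome)$protein,
                   toy_wt_protein)
})

test_that("canonical splice-site SNVs are classified as LOF", {
  don <- classify_variant(toy$gene, snv_at(161, "A", toy$genome),
                          toy$genome)
  expect_identical(don$effect_class, "splice_donor")
  expect_true(don$lof_flag)
  acc <- classify_variant(toy$gene, snv_at(222, "C", toy$genome),
                          toy$genome)
  expect_identical(acc$effect_class, "splice_acceptor")
  expect_true(acc$lof_flag)
})

test_that("codon-level SNV calls follow the genetic code", {
  # GCT -> GCC at codon 2, third position: synonymous
  syn <- classify_variant(toy$gene, snv_at(106, "C", toy$genome),
                          toy$genome)
  expect_identical(syn$effect_class, "synonymous")
  expect_false(syn$lof_flag)
  # GCT -> GTT at codon 2: missense A2V
  mis <- classify_variant(toy$gene, snv_at(105, "T", toy$genome),
                          toy$genome)
  expect_identical(mis$effect_class, "missense")
  expect_identical(mis$protein_change, "A2V")
  # TGG -> TGA at codon 5: early stop, 89.7% truncated -> LOF
  st5 <- classify_variant(toy$gene, snv_at(115, "A", toy$genome),
                          toy$genome)
  expect_identical(st5$effect_class, "stop_gained")
  expect_true(st5$lof_flag)
  expect_equal(st5$truncation_fraction, 35 / 39)
  # TGG -> TGA at codon 39: truncates 1/39 < 10% -> stop_gained, not LOF
  st39 <- classify_variant(toy$gene, snv_at(279, "A", toy$genome),
                           toy$genome)
  expect_identical(st39$effect_class, "stop_gained")
  expect_false(st39$lof_flag)
  # ATG -> ACG: start lost
  sl <- classify_variant(toy$gene, snv_at(102, "C", toy$genome),
                         toy$genome)
  expect_identical(sl$effect_class, "start_lost")
  expect_true(sl$lof_flag)
  # TAA -> CAA: stop lost
  slo <- classify_variant(toy$gene, snv_at(280, "C", toy$genome),
                          toy$genome)
  expect_identical(slo$effect_class, "stop_lost")
  expect_false(slo$lof_flag)
})

test_that("indel calls distinguish frame disruption from in-frame", {
  ins <- data.frame(chrom = "chr1", pos = 130L, id = "i1",
                    ref = substr(toy$genome[["chr1"]], 130, 130),
                    alt = paste0(substr(toy$genome[["chr1"]], 130, 130), "A"))
  call <- classify_variant(toy$gene, ins, toy$genome)
  expect_identical(call$effect_class, "frameshift")
  expect_true(call$lof_flag)
  # the mutant protein diverges at/after the insertion codon (oracle)
  mut <- splice_and_translate(toy$gene, toy$genome, ins)$protein
  expect_identical(substr(mut, 1, 9), substr(toy_wt_protein, 1, 9))
  expect_false(identical(mut, toy_wt_protein))
  # deleting codon 10 exactly: in-frame, not LOF
  del9 <- data.frame(chrom = "chr1", pos = 127L, id = "d1",
                     ref = substr(toy$genome[["chr1"]], 127, 130),
                     alt = substr(toy$genome[["chr1"]], 127, 127))
  call <- classify_variant(toy$gene, del9, toy$genome)
  expect_identical(call$effect_class, "inframe_indel")
  expect_false(call$lof_flag)
})

test_that("large deletions are LOF even when in-frame", {
  # 54 coding bp (18 codons, in frame) >= 50 bp threshold
  del54 <- data.frame(chrom = "chr1", pos = 103L, id = "d54",
                      ref = substr(toy$genome[["chr1"]], 103, 157),
                      alt = substr(toy$genome[["chr1"]], 103, 103))
  call <- classify_variant(toy$gene, del54, toy$genome)
  expect_identical(call$effect_class, "large_exonic_deletion")
  expect_true(call$lof_flag)
  expect_equal(call$truncation_fraction, 54 / 120)
  # same deletion under a higher threshold: in-frame indel
  call2 <- classify_variant(toy$gene, del54, toy$genome,
                            large_del_threshold = 100L)
  expect_identical(call2$effect_class, "inframe_indel")
  # deletion spanning a complete coding exon
  delx <- data.frame(chrom = "chr1", pos = 222L, id = "dx",
                     ref = substr(toy$genome[["chr1"]], 222, 283),
                     alt = substr(toy$genome[["chr1"]], 222, 222))
  call3 <- classify_variant(toy$gene, delx, toy$genome,
                            large_del_threshold = 100L)
  expect_identical(call3$effect_class, "large_exonic_deletion")
  expect_true(call3$lof_flag)
})

test_that("non-coding calls: utr, intronic, intergenic", {
  u <- make_utr_gene()
  expect_identical(classify_variant(u$gene, snv_at(105, "A", u$genome),
                                    u$genome)$effect_class, "utr")
  expect_identical(classify_variant(u$gene, snv_at(275, "A", u$genome),
                                    u$genome)$effect_class, "utr")
  expect_identical(classify_variant(toy$gene, snv_at(190, "G", toy$genome),
                                    toy$genome)$effect_class, "intronic")
  ann <- annotation_set(list(toy$gene))
  far <- snv_at(3000, "G", toy$genome)
  calls <- classify_variants(ann, far, toy$genome)
  expect_identical(calls$effect_class, "intergenic")
})

test_that("indels are left-aligned before classification", {
  # place the deletion inside the intron's C-homopolymer (174..220):
  # a 1 bp C deletion anchored late must shift left to the run start
  del <- data.frame(chrom = "chr1", pos = 200L, id = "dL",
                    ref = substr(toy$genome[["chr1"]], 200, 201),
                    alt = substr(toy$genome[["chr1"]], 200, 200))
  shifted <- left_align_variant(del, toy$genome[["chr1"]])
  expect_lt(shifted$pos, 180L)
  expect_identical(classify_variant(toy$gene, del, toy$genome)$effect_class,
                   "intronic")
})

test_that("REF mismatches and same-allele records are hard errors", {
  bad <- data.frame(chrom = "chr1", pos = 105L, id = "b", ref = "G",
                    alt = "A")
  expect_error(classify_variant(toy$gene, bad, toy$genome),
               "REF mismatch at chr1:105")
  expect_error(splice_and_translate(toy$gene, toy$genome, bad),
               "REF mismatch")
  same <- snv_at(105, substr(toy$genome[["chr1"]], 105, 105), toy$genome)
  expect_error(classify_variant(toy$gene, same, toy$genome), "identical")
})

test_that("classification is strand-invariant under mirror construction", {
  toy_m <- make_toy_gene("-")
  L <- toy$chrom_len
  cases <- data.frame(pos = c(161, 222, 106, 105, 115, 102, 190),
                      alt = c("A", "C", "C", "T", "A", "C", "G"))
  for (i in seq_len(nrow(cases))) {
    fwd <- classify_variant(toy$gene,
                            snv_at(cases$pos[i], cases$alt[i], toy$genome),
                            toy$genome)
    mpos <- L - cases$pos[i] + 1L
    malt <- chartr("ACGT", "TGCA", cases$alt[i])
    rev <- classify_variant(toy_m$gene, snv_at(mpos, malt, toy_m$genome),
                            toy_m$genome)
    expect_identical(rev$effect_class, fwd$effect_class)
    expect_identical(rev$lof_flag, fwd$lof_flag)
  }
})

test_that("classification is total over generated variants", {
  gg <- gen_gene_models(gen_genome(1, 150000, 51), 8, seed = 52)
  iv <- inject_variants(gg$genome, gg$annotation,
                        stats::setNames(rep(3, 10),
                                        convloss:::variant_classes()),
                        seed = 53)
  calls <- classify_variants(gg$annotation, iv$variants, gg$genome)
  expect_identical(nrow(calls), nrow(iv$variants))
  expect_true(all(calls$effect_class %in% effect_classes()))
  expect_false(anyNA(calls$effect_class))
})

test_that("intron retention is translated and classified correctly", {
  # 62 bp intron with an early stop cassette: frame-disrupting truncation
  ms <- simulate_missplice(toy$gene, toy$genome, 1)
  expect_identical(ms$effect$effect_class, "frameshift")
  expect_true(ms$effect$lof_flag)
  expect_lt(nchar(ms$effect$protein), nchar(toy_wt_protein))
  expect_identical(nchar(ms$transcript), 120L + toy$intron_len)
  # 63 bp stop-free intron at a codon boundary: clean in-frame insertion
  toy3 <- make_toy_gene("+", intron_seq = paste0("GT", strrep("C", 59), "AG"))
  ms3 <- simulate_missplice(toy3$gene, toy3$genome, 1)
  expect_identical(ms3$effect$effect_class, "inframe_indel")
  expect_false(ms3$effect$lof_flag)
  expect_identical(nchar(ms3$effect$protein), 39L + 21L)
  # index checks
  expect_error(simulate_missplice(toy$gene, toy$genome, 3), "out of range")
  gg <- gen_gene_models(gen_genome(1, 30000, 61), 1,
                        exon_count_range = c(1, 1), seed = 62)
  expect_error(simulate_missplice(gg$annotation[[1]], gg$genome, 1),
               "no introns")
  # works on reverse-strand genes too
  toy_m <- make_toy_gene("-")
  msm <- simulate_missplice(toy_m$gene, toy_m$genome, 1)
  expect_identical(msm$effect$effect_class, "frameshift")
})
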