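test_that("single-column substitutions are called with full annotation", {
  aln <- alignment_set(c(ref = "ATGAAA", s1 = "ATGAAG"), "ref")
  snps <- call_snps(aln, "s1")
  expect_equal(nrow(snps), 1)
  expect_equal(snps$position, 6L)
  expect_equal(snps$ref_base, "A")
  expect_equal(snps$alt_base, "G")
  expect_equal(snps$subst_class, "transition")
  expect_equal(snps$ref_aa, "Lys")
  expect_equal(snps$alt_aa, "Lys")
  expect_equal(snps$effect, "synonymous")

  # identity: no records
  same <- alignment_set(c(ref = "ATGAAA", s1 = "ATGAAA"), "ref")
  expect_equal(nrow(call_snps(same, "s1")), 0)
})

test_that("gap and N columns never yield SNP records", {
  aln <- alignment_set(c(ref = "ATGAAACCC", s1 = "ATGNA-CCA"), "ref")
  snps <- call_snps(aln, "s1")
  # only the C>A at position 9 is callable; N (pos 4) and gap (pos 6) are not
  expect_equal(snps$position, 9L)
  expect_equal(attr(snps, "n_excluded"), 2L)
})

test_that("unknown samples and malformed alignments are rejected", {
  aln <- alignment_set(c(ref = "ATGAAA", s1 = "ATGAAG"), "ref")
  expect_error(call_snps(aln, "nope"), class = "musadicho_missing_sample")
  expect_error(alignment_set(c(ref = "ATGAAA", s1 = "ATGAXG"), "ref"),
               class = "musadicho_invalid_alignment")
  expect_error(alignment_set(c(ref = "ATGAAA", s1 = "ATG"), "ref"),
               class = "musadicho_invalid_alignment")
  expect_error(alignment_set(c(ref = "ATGAAA", s1 = "ATGAAG"), "missing"),
               class = "musadicho_missing_sample")
})

test_that("deletions are reported per gap run, insertions separately", {
  aln <- alignment_set(
    c(ref = "ATGAAACCCGGGTTTAAA", s1 = "ATGAAA------TTTAAA"), "ref")
  dels <- detect_deletions(aln, "s1")
  expect_equal(nrow(dels), 1)
  expect_equal(dels$start, 7L)
  expect_equal(dels$length, 6L)

  # gap in the reference row is an insertion, never a deletion
  aln2 <- alignment_set(c(ref = "ATG---AAATAA", s1 = "ATGCCCAAATAA"), "ref")
  expect_equal(nrow(detect_deletions(aln2, "s1")), 0)
  ins <- detect_insertions(aln2, "s1")
  expect_equal(nrow(ins), 1)
  expect_equal(ins$length, 3L)
})

test_that("codon-effect annotation matches direct translation", {
  # GGT -> GTT at the second base of codon 27
  ref <- paste(c(rep("AAA", 26), "GGT", rep("AAA", 13)), collapse = "")
  eff <- annotate_codon_effect(80, "G", "T", ref)
  expect_equal(eff$codon_index, 27L)
  expect_equal(eff$ref_aa, "Gly")
  expect_equal(eff$alt_aa, "Val")
  expect_equal(eff$effect, "non-synonymous")

  # third-position transition in a 4-fold degenerate codon is synonymous
  eff2 <- annotate_codon_effect(3, "A", "G", "GGAAAA")
  expect_equal(eff2$effect, "synonymous")

  # trailing incomplete codon
  expect_error(annotate_codon_effect(5, "A", "G", "ATGAA"),
               class = "musadicho_out_of_frame")
  # frame offset shifts the codon grid: position 4 is the G of ATG
  eff3 <- annotate_codon_effect(4, "G", "A", "CATGAAA", frame_offset = 2)
  expect_equal(eff3$codon_index, 1L)
  expect_equal(eff3$effect, "non-synonymous") # Met -> Ile
  expect_error(annotate_codon_effect(1, "C", "G", "CATGAAA", frame_offset = 2),
               class = "musadicho_out_of_frame")
})

test_that("reported positions index the stated base in the ungapped reference", {
  ref <- generate_reference_cds(300, seed = 17)
  sp <- cultivar_profiles()[["TB3P"]]$substitution_profile
  imp <- implant_variants(ref, sp, deletion_spec = c(31, 6), seed = 18)
  snps <- call_snps(imp$alignment, "TB3P")
  ref_chars <- strsplit(ref, "")[[1]]
  expect_identical(ref_chars[snps$position], as.character(snps$ref_base))
  # and deletion coordinates round-trip against the generator's truth
  expect_equal(detect_deletions(imp$alignment, "TB3P")$start, 31L)
  expect_equal(detect_deletions(imp$alignment, "TB3P")$length, 6L)
})

test_that("cultivar summaries report the top substitution types and class", {
  ref <- generate_reference_cds(600, seed = 7)
  profs <- cultivar_profiles()
  for (nm in c("Agbagba", "DB1P")) {
    sp <- profs[[nm]]$substitution_profile
    imp <- implant_variants(ref, sp, seed = 3)
    out <- summarize_cultivar(call_snps(imp$alignment, nm), nm)
    expect_equal(out$n_snp_sites, sp$n_snp_sites)
    expect_equal(out$overall_class, sp$overall_class)
    expect_equal(out$mutation_type, sp$mutation_type)
    expect_equal(out$listed_types[order(out$listed_types$count,
                                        decreasing = TRUE), ],
                 sp$listed_types, ignore_attr = TRUE)
  }
  empty <- summarize_cultivar(call_snps(
    alignment_set(c(ref = "ATGAAA", s = "ATGAAA"), "ref"), "s"), "s")
  expect_equal(empty$n_snp_sites, 0)
  expect_equal(empty$mutation_type, "synonymous")
  expect_true(is.na(empty$overall_class))
})

test_that("ties in the type ranking break lexicographically", {
  mk <- function(pos, ref, alt, cls) {
    data.frame(position = pos, ref_base = ref, alt_base = alt,
               ref_class = base_class_pub(ref), alt_class = base_class_pub(alt),
               subst_class = cls, codon_index = 1L, ref_aa = "Lys",
               alt_aa = "Lys", effect = "synonymous",
               stringsAsFactors = FALSE)
  }
  base_class_pub <- function(b) ifelse(b %in% c("A", "G"), "Pu", "Py")
  snps <- rbind(mk(1L, "G", "A", "transition"), mk(4L, "C", "T", "transition"),
                mk(7L, "A", "G", "transition"))
  out <- summarize_cultivar(snps, "tie")
  expect_equal(paste0(out$listed_types$ref_base, ">", out$listed_types$alt_base),
               c("A>G", "C>T")) # alphabetical among equal counts
})
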