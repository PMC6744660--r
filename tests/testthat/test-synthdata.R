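test_that("reference generator yields seeded stop-free coding sequence", {
  # smallest legal CDS: one non-stop codon
  tiny <- generate_reference_cds(3, seed = 42)
  expect_equal(nchar(tiny), 3)
  expect_false(tiny %in% c("TAA", "TAG", "TGA"))

  ref <- generate_reference_cds(300, seed = 7)
  expect_identical(ref, generate_reference_cds(300, seed = 7))
  expect_equal(nchar(ref), 300)
  expect_true(all(strsplit(ref, "")[[1]] %in% c("A", "C", "G", "T")))

  # no internal stop, checked with an independent translation oracle
  aa <- oracle_translate(ref)
  expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))

  expect_error(generate_reference_cds(10, seed = 1),
               class = "musadicho_invalid_argument")
  expect_error(generate_reference_cds(0, seed = 1),
               class = "musadicho_invalid_argument")
})

test_that("implanted variants are exactly realized in the mutant", {
  ref <- generate_reference_cds(600, seed = 7)
  ref_chars <- strsplit(ref, "")[[1]]
  for (prof in cultivar_profiles()) {
    sp <- prof$substitution_profile
    imp <- implant_variants(ref, sp, deletion_spec = c(421, 12), seed = 3)
    vt <- imp$truth$variant_truth
    mut <- strsplit(imp$mutant, "")[[1]]
    # conservation: exactly n_snp_sites substitutions, no column reused
    expect_equal(nrow(vt), sp$n_snp_sites)
    expect_false(anyDuplicated(vt$position) > 0)
    expect_true(all(diff(vt$position) > 0))
    # truth consistency by direct inspection of the artifact
    expect_identical(ref_chars[vt$position], vt$ref_base)
    expect_identical(mut[vt$position], vt$alt_base)
    # listed types occur their exact listed counts
    pair <- paste0(vt$ref_base, ">", vt$alt_base)
    for (i in seq_len(nrow(sp$listed_types))) {
      lp <- paste0(sp$listed_types$ref_base[i], ">", sp$listed_types$alt_base[i])
      expect_equal(sum(pair == lp), sp$listed_types$count[i])
    }
    # deletion realized as a gap run opposite reference bases
    expect_identical(mut[421:432], rep("-", 12))
    expect_equal(imp$truth$deletion_truth$start, 421)
    expect_equal(imp$truth$deletion_truth$length, 12)
    expect_false(any(vt$position %in% 421:432))
  }
})

test_that("a zero-site profile returns the reference unchanged", {
  ref <- generate_reference_cds(60, seed = 1)
  empty <- substitution_profile("none", 0L)
  imp <- implant_variants(ref, empty, seed = 5)
  expect_identical(imp$mutant, ref)
  expect_equal(nrow(imp$truth$variant_truth), 0)
})

test_that("named amino-acid changes are realized at the codon level", {
  ref <- generate_reference_cds(600, seed = 11)
  profs <- cultivar_profiles()
  # Gly -> Val is single-base reachable; Val -> Lys needs a two-base codon
  # change. Both must appear in the translated mutant.
  for (nm in c("DB1P", "TB1P")) {
    sp <- profs[[nm]]$substitution_profile
    imp <- implant_variants(ref, sp, seed = 13)
    ref_aa <- strsplit(oracle_translate(ref), "")[[1]]
    mut_aa <- strsplit(oracle_translate(imp$mutant), "")[[1]]
    one <- c(Gly = "G", Val = "V", Lys = "K")
    hit <- which(ref_aa == one[[sp$aa_change$from_aa]] &
                   mut_aa == one[[sp$aa_change$to_aa]])
    expect_true(length(hit) >= 1)
  }
})

test_that("implantation rejects infeasible or malformed requests", {
  expect_error(
    substitution_profile("bad", 3L,
                         data.frame(ref_base = "G", alt_base = "A",
                                    count = 5L)),
    class = "musadicho_invalid_profile")
  sp <- cultivar_profiles()[["Agbagba"]]$substitution_profile
  expect_error(implant_variants(generate_reference_cds(60, seed = 1), sp,
                                seed = 1),
               class = "musadicho_invalid_argument") # too short
  # no Trp -> Ter single-base route exists from a Phe-only reference
  odd <- substitution_profile("odd", 2L, NULL, "Pu-Pu",
                              list(from_aa = "Trp", codon_index = 1L,
                                   to_aa = "Trp"), "synonymous")
  expect_error(implant_variants(paste(rep("TTT", 10), collapse = ""), odd,
                                seed = 1),
               class = "musadicho_placement_failure")
})

test_that("phenology generator honours the concordance probability", {
  profs <- cultivar_profiles()
  ph1 <- generate_phenology(profs["Agbagba"], 10, 2, seed = 4)
  s <- compute_concordance(ph1$records, "Agbagba")
  expect_equal(s$cc, 1.0) # prob 1 -> fully concordant

  ph0 <- generate_phenology(profs["TB3P"], 10, 2, seed = 4)
  expect_equal(compute_concordance(ph0$records, "TB3P")$cc, 0.0)

  # record count conservation and determinism
  ph <- generate_phenology(profs, 10, 2, seed = 9)
  expect_equal(nrow(ph$records), 6 * 10 * (1 + 2))
  expect_identical(ph, generate_phenology(profs, 10, 2, seed = 9))
  expect_error(generate_phenology(list(), 10, 2, seed = 1),
               class = "musadicho_invalid_argument")

  # Monte-Carlo: 10 plants x 2 obs at prob 0.65 -> ~13 concordant of 20
  n_conc <- vapply(1:300, function(s) {
    r <- generate_phenology(profs["DB1P"], 10, 2, seed = s)
    compute_concordance(r$records, "DB1P")$n_concordant
  }, integer(1))
  expect_lt(abs(mean(n_conc) - 13), 0.5)
})

test_that("flow histograms place peaks by the ploidy-to-control ratio", {
  # diploid sample against a triploid control at channel 75 -> centre 50
  h <- generate_flow_histogram(2, control_ploidy = 3, control_channel = 75,
                               seed = 21)
  expect_s3_class(h, "flow_histogram")
  expect_equal(sum(h$counts), 5000) # conservation
  sample_region <- h$counts[40:60]
  expect_lt(abs(h$channels[40:60][which.max(sample_region)] - 50), 3)

  # control's own ploidy -> single merged peak at the control channel
  h3 <- generate_flow_histogram(3, seed = 21)
  expect_lt(abs(h3$channels[which.max(h3$counts)] - 75), 3)

  expect_identical(generate_flow_histogram(2, seed = 5),
                   generate_flow_histogram(2, seed = 5))
  expect_error(generate_flow_histogram(8, control_channel = 75,
                                       n_channels = 128, seed = 1),
               class = "musadicho_invalid_argument") # centre off-scale
})

test_that("cohort generation is seeded, labelled and conserved", {
  comp <- data.frame(ploidy = c(2, 4), count = c(9, 1))
  coh <- generate_cohort(comp, seed = 6)
  expect_length(coh$histograms, 10)
  expect_equal(unname(table(coh$truth$ploidy_truth)[["2"]]), 9)
  expect_identical(coh, generate_cohort(comp, seed = 6))
  one <- generate_cohort(list(c(3, 1)), seed = 2)
  expect_length(one$histograms, 1)
  expect_error(generate_cohort(data.frame(), seed = 1),
               class = "musadicho_invalid_argument")
})

test_that("chromosome-count tables reflect true ploidy with rare miscounts", {
  truth <- c(p1 = 2L, p2 = 3L)
  cy <- generate_chromosome_counts(truth, n_cells = 10, miscount_prob = 0.1,
                                   seed = 8)
  expect_equal(nrow(cy$counts), 20)
  for (pid in names(truth)) {
    counts <- cy$counts$chromosome_count[cy$counts$plant_id == pid]
    expect_true(all(abs(counts - truth[[pid]] * 11) <= 1))
  }
  expect_identical(cy, generate_chromosome_counts(truth, n_cells = 10,
                                                  miscount_prob = 0.1,
                                                  seed = 8))
})
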