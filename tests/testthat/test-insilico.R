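test_that("PCR simulation reproduces the concatenation oracle", {
  pair <- design_c_tag(toy_locus(), toy_cfg_c())
  amp <- simulate_pcr(toy_template(), pair)
  expect_identical(amp$seq, "GCCAAAGGTTCTGGTAACGAAGCTTAAGGTAGTGGGGGGGT")
  expect_identical(amp$arm5, pair$fwd_arm)
  expect_identical(amp$arm3, reverse_complement(pair$rev_arm))
  expect_identical(nchar(amp$seq), 2L * 6L + nchar(amp$interior))
})

test_that("amplification fails for absent or duplicated annealing sites", {
  pair <- design_c_tag(toy_locus(), toy_cfg_c())
  off_template <- plasmid_template("TTAACCGGTTAACCGGTTAACCGG", circular = FALSE)
  expect_error(simulate_pcr(off_template, pair), class = "potkit_amplification_error")
  dup <- plasmid_template(
    paste0("TT", "GGTTCTGGT", "AACGAA", "GGTTCTGGT", "GCTTAA", "GGTAGTGG", "AA"),
    circular = FALSE)
  expect_error(simulate_pcr(dup, pair), class = "potkit_amplification_error")
})

test_that("circular templates amplify across the origin", {
  pair <- design_c_tag(toy_locus(), toy_cfg_c())
  linear <- paste0("TT", "GGTTCTGGT", "AACGAAGCTTAA", "GGTAGTGG", "AA")
  straight <- simulate_pcr(plasmid_template(linear, circular = TRUE), pair)
  # rotate so the amplified segment spans the sequence origin
  rotated <- paste0(substr(linear, 16, nchar(linear)), substr(linear, 1, 15))
  wrapped <- simulate_pcr(plasmid_template(rotated, circular = TRUE), pair)
  expect_identical(wrapped$seq, straight$seq)
  expect_error(simulate_pcr(plasmid_template(rotated, circular = FALSE), pair),
               class = "potkit_amplification_error")
})

test_that("integration splices the amplicon interior between the arms", {
  lc <- toy_locus()
  amp <- simulate_pcr(toy_template(), design_c_tag(lc, toy_cfg_c()))
  modified <- integrate_amplicon(lc, amp, min_arm = 6L)
  expect_identical(modified$seq,
    "AAAAACCCCCATGGCCAAAGGTTCTGGTAACGAAGCTTAAGGTAGTGGGGGGGTTTTT")
  expect_identical(modified$replaced, c(19L, 22L))   # the stop codon
  # sequence outside the replaced span is conserved byte-for-byte
  original <- paste0(lc$up_flank, lc$cds, lc$down_flank)
  expect_identical(substr(modified$seq, 1, 19), substr(original, 1, 19))
  expect_identical(substr(modified$seq, nchar(modified$seq) - 9, nchar(modified$seq)),
                   substr(original, nchar(original) - 9, nchar(original)))
})

test_that("adjacent arms give a pure insertion", {
  lc <- toy_locus()
  # arms flank nothing: 5' arm ends where 3' arm begins
  amp <- structure(list(seq = paste0("GCCAAATAA", "XXX", "GGGGG"),
                        arm5 = "GCCAAATAA", arm3 = "GGGGG",
                        interior = "CGATCG", gene_id = "toy", mode = "c"),
                   class = "amplicon")
  amp$seq <- paste0(amp$arm5, amp$interior, amp$arm3)
  modified <- integrate_amplicon(lc, amp, min_arm = 5L)
  expect_identical(nchar(modified$seq),
                   nchar(paste0(lc$up_flank, lc$cds, lc$down_flank)) + 6L)
  expect_identical(modified$replaced[1], modified$replaced[2])
})

test_that("a single-nucleotide arm mismatch aborts integration", {
  lc <- toy_locus()
  amp <- simulate_pcr(toy_template(), design_c_tag(lc, toy_cfg_c()))
  mutated <- amp
  mutated$arm5 <- paste0("T", substr(amp$arm5, 2, nchar(amp$arm5)))
  mutated$seq <- paste0(mutated$arm5, amp$interior, amp$arm3)
  expect_error(integrate_amplicon(lc, mutated, min_arm = 6L),
               class = "potkit_integration_error")
})

test_that("arm ordering and multiplicity are enforced", {
  lc <- locus("rep", "AAGCCAAATT", "ATGGCCAAATAA", "GGGGGTTTTT")
  amp <- list(arm5 = "GCCAAA", arm3 = "GGGGG", interior = "CCC")
  amp$seq <- paste0(amp$arm5, amp$interior, amp$arm3)
  class(amp) <- "amplicon"
  # GCCAAA occurs in the up flank and the CDS
  expect_error(integrate_amplicon(lc, amp, min_arm = 3L),
               class = "potkit_integration_error")
})

test_that("the C-tag toy round trip translates target, linker and tag", {
  lc <- toy_locus()
  amp <- simulate_pcr(toy_template(), design_c_tag(lc, toy_cfg_c()))
  modified <- integrate_amplicon(lc, amp, min_arm = 6L)
  report <- verify_fusion(modified, lc, "c", expected_tag = "NEA")
  expect_true(report$in_frame)
  expect_true(report$junction_ok)
  expect_false(report$premature_stop)
  expect_identical(report$fusion_protein, "MAKGSGNEA")
})

test_that("a one-nucleotide frameshift in the cassette is detected", {
  lc <- toy_locus()
  amp <- simulate_pcr(toy_template(), design_c_tag(lc, toy_cfg_c()))
  shifted <- amp
  shifted$interior <- paste0(substr(amp$interior, 1, 9), "G",
                             substr(amp$interior, 10, nchar(amp$interior)))
  shifted$seq <- paste0(shifted$arm5, shifted$interior, shifted$arm3)
  modified <- integrate_amplicon(lc, shifted, min_arm = 6L)
  report <- verify_fusion(modified, lc, "c", expected_tag = "NEA")
  expect_false(report$in_frame)
})

test_that("an empty expected tag reduces to a stop-free ORF check", {
  lc <- toy_locus()
  amp <- simulate_pcr(toy_template(), design_c_tag(lc, toy_cfg_c()))
  modified <- integrate_amplicon(lc, amp, min_arm = 6L)
  report <- verify_fusion(modified, lc, "c", expected_tag = "")
  expect_true(report$in_frame)
  expect_true(report$junction_ok)
})

test_that("all four modes round-trip in frame on random loci", {
  template <- pot_plasmid()
  for (seed in 1:25) {
    lc <- random_locus(cds_len = sample(seq(300, 1200, by = 3), 1),
                       flank_len = 120, seed = 200 + seed)
    n_aa <- nchar(lc$cds) / 3 - 1
    ann <- signal_annotation(lc$gene_id, sp_end_aa = 20,
                             ctd_start_aa = floor(n_aa - 30))
    for (mode in c("n", "c", "sp", "ctd")) {
      report <- round_trip(lc, mode, template, ann = ann)
      expect_true(report$in_frame,
                  info = sprintf("seed %d mode %s", seed, mode))
    }
  }
})

test_that("modified loci serialize to FASTA with a GFF3 cassette annotation", {
  lc <- toy_locus()
  amp <- simulate_pcr(toy_template(), design_c_tag(lc, toy_cfg_c()))
  modified <- integrate_amplicon(lc, amp, min_arm = 6L)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "mod.fasta"); gff <- file.path(dir, "mod.gff3")
  write_modified_locus(modified, fa, gff)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_identical(as.character(seqs[[1]]), modified$seq)
  feats <- rtracklayer::import(gff)
  expect_identical(GenomicRanges::start(feats), modified$insert[1] + 1L)
  expect_identical(GenomicRanges::end(feats), modified$insert[2])
})

test_that("the shipped plasmid map parses with its annealing features", {
  template <- pot_plasmid()
  expect_true(template$circular)
  for (mode in c("n", "c")) {
    sites <- anneal_sites(mode, template)
    expect_gt(nchar(sites$fwd), 0)
    expect_gt(nchar(sites$rev), 0)
  }
  expect_match(tag_protein(template, "n"), "^M")
  expect_error(feature_seq <- potkit:::feature_seq(template, "nonexistent"),
               class = "potkit_lookup_error")
})
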