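test_that("C-terminal design matches the string-construction oracle", {
  pair <- design_c_tag(toy_locus(), toy_cfg_c())
  expect_identical(pair$forward, "GCCAAAGGTTCTGGT")   # last 6 nt of ATGGCCAAA + anneal
  expect_identical(pair$reverse, "ACCCCCCCACTACC")    # rc(GGGGGT) + anneal
  expect_identical(pair$junction, c(19L, 22L))        # replaces exactly the stop
})

test_that("C-terminal design refuses arms longer than the template regions", {
  err <- expect_error(design_c_tag(toy_locus(), toy_cfg_c(arm_len = 12L)),
                      class = "potkit_design_error")
  expect_match(conditionMessage(err), "deficit")
  expect_error(design_c_tag(toy_locus(), toy_cfg_c(arm_len = 11L)),
               class = "potkit_design_error")  # downstream flank only 10 nt
})

test_that("N-terminal design handles both start-codon conventions", {
  pair <- design_n_tag(toy_locus(), toy_cfg_n())
  expect_identical(pair$forward, "ACCCCCCATTACGG")    # last 6 nt of up flank + anneal
  expect_identical(pair$reverse, "TTTGGCGGCCTAGG")    # rc of cds nt 4-9 + anneal
  with_atg <- design_n_tag(toy_locus(), toy_cfg_n(include_start_codon = TRUE))
  expect_identical(with_atg$rev_arm, "GGCCAT")        # rc(ATGGCC)
})

test_that("SP replacement removes the signal peptide codons", {
  lc <- locus("toy2", "AAAAACCCCC", "ATGTTTGCCAAAGATTAA", "GGGGGTTTTT")
  ann <- signal_annotation("toy2", sp_end_aa = 2)
  pair <- design_sp_replacement(lc, ann, toy_cfg_n())
  expect_identical(pair$rev_arm, reverse_complement("GCCAAA"))
  expect_identical(pair$fwd_arm, design_n_tag(lc, toy_cfg_n())$fwd_arm)
  expect_identical(pair$junction, c(10L, 16L))        # codons 1..2 removed
  expect_error(design_sp_replacement(lc, signal_annotation("toy2", sp_end_aa = 4),
                                     toy_cfg_n()),
               class = "potkit_design_error")
  expect_error(design_sp_replacement(lc, signal_annotation("toy2"), toy_cfg_n()),
               class = "potkit_annotation_error")
})

test_that("CTD replacement removes the GPI processing domain through the stop", {
  lc <- locus("toy2", "AAAAACCCCC", "ATGTTTGCCAAAGATTAA", "GGGGGTTTTT")
  ann <- signal_annotation("toy2", ctd_start_aa = 4)
  pair <- design_ctd_replacement(lc, ann, toy_cfg_c())
  expect_identical(pair$fwd_arm, "TTTGCC")            # last 6 nt of ATGTTTGCC
  expect_identical(pair$rev_arm, reverse_complement("GGGGGT"))
  expect_identical(pair$junction, c(19L, 28L))        # codons 4..stop removed
  expect_error(design_ctd_replacement(lc, signal_annotation("toy2", ctd_start_aa = 2),
                                      toy_cfg_c()),
               class = "potkit_design_error")
  expect_error(design_ctd_replacement(lc, signal_annotation("toy2"), toy_cfg_c()),
               class = "potkit_annotation_error")
})

test_that("primers end in the annealing sequence with the configured length", {
  template <- pot_plasmid()
  ann <- signal_annotation("GENE1", sp_end_aa = 20, ctd_start_aa = 80)
  for (seed in 1:10) {
    lc <- random_locus(cds_len = 400, flank_len = 120, seed = seed)
    for (mode in c("n", "c", "sp", "ctd")) {
      cfg <- tagging_config(arm_len = 80L, mode = mode, template = template)
      pair <- switch(mode,
        c = design_c_tag(lc, cfg), n = design_n_tag(lc, cfg),
        sp = design_sp_replacement(lc, ann, cfg),
        ctd = design_ctd_replacement(lc, ann, cfg))
      expect_identical(nchar(pair$forward), 80L + nchar(cfg$fwd_anneal))
      expect_identical(nchar(pair$reverse), 80L + nchar(cfg$rev_anneal))
      expect_match(pair$forward, paste0(cfg$fwd_anneal, "$"))
      expect_match(pair$reverse, paste0(cfg$rev_anneal, "$"))
      # junctions respect codon boundaries relative to the CDS
      up <- nchar(lc$up_flank)
      expect_identical((pair$junction[1] - up) %% 3L, 0L)
      expect_identical((pair$junction[2] - up) %% 3L, 0L)
    }
  }
})

test_that("arms are unique on their strands for non-repetitive loci", {
  template <- pot_plasmid()
  for (seed in 1:20) {
    lc <- random_locus(cds_len = 600, flank_len = 120, seed = 100 + seed)
    seq <- paste0(lc$up_flank, lc$cds, lc$down_flank)
    for (mode in c("n", "c")) {
      cfg <- tagging_config(arm_len = 80L, mode = mode, template = template)
      pair <- if (mode == "c") design_c_tag(lc, cfg) else design_n_tag(lc, cfg)
      expect_identical(lengths(regmatches(seq, gregexpr(pair$fwd_arm, seq, fixed = TRUE))), 1L)
      rc_rev <- reverse_complement(pair$rev_arm)
      expect_identical(lengths(regmatches(seq, gregexpr(rc_rev, seq, fixed = TRUE))), 1L)
    }
  }
})

test_that("batch design equals per-gene designs and flags failures", {
  template <- pot_plasmid()
  cfg <- tagging_config(arm_len = 80L, mode = "c", template = template)
  loci <- list(
    b = random_locus(300, 120, "geneB", seed = 3),
    a = random_locus(300, 120, "geneA", seed = 2),
    c = random_locus(300, 120, "geneC", seed = 4))
  tab <- design_genome_batch(loci, cfg, mode = "c")
  expect_identical(tab$gene_id, c("geneA", "geneB", "geneC"))  # deterministic order
  for (i in seq_len(nrow(tab))) {
    single <- design_c_tag(loci[[match(tab$gene_id[i], c("geneB", "geneA", "geneC"))]], cfg)
    expect_identical(tab$forward_primer[i], single$forward)
    expect_identical(tab$reverse_primer[i], single$reverse)
  }
  expect_true(all(tab$flags == ""))

  empty <- design_genome_batch(list(), cfg, mode = "c")
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("gene_id", "forward_primer", "flags") %in% names(empty)))

  short <- list(s = locus("geneS", strrep("A", 120), "ATGGCCAAATAA", strrep("T", 120)))
  tab2 <- design_genome_batch(short, cfg, mode = "c")
  expect_identical(tab2$forward_primer, "")
  expect_match(tab2$flags, "^error:")
})

test_that("signal annotations load from TSV with blanks meaning absent", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ann.tsv")
  writeLines(c("gene_id\tsp_end_aa\tctd_start_aa",
               "g1\t30\t117",
               "g2\t16\t",
               "g3\t\t92"), path)
  anns <- read_signal_annotations(path)
  expect_identical(anns[["g1"]]$sp_end_aa, 30L)
  expect_identical(anns[["g1"]]$ctd_start_aa, 117L)
  expect_true(is.na(anns[["g2"]]$ctd_start_aa))
  expect_true(is.na(anns[["g3"]]$sp_end_aa))
  expect_error(signal_annotation("bad", sp_end_aa = 10, ctd_start_aa = 5),
               class = "potkit_annotation_error")
})

test_that("primer tables are written as TSV and CSV", {
  cfg <- toy_cfg_c()
  tab <- design_genome_batch(list(toy = toy_locus()), cfg, mode = "c")
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "primers.tsv"); csv <- file.path(dir, "primers.csv")
  write_primer_table(tab, tsv)
  write_primer_table(tab, csv)
  expect_identical(utils::read.delim(tsv, stringsAsFactors = FALSE)$forward_primer,
                   tab$forward_primer)
  expect_identical(utils::read.csv(csv, stringsAsFactors = FALSE)$reverse_primer,
                   tab$reverse_primer)
})
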