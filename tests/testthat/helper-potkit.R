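# shared fixtures built in code

toy_locus <- function() {
  locus("toy", "AAAAACCCCC", "ATGGCCAAATAA", "GGGGGTTTTT")
}

toy_cfg_c <- function(arm_len = 6L) {
  tagging_config(arm_len = arm_len, fwd_anneal = "GGTTCTGGT",
                 rev_anneal = "CCACTACC", plasmid_id = "toy")
}

toy_cfg_n <- function(arm_len = 6L, include_start_codon = FALSE) {
  tagging_config(arm_len = arm_len, fwd_anneal = "CATTACGG",
                 rev_anneal = "GGCCTAGG", plasmid_id = "toy",
                 include_start_codon = include_start_codon)
}

# linear toy template matching toy_cfg_c: TT | fwd site | insert | rev site | AA
toy_template <- function() {
  plasmid_template(paste0("TT", "GGTTCTGGT", "AACGAAGCTTAA", "GGTAGTGG", "AA"),
                   circular = FALSE, id = "toy_template")
}

# write a one-contig genome FASTA + one-gene GFF3 and return the paths
write_toy_genome <- function(up, cds, down, strand = "+",
                             dir = withr::local_tempdir(.local_envir = parent.frame())) {
  if (strand == "+") {
    contig <- paste0(up, cds, down)
    s <- nchar(up) + 1L
    e <- nchar(up) + nchar(cds)
  } else {
    contig <- reverse_complement(paste0(up, cds, down))
    s <- nchar(down) + 1L
    e <- nchar(down) + nchar(cds)
  }
  fa <- file.path(dir, "genome.fasta")
  gff <- file.path(dir, "genes.gff3")
  writeLines(c(">chr1", contig), fa)
  writeLines(c(
    "##gff-version 3",
    sprintf("chr1\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=gene1", s, e, strand),
    sprintf("chr1\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tID=g1;Parent=gene1", s, e, strand)
  ), gff)
  list(fasta = fa, gff = gff)
}

# full design -> PCR -> integration -> verification round trip for one locus
round_trip <- function(lc, mode, template = pot_plasmid(), arm_len = 80L,
                       ann = NULL) {
  cfg <- tagging_config(arm_len = arm_len, mode = mode, template = template)
  pair <- switch(mode,
    c = design_c_tag(lc, cfg),
    n = design_n_tag(lc, cfg),
    sp = design_sp_replacement(lc, ann, cfg),
    ctd = design_ctd_replacement(lc, ann, cfg))
  amp <- simulate_pcr(template, pair)
  modified <- integrate_amplicon(lc, amp)
  verify_fusion(modified, lc, mode, tag_protein(template, mode))
}
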