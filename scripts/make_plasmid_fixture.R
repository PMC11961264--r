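#!/usr/bin/env Rscript
# Builds inst/extdata/pPOT_synthetic.gb: a deterministic, fully synthetic
# tagging-plasmid map with the layout of a PCR-only tagging plasmid
# (universal N/C annealing sites embedded in GS-linker coding sequence,
# synthetic tag ORFs, synthetic resistance cassette). Re-run only if the
# layout changes; the output is committed.

set.seed(20240401)

sense_codons <- {
  bases <- c("A", "C", "G", "T")
  cods <- as.vector(outer(as.vector(outer(bases, bases, paste0)), bases, paste0))
  setdiff(cods, c("TAA", "TAG", "TGA"))
}
rand_codons <- function(n) paste(sample(sense_codons, n, replace = TRUE), collapse = "")
rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

rc <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# universal annealing sequences (as written 5'->3' on the primers)
N_FWD <- "GACCAGTTGAAAGATGCGCA"                 # N-type forward primer 3' end
N_REV <- rc("GGAAGTGGTTCTGGTAGTGGT")            # rc = GS linker on top strand
C_FWD <- "GGTTCTGGTAGTGGTTCCGGA"                # GS linker, frame 0
C_REV <- "CCAATTTGAGAGACCTGTGC"

backbone_up  <- rand_nt(30)
igrA <- rand_nt(40)
res_orf <- paste0("ATG", rand_codons(20), "TGA")
igrB <- rand_nt(40)
tagN_body <- rand_codons(30)                    # no internal stop, no terminal stop
tagN_orf <- paste0("ATG", tagN_body, rc(N_REV)) # in frame through the GS linker
spacer <- rand_nt(12)
tagC_body <- rand_codons(30)
tagC_orf <- paste0(C_FWD, tagC_body, "TAA")     # fusion frame continues from arm
igrC <- rand_nt(40)
backbone_down <- rand_nt(30)

seq <- paste0(backbone_up, N_FWD, igrA, res_orf, igrB, tagN_orf, spacer,
              tagC_orf, igrC, rc(C_REV), backbone_down)

stopifnot(
  lengths(regmatches(seq, gregexpr(N_FWD, seq, fixed = TRUE))) == 1L,
  lengths(regmatches(seq, gregexpr(rc(N_REV), seq, fixed = TRUE))) == 1L,
  lengths(regmatches(seq, gregexpr(C_FWD, seq, fixed = TRUE))) == 1L,
  lengths(regmatches(seq, gregexpr(rc(C_REV), seq, fixed = TRUE))) == 1L,
  nchar(tagN_orf) %% 3 == 0, nchar(tagC_orf) %% 3 == 0
)

pos <- function(sub) as.integer(regexpr(sub, seq, fixed = TRUE))
feat <- function(key, start, len, strand, label) {
  loc <- sprintf("%d..%d", start, start + len - 1L)
  if (strand == "-") loc <- sprintf("complement(%s)", loc)
  c(sprintf("     %-16s%s", key, loc), sprintf('                     /label="%s"', label))
}

features <- c(
  feat("source", 1L, nchar(seq), "+", "pPOT_synthetic"),
  feat("misc_feature", pos(N_FWD), nchar(N_FWD), "+", "fwd_anneal_N"),
  feat("CDS", pos(res_orf), nchar(res_orf), "+", "resistance_synthetic"),
  feat("CDS", pos(tagN_orf), nchar(tagN_orf), "+", "tag_orf_N"),
  feat("misc_feature", pos(rc(N_REV)), nchar(N_REV), "-", "rev_anneal_N"),
  feat("misc_feature", pos(C_FWD), nchar(C_FWD), "+", "fwd_anneal_C"),
  feat("CDS", pos(tagC_orf), nchar(tagC_orf), "+", "tag_orf_C"),
  feat("misc_feature", pos(rc(C_REV)), nchar(C_REV), "-", "rev_anneal_C")
)

seq_lines <- character(0)
low <- tolower(seq)
i <- 1L
while (i <= nchar(low)) {
  chunk <- substr(low, i, min(i + 59L, nchar(low)))
  blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
  seq_lines <- c(seq_lines, sprintf("%9d %s", i, paste(blocks, collapse = " ")))
  i <- i + 60L
}

out <- c(
  sprintf("LOCUS       pPOT_synthetic %10d bp    DNA     circular SYN 01-APR-2024", nchar(seq)),
  "DEFINITION  Synthetic stand-in tagging plasmid (not a published sequence).",
  "COMMENT     Fully synthetic map generated by scripts/make_plasmid_fixture.R;",
  "COMMENT     layout mimics a PCR-only tagging plasmid for round-trip testing.",
  "FEATURES             Location/Qualifiers",
  features,
  "ORIGIN",
  seq_lines,
  "//"
)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
writeLines(out, "inst/extdata/pPOT_synthetic.gb")
cat("wrote inst/extdata/pPOT_synthetic.gb (", nchar(seq), "bp )\n")
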