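# Sequence primitives shared by the design and simulation modules.
#
# Nucleotide and protein sequences are plain upper-case character scalars
# validated on construction; heavy lifting (complementation, FASTA/GFF3 I/O)
# is delegated to Biostrings/rtracklayer.

NUC_ALPHABET  <- c("A", "C", "G", "T", "N")
PROT_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                   "F","P","S","T","W","Y","V")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Validate and normalize a DNA sequence
#'
#' Accepts lower- or mixed-case input over the alphabet A, C, G, T, N and
#' returns the upper-cased string. RNA (U) and IUPAC ambiguity codes other
#' than N are rejected: the toolkit operates on unambiguous genomic DNA.
#'
#' @param x character scalar (may be empty).
#' @return upper-case character scalar.
#' @export
nuc_seq <- function(x) {
  if (!is_string(x)) abort_alphabet("nucleotide sequence must be a single character string")
  x <- toupper(x)
  if (nchar(x) > 0L) {
    bad <- setdiff(unique(strsplit(x, "", fixed = TRUE)[[1]]), NUC_ALPHABET)
    if (length(bad) > 0L) {
      abort_alphabet(sprintf("invalid nucleotide character(s): %s",
                             paste(bad, collapse = ", ")))
    }
  }
  x
}

#' Validate a protein sequence
#'
#' One-letter amino-acid codes, optionally ending in a single terminal '*'
#' stop marker. Internal stops are rejected unless `allow_internal_stop` is
#' set (used when inspecting raw translations).
#'
#' @param x character scalar.
#' @param allow_internal_stop permit '*' anywhere, not just terminally.
#' @return upper-case character scalar.
#' @export
prot_seq <- function(x, allow_internal_stop = FALSE) {
  if (!is_string(x)) abort_alphabet("protein sequence must be a single character string")
  x <- toupper(x)
  if (nchar(x) > 0L) {
    chars <- strsplit(x, "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(chars), c(PROT_ALPHABET, "*"))
    if (length(bad) > 0L) {
      abort_alphabet(sprintf("invalid amino-acid character(s): %s",
                             paste(bad, collapse = ", ")))
    }
    if (!allow_internal_stop) {
      stops <- which(chars == "*")
      if (length(stops) > 1L || (length(stops) == 1L && stops != length(chars))) {
        abort_alphabet("internal '*' not permitted in a protein sequence")
      }
    }
  }
  x
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick reverse complement; N maps to N. An involution:
#' `reverse_complement(reverse_complement(s)) == s`.
#'
#' @param s DNA string (see [nuc_seq()]).
#' @return reverse-complemented string, read 5' to 3'.
#' @export
reverse_complement <- function(s) {
  s <- nuc_seq(s)
  if (nchar(s) == 0L) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# codon -> amino acid lookup from the standard genetic code
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a coding sequence with the standard genetic code
#'
#' Stop codons render as '*'. Internal stops are permitted (and flagged via
#' the `"internal_stop"` attribute) so that frameshifted fusions can be
#' inspected; codons containing N translate to 'X'.
#'
#' @param cds DNA string, length divisible by 3.
#' @return protein string; attribute `internal_stop` is TRUE when a stop
#'   occurs before the final codon.
#' @export
translate_cds <- function(cds) {
  cds <- nuc_seq(cds)
  if (nchar(cds) %% 3L != 0L) {
    abort_frame(sprintf("CDS length %d is not divisible by 3", nchar(cds)))
  }
  codons <- split_codons(cds)
  tab <- codon_table()
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"
  prot <- paste(aa, collapse = "")
  internal <- length(aa) > 1L && any(aa[-length(aa)] == "*")
  structure(prot, internal_stop = internal)
}

#' Construct a gene locus in coding orientation
#'
#' A locus bundles a CDS with its strand-resolved flanking sequences: the
#' flanks are stored so that `up_flank + cds + down_flank` reads 5'->3' on the
#' coding strand regardless of the gene's genomic strand.
#'
#' @param gene_id identifier.
#' @param up_flank sequence immediately 5' of the start codon.
#' @param cds coding sequence: starts ATG, ends with a stop, length %% 3 == 0.
#' @param down_flank sequence immediately 3' of the stop codon.
#' @param strand genomic source strand, "+" or "-".
#' @return object of class `locus`.
#' @export
locus <- function(gene_id, up_flank, cds, down_flank, strand = "+") {
  cds <- nuc_seq(cds)
  if (nchar(cds) %% 3L != 0L) abort_frame(sprintf("%s: CDS length not divisible by 3", gene_id))
  if (nchar(cds) < 6L) abort_frame(sprintf("%s: CDS shorter than two codons", gene_id))
  if (substr(cds, 1L, 3L) != "ATG") abort_frame(sprintf("%s: CDS does not begin with ATG", gene_id))
  last <- substr(cds, nchar(cds) - 2L, nchar(cds))
  if (!last %in% STOP_CODONS) abort_frame(sprintf("%s: CDS does not end with a stop codon", gene_id))
  if (!strand %in% c("+", "-")) abort_data(sprintf("%s: strand must be '+' or '-'", gene_id))
  structure(
    list(gene_id = gene_id, up_flank = nuc_seq(up_flank), cds = cds,
         down_flank = nuc_seq(down_flank), strand = strand),
    class = "locus"
  )
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("<locus> %s (%s strand): %d nt CDS, flanks %d/%d nt\n",
              x$gene_id, x$strand, nchar(x$cds), nchar(x$up_flank),
              nchar(x$down_flank)))
  invisible(x)
}

# full top-strand sequence of a locus in coding orientation
locus_seq <- function(locus) {
  paste0(locus$up_flank, locus$cds, locus$down_flank)
}

#' Extract strand-resolved loci from a genome FASTA and GFF3 annotation
#'
#' One locus per single-exon protein-coding gene (CDS feature), with flanks of
#' `flank_len` nucleotides taken from the genomic context and
#' reverse-complemented for minus-strand genes so every locus is in coding
#' orientation. Flanks truncated at contig ends raise a warning. Genes whose
#' CDS violates the locus invariants (no ATG start, no terminal stop, length
#' not divisible by 3, multiple CDS segments) are skipped and recorded in the
#' `"skipped"` attribute, a data frame of gene_id and reason.
#'
#' GFF3 coordinates (1-based inclusive) are converted to internal 0-based
#' half-open coordinates at the parser boundary.
#'
#' @param genome path to a FASTA file.
#' @param annotations path to a GFF3 file with CDS features; the ID (or
#'   Parent) attribute identifies the gene.
#' @param flank_len flank length in nucleotides.
#' @return named list of `locus` objects with attribute `skipped`.
#' @export
load_loci <- function(genome, annotations, flank_len = 120L) {
  if (!file.exists(genome)) abort_lookup(sprintf("genome FASTA not found: %s", genome))
  if (!file.exists(annotations)) abort_lookup(sprintf("GFF3 not found: %s", annotations))
  contigs <- Biostrings::readDNAStringSet(genome)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gff <- rtracklayer::import(annotations)
  gff <- gff[tolower(as.character(gff$type)) == "cds"]
  ids <- gff$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gff))
  if (!is.null(gff$Parent)) {
    par <- vapply(gff$Parent, function(p) if (length(p)) p[[1]] else NA_character_, character(1))
    ids <- ifelse(is.na(ids) | ids == "", par, ids)
  }
  if (anyNA(ids)) abort_data("CDS feature without ID/Parent attribute")

  skipped <- list()
  out <- list()
  for (gid in sort(unique(ids))) {
    feats <- gff[ids == gid]
    if (length(feats) > 1L) {
      skipped[[gid]] <- "multi-exon CDS not supported"
      next
    }
    chrom <- as.character(GenomicRanges::seqnames(feats))
    if (!chrom %in% names(contigs)) {
      abort_lookup(sprintf("contig '%s' referenced by %s absent from FASTA", chrom, gid))
    }
    ctg <- contigs[[chrom]]
    L <- length(ctg)
    # convert to 0-based half-open
    s0 <- GenomicRanges::start(feats) - 1L
    e0 <- GenomicRanges::end(feats)
    strand <- as.character(GenomicRanges::strand(feats))
    if (!strand %in% c("+", "-")) strand <- "+"
    cds_g <- as.character(Biostrings::subseq(ctg, s0 + 1L, e0))
    up_s <- max(0L, s0 - flank_len); down_e <- min(L, e0 + flank_len)
    up_g   <- if (s0 > up_s) as.character(Biostrings::subseq(ctg, up_s + 1L, s0)) else ""
    down_g <- if (down_e > e0) as.character(Biostrings::subseq(ctg, e0 + 1L, down_e)) else ""
    if (nchar(up_g) < flank_len || nchar(down_g) < flank_len) {
      warning(sprintf("%s: flank truncated at contig end", gid), call. = FALSE)
    }
    if (strand == "-") {
      cds <- reverse_complement(cds_g)
      up <- reverse_complement(down_g)
      down <- reverse_complement(up_g)
    } else {
      cds <- nuc_seq(cds_g); up <- nuc_seq(up_g); down <- nuc_seq(down_g)
    }
    lc <- tryCatch(locus(gid, up, cds, down, strand), potkit_error = function(e) e)
    if (inherits(lc, "condition")) {
      skipped[[gid]] <- conditionMessage(lc)
    } else {
      out[[gid]] <- lc
    }
  }
  skipdf <- if (length(skipped)) {
    data.frame(gene_id = names(skipped), reason = unlist(skipped),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(0), reason = character(0))
  }
  structure(out, skipped = skipdf)
}

#' Serialize loci as FASTA plus a GFF3 sidecar
#'
#' Each locus becomes one contig (`up_flank + cds + down_flank`) carrying a
#' single CDS feature on the plus strand, so [load_loci()] on the written pair
#' reconstructs the input (round-trip property).
#'
#' @param loci list of `locus` objects.
#' @param fasta,gff output paths.
#' @return invisibly, the two paths.
#' @export
write_loci <- function(loci, fasta, gff) {
  seqs <- Biostrings::DNAStringSet(vapply(loci, locus_seq, character(1)))
  ids <- vapply(loci, function(l) l$gene_id, character(1))
  names(seqs) <- paste0(ids, "_region")
  Biostrings::writeXStringSet(seqs, fasta)
  gr <- GenomicRanges::GRanges(
    seqnames = names(seqs),
    ranges = IRanges::IRanges(
      start = vapply(loci, function(l) nchar(l$up_flank) + 1L, integer(1)),
      end = vapply(loci, function(l) nchar(l$up_flank) + nchar(l$cds), integer(1))
    ),
    strand = "+", type = "CDS", ID = ids, phase = 0L
  )
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(c(fasta = fasta, gff = gff))
}

#' Generate a random locus with valid CDS structure
#'
#' Used by property tests and the acceptance checks: a uniform-random CDS
#' (ATG, stop-free random internal codons, terminal stop) with random flanks.
#' Long random arms are effectively unique within the locus, mimicking the
#' non-repetitive context the tagging scheme assumes.
#'
#' @param cds_len CDS length in nt (coerced to a multiple of 3, >= 9).
#' @param flank_len flank length in nt.
#' @param gene_id identifier.
#' @param seed optional integer seed.
#' @return a `locus`.
#' @export
random_locus <- function(cds_len = 300L, flank_len = 120L,
                         gene_id = "GENE1", seed = NULL) {
  with_seed(seed, {
    cds_len <- max(9L, (as.integer(cds_len) %/% 3L) * 3L)
    n_internal <- cds_len %/% 3L - 2L
    tab <- codon_table()
    sense <- names(tab)[tab != "*"]
    codons <- sample(sense, n_internal, replace = TRUE)
    cds <- paste0("ATG", paste(codons, collapse = ""), sample(STOP_CODONS, 1L))
    rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    locus(gene_id, rnd(flank_len), cds, rnd(flank_len))
  })
}
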