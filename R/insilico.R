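# In-silico PCR, homology-directed integration and fusion verification:
# the round-trip oracle every primer design must pass.

#' Simulate PCR amplification from a plasmid template
#'
#' The forward primer's annealing portion must match the template top strand
#' exactly once; the reverse primer's annealing portion must match the bottom
#' strand exactly once (i.e. its reverse complement occurs once on the top
#' strand). The amplicon is the template segment from the start of the forward
#' annealing site through the end of the reverse site, flanked by the primer
#' homology arms. Circular templates are traversed across the origin by
#' searching the doubled sequence and normalizing coordinates.
#'
#' @param template a [plasmid_template()].
#' @param primers a `primer_pair`.
#' @return object of class `amplicon`: `seq`, with `arm5`/`arm3` (the arm
#'   sequences as they appear at the amplicon ends) and `interior` (the
#'   template-derived segment between them).
#' @export
simulate_pcr <- function(template, primers) {
  seq <- template$seq
  L <- nchar(seq)
  search <- if (template$circular) paste0(seq, seq) else seq
  fwd <- primers$fwd_anneal
  rev_site <- reverse_complement(primers$rev_anneal)

  n_fwd <- count_matches(fwd, seq)
  if (template$circular) {
    # occurrences spanning the origin
    n_fwd <- n_fwd + max(0L, count_matches(fwd, search) - 2L * n_fwd)
  }
  if (n_fwd == 0L) abort_amplify("forward annealing sequence absent from template")
  if (n_fwd > 1L) abort_amplify("forward annealing sequence occurs more than once (ambiguous)")
  n_rev <- count_matches(rev_site, seq)
  if (template$circular) {
    n_rev <- n_rev + max(0L, count_matches(rev_site, search) - 2L * n_rev)
  }
  if (n_rev == 0L) abort_amplify("reverse annealing sequence absent from template")
  if (n_rev > 1L) abort_amplify("reverse annealing sequence occurs more than once (ambiguous)")

  f_pos <- match_pos(fwd, search)
  r_pos <- match_pos(rev_site, substr(search, f_pos, nchar(search)))
  if (r_pos == 0L) {
    abort_amplify("reverse annealing site not found downstream of the forward site")
  }
  r_abs <- f_pos + r_pos - 1L
  interior_end <- r_abs + nchar(rev_site) - 1L
  if (template$circular && interior_end - f_pos + 1L > L) {
    abort_amplify("annealing sites do not define a segment within one template length")
  }
  interior <- substr(search, f_pos, interior_end)
  arm3 <- reverse_complement(primers$rev_arm)
  structure(list(
    seq = paste0(primers$fwd_arm, interior, arm3),
    arm5 = primers$fwd_arm, arm3 = arm3, interior = interior,
    gene_id = primers$gene_id, mode = primers$mode
  ), class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon> %s [%s]: %d bp (arms %d/%d, interior %d)\n",
              x$gene_id %||% "?", toupper(x$mode %||% "?"), nchar(x$seq),
              nchar(x$arm5), nchar(x$arm3), nchar(x$interior)))
  invisible(x)
}

#' Integrate an amplicon into a locus by its homology arms
#'
#' Models homologous recombination of the long primer overhangs: the 5' arm
#' must occur exactly once on the locus top strand, the 3' arm exactly once
#' downstream of it, both at least `min_arm` nt long; matching is exact (a
#' single mismatch is a failed design, not a tolerated one). The segment
#' strictly between the two arm matches is replaced by the amplicon interior;
#' each arm is retained once.
#'
#' @param locus a [locus()].
#' @param amp an `amplicon`.
#' @param min_arm minimum arm length accepted (nt).
#' @return object of class `modified_locus`: `seq`, `replaced` (0-based
#'   half-open span of the original locus that was removed), `insert`
#'   (0-based half-open span of the interior within the new sequence),
#'   `gene_id`, `mode`.
#' @export
integrate_amplicon <- function(locus, amp, min_arm = 20L) {
  if (nchar(amp$arm5) < min_arm) {
    abort_integrate(sprintf("5' arm is %d nt, below min_arm %d", nchar(amp$arm5), min_arm))
  }
  if (nchar(amp$arm3) < min_arm) {
    abort_integrate(sprintf("3' arm is %d nt, below min_arm %d", nchar(amp$arm3), min_arm))
  }
  seq <- locus_seq(locus)
  n5 <- count_matches(amp$arm5, seq)
  if (n5 == 0L) abort_integrate("5' arm not found in locus")
  if (n5 > 1L) abort_integrate("5' arm matches the locus more than once")
  p5 <- match_pos(amp$arm5, seq)
  end5 <- p5 + nchar(amp$arm5) - 1L           # last base of 5' arm (1-based)
  rest <- substr(seq, end5 + 1L, nchar(seq))
  n3 <- count_matches(amp$arm3, rest)
  if (n3 == 0L) {
    if (count_matches(amp$arm3, seq) > 0L) {
      abort_integrate("3' arm found only upstream of the 5' arm (arms out of order)")
    }
    abort_integrate("3' arm not found in locus")
  }
  if (n3 > 1L) abort_integrate("3' arm matches the locus more than once")
  p3 <- end5 + match_pos(amp$arm3, rest)      # 1-based start of 3' arm match
  modified <- paste0(substr(seq, 1L, end5), amp$interior,
                     substr(seq, p3, nchar(seq)))
  structure(list(
    seq = modified,
    replaced = c(end5, p3 - 1L),              # 0-based half-open in original
    insert = c(end5, end5 + nchar(amp$interior)),  # 0-based half-open in new
    gene_id = locus$gene_id, mode = amp$mode
  ), class = "modified_locus")
}

#' @export
print.modified_locus <- function(x, ...) {
  cat(sprintf("<modified_locus> %s [%s]: %d bp; replaced span [%d, %d)\n",
              x$gene_id, toupper(x$mode %||% "?"), nchar(x$seq),
              x$replaced[1], x$replaced[2]))
  invisible(x)
}

# residues of the target CDS retained on each side of the replaced span
retained_residues <- function(modified, locus) {
  up <- nchar(locus$up_flank)
  n_cds <- nchar(locus$cds)
  r <- modified$replaced
  lo <- min(max(r[1] - up, 0L), n_cds)   # nt of CDS retained 5' of the cut
  hi <- min(max(up + n_cds - r[2], 0L), n_cds)  # nt retained 3' (incl. stop)
  if (lo %% 3L != 0L || hi %% 3L != 0L) {
    return(list(ok = FALSE, five = NULL, three = NULL))
  }
  five <- if (lo > 0L) sub("\\*$", "", as.character(translate_cds(substr(locus$cds, 1L, lo)))) else ""
  three <- if (hi > 0L) {
    sub("\\*$", "", as.character(translate_cds(substr(locus$cds, n_cds - hi + 1L, n_cds))))
  } else ""
  list(ok = TRUE, five = five, three = three)
}

# translate the modified sequence from a 1-based nt position to the first stop
orf_from <- function(seq, start1) {
  n_avail <- nchar(seq) - start1 + 1L
  n_use <- (n_avail %/% 3L) * 3L
  if (n_use < 3L) return(list(prot = "", stopped = FALSE))
  aa <- split_codons(substr(seq, start1, start1 + n_use - 1L))
  tab <- codon_table()
  res <- unname(tab[aa]); res[is.na(res)] <- "X"
  stop_at <- which(res == "*")
  if (length(stop_at)) {
    list(prot = paste(res[seq_len(stop_at[1] - 1L)], collapse = ""), stopped = TRUE)
  } else {
    list(prot = paste(res, collapse = ""), stopped = FALSE)
  }
}

#' Verify the reading frame of a tagged locus
#'
#' Scans the open reading frame of the modified locus: from the target's
#' original ATG for C-terminal/CTD modes (where the target start codon is
#' retained), or from an ATG inside the inserted cassette for N-terminal/SP
#' modes (where the cassette supplies initiation). The fusion is in frame when
#' the translation reaches a stop codon and contains, contiguously, the
#' target-derived residues retained on each side of the junction together
#' with the expected tag peptide, in the correct order.
#'
#' @param modified a `modified_locus` from [integrate_amplicon()].
#' @param locus the original [locus()].
#' @param mode tagging mode ("n", "c", "sp", "ctd").
#' @param expected_tag tag peptide the cassette should contribute (may be ""
#'   to check only an uninterrupted ORF).
#' @return object of class `fusion_report`: `in_frame`, `fusion_protein`,
#'   `premature_stop`, `junction_ok`, `messages`.
#' @export
verify_fusion <- function(modified, locus, mode = c("n", "c", "sp", "ctd"),
                          expected_tag = "") {
  mode <- match.arg(mode)
  expected_tag <- if (nchar(expected_tag)) prot_seq(expected_tag) else ""
  ret <- retained_residues(modified, locus)
  msgs <- character(0)
  junction_ok <- ret$ok
  if (!junction_ok) msgs <- c(msgs, "replaced span does not respect codon boundaries")

  seq <- modified$seq
  up <- nchar(locus$up_flank)

  ordered_contains <- function(prot) {
    pieces <- c(ret$five %||% "", expected_tag, ret$three %||% "")
    pos <- 1L
    for (p in pieces) {
      if (!nchar(p)) next
      hit <- regexpr(p, substr(prot, pos, nchar(prot)), fixed = TRUE)
      if (hit == -1L) return(FALSE)
      pos <- pos + as.integer(hit) + nchar(p) - 1L
    }
    TRUE
  }

  if (mode %in% c("c", "ctd")) {
    start1 <- up + 1L
    if (substr(seq, start1, start1 + 2L) != "ATG") {
      abort_verify("no ATG at the expected target start position")
    }
    starts <- start1
  } else {
    ins <- modified$insert
    region <- substr(seq, ins[1] + 1L, ins[2])
    hits <- gregexpr("ATG", region, fixed = TRUE)[[1]]
    if (hits[1] == -1L) abort_verify("no ATG found in the inserted cassette")
    starts <- ins[1] + as.integer(hits)
  }

  best <- NULL
  for (s in starts) {
    orf <- orf_from(seq, s)
    ok <- junction_ok && orf$stopped && ordered_contains(orf$prot)
    if (ok) { best <- list(orf = orf, ok = TRUE); break }
    if (is.null(best)) best <- list(orf = orf, ok = FALSE)
  }
  in_frame <- isTRUE(best$ok)
  if (!in_frame) {
    msgs <- c(msgs, if (!best$orf$stopped) "ORF runs off the sequence without a stop"
              else "translation does not contain target residues and tag in order")
  }
  structure(list(
    in_frame = in_frame,
    fusion_protein = best$orf$prot,
    premature_stop = !in_frame && best$orf$stopped,
    junction_ok = junction_ok,
    messages = msgs
  ), class = "fusion_report")
}

#' @export
print.fusion_report <- function(x, ...) {
  cat(sprintf("<fusion_report> in_frame=%s junction_ok=%s premature_stop=%s\n  %s\n",
              x$in_frame, x$junction_ok, x$premature_stop,
              substr(x$fusion_protein, 1, 60)))
  if (length(x$messages)) cat("  ", paste(x$messages, collapse = "; "), "\n")
  invisible(x)
}

#' Write a modified locus as FASTA with a GFF3 sidecar
#'
#' The sidecar annotates the inserted cassette span on the modified sequence.
#'
#' @param modified a `modified_locus`.
#' @param fasta,gff output paths.
#' @return invisibly, the two paths.
#' @export
write_modified_locus <- function(modified, fasta, gff) {
  seqs <- Biostrings::DNAStringSet(modified$seq)
  names(seqs) <- paste0(modified$gene_id, "_tagged")
  Biostrings::writeXStringSet(seqs, fasta)
  gr <- GenomicRanges::GRanges(
    seqnames = names(seqs),
    ranges = IRanges::IRanges(start = modified$insert[1] + 1L,
                              end = modified$insert[2]),
    strand = "+", type = "misc_feature",
    ID = paste0(modified$gene_id, "_cassette"))
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(c(fasta = fasta, gff = gff))
}
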