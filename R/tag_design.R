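# Long tagging-primer design: a gene-specific homology arm joined to a
# universal plasmid annealing sequence, for N-terminal, C-terminal,
# signal-peptide-replacement and GPI/CTD-replacement tagging.

#' Tagging configuration
#'
#' Bundles the homology-arm length and the universal annealing sequences of
#' the chosen plasmid/terminus. Annealing sequences are given as they are
#' written on the primers, 5'->3'. Defaults come from the plasmid map shipped
#' with the package (see [pot_plasmid()]) for the geometry implied by `mode`.
#'
#' @param arm_len homology-arm length in nt. Default 80, the long-primer
#'   convention for this tagging system; 20-120 is the practical range
#'   (shorter arms recombine poorly, longer primers synthesize poorly).
#' @param fwd_anneal,rev_anneal universal annealing sequences; if NULL they
#'   are taken from `template` for `mode`.
#' @param mode tagging geometry used for default annealing sites.
#' @param plasmid_id identifier recorded on designs.
#' @param include_start_codon keep the target ATG in the N-tagging homology
#'   arm (default FALSE: the tag ORF supplies initiation).
#' @param template plasmid map used for defaults.
#' @return object of class `tagging_config`.
#' @export
tagging_config <- function(arm_len = 80L, fwd_anneal = NULL, rev_anneal = NULL,
                           mode = c("c", "n", "sp", "ctd"),
                           plasmid_id = NULL, include_start_codon = FALSE,
                           template = NULL) {
  mode <- match.arg(mode)
  arm_len <- as.integer(arm_len)
  if (is.na(arm_len) || arm_len < 1L) {
    abort_design(sprintf("arm_len must be a positive integer, got %s", arm_len))
  }
  if (is.null(fwd_anneal) || is.null(rev_anneal)) {
    template <- template %||% pot_plasmid()
    sites <- anneal_sites(mode, template)
    fwd_anneal <- fwd_anneal %||% sites$fwd
    rev_anneal <- rev_anneal %||% sites$rev
    plasmid_id <- plasmid_id %||% template$id
  }
  fwd_anneal <- nuc_seq(fwd_anneal); rev_anneal <- nuc_seq(rev_anneal)
  if (nchar(fwd_anneal) == 0L || nchar(rev_anneal) == 0L) {
    abort_design("annealing sequences must be non-empty")
  }
  structure(list(arm_len = arm_len, fwd_anneal = fwd_anneal,
                 rev_anneal = rev_anneal, plasmid_id = plasmid_id %||% "plasmid",
                 include_start_codon = isTRUE(include_start_codon)),
            class = "tagging_config")
}

new_primer_pair <- function(gene_id, mode, fwd_arm, rev_arm, cfg, junction) {
  structure(list(
    gene_id = gene_id, mode = mode,
    forward = paste0(fwd_arm, cfg$fwd_anneal),
    reverse = paste0(rev_arm, cfg$rev_anneal),
    fwd_arm = fwd_arm, rev_arm = rev_arm,
    fwd_anneal = cfg$fwd_anneal, rev_anneal = cfg$rev_anneal,
    plasmid_id = cfg$plasmid_id,
    junction = junction  # 0-based half-open span replaced on the locus
  ), class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s [%s]\n  F: %s\n  R: %s\n",
              x$gene_id, toupper(x$mode), x$forward, x$reverse))
  invisible(x)
}

check_arm_source <- function(avail, need, what, gene_id) {
  if (avail < need) {
    abort_design(sprintf(
      "%s: %s provides %d nt but arm_len is %d (deficit %d nt)",
      gene_id, what, avail, need, need - avail))
  }
}

#' Design a C-terminal tagging primer pair
#'
#' The forward arm is the last `arm_len` nt of the CDS excluding the stop
#' codon; the reverse arm is the reverse complement of the first `arm_len` nt
#' of the downstream flank. Integration replaces exactly the stop codon, so
#' the amplified tag cassette is fused in frame to the full-length protein.
#'
#' @param locus a [locus()].
#' @param cfg a [tagging_config()] (C-type annealing sites).
#' @return a `primer_pair`.
#' @export
design_c_tag <- function(locus, cfg) {
  n_cds <- nchar(locus$cds)
  check_arm_source(n_cds - 3L, cfg$arm_len, "CDS (excluding stop)", locus$gene_id)
  check_arm_source(nchar(locus$down_flank), cfg$arm_len, "downstream flank", locus$gene_id)
  body <- substr(locus$cds, 1L, n_cds - 3L)
  fwd_arm <- substr(body, nchar(body) - cfg$arm_len + 1L, nchar(body))
  rev_arm <- reverse_complement(substr(locus$down_flank, 1L, cfg$arm_len))
  up <- nchar(locus$up_flank)
  new_primer_pair(locus$gene_id, "c", fwd_arm, rev_arm, cfg,
                  junction = c(up + n_cds - 3L, up + n_cds))
}

#' Design an N-terminal tagging primer pair
#'
#' The forward arm is the last `arm_len` nt of the upstream flank; the reverse
#' arm is the reverse complement of the first `arm_len` nt of coding sequence,
#' starting after the ATG by default (`include_start_codon = FALSE`; the tag
#' ORF supplies initiation) or at the ATG when the flag is set.
#'
#' @inheritParams design_c_tag
#' @return a `primer_pair`.
#' @export
design_n_tag <- function(locus, cfg) {
  offset <- if (cfg$include_start_codon) 0L else 3L
  n_cds <- nchar(locus$cds)
  check_arm_source(nchar(locus$up_flank), cfg$arm_len, "upstream flank", locus$gene_id)
  check_arm_source(n_cds - 3L - offset, cfg$arm_len,
                   "CDS (excluding stop and skipped start)", locus$gene_id)
  up <- nchar(locus$up_flank)
  fwd_arm <- substr(locus$up_flank, up - cfg$arm_len + 1L, up)
  rev_arm <- reverse_complement(substr(locus$cds, offset + 1L, offset + cfg$arm_len))
  new_primer_pair(locus$gene_id, "n", fwd_arm, rev_arm, cfg,
                  junction = c(up, up + offset))
}

#' Design a signal-peptide replacement primer pair
#'
#' Removes codons 1..sp_end_aa (the predicted signal peptide) so the amplified
#' cassette can supply a donor signal peptide fused to the tag. The forward
#' arm matches the upstream flank as in N-tagging; the reverse arm anneals to
#' the first mature codon.
#'
#' @param locus a [locus()].
#' @param ann a [signal_annotation()] with `sp_end_aa` set.
#' @param cfg a [tagging_config()] (N-type annealing sites).
#' @return a `primer_pair`.
#' @export
design_sp_replacement <- function(locus, ann, cfg) {
  if (is.null(ann$sp_end_aa) || is.na(ann$sp_end_aa)) {
    abort_annotation(sprintf("%s: sp_end_aa is required for SP replacement", locus$gene_id))
  }
  sp_end <- as.integer(ann$sp_end_aa)
  n_cds <- nchar(locus$cds)
  n_aa <- n_cds %/% 3L - 1L
  if (sp_end < 1L || sp_end >= n_aa) {
    abort_annotation(sprintf("%s: sp_end_aa %d outside 1..%d", locus$gene_id, sp_end, n_aa - 1L))
  }
  check_arm_source(nchar(locus$up_flank), cfg$arm_len, "upstream flank", locus$gene_id)
  cut <- 3L * sp_end
  check_arm_source(n_cds - 3L - cut, cfg$arm_len, "CDS after the signal peptide", locus$gene_id)
  up <- nchar(locus$up_flank)
  fwd_arm <- substr(locus$up_flank, up - cfg$arm_len + 1L, up)
  rev_arm <- reverse_complement(substr(locus$cds, cut + 1L, cut + cfg$arm_len))
  new_primer_pair(locus$gene_id, "sp", fwd_arm, rev_arm, cfg,
                  junction = c(up, up + cut))
}

#' Design a CTD/GPI-signal replacement primer pair
#'
#' Removes codons ctd_start_aa..stop (the predicted GPI-anchor addition and
#' cleavage domain) so the cassette can supply the tag fused to a donor CTD.
#' The forward arm ends at codon ctd_start_aa - 1; the reverse arm matches the
#' downstream flank as in C-tagging.
#'
#' @param locus a [locus()].
#' @param ann a [signal_annotation()] with `ctd_start_aa` set.
#' @param cfg a [tagging_config()] (C-type annealing sites).
#' @return a `primer_pair`.
#' @export
design_ctd_replacement <- function(locus, ann, cfg) {
  if (is.null(ann$ctd_start_aa) || is.na(ann$ctd_start_aa)) {
    abort_annotation(sprintf("%s: ctd_start_aa is required for CTD replacement", locus$gene_id))
  }
  ctd <- as.integer(ann$ctd_start_aa)
  n_cds <- nchar(locus$cds)
  n_aa <- n_cds %/% 3L - 1L
  if (ctd < 2L || ctd > n_aa) {
    abort_annotation(sprintf("%s: ctd_start_aa %d outside 2..%d", locus$gene_id, ctd, n_aa))
  }
  kept <- 3L * (ctd - 1L)
  check_arm_source(kept, cfg$arm_len, "CDS before the CTD", locus$gene_id)
  check_arm_source(nchar(locus$down_flank), cfg$arm_len, "downstream flank", locus$gene_id)
  fwd_arm <- substr(locus$cds, kept - cfg$arm_len + 1L, kept)
  rev_arm <- reverse_complement(substr(locus$down_flank, 1L, cfg$arm_len))
  up <- nchar(locus$up_flank)
  new_primer_pair(locus$gene_id, "ctd", fwd_arm, rev_arm, cfg,
                  junction = c(up + kept, up + n_cds))
}

#' Signal-peptide / GPI omega-site annotation for one gene
#'
#' @param gene_id identifier.
#' @param sp_end_aa 1-based index of the last signal-peptide residue, or NA.
#' @param ctd_start_aa 1-based index of the first residue of the C-terminal
#'   GPI-processing domain, or NA.
#' @return object of class `signal_annotation`.
#' @export
signal_annotation <- function(gene_id, sp_end_aa = NA_integer_,
                              ctd_start_aa = NA_integer_) {
  sp <- suppressWarnings(as.integer(sp_end_aa))
  ct <- suppressWarnings(as.integer(ctd_start_aa))
  if (!is.na(sp) && !is.na(ct) && !(sp >= 1L && sp < ct)) {
    abort_annotation(sprintf("%s: need 1 <= sp_end_aa < ctd_start_aa", gene_id))
  }
  structure(list(gene_id = gene_id, sp_end_aa = sp, ctd_start_aa = ct),
            class = "signal_annotation")
}

#' Read signal-peptide / GPI annotations from TSV
#'
#' Columns: gene_id, sp_end_aa, ctd_start_aa; blank or NA entries mean the
#' feature is absent.
#'
#' @param path TSV file.
#' @return named list of `signal_annotation` objects.
#' @export
read_signal_annotations <- function(path) {
  if (!file.exists(path)) abort_lookup(sprintf("annotation TSV not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "sp_end_aa", "ctd_start_aa")
  if (!all(need %in% names(df))) {
    abort_data(sprintf("annotation TSV must have columns: %s", paste(need, collapse = ", ")))
  }
  anns <- lapply(seq_len(nrow(df)), function(i) {
    signal_annotation(df$gene_id[i], df$sp_end_aa[i], df$ctd_start_aa[i])
  })
  names(anns) <- df$gene_id
  anns
}

# arm uniqueness check within the locus: fwd_arm once on the top strand,
# rev_arm once on the bottom strand (== rc(rev_arm) once on top)
arm_unique_flags <- function(locus, pair) {
  seq <- locus_seq(locus)
  n_f <- count_matches(pair$fwd_arm, seq)
  n_r <- count_matches(reverse_complement(pair$rev_arm), seq)
  flags <- character(0)
  if (n_f != 1L) flags <- c(flags, "fwd_arm_not_unique")
  if (n_r != 1L) flags <- c(flags, "rev_arm_not_unique")
  flags
}

#' Batch primer design over a locus collection
#'
#' Applies the single-gene design of `mode` to every locus; per-gene failures
#' are reported as flagged rows with empty primers rather than aborting the
#' batch. Rows are ordered by gene_id. Arm-uniqueness within each locus is
#' checked and flagged.
#'
#' @param loci list of `locus` objects (e.g. from [load_loci()]).
#' @param cfg a [tagging_config()].
#' @param mode one of "n", "c", "sp", "ctd".
#' @param annotations named list of `signal_annotation` (required for
#'   "sp"/"ctd").
#' @return data frame: gene_id, mode, forward_primer, reverse_primer,
#'   fwd_arm, rev_arm, plasmid_id, flags.
#' @export
design_genome_batch <- function(loci, cfg, mode = c("c", "n", "sp", "ctd"),
                                annotations = NULL) {
  mode <- match.arg(mode)
  empty <- data.frame(
    gene_id = character(0), mode = character(0), forward_primer = character(0),
    reverse_primer = character(0), fwd_arm = character(0), rev_arm = character(0),
    plasmid_id = character(0), flags = character(0), stringsAsFactors = FALSE)
  if (length(loci) == 0L) return(empty)
  ids <- vapply(loci, function(l) l$gene_id, character(1))
  rows <- lapply(loci[order(ids)], function(lc) {
    res <- tryCatch({
      pair <- switch(mode,
        c = design_c_tag(lc, cfg),
        n = design_n_tag(lc, cfg),
        sp = design_sp_replacement(lc, annotations[[lc$gene_id]] %||%
                                     signal_annotation(lc$gene_id), cfg),
        ctd = design_ctd_replacement(lc, annotations[[lc$gene_id]] %||%
                                       signal_annotation(lc$gene_id), cfg))
      flags <- arm_unique_flags(lc, pair)
      data.frame(gene_id = lc$gene_id, mode = mode,
                 forward_primer = pair$forward, reverse_primer = pair$reverse,
                 fwd_arm = pair$fwd_arm, rev_arm = pair$rev_arm,
                 plasmid_id = pair$plasmid_id,
                 flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
    }, potkit_error = function(e) {
      data.frame(gene_id = lc$gene_id, mode = mode, forward_primer = "",
                 reverse_primer = "", fwd_arm = "", rev_arm = "",
                 plasmid_id = cfg$plasmid_id,
                 flags = paste0("error:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a primer table as TSV or CSV
#'
#' @param table data frame from [design_genome_batch()].
#' @param path output path; format chosen by extension (.csv -> CSV, else TSV).
#' @return invisibly, `path`.
#' @export
write_primer_table <- function(table, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(table, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
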