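# Minimal read-only GenBank flat-file support for plasmid maps.
#
# Only the subset needed for tagging-plasmid templates is parsed: LOCUS
# (length, circular topology), FEATURES with simple `start..end` or
# `complement(start..end)` locations plus /label qualifiers, and ORIGIN.
# No installed R package parses local GenBank feature tables, so this small
# parser is provided here.

#' Read a plasmid map from a GenBank flat file
#'
#' @param path GenBank file.
#' @return a `plasmid_template` (see [plasmid_template()]).
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) abort_lookup(sprintf("GenBank file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  locus_line <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus_line) == 0L) abort_data("not a GenBank file: no LOCUS line")
  toks <- strsplit(trimws(locus_line[1]), "\\s+")[[1]]
  id <- if (length(toks) >= 2L) toks[2] else "plasmid"
  circular <- any(grepl("circular", locus_line[1], ignore.case = TRUE))

  feat_start <- grep("^FEATURES", lines)
  orig_start <- grep("^ORIGIN", lines)
  if (length(orig_start) == 0L) abort_data("GenBank file has no ORIGIN section")
  end_rec <- grep("^//", lines)
  end_rec <- if (length(end_rec)) end_rec[1] else length(lines) + 1L

  # sequence
  seq_lines <- lines[(orig_start[1] + 1L):(end_rec - 1L)]
  seq <- gsub("[0-9 ]", "", paste(seq_lines, collapse = ""))
  seq <- nuc_seq(seq)

  # features: a new feature starts with a key in columns 6-20
  features <- data.frame(label = character(0), key = character(0),
                         start = integer(0), end = integer(0),
                         strand = character(0), stringsAsFactors = FALSE)
  if (length(feat_start) > 0L) {
    block <- lines[(feat_start[1] + 1L):(orig_start[1] - 1L)]
    idx <- grep("^ {5}\\S", block)
    for (k in seq_along(idx)) {
      first <- block[idx[k]]
      last_line <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
      body <- block[idx[k]:last_line]
      key <- sub("^ {5}(\\S+).*$", "\\1", first)
      loc <- trimws(sub("^ {5}\\S+\\s+", "", first))
      strand <- "+"
      if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
      }
      if (grepl("join|order", loc)) abort_data("compound GenBank locations are not supported")
      m <- regmatches(loc, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", loc))[[1]]
      if (length(m) == 0L) {
        m1 <- regmatches(loc, regexec("^(\\d+)$", loc))[[1]]
        if (length(m1) == 0L) next
        st <- as.integer(m1[2]); en <- st
      } else {
        st <- as.integer(m[2]); en <- as.integer(m[3])
      }
      lab <- grep("/label=", body, value = TRUE)
      label <- key
      if (length(lab)) {
        m_lab <- regmatches(lab[1], regexec('/label="([^"]*)"', lab[1]))[[1]]
        if (length(m_lab) == 0L) {
          m_lab <- regmatches(lab[1], regexec("/label=(\\S+)", lab[1]))[[1]]
        }
        if (length(m_lab) == 2L) label <- m_lab[2]
      }
      features <- rbind(features, data.frame(
        label = label, key = key, start = st, end = en, strand = strand,
        stringsAsFactors = FALSE))
    }
  }
  plasmid_template(seq, features, circular = circular, id = id)
}

#' Construct a plasmid template for in-silico amplification
#'
#' @param seq plasmid sequence (top strand, 5'->3').
#' @param features data frame with columns label, start, end (1-based
#'   inclusive, GenBank convention) and strand ("+"/"-"); a `key` column is
#'   optional.
#' @param circular is the template circular?
#' @param id identifier.
#' @return object of class `plasmid_template`.
#' @export
plasmid_template <- function(seq, features = NULL, circular = TRUE, id = "plasmid") {
  seq <- nuc_seq(seq)
  if (is.null(features)) {
    features <- data.frame(label = character(0), key = character(0),
                           start = integer(0), end = integer(0),
                           strand = character(0), stringsAsFactors = FALSE)
  }
  if (nrow(features) > 0L && any(features$end > nchar(seq) | features$start < 1L)) {
    abort_data("plasmid feature outside sequence bounds")
  }
  structure(list(seq = seq, features = features, circular = circular, id = id),
            class = "plasmid_template")
}

#' @export
print.plasmid_template <- function(x, ...) {
  cat(sprintf("<plasmid_template> %s: %d bp, %s, %d features\n", x$id,
              nchar(x$seq), if (x$circular) "circular" else "linear",
              nrow(x$features)))
  invisible(x)
}

feature_seq <- function(template, label) {
  f <- template$features[template$features$label == label, , drop = FALSE]
  if (nrow(f) != 1L) {
    abort_lookup(sprintf("feature '%s' absent or duplicated on %s", label, template$id))
  }
  s <- substr(template$seq, f$start, f$end)
  if (f$strand == "-") s <- reverse_complement(s) else s <- nuc_seq(s)
  s
}

#' The tagging plasmid map shipped with the package
#'
#' Loads the bundled `pPOT_synthetic.gb` map: a fully synthetic stand-in
#' plasmid laid out like a PCR-only tagging plasmid, with universal N- and
#' C-terminal primer annealing sites embedded in glycine-serine linker coding
#' sequence, short synthetic tag ORFs and a synthetic resistance cassette. It
#' is not any published plasmid sequence; it exists so the design/simulation
#' round trip has a self-contained template.
#'
#' @return a `plasmid_template`.
#' @export
pot_plasmid <- function() {
  read_genbank(system.file("extdata", "pPOT_synthetic.gb", package = "potkit",
                           mustWork = TRUE))
}

#' Universal annealing sequences for a tagging mode
#'
#' Extracts the forward and reverse primer annealing sequences (each written
#' 5'->3' as it appears on the primer) from a plasmid map. N-terminal-type
#' geometry is used by modes "n" and "sp"; C-terminal-type by "c" and "ctd".
#' Features must be labelled `fwd_anneal_N` / `rev_anneal_N` and
#' `fwd_anneal_C` / `rev_anneal_C`.
#'
#' @param mode one of "n", "c", "sp", "ctd".
#' @param template a `plasmid_template`; default the shipped synthetic map.
#' @return list with elements `fwd` and `rev`.
#' @export
anneal_sites <- function(mode = c("n", "c", "sp", "ctd"), template = pot_plasmid()) {
  mode <- match.arg(mode)
  side <- if (mode %in% c("n", "sp")) "N" else "C"
  list(fwd = feature_seq(template, paste0("fwd_anneal_", side)),
       rev = feature_seq(template, paste0("rev_anneal_", side)))
}

#' Translated tag peptide supplied by a plasmid cassette
#'
#' For C-type modes, the peptide encoded from the forward annealing site (in
#' the fusion reading frame) through the tag ORF's stop; for N-type modes, the
#' peptide from the tag ORF's own ATG through the reverse annealing linker.
#' Used as `expected_tag` when verifying fusions.
#'
#' @param template a `plasmid_template`.
#' @param mode tagging mode.
#' @return protein string (no stop marker).
#' @export
tag_protein <- function(template, mode = c("n", "c", "sp", "ctd")) {
  mode <- match.arg(mode)
  side <- if (mode %in% c("n", "sp")) "N" else "C"
  s <- feature_seq(template, paste0("tag_orf_", side))
  p <- translate_cds(s)
  sub("\\*$", "", as.character(p))
}
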