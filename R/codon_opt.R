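# Codon-usage tables from a CDS corpus and back-translation of proteins to a
# target usage, as used when synthesizing tag genes for the trypanosome
# genome's codon frequencies.

#' Build a codon-usage table from coding sequences
#'
#' Counts every in-frame codon over the supplied CDS records and normalizes
#' counts to relative frequencies within each amino acid (stop codons are
#' tallied as their own class, "*"). Records whose length is not divisible by
#' 3 or that contain non-ACGT characters are skipped and listed in the
#' `"skipped"` attribute.
#'
#' @param cds_records a FASTA path, a `Biostrings::DNAStringSet`, or a
#'   character vector of coding sequences.
#' @return data frame of class `usage_table` with columns codon, aa, count,
#'   frequency (0 for unobserved codons; NA frequency when an amino acid was
#'   never observed, flagged in the `"undefined_aa"` attribute).
#' @export
build_usage_table <- function(cds_records) {
  if (is_string(cds_records) && file.exists(cds_records)) {
    s <- Biostrings::readDNAStringSet(cds_records)
    recs <- as.character(s)
    names(recs) <- sub("\\s.*$", "", names(s))
  } else if (methods::is(cds_records, "DNAStringSet")) {
    recs <- as.character(cds_records)
  } else if (is.character(cds_records)) {
    recs <- cds_records
  } else {
    abort_data("cds_records must be a FASTA path, DNAStringSet or character vector")
  }
  if (length(recs) > 0L && (is.null(names(recs)) || any(names(recs) == ""))) {
    names(recs) <- paste0("record", seq_along(recs))
  }
  tab <- codon_table()
  counts <- stats::setNames(integer(length(tab)), names(tab))
  skipped <- list()
  for (id in names(recs)) {
    x <- toupper(recs[[id]])
    if (nchar(x) %% 3L != 0L) {
      skipped[[id]] <- "length not divisible by 3"
      next
    }
    if (grepl("[^ACGT]", x)) {
      skipped[[id]] <- "non-ACGT characters"
      next
    }
    cods <- split_codons(x)
    t <- table(cods)
    counts[names(t)] <- counts[names(t)] + as.integer(t)
  }
  aa <- unname(tab)
  freq <- rep(NA_real_, length(counts))
  for (a in unique(aa)) {
    idx <- which(aa == a)
    tot <- sum(counts[idx])
    freq[idx] <- if (tot > 0L) counts[idx] / tot else NA_real_
  }
  out <- data.frame(codon = names(counts), aa = aa, count = unname(counts),
                    frequency = freq, stringsAsFactors = FALSE)
  out <- out[order(out$aa, out$codon), ]
  rownames(out) <- NULL
  class(out) <- c("usage_table", "data.frame")
  attr(out, "skipped") <- if (length(skipped)) {
    data.frame(id = names(skipped), reason = unlist(skipped), row.names = NULL,
               stringsAsFactors = FALSE)
  } else {
    data.frame(id = character(0), reason = character(0))
  }
  attr(out, "undefined_aa") <- setdiff(unique(aa), unique(aa[out$count > 0]))
  out
}

#' Write / read a usage table as TSV
#'
#' @param table a `usage_table`.
#' @param path TSV path.
#' @return `write_usage_table` returns `path` invisibly; `read_usage_table`
#'   returns a `usage_table`.
#' @export
write_usage_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_usage_table
#' @export
read_usage_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("codon", "aa", "count", "frequency")
  if (!all(need %in% names(df))) {
    abort_data("usage table TSV must have columns codon, aa, count, frequency")
  }
  class(df) <- c("usage_table", "data.frame")
  df
}

# motif occurs in seq on either strand?
motif_hit <- function(seq, motifs) {
  for (m in motifs) {
    if (match_pos(m, seq) > 0L) return(m)
    if (match_pos(reverse_complement(m), seq) > 0L) return(m)
  }
  NULL
}

#' Recode a protein to a codon-usage table
#'
#' Back-translates `protein` codon by codon. `mode = "max"` picks each
#' residue's highest-frequency codon (ties broken alphabetically, so the
#' result is deterministic); `mode = "weighted"` samples codon c with
#' probability f(c) under `seed`. If the protein ends in '*', a stop codon is
#' appended (the corpus's most frequent stop, or `stop_codon`).
#'
#' Restriction-type motifs in `avoid_motifs` are excluded on both strands by
#' greedy left-to-right construction with per-codon substitution (next-best or
#' resampled synonymous codon) and backtracking up to two codons; if no
#' synonymous choice clears a window, a constraint error names the stuck
#' window.
#'
#' @param protein protein string (terminal '*' optional).
#' @param table a `usage_table`.
#' @param mode "max" or "weighted".
#' @param seed integer seed for weighted sampling.
#' @param avoid_motifs character vector of DNA motifs to exclude.
#' @param stop_codon override for the appended stop codon.
#' @return DNA string whose translation equals `protein`.
#' @export
recode <- function(protein, table, mode = c("max", "weighted"), seed = NULL,
                   avoid_motifs = character(0), stop_codon = NULL) {
  mode <- match.arg(mode)
  protein <- prot_seq(protein)
  add_stop <- grepl("\\*$", protein)
  body <- sub("\\*$", "", protein)
  residues <- if (nchar(body)) strsplit(body, "", fixed = TRUE)[[1]] else character(0)
  avoid_motifs <- vapply(avoid_motifs, nuc_seq, character(1), USE.NAMES = FALSE)

  # per-residue codon choices, ordered by decreasing frequency then codon
  choices <- function(a) {
    rows <- table[table$aa == a & !is.na(table$frequency) & table$frequency > 0, ]
    if (nrow(rows) == 0L) {
      abort_recode(sprintf("no usable codon for residue '%s' in the usage table", a))
    }
    rows[order(-rows$frequency, rows$codon), c("codon", "frequency")]
  }
  if (add_stop) {
    stop_rows <- choices("*")
    stop_codon <- stop_codon %||% stop_rows$codon[1]
  }

  targets <- lapply(residues, choices)
  max_motif <- if (length(avoid_motifs)) max(nchar(avoid_motifs)) else 0L

  # candidate codon order at position i, given how many candidates were
  # already rejected there
  with_seed(seed, {
    ranked <- lapply(targets, function(ch) {
      if (mode == "max") {
        ch$codon
      } else {
        # weighted: first candidate sampled by frequency, fallbacks sampled
        # without replacement (still frequency-biased)
        if (nrow(ch) == 1L) ch$codon
        else sample(ch$codon, nrow(ch), replace = FALSE, prob = ch$frequency)
      }
    })
    picked <- character(length(residues))
    tried <- vector("list", length(residues))
    i <- 1L
    backtracks <- 0L
    while (i <= length(residues)) {
      cand <- setdiff(ranked[[i]], tried[[i]])
      advanced <- FALSE
      for (cod in cand) {
        tried[[i]] <- c(tried[[i]], cod)
        picked[i] <- cod
        if (max_motif > 0L) {
          # any newly created motif must end within codon i: check a window
          # of the trailing codons long enough to contain the longest motif
          first <- max(1L, i - (max_motif + 2L) %/% 3L - 1L)
          window <- paste(picked[first:i], collapse = "")
          if (!is.null(motif_hit(window, avoid_motifs))) next
        }
        advanced <- TRUE
        break
      }
      if (advanced) {
        i <- i + 1L
        if (i <= length(residues)) tried[[i]] <- character(0)
      } else {
        # backtrack up to depth 2
        if (i == 1L || backtracks >= 2L * length(residues) + 4L) {
          abort_constraint(sprintf(
            "cannot avoid motif(s) %s around codon %d of the recoded sequence",
            paste(avoid_motifs, collapse = ","), i))
        }
        tried[[i]] <- character(0)
        picked[i] <- ""
        i <- i - 1L
        backtracks <- backtracks + 1L
      }
    }
    out <- paste(picked, collapse = "")
    if (add_stop) out <- paste0(out, stop_codon)
    if (length(avoid_motifs)) {
      hit <- motif_hit(out, avoid_motifs)
      if (!is.null(hit)) {
        abort_constraint(sprintf("recoded sequence still contains motif %s", hit))
      }
    }
    nuc_seq(out)
  })
}
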