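## FASTA / TSV input-output and fragment validation.
## Coordinates are 1-based and inclusive on the precursor (signal-peptide
## containing) sequence throughout the package.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read protein records from a FASTA file
#'
#' Headers of the form `>id|allergen_label|name` populate all three
#' description fields; otherwise the first whitespace-delimited token becomes
#' the id and the remainder the name. Sequences are uppercased and validated
#' against the 20-letter amino-acid alphabet.
#'
#' @param path path to a FASTA file.
#' @return A data.frame with columns `id`, `name`, `allergen_label`,
#'   `sequence`, `length`, one row per entry, input order preserved.
#' @export
#' @examples
#' fa <- system.file("extdata", "milk_proteins.fasta", package = "allerscreen")
#' read_fasta(fa)[, c("id", "allergen_label", "length")]
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  headers <- names(aa)
  seqs <- toupper(as.character(aa))
  parse_header <- function(h) {
    if (grepl("|", h, fixed = TRUE)) {
      parts <- strsplit(h, "|", fixed = TRUE)[[1]]
      c(id = trimws(parts[1]),
        allergen_label = if (length(parts) >= 2) trimws(parts[2]) else NA_character_,
        name = if (length(parts) >= 3) trimws(paste(parts[-(1:2)], collapse = "|")) else NA_character_)
    } else {
      tokens <- strsplit(trimws(h), "\\s+")[[1]]
      c(id = tokens[1],
        allergen_label = NA_character_,
        name = if (length(tokens) > 1) paste(tokens[-1], collapse = " ") else NA_character_)
    }
  }
  meta <- t(vapply(headers, parse_header, character(3)))
  rec <- data.frame(id = meta[, "id"],
                    name = meta[, "name"],
                    allergen_label = meta[, "allergen_label"],
                    sequence = seqs,
                    length = nchar(seqs),
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(rec))) {
    bad <- which(!strsplit(rec$sequence[i], "")[[1]] %in% AA_ALPHABET)
    if (length(bad) > 0L) {
      stop("record '", rec$id[i], "': non-amino-acid character '",
           substr(rec$sequence[i], bad[1], bad[1]), "' at position ", bad[1])
    }
  }
  rec
}

#' Write / read a peptide table as TSV
#'
#' The exchange schema is `protein_id`, `allergen_label`, `start`, `end`,
#' `sequence`, `source` (plus any extra columns present). UTF-8, header
#' row, tab-separated. Coordinates are 1-based inclusive on the precursor.
#'
#' @param peptides data.frame of peptide fragments.
#' @param path output (or input) file path.
#' @return `read_peptides` returns the data.frame; `write_peptides` returns
#'   `path` invisibly.
#' @export
write_peptides <- function(peptides, path) {
  required <- c("protein_id", "start", "end", "sequence", "source")
  missing <- setdiff(required, names(peptides))
  if (length(missing) > 0L) {
    stop("peptide table lacks columns: ", paste(missing, collapse = ", "))
  }
  utils::write.table(peptides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_peptides
#' @export
read_peptides <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if ("start" %in% names(df)) df$start <- as.integer(df$start)
  if ("end" %in% names(df)) df$end <- as.integer(df$end)
  df
}

#' Validate a peptide fragment against its coordinates (and parent)
#'
#' Published peptide tables occasionally print coordinates that disagree
#' with the printed sequence. This validator therefore reports
#' inconsistencies instead of rejecting them, so such rows remain loadable.
#' Checked rules: start/end ordering, span vs. sequence length, alphabet
#' membership, and (when the parent sequence is supplied) bounds and
#' substring identity at the stated location.
#'
#' @param fragment a one-row data.frame or named list with `start`, `end`,
#'   `sequence` (and optionally `protein_id`).
#' @param parent optional parent protein sequence (a string) or a one-row
#'   record from [read_fasta()].
#' @return Character vector of violation reports; empty when fully
#'   consistent. The input is never modified.
#' @export
#' @examples
#' validate_fragment(list(start = 108, end = 131,
#'                        sequence = "GYLEQLLRLKKYKVPQLEIVPNSA"))
validate_fragment <- function(fragment, parent = NULL) {
  reports <- character(0)
  start <- as.integer(fragment$start)
  end <- as.integer(fragment$end)
  seqc <- as.character(fragment$sequence)
  if (is.na(start) || is.na(end)) {
    return("coordinates: start/end missing")
  }
  if (start > end) {
    reports <- c(reports, sprintf("ordering: start %d > end %d", start, end))
  }
  if (start < 1L) {
    reports <- c(reports, sprintf("bounds: start %d < 1", start))
  }
  bad <- which(!strsplit(seqc, "")[[1]] %in% AA_ALPHABET)
  if (length(bad) > 0L) {
    reports <- c(reports, sprintf("alphabet: invalid character at position %d", bad[1]))
  }
  span <- end - start + 1L
  if (start <= end && nchar(seqc) != span) {
    reports <- c(reports, sprintf("length: sequence has %d residues but span %d-%d covers %d",
                                  nchar(seqc), start, end, span))
  }
  if (!is.null(parent)) {
    pseq <- if (is.character(parent)) parent else as.character(parent$sequence)
    if (end > nchar(pseq)) {
      reports <- c(reports, sprintf("bounds: end %d exceeds parent length %d",
                                    end, nchar(pseq)))
    } else if (start >= 1L && start <= end) {
      sub <- substr(pseq, start, end)
      if (sub != seqc) {
        reports <- c(reports, sprintf("identity: parent[%d-%d] is '%s', not '%s'",
                                      start, end, sub, seqc))
      }
    }
  }
  reports
}
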