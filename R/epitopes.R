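## Interval- and sequence-based matching of peptides against curated IgE and
## T-cell epitope catalogs, and comparison of peptide sets (e.g. simulated
## vs. experimentally identified digests).

#' Map one peptide onto an epitope catalog
#'
#' Reports every catalog epitope on the same parent protein that overlaps
#' the peptide by at least one residue, quantitatively: overlap length,
#' overlap as a fraction of the peptide, and the interval relation. No
#' overlap threshold is imposed; verdicts are left to the caller.
#'
#' Match classes: `exact` (identical intervals), `peptide_within_epitope`,
#' `epitope_within_peptide`, `partial` (all with overlap >= 1).
#'
#' @param peptide one-row data.frame or named list with `protein_id`,
#'   `start`, `end` (1-based inclusive, precursor coordinates).
#' @param epitopes epitope catalog data.frame with `protein_id`, `kind`
#'   (`"IgE"` or `"Tcell"`), `start`, `end` and optionally `sequence`,
#'   `citation`.
#' @return Data.frame of matches, one row per overlapping epitope, sorted
#'   by descending overlap length (ties by epitope start): columns `kind`,
#'   `epitope_start`, `epitope_end`, `overlap_length`,
#'   `overlap_fraction_of_peptide`, `match_class` (+ `sequence`, `citation`
#'   when present in the catalog). Zero rows when nothing overlaps.
#' @export
#' @examples
#' cat <- data.frame(protein_id = "P1", kind = "IgE", start = 188, end = 207)
#' map_peptide_to_epitopes(list(protein_id = "P1", start = 195, end = 208), cat)
map_peptide_to_epitopes <- function(peptide, epitopes) {
  ps <- as.integer(peptide$start)
  pe <- as.integer(peptide$end)
  same <- epitopes$protein_id == as.character(peptide$protein_id)
  if (!all(same)) {
    skipped <- unique(epitopes$protein_id[!same])
    if (length(skipped) > 0L) {
      message("skipping epitopes on other parents: ",
              paste(skipped, collapse = ", "))
    }
  }
  cand <- epitopes[same, , drop = FALSE]
  ov <- pmax(0L, pmin(pe, cand$end) - pmax(ps, cand$start) + 1L)
  cand <- cand[ov >= 1L, , drop = FALSE]
  ov <- ov[ov >= 1L]
  cls <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    es <- cand$start[i]; ee <- cand$end[i]
    cls[i] <- if (es == ps && ee == pe) "exact"
      else if (es <= ps && ee >= pe) "peptide_within_epitope"
      else if (ps <= es && pe >= ee) "epitope_within_peptide"
      else "partial"
  }
  out <- data.frame(kind = cand$kind,
                    epitope_start = cand$start,
                    epitope_end = cand$end,
                    overlap_length = ov,
                    overlap_fraction_of_peptide = ov / (pe - ps + 1L),
                    match_class = cls,
                    stringsAsFactors = FALSE)
  if ("sequence" %in% names(cand)) out$sequence <- cand$sequence
  if ("citation" %in% names(cand)) out$citation <- cand$citation
  out <- out[order(-out$overlap_length, out$epitope_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map every peptide of a table onto an epitope catalog
#'
#' @param peptides peptide table (`protein_id`, `start`, `end`, `sequence`).
#' @param epitopes epitope catalog, see [map_peptide_to_epitopes()].
#' @return Data.frame of all matches with a leading `peptide` column.
#' @export
map_all_epitopes <- function(peptides, epitopes) {
  out <- lapply(seq_len(nrow(peptides)), function(i) {
    m <- map_peptide_to_epitopes(peptides[i, ], epitopes)
    if (nrow(m) == 0L) return(NULL)
    cbind(peptide = peptides$sequence[i], m, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(peptide = character(0), kind = character(0),
                      epitope_start = integer(0), epitope_end = integer(0),
                      overlap_length = integer(0),
                      overlap_fraction_of_peptide = numeric(0),
                      match_class = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Compare two peptide sets
#'
#' Pairs peptides of set A with peptides of set B and classifies each pair:
#' `identical` (equal sequence strings), `containment` (one sequence a
#' strict substring of the other), or `overlapping` (coordinate overlap on
#' the same parent without a substring relation). Sequence comparison is
#' primary; coordinates are consulted only when the parents match. The
#' categories are mutually exclusive per pair with precedence
#' identical > containment > overlapping, and the result is symmetric in A
#' and B (the direction of containment is recorded per pair).
#'
#' @param set_a,set_b peptide tables with `sequence` and optionally
#'   `protein_id`, `start`, `end`.
#' @return List of three data.frames `identical`, `containment`,
#'   `overlapping`, each with columns `seq_a`, `seq_b` (and `direction` for
#'   containment: `"a_within_b"` or `"b_within_a"`).
#' @export
#' @examples
#' a <- data.frame(sequence = "SSNICNISCDK")
#' b <- data.frame(sequence = "NNKIWCKDDQNPHSSNICNISCDK")
#' compare_peptide_sets(a, b)$containment
compare_peptide_sets <- function(set_a, set_b) {
  idn <- cnt <- ovl <- list()
  has_coord <- function(s) all(c("protein_id", "start", "end") %in% names(s))
  coords <- has_coord(set_a) && has_coord(set_b)
  for (i in seq_len(nrow(set_a))) {
    for (j in seq_len(nrow(set_b))) {
      sa <- set_a$sequence[i]; sb <- set_b$sequence[j]
      if (sa == sb) {
        idn[[length(idn) + 1L]] <- data.frame(seq_a = sa, seq_b = sb,
                                              stringsAsFactors = FALSE)
      } else if (grepl(sa, sb, fixed = TRUE)) {
        cnt[[length(cnt) + 1L]] <- data.frame(seq_a = sa, seq_b = sb,
                                              direction = "a_within_b",
                                              stringsAsFactors = FALSE)
      } else if (grepl(sb, sa, fixed = TRUE)) {
        cnt[[length(cnt) + 1L]] <- data.frame(seq_a = sa, seq_b = sb,
                                              direction = "b_within_a",
                                              stringsAsFactors = FALSE)
      } else if (coords &&
                 !is.na(set_a$protein_id[i]) &&
                 identical(set_a$protein_id[i], set_b$protein_id[j]) &&
                 min(set_a$end[i], set_b$end[j]) >=
                 max(set_a$start[i], set_b$start[j])) {
        ovl[[length(ovl) + 1L]] <- data.frame(seq_a = sa, seq_b = sb,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  empty <- function(cols) {
    as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                  stringsAsFactors = FALSE)
  }
  list(identical = if (length(idn)) do.call(rbind, idn) else empty(c("seq_a", "seq_b")),
       containment = if (length(cnt)) do.call(rbind, cnt) else empty(c("seq_a", "seq_b", "direction")),
       overlapping = if (length(ovl)) do.call(rbind, ovl) else empty(c("seq_a", "seq_b")))
}
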