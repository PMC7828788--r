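## Rule-based protease cleavage-site prediction.
##
## Specificity is expressed in the P4..P1 / P1'..P4' positional nomenclature:
## the scissile bond lies between P1 and P1'. A rule is a set of "cut"
## clauses and optional "block" clauses; a bond is cut iff at least one cut
## clause is satisfied and no block clause is. Each clause constrains window
## slots with an allowed set or a forbidden set; a clause that references a
## slot beyond the termini is not satisfiable there (lookaround semantics:
## a constraint on a residue that does not exist cannot hold, exactly as a
## regular-expression transcription of the tables behaves). Slots a clause
## does not reference are unconstrained.
##
## The shipped tables (inst/extdata/cleavage_rules.tsv) transcribe the ExPASy
## PeptideCutter documentation: trypsin with its exception patterns,
## chymotrypsin at high (F/Y/W) and low (additionally L/M/H) specificity,
## and the two-clause pepsin forms for pH 1.3 and pH > 2. The tables live in
## a versioned data file, not in code, so corrections require no code change.

.rules_cache <- new.env(parent = emptyenv())

SLOT_OFFSETS <- c("P4" = -3L, "P3" = -2L, "P2" = -1L, "P1" = 0L,
                  "P1'" = 1L, "P2'" = 2L, "P3'" = 3L, "P4'" = 4L)

#' Protease cleavage rules
#'
#' Loads (and caches) the shipped cleavage-rule tables. Each enzyme maps to
#' a list with `cut` and `block` clause lists; a clause is a named list of
#' window-slot constraints `list(mode = "allowed"|"forbidden", residues =
#' <character vector>)`.
#'
#' @param path rule table (TSV: enzyme, clause, action, slot, mode,
#'   residues). Defaults to the packaged table.
#' @return Named list of rules, one element per enzyme.
#' @export
cleavage_rules <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.rules_cache$rules)) return(.rules_cache$rules)
  if (default) {
    path <- system.file("extdata", "cleavage_rules.tsv", package = "allerscreen")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("enzyme", "clause", "action", "slot", "mode", "residues")
  stopifnot(all(needed %in% names(tab)))
  rules <- list()
  for (enz in unique(tab$enzyme)) {
    sub <- tab[tab$enzyme == enz, ]
    rule <- list(cut = list(), block = list())
    for (cid in unique(sub$clause)) {
      cl <- sub[sub$clause == cid, ]
      action <- cl$action[1]
      clause <- list()
      for (i in seq_len(nrow(cl))) {
        slot <- cl$slot[i]
        if (!slot %in% names(SLOT_OFFSETS)) {
          stop("unknown window slot '", slot, "' for enzyme ", enz)
        }
        clause[[slot]] <- list(mode = cl$mode[i],
                               residues = strsplit(cl$residues[i], "")[[1]])
      }
      if (!any(c("P1", "P1'") %in% names(clause))) {
        stop("clause ", cid, " of ", enz, " constrains neither P1 nor P1'")
      }
      rule[[action]] <- c(rule[[action]], list(clause))
    }
    rules[[enz]] <- rule
  }
  if (default) .rules_cache$rules <- rules
  rules
}

#' @rdname cleavage_rules
#' @export
list_enzymes <- function(path = NULL) names(cleavage_rules(path))

# Evaluate one clause over every bond of a sequence at once.
# residues: character vector of the sequence; returns logical over bonds
# 1..(n-1), where bond i lies between residues i and i+1 (P1 = residue i).
.clause_satisfied <- function(residues, clause) {
  n <- length(residues)
  nb <- n - 1L
  ok <- rep(TRUE, nb)
  bonds <- seq_len(nb)
  for (slot in names(clause)) {
    pos <- bonds + SLOT_OFFSETS[[slot]]
    inside <- pos >= 1L & pos <= n
    hit <- rep(FALSE, nb)
    hit[inside] <- residues[pos[inside]] %in% clause[[slot]]$residues
    # a referenced slot must exist for the clause to hold at this bond
    slot_ok <- if (clause[[slot]]$mode == "allowed") {
      inside & hit
    } else {
      inside & !hit
    }
    ok <- ok & slot_ok
  }
  ok
}

#' Predict cleavage sites of one enzyme on a sequence
#'
#' @param sequence amino-acid string.
#' @param enzyme rule name, one of [list_enzymes()].
#' @param rules rule set as returned by [cleavage_rules()].
#' @return Sorted integer vector of cut bond indices; bond `i` lies between
#'   residues `i` and `i + 1` (1-based). Deterministic.
#' @export
#' @examples
#' find_cleavage_sites("AKAA", "trypsin")   # 2
#' find_cleavage_sites("AKPA", "trypsin")   # proline block: none
find_cleavage_sites <- function(sequence, enzyme, rules = cleavage_rules()) {
  if (!enzyme %in% names(rules)) {
    stop("unknown enzyme '", enzyme, "'; available: ",
         paste(names(rules), collapse = ", "))
  }
  residues <- strsplit(toupper(sequence), "")[[1]]
  if (length(residues) < 2L) return(integer(0))
  rule <- rules[[enzyme]]
  cut <- Reduce(`|`, lapply(rule$cut, .clause_satisfied, residues = residues))
  if (length(rule$block) > 0L) {
    blocked <- Reduce(`|`, lapply(rule$block, .clause_satisfied, residues = residues))
    cut <- cut & !blocked
  }
  which(cut)
}

#' Digest a protein with a set of enzymes
#'
#' Simultaneous (union-of-sites) digestion on the intact sequence: the cut
#' set of the multi-enzyme digest is the union of the single-enzyme cut
#' sets, and fragments are the maximal uncut runs between them. Survivors
#' are fragments of at least `min_length` residues (a 9-mer survives under
#' the default).
#'
#' @param sequence amino-acid string (non-empty).
#' @param enzymes character vector of rule names.
#' @param min_length survivor length threshold, inclusive.
#' @param parent_id identifier recorded in the fragment table.
#' @param source fragment source tag (`"IS"` for simulated digestion).
#' @param rules rule set as returned by [cleavage_rules()].
#' @return An object of class `digest_result`: a list with `parent_id`,
#'   `sequence`, `cut_positions` (integer bond indices), `fragments` and
#'   `survivors` (data.frames with `protein_id`, `start`, `end`,
#'   `sequence`, `source`). Fragments tile the parent exactly.
#' @export
#' @examples
#' d <- digest("AKRA", "trypsin", min_length = 1)
#' d$fragments$sequence   # "AK" "R" "A"
digest <- function(sequence, enzymes, min_length = 9L, parent_id = "protein",
                   source = "IS", rules = cleavage_rules()) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("cannot digest an empty sequence")
  cuts <- sort(unique(unlist(lapply(enzymes, function(e) {
    find_cleavage_sites(sequence, e, rules)
  }))))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  fragments <- data.frame(protein_id = parent_id,
                          start = starts,
                          end = ends,
                          sequence = substring(sequence, starts, ends),
                          source = source,
                          stringsAsFactors = FALSE)
  survivors <- fragments[ends - starts + 1L >= min_length, , drop = FALSE]
  rownames(survivors) <- NULL
  structure(list(parent_id = parent_id,
                 sequence = sequence,
                 cut_positions = as.integer(cuts),
                 fragments = fragments,
                 survivors = survivors),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat("Digest of", x$parent_id, "(", nchar(x$sequence), "aa ):",
      length(x$cut_positions), "cut sites,",
      nrow(x$fragments), "fragments,",
      nrow(x$survivors), "survivors\n")
  if (nrow(x$survivors) > 0L) {
    print(x$survivors[, c("sequence", "start", "end")], row.names = FALSE)
  }
  invisible(x)
}

#' Digest every protein of a record table
#'
#' @param proteins data.frame from [read_fasta()] (columns `id`, `sequence`,
#'   optionally `allergen_label`).
#' @inheritParams digest
#' @return A data.frame of survivors across all proteins (columns
#'   `protein_id`, `allergen_label`, `start`, `end`, `sequence`, `source`),
#'   with the per-protein `digest_result` list attached as attribute
#'   `"results"`.
#' @export
digest_all <- function(proteins, enzymes = screen_config()$enzyme_set,
                       min_length = 9L, source = "IS",
                       rules = cleavage_rules()) {
  results <- lapply(seq_len(nrow(proteins)), function(i) {
    digest(proteins$sequence[i], enzymes, min_length,
           parent_id = proteins$id[i], source = source, rules = rules)
  })
  names(results) <- proteins$id
  surv <- do.call(rbind, lapply(results, `[[`, "survivors"))
  rownames(surv) <- NULL
  label <- if ("allergen_label" %in% names(proteins)) {
    proteins$allergen_label[match(surv$protein_id, proteins$id)]
  } else NA_character_
  surv <- data.frame(protein_id = surv$protein_id,
                     allergen_label = label,
                     start = surv$start, end = surv$end,
                     sequence = surv$sequence, source = surv$source,
                     stringsAsFactors = FALSE)
  attr(surv, "results") <- results
  surv
}

#' Is a peptide a digestion fixed point?
#'
#' A peptide is a fixed point when re-digesting it in isolation produces no
#' internal cleavage site, i.e. it would pass through the simulated
#' digestion unchanged. Single-residue peptides have no bonds and are fixed
#' points trivially.
#'
#' @param sequence peptide amino-acid string (non-empty).
#' @param enzymes character vector of rule names.
#' @param rules rule set as returned by [cleavage_rules()].
#' @return `TRUE` iff the union of cut sets over `enzymes` is empty.
#' @export
#' @examples
#' is_fixed_point("SSNICNISCDK", c("pepsin_ph2", "trypsin", "chymotrypsin_low"))
is_fixed_point <- function(sequence, enzymes, rules = cleavage_rules()) {
  if (nchar(sequence) == 0L) stop("empty sequence")
  all(vapply(enzymes, function(e) {
    length(find_cleavage_sites(sequence, e, rules)) == 0L
  }, logical(1)))
}
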