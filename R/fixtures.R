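## Packaged reference tables for the cow's-milk case study, and a seeded
## synthetic-data generator with planted ground truth.

#' Load the packaged cow's-milk reference data set
#'
#' Returns the curated tables bundled with the package: the seven milk
#' allergen precursor sequences (a plain-text snapshot of the published
#' accessions), the 24 peptides surviving simulated (IS) digestion, the 7
#' peptides identified after in-vitro (IV) digestion, the IgE / T-cell
#' epitope catalog, per-locus binder counts, the peptide x allele IC50
#' affinity matrix in long form (censored ">5000 nM" cells flagged),
#' cytokine-induction summaries, bioactivity tags and the MS
#' identification summary. Known inconsistencies in the published tables
#' (coordinate spans disagreeing with sequence lengths) are carried
#' verbatim and annotated in a `note` column rather than silently fixed.
#'
#' @return A list of class `reference_data` with elements `proteins`,
#'   `is_peptides`, `iv_peptides`, `epitopes`, `binder_counts`,
#'   `affinities`, `cytokines`, `bioactivity`, `ms_summary`.
#' @export
#' @examples
#' fx <- load_reference_data()
#' nrow(fx$is_peptides)   # 24
load_reference_data <- function() {
  ext <- function(f) system.file("extdata", f, package = "allerscreen")
  tsv <- function(f) utils::read.delim(ext(f), stringsAsFactors = FALSE,
                                       check.names = FALSE)
  fx <- list(proteins = read_fasta(ext("milk_proteins.fasta")),
             is_peptides = tsv("is_peptides.tsv"),
             iv_peptides = tsv("iv_peptides.tsv"),
             epitopes = tsv("epitopes.tsv"),
             binder_counts = tsv("binder_counts.tsv"),
             affinities = tsv("affinities.tsv"),
             cytokines = tsv("cytokines.tsv"),
             bioactivity = tsv("bioactivity.tsv"),
             ms_summary = tsv("ms_summary.tsv"))
  fx$affinities$censored <- fx$affinities$censored %in% c(TRUE, "TRUE")
  # cross-reference checks: every peptide mentioned downstream resolves
  peps <- c(fx$is_peptides$sequence, fx$iv_peptides$sequence)
  for (tab in c("binder_counts", "affinities", "cytokines", "bioactivity")) {
    unknown <- setdiff(fx[[tab]]$peptide_id, peps)
    if (length(unknown) > 0L) {
      stop("fixture table '", tab, "' references unknown peptide(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  known <- fx$is_peptides$protein_id %in% fx$proteins$id
  if (!all(known)) stop("IS peptide with unknown parent protein")
  class(fx) <- "reference_data"
  fx
}

#' @export
print.reference_data <- function(x, ...) {
  cat("Packaged reference data:\n")
  cat("  proteins:      ", nrow(x$proteins), "\n")
  cat("  IS peptides:   ", nrow(x$is_peptides), "\n")
  cat("  IV peptides:   ", nrow(x$iv_peptides), "\n")
  cat("  epitopes:      ", nrow(x$epitopes), "\n")
  cat("  affinity rows: ", nrow(x$affinities), "\n")
  invisible(x)
}

#' Specification for the synthetic-data generator
#'
#' The generator emulates the screening pipeline's inputs with exact,
#' planted ground truth. Protein sequences are drawn from a reduced
#' amino-acid alphabet containing no cleavable residue, then tryptic
#' lysines are planted at Bernoulli-sampled positions, so the planted bonds
#' are provably the only cleavage sites under the default enzyme set.
#' Affinities are log-uniform IC50 draws over [1, 10000] nM, with planted
#' strong binders drawn below the strong-binder boundary and the rest
#' safely above it; SVM scores are normal draws around the 0.2 threshold.
#'
#' @param n_proteins number of proteins.
#' @param length_range protein length range (residues), sampled uniformly.
#' @param site_density per-bond probability of a planted cleavage site.
#' @param n_alleles alleles in the synthetic affinity table.
#' @param n_strong_per_peptide planted strong-binder alleles per peptide.
#' @param svm_mean,svm_sd SVM score distribution parameters.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 5L, length_range = c(60L, 120L),
                           site_density = 0.08, n_alleles = 6L,
                           n_strong_per_peptide = 2L,
                           svm_mean = 0.2, svm_sd = 0.5) {
  stopifnot(site_density >= 0, site_density <= 1,
            n_strong_per_peptide <= n_alleles)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 site_density = site_density,
                 n_alleles = as.integer(n_alleles),
                 n_strong_per_peptide = as.integer(n_strong_per_peptide),
                 svm_mean = svm_mean, svm_sd = svm_sd),
            class = "synthetic_spec")
}

# residues that no default-enzyme clause can cut at or around
INERT_ALPHABET <- c("A", "E", "G", "N", "Q", "S", "T", "I", "V")

#' Generate a synthetic screening bundle with planted ground truth
#'
#' See [synthetic_spec()] for what is emulated. Runs with the same seed are
#' bit-reproducible.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer random seed.
#' @param min_length survivor length threshold used when deriving peptides.
#' @return List with `proteins` (data.frame usable wherever
#'   [read_fasta()] output is), `peptides` (surviving fragments implied by
#'   the planted sites), `affinities` (long table, pIC50 scale),
#'   `scores` (per-window SVM scores per peptide) and `truth`
#'   (`cut_sites`: protein_id/bond, `strong`: peptide_id/allele planted
#'   strong binders).
#' @export
generate_synthetic <- function(spec = synthetic_spec(), seed = 1L,
                               min_length = 9L) {
  set.seed(seed)
  proteins <- data.frame(id = sprintf("SYN%03d", seq_len(spec$n_proteins)),
                         name = "synthetic protein",
                         allergen_label = NA_character_,
                         sequence = NA_character_,
                         length = NA_integer_,
                         stringsAsFactors = FALSE)
  cut_rows <- list()
  for (i in seq_len(spec$n_proteins)) {
    L <- sample(seq(spec$length_range[1], spec$length_range[2]), 1L)
    res <- sample(INERT_ALPHABET, L, replace = TRUE)
    # plant tryptic sites: K at bond position b cuts between b and b+1;
    # the inert alphabet guarantees no exception clause can block it and
    # no other enzyme gains a site
    bonds <- which(stats::runif(L - 1L) < spec$site_density)
    res[bonds] <- "K"
    proteins$sequence[i] <- paste(res, collapse = "")
    proteins$length[i] <- L
    if (length(bonds) > 0L) {
      cut_rows[[length(cut_rows) + 1L]] <-
        data.frame(protein_id = proteins$id[i], bond = bonds,
                   stringsAsFactors = FALSE)
    }
  }
  cut_sites <- if (length(cut_rows)) do.call(rbind, cut_rows) else
    data.frame(protein_id = character(0), bond = integer(0))
  peptides <- digest_all(proteins, enzymes = screen_config()$enzyme_set,
                         min_length = min_length, source = "IS")
  attr(peptides, "results") <- NULL
  alleles <- sprintf("ALLELE%02d", seq_len(spec$n_alleles))
  aff_rows <- list(); strong_rows <- list(); score_rows <- list()
  for (i in seq_len(nrow(peptides))) {
    pep <- peptides$sequence[i]
    strong_idx <- sample(spec$n_alleles, spec$n_strong_per_peptide)
    # planted strong binders sit clearly below the 6.3-pIC50 boundary
    # (~501 nM); everything else clearly above it
    ic50 <- 10^stats::runif(spec$n_alleles, log10(600), log10(10000))
    ic50[strong_idx] <- 10^stats::runif(spec$n_strong_per_peptide, 0, log10(450))
    aff_rows[[i]] <- data.frame(peptide_id = pep, source = "IS",
                                allele = alleles,
                                locus = "DRB1", scale = "pic50",
                                value = ic50_to_pic50(ic50),
                                censored = FALSE,
                                stringsAsFactors = FALSE)
    strong_rows[[i]] <- data.frame(peptide_id = pep,
                                   allele = alleles[sort(strong_idx)],
                                   stringsAsFactors = FALSE)
    nwin <- max(0L, nchar(pep) - 9L + 1L)
    if (nwin > 0L) {
      score_rows[[length(score_rows) + 1L]] <-
        data.frame(peptide_id = pep, offset = seq_len(nwin),
                   score = stats::rnorm(nwin, spec$svm_mean, spec$svm_sd),
                   stringsAsFactors = FALSE)
    }
  }
  list(proteins = proteins,
       peptides = peptides,
       affinities = if (length(aff_rows)) do.call(rbind, aff_rows) else NULL,
       scores = if (length(score_rows)) do.call(rbind, score_rows) else NULL,
       truth = list(cut_sites = cut_sites,
                    strong = if (length(strong_rows)) do.call(rbind, strong_rows) else
                      data.frame(peptide_id = character(0), allele = character(0))))
}
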