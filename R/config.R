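#' Screening configuration
#'
#' Collects every tunable threshold of the screening pipeline in one object.
#' Defaults reproduce the published study conditions: peptides of at least 9
#' residues are retained after digestion (the MHC class II groove needs 9+
#' residues), pIC50 > 6.3 marks strong binders and 5.3 < pIC50 <= 6.3 weak
#' binders, IC50 tiers are < 50 / < 500 / < 5000 nM, SVM windows of length 9
#' or 15 count as inducing above a score of 0.2, and Mascot identifications
#' are kept at score >= 32.
#'
#' @param enzyme_set character vector of cleavage-rule names (see
#'   [list_enzymes()]). The default set is calibrated so that digestion of
#'   the seven bundled milk-protein precursors reproduces the 24 reference
#'   survivors exactly.
#' @param min_peptide_length minimum surviving fragment length, residues.
#' @param pic50_strong,pic50_weak strong / weak binder cut-offs on the pIC50
#'   scale (unitless, -log10 of IC50 in molar).
#' @param ic50_high_nM,ic50_intermediate_nM,ic50_low_nM affinity-tier upper
#'   bounds in nM (exclusive).
#' @param svm_threshold score above which a predictor window counts as
#'   inducing.
#' @param window_lengths admissible predictor window lengths.
#' @param mascot_cutoff minimum Mascot score retained (inclusive).
#' @param normalization_scheme `"panel-max"` (counts scaled by the fixed
#'   allele-panel sizes) or `"batch-max"` (every factor scaled by its batch
#'   maximum).
#' @param panels allele panels, see [allele_panels()].
#' @param verdict_margin,verdict_floor verdict rule parameters, see
#'   [score_verdict()].
#'
#' @return An object of class `screen_config` (a named list).
#' @export
#' @examples
#' cfg <- screen_config()
#' cfg$pic50_strong
screen_config <- function(enzyme_set = c("pepsin_ph2", "trypsin", "chymotrypsin_low"),
                          min_peptide_length = 9L,
                          pic50_strong = 6.3,
                          pic50_weak = 5.3,
                          ic50_high_nM = 50,
                          ic50_intermediate_nM = 500,
                          ic50_low_nM = 5000,
                          svm_threshold = 0.2,
                          window_lengths = c(9L, 15L),
                          mascot_cutoff = 32,
                          normalization_scheme = c("panel-max", "batch-max"),
                          panels = allele_panels(),
                          verdict_margin = 0.1,
                          verdict_floor = 0.01) {
  normalization_scheme <- match.arg(normalization_scheme)
  stopifnot(min_peptide_length >= 1L,
            pic50_strong > pic50_weak,
            ic50_high_nM < ic50_intermediate_nM,
            ic50_intermediate_nM < ic50_low_nM)
  structure(list(enzyme_set = enzyme_set,
                 min_peptide_length = as.integer(min_peptide_length),
                 pic50_strong = pic50_strong,
                 pic50_weak = pic50_weak,
                 ic50_high_nM = ic50_high_nM,
                 ic50_intermediate_nM = ic50_intermediate_nM,
                 ic50_low_nM = ic50_low_nM,
                 svm_threshold = svm_threshold,
                 window_lengths = as.integer(window_lengths),
                 mascot_cutoff = mascot_cutoff,
                 normalization_scheme = normalization_scheme,
                 panels = panels,
                 verdict_margin = verdict_margin,
                 verdict_floor = verdict_floor),
            class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat("Screening configuration\n")
  cat("  enzymes:            ", paste(x$enzyme_set, collapse = ", "), "\n")
  cat("  min peptide length: ", x$min_peptide_length, " aa\n", sep = "")
  cat("  binder thresholds:   strong pIC50 > ", x$pic50_strong,
      ", weak > ", x$pic50_weak, "\n", sep = "")
  cat("  IC50 tiers (nM):     high < ", x$ic50_high_nM,
      ", intermediate < ", x$ic50_intermediate_nM,
      ", low < ", x$ic50_low_nM, "\n", sep = "")
  cat("  SVM threshold:      ", x$svm_threshold,
      " (windows ", paste(x$window_lengths, collapse = "/"), ")\n", sep = "")
  cat("  Mascot cutoff:      ", x$mascot_cutoff, "\n", sep = "")
  cat("  normalization:      ", x$normalization_scheme, "\n", sep = "")
  invisible(x)
}

#' Default MHC class II allele panels
#'
#' The susceptibility panel holds alleles associated with cow's-milk allergy
#' (DRB1*01:01, DQ7, DQ8); the protection panel holds alleles regarded as
#' protective (DRB1*03:01, DRB1*14:19, DRB1*14:21).
#'
#' @return A named list of two `allele_panel` objects, each with `name`,
#'   `alleles` and `role` fields.
#' @export
allele_panels <- function() {
  panel <- function(name, alleles, role) {
    structure(list(name = name, alleles = alleles, role = role),
              class = "allele_panel")
  }
  list(susceptibility = panel("susceptibility",
                              c("DRB1*01:01", "DQ7", "DQ8"),
                              "susceptibility"),
       protection = panel("protection",
                          c("DRB1*03:01", "DRB1*14:19", "DRB1*14:21"),
                          "protection"))
}
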