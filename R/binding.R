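## Threshold classification of MHC class II binding affinities.
##
## Affinities arrive either as pIC50 (unitless, -log10 of IC50 in molar) or
## as IC50 in nM; the scales interconvert via pIC50 = 9 - log10(IC50_nM).
## Binder classes live on the pIC50 scale (strong: pIC50 > 6.3; weak:
## 5.3 < pIC50 <= 6.3), affinity tiers on the IC50 scale with half-open
## bins (high < 50 nM, intermediate < 500 nM, low < 5000 nM, else none).
## Note that the pIC50 6.3 boundary equals 10^2.7 ~ 501.19 nM, commonly
## rounded to "500 nM"; when both scales are supplied the pIC50 rule is
## authoritative.

#' Convert between pIC50 and IC50 (nM)
#'
#' `pIC50 = 9 - log10(IC50 in nM)`; the round trip is an identity.
#'
#' @param pic50 pIC50 values (unitless).
#' @param ic50_nM IC50 values in nM (strictly positive).
#' @return Numeric vector on the other scale.
#' @export
#' @examples
#' pic50_to_ic50(6.3)        # ~501.19 nM, the "500 nM" strong-binder bound
#' ic50_to_pic50(500)        # ~6.301
pic50_to_ic50 <- function(pic50) 10^(9 - pic50)

#' @rdname pic50_to_ic50
#' @export
ic50_to_pic50 <- function(ic50_nM) {
  if (any(ic50_nM <= 0, na.rm = TRUE)) {
    stop("IC50 must be strictly positive (offending value: ",
         ic50_nM[which(ic50_nM <= 0)[1]], " nM)")
  }
  9 - log10(ic50_nM)
}

#' Classify binding affinities
#'
#' Deterministic threshold binning of measurements into a binder class
#' (pIC50 scale) and an affinity tier (IC50 scale). Values printed with a
#' spurious leading minus on the pIC50 scale (e.g. "-6.658") are read as
#' positive, with a message. Censored IC50 values (">5000 nM" table cells)
#' should be passed with `censored = TRUE`; they classify as tier `none`.
#'
#' @param value numeric vector of affinities.
#' @param scale `"pic50"` or `"ic50_nM"`.
#' @param censored logical vector; `TRUE` marks right-censored IC50 values.
#' @param config a [screen_config()].
#' @return Data.frame with `pic50`, `ic50_nM`, `binder_class`
#'   (strong/weak/none) and `affinity_tier` (high/intermediate/low/none).
#' @export
#' @examples
#' classify_affinity(c(6.658, 6.3, 5.3), scale = "pic50")$binder_class
#' classify_affinity(16.96, scale = "ic50_nM")$affinity_tier   # "high"
classify_affinity <- function(value, scale = c("pic50", "ic50_nM"),
                              censored = FALSE, config = screen_config()) {
  scale <- match.arg(scale)
  censored <- rep_len(as.logical(censored), length(value))
  if (scale == "pic50") {
    if (any(value < 0, na.rm = TRUE)) {
      message("negative pIC50 values read as positive (",
              sum(value < 0, na.rm = TRUE), " value(s))")
      value <- abs(value)
    }
    pic50 <- value
    ic50 <- pic50_to_ic50(value)
  } else {
    ic50 <- value
    pic50 <- ic50_to_pic50(value)
  }
  binder <- ifelse(censored, "none",
            ifelse(pic50 > config$pic50_strong, "strong",
            ifelse(pic50 > config$pic50_weak, "weak", "none")))
  tier <- ifelse(censored, "none",
          ifelse(ic50 < config$ic50_high_nM, "high",
          ifelse(ic50 < config$ic50_intermediate_nM, "intermediate",
          ifelse(ic50 < config$ic50_low_nM, "low", "none"))))
  data.frame(pic50 = pic50, ic50_nM = ic50,
             binder_class = binder, affinity_tier = tier,
             stringsAsFactors = FALSE)
}

#' Per-locus binder counts for one peptide
#'
#' Each measured allele contributes to exactly one class (strong, weak or
#' none) per the classification thresholds, so
#' `n_strong + n_weak + n_none` equals the number of measured alleles in
#' every locus.
#'
#' @param measurements data.frame with columns `allele`, `locus` (DRB1, DQ
#'   or DP), `scale` (`"pic50"` or `"ic50_nM"`), `value` and optionally
#'   `censored`; one row per allele.
#' @param config a [screen_config()].
#' @return List with `counts` (data.frame locus x n_strong/n_weak/n_none)
#'   and `total_binders` (strong + weak over all loci).
#' @export
locus_binder_counts <- function(measurements, config = screen_config()) {
  loci <- c("DRB1", "DQ", "DP")
  if (nrow(measurements) > 0L) {
    key <- paste(measurements$allele)
    dup <- key[duplicated(key)]
    if (length(dup) > 0L) {
      stop("duplicate measurement for allele(s): ",
           paste(unique(dup), collapse = ", "))
    }
  }
  counts <- data.frame(locus = loci, n_strong = 0L, n_weak = 0L, n_none = 0L,
                       stringsAsFactors = FALSE)
  if (nrow(measurements) > 0L) {
    cens <- if ("censored" %in% names(measurements)) measurements$censored else FALSE
    cls <- vapply(seq_len(nrow(measurements)), function(i) {
      classify_affinity(measurements$value[i], measurements$scale[i],
                        censored = cens[i] %in% c(TRUE, "TRUE"),
                        config = config)$binder_class
    }, character(1))
    for (k in seq_along(loci)) {
      sel <- measurements$locus == loci[k]
      counts$n_strong[k] <- sum(cls[sel] == "strong")
      counts$n_weak[k] <- sum(cls[sel] == "weak")
      counts$n_none[k] <- sum(cls[sel] == "none")
    }
  }
  list(counts = counts,
       total_binders = sum(counts$n_strong) + sum(counts$n_weak))
}

#' Summarize a peptide's affinities over allele panels
#'
#' For each panel (see [allele_panels()]) the strong/weak binder counts,
#' the tier counts, and the best affinity (minimum IC50 = maximum pIC50)
#' within the panel. Panel alleles without a measurement are reported, not
#' imputed.
#'
#' @param measurements data.frame with `allele`, `scale`, `value` and
#'   optionally `censored`, one row per allele.
#' @param panels named list of panels as from [allele_panels()].
#' @param config a [screen_config()].
#' @return Data.frame with one row per panel: `panel`, `role`, `n_strong`,
#'   `n_weak`, `n_high`, `n_intermediate`, `n_low`, `best_ic50_nM`,
#'   `best_tier`, `missing_alleles` (comma-separated, `""` if none).
#' @export
panel_summary <- function(measurements, panels = allele_panels(),
                          config = screen_config()) {
  rows <- lapply(panels, function(p) {
    sel <- measurements[measurements$allele %in% p$alleles, , drop = FALSE]
    missing <- setdiff(p$alleles, sel$allele)
    if (nrow(sel) == 0L) {
      return(data.frame(panel = p$name, role = p$role,
                        n_strong = 0L, n_weak = 0L,
                        n_high = 0L, n_intermediate = 0L, n_low = 0L,
                        best_ic50_nM = NA_real_, best_tier = "none",
                        missing_alleles = paste(missing, collapse = ","),
                        stringsAsFactors = FALSE))
    }
    cens <- if ("censored" %in% names(sel)) sel$censored %in% c(TRUE, "TRUE") else rep(FALSE, nrow(sel))
    calls <- do.call(rbind, lapply(seq_len(nrow(sel)), function(i) {
      classify_affinity(sel$value[i], sel$scale[i], censored = cens[i],
                        config = config)
    }))
    uncens <- which(!cens)
    best <- if (length(uncens) > 0L) min(calls$ic50_nM[uncens]) else NA_real_
    best_tier <- if (is.na(best)) "none" else {
      classify_affinity(best, "ic50_nM", config = config)$affinity_tier
    }
    data.frame(panel = p$name, role = p$role,
               n_strong = sum(calls$binder_class == "strong"),
               n_weak = sum(calls$binder_class == "weak"),
               n_high = sum(calls$affinity_tier == "high"),
               n_intermediate = sum(calls$affinity_tier == "intermediate"),
               n_low = sum(calls$affinity_tier == "low"),
               best_ic50_nM = best, best_tier = best_tier,
               missing_alleles = paste(missing, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
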