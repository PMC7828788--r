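## Integrated evaluation: 16-factor feature vector, normalization to [0, 1],
## radar-polygon sector areas, and the allergenic / tolerogenic verdict.
##
## Factor order is part of the public contract (permuting factors within a
## sector changes the sector area):
##   1 DRB1-weak, 2 DQ-weak, 3 DP-weak, 4 DRB1-strong, 5 DQ-strong,
##   6 DP-strong, 7 strong allergy-panel, 8 weak allergy-panel, 9 IL-4,
##   10 IFN-gamma, 11 strong tolerance-panel, 12 weak tolerance-panel,
##   13 IL-10, 14 immunomodulatory, 15 antimicrobial, 16 anti-inflammatory.
## Factors 4-9 form the allergenic sector and 10-16 the tolerogenic sector;
## factors 1-3 (weak binders across loci) can matter in both reaction types
## and therefore enter only the total (cyclic) area. IFN-gamma sits in the
## tolerogenic sector by the adopted factor ordering; its dual
## pro-inflammatory reading is documented in the vignette.

FACTOR_NAMES <- c("drb1_weak", "dq_weak", "dp_weak",
                  "drb1_strong", "dq_strong", "dp_strong",
                  "allergy_panel_strong", "allergy_panel_weak",
                  "il4", "ifng",
                  "tolerance_panel_strong", "tolerance_panel_weak",
                  "il10", "immunomodulatory", "antimicrobial",
                  "anti_inflammatory")

ALLERGENIC_FACTORS <- 4:9
TOLEROGENIC_FACTORS <- 10:16

# How many alleles each locus panel holds in the affinity predictor
# (12 HLA-DRB1, 5 HLA-DQ, 7 HLA-DP), used as fixed normalization maxima.
LOCUS_MAXIMA <- c(DRB1 = 12, DQ = 5, DP = 7)
SVM_FACTORS <- c(9L, 10L, 13L)
BINARY_FACTORS <- 14:16
PANEL_FACTORS <- c(7L, 8L, 11L, 12L)

#' Build the raw 16-factor feature vector for one peptide
#'
#' Factors 1-6 come from per-locus weak/strong binder counts, 7-8 and 11-12
#' from the susceptibility and protection allele-panel summaries, 9/10/13
#' from cytokine records (the maximum SVM score when any window induces,
#' else 0), and 14-16 are binary presence of the bioactivity function.
#' Missing evidence contributes 0. When no IL-10 cytokine record exists but
#' an `il10_inducer` bioactivity tag does, factor 13 falls back to binary
#' presence.
#'
#' @param binder_counts one-row data.frame with `drb1_weak`, `dq_weak`,
#'   `dp_weak`, `drb1_strong`, `dq_strong`, `dp_strong`, or `NULL`.
#' @param panels panel summary from [panel_summary()], or `NULL`.
#' @param cytokines cytokine records for this peptide (`cytokine`,
#'   `n_inducing`, `score_max`), or `NULL`.
#' @param tags bioactivity rows for this peptide (`function` column), or
#'   `NULL`.
#' @return Named numeric vector of length 16 (raw scale).
#' @export
build_features <- function(binder_counts = NULL, panels = NULL,
                           cytokines = NULL, tags = NULL) {
  f <- setNames(numeric(16), FACTOR_NAMES)
  if (!is.null(binder_counts) && nrow(binder_counts) > 0L) {
    f["drb1_weak"] <- binder_counts$drb1_weak[1]
    f["dq_weak"] <- binder_counts$dq_weak[1]
    f["dp_weak"] <- binder_counts$dp_weak[1]
    f["drb1_strong"] <- binder_counts$drb1_strong[1]
    f["dq_strong"] <- binder_counts$dq_strong[1]
    f["dp_strong"] <- binder_counts$dp_strong[1]
  }
  if (!is.null(panels) && nrow(panels) > 0L) {
    sus <- panels[panels$role == "susceptibility", ]
    pro <- panels[panels$role == "protection", ]
    if (nrow(sus) > 0L) {
      f["allergy_panel_strong"] <- sus$n_strong[1]
      f["allergy_panel_weak"] <- sus$n_weak[1]
    }
    if (nrow(pro) > 0L) {
      f["tolerance_panel_strong"] <- pro$n_strong[1]
      f["tolerance_panel_weak"] <- pro$n_weak[1]
    }
  }
  cyt_max <- function(which) {
    if (is.null(cytokines)) return(NA_real_)
    r <- cytokines[cytokines$cytokine == which, , drop = FALSE]
    if (nrow(r) == 0L) return(NA_real_)
    if (all(r$n_inducing == 0L)) return(0)
    max(r$score_max[r$n_inducing > 0L], na.rm = TRUE)
  }
  il4 <- cyt_max("IL4"); ifng <- cyt_max("IFNG"); il10 <- cyt_max("IL10")
  f["il4"] <- if (is.na(il4)) 0 else il4
  f["ifng"] <- if (is.na(ifng)) 0 else ifng
  has_tag <- function(fun) {
    !is.null(tags) && nrow(tags) > 0L && any(tags[["function"]] == fun)
  }
  f["il10"] <- if (!is.na(il10)) il10 else as.numeric(has_tag("il10_inducer"))
  f["immunomodulatory"] <- as.numeric(has_tag("immunomodulatory"))
  f["antimicrobial"] <- as.numeric(has_tag("antimicrobial"))
  f["anti_inflammatory"] <- as.numeric(has_tag("anti_inflammatory"))
  f
}

#' Normalize a batch of raw feature vectors to [0, 1]
#'
#' Scheme `"panel-max"` (default): binder-count factors are divided by the
#' fixed locus panel sizes (DRB1 12, DQ 5, DP 7), allele-panel factors by
#' the panel size 3, SVM-score factors are min-max scaled over the batch
#' with negative raw scores floored at 0, and binary factors pass through.
#' Scheme `"batch-max"`: every factor is divided by its batch maximum (an
#' all-zero column stays 0).
#'
#' @param raw numeric matrix or data.frame, peptides in rows, 16 factor
#'   columns in the canonical order.
#' @param scheme `"panel-max"` or `"batch-max"`.
#' @return Numeric matrix of the same shape with all entries in [0, 1].
#' @export
normalize_features <- function(raw, scheme = c("panel-max", "batch-max")) {
  scheme <- match.arg(scheme)
  raw <- as.matrix(raw)
  if (ncol(raw) != 16L) stop("expected 16 factor columns, got ", ncol(raw))
  if (nrow(raw) == 0L) stop("at least one feature vector is required")
  norm <- raw
  if (scheme == "panel-max") {
    denom <- c(LOCUS_MAXIMA[c("DRB1", "DQ", "DP")],
               LOCUS_MAXIMA[c("DRB1", "DQ", "DP")])
    for (k in 1:6) norm[, k] <- raw[, k] / denom[k]
    for (k in PANEL_FACTORS) norm[, k] <- raw[, k] / 3
    for (k in SVM_FACTORS) {
      x <- pmax(raw[, k], 0)
      m <- max(x)
      norm[, k] <- if (m > 0) x / m else 0
    }
    # binary factors pass through unchanged
  } else {
    for (k in 1:16) {
      m <- max(raw[, k])
      norm[, k] <- if (m > 0) raw[, k] / m else 0
    }
  }
  norm <- pmin(pmax(norm, 0), 1)
  colnames(norm) <- FACTOR_NAMES
  norm
}

#' Radar-polygon area over normalized factors
#'
#' The 16 factors sit on axes at equal angles of 2*pi/16. With the full
#' cyclic range the area is that of the closed polygon through the 16
#' vertices, `0.5 * sin(2*pi/16) * sum(r_k * r_{k+1})` (k cyclic); over a
#' contiguous sub-range `i..j` it is the open chain of origin-anchored
#' triangles, `0.5 * sin(2*pi/16) * sum_{k=i}^{j-1} r_k * r_{k+1}`. A
#' single nonzero axis therefore has zero area (a lone radius spans no
#' surface). The all-ones polygon attains the maximum total area
#' `8 * sin(pi/8)`.
#'
#' @param r numeric vector of 16 normalized factor values.
#' @param factor_range `NULL` for the total (cyclic) area, or an integer
#'   vector of contiguous factor indices for a sector.
#' @return Non-negative area.
#' @export
#' @examples
#' radar_area(rep(1, 16))          # 8 * sin(pi / 8)
#' radar_area(rep(1, 16), 4:9)     # allergenic-sector chain
radar_area <- function(r, factor_range = NULL) {
  if (length(r) != 16L) stop("feature vector must have length 16, got ", length(r))
  step <- 2 * pi / 16
  if (is.null(factor_range)) {
    return(0.5 * sin(step) * sum(r * r[c(2:16, 1L)]))
  }
  factor_range <- as.integer(factor_range)
  if (any(diff(factor_range) != 1L)) stop("factor_range must be contiguous")
  if (length(factor_range) < 2L) return(0)
  k <- factor_range[-length(factor_range)]
  0.5 * sin(step) * sum(r[k] * r[k + 1L])
}

#' Allergenic / tolerogenic verdict from sector areas
#'
#' `allergenic_dominant` when the allergenic area exceeds the tolerogenic
#' area by more than the relative margin, `tolerogenic_dominant`
#' symmetrically, `dual` when the two areas lie within the margin and both
#' exceed the floor, `inert` when both are at or below the floor.
#'
#' @param allergenic_area,tolerogenic_area sector areas (vectors recycle).
#' @param margin relative dominance margin (default 0.1).
#' @param floor area below which a sector counts as empty (default 0.01).
#' @return Character vector of verdict labels.
#' @export
#' @examples
#' score_verdict(0.5, 0.1)   # "allergenic_dominant"
#' score_verdict(0, 0)       # "inert"
score_verdict <- function(allergenic_area, tolerogenic_area,
                          margin = 0.1, floor = 0.01) {
  n <- max(length(allergenic_area), length(tolerogenic_area))
  a <- rep_len(allergenic_area, n)
  t <- rep_len(tolerogenic_area, n)
  ifelse(a <= floor & t <= floor, "inert",
  ifelse(a > t * (1 + margin), "allergenic_dominant",
  ifelse(t > a * (1 + margin), "tolerogenic_dominant", "dual")))
}

#' Integrated screening of a peptide table
#'
#' Runs the full integrated evaluation for every peptide: assembles the raw
#' 16-factor vector from binder counts, panel summaries of the affinity
#' table, cytokine records and bioactivity tags; normalizes the batch;
#' computes the allergenic (factors 4-9) and tolerogenic (factors 10-16)
#' sector areas and the total cyclic area; and attaches the verdict.
#'
#' @param peptides peptide table with `sequence` and `source` (peptides are
#'   keyed by sequence within source).
#' @param binder_counts table with `peptide_id`, `source` and the six
#'   per-locus weak/strong count columns.
#' @param affinities long affinity table (`peptide_id`, `source`, `allele`,
#'   `scale`, `value`, `censored`).
#' @param cytokines cytokine summary table (`peptide_id`, `source`,
#'   `cytokine`, `n_inducing`, `score_max`).
#' @param bioactivity bioactivity tag table (`peptide_id`, `source`,
#'   `function`).
#' @param config a [screen_config()]; supplies the allele panels, the
#'   normalization scheme and the verdict parameters.
#' @return Data.frame with one row per peptide: `peptide_id`, `source`, 16
#'   raw factors (`raw_*`), 16 normalized factors (`norm_*`),
#'   `allergenic_area`, `tolerogenic_area`, `total_area`, `verdict`.
#' @export
screen_peptides <- function(peptides, binder_counts = NULL,
                            affinities = NULL, cytokines = NULL,
                            bioactivity = NULL, config = screen_config()) {
  pick <- function(tab, seqc, src) {
    if (is.null(tab)) return(NULL)
    sel <- tab$peptide_id == seqc
    if ("source" %in% names(tab) && !is.null(src) && !is.na(src)) {
      sel <- sel & tab$source == src
    }
    tab[sel, , drop = FALSE]
  }
  src_of <- if ("source" %in% names(peptides)) peptides$source else rep(NA_character_, nrow(peptides))
  raw <- t(vapply(seq_len(nrow(peptides)), function(i) {
    seqc <- peptides$sequence[i]; src <- src_of[i]
    aff <- pick(affinities, seqc, src)
    pan <- if (!is.null(aff) && nrow(aff) > 0L) {
      panel_summary(aff, config$panels, config)
    } else NULL
    build_features(binder_counts = pick(binder_counts, seqc, src),
                   panels = pan,
                   cytokines = pick(cytokines, seqc, src),
                   tags = pick(bioactivity, seqc, src))
  }, numeric(16)))
  norm <- normalize_features(raw, config$normalization_scheme)
  aa <- apply(norm, 1, radar_area, factor_range = ALLERGENIC_FACTORS)
  ta <- apply(norm, 1, radar_area, factor_range = TOLEROGENIC_FACTORS)
  tot <- apply(norm, 1, radar_area)
  out <- data.frame(peptide_id = peptides$sequence, source = src_of,
                    stringsAsFactors = FALSE)
  raw_df <- as.data.frame(raw)
  names(raw_df) <- paste0("raw_", FACTOR_NAMES)
  norm_df <- as.data.frame(norm)
  names(norm_df) <- paste0("norm_", FACTOR_NAMES)
  out <- cbind(out, raw_df, norm_df)
  out$allergenic_area <- aa
  out$tolerogenic_area <- ta
  out$total_area <- tot
  out$verdict <- score_verdict(aa, ta, config$verdict_margin, config$verdict_floor)
  rownames(out) <- NULL
  out
}

#' Radar plot of one screened peptide
#'
#' Base-graphics rendering of the 16 normalized factors with the allergenic
#' and tolerogenic sectors outlined.
#'
#' @param normalized numeric vector of 16 normalized factors, or one row of
#'   the [screen_peptides()] output (the `norm_*` columns are used).
#' @param main plot title.
#' @export
plot_radar <- function(normalized, main = "") {
  if (is.data.frame(normalized)) {
    normalized <- as.numeric(normalized[1, paste0("norm_", FACTOR_NAMES)])
  }
  stopifnot(length(normalized) == 16L)
  theta <- (seq_len(16L) - 1) * 2 * pi / 16
  x <- normalized * cos(theta); y <- normalized * sin(theta)
  graphics::plot(NA, xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::segments(0, 0, cos(theta), sin(theta), col = "grey85")
  graphics::text(1.12 * cos(theta), 1.12 * sin(theta), labels = seq_len(16L),
                 cex = 0.7, col = "grey40")
  graphics::polygon(x, y, border = "grey30", col = grDevices::adjustcolor("grey60", 0.3))
  a <- ALLERGENIC_FACTORS; t <- TOLEROGENIC_FACTORS
  graphics::lines(c(0, x[a], 0), c(0, y[a], 0), col = "black", lty = 3, lwd = 2)
  graphics::lines(c(0, x[t], 0), c(0, y[t], 0), col = "grey50", lty = 3, lwd = 2)
  invisible(NULL)
}
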