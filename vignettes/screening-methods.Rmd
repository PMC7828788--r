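---
title: "Methods: digestion-based allergenic vs tolerogenic peptide screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digestion-based allergenic vs tolerogenic peptide screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allerscreen)
```

This vignette documents the models, thresholds and design choices behind
the package, in the order the screening cascade applies them.

## Cleavage model

Protease specificity is written in the P4…P1/P1'…P4' window nomenclature:
the scissile bond lies between the residues in slots P1 and P1'. An
enzyme's rule is a set of *cut* clauses plus optional *block* clauses;
each clause constrains some window slots with an allowed or a forbidden
residue set, and a bond is predicted cleaved iff at least one cut clause
is satisfied and no block clause is. The shipped tables
(`inst/extdata/cleavage_rules.tsv`) transcribe the ExPASy PeptideCutter
documentation:

* **trypsin** — K or R at P1, no proline at P1', with the classical
  exception patterns (W-K-P and M-R-P restore the cut; C/D-K-D, C-K-H/Y,
  C-R-K and R-R-H/R block it);
* **chymotrypsin, high specificity** — F/Y at P1 not before P, W not
  before M/P;
* **chymotrypsin, low specificity** — additionally L/M (not before P/Y)
  and H (not before D/M/P/W);
* **pepsin (pH 1.3 and pH > 2)** — the two-clause forms constraining
  P3 (no H/K/R), P2 (no P), P1/P1' (F/L, plus W/Y at pH > 2) and
  P2' (no P).

Keeping the tables in a versioned data file rather than in code means a
transcription correction never touches the engine.

**Termini.** A clause that references a window slot lying beyond the
sequence ends is treated as unsatisfiable at that bond — the lookaround
semantics a regular-expression transcription of the tables produces. The
alternative (out-of-range slots pass) manufactures cleavage sites at
peptide termini that do not exist in the parent context: the surviving
fragment PFPGPIPNSL, for instance, would acquire a spurious pepsin site
at its last bond only because the blocking proline that follows it in
β-casein falls outside the isolated peptide. Under the adopted semantics
every surviving fragment of the bundled digestion is a fixed point
(re-digestion cuts nothing), which is the property the screen relies on.

**Enzyme set.** The default is pepsin (pH > 2) + trypsin + chymotrypsin
at *low* specificity. The pH > 2 variant is the sensible reading of a
gastric simulation annotated "pH -2", and the chymotrypsin variant was
fixed by calibration: of the four pepsin × chymotrypsin combinations,
only this one reproduces the 24 reference survivors of the seven milk
precursors exactly (high-specificity chymotrypsin leaves 32 fragments of
≥ 9 residues, including artefacts such as CKDDQNPHSSNICNISCDK in place
of SSNICNISCDK). All five rules ship and can be combined freely.

Digestion is simultaneous: the multi-enzyme cut set is the union of the
single-enzyme sets, fragments are maximal uncut runs, and the ≥ 9 residue
filter is inclusive (a 9-mer such as ENSAEPEQS survives) because nine
residues is the canonical MHC class II core length.

## Affinity thresholds

pIC50 and IC50 interconvert exactly (`pIC50 = 9 − log10(IC50/nM)`).
Binder classes follow the pIC50 convention — strong above 6.3, weak on
(5.3, 6.3] — while affinity tiers use half-open IC50 bins below 50, 500
and 5000 nM. The two conventions disagree only on (500, 501.19) nM,
the rounding gap of the "strong means < 500 nM" shorthand; when both
scales are supplied the pIC50 rule wins. Censored table cells
(">5000 nM") are stored at the censoring bound with a flag and classify
as tier `none`. Printed pIC50 values with a spurious leading minus are
read as positive and logged.

Two fixed allele panels summarize the affinity matrix per peptide:
*susceptibility* (DRB1\*01:01, DQ7, DQ8) and *protection* (DRB1\*03:01,
DRB1\*14:19, DRB1\*14:21). Missing panel alleles are reported, never
imputed.

## Epitope mapping and pool comparison

Epitope matching is purely quantitative: every catalog epitope on the
same parent overlapping the peptide by ≥ 1 residue is reported with its
overlap length, its fraction of the peptide, and the interval relation
(exact, peptide-within-epitope, epitope-within-peptide, partial). No
minimum-overlap verdict is imposed, since the distinction between
"matches" and "partially matches" is a reporting question, not a model
one. Pool comparison classifies pairs with precedence identical >
containment > coordinate-overlap; sequence identity is primary and
coordinates are consulted only for same-parent pairs, so pools from
different numbering conventions still compare.

## Cytokine and bioactivity evidence

Predictor outputs are opaque evidence: the package stores window counts
and SVM score ranges, and counts a window as inducing when its score is
*strictly* above the threshold (default 0.2, configurable). A
consistency checker flags rows whose reported inducing-window count
exceeds the number of windows that fit in the peptide — the bundled IL-4
row for the 14-mer SDIPNPIGSENSEK reports 7 inducing 9-mers where only 6
windows exist; such rows are flagged and kept, because the screen must
load published tables as printed.

## The 16-factor radial score

Each peptide maps to 16 factors in a fixed order: per-locus weak binder
counts (1–3), per-locus strong binder counts (4–6), strong/weak counts on
the susceptibility panel (7–8), the IL-4 score (9), the IFN-γ score (10),
strong/weak counts on the protection panel (11–12), the IL-10 score (13),
and binary immunomodulatory / antimicrobial / anti-inflammatory flags
(14–16). Factors 4–9 form the allergenic sector, 10–16 the tolerogenic
sector; factors 1–3 are deliberately excluded from both (weak binding
across loci can accompany either reaction type) and contribute only to
the total area. IFN-γ sits in the tolerogenic sector by this ordering,
but it reads both ways — pro-inflammatory alongside IL-4, tolerance-
supporting alongside IL-10 — and reports should say so. When a peptide
has an IL-10 inducer tag but no numeric IL-10 record, factor 13 falls
back to binary presence so that documented IL-10 evidence is not silently
dropped.

**Normalization.** "Normalized to one" admits two readings, and both
ship. The default `panel-max` scheme divides counts by their theoretical
maxima — 12 DRB1, 5 DQ and 7 DP alleles in the affinity predictor's
panel, 3 alleles per susceptibility/protection panel — and min–max
scales the SVM-score factors over the batch with negative scores floored
at zero. It is reproducible peptide by peptide and keeps batches
comparable. The alternative `batch-max` scheme divides every factor by
its batch maximum (zero columns stay zero); it always attains 1 somewhere
but changes with the batch composition.

**Geometry.** The 16 normalized factors are radii on axes at equal
angles θ = 2π/16. The total score is the area of the closed polygon,
`½·sin(θ)·Σₖ r_k·r_{k+1}` (cyclic); a sector over factors i…j is the
open chain of origin-anchored triangles, the same sum over consecutive
pairs without the closing edge. Consequences worth knowing: a single
nonzero axis has zero area (a lone radius spans no surface, which is the
point of an *integrated* score); areas scale quadratically; the total is
bounded by the all-ones polygon, `8·sin(π/8) ≈ 3.061`; and factor order
matters, which is why the order above is part of the public contract.
The implementation is cross-checked against a shoelace evaluation of the
explicit polygon vertices to 1e−9.

**Verdict.** With allergenic area *a* and tolerogenic area *t*:
`allergenic_dominant` if *a* > *t*·(1 + margin), symmetrically
`tolerogenic_dominant`, `dual` when within the margin and both above the
floor, `inert` when both are at or below the floor. Defaults
margin = 0.1 and floor = 0.01 are deliberately mild: the margin absorbs
rounding-level differences between sectors of unequal length (6 vs 7
factors), and the floor separates "no evidence" from "weak evidence".
No published area values exist to calibrate against, so the verdict is a
screening label, not a calibrated probability; the one qualitative
anchor available — the Bos d 4 core SSNICNISCDK screening
allergenic-dominant while its longer in-vitro context screens
tolerogenic-dominant — holds under the defaults.

## Replicate homogeneity

Identification score and emPAI live on wildly different scales, so the
Manhattan distance between replicates in that plane standardizes each
dimension by its pooled standard deviation by default; a raw mode is
retained because the published procedure does not state a scaling. Keys
missing from any replicate are excluded and listed. Flagging uses the
per-key minimum pairwise distance against mean + 2 SD of those minima, a
conventional outlier cut that can be overridden with an explicit
threshold.

## Synthetic data and what it shows

The generator builds proteins over a reduced alphabet (A, E, G, N, Q, S,
T, I, V) containing no residue any default-enzyme clause can act on, then
plants lysines at Bernoulli-sampled bonds. Because the alphabet also
contains none of the residues appearing in trypsin's block patterns,
every planted bond is provably cut and no other bond can be: planted
ground truth is exact, and the pipeline must recover cut sites and
planted strong binders (IC50 drawn below 450 nM vs above 600 nM,
log-uniform) perfectly — there is nothing statistical to estimate.
Defaults: 5 proteins of 60–120 residues, site density 0.08 per bond, 6
alleles with 2 planted strong binders per peptide, SVM scores normal
around the 0.2 threshold (sd 0.5). Seeded runs are bit-reproducible.

This emulates the pipeline's *contracts*, not milk: real sequences use
the full alphabet, real cleavage contexts overlap and interact, and real
affinity tables are neither log-uniform nor independent across alleles.
Passing synthetic recovery therefore validates the machinery (engine,
classification, bookkeeping), while fidelity to real data rests on the
bundled reference tables.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive on the precursor sequence everywhere.
* Validation of peptide rows *reports* coordinate/sequence mismatches
  instead of rejecting them; the bundled in-vitro table carries two such
  rows exactly as printed, with notes.
* Empty sequences are errors for digestion and fixed-point checks; a
  single residue has no bonds and is trivially a fixed point.
* A window longer than its peptide yields zero windows, not an error.
* Zero-variance dimensions in the homogeneity check fall back to scale 1
  to avoid 0/0.
* Ties in epitope match ordering break by epitope start.

The test suite exercises these contracts with, among others, 1000 random
sequences (length ≤ 50) against a brute-force per-bond oracle for every
enzyme, 500 random vectors against the shoelace oracle, and three seeded
synthetic bundles; the whole suite runs in well under five minutes on one
CPU.

## Limitations

Digestion is all-or-nothing at predicted sites: no kinetics, no missed
cleavages, no matrix or emulsion effects, no compartment models. The
affinity, cytokine and bioactivity inputs are ingested predictions, so
every upstream predictor bias flows through unchanged. The radial score
is a screening heuristic — its factor weights are implicit in the
normalization and factor order, and nothing here is a clinical
allergenicity claim.
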