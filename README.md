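# allerscreen

Integrated in-silico screening of food-protein peptides for allergenic
versus tolerogenic potential.

Food proteins reach the immune system as peptides: gastrointestinal
proteases fragment them, fragments of nine or more residues can occupy the
MHC class II binding groove, and the presented peptides then steer the
response towards sensitization (IgE class switching, IL-4) or tolerance
(IL-10, protective HLA alleles, anti-inflammatory activity). `allerscreen`
implements that screening cascade for sequence-level data, with cow's-milk
allergens as the bundled worked case:

1. **Simulated digestion** — rule-based cleavage-site prediction for
   pepsin (pH 1.3 and pH > 2), trypsin and chymotrypsin (high and low
   specificity), with the protease specificity tables expressed in the
   P4…P1/P1'…P4' window nomenclature. A bond between P1 and P1' is cut iff
   some cut clause holds and no exception clause does; multi-enzyme
   digestion takes the union of cut sets, and survivors are the uncut runs
   of ≥ 9 residues.
2. **Epitope mapping** — quantitative interval overlap of peptides with
   curated IgE and T-cell epitopes (overlap length, fraction, and the
   interval relation), plus set comparison of peptide pools (identical /
   containment / overlapping pairs).
3. **MHC class II binder classification** — thresholds on the pIC50 scale
   (strong: pIC50 > 6.3, i.e. IC50 below ≈ 500 nM; weak: 5.3 < pIC50 ≤ 6.3)
   and IC50 affinity tiers (high < 50 nM, intermediate < 500 nM,
   low < 5000 nM), with per-locus counting (HLA-DRB1/DQ/DP) and
   susceptibility/protection allele-panel summaries.
4. **Cytokine and bioactivity annotation** — ingestion of IL-4 / IFN-γ /
   IL-10 induction summaries (SVM scores over 9- or 15-mer windows,
   inducing above 0.2) and bioactivity tags, with consistency checking.
5. **Integrated radial score** — a 16-factor vector per peptide,
   normalized to [0, 1], drawn on 16 radar axes at equal angles; the
   polygon area over factors 4–9 quantifies allergenic evidence, over
   10–16 tolerogenic evidence, and the verdict compares the two sector
   areas. For axes at angle step θ = 2π/16 the area is
   `½·sin(θ)·Σ r_k·r_{k+1}`.

A replicate-homogeneity check for mass-spectrometry identification
summaries (Manhattan distance in the score × emPAI plane) and a seeded
synthetic-data generator with planted ground truth round out the package.

## Worked example

```r
library(allerscreen)

fx <- load_reference_data()
surv <- digest_all(fx$proteins)      # pepsin pH>2 + trypsin + chymotrypsin (low)
nrow(surv)
#> [1] 24
head(surv, 3)
#>   protein_id allergen_label start end      sequence source
#> 1     P00711        Bos d 4    56  68 DTQAIVQNNDSTE     IS
#> 2     P00711        Bos d 4    88  98   SSNICNISCDK     IS
#> 3     P02754        Bos d 5   124 132     ENSAEPEQS     IS
```

The seven precursors fragment into exactly 24 peptides of ≥ 9 residues
(2/1/5/4/3/5/4 per protein), each a digestion fixed point — re-digesting
any survivor cuts nothing. Comparing them with the seven peptides found
after in-vitro digestion:

```r
cmp <- compare_peptide_sets(fx$is_peptides, fx$iv_peptides)
cmp$identical$seq_a
#> [1] "SDIPNPIGSENSEK"
cmp$containment
#>         seq_a                    seq_b  direction
#> 1 SSNICNISCDK NNKIWCKDDQNPHSSNICNISCDK a_within_b
```

One sequence is recovered identically in both pools and one simulated
fragment survives in vitro inside a longer peptide. Scoring the combined
pool:

```r
cols <- c("protein_id", "start", "end", "sequence", "source")
sc <- screen_peptides(rbind(fx$is_peptides[cols], fx$iv_peptides[cols]),
                      binder_counts = fx$binder_counts,
                      affinities = fx$affinities,
                      cytokines = fx$cytokines,
                      bioactivity = fx$bioactivity)
sc[sc$peptide_id == "SSNICNISCDK",
   c("allergenic_area", "tolerogenic_area", "verdict")]
#>   allergenic_area tolerogenic_area             verdict
#> 2      0.09191906                0 allergenic_dominant
```

The Bos d 4 fragment SSNICNISCDK carries only strong-binder and IL-4
evidence, so its allergenic sector dominates; the same residues embedded
in the longer in-vitro peptide NNKIWCKDDQNPHSSNICNISCDK accumulate
anti-inflammatory and IL-10 evidence instead and flip to
`tolerogenic_dominant` — the screen's central contrast between a
sensitizing core and its tolerized context.

A thin command-line front end (`exec/allerscreen`) exposes the same steps
as `digest`, `map-epitopes`, `classify-binding`, `annotate`, `score`,
`compare`, `qc-homogeneity` and `fixtures` subcommands.

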