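# ptmtalk

Crosstalk between posttranslational modifications (PTMs) — phosphorylation,
O-β-GlcNAcylation and Arg/Lys methylation — on a protein sequence, called
from per-residue predictor scores, ortholog alignments and curated
experimental annotations.

Serine/threonine hydroxyls can carry either a phosphate or an O-linked
GlcNAc; a residue strongly predicted for **both** is a *Yin Yang site*, a
candidate point of reciprocal regulation. `ptmtalk` classifies every
Ser/Thr/Tyr site of a protein by this logic, flags *false-negative Yin
Yang* sites (conserved residues with one channel above threshold and the
other just below it), applies selection filters (experimental support,
evolutionary conservation, surface accessibility), calls consensus Arg/Lys
methylation sites across multiple predictors, transfers known sites
between homologs by global alignment, and annotates
methylation–phosphorylation neighbor pairs. Human FoxO3 — whose
phosphorylation by AKT/ERK/IKK drives its nuclear exclusion in cancer —
ships as the fully curated regression fixture.

With `P`/`G` meaning a channel potential at or above its threshold
(default 0.5) and `near` meaning within ε (default 0.1) below it:

```
yy_positive         P ∧ G
yy_false_negative   conserved ∧ ((P ∧ nearG) ∨ (G ∧ nearP))
phospho_only        P          glyc_only   G          none   otherwise
```

The package is tidyverse-native: functions take data frames first, return
tibbles, and results support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(ptmtalk)

ann <- foxo3_annotations()          # classify + filter the FoxO3 fixture
glance(ann)[, 1:6]
#> # A tibble: 1 x 6
#>   n_sites n_phospho_pred n_glyc_pred n_yy_positive n_yy_false_negative
#>      <int>          <int>       <int>         <int>               <int>
#> 1       97             72          41            19                   4
#> # i 1 more variable: n_phospho_only <int>

sort(ann$position[ann$classification == "yy_false_negative"])
#> [1]  32 294 425 644

consensus_calls(foxo3_methylation_calls(), min_agree = 2,
                record = foxo3_record())[, 1:3]
#> # A tibble: 9 x 3
#>   position residue n_predictors
#>      <int> <chr>          <int>
#> 1      149 K                  2
#> 2      207 K                  2
#> 3      248 R                  3
#> ...

transfer_sites(foxo1_record(), foxo3_record(), c(248, 250))
#> # A tibble: 2 x 6
#>   src_pos src_residue aligned_column dst_pos dst_residue residue_match
#>     <int> <chr>                <int>   <int> <chr>       <lgl>
#> 1     248 R                      248     248 R           TRUE
#> 2     250 R                      250     250 R           TRUE
```

Reading: of the 97 fixture sites, 72 are phosphorylation-positive
(59 Ser, 9 Thr, 4 Tyr) and 41 O-GlcNAc-positive (33 Ser, 8 Thr); 19 are
positive Yin Yang sites and four (Thr32, Ser294, Ser425, Ser644 — AKT,
ERK and IKK substrates) are conserved false-negative Yin Yang sites, the
prime crosstalk candidates. The nine-site methylation consensus includes
Arg248/Arg250, which map position-for-position onto the FoxO1 arginines
whose methylation blocks AKT phosphorylation of the neighboring serine.

The full pipeline (conservation → classification → selection → methylation
→ transfer → reports) runs from one config:

```r
res <- run_pipeline(foxo3_config(out_dir = "reports"))
res$files   # site_table.tsv, methyl_table.tsv, neighbors.tsv, summary.json, transfers.tsv
```

Note the packaged sequences are synthetic stand-ins (constructed to carry
the curated site residues and published flanking windows; see
`inst/extdata/foxo3_fixture_notes.md`), not redistributed database
entries.

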