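---
title: "Methods: calling PTM crosstalk sites with ptmtalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling PTM crosstalk sites with ptmtalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmtalk)
```

## The problem

Serine and threonine hydroxyls can carry either a phosphate (written by
kinases) or a single O-linked N-acetylglucosamine (written by OGT, removed
by O-GlcNAcase). Because the two modifications compete for the same
hydroxyl, a residue that is strongly predicted for *both* is a candidate
point of reciprocal regulation — a **Yin Yang site**. Mapping such sites,
together with nearby methylation of Arg/Lys residues that can sterically
mask a phosphosite, gives a per-residue picture of where a protein's
regulation can be switched. The package implements this workflow for any
protein, with human FoxO3 — a tumor-suppressor transcription factor whose
phosphorylation by AKT, ERK and IKK drives its nuclear exclusion and
degradation — as the packaged, fully worked regression case.

The upstream per-residue scores (NetPhos-style phosphorylation potentials,
YinOYang-style O-GlcNAc potentials, ScanSite-style surface accessibility)
come from neural-network predictors that the package deliberately does not
re-implement; their outputs are ingested as score tables. What the package
owns is everything downstream: the crosstalk classification, the selection
filters, conservation inference, consensus methylation calling, homology
transfer, kinase-motif scanning, and the reporting layer.

## The classification rule

Each channel of a site is reduced to a category relative to its predictor
threshold \(\theta\) (0.5 for the phosphorylation potential) with a margin
\(\varepsilon\):

* **above**: potential \(\ge \theta\)
* **near**: \(\theta - \varepsilon \le\) potential \(< \theta\)
* **below**: otherwise.

With \(P\)/\(G\) the above-states and \(nearP\)/\(nearG\) the near-states
of the phospho and glyc channels, a site is classified with the precedence

1. `yy_positive` if \(P \wedge G\);
2. `yy_false_negative` if the site is conserved and
   \((P \wedge nearG) \vee (G \wedge nearP)\);
3. `phospho_only` if \(P\); `glyc_only` if \(G\);
4. `none` otherwise.

The precedence ordering is stated explicitly because the prose definitions
of these site classes imply but never order the rules; making
`yy_positive` dominate guarantees the classes are mutually exclusive and
exhaustive, which the test suite asserts against an independently written
truth-table oracle over all 18 categorical cells. Tyrosine sites carry no
glycosylation channel (O-GlcNAc does not occur on Tyr), encoded as `NA`,
so only `phospho_only`/`none` are reachable for them.

**Choice of \(\varepsilon\).** "Near threshold" is not quantified by the
upstream predictors; the package defaults to 0.1 on the potential scale
(one fifth of the threshold), configurable in `crosstalk_params()`. The
packaged FoxO3 fixture stores the published categorical calls rather than
raw potentials, so the regression totals do not depend on this default.

## Selection filters

Three per-site filters temper false positives:

1. **Experimental support** — presence in a curated table of
   experimentally verified phosphosites (Phospho.ELM / Swiss-Prot style);
   matching is by position *and* residue letter, and a residue conflict is
   treated as a fixture error rather than a silent miss.
2. **Evolutionary conservation** — the site's residue is identical across
   the ortholog alignment. The identity fraction required is
   configurable; the default is strict identity across all aligned
   species (`min_fraction = 1`), the conservative reading of "conserved
   among species". Gaps count as mismatches: an ortholog deletion is
   evidence against conservation. Similarity-group conservation (e.g.
   S≈T) is off by default but available via an equivalence table.
3. **Structural accessibility** — surface accessibility \(\ge 0.5\).
   Sites with no SA value keep `accessible = NA` and remain positive
   predictions; they are never silently dropped. A site is `accepted`
   when conserved and not demonstrably buried.

## Kinase motif scanning

Kinase preference is modeled as a 15-position (±7 residues) weight matrix
over the 20 residues. A window's score is the **raw sum** of per-position
weights (no length normalisation — windows are fixed-width, so
normalisation would only rescale). Termini are padded with `X`, which
scores zero at every position. A candidate is ranked by the fraction of
background windows (every targetable window of a user-supplied reference
set) scoring strictly better: percentile 0 is the best possible rank,
ties resolve in the candidate's favor, and hits are reported at
percentile \(\le\) 0.05 by default — the stringency is configurable since
no canonical value exists. The scanner is a generic re-implementation
validated on synthetic motifs; the packaged FoxO3 kinase assignments are
ingested as part of the curated fixture, not recomputed, because the
original scanner's matrices are proprietary.

## Methylation consensus and homology transfer

Multiple Arg/Lys methylation predictors are combined by voting: a site is
called when at least `min_agree` predictors agree. The default is a 2-of-3
majority — intersection of all predictors is stricter than a published
"consensus" plausibly is, and union would defeat the purpose of
combining predictors.

Known sites are transferred between homologs through a global
(Needleman–Wunsch) pairwise alignment — BLOSUM62, gap open 10, gap extend
0.5 by default — delegated to `Biostrings::pairwiseAlignment()` and
cross-checked in the tests against a brute-force dynamic-programming
oracle on short sequences. A transfer is a candidate only when the mapped
residue is identical (R→R, K→K); similar-residue transfer is off by
default. When several alignments are co-optimal the traceback returned by
Biostrings is used as-is; it is deterministic, and scores (which the
oracle checks) are unaffected — only which co-optimal path is reported
could differ from another aligner.

## Neighbor crosstalk and domain context

Methylation–phosphorylation neighbor pairs are reported within a default
radius of 5 residues, which covers the two canonical FoxO3 cases: the
AKT-motif arginines at 248/250 flanking Ser253 (distance 5 and 3) and
Lys207 next to the MST1 site Ser209 (distance 2). Domain context uses a
plain interval map supplied as data; the packaged FoxO3 map carries the
DNA-binding domain (148–257), the nuclear localisation signal as two
separate `NLS` entries (249–251, 269–271 — the feature is discontinuous
and nothing in the source material decides whether it is "one" feature;
two intervals with a shared name lose no information), the nuclear export
sequence (386–396) and the transactivation domain (258–673).

## The packaged FoxO3 fixture

The per-residue fixture (97 Ser/Thr/Tyr rows) stores published categorical
calls, kinase assignments, SA values, conservation flags, and the
21-residue experimentally-verified list. Two curation points are worth
knowing (details in `inst/extdata/foxo3_fixture_notes.md`):

* The row-level transcription was reconciled to the published per-residue
  totals (72 phosphosites: 59 S / 9 T / 4 Y). Three serines that are
  O-GlcNAc-positive but carry no Yin Yang call (S144, S321, S421) were
  set phospho-below — the only internally consistent reading under the
  classification rule — plus the three least-evidenced surplus rows
  (S30, S55, T228).
* The packaged sequences are **synthetic stand-ins**: the real
  UniProt/RefSeq entries are not redistributed. The stand-ins carry the
  correct residue letter at every curated position and the published
  13-residue methylation flanks verbatim at their printed coordinates, so
  flank extraction, conservation at site positions and the
  FoxO1→FoxO3 Arg248/Arg250 transfer behave exactly as with the real
  sequences; background positions are seeded random residues.

```{r fixture-run}
ann <- foxo3_annotations()
glance(ann)
summarize_classifications(ann)
```

## What the synthetic generators emulate

`gen_protein()` draws i.i.d. residues from a given composition;
`gen_orthologs()` applies independent per-position substitutions (rate
`sub_rate`) with no indels, so positional bookkeeping is exact and the
conservation module can be checked against planted truth;
`gen_site_scores()` draws potentials uniformly within class-consistent
intervals kept clear of the decision boundaries, so classification
recovery is exact by construction; `gen_callsets()` applies independent
sensitivity/false-positive noise per predictor, so consensus recall can
be checked against its closed-form binomial expectation
\(P(\ge k \text{ of } n)\).

These generators are deliberately idealised: no rate heterogeneity across
sites, no phylogenetic structure, no indels by default, and no attempt to
mimic the score distributions of real neural-network predictors.
Consequently, passing recovery tests demonstrates the *logic* of the
pipeline (classification, thresholding, voting, conservation counting) is
correct, not that the upstream predictors are accurate on real proteins.

## Problem sizes and numerical choices

The test suite uses 300–800-residue synthetic proteins, 100 seeds for
classification recovery, 200 random pairs (lengths ≤ 8, three-letter
alphabet) for the alignment oracle, and 50 planted sites over 500
positions for consensus statistics — sizes at which every property is
exact or its sampling band is known in closed form. All generator
functions are pure in (parameters, seed). Potentials live on [0, 1];
category boundaries use `>=` at the threshold so the encoding
`above ⇔ potential ≥ θ` is exact, and planted potentials are kept at
least \(\varepsilon/4\) from every boundary so no test can flake on a
floating-point tie.

## Limitations

* The package never recomputes neural-network potentials; garbage scores
  in, garbage classifications out.
* Strict-identity conservation is harsh on distant orthologs; relax
  `min_fraction` or supply an equivalence table for deep alignments.
* Homology transfer assumes the global alignment is trustworthy around
  the site; for multi-domain proteins with rearrangements a local or
  anchored alignment would be preferable.
* The kinase scanner's percentile calibration is only as representative
  as the supplied background reference set.
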