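# FoxO3 fixture notes and changelog

## Provenance

`foxo3_site_scores.tsv` is a curated transcription of the published
per-residue FoxO3 prediction results (NetPhos 2.0 phosphorylation
categories, YinOYang 1.2 O-GlcNAc categories, ScanSite 2.0 kinase
assignments and surface-accessibility values, and conservation status from a
five-species ortholog alignment). `foxo3_ev_sites.tsv` lists the 21
experimentally verified phosphorylation residues (20 Ser, 1 Thr) curated
from Phospho.ELM and Swiss-Prot. The upstream neural-network scores are not
recomputable, so the table stores the published categorical calls
(`above`/`near`/`below` relative to each predictor's threshold), not raw
potentials.

## Curation changelog

- The per-row transcription initially carried 64 Ser and 10 Thr
  phosphorylation-positive rows, while the published per-residue totals are
  59 Ser / 9 Thr / 4 Tyr. Six rows were reconciled to `phos_cat = below`:
  - S144, S321, S421: each is O-GlcNAc-positive yet carries no Yin Yang
    call; under the crosstalk rule (both channels above => Yin Yang) the row
    is internally consistent only if the phosphorylation channel was below
    threshold. S321 and S421 remain experimentally verified phosphosites
    (verification does not require a positive prediction).
  - S30, S55, T228: the lowest-positioned surplus rows with no experimental
    support, no kinase assignment, no SA value and no glycosylation signal.
- Ser173 SA appears as 3.5 in one published summary and 3.6 in the
  per-residue table; the fixture follows the per-residue table (3.6).
- `near` is recorded for the glycosylation channel of the four
  false-negative Yin Yang rows (T32, S294, S425, S644), matching their
  published description (high phosphorylation potential, O-GlcNAc potential
  very close to threshold, conserved).
- T395, T404, T418 are the only rows not marked conserved.

## Synthetic sequences

`foxo3_synthetic.fasta`, `foxo3_orthologs_synthetic.afa` and
`foxo1_synthetic.fasta` are SYNTHETIC STAND-INS built by
`data-raw/build-fixtures.R`, not the UniProt/RefSeq entries whose accessions
they echo (those sequences are not redistributed here). They are constructed
so that every curated site position carries the correct residue letter, the
published 13-residue methylation flanking windows occur verbatim at their
printed coordinates, ortholog stand-ins are substitution-only variants
conserved at every site position except T395/T404/T418, and the FoxO1
stand-in differs by background substitutions plus a 21-residue deletion
outside the site-mapping region. Everything else is seeded random
background.

## Methylation call sets

Which predictor (MeMo, BPB-PPMS, MASA) called which of the nine consensus
methylation sites was not published. `foxo3_methylation_calls.tsv` is a
CONSTRUCTED fixture: each of the nine sites (R248, R250, R264, R266, K149,
K207, K270, K271, K569) appears in at least two of the three call sets, and
two decoy singleton calls (K262 in MeMo, R249 in MASA) appear in exactly
one, so the 2-of-3 consensus reproduces the published nine and the decoys
drop out.
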