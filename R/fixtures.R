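#' Packaged FoxO3 fixtures
#'
#' Accessors for the packaged human-FoxO3 regression fixtures:
#'
#' * `foxo3_site_scores()` — curated per-residue prediction table: 97
#'   Ser/Thr/Tyr sites with categorical phosphorylation (NetPhos-style,
#'   threshold 0.5) and O-GlcNAc (YinOYang-style) channels, ScanSite-style
#'   surface accessibility and kinase assignments, and conservation flags.
#' * `foxo3_ev_sites()` — the 21 experimentally verified phosphosites
#'   (20 Ser, 1 Thr) curated from Phospho.ELM / Swiss-Prot.
#' * `foxo3_methylation_calls()` — constructed three-predictor
#'   (MeMo / BPB-PPMS / MASA style) Arg/Lys methylation call sets whose
#'   2-of-3 consensus is the nine published sites.
#' * `foxo3_domains()` — the FoxO3 domain map (DBD 148-257, split NLS
#'   249-251 and 269-271, NES 386-396, transactivation domain 258-673).
#' * `foxo3_record()`, `foxo3_msa()`, `foxo1_record()` — SYNTHETIC
#'   stand-in sequences (see `foxo3_fixture_notes.md` in the package
#'   `extdata`): they carry the correct residue letter at every curated
#'   site position and the published methylation flanking windows at their
#'   printed coordinates, with seeded random background elsewhere. They
#'   are not the UniProt/RefSeq database entries.
#'
#' @return A tibble (or `msa` for `foxo3_msa()`).
#' @name foxo3_fixtures
NULL

fixture_path <- function(f) {
  system.file("extdata", f, package = "ptmtalk", mustWork = TRUE)
}

#' @rdname foxo3_fixtures
#' @export
foxo3_site_scores <- function() {
  read_site_scores(fixture_path("foxo3_site_scores.tsv"))
}

#' @rdname foxo3_fixtures
#' @export
foxo3_ev_sites <- function() {
  read_ev_sites(fixture_path("foxo3_ev_sites.tsv"))
}

#' @rdname foxo3_fixtures
#' @export
foxo3_methylation_calls <- function() {
  read_methylation_calls(fixture_path("foxo3_methylation_calls.tsv"))
}

#' @rdname foxo3_fixtures
#' @export
foxo3_domains <- function() {
  read_domains(fixture_path("foxo3_domains.tsv"))
}

#' @rdname foxo3_fixtures
#' @export
foxo3_record <- function() {
  read_fasta(fixture_path("foxo3_synthetic.fasta"))[1, ]
}

#' @rdname foxo3_fixtures
#' @export
foxo3_msa <- function() {
  read_alignment(fixture_path("foxo3_orthologs_synthetic.afa"),
                 dialect = "fasta")
}

#' @rdname foxo3_fixtures
#' @export
foxo1_record <- function() {
  read_fasta(fixture_path("foxo1_synthetic.fasta"))[1, ]
}

#' Annotated FoxO3 sites from the packaged fixtures
#'
#' Convenience wrapper running [annotate_sites()] on the packaged score
#' and EV tables.
#'
#' @param params A [crosstalk_params()].
#' @return A `yy_annotation` tibble.
#' @export
foxo3_annotations <- function(params = crosstalk_params()) {
  annotate_sites(foxo3_site_scores(), ev = foxo3_ev_sites(),
                 params = params)
}
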