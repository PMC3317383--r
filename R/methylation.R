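#' Read methylation predictor call sets
#'
#' @param path TSV with columns `predictor`, `position`, `residue`
#'   (`R`/`K`), one row per call.
#' @return A tibble of calls.
#' @export
read_methylation_calls <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    predictor = readr::col_character(),
                    position = readr::col_integer(),
                    residue = readr::col_character()
                  ))
}

#' Consensus methylation calls across predictors
#'
#' A site is part of the consensus when at least `min_agree` predictors
#' call it. The default 2-of-3 majority reflects the usual multi-predictor
#' setting; `min_agree = 1` gives the union, `min_agree` equal to the
#' number of predictors the intersection.
#'
#' @param calls Call tibble (`predictor`, `position`, `residue`), e.g.
#'   from [read_methylation_calls()] or [gen_callsets()].
#' @param min_agree Minimum number of agreeing predictors (`>= 1`, at most
#'   the number of distinct predictors in `calls`).
#' @param record Optional record/sequence; when given, called residues are
#'   validated against the sequence.
#' @return A tibble (`position`, `residue`, `n_predictors`, `predictors`),
#'   sorted by position.
#' @export
consensus_calls <- function(calls, min_agree = 2, record = NULL) {
  stopifnot(all(c("predictor", "position", "residue") %in% names(calls)))
  n_pred <- dplyr::n_distinct(calls$predictor)
  if (min_agree < 1 || (n_pred > 0 && min_agree > n_pred)) {
    abort(paste0("min_agree (", min_agree, ") must be between 1 and the ",
                 "number of call sets (", n_pred, ")"),
          class = "ptmtalk_usage_error")
  }
  if (!is.null(record)) {
    seqstr <- as_sequence(record)
    actual <- substring(seqstr, calls$position, calls$position)
    bad <- actual != calls$residue
    if (any(bad)) {
      abort(paste0("call at position ", calls$position[bad][1],
                   " claims residue ", calls$residue[bad][1],
                   " but sequence has ", actual[bad][1]),
            class = "ptmtalk_validation_error")
    }
  }
  calls |>
    dplyr::distinct(.data$predictor, .data$position, .data$residue) |>
    dplyr::group_by(.data$position, .data$residue) |>
    dplyr::summarise(
      n_predictors = dplyr::n(),
      predictors = paste(sort(.data$predictor), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_predictors >= min_agree) |>
    dplyr::arrange(.data$position)
}

#' Global pairwise alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment via
#' [Biostrings::pairwiseAlignment()], defaulting to BLOSUM62 with affine
#' gap penalties (open 10, extend 0.5). Pass a plain numeric
#' `substitution_matrix` (with the alphabet as dimnames) for toy scoring
#' schemes; `gap_open = 0` makes gaps linear at `gap_extend` per residue.
#'
#' @param a,b One-row record tibbles or sequence strings.
#' @param substitution_matrix Name of a packaged matrix (e.g.
#'   `"BLOSUM62"`) or a numeric substitution matrix.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return A list of class `pairwise_alignment`: `a_id`, `b_id`, `a_aln`,
#'   `b_aln` (gapped strings), `score`, and `msa` (a two-row [new_msa()]
#'   for coordinate mapping).
#' @export
align_global <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  a_seq <- as_sequence(a)
  b_seq <- as_sequence(b)
  if (nchar(a_seq) == 0 || nchar(b_seq) == 0) {
    abort("cannot align empty sequences", class = "ptmtalk_usage_error")
  }
  a_id <- if (is.data.frame(a)) a$id else "a"
  b_id <- if (is.data.frame(b)) b$id else "b"
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a_seq), Biostrings::AAString(b_seq),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  a_aln <- as.character(Biostrings::alignedPattern(pa))
  b_aln <- as.character(Biostrings::alignedSubject(pa))
  structure(
    list(a_id = a_id, b_id = b_id, a_aln = unname(a_aln),
         b_aln = unname(b_aln), score = Biostrings::score(pa),
         msa = new_msa(c(a_id, b_id), c(unname(a_aln), unname(b_aln)))),
    class = "pairwise_alignment"
  )
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global alignment ", x$a_id, " / ", x$b_id, ", score ", x$score,
      "\n", sep = "")
  invisible(x)
}

#' Transfer modification sites between homologs through an alignment
#'
#' Maps each source-protein site through a global pairwise alignment to
#' the homolog and records the mapped position, residue and whether the
#' residues are identical. Only identical-residue results
#' (`residue_match`) are candidate homology transfers; sites opposite a
#' gap get `dst_pos = NA`.
#'
#' @param src,dst One-row record tibbles or sequence strings (source
#'   carries the known sites, destination receives them).
#' @param src_sites Integer vector of 1-based source positions.
#' @param ... Passed to [align_global()].
#' @param alignment Optional precomputed [align_global()] result for the
#'   pair (source first).
#' @return A tibble (`src_pos`, `src_residue`, `aligned_column`,
#'   `dst_pos`, `dst_residue`, `residue_match`).
#' @export
transfer_sites <- function(src, dst, src_sites, ..., alignment = NULL) {
  if (is.null(alignment)) alignment <- align_global(src, dst, ...)
  msa <- alignment$msa
  src_id <- alignment$a_id
  dst_id <- alignment$b_id
  cols <- map_position(msa, src_id, src_sites)
  src_chars <- strsplit(msa_row(msa, src_id), "")[[1]]
  dst_chars <- strsplit(msa_row(msa, dst_id), "")[[1]]
  dst_pos <- unmap_position(msa, dst_id, cols)
  dst_res <- ifelse(dst_chars[cols] == "-", NA_character_, dst_chars[cols])
  tibble(
    src_pos = as.integer(src_sites),
    src_residue = src_chars[cols],
    aligned_column = as.integer(cols),
    dst_pos = dst_pos,
    dst_residue = dst_res,
    residue_match = !is.na(dst_res) & dst_res == src_chars[cols]
  )
}

#' Write a homology-transfer report as TSV
#'
#' @param transfers A [transfer_sites()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transfer_tsv <- function(transfers, path) {
  readr::write_tsv(transfers, path)
  invisible(path)
}
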