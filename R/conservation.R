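#' Per-residue conservation profile of a query against its orthologs
#'
#' For every ungapped position of the reference row, computes the fraction
#' of non-reference rows carrying the identical residue in that alignment
#' column (`support`), and flags the position conserved when
#' `support >= min_fraction`. A gap in an ortholog counts as a mismatch: a
#' deletion is evidence against conservation. The default `min_fraction = 1`
#' is strict identity across all aligned species, the conservative reading
#' of "conserved among species"; relax it to accept majority conservation.
#'
#' @param msa An [new_msa()] alignment containing the reference row and at
#'   least one ortholog.
#' @param min_fraction Minimum identical-residue fraction in `(0, 1]` for a
#'   position to be flagged conserved.
#' @param equivalence Optional named list of residue groups (e.g.
#'   `list(c("S", "T"))`) treated as identical; off by default.
#' @return A tibble of class `conservation_profile` with columns `position`,
#'   `ref_residue`, `support`, `conserved`, one row per reference residue.
#' @examples
#' msa <- new_msa(c("q", "o1"), c("MKT", "MAT"))
#' conservation_profile(msa)
#' @export
conservation_profile <- function(msa, min_fraction = 1, equivalence = NULL) {
  stopifnot(inherits(msa, "msa"))
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    abort("min_fraction must be in (0, 1]", class = "ptmtalk_usage_error")
  }
  if (nrow(msa) < 2) {
    abort("conservation is undefined without ortholog rows",
          class = "ptmtalk_usage_error")
  }
  ref_id <- msa_ref(msa)
  ref_chars <- strsplit(msa_row(msa, ref_id), "")[[1]]
  other <- msa$aligned[msa$id != ref_id]
  other_chars <- do.call(rbind, strsplit(other, ""))

  cols <- which(ref_chars != "-")
  support <- vapply(cols, function(col) {
    ref_res <- ref_chars[col]
    hits <- other_chars[, col] == ref_res
    if (!is.null(equivalence)) {
      grp <- purrr::detect(equivalence, ~ ref_res %in% .x)
      if (!is.null(grp)) hits <- hits | other_chars[, col] %in% grp
    }
    mean(hits)
  }, numeric(1))

  out <- tibble(
    position = seq_along(cols),
    ref_residue = ref_chars[cols],
    support = support,
    conserved = support >= min_fraction
  )
  attr(out, "ref_id") <- ref_id
  attr(out, "min_fraction") <- min_fraction
  class(out) <- c("conservation_profile", class(out))
  out
}

#' Is a reference position conserved?
#'
#' @param profile A [conservation_profile()].
#' @param pos 1-based position(s) in the reference sequence.
#' @return Logical vector of conservation flags.
#' @export
is_conserved <- function(profile, pos) {
  stopifnot(inherits(profile, "conservation_profile"))
  if (any(pos < 1 | pos > nrow(profile))) {
    abort(paste0("position outside reference length ", nrow(profile)),
          class = "ptmtalk_position_error")
  }
  profile$conserved[pos]
}

#' Write a conservation profile as TSV
#'
#' @param profile A [conservation_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation_tsv <- function(profile, path) {
  readr::write_tsv(as_tibble(profile), path)
  invisible(path)
}
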