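#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly multi-record) protein FASTA file into a tibble with one
#' row per record. Sequences are upper-cased and internal whitespace is
#' removed, so files with wrapped or space-separated sequence lines normalise
#' to a single residue string. Residues outside the 20 standard amino acids
#' are handled as follows: the ambiguity/rare codes `B`, `Z`, `U` are mapped
#' to `X` with a warning; any other character is a format error reported with
#' its line number.
#'
#' @param path Path to a FASTA file.
#' @param allow_gaps Accept `-` characters (used by [read_alignment()] for
#'   aligned FASTA); plain sequence files should leave this `FALSE`.
#' @return A tibble with columns `id`, `description` and `sequence`
#'   (upper-case, 1-based residue addressing), in file order.
#' @seealso [write_fasta()], [read_alignment()]
#' @examples
#' fa <- system.file("extdata", "foxo3_synthetic.fasta", package = "ptmtalk")
#' read_fasta(fa)
#' @export
read_fasta <- function(path, allow_gaps = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "ptmtalk_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0) {
    abort(paste0("empty FASTA file: ", path), class = "ptmtalk_format_error")
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    abort(
      paste0("malformed FASTA (line ", nonblank[1],
             "): expected a '>' header before sequence data"),
      class = "ptmtalk_format_error"
    )
  }

  ids <- character()
  descs <- character()
  seqs <- character()
  chunks <- character()
  flush <- function() {
    if (length(ids) > 0) seqs[length(ids)] <<- paste(chunks, collapse = "")
    chunks <<- character()
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (trimws(line) == "") next
    if (startsWith(trimws(line), ">")) {
      flush()
      header <- sub("^\\s*>", "", trimws(line))
      if (header == "") {
        abort(paste0("malformed FASTA header (line ", i, "): empty id"),
              class = "ptmtalk_format_error")
      }
      ids <- c(ids, sub("\\s.*$", "", header))
      descs <- c(descs, sub("^\\S+\\s*", "", header))
      seqs <- c(seqs, "")
    } else {
      chunk <- toupper(gsub("\\s+", "", line))
      bad <- setdiff(strsplit(chunk, "")[[1]],
                     c(AA_STANDARD, "X", "B", "Z", "U",
                       if (allow_gaps) "-"))
      if (length(bad) > 0) {
        abort(
          paste0("illegal residue character '", bad[1], "' (line ", i, ")"),
          class = "ptmtalk_format_error"
        )
      }
      chunks <- c(chunks, chunk)
    }
  }
  flush()
  if (any(seqs == "")) {
    abort(paste0("record '", ids[seqs == ""][1], "' has an empty sequence"),
          class = "ptmtalk_format_error")
  }
  seqs <- normalize_residues(seqs)
  tibble(id = ids, description = descs, sequence = seqs)
}

# map the rare/ambiguity codes B, Z, U to X (warning), leave the rest alone
normalize_residues <- function(seqs) {
  if (any(grepl("[BZU]", seqs))) {
    warn("non-standard residues (B/Z/U) mapped to X")
    seqs <- gsub("[BZU]", "X", seqs)
  }
  seqs
}

#' Write protein records to a FASTA file
#'
#' @param records A tibble with columns `id`, `sequence` and optionally
#'   `description`, as returned by [read_fasta()].
#' @param path Output file path.
#' @param width Residues per sequence line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  header <- ifelse(desc == "", paste0(">", records$id),
                   paste0(">", records$id, " ", desc))
  out <- unlist(purrr::map2(header, records$sequence, function(h, s) {
    starts <- seq(1, nchar(s), by = width)
    c(h, substring(s, starts, pmin(starts + width - 1, nchar(s))))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Construct a multiple sequence alignment object
#'
#' An `msa` is a tibble with one row per aligned sequence (`id`, `aligned`)
#' plus a designated reference row (`ref_id`), typically the query protein
#' whose residue numbering all downstream coordinates use.
#'
#' @param ids Character vector of row ids.
#' @param aligned Character vector of equal-length gapped sequences
#'   (residues plus `-`).
#' @param ref_id Id of the reference (query) row; defaults to the first row.
#' @return A tibble of class `msa` with attribute `ref_id`.
#' @export
new_msa <- function(ids, aligned, ref_id = ids[1]) {
  if (length(ids) != length(aligned) || length(ids) == 0) {
    abort("ids and aligned sequences must be non-empty and equal length",
          class = "ptmtalk_usage_error")
  }
  if (anyDuplicated(ids)) {
    abort("duplicate row ids in alignment", class = "ptmtalk_alignment_error")
  }
  widths <- nchar(aligned)
  if (length(unique(widths)) != 1) {
    abort("ragged alignment: rows have unequal widths",
          class = "ptmtalk_alignment_error")
  }
  if (!ref_id %in% ids) {
    abort(paste0("ref_id '", ref_id, "' not among alignment rows"),
          class = "ptmtalk_usage_error")
  }
  aligned <- normalize_residues(toupper(aligned))
  bad <- grepl(paste0("[^-X", paste(AA_STANDARD, collapse = ""), "]"), aligned)
  if (any(bad)) {
    abort(paste0("row '", ids[bad][1], "' contains illegal characters"),
          class = "ptmtalk_format_error")
  }
  out <- tibble(id = ids, aligned = aligned)
  attr(out, "ref_id") <- ref_id
  class(out) <- c("msa", class(out))
  out
}

#' @export
print.msa <- function(x, ...) {
  cat("Multiple sequence alignment: ", nrow(x), " rows x ",
      nchar(x$aligned[1]), " columns (ref: ", msa_ref(x), ")\n", sep = "")
  NextMethod()
}

#' Reference row id of an alignment
#' @param msa An `msa` object.
#' @return The reference row id.
#' @export
msa_ref <- function(msa) attr(msa, "ref_id")

#' Read a multiple sequence alignment
#'
#' Reads CLUSTAL (`.aln`, including multi-block files) or aligned-FASTA
#' alignments. CLUSTAL parsing is delegated to
#' [Biostrings::readAAMultipleAlignment()].
#'
#' @param path Path to the alignment file.
#' @param dialect `"clustal"` or `"fasta"`.
#' @param ref_id Reference row id; defaults to the first row in the file.
#' @return An [new_msa()] object.
#' @export
read_alignment <- function(path, dialect = c("fasta", "clustal"),
                           ref_id = NULL) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) abort(
                        paste0("unknown alignment dialect: ", dialect[1]),
                        class = "ptmtalk_usage_error"))
  if (!file.exists(path)) {
    abort(paste0("alignment file not found: ", path),
          class = "ptmtalk_io_error")
  }
  if (dialect == "clustal") {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    gapped <- as.character(Biostrings::unmasked(aln))
    ids <- names(gapped)
    gapped <- unname(gapped)
  } else {
    recs <- read_fasta(path, allow_gaps = TRUE)
    ids <- recs$id
    gapped <- recs$sequence
    if (length(unique(nchar(gapped))) != 1) {
      abort("ragged alignment: rows have unequal widths",
            class = "ptmtalk_alignment_error")
    }
  }
  new_msa(ids, gapped, ref_id = if (is.null(ref_id)) ids[1] else ref_id)
}

msa_row <- function(msa, row_id) {
  i <- match(row_id, msa$id)
  if (is.na(i)) {
    abort(paste0("row '", row_id, "' not in alignment"),
          class = "ptmtalk_usage_error")
  }
  msa$aligned[i]
}

#' Strip gaps from an alignment row
#' @param msa An `msa` object.
#' @param row_id Row id (defaults to the reference row).
#' @return The ungapped sequence string.
#' @export
ungapped_sequence <- function(msa, row_id = msa_ref(msa)) {
  gsub("-", "", msa_row(msa, row_id), fixed = TRUE)
}

#' Map an ungapped residue position to its alignment column
#'
#' @param msa An `msa` object.
#' @param row_id Row whose coordinates `pos` uses.
#' @param pos 1-based ungapped position(s) in that row.
#' @return Integer vector of 1-based alignment columns.
#' @seealso [unmap_position()] for the inverse.
#' @export
map_position <- function(msa, row_id, pos) {
  chars <- strsplit(msa_row(msa, row_id), "")[[1]]
  residue_cols <- which(chars != "-")
  bad <- pos < 1 | pos > length(residue_cols) | pos != as.integer(pos)
  if (any(bad)) {
    abort(paste0("position ", pos[bad][1], " outside ungapped length ",
                 length(residue_cols), " of row '", row_id, "'"),
          class = "ptmtalk_position_error")
  }
  residue_cols[pos]
}

#' Map an alignment column back to an ungapped position
#'
#' @inheritParams map_position
#' @param column 1-based alignment column(s).
#' @return Integer vector of ungapped positions; `NA` where the row has a
#'   gap in that column.
#' @export
unmap_position <- function(msa, row_id, column) {
  chars <- strsplit(msa_row(msa, row_id), "")[[1]]
  if (any(column < 1 | column > length(chars))) {
    abort(paste0("column outside alignment width ", length(chars)),
          class = "ptmtalk_position_error")
  }
  ungapped_index <- cumsum(chars != "-")
  out <- ungapped_index[column]
  out[chars[column] == "-"] <- NA_integer_
  as.integer(out)
}

#' Extract the flanking window around a residue
#'
#' Returns up to `k` residues on each side of `pos`, truncated at the
#' termini, with the center residue marked (by default in square brackets),
#' e.g. `"NKYTKS[R]GRAAKK"`.
#'
#' @param record A one-row record tibble (from [read_fasta()]) or a plain
#'   sequence string.
#' @param pos 1-based center position(s).
#' @param k Window half-width (residues on each side).
#' @param marker Length-2 character vector wrapped around the center residue.
#' @return Character vector of marked flank strings.
#' @export
extract_flank <- function(record, pos, k = 6, marker = c("[", "]")) {
  seqstr <- as_sequence(record)
  n <- nchar(seqstr)
  if (any(pos < 1 | pos > n)) {
    abort(paste0("position ", pos[pos < 1 | pos > n][1],
                 " outside sequence of length ", n),
          class = "ptmtalk_position_error")
  }
  left <- substring(seqstr, pmax(1, pos - k), pos - 1)
  center <- substring(seqstr, pos, pos)
  right <- substring(seqstr, pos + 1, pmin(n, pos + k))
  paste0(left, marker[1], center, marker[2], right)
}

# accept a sequence string, a one-row records tibble, or an AAString-like
as_sequence <- function(x) {
  if (is.character(x) && length(x) == 1) {
    return(toupper(unname(x)))
  }
  if (is.data.frame(x)) {
    if (nrow(x) != 1 || !"sequence" %in% names(x)) {
      abort("expected a one-row record tibble with a 'sequence' column",
            class = "ptmtalk_usage_error")
    }
    return(toupper(x$sequence))
  }
  toupper(as.character(x))
}
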