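#' Construct a kinase recognition motif
#'
#' A kinase motif is a 15-position (center residue +/- 7) position weight
#' matrix over the 20 standard residues, together with the set of residues
#' the kinase can modify and, optionally, a background reservoir of window
#' scores used for percentile ranking. The window score of a candidate site
#' is the plain sum of the per-position weights of its residues; `X`
#' (terminal padding or unknowns) contributes 0 at every position.
#'
#' @param name Kinase label.
#' @param weights Numeric matrix, 15 rows (positions -7..+7) by 20 columns
#'   (named by residue). Row order is position order.
#' @param target_residues Subset of `c("S", "T", "Y")` the kinase targets.
#' @param background Optional numeric vector of reference window scores
#'   (see [motif_background()]).
#' @return A `kinase_motif` object.
#' @export
kinase_motif <- function(name, weights, target_residues = c("S", "T"),
                         background = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != 15) {
    abort("motif weights must have 15 rows (positions -7..+7)",
          class = "ptmtalk_usage_error")
  }
  if (!all(AA_STANDARD %in% colnames(weights))) {
    abort("motif weights must have one named column per standard residue",
          class = "ptmtalk_usage_error")
  }
  weights <- weights[, AA_STANDARD, drop = FALSE]
  if (anyNA(weights)) {
    abort("motif weight table has missing cells",
          class = "ptmtalk_usage_error")
  }
  if (!all(target_residues %in% c("S", "T", "Y"))) {
    abort("target_residues must be a subset of S, T, Y",
          class = "ptmtalk_usage_error")
  }
  center_on <- colnames(weights)[weights[8, ] != 0]
  if (!all(center_on %in% target_residues)) {
    abort("center-position weights must be nonzero only for target residues",
          class = "ptmtalk_usage_error")
  }
  rownames(weights) <- as.character(-7:7)
  structure(
    list(name = name, weights = weights,
         target_residues = target_residues, background = background),
    class = "kinase_motif"
  )
}

#' @export
print.kinase_motif <- function(x, ...) {
  cat("Kinase motif '", x$name, "' targeting ",
      paste(x$target_residues, collapse = "/"), "; background n = ",
      length(x$background), "\n", sep = "")
  invisible(x)
}

#' Score a 15-residue window against a motif
#'
#' @param motif A [kinase_motif()].
#' @param window A 15-character window centered on the candidate residue;
#'   pad termini with `X` (which scores 0 everywhere).
#' @return The window score (sum of per-position weights), or `NA` if the
#'   center residue is not targetable by this motif.
#' @export
score_window <- function(motif, window) {
  stopifnot(inherits(motif, "kinase_motif"))
  chars <- strsplit(toupper(window), "")[[1]]
  if (length(chars) != 15) {
    abort("window must be exactly 15 residues (pad termini with X)",
          class = "ptmtalk_usage_error")
  }
  if (!chars[8] %in% motif$target_residues) {
    return(NA_real_)
  }
  idx <- match(chars, colnames(motif$weights))  # X and gaps -> NA -> 0
  sum(motif$weights[cbind(seq_len(15), idx)], na.rm = TRUE)
}

# all 15-residue windows of a sequence whose center is in `centers`;
# returns tibble(position, residue, window)
sequence_windows <- function(seqstr, centers) {
  n <- nchar(seqstr)
  padded <- paste0(strrep("X", 7), seqstr, strrep("X", 7))
  chars <- strsplit(seqstr, "")[[1]]
  pos <- which(chars %in% centers)
  if (length(pos) == 0) {
    return(tibble(position = integer(), residue = character(),
                  window = character()))
  }
  tibble(
    position = pos,
    residue = chars[pos],
    window = substring(padded, pos, pos + 14)
  )
}

#' Build a background score reservoir for a motif
#'
#' Scores every targetable window of a reference sequence set with the
#' motif; the resulting score distribution is the empirical background that
#' [background_percentile()] ranks candidate sites against. Deterministic
#' given the reference set.
#'
#' @param motif A [kinase_motif()].
#' @param records Reference records tibble (e.g. from [read_fasta()]).
#' @return The motif with its `background` slot filled.
#' @export
motif_background <- function(motif, records) {
  stopifnot(inherits(motif, "kinase_motif"))
  scores <- unlist(purrr::map(records$sequence, function(s) {
    w <- sequence_windows(toupper(s), motif$target_residues)
    vapply(w$window, function(win) score_window(motif, win), numeric(1))
  }))
  if (length(scores) == 0) {
    abort("reference set contains no targetable windows",
          class = "ptmtalk_usage_error")
  }
  motif$background <- unname(scores)
  motif
}

#' Percentile rank of a score against a background reservoir
#'
#' Percentile is the fraction of background scores strictly better than the
#' candidate: 0 is the best attainable rank, 1 the worst, and ties resolve
#' in the candidate's favor.
#'
#' @param score Numeric score(s).
#' @param background Non-empty numeric vector of background scores.
#' @return Percentile(s) in `[0, 1]`.
#' @export
background_percentile <- function(score, background) {
  if (length(background) == 0) {
    abort("background reservoir is empty", class = "ptmtalk_usage_error")
  }
  vapply(score, function(s) mean(background > s), numeric(1))
}

#' Scan a protein for kinase motif hits
#'
#' Evaluates every position whose residue is targetable by each motif,
#' ranks the window score against the motif's background reservoir, and
#' emits a hit when the percentile is at or below `percentile_cutoff`
#' (lower percentile = better rank). Surface-accessibility values, when
#' supplied, are carried on the hits but do not gate them.
#'
#' @param record A one-row records tibble or sequence string.
#' @param motifs A [kinase_motif()] or list of them; each must carry a
#'   background reservoir (see [motif_background()]).
#' @param sa_values Optional numeric vector of per-position surface
#'   accessibility values (`NA` allowed), aligned to record positions.
#' @param percentile_cutoff Maximum percentile for a reported hit.
#' @return A tibble of hits (`kinase`, `position`, `residue`, `score`,
#'   `percentile`, `sa`), sorted by position then kinase.
#' @export
scan_protein <- function(record, motifs, sa_values = NULL,
                         percentile_cutoff = 0.05) {
  seqstr <- as_sequence(record)
  if (inherits(motifs, "kinase_motif")) motifs <- list(motifs)
  if (!is.null(sa_values) && length(sa_values) != nchar(seqstr)) {
    abort("sa_values must align to record positions",
          class = "ptmtalk_usage_error")
  }
  hits <- purrr::map_dfr(motifs, function(motif) {
    stopifnot(inherits(motif, "kinase_motif"))
    if (is.null(motif$background)) {
      abort(paste0("motif '", motif$name, "' has no background reservoir"),
            class = "ptmtalk_usage_error")
    }
    w <- sequence_windows(seqstr, motif$target_residues)
    if (nrow(w) == 0) return(tibble())
    score <- vapply(w$window, function(win) score_window(motif, win),
                    numeric(1), USE.NAMES = FALSE)
    pct <- background_percentile(score, motif$background)
    keep <- pct <= percentile_cutoff
    tibble(
      kinase = motif$name,
      position = w$position[keep],
      residue = w$residue[keep],
      score = score[keep],
      percentile = pct[keep],
      sa = if (is.null(sa_values)) NA_real_ else sa_values[w$position[keep]]
    )
  })
  if (nrow(hits) == 0) {
    return(tibble(kinase = character(), position = integer(),
                  residue = character(), score = numeric(),
                  percentile = numeric(), sa = numeric()))
  }
  dplyr::arrange(hits, .data$position, .data$kinase)
}

#' Read a kinase motif from TSV
#'
#' The format is metadata comment lines (`# name: <label>`,
#' `# targets: S,T`) followed by a tab-separated table of 15 rows
#' (positions -7..+7, first column `position`) by 20 residue columns.
#'
#' @param path Path to a motif TSV.
#' @return A [kinase_motif()].
#' @export
read_kinase_motif <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(hit) == 0) {
      abort(paste0("motif TSV missing '# ", key, ":' metadata"),
            class = "ptmtalk_format_error")
    }
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
  }
  tab <- readr::read_tsv(I(grep("^#", lines, invert = TRUE, value = TRUE)),
                         show_col_types = FALSE)
  weights <- as.matrix(tab[, setdiff(names(tab), "position")])
  kinase_motif(
    name = get_meta("name"),
    weights = weights,
    target_residues = strsplit(get_meta("targets"), "\\s*,\\s*")[[1]]
  )
}

#' Write a kinase motif to TSV
#'
#' @param motif A [kinase_motif()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinase_motif <- function(motif, path) {
  header <- c(paste0("# name: ", motif$name),
              paste0("# targets: ",
                     paste(motif$target_residues, collapse = ",")))
  tab <- cbind(tibble(position = -7:7), as_tibble(motif$weights))
  body <- c(paste(names(tab), collapse = "\t"),
            apply(tab, 1, paste, collapse = "\t"))
  writeLines(c(header, gsub(" ", "", body)), path)
  invisible(path)
}
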