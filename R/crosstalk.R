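#' Parameters of the crosstalk classifier
#'
#' Collects the tunable constants of the site classifier:
#'
#' * `phos_threshold`: phosphorylation potential at or above which a residue
#'   is phosphorylation-positive (the upstream predictor's published 0.5).
#' * `sa_min`: minimum surface-accessibility value for a residue to be
#'   considered solvent-exposed (0.5).
#' * `epsilon`: the "near threshold" margin on the potential scale. A
#'   channel is *near* when `threshold - epsilon <= potential < threshold`;
#'   this margin defines false-negative Yin Yang candidates.
#' * `min_fraction`: conservation support fraction passed through to
#'   [conservation_profile()].
#'
#' @param phos_threshold Phosphorylation threshold in `(0, 1)`.
#' @param sa_min Surface-accessibility cutoff.
#' @param epsilon Near-threshold margin, `>= 0`.
#' @param min_fraction Conservation fraction in `(0, 1]`.
#' @return A list of class `crosstalk_params`.
#' @export
crosstalk_params <- function(phos_threshold = 0.5, sa_min = 0.5,
                             epsilon = 0.1, min_fraction = 1) {
  if (epsilon < 0) abort("epsilon must be >= 0", class = "ptmtalk_usage_error")
  if (phos_threshold <= 0 || phos_threshold >= 1) {
    abort("phos_threshold must be in (0, 1)", class = "ptmtalk_usage_error")
  }
  structure(list(phos_threshold = phos_threshold, sa_min = sa_min,
                 epsilon = epsilon, min_fraction = min_fraction),
            class = "crosstalk_params")
}

#' Convert a numeric potential to a threshold category
#'
#' `above` when `potential >= threshold`; `near` when within `epsilon`
#' below the threshold; `below` otherwise.
#'
#' @param potential Numeric predictor potential(s).
#' @param threshold Decision threshold (recycled).
#' @param epsilon Near-threshold margin.
#' @return Character vector in `c("above", "near", "below")` (`NA` in,
#'   `NA` out).
#' @export
site_category <- function(potential, threshold, epsilon = 0.1) {
  dplyr::case_when(
    is.na(potential) ~ NA_character_,
    potential >= threshold ~ "above",
    potential >= threshold - epsilon ~ "near",
    TRUE ~ "below"
  )
}

#' Classify a site's phosphorylation / O-GlcNAc crosstalk status
#'
#' The core decision rule, applied per residue. With `P` = phosphorylation
#' channel above threshold, `G` = glycosylation channel above threshold and
#' `nearP`/`nearG` the near-threshold states:
#'
#' * `yy_positive` when `P` and `G` — a Yin Yang site, both modifications
#'   strongly predicted;
#' * `yy_false_negative` when the site is conserved and one channel is
#'   above while the other is near threshold — a crosstalk candidate the
#'   hard thresholds would miss;
#' * `phospho_only` / `glyc_only` when a single channel is above;
#' * `none` otherwise.
#'
#' Precedence is `yy_positive` over `yy_false_negative` over the
#' single-modification classes. Tyrosine sites have no glycosylation
#' channel (encode it `NA`), so only `phospho_only`/`none` are reachable.
#'
#' @param phos_cat,glyc_cat Channel categories (`"above"`, `"near"`,
#'   `"below"`; `glyc_cat` may be `NA` for Tyr). Vectors are recycled to
#'   common length.
#' @param conserved Logical conservation flag(s).
#' @return Character vector of classification labels.
#' @seealso [classify_sites()] for the data-frame interface,
#'   [site_category()] to derive categories from numeric potentials.
#' @examples
#' classify_site("above", "above", TRUE)   # yy_positive
#' classify_site("above", "near", TRUE)    # yy_false_negative
#' classify_site("above", "near", FALSE)   # phospho_only
#' @export
classify_site <- function(phos_cat, glyc_cat, conserved) {
  n <- max(length(phos_cat), length(glyc_cat), length(conserved))
  phos_cat <- rep_len(phos_cat, n)
  glyc_cat <- rep_len(glyc_cat, n)
  conserved <- rep_len(conserved, n)
  ok <- function(x) is.na(x) | x %in% c("above", "near", "below")
  if (!all(ok(phos_cat)) || !all(ok(glyc_cat))) {
    abort("channel categories must be 'above', 'near', 'below' or NA",
          class = "ptmtalk_validation_error")
  }
  if (any(is.na(phos_cat))) {
    abort("phosphorylation channel category is required for every site",
          class = "ptmtalk_validation_error")
  }
  p <- phos_cat == "above"
  near_p <- phos_cat == "near"
  g <- !is.na(glyc_cat) & glyc_cat == "above"
  near_g <- !is.na(glyc_cat) & glyc_cat == "near"
  dplyr::case_when(
    p & g ~ "yy_positive",
    conserved & ((p & near_g) | (g & near_p)) ~ "yy_false_negative",
    p ~ "phospho_only",
    g ~ "glyc_only",
    TRUE ~ "none"
  )
}

# derive/validate channel categories on a score table; numeric potentials
# take precedence over pre-encoded categories when both are present
resolve_categories <- function(scores, params) {
  out <- scores
  if ("phos_potential" %in% names(scores)) {
    thr <- if ("phos_threshold" %in% names(scores)) {
      dplyr::coalesce(scores$phos_threshold, params$phos_threshold)
    } else {
      params$phos_threshold
    }
    out$phos_cat <- site_category(scores$phos_potential, thr, params$epsilon)
  }
  if ("glyc_potential" %in% names(scores)) {
    thr <- if ("glyc_threshold" %in% names(scores)) {
      dplyr::coalesce(scores$glyc_threshold, params$phos_threshold)
    } else {
      params$phos_threshold
    }
    out$glyc_cat <- site_category(scores$glyc_potential, thr, params$epsilon)
  }
  if (!all(c("phos_cat", "glyc_cat") %in% names(out))) {
    abort(paste0("site scores need phos/glyc channels, either as numeric ",
                 "*_potential columns or categorical *_cat columns"),
          class = "ptmtalk_validation_error")
  }
  bad_tyr <- out$residue == "Y" & !is.na(out$glyc_cat)
  if (any(bad_tyr)) {
    abort("tyrosine sites cannot carry a glycosylation channel",
          class = "ptmtalk_validation_error")
  }
  out
}

#' Classify every site in a score table
#'
#' Data-frame interface to [classify_site()]: takes a per-residue score
#' table, derives channel categories from numeric potentials where needed,
#' and appends a `classification` column.
#'
#' @param scores Tibble with columns `position`, `residue`, a conservation
#'   flag `conserved`, and either categorical channels (`phos_cat`,
#'   `glyc_cat`) or numeric ones (`phos_potential`, `glyc_potential`, with
#'   optional per-site `*_threshold` columns).
#' @param params A [crosstalk_params()].
#' @return The input tibble with `phos_cat`, `glyc_cat` and
#'   `classification` columns.
#' @export
classify_sites <- function(scores, params = crosstalk_params()) {
  stopifnot(is.data.frame(scores),
            all(c("position", "residue", "conserved") %in% names(scores)))
  scores <- resolve_categories(scores, params)
  scores$classification <- classify_site(scores$phos_cat, scores$glyc_cat,
                                         scores$conserved)
  scores
}

#' Annotate classified sites with the selection filters
#'
#' Applies the three selection filters to every site: (i) experimental
#' support — is the site present in the curated database of experimentally
#' verified phosphosites; (ii) evolutionary conservation; (iii) structural
#' accessibility — surface accessibility at or above `sa_min`. Sites with
#' no SA value keep `accessible = NA` and remain positive predictions; a
#' site is `accepted` when it is conserved and not demonstrably buried.
#'
#' @param scores Site score table (see [classify_sites()]).
#' @param ev Experimental-annotation tibble with columns `position`,
#'   `residue` and optionally `kinases`, `source_tag`. An EV position whose
#'   residue letter disagrees with the score table is a fixture error and
#'   aborts.
#' @param params A [crosstalk_params()].
#' @param conservation Optional [conservation_profile()]; when supplied it
#'   overrides/creates the `conserved` column of `scores`.
#' @return A tibble of class `yy_annotation`: the classified score table
#'   plus `ev_support`, `accessible`, `accepted` and a `kinases` list
#'   column.
#' @export
annotate_sites <- function(scores, ev = NULL, params = crosstalk_params(),
                           conservation = NULL) {
  if (!is.null(conservation)) {
    scores$conserved <- is_conserved(conservation, scores$position)
  }
  ann <- classify_sites(scores, params)
  if (anyDuplicated(ann$position)) {
    abort("duplicate site positions in score table",
          class = "ptmtalk_validation_error")
  }
  if (is.null(ev)) {
    ev <- tibble(position = integer(), residue = character())
  }
  mism <- dplyr::inner_join(
    ann[, c("position", "residue")],
    ev[, c("position", "residue")],
    by = "position", suffix = c("", "_ev")
  )
  bad <- mism$residue != mism$residue_ev
  if (any(bad)) {
    abort(paste0("EV table residue mismatch at position ",
                 mism$position[bad][1], ": score table has ",
                 mism$residue[bad][1], ", EV table has ",
                 mism$residue_ev[bad][1]),
          class = "ptmtalk_validation_error")
  }
  ann$ev_support <- ann$position %in% ev$position
  sa <- if ("sa" %in% names(ann)) ann$sa else rep(NA_real_, nrow(ann))
  ann$accessible <- ifelse(is.na(sa), NA, sa >= params$sa_min)
  ann$accepted <- ann$conserved & (is.na(ann$accessible) | ann$accessible)
  if ("kinases" %in% names(ann) && !is.list(ann$kinases)) {
    ann$kinases <- split_kinases(ann$kinases)
  }
  attr(ann, "params") <- params
  class(ann) <- unique(c("yy_annotation", class(ann)))
  ann
}

split_kinases <- function(x) {
  purrr::map(x, function(k) {
    if (is.na(k) || trimws(k) == "") character() else
      trimws(strsplit(k, ";", fixed = TRUE)[[1]])
  })
}

#' Count classifications by residue type
#'
#' @param annotations A [annotate_sites()] result (or any tibble with
#'   `position`, `residue` and `classification`).
#' @return A tibble `residue` x `classification` x `n` over the full grid
#'   of observed residue types and all classification labels.
#' @export
summarize_classifications <- function(annotations) {
  stopifnot(all(c("position", "residue", "classification")
                %in% names(annotations)))
  if (anyDuplicated(annotations$position)) {
    abort("duplicate site positions", class = "ptmtalk_validation_error")
  }
  annotations |>
    dplyr::count(.data$residue, .data$classification) |>
    tidyr::complete(
      residue = unique(annotations$residue),
      classification = YY_CLASSES,
      fill = list(n = 0L)
    ) |>
    dplyr::mutate(
      classification = factor(.data$classification, levels = YY_CLASSES)
    ) |>
    dplyr::arrange(.data$residue, .data$classification)
}

#' Cross-tabulate kinase assignments against annotated sites
#'
#' @param annotations A [annotate_sites()] result carrying a `kinases`
#'   list column, or any annotation tibble when `assignments` is given.
#' @param assignments Optional tibble (`kinase`, `position`) of external
#'   kinase assignments (e.g. scanner hits); assignments at positions
#'   absent from `annotations` are dropped with a warning.
#' @return A tibble with one row per kinase: `kinase`, `n_sites`,
#'   `positions` (list column, sorted), `max_sa_position`, `max_sa`.
#' @export
kinase_crosstab <- function(annotations, assignments = NULL) {
  if (is.null(assignments)) {
    stopifnot("kinases" %in% names(annotations))
    assignments <- annotations |>
      dplyr::select("position", "kinases") |>
      tidyr::unnest_longer("kinases", values_to = "kinase") |>
      dplyr::filter(!is.na(.data$kinase))
  } else {
    missing <- setdiff(assignments$position, annotations$position)
    if (length(missing) > 0) {
      warn(paste0("dropping kinase assignments at non-site positions: ",
                  paste(sort(missing), collapse = ", ")))
      assignments <- assignments[!assignments$position %in% missing, ]
    }
  }
  sa_col <- if ("sa" %in% names(annotations)) annotations$sa else NA_real_
  site_info <- tibble(position = annotations$position,
                      residue = annotations$residue, sa = sa_col)
  assignments |>
    dplyr::inner_join(site_info, by = "position") |>
    dplyr::group_by(.data$kinase) |>
    dplyr::arrange(.data$position, .by_group = TRUE) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      positions = list(.data$position),
      max_sa_position = if (all(is.na(.data$sa))) NA_integer_ else
        .data$position[which.max(.data$sa)],
      max_sa = if (all(is.na(.data$sa))) NA_real_ else
        max(.data$sa, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$kinase)
}

#' Read a per-residue site score table
#'
#' @param path TSV with columns `position`, `residue`, channel columns
#'   (categorical `phos_cat`/`glyc_cat` or numeric potentials), and
#'   optionally `sa`, `conserved`, `kinases`.
#' @return A tibble, `kinases` kept as `;`-separated strings.
#' @export
read_site_scores <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA"),
                  col_types = readr::cols(
                    position = readr::col_integer(),
                    residue = readr::col_character()
                  ))
}

#' Read an experimentally-verified-site table
#'
#' @param path TSV with columns `position`, `residue`, `kinases`,
#'   `source_tag`.
#' @return A tibble.
#' @export
read_ev_sites <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA"),
                  col_types = readr::cols(
                    position = readr::col_integer(),
                    residue = readr::col_character(),
                    .default = readr::col_character()
                  ))
}
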