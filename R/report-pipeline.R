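#' Read a protein domain map
#'
#' @param path TSV with columns `name`, `start`, `end` (1-based inclusive
#'   intervals; overlaps permitted, repeated names allowed for
#'   discontinuous features such as a split NLS).
#' @return A tibble domain map.
#' @export
read_domains <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    name = readr::col_character(),
                    start = readr::col_integer(),
                    end = readr::col_integer()
                  ))
}

#' Which domains contain a position?
#'
#' @param pos 1-based residue position(s).
#' @param domains Domain map tibble (`name`, `start`, `end`).
#' @param protein_length Optional length used to range-check `pos`.
#' @return A tibble (`position`, `domain`) with one row per containing
#'   interval, in map order; positions inside no interval are absent.
#' @examples
#' dom <- foxo3_domains()
#' assign_domains(250, dom)  # DBD and NLS overlap here
#' @export
assign_domains <- function(pos, domains, protein_length = NULL) {
  stopifnot(all(c("name", "start", "end") %in% names(domains)))
  if (any(domains$start < 1 | domains$start > domains$end)) {
    abort("invalid domain interval", class = "ptmtalk_validation_error")
  }
  limit <- if (is.null(protein_length)) max(domains$end) else protein_length
  if (any(pos < 1 | pos > limit)) {
    abort(paste0("position outside protein length ", limit),
          class = "ptmtalk_position_error")
  }
  purrr::map_dfr(pos, function(p) {
    hit <- domains$start <= p & p <= domains$end
    tibble(position = as.integer(p), domain = domains$name[hit])
  })
}

#' Cross-modification neighbor pairs
#'
#' Pairs every methylation site with every phosphorylation site within
#' `radius` residues — the proximity pattern behind steric-masking
#' crosstalk, where methylation of an Arg/Lys can block phosphorylation of
#' a nearby Ser/Thr. Each cross pair is reported once, sorted by the
#' smaller position then distance.
#'
#' @param phospho_sites,methyl_sites Integer vectors of 1-based positions.
#' @param radius Maximum residue separation (`>= 0`).
#' @return A tibble (`methyl_pos`, `phospho_pos`, `distance`).
#' @examples
#' neighbor_crosstalk(c(253), c(248, 250), radius = 5)
#' @export
neighbor_crosstalk <- function(phospho_sites, methyl_sites, radius = 5) {
  if (radius < 0) abort("radius must be >= 0", class = "ptmtalk_usage_error")
  pairs <- tidyr::expand_grid(methyl_pos = as.integer(methyl_sites),
                              phospho_pos = as.integer(phospho_sites)) |>
    dplyr::mutate(distance = abs(.data$methyl_pos - .data$phospho_pos)) |>
    dplyr::filter(.data$distance <= radius,
                  .data$methyl_pos != .data$phospho_pos) |>
    dplyr::distinct()
  pairs |>
    dplyr::arrange(pmin(.data$methyl_pos, .data$phospho_pos),
                   .data$distance)
}

#' Write the report bundle for an annotated protein
#'
#' Writes `site_table.tsv` (per-residue annotations), `methyl_table.tsv`
#' (consensus methylation sites, with flanking windows when a sequence is
#' supplied), `neighbors.tsv` (cross-modification pairs) and
#' `summary.json` (all counts; schema_version 1). Re-reading
#' `site_table.tsv` with [read_site_annotations()] reproduces the
#' annotation set.
#'
#' @param annotations A [annotate_sites()] result.
#' @param methyl A [consensus_calls()] result (or `NULL`).
#' @param domains Domain map tibble (or `NULL`).
#' @param out_dir Output directory, created if missing.
#' @param record Optional record/sequence for flank extraction.
#' @param neighbor_radius Radius for [neighbor_crosstalk()].
#' @return Named character vector of the files written, invisibly.
#' @export
write_reports <- function(annotations, methyl = NULL, domains = NULL,
                          out_dir, record = NULL, neighbor_radius = 5) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    abort(paste0("cannot create output directory: ", out_dir),
          class = "ptmtalk_io_error")
  }
  files <- c(site_table = file.path(out_dir, "site_table.tsv"),
             methyl_table = file.path(out_dir, "methyl_table.tsv"),
             neighbors = file.path(out_dir, "neighbors.tsv"),
             summary = file.path(out_dir, "summary.json"))

  flat <- as_tibble(annotations)
  if (is.list(flat[["kinases"]])) {
    flat$kinases <- purrr::map_chr(flat$kinases, paste, collapse = ";")
  }
  readr::write_tsv(flat, files["site_table"], na = "NA")

  if (is.null(methyl)) {
    methyl <- tibble(position = integer(), residue = character(),
                     n_predictors = integer(), predictors = character())
  }
  methyl_out <- methyl
  if (!is.null(record) && nrow(methyl) > 0) {
    methyl_out$flank <- extract_flank(record, methyl$position, k = 6)
    if (!is.null(domains)) {
      methyl_out$domains <- purrr::map_chr(
        methyl$position,
        ~ paste(assign_domains(.x, domains)$domain, collapse = ";"))
    }
  }
  readr::write_tsv(methyl_out, files["methyl_table"], na = "NA")

  phospho_pos <- flat$position[flat$phos_cat == "above"]
  neigh <- neighbor_crosstalk(phospho_pos, methyl$position,
                              radius = neighbor_radius)
  readr::write_tsv(neigh, files["neighbors"], na = "NA")

  counts <- summarize_classifications(annotations)
  summary <- list(
    schema_version = 1L,
    n_sites = nrow(flat),
    phospho_predicted = class_channel_counts(flat, "phos_cat"),
    glyc_predicted = class_channel_counts(flat, "glyc_cat"),
    classifications = stats::setNames(
      as.list(vapply(YY_CLASSES, function(cl) {
        sum(counts$n[counts$classification == cl])
      }, integer(1))), YY_CLASSES),
    false_negative_positions = sort(
      flat$position[flat$classification == "yy_false_negative"]),
    ev_supported = sum(flat$ev_support),
    methylation_consensus = list(
      total = nrow(methyl),
      by_residue = as.list(table(methyl$residue))
    ),
    neighbor_pairs = nrow(neigh)
  )
  jsonlite::write_json(summary, files["summary"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(files)
}

# per-residue-type counts of channel == "above"
class_channel_counts <- function(flat, channel) {
  above <- flat[!is.na(flat[[channel]]) & flat[[channel]] == "above", ]
  c(list(total = nrow(above)), as.list(table(above$residue)))
}

#' Re-read a written site table as an annotation set
#'
#' Inverse of the `site_table.tsv` written by [write_reports()].
#'
#' @param path Path to a written site table.
#' @return A `yy_annotation` tibble.
#' @export
read_site_annotations <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, na = "NA",
                         col_types = readr::cols(
                           position = readr::col_integer(),
                           residue = readr::col_character(),
                           phos_cat = readr::col_character(),
                           glyc_cat = readr::col_character(),
                           conserved = readr::col_logical()
                         ))
  if ("kinases" %in% names(ann)) {
    ann$kinases <- split_kinases(dplyr::coalesce(ann$kinases, ""))
  }
  class(ann) <- unique(c("yy_annotation", class(ann)))
  ann
}

#' Run the full crosstalk pipeline from a configuration
#'
#' Executes conservation inference, site classification, selection
#' filtering, consensus methylation calling, optional homology transfer,
#' neighbor-crosstalk annotation and report writing, end to end. The
#' configuration is a named list or a YAML file with keys:
#'
#' * `fasta` — query protein FASTA (required)
#' * `site_scores` — per-residue score TSV (required)
#' * `ev_sites` — experimentally-verified-site TSV (optional)
#' * `alignment`, `alignment_dialect` — ortholog alignment; when given,
#'   conservation is computed from it, otherwise the score table's
#'   `conserved` column is used
#' * `methyl_calls`, `min_agree` — methylation call sets and consensus rule
#' * `transfer_fasta`, `transfer_sites` — homolog FASTA and its known
#'   site positions for homology transfer
#' * `domains` — domain map TSV
#' * `out_dir` — report directory (required)
#' * `params` — sub-list passed to [crosstalk_params()]
#' * `neighbor_radius` — see [neighbor_crosstalk()]
#'
#' Deterministic given the configuration: running twice writes
#' byte-identical reports.
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, a list with `annotations`, `summary_counts`,
#'   `methyl`, `transfers`, `neighbors` and `files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(paste0("config file not found: ", config),
            class = "ptmtalk_io_error")
    }
    config <- yaml::read_yaml(config)
  }
  known <- c("fasta", "site_scores", "ev_sites", "alignment",
             "alignment_dialect", "methyl_calls", "min_agree",
             "transfer_fasta", "transfer_sites", "domains", "out_dir",
             "params", "neighbor_radius")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort(paste0("invalid config key(s): ", paste(unknown, collapse = ", ")),
          class = "ptmtalk_usage_error")
  }
  need <- function(key) {
    if (is.null(config[[key]])) {
      abort(paste0("config key '", key, "' is required"),
            class = "ptmtalk_usage_error")
    }
    config[[key]]
  }
  check_file <- function(path) {
    if (!file.exists(path)) {
      abort(paste0("missing input file: ", path),
            class = "ptmtalk_io_error")
    }
    path
  }
  params <- do.call(crosstalk_params, as.list(config$params))

  record <- read_fasta(check_file(need("fasta")))[1, ]
  scores <- read_site_scores(check_file(need("site_scores")))
  ev <- if (!is.null(config$ev_sites)) {
    read_ev_sites(check_file(config$ev_sites))
  }
  conservation <- if (!is.null(config$alignment)) {
    msa <- read_alignment(check_file(config$alignment),
                          dialect = config$alignment_dialect %||% "fasta",
                          ref_id = record$id)
    conservation_profile(msa, min_fraction = params$min_fraction)
  }
  annotations <- annotate_sites(scores, ev = ev, params = params,
                                conservation = conservation)

  methyl <- NULL
  if (!is.null(config$methyl_calls)) {
    calls <- read_methylation_calls(check_file(config$methyl_calls))
    methyl <- consensus_calls(calls, min_agree = config$min_agree %||% 2,
                              record = record)
  }
  transfers <- NULL
  if (!is.null(config$transfer_fasta)) {
    src <- read_fasta(check_file(config$transfer_fasta))[1, ]
    transfers <- transfer_sites(src, record,
                                as.integer(need("transfer_sites")))
  }
  domains <- if (!is.null(config$domains)) {
    read_domains(check_file(config$domains))
  }

  files <- write_reports(
    annotations, methyl = methyl, domains = domains,
    out_dir = need("out_dir"), record = record,
    neighbor_radius = config$neighbor_radius %||% 5
  )
  if (!is.null(transfers)) {
    transfer_path <- file.path(config$out_dir, "transfers.tsv")
    write_transfer_tsv(transfers, transfer_path)
    files <- c(files, transfers = transfer_path)
  }
  neighbors <- readr::read_tsv(files[["neighbors"]], show_col_types = FALSE)
  invisible(list(
    annotations = annotations,
    summary_counts = summarize_classifications(annotations),
    methyl = methyl,
    transfers = transfers,
    neighbors = neighbors,
    files = files
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Packaged FoxO3 pipeline configuration
#'
#' Configuration pointing at the packaged FoxO3 fixtures (curated score
#' and EV tables, synthetic stand-in sequences, constructed methylation
#' call sets, domain map), ready for [run_pipeline()].
#'
#' @param out_dir Report output directory.
#' @return A configuration list.
#' @export
foxo3_config <- function(out_dir = tempfile("foxo3_reports")) {
  ext <- function(f) system.file("extdata", f, package = "ptmtalk")
  list(
    fasta = ext("foxo3_synthetic.fasta"),
    site_scores = ext("foxo3_site_scores.tsv"),
    ev_sites = ext("foxo3_ev_sites.tsv"),
    alignment = ext("foxo3_orthologs_synthetic.afa"),
    alignment_dialect = "fasta",
    methyl_calls = ext("foxo3_methylation_calls.tsv"),
    min_agree = 2,
    transfer_fasta = ext("foxo1_synthetic.fasta"),
    transfer_sites = c(248L, 250L),
    domains = ext("foxo3_domains.tsv"),
    out_dir = out_dir
  )
}
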