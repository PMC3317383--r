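#' Generate a random protein record
#'
#' Residues are drawn i.i.d. from `composition`; deterministic for a given
#' seed (all generators in this module are pure functions of their
#' parameters and seed).
#'
#' @param length Sequence length (`>= 1`).
#' @param composition Named numeric vector of residue frequencies over the
#'   20 standard residues, summing to 1; defaults to uniform. Residues may
#'   be omitted (frequency 0).
#' @param seed Integer RNG seed.
#' @param id Record id.
#' @return A one-row records tibble (`id`, `description`, `sequence`).
#' @export
gen_protein <- function(length, composition = NULL, seed = 1,
                        id = "synthetic") {
  if (length < 1) abort("length must be >= 1", class = "ptmtalk_usage_error")
  if (is.null(composition)) {
    composition <- stats::setNames(rep(1 / 20, 20), AA_STANDARD)
  }
  if (is.null(names(composition)) ||
      !all(names(composition) %in% AA_STANDARD) ||
      any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-8) {
    abort("composition must be named over standard residues and sum to 1",
          class = "ptmtalk_usage_error")
  }
  seqstr <- withr::with_seed(seed, {
    paste(sample(names(composition), length, replace = TRUE,
                 prob = composition), collapse = "")
  })
  tibble(id = id, description = "synthetic random protein",
         sequence = seqstr)
}

#' Generate noisy synthetic orthologs of a protein
#'
#' Each of `n` orthologs substitutes each position independently with
#' probability `sub_rate` (always to a different residue); there are no
#' indels, so ortholog coordinates equal query coordinates and the true
#' set of disturbed positions is returned alongside the alignment. At
#' `min_fraction = 1`, [conservation_profile()] flags exactly the
#' complement of that truth set.
#'
#' @param record One-row records tibble or sequence string.
#' @param n Number of orthologs (`>= 1`).
#' @param sub_rate Per-position substitution probability in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @return A list: `msa` (query + orthologs, query as reference) and
#'   `mutated_positions` (sorted union of substituted positions).
#' @export
gen_orthologs <- function(record, n, sub_rate, seed = 1) {
  if (n < 1) abort("n must be >= 1", class = "ptmtalk_usage_error")
  if (sub_rate < 0 || sub_rate > 1) {
    abort("sub_rate must be in [0, 1]", class = "ptmtalk_usage_error")
  }
  seqstr <- as_sequence(record)
  chars <- strsplit(seqstr, "")[[1]]
  ref_id <- if (is.data.frame(record)) record$id else "query"
  res <- withr::with_seed(seed, {
    mutated <- integer()
    orths <- vapply(seq_len(n), function(i) {
      hit <- which(runif(length(chars)) < sub_rate)
      mutated <<- union(mutated, hit)
      out <- chars
      for (p in hit) out[p] <- sample(setdiff(AA_STANDARD, chars[p]), 1)
      paste(out, collapse = "")
    }, character(1))
    list(orths = orths, mutated = sort(mutated))
  })
  list(
    msa = new_msa(c(ref_id, paste0("ortholog_", seq_len(n))),
                  c(seqstr, res$orths), ref_id = ref_id),
    mutated_positions = res$mutated
  )
}

#' Generate a site score table with planted classifications
#'
#' Plants the requested number of sites of each crosstalk class on the
#' protein's Ser/Thr positions and draws numeric potentials uniformly
#' within class-consistent intervals kept at least `epsilon/2` away from
#' every decision boundary, so [classify_sites()] recovers the planted
#' labels exactly (no floating-point ties possible). False-negative
#' plants are marked conserved (the class requires it); all other planted
#' sites are conserved at random. SA values are drawn uniformly on
#' `[0, 3]`.
#'
#' @param record One-row records tibble or sequence string.
#' @param planted Named integer vector of class counts, names among
#'   `c("yy_positive", "yy_false_negative", "phospho_only", "glyc_only",
#'   "none")`.
#' @param params A [crosstalk_params()]; `epsilon` must be positive when
#'   false negatives are planted.
#' @param seed Integer RNG seed.
#' @return A list: `scores` (tibble ready for [classify_sites()]) and
#'   `truth` (tibble `position`, `classification`).
#' @export
gen_site_scores <- function(record, planted, params = crosstalk_params(),
                            seed = 1) {
  stopifnot(!is.null(names(planted)),
            all(names(planted) %in% YY_CLASSES))
  planted <- planted[planted > 0]
  if ("yy_false_negative" %in% names(planted) && params$epsilon <= 0) {
    abort("epsilon must be > 0 to plant false-negative sites",
          class = "ptmtalk_usage_error")
  }
  seqstr <- as_sequence(record)
  chars <- strsplit(seqstr, "")[[1]]
  eligible <- which(chars %in% c("S", "T"))
  if (sum(planted) > length(eligible)) {
    abort(paste0("cannot plant ", sum(planted), " sites on ",
                 length(eligible), " eligible Ser/Thr positions"),
          class = "ptmtalk_usage_error")
  }
  thr <- params$phos_threshold
  eps <- params$epsilon
  margin <- eps / 2
  draw <- list(
    above = function(n) runif(n, thr + margin, 1),
    near = function(n) runif(n, thr - eps + eps / 4, thr - eps / 4),
    below = function(n) runif(n, 0, max(thr - eps - margin, 1e-3))
  )
  channel_spec <- list(
    yy_positive = c("above", "above"),
    yy_false_negative = c("above", "near"),
    phospho_only = c("above", "below"),
    glyc_only = c("below", "above"),
    none = c("below", "below")
  )
  withr::with_seed(seed, {
    pos <- sample(eligible, sum(planted))
    labels <- rep(names(planted), planted)
    phos <- numeric(length(pos))
    glyc <- numeric(length(pos))
    for (cl in unique(labels)) {
      i <- labels == cl
      spec <- channel_spec[[cl]]
      phos[i] <- draw[[spec[1]]](sum(i))
      glyc[i] <- draw[[spec[2]]](sum(i))
    }
    # half the FN plants get the mirrored channel pattern (glyc above,
    # phospho near) so both arms of the rule are exercised
    fn <- which(labels == "yy_false_negative")
    flip <- fn[seq_along(fn) %% 2 == 0]
    tmp <- phos[flip]; phos[flip] <- glyc[flip]; glyc[flip] <- tmp
    conserved <- runif(length(pos)) < 0.5
    conserved[labels == "yy_false_negative"] <- TRUE
    ord <- order(pos)
    scores <- tibble(
      position = as.integer(pos[ord]),
      residue = chars[pos[ord]],
      phos_potential = phos[ord],
      glyc_potential = glyc[ord],
      sa = runif(length(pos), 0, 3),
      conserved = conserved[ord]
    )
    list(scores = scores,
         truth = tibble(position = as.integer(pos[ord]),
                        classification = labels[ord]))
  })
}

#' Generate noisy multi-predictor methylation call sets
#'
#' Each predictor includes each true site independently with probability
#' `sensitivity` and each other eligible position with probability `fpr`.
#'
#' @param true_sites Integer vector of true site positions.
#' @param n_predictors Number of predictors.
#' @param sensitivity Per-predictor true-site recall in `[0, 1]`.
#' @param fpr Per-predictor false-positive rate on non-sites in `[0, 1]`.
#' @param eligible_positions All positions a predictor may call
#'   (superset of `true_sites`).
#' @param seed Integer RNG seed.
#' @param residues Optional named residue lookup (names = positions);
#'   defaults to `"K"` everywhere.
#' @return A call tibble (`predictor`, `position`, `residue`) suitable
#'   for [consensus_calls()].
#' @export
gen_callsets <- function(true_sites, n_predictors, sensitivity, fpr,
                         eligible_positions, seed = 1, residues = NULL) {
  if (sensitivity < 0 || sensitivity > 1 || fpr < 0 || fpr > 1) {
    abort("sensitivity and fpr must be in [0, 1]",
          class = "ptmtalk_usage_error")
  }
  stopifnot(all(true_sites %in% eligible_positions))
  lookup <- function(pos) {
    if (is.null(residues)) rep("K", length(pos)) else
      unname(residues[as.character(pos)])
  }
  non_sites <- setdiff(eligible_positions, true_sites)
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_predictors), function(i) {
      called <- c(true_sites[runif(length(true_sites)) < sensitivity],
                  non_sites[runif(length(non_sites)) < fpr])
      called <- sort(called)
      tibble(predictor = paste0("predictor_", i),
             position = as.integer(called),
             residue = lookup(called))
    })
  })
}
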