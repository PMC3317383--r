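#' Tidy an annotated site set
#'
#' @param x A `yy_annotation` tibble (see [annotate_sites()]).
#' @param ... Unused.
#' @return A plain tibble with one row per site and the kinase list
#'   flattened to a `;`-separated string.
#' @method tidy yy_annotation
#' @export
tidy.yy_annotation <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "yy_annotation")
  attr(out, "params") <- NULL
  if (is.list(out[["kinases"]])) {
    out$kinases <- purrr::map_chr(out$kinases, paste, collapse = ";")
  }
  out
}

#' One-row summary of an annotated site set
#'
#' @param x A `yy_annotation` tibble.
#' @param ... Unused.
#' @return A one-row tibble: site totals, per-channel positive counts,
#'   classification counts and filter tallies.
#' @method glance yy_annotation
#' @export
glance.yy_annotation <- function(x, ...) {
  counts <- summarize_classifications(x)
  n_class <- function(cl) sum(counts$n[counts$classification == cl])
  tibble(
    n_sites = nrow(x),
    n_phospho_pred = sum(x$phos_cat == "above", na.rm = TRUE),
    n_glyc_pred = sum(!is.na(x$glyc_cat) & x$glyc_cat == "above"),
    n_yy_positive = n_class("yy_positive"),
    n_yy_false_negative = n_class("yy_false_negative"),
    n_phospho_only = n_class("phospho_only"),
    n_glyc_only = n_class("glyc_only"),
    n_none = n_class("none"),
    n_ev_supported = sum(x$ev_support),
    n_conserved = sum(x$conserved),
    n_accessible = sum(x$accessible, na.rm = TRUE),
    n_accepted = sum(x$accepted)
  )
}
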