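#' Tidy a GO-term selection
#'
#' @param x A `go_selection` from [select_best_terms()].
#' @param ... Unused.
#' @return One row per term with its status (`bestN`, `bestF`, `redundant`,
#'   `screened`), residues, fold change, HGT and parent link.
#' @method tidy go_selection
#' @export
tidy.go_selection <- function(x, ...) {
  x$terms
}

#' One-row summary of a GO-term selection
#'
#' @inheritParams tidy.go_selection
#' @return A one-row tibble: counts per stage and the bias-protein coverage
#'   achieved by the BestN + BestF set.
#' @method glance go_selection
#' @export
glance.go_selection <- function(x, ...) {
  tibble::tibble(
    domain = x$domain %||% NA_character_,
    n_screened = dplyr::n_distinct(x$entries$term_id[x$entries$status != "removed_low_bias"]),
    n_removed_low_bias = dplyr::n_distinct(
      x$entries$term_id[x$entries$status == "removed_low_bias"]),
    n_bestN = sum(x$terms$status == "bestN"),
    n_bestF = sum(x$terms$status == "bestF"),
    coverage = x$coverage
  )
}

#' Tidy a threshold sweep
#'
#' @param x A `nterm_sweep` from [threshold_sweep()].
#' @param ... Unused.
#' @return The per-threshold, per-class tibble.
#' @method tidy nterm_sweep
#' @export
tidy.nterm_sweep <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row-per-class summary of a threshold sweep
#'
#' @inheritParams tidy.nterm_sweep
#' @return For each class: the threshold maximising its HGT score, the peak
#'   score and the peak proportion.
#' @method glance nterm_sweep
#' @export
glance.nterm_sweep <- function(x, ...) {
  x |>
    dplyr::filter(!is.na(.data$hgt)) |>
    dplyr::group_by(.data$class) |>
    dplyr::slice_max(.data$hgt, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("class", peak_threshold = "threshold", peak_hgt = "hgt",
                  peak_proportion = "proportion")
}
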