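#' Read GO annotations from a GAF 2.x file
#'
#' Parses the 17-column tab-separated Gene Association File format. Comment
#' lines starting with `!` are skipped, rows with a `NOT` qualifier are
#' dropped (they assert the absence of an association), duplicate
#' (term, protein) pairs are collapsed, and annotations naming proteins
#' absent from the companion proteome are dropped with a warning count.
#' No propagation to ancestor terms is performed.
#'
#' @param path Path to an (uncompressed) GAF 2.x file.
#' @param proteome Optional `nterm_proteome`; annotations are restricted to
#'   its accessions when given.
#' @return A tibble of class `nterm_go` with columns `domain` (one of
#'   `"component"`, `"process"`, `"function"`), `term_id`, `term_name`
#'   (`NA` — GAF carries no term names) and `accession`; one row per
#'   (term, protein) association.
#' @export
read_gaf <- function(path, proteome = NULL) {
  raw <- readr::read_tsv(path, comment = "!", col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) abort(paste0("no annotation rows in ", path))
  if (ncol(raw) < 15) {
    abort(sprintf("malformed GAF: expected >= 15 tab-separated columns, got %d (first data line)",
                  ncol(raw)))
  }
  aspect_map <- c(C = "component", P = "process", F = "function")
  out <- tibble::tibble(
    accession = raw[[2]],
    qualifier = raw[[4]] %||% "",
    term_id   = raw[[5]],
    aspect    = raw[[9]]
  ) |>
    dplyr::filter(!stringr::str_detect(tidyr::replace_na(.data$qualifier, ""),
                                       "(^|\\|)NOT($|\\|)")) |>
    dplyr::filter(.data$aspect %in% names(aspect_map)) |>
    dplyr::transmute(domain = aspect_map[.data$aspect],
                     term_id = .data$term_id,
                     term_name = NA_character_,
                     accession = .data$accession) |>
    dplyr::distinct()
  if (!is.null(proteome)) {
    known <- out$accession %in% proteome$accession
    if (any(!known)) {
      warn(sprintf("dropping %d annotation(s) naming accessions absent from the proteome",
                   sum(!known)))
      out <- out[known, ]
    }
  }
  if (nrow(out) == 0) abort("no usable annotation rows after filtering")
  structure(out, class = c("nterm_go", class(out)))
}

#' Read a curated mitochondrial annotation table
#'
#' Reads a TSV with columns `accession`, `is_mito`, `has_mts` and optionally
#' `compartment`, describing which proteins are curated mitochondrial and
#' which of those carry an N-terminal mitochondrial targeting sequence (MTS).
#' The invariant `has_mts => is_mito` is enforced.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `accession`, `is_mito` (logical), `has_mts`
#'   (logical), `compartment` (character).
#' @export
read_mito_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    accession = readr::col_character(),
    is_mito = readr::col_logical(),
    has_mts = readr::col_logical(),
    .default = readr::col_character()
  ), progress = FALSE)
  if (!all(c("accession", "is_mito", "has_mts") %in% names(x))) {
    abort("mito table needs columns accession, is_mito, has_mts")
  }
  if (!"compartment" %in% names(x)) x$compartment <- NA_character_
  if (any(x$has_mts & !x$is_mito)) {
    abort("invalid mito table: has_mts = TRUE requires is_mito = TRUE")
  }
  dplyr::select(x, "accession", "is_mito", "has_mts", "compartment")
}

#' Read ortholog groups
#'
#' Reads a TSV whose first column (`sc_accession`) lists S. cerevisiae genes
#' and whose remaining columns, one per species tag, hold the corresponding
#' ortholog accession in that species (empty = no ortholog detected).
#' Cells listing several orthologs separated by `,` or `;` keep the first
#' one; the multiplicity is recorded.
#'
#' @param path Path to the TSV file.
#' @return A tibble of class `nterm_orthogroups` in long form: `sc_accession`,
#'   `species`, `ortholog` (`NA` when absent), `n_listed`. Attribute
#'   `species_tags` holds the species column order.
#' @export
read_ortholog_groups <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (ncol(x) < 2) abort("ortholog table needs an sc_accession column plus species columns")
  names(x)[1] <- "sc_accession"
  dup <- x$sc_accession[duplicated(x$sc_accession)]
  if (length(dup)) {
    abort(paste0("duplicated S. cerevisiae gene row(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  species_tags <- names(x)[-1]
  long <- tidyr::pivot_longer(x, -"sc_accession", names_to = "species",
                              values_to = "cell") |>
    dplyr::mutate(
      cell = dplyr::na_if(tidyr::replace_na(.data$cell, ""), ""),
      n_listed = ifelse(is.na(.data$cell), 0L,
                        stringr::str_count(.data$cell, "[,;]") + 1L),
      ortholog = ifelse(is.na(.data$cell), NA_character_,
                        stringr::str_split_i(.data$cell, "[,;]", 1))
    ) |>
    dplyr::select("sc_accession", "species", "ortholog", "n_listed")
  structure(long, species_tags = species_tags,
            class = c("nterm_orthogroups", class(long)))
}

#' Per-group species coverage of ortholog groups
#'
#' @param groups A `nterm_orthogroups` tibble.
#' @return A tibble with one row per S. cerevisiae gene: `sc_accession`,
#'   `n_species` (species with at least one ortholog).
#' @export
orthogroup_coverage <- function(groups) {
  groups |>
    dplyr::group_by(.data$sc_accession) |>
    dplyr::summarise(n_species = sum(!is.na(.data$ortholog)), .groups = "drop")
}
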