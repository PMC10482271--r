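#' Classify a protein N-terminus by its position-2 residue
#'
#' The residue after the initiator methionine (iMet) determines the fate of
#' the N-terminus: small-radius-of-gyration residues (A, C, G, P, S, T, V)
#' trigger iMet cleavage by methionine aminopeptidase, after which NatA may
#' acetylate; large hydrophobic residues (L, F, I, W) retain the iMet and
#' define potential NatC substrates; acidic/amide residues (D, E, N, Q)
#' retain the iMet and define potential NatB substrates. The remaining
#' residues (H, K, M, R, Y) form the `other` class (iMet retained).
#'
#' @param sequence Character vector of protein sequences (length >= 2 each).
#' @return A tibble with columns `residue2`, `class` (factor with levels
#'   `natc_type`, `metap_type`, `natb_type`, `other`) and `imet_retained`.
#' @examples
#' classify_nterm(c("MLRTP", "MASTQ", "MDELS"))
#' @export
classify_nterm <- function(sequence) {
  if (any(nchar(sequence) < 2)) abort("sequences must have length >= 2")
  r2 <- substr(sequence, 2, 2)
  cls <- dplyr::case_when(
    r2 %in% c("L", "F", "I", "W") ~ "natc_type",
    r2 %in% c("A", "C", "G", "P", "S", "T", "V") ~ "metap_type",
    r2 %in% c("D", "E", "N", "Q") ~ "natb_type",
    TRUE ~ "other"
  )
  tibble::tibble(
    residue2 = r2,
    class = factor(cls, levels = c("natc_type", "metap_type", "natb_type", "other")),
    imet_retained = cls != "metap_type"
  )
}

#' Add N-terminus classification columns to a proteome or record table
#'
#' @param x A data frame with a `sequence` column.
#' @return `x` with `residue2`, `nterm_class` and `imet_retained` appended.
#' @export
add_nterm_class <- function(x) {
  cl <- classify_nterm(x$sequence)
  x$residue2 <- cl$residue2
  x$nterm_class <- cl$class
  x$imet_retained <- cl$imet_retained
  x
}

#' Positional bias matrices of mitochondrial precursors with and without MTS
#'
#' Builds two signed-HGT matrices over the leading positions, comparing
#' (1) MTS-bearing and (2) MTS-less curated mitochondrial precursors with
#' the whole proteome at the same positions. The MTS cohort's hallmark is a
#' strong arginine over-representation (and acidic under-representation) at
#' positions 3-20 plus a hydrophobic signature confined to position 2.
#'
#' @param proteome A `nterm_proteome`.
#' @param mito A mitochondrial annotation table (see [read_mito_table()]).
#' @param positions Positions analysed; default `1:20`.
#' @return A list with `with_mts` and `without_mts`, each a
#'   `nterm_hgt_matrix`.
#' @export
mts_positional_bias <- function(proteome, mito, positions = 1:20) {
  mts_ids <- mito$accession[mito$has_mts]
  nomts_ids <- mito$accession[mito$is_mito & !mito$has_mts]
  list(
    with_mts = positional_hgt_matrix(
      dplyr::filter(proteome, .data$accession %in% mts_ids), proteome, positions),
    without_mts = positional_hgt_matrix(
      dplyr::filter(proteome, .data$accession %in% nomts_ids), proteome, positions)
  )
}

#' Position-2 residue bias of MTS-bearing precursors
#'
#' Signed HGT score per residue comparing position-2 usage in the
#' MTS-bearing cohort with position-2 usage in the whole proteome, plus the
#' aggregate fraction of the cohort falling in each N-terminus class.
#'
#' @param proteome A `nterm_proteome`.
#' @param mts_accessions Accessions of the MTS-bearing precursors.
#' @return A list with `bias` (tibble: `residue`, `k`, `n`, `K`, `N`,
#'   `f_obs`, `f_ref`, `log2_ratio`, `hgt`) and `class_fractions` (tibble:
#'   `class`, `n`, `fraction`).
#' @export
mts_position2_table <- function(proteome, mts_accessions) {
  subset <- dplyr::filter(proteome, .data$accession %in% mts_accessions)
  if (nrow(subset) == 0) abort("no MTS accession found in the proteome")
  mat <- positional_hgt_matrix(subset, proteome, positions = 2L)
  bias <- mat |>
    dplyr::mutate(f_obs = .data$k / .data$n, f_ref = .data$K / .data$N,
                  log2_ratio = log2(.data$f_obs / .data$f_ref)) |>
    dplyr::select("residue", "k", "n", "K", "N",
                  "f_obs", "f_ref", "log2_ratio", "hgt")
  cls <- classify_nterm(subset$sequence[nchar(subset$sequence) >= 2])
  class_fractions <- cls |>
    dplyr::count(.data$class, .drop = FALSE) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  list(bias = bias, class_fractions = class_fractions)
}

#' Cross-species conservation of the MTS position-2 signature
#'
#' Transfers the S. cerevisiae MTS-bearing gene set to each species through
#' ortholog groups (missing orthologs are skipped and counted) and computes,
#' per species, (1) the per-residue signed HGT score at position 2 of the
#' ortholog set against the species' own position-2 proteome background and
#' (2) the maximum per-residue HGT over `deeper_positions` (default 3-30),
#' which verifies that the signature is confined to position 2.
#'
#' @param groups A `nterm_orthogroups` from [read_ortholog_groups()].
#' @param species_proteomes Named list of `nterm_proteome` tibbles, one per
#'   species tag appearing in `groups`.
#' @param sc_mts_ids S. cerevisiae accessions of MTS-bearing precursors.
#' @param deeper_positions Positions summarised by the max-HGT profile.
#' @return A list with `position2` (tibble: `species`, `residue`, counts and
#'   `hgt`) , `deeper_max` (tibble: `species`, `residue`, `hgt_max`) and
#'   `log` (tibble: per-species ortholog counts used / missing).
#' @export
cross_species_mts_bias <- function(groups, species_proteomes, sc_mts_ids,
                                   deeper_positions = 3:30) {
  tags <- unique(groups$species)
  missing_sp <- setdiff(tags, names(species_proteomes))
  if (length(missing_sp)) {
    abort(paste0("no proteome loaded for species: ", paste(missing_sp, collapse = ", ")))
  }
  res <- purrr::map(tags, function(sp) {
    g <- dplyr::filter(groups, .data$species == sp,
                       .data$sc_accession %in% sc_mts_ids)
    orth <- g$ortholog[!is.na(g$ortholog)]
    prot <- species_proteomes[[sp]]
    orth <- intersect(orth, prot$accession)
    subset <- dplyr::filter(prot, .data$accession %in% orth)
    p2 <- positional_hgt_matrix(subset, prot, positions = 2L) |>
      dplyr::mutate(species = sp, .before = 1)
    deep <- positional_hgt_matrix(subset, prot, positions = deeper_positions) |>
      dplyr::group_by(.data$residue) |>
      dplyr::summarise(hgt_max = max(.data$hgt, na.rm = TRUE), .groups = "drop") |>
      dplyr::mutate(species = sp, .before = 1)
    log <- tibble::tibble(species = sp,
                          n_mts_groups = length(unique(g$sc_accession)),
                          n_orthologs_used = nrow(subset),
                          n_missing = length(unique(g$sc_accession)) - nrow(subset))
    list(p2 = p2, deep = deep, log = log)
  })
  list(position2 = purrr::map_dfr(res, "p2"),
       deeper_max = purrr::map_dfr(res, "deep"),
       log = purrr::map_dfr(res, "log"))
}
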