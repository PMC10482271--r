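#' Correct sel-TRAP enrichment against the canonical-ribosome reference
#'
#' Subtracts, gene by gene and replicate by replicate, the log2(IP/input)
#' enrichment measured in the canonical ribosomal-protein immunoprecipitation
#' (Rpl16A-type reference) from the bait immunoprecipitation, removing the
#' shared translating-ribosome component. Genes absent from either table are
#' dropped and counted.
#'
#' @param bait,reference Tibbles with columns `gene_id`, `replicate`,
#'   `log2_ratio` (the measured log2(IP/input)).
#' @return A tibble `gene_id`, `replicate`, `log2_ratio` (corrected);
#'   attribute `n_dropped` counts gene-replicate pairs without a match.
#' @examples
#' b <- tibble::tibble(gene_id = "g1", replicate = 1L, log2_ratio = 2)
#' r <- tibble::tibble(gene_id = "g1", replicate = 1L, log2_ratio = 0.5)
#' correct_enrichment(b, r)  # 1.5
#' @export
correct_enrichment <- function(bait, reference) {
  joined <- dplyr::inner_join(bait, reference,
                              by = c("gene_id", "replicate"),
                              suffix = c("", ".ref"))
  if (nrow(joined) == 0) abort("bait and reference tables share no gene/replicate")
  n_dropped <- nrow(bait) + nrow(reference) - 2L * nrow(joined)
  out <- joined |>
    dplyr::transmute(gene_id = .data$gene_id, replicate = .data$replicate,
                     log2_ratio = .data$log2_ratio - .data$log2_ratio.ref)
  structure(out, n_dropped = n_dropped)
}

#' Combine replicate enrichments into per-gene records
#'
#' Averages the corrected enrichment over replicates; a gene is kept only if
#' measured in every replicate. When a proteome (and optionally a
#' mitochondrial annotation table) is supplied, the N-terminus class and
#' mitochondrial annotations are joined in by accession.
#'
#' @param corrected A tibble `gene_id`, `replicate`, `log2_ratio`.
#' @param proteome Optional `nterm_proteome` used to attach `residue2`,
#'   `nterm_class` and `imet_retained`.
#' @param mito Optional mito annotation table attaching `is_mito`,
#'   `has_mts`, `compartment` (absent genes get `FALSE`/`NA`).
#' @return A tibble of class `nterm_enrichment` with one row per gene:
#'   `gene_id`, `mean_enrichment`, `n_replicates`, plus any joined columns.
#'   Attribute `n_dropped_incomplete` counts genes missing from at least one
#'   replicate.
#' @export
combine_replicates <- function(corrected, proteome = NULL, mito = NULL) {
  n_rep <- dplyr::n_distinct(corrected$replicate)
  agg <- corrected |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(mean_enrichment = mean(.data$log2_ratio),
                     n_replicates = dplyr::n_distinct(.data$replicate),
                     .groups = "drop")
  out <- dplyr::filter(agg, .data$n_replicates == n_rep)
  dropped <- nrow(agg) - nrow(out)
  if (!is.null(proteome)) {
    ann <- add_nterm_class(proteome) |>
      dplyr::select("accession", "residue2", "nterm_class", "imet_retained")
    out <- dplyr::left_join(out, ann, by = c(gene_id = "accession"))
  }
  if (!is.null(mito)) {
    out <- dplyr::left_join(out, mito, by = c(gene_id = "accession")) |>
      dplyr::mutate(is_mito = tidyr::replace_na(.data$is_mito, FALSE),
                    has_mts = tidyr::replace_na(.data$has_mts, FALSE))
  }
  structure(out, n_dropped_incomplete = dropped,
            class = c("nterm_enrichment", class(out)))
}

#' Threshold-independent sweep of class composition and enrichment
#'
#' For every threshold `t` on a fixed grid (default -3 to +4 in steps of
#' 0.1), takes the gene set `S(t) = {mean_enrichment >= t}` and computes,
#' for each class, its proportion within `S(t)` and the signed HGT score of
#' the class count against the full record background. Sweeping the
#' threshold rather than fixing one makes the composition signal — and the
#' threshold at which it peaks — visible without any a-priori cutoff.
#'
#' @param records A `nterm_enrichment` tibble from [combine_replicates()].
#' @param class_col Name of the column holding the class labels (default
#'   `"nterm_class"`; any categorical column works, e.g. `"residue2"`).
#' @param config A [nterm_config()] providing the grid.
#' @return A tibble of class `nterm_sweep`: `threshold`, `class`,
#'   `n_selected`, `k`, `K`, `proportion`, `background`, `hgt`. Cells at
#'   thresholds where `S(t)` is empty carry `NA` proportions/scores.
#' @export
threshold_sweep <- function(records, class_col = "nterm_class",
                            config = nterm_config()) {
  if (nrow(records) == 0) abort("no enrichment records")
  cls <- as.character(records[[class_col]])
  keep <- !is.na(cls)
  x <- records$mean_enrichment[keep]
  cls <- cls[keep]
  levels <- sort(unique(cls))
  N <- length(x)
  Kv <- table(factor(cls, levels = levels))
  # integer-stepped grid avoids floating-point accumulation
  steps <- seq(round(config$sweep_min / config$sweep_step),
               round(config$sweep_max / config$sweep_step))
  grid <- steps * config$sweep_step
  out <- purrr::map_dfr(grid, function(t) {
    sel <- x >= t
    n <- sum(sel)
    k <- as.integer(table(factor(cls[sel], levels = levels)))
    tibble::tibble(threshold = t, class = levels, n_selected = n,
                   k = k, K = as.integer(Kv),
                   proportion = if (n > 0) k / n else NA_real_,
                   background = as.integer(Kv) / N)
  })
  out$hgt <- NA_real_
  ok <- out$n_selected > 0
  out$hgt[ok] <- hgt_score(out$k[ok], out$K[ok], out$n_selected[ok], N)
  structure(out, n_records = N,
            class = c("nterm_sweep", class(tibble::as_tibble(out))))
}

#' Call enrichment targets at a threshold
#'
#' Keeps the genes whose mean corrected enrichment is at or above the
#' threshold (inclusive). The default of 0.8 is where the HGT score curves
#' of the sweep typically peak for a specific bait.
#'
#' @param records A `nterm_enrichment` tibble.
#' @param threshold Enrichment threshold (default 0.8).
#' @return The target rows of `records`.
#' @export
call_targets <- function(records, threshold = 0.8) {
  dplyr::filter(records, .data$mean_enrichment >= threshold)
}

#' Composition of a target set against its background
#'
#' For each category level (cellular compartment; MTS status split as
#' MTS-bearing / mito without MTS / non-mitochondrial; N-terminus class; and
#' position-2 residue among MTS-bearing targets), reports the fraction of
#' targets versus the background fraction and a signed HGT score. The
#' background universe is the full record table (every gene with a defined
#' class on the array), not the whole proteome.
#'
#' @param records A `nterm_enrichment` tibble with annotation columns.
#' @param targets Target rows (subset of `records`), e.g. from
#'   [call_targets()].
#' @return A tibble: `category`, `level`, `k`, `n`, `K`, `N`,
#'   `fraction_targets`, `fraction_background`, `hgt`.
#' @export
composition_report <- function(records, targets) {
  if (!all(targets$gene_id %in% records$gene_id)) {
    abort("targets must be a subset of records")
  }
  one <- function(category, values_bg, values_tg) {
    keep_bg <- !is.na(values_bg); keep_tg <- !is.na(values_tg)
    vb <- as.character(values_bg[keep_bg]); vt <- as.character(values_tg[keep_tg])
    levels <- sort(unique(vb))
    if (!length(levels)) return(NULL)
    N <- length(vb); n <- length(vt)
    K <- as.integer(table(factor(vb, levels = levels)))
    k <- as.integer(table(factor(vt, levels = levels)))
    frac_t <- if (n > 0) k / n else rep(NA_real_, length(levels))
    scores <- if (n > 0) hgt_score(k, K, n, N) else rep(NA_real_, length(levels))
    tibble::tibble(category = category, level = levels, k = k, n = n,
                   K = K, N = N,
                   fraction_targets = frac_t,
                   fraction_background = K / N,
                   hgt = scores)
  }
  mts_status <- function(df) {
    dplyr::case_when(df$has_mts ~ "mts",
                     df$is_mito ~ "mito_no_mts",
                     TRUE ~ "non_mito")
  }
  out <- list()
  if ("compartment" %in% names(records)) {
    out$compartment <- one("compartment", records$compartment, targets$compartment)
  }
  if (all(c("is_mito", "has_mts") %in% names(records))) {
    out$mts <- one("mts_status", mts_status(records), mts_status(targets))
  }
  if ("nterm_class" %in% names(records)) {
    out$class <- one("nterm_class", records$nterm_class, targets$nterm_class)
  }
  if (all(c("has_mts", "residue2") %in% names(records))) {
    out$mts_res <- one("mts_residue2",
                       ifelse(records$has_mts, records$residue2, NA),
                       ifelse(targets$has_mts, targets$residue2, NA))
  }
  dplyr::bind_rows(out)
}

#' Filter mass-spectrometry partners of tagged baits
#'
#' Applies the Mascot-score filtering rules to sel-TRAP proteomics data:
#' within each replicate a protein is kept for a bait when its score exceeds
#' the cutoff (250), the control (mock IP) score does not exceed the cutoff,
#' and the tagged/control score ratio is at least 2 (a protein absent from
#' the control counts as score 0). A partner must pass in every replicate
#' ("reproducibly detected"). Across baits, a kept partner whose mean score
#' in one bait is at least 5-fold higher than in every other bait is
#' assigned as specific to that bait; otherwise it is shared.
#'
#' @param tagged Tibble `protein_id`, `bait`, `replicate`, `score` of the
#'   tagged-strain immunoprecipitations.
#' @param control Tibble `protein_id`, `score` of the untagged control IP.
#' @param config A [nterm_config()].
#' @return A list with `records` (per protein/bait/replicate verdicts in
#'   kept / below_cutoff / excluded_control / excluded_ratio), `partners`
#'   (per protein/bait: kept in all replicates) and `specificity`
#'   (per kept protein: `assignment` = bait label or `"shared"`).
#' @export
filter_ms_partners <- function(tagged, control, config = nterm_config()) {
  ctrl <- setNames(control$score, control$protein_id)
  records <- tagged |>
    dplyr::mutate(
      control_score = tidyr::replace_na(unname(ctrl[.data$protein_id]), 0),
      verdict = dplyr::case_when(
        .data$score <= config$mascot_cutoff ~ "below_cutoff",
        .data$control_score > config$mascot_cutoff ~ "excluded_control",
        .data$score / pmax(.data$control_score, 1e-9) < config$mascot_ratio_min ~ "excluded_ratio",
        TRUE ~ "kept"
      )
    )
  partners <- records |>
    dplyr::group_by(.data$protein_id, .data$bait) |>
    dplyr::summarise(n_replicates = dplyr::n(),
                     kept = all(.data$verdict == "kept"),
                     mean_score = mean(.data$score), .groups = "drop") |>
    dplyr::filter(.data$kept)
  specificity <- partners |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::group_modify(function(d, key) {
      all_scores <- records |>
        dplyr::filter(.data$protein_id == key$protein_id) |>
        dplyr::group_by(.data$bait) |>
        dplyr::summarise(mean_score = mean(.data$score), .groups = "drop")
      top <- all_scores$bait[which.max(all_scores$mean_score)]
      others <- all_scores$mean_score[all_scores$bait != top]
      specific <- top %in% d$bait &&
        (length(others) == 0 ||
           max(all_scores$mean_score) >= config$mascot_specificity_fold * max(others))
      tibble::tibble(assignment = if (specific) top else "shared")
    }) |>
    dplyr::ungroup()
  list(records = records, partners = partners, specificity = specificity)
}
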