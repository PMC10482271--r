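#' Residue usage bias at one position versus the proteome background
#'
#' Compares, for each of the 20 residues, the observed frequency at a given
#' position (`F_obs`, typically position 2) with the proteome-wide pooled
#' frequency (`F_ref`, a.k.a. `Fmean`). The background frequency is
#' materialised as a finite urn: the population is the pool of all residues
#' of all non-excluded proteins (`N` residues, `K` of them the residue under
#' test) from which `n_at_position` draws are made, so one hypergeometric
#' test family serves every comparison in the package.
#'
#' @param profile A `nterm_profile` from [position_profile()].
#' @param background A `nterm_background` from [background_frequencies()].
#' @param position Position to test (1-based; the initiator methionine is
#'   position 1). Default 2.
#' @return A tibble of class `nterm_bias` with one row per residue: counts
#'   `k`, `n`, `K`, `N`, frequencies `f_obs` and `f_ref`, `log2_ratio`
#'   (`log2(F_obs/F_ref)`), and the signed `hgt` score. A tie
#'   (`f_obs == f_ref`) is scored on the upper tail with a positive sign.
#' @examples
#' p <- as_proteome(data.frame(accession = c("a", "b", "c"),
#'                             sequence = c("MSA", "MSG", "MLD")))
#' position_bias_table(position_profile(p, 2), background_frequencies(p))
#' @export
position_bias_table <- function(profile, background, position = 2L) {
  row <- dplyr::filter(profile, .data$position == !!as.integer(position))
  if (nrow(row) == 0) abort(sprintf("position %d not in profile", position))
  if (all(row$n_at_position == 0)) abort(sprintf("no protein covers position %d", position))
  N <- attr(background, "total")
  out <- row |>
    dplyr::left_join(dplyr::select(background, "residue", K = "count", f_ref = "freq"),
                     by = "residue") |>
    dplyr::transmute(
      residue = .data$residue,
      position = .data$position,
      k = .data$count,
      n = .data$n_at_position,
      K = .data$K,
      N = N,
      f_obs = .data$freq,
      f_ref = .data$f_ref,
      log2_ratio = log2(.data$f_obs / .data$f_ref),
      hgt = hgt_score(.data$k, .data$K, .data$n, N)
    )
  structure(out, class = c("nterm_bias", class(out)))
}

# Core aspecificity computation on a vector of per-position frequencies that
# have already been restricted to the analyzed positions (invalid positions
# dropped, so the window denominator shrinks with them).
aspecificity_from_vector <- function(freqs, f2, fmean, window = 100L) {
  if (length(freqs) == 0) abort("no analyzable positions for the aspecificity score")
  f2ref <- if (f2 > fmean) 0.9 * f2 else 1.1 * f2
  crossing <- if (f2 > fmean) freqs > f2ref else freqs <= f2ref
  w <- min(as.integer(window), length(freqs))
  cs <- cumsum(c(0L, as.integer(crossing)))
  starts <- seq_len(length(freqs) - w + 1L)
  local <- (cs[starts + w] - cs[starts]) / w
  100 * max(local)
}

#' Positional aspecificity of a position-2 usage bias
#'
#' Quantifies whether a residue's usage bias at position 2 is specific to
#' that position. From `F2` (frequency at position 2) and `Fmean` (pooled
#' proteome frequency) a reference `F_2ref` is derived: `0.9 * F2` when
#' `F2 > Fmean`, else `1.1 * F2`. A window of `aspecificity_window`
#' consecutive analyzed positions slides over the first
#' `aspecificity_span` proteome positions (positions 1 and 2 excluded by
#' default: 1 is the constant initiator methionine, 2 the tested position);
#' in each window the percentage of positions whose frequency crosses
#' `F_2ref` (exceeds it for over-represented residues; is `<=` it for
#' under-represented ones) is the local score, and the reported aspecificity
#' is the maximum local score. 0% means no other region of the proteome
#' mimics the position-2 usage, i.e. a fully position-specific bias.
#'
#' Positions not covered by any protein are dropped and the local window
#' denominator shrinks accordingly.
#'
#' @param profile A `nterm_profile` extending over the span to analyse.
#' @param background A `nterm_background`.
#' @param position Tested position (default 2).
#' @param config A [nterm_config()]; `aspecificity_window`,
#'   `aspecificity_span` and `aspecificity_exclude` are used.
#' @return A tibble with one row per residue: `residue`, `f2`, `fmean`,
#'   `f2ref`, `aspecificity` (percentage in `[0, 100]`).
#' @export
aspecificity_scores <- function(profile, background, position = 2L,
                                config = nterm_config()) {
  span <- min(config$aspecificity_span, max(profile$position))
  excl <- unique(c(config$aspecificity_exclude, as.integer(position)))
  grid <- profile |>
    dplyr::filter(.data$position <= span, !.data$position %in% excl,
                  .data$n_at_position > 0)
  f2 <- dplyr::filter(profile, .data$position == !!as.integer(position))
  purrr::map_dfr(AA20, function(r) {
    fr2 <- f2$freq[f2$residue == r]
    fm <- background$freq[background$residue == r]
    v <- grid$freq[grid$residue == r]
    tibble::tibble(
      residue = r, f2 = fr2, fmean = fm,
      f2ref = if (fr2 > fm) 0.9 * fr2 else 1.1 * fr2,
      aspecificity = aspecificity_from_vector(v, fr2, fm, config$aspecificity_window)
    )
  })
}

#' Signed HGT score matrix of a protein subset over N-terminal positions
#'
#' At each position `p`, the reference urn is the set of reference proteins
#' covering `p` with a canonical residue (`N`, of which `K` carry residue
#' `r`), and the sample is the subset (`n`, `k`). Each cell is the signed
#' [hgt_score()]. This is the positional heatmap underlying the MTS and
#' GO-term specificity analyses.
#'
#' @param subset A `nterm_proteome` tibble (or data frame with `accession`,
#'   `sequence`) whose accessions are all present in `reference`.
#' @param reference The reference `nterm_proteome`.
#' @param positions Integer vector of 1-based positions, e.g. `1:20`.
#' @return A tibble of class `nterm_hgt_matrix` with columns `position`,
#'   `residue`, `k`, `n`, `K`, `N`, `hgt` (`NA` where no subset protein
#'   covers the position).
#' @export
positional_hgt_matrix <- function(subset, reference, positions = 1:20) {
  missing_acc <- setdiff(subset$accession, reference$accession)
  if (length(missing_acc)) {
    abort(paste0("subset accession(s) absent from reference: ",
                 paste(head(missing_acc, 3), collapse = ", ")))
  }
  ref_seq <- active_sequences(reference)
  sub_seq <- active_sequences(subset)
  out <- purrr::map_dfr(as.integer(positions), function(pos) {
    rr <- residue_at(ref_seq[nchar(ref_seq) >= pos], pos)
    rr <- rr[!is.na(rr)]
    sr <- residue_at(sub_seq[nchar(sub_seq) >= pos], pos)
    sr <- sr[!is.na(sr)]
    Kv <- as.integer(table(factor(rr, levels = AA20)))
    kv <- as.integer(table(factor(sr, levels = AA20)))
    tibble::tibble(position = pos, residue = AA20, k = kv,
                   n = length(sr), K = Kv, N = length(rr))
  })
  out$hgt <- NA_real_
  ok <- out$n > 0 & out$N > 0
  out$hgt[ok] <- hgt_score(out$k[ok], out$K[ok], out$n[ok], out$N[ok])
  structure(out, class = c("nterm_hgt_matrix", class(out)))
}
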