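#' Per-GO-term residue contingency counts at an N-terminal position
#'
#' For every GO term of one domain, counts how many proteins carry each
#' residue at the tested position. Proteins sharing the same first 10
#' residues are collapsed to one deduplicated identifier first (see
#' [nterm_dedup()]), so paralogous families with identical N-termini cannot
#' drive a bias on their own. Proteome margins (`K`, `N`) are computed on the
#' same deduplicated identifiers.
#'
#' @param annotations A `nterm_go` tibble from [read_gaf()] (or a compatible
#'   data frame with `domain`, `term_id`, `term_name`, `accession`).
#' @param proteome A `nterm_proteome`.
#' @param domain GO domain to scan: `"component"`, `"process"` or
#'   `"function"`.
#' @param position Tested position (default 2; must not exceed the dedup
#'   prefix length so that members of one dedup group agree at it).
#' @param config A [nterm_config()].
#' @return A tibble of class `go_contingency` with columns `term_id`,
#'   `term_name`, `residue`, `k`, `n`, `K`, `N` (one row per term/residue
#'   with `k >= 1`). Attributes: `members` (named list, term -> deduplicated
#'   ids with a defined residue at the position), `residue_of` (named vector,
#'   dedup id -> residue), `domain`, `position`.
#' @export
build_go_contingency <- function(annotations, proteome, domain = "component",
                                 position = 2L, config = nterm_config()) {
  position <- as.integer(position)
  if (position > config$dedup_prefix_len) {
    abort("position must lie within the dedup prefix")
  }
  ann <- dplyr::filter(annotations, .data$domain == !!domain)
  if (nrow(ann) == 0) abort(sprintf("no annotations for domain '%s'", domain))
  dd <- nterm_dedup(proteome, config$dedup_prefix_len)
  # every member of a dedup group shares the prefix, hence the residue
  reps <- dd |>
    dplyr::distinct(.data$dedup_id, .data$nterm_key) |>
    dplyr::mutate(residue = residue_at(.data$nterm_key, position)) |>
    dplyr::filter(!is.na(.data$residue))
  residue_of <- setNames(reps$residue, reps$dedup_id)
  N <- nrow(reps)
  margins <- reps |> dplyr::count(.data$residue, name = "K")

  term_members <- ann |>
    dplyr::inner_join(dplyr::select(dd, "accession", "dedup_id"), by = "accession") |>
    dplyr::filter(.data$dedup_id %in% reps$dedup_id) |>
    dplyr::distinct(.data$term_id, .data$term_name, .data$dedup_id)
  if (nrow(term_members) == 0) abort("no annotated protein has a defined residue at the position")
  members <- split(term_members$dedup_id, term_members$term_id)

  out <- term_members |>
    dplyr::mutate(residue = residue_of[.data$dedup_id]) |>
    dplyr::group_by(.data$term_id, .data$term_name) |>
    dplyr::mutate(n = dplyr::n_distinct(.data$dedup_id)) |>
    dplyr::group_by(.data$term_id, .data$term_name, .data$n, .data$residue) |>
    dplyr::summarise(k = dplyr::n_distinct(.data$dedup_id), .groups = "drop") |>
    dplyr::left_join(margins, by = "residue") |>
    dplyr::mutate(N = N) |>
    dplyr::select("term_id", "term_name", "residue", "k", "n", "K", "N") |>
    dplyr::arrange(.data$term_id, .data$residue)
  structure(out, members = members, residue_of = residue_of,
            domain = domain, position = position,
            class = c("go_contingency", class(out)))
}

#' Screen GO terms for over-represented residues
#'
#' Scores every (term, residue) contingency row with the signed [hgt_score()]
#' and keeps those exceeding the screening threshold (`hgt > 4` by default,
#' i.e. hypergeometric p < 1e-4).
#'
#' @param contingency A `go_contingency` from [build_go_contingency()].
#' @param config A [nterm_config()].
#' @return A tibble of class `go_screen`: the screened rows plus
#'   `fold_change` (`(k/n) / (K/N)`), `hgt` and `status = "screened"`.
#'   Contingency attributes are carried forward.
#' @export
screen_go_terms <- function(contingency, config = nterm_config()) {
  out <- contingency |>
    dplyr::mutate(
      fold_change = (.data$k / .data$n) / (.data$K / .data$N),
      hgt = hgt_score(.data$k, .data$K, .data$n, .data$N)
    ) |>
    dplyr::filter(.data$hgt > config$hgt_screen_min) |>
    dplyr::mutate(status = "screened") |>
    dplyr::arrange(.data$term_id, .data$residue)
  structure(out, members = attr(contingency, "members"),
            residue_of = attr(contingency, "residue_of"),
            domain = attr(contingency, "domain"),
            position = attr(contingency, "position"),
            class = c("go_screen", class(tibble::as_tibble(out))))
}

#' Remove weakly biased, typically very generic, GO terms
#'
#' Marks screened (term, residue) entries whose fold change falls below the
#' threshold (default 1.8, boundary inclusive: exactly 1.8 is kept) with
#' status `"removed_low_bias"`. Such entries usually belong to very large,
#' generic terms whose sheer size makes small biases significant.
#'
#' @param screened A `go_screen` from [screen_go_terms()].
#' @param config A [nterm_config()].
#' @return The input with `status` updated; attributes carried forward.
#' @export
filter_generic_terms <- function(screened, config = nterm_config()) {
  out <- dplyr::mutate(screened, status = ifelse(
    .data$fold_change < config$fold_change_min, "removed_low_bias", .data$status))
  structure(out, members = attr(screened, "members"),
            residue_of = attr(screened, "residue_of"),
            domain = attr(screened, "domain"),
            position = attr(screened, "position"),
            class = class(screened))
}

overlap_frac <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(0)
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Greedy BestN / BestF selection of low-redundancy GO terms
#'
#' Reduces the list of screened-and-filtered GO terms to a non-redundant
#' description in two passes over the protein sets behind the terms (never
#' over the GO hierarchy):
#'
#' * **BestN** — iteratively pick the admissible term covering the largest
#'   number of not-yet-covered *bias proteins* (deduplicated proteins
#'   carrying one of the term's qualifying residues at the tested position).
#'   A candidate is admissible when its protein-set overlap
#'   (`|A & B| / min(|A|,|B|)`) with every already selected BestN stays below
#'   `bestN_overlap_max` (40%). Selection stops when no admissible candidate
#'   contributes a new bias protein. Ties break on coverage gain, then HGT,
#'   then smaller term size, then term id.
#' * **BestF** — smaller terms contained in a BestN (containment
#'   `|F & B| / |F| >= bestF_containment_min`, parent = maximum containment)
#'   whose best fold change exceeds the parent's by `bestF_bias_gain`
#'   (1.3x). Candidates are processed in decreasing fold order; a candidate
#'   overlapping an accepted BestF by `>= bestF_overlap_max` (30%) replaces
#'   it only if it is enriched for more distinct residues (then higher fold,
#'   then term id), otherwise it is marked redundant.
#'
#' @param filtered A `go_screen` after [filter_generic_terms()].
#' @param config A [nterm_config()].
#' @return An object of class `go_selection`: list with `terms` (per-term
#'   tibble with `status` in screened/removed_low_bias/bestN/bestF/redundant
#'   and `parent_bestN`), `entries` (the per term/residue input), `coverage`
#'   (fraction of all filtered-term bias proteins covered by BestN + BestF)
#'   and `config`. Use [tidy()] / [glance()] to extract results.
#' @export
select_best_terms <- function(filtered, config = nterm_config()) {
  members <- attr(filtered, "members")
  residue_of <- attr(filtered, "residue_of")
  surv <- dplyr::filter(filtered, .data$status == "screened")
  if (nrow(surv) == 0) abort("no terms survive screening and filtering")

  terms <- surv |>
    dplyr::group_by(.data$term_id, .data$term_name, .data$n) |>
    dplyr::summarise(residues = list(sort(unique(.data$residue))),
                     best_fold = max(.data$fold_change),
                     best_hgt = max(.data$hgt), .groups = "drop") |>
    dplyr::mutate(n_residues = lengths(.data$residues))
  bias_sets <- purrr::map2(terms$term_id, terms$residues, function(id, res) {
    ids <- members[[id]]
    ids[residue_of[ids] %in% res]
  })
  names(bias_sets) <- terms$term_id
  term_sets <- members[terms$term_id]
  all_bias <- unique(unlist(bias_sets))

  # ---- BestN greedy ----
  best_n <- character()
  covered <- character()
  remaining <- terms$term_id
  repeat {
    cand <- remaining[purrr::map_lgl(remaining, function(id) {
      all(purrr::map_dbl(best_n, function(b) {
        overlap_frac(term_sets[[id]], term_sets[[b]])
      }) < config$bestN_overlap_max)
    })]
    if (length(cand) == 0) break
    gain <- purrr::map_int(cand, function(id) length(setdiff(bias_sets[[id]], covered)))
    if (max(gain) < 1) break
    ix <- match(cand, terms$term_id)
    ord <- order(-gain, -terms$best_hgt[ix], terms$n[ix], cand)
    pick <- cand[ord[1]]
    best_n <- c(best_n, pick)
    covered <- union(covered, bias_sets[[pick]])
    remaining <- setdiff(remaining, pick)
  }

  # ---- BestF greedy with replacement ----
  parent_of <- setNames(rep(NA_character_, nrow(terms)), terms$term_id)
  cand_f <- setdiff(terms$term_id, best_n)
  cand_info <- purrr::map_dfr(cand_f, function(id) {
    cont <- purrr::map_dbl(best_n, function(b) {
      f <- term_sets[[id]]
      if (length(f) == 0) return(0)
      length(intersect(f, term_sets[[b]])) / length(f)
    })
    if (!length(cont) || max(cont) < config$bestF_containment_min) return(NULL)
    j <- which.max(cont)
    parent <- best_n[j]
    fold <- terms$best_fold[terms$term_id == id]
    pfold <- terms$best_fold[terms$term_id == parent]
    if (fold < config$bestF_bias_gain * pfold) return(NULL)
    tibble::tibble(term_id = id, parent = parent, containment = cont[j],
                   fold = fold,
                   n_res = terms$n_residues[terms$term_id == id])
  })

  best_f <- character()
  redundant <- character()
  if (nrow(cand_info)) {
    cand_info <- dplyr::arrange(cand_info, dplyr::desc(.data$fold),
                                dplyr::desc(.data$n_res), .data$term_id)
    beats <- function(a, b) {  # replacement preference order
      ia <- cand_info[cand_info$term_id == a, ]; ib <- cand_info[cand_info$term_id == b, ]
      if (ia$n_res != ib$n_res) return(ia$n_res > ib$n_res)
      if (ia$fold != ib$fold) return(ia$fold > ib$fold)
      a < b
    }
    for (i in seq_len(nrow(cand_info))) {
      id <- cand_info$term_id[i]
      conflicts <- best_f[purrr::map_dbl(best_f, function(b) {
        overlap_frac(term_sets[[id]], term_sets[[b]])
      }) >= config$bestF_overlap_max]
      if (length(conflicts) == 0) {
        best_f <- c(best_f, id)
      } else if (all(purrr::map_lgl(conflicts, function(b) beats(id, b)))) {
        redundant <- c(redundant, conflicts)
        best_f <- c(setdiff(best_f, conflicts), id)
      } else {
        redundant <- c(redundant, id)
      }
    }
    parent_of[best_f] <- cand_info$parent[match(best_f, cand_info$term_id)]
  }

  covered_final <- unique(unlist(bias_sets[c(best_n, best_f)]))
  coverage <- if (length(all_bias)) length(intersect(covered_final, all_bias)) / length(all_bias) else NA_real_

  term_status <- terms |>
    dplyr::mutate(
      status = dplyr::case_when(
        .data$term_id %in% best_n ~ "bestN",
        .data$term_id %in% best_f ~ "bestF",
        .data$term_id %in% redundant ~ "redundant",
        TRUE ~ "screened"
      ),
      parent_bestN = unname(parent_of[.data$term_id]),
      n_bias = unname(lengths(bias_sets[.data$term_id])),
      residues = purrr::map_chr(.data$residues, paste, collapse = ",")
    ) |>
    dplyr::arrange(dplyr::desc(.data$status == "bestN"),
                   dplyr::desc(.data$status == "bestF"), .data$term_id)

  structure(list(terms = term_status, entries = filtered,
                 coverage = coverage, config = config,
                 domain = attr(filtered, "domain")),
            class = "go_selection")
}

#' @export
print.go_selection <- function(x, ...) {
  cat(sprintf("<go_selection> %s domain: %d bestN, %d bestF, coverage %.1f%%\n",
              x$domain %||% "?", sum(x$terms$status == "bestN"),
              sum(x$terms$status == "bestF"), 100 * x$coverage))
  print(dplyr::filter(x$terms, .data$status %in% c("bestN", "bestF")))
  invisible(x)
}

#' Check that a term's usage bias is specific to the tested position
#'
#' Extends the bias search to the first `max(positions)` positions: the
#' flag is raised (bias *not* specific) when any position other than the
#' tested one reaches an HGT score at least as high as the tested position's
#' for the same residue.
#'
#' @param subset Proteins of the term (a `nterm_proteome`-like data frame).
#' @param reference The reference proteome.
#' @param residue Residue whose bias is being checked.
#' @param position The position where the bias was detected (default 2).
#' @param positions Positions scanned (default `1:100`).
#' @return A list with `profile` (the [positional_hgt_matrix()] rows for
#'   `residue`) and `nonspecific` (logical flag).
#' @export
positional_specificity_check <- function(subset, reference, residue,
                                         position = 2L, positions = 1:100) {
  mat <- positional_hgt_matrix(subset, reference, positions)
  prof <- dplyr::filter(mat, .data$residue == !!residue)
  h2 <- prof$hgt[prof$position == position]
  others <- prof$hgt[prof$position != position]
  # a flat (no-bias) profile is trivially specific
  list(profile = prof,
       nonspecific = isTRUE(h2 > 0) && isTRUE(any(others >= h2, na.rm = TRUE)))
}
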