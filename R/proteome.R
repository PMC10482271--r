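#' Read a proteome from FASTA
#'
#' Reads a protein FASTA file into a proteome tibble, the substrate of all
#' downstream counting. UniProt-style headers (`sp|ACC|NAME description`) are
#' auto-detected; otherwise the first whitespace-delimited token is the
#' accession. Records whose accession appears in `exclusion_ids` (e.g.
#' transposon-encoded proteins) are flagged `is_excluded` and ignored by all
#' frequency computations while remaining visible in the table.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @param exclusion_ids Optional character vector of accessions to exclude.
#' @param species_tag Label stored on the result (used by cross-species
#'   analyses).
#'
#' @return A tibble of class `nterm_proteome` with columns `accession`,
#'   `gene_name`, `sequence`, `length`, `is_excluded` and `nterm_key` (the
#'   first 10 residues, or the full sequence if shorter).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P1|A", "MSTAAA", ">sp|P2|B", "MLRTPT"), fa)
#' read_fasta_proteome(fa)
#' @export
read_fasta_proteome <- function(path, exclusion_ids = NULL, species_tag = NA_character_) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) abort(paste0("no FASTA records in ", path))
  headers <- names(aa)
  uniprot <- stringr::str_match(headers, "^(?:sp|tr)\\|([^|]+)\\|(\\S+)")
  accession <- ifelse(is.na(uniprot[, 2]),
                      stringr::str_extract(headers, "^\\S+"),
                      uniprot[, 2])
  gene_name <- uniprot[, 3]
  sequences <- unname(toupper(as.character(aa)))
  as_proteome(tibble::tibble(accession = accession,
                             gene_name = gene_name,
                             sequence = sequences),
              exclusion_ids = exclusion_ids, species_tag = species_tag)
}

#' Build a proteome tibble from in-memory sequences
#'
#' Validates sequences and derives the columns every analysis relies on. Used
#' by [read_fasta_proteome()] and by the synthetic generators.
#'
#' @param x A data frame with at least `accession` and `sequence` columns.
#' @inheritParams read_fasta_proteome
#' @return A `nterm_proteome` tibble; see [read_fasta_proteome()].
#' @export
as_proteome <- function(x, exclusion_ids = NULL, species_tag = NA_character_) {
  x <- tibble::as_tibble(x)
  if (!all(c("accession", "sequence") %in% names(x))) {
    abort("need `accession` and `sequence` columns")
  }
  if (!"gene_name" %in% names(x)) x$gene_name <- NA_character_
  dup <- x$accession[duplicated(x$accession)]
  if (length(dup)) {
    abort(paste0("duplicate accession(s): ", paste(unique(dup), collapse = ", ")))
  }
  x$sequence <- toupper(x$sequence)
  ok_alpha <- paste0("^[", paste(c(AA20, AA_AMBIGUOUS), collapse = ""), "]+$")
  bad <- which(!stringr::str_detect(x$sequence, ok_alpha) | nchar(x$sequence) < 1)
  if (length(bad)) {
    chars <- stringr::str_remove_all(x$sequence[bad[1]],
                                     paste0("[", paste(c(AA20, AA_AMBIGUOUS), collapse = ""), "]"))
    abort(sprintf("non-amino-acid character(s) '%s' in record %d (%s)",
                  substr(chars, 1, 5), bad[1], x$accession[bad[1]]))
  }
  prefix <- 10L
  out <- x |>
    dplyr::mutate(
      length = nchar(.data$sequence),
      is_excluded = .data$accession %in% (exclusion_ids %||% character()),
      nterm_key = substr(.data$sequence, 1L, prefix)
    ) |>
    dplyr::select("accession", "gene_name", "sequence", "length",
                  "is_excluded", "nterm_key")
  structure(out, species_tag = species_tag,
            class = c("nterm_proteome", class(out)))
}

#' Collapse proteins sharing an identical N-terminal prefix
#'
#' Proteins whose first `prefix_len` residues are identical are grouped under
#' one deterministic representative (the lexicographically smallest
#' accession), so that paralogous families with one shared N-terminus count
#' only once in contingency tables. Sequences shorter than `prefix_len` use
#' the full sequence as key. Excluded records are not grouped.
#'
#' @param proteome A `nterm_proteome` tibble.
#' @param prefix_len Prefix length; default 10.
#' @return A tibble with one row per non-excluded protein: `accession`,
#'   `nterm_key`, `dedup_id` (representative accession of its group).
#' @examples
#' p <- as_proteome(data.frame(accession = c("B", "A"),
#'                             sequence = c("MSTAAAXXXXQQ", "MSTAAAXXXX")))
#' nterm_dedup(p)  # both map to dedup_id "A"
#' @export
nterm_dedup <- function(proteome, prefix_len = 10L) {
  stopifnot(prefix_len >= 1)
  proteome |>
    dplyr::filter(!.data$is_excluded) |>
    dplyr::mutate(nterm_key = substr(.data$sequence, 1L, as.integer(prefix_len))) |>
    dplyr::group_by(.data$nterm_key) |>
    dplyr::mutate(dedup_id = min(.data$accession)) |>
    dplyr::ungroup() |>
    dplyr::select("accession", "nterm_key", "dedup_id") |>
    dplyr::arrange(.data$accession)
}

# residue at `position` for each sequence; NA when too short or non-canonical
residue_at <- function(sequence, position) {
  r <- substr(sequence, position, position)
  r[!r %in% AA20] <- NA_character_
  r
}

#' Positional residue-frequency profile
#'
#' Counts, at each of the first `max_position` positions, how many
#' non-excluded proteins carry each of the 20 canonical residues there.
#' Proteins shorter than a position, and positions holding an ambiguity code,
#' are excluded from both the numerator and the denominator, so per-position
#' counts always sum to `n_at_position`.
#'
#' @param proteome A `nterm_proteome` tibble (or any data frame with
#'   `sequence`; an `is_excluded` column is honoured when present).
#' @param max_position Last position profiled (>= 2).
#' @return A tibble of class `nterm_profile` with columns `position`,
#'   `residue`, `count`, `n_at_position`, `freq`.
#' @examples
#' p <- as_proteome(data.frame(accession = c("a", "b"), sequence = c("MST", "MLD")))
#' dplyr::filter(position_profile(p, 2), position == 2, count > 0)
#' @export
position_profile <- function(proteome, max_position = 20L) {
  max_position <- as.integer(max_position)
  if (max_position < 2) abort("max_position must be >= 2")
  seqs <- active_sequences(proteome)
  if (length(seqs) == 0) abort("no non-excluded proteins to profile")
  out <- purrr::map_dfr(seq_len(max_position), function(pos) {
    r <- residue_at(seqs[nchar(seqs) >= pos], pos)
    r <- r[!is.na(r)]
    cnt <- table(factor(r, levels = AA20))
    tibble::tibble(position = pos, residue = AA20,
                   count = as.integer(cnt), n_at_position = length(r))
  })
  out$freq <- ifelse(out$n_at_position > 0, out$count / out$n_at_position, NA_real_)
  structure(out, class = c("nterm_profile", class(out)))
}

active_sequences <- function(proteome) {
  s <- proteome$sequence
  if ("is_excluded" %in% names(proteome)) s <- s[!proteome$is_excluded]
  s
}

#' Proteome-wide background residue frequencies
#'
#' Pools every canonical residue of every position of every non-excluded
#' protein into one frequency table — the reference distribution (`Fmean`)
#' against which positional usage is compared.
#'
#' @inheritParams position_profile
#' @return A tibble of class `nterm_background` with columns `residue`,
#'   `count`, `freq`; attribute `total` holds the pooled residue count.
#' @examples
#' p <- as_proteome(data.frame(accession = c("a", "b"), sequence = c("MA", "MG")))
#' background_frequencies(p)  # M 0.5, A 0.25, G 0.25
#' @export
background_frequencies <- function(proteome) {
  seqs <- active_sequences(proteome)
  if (length(seqs) == 0) abort("no non-excluded proteins")
  counts <- colSums(Biostrings::letterFrequency(
    Biostrings::AAStringSet(seqs), letters = AA20))
  total <- sum(counts)
  out <- tibble::tibble(residue = AA20, count = as.numeric(counts),
                        freq = as.numeric(counts) / total)
  structure(out, total = total,
            class = c("nterm_background", class(out)))
}

#' Write a proteome to FASTA
#'
#' @param proteome A `nterm_proteome` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_proteome <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(setNames(proteome$sequence, proteome$accession))
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}
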