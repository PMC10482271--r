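# Seeded generators emulating the statistical structure of the real inputs:
# proteomes with planted position-2 biases inside GO groups, MTS cohorts with
# an Arg-rich 3-20 region, pseudo-species orthogroups, and sel-TRAP
# enrichment tables with a planted class shift. Each generator uses one
# explicitly seeded RNG stream and leaves the global RNG state untouched.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Yeast-like background residue frequencies
#'
#' A documented constant table approximating the pooled amino-acid
#' composition of a budding-yeast proteome; the default background of the
#' synthetic generators. Use `uniform = TRUE` for an exchangeable null.
#'
#' @param uniform If `TRUE`, return the uniform distribution over the 20
#'   canonical residues.
#' @return A named numeric vector over the 20 residues, summing to 1.
#' @export
yeast_background_frequencies <- function(uniform = FALSE) {
  if (uniform) return(setNames(rep(1 / 20, 20), AA20))
  f <- c(A = 0.055, C = 0.013, D = 0.058, E = 0.064, F = 0.045,
         G = 0.050, H = 0.022, I = 0.065, K = 0.073, L = 0.096,
         M = 0.021, N = 0.061, P = 0.044, Q = 0.039, R = 0.044,
         S = 0.090, T = 0.059, V = 0.056, W = 0.010, Y = 0.034)
  f / sum(f)
}

sample_lengths <- function(n, length_mean, length_min) {
  length_min + rgeom(n, 1 / (length_mean - length_min))
}

# draw residues from `background`, optionally excluding one residue
draw_residues <- function(n, background, exclude = NULL) {
  p <- background
  if (!is.null(exclude)) p <- p[setdiff(names(p), exclude)]
  sample(names(p), n, replace = TRUE, prob = p)
}

random_sequences <- function(lengths, background) {
  body_len <- lengths - 1L
  pool <- draw_residues(sum(body_len), background)
  ends <- cumsum(body_len)
  starts <- ends - body_len + 1L
  vapply(seq_along(lengths), function(i) {
    paste0("M", paste(pool[starts[i]:ends[i]], collapse = ""))
  }, character(1))
}

set_position2 <- function(seqs, idx, residue, prob, background) {
  hit <- runif(length(idx)) < prob
  repl <- ifelse(hit, residue,
                 draw_residues(length(idx), background, exclude = residue))
  substr(seqs[idx], 2, 2) <- repl
  seqs
}

#' Simulate a proteome with planted GO-group position-2 biases
#'
#' Generates `n_proteins` sequences (initiator methionine at position 1,
#' remaining residues i.i.d. from `background`), plants a position-2 residue
#' bias inside designated, mutually disjoint GO groups, and emits matching
#' GO annotations (each planted group is one term; decoy terms annotate
#' random protein sets). The returned truth table records the requested and
#' realized planted frequencies.
#'
#' @param n_proteins Number of proteins.
#' @param planted A data frame with columns `term_id`, `residue`,
#'   `prob` (target position-2 frequency) and `n_proteins` (group size), or
#'   `NULL` for a null proteome.
#' @param background Named residue probability vector
#'   (default [yeast_background_frequencies()]).
#' @param n_decoy_terms Number of unplanted decoy GO terms.
#' @param length_mean,length_min Geometric length model (means and floor) of
#'   the simulated proteins.
#' @param domain GO domain label given to the emitted annotations.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `proteome` (`nterm_proteome`), `annotations`
#'   (`nterm_go` tibble) and `truth`.
#' @export
simulate_proteome <- function(n_proteins = 1000, planted = NULL,
                              background = yeast_background_frequencies(),
                              n_decoy_terms = 20, length_mean = 450,
                              length_min = 30, domain = "component",
                              seed = 1) {
  if (!is.null(planted)) {
    planted <- tibble::as_tibble(planted)
    if (any(planted$prob < 0 | planted$prob > 1)) abort("planted prob outside [0, 1]")
    if (sum(planted$n_proteins) > n_proteins) {
      abort("planted groups exceed the proteome size")
    }
  }
  with_local_seed(seed, {
    acc <- sprintf("SYN%05d", seq_len(n_proteins))
    seqs <- random_sequences(sample_lengths(n_proteins, length_mean, length_min),
                             background)
    ann <- list()
    truth_rows <- list()
    nxt <- 1L
    if (!is.null(planted)) {
      for (i in seq_len(nrow(planted))) {
        idx <- seq(nxt, length.out = planted$n_proteins[i])
        nxt <- nxt + planted$n_proteins[i]
        seqs <- set_position2(seqs, idx, planted$residue[i], planted$prob[i],
                              background)
        ann[[length(ann) + 1L]] <- tibble::tibble(
          domain = domain, term_id = planted$term_id[i],
          term_name = planted$term_id[i], accession = acc[idx])
        truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
          term_id = planted$term_id[i], residue = planted$residue[i],
          prob = planted$prob[i], n_proteins = planted$n_proteins[i],
          realized_count = sum(substr(seqs[idx], 2, 2) == planted$residue[i]))
      }
    }
    for (d in seq_len(n_decoy_terms)) {
      size <- sample(10:50, 1)
      ann[[length(ann) + 1L]] <- tibble::tibble(
        domain = domain, term_id = sprintf("GO:D%04d", d),
        term_name = sprintf("decoy %d", d),
        accession = sample(acc, min(size, n_proteins)))
    }
    annotations <- dplyr::bind_rows(ann)
    if (nrow(annotations)) {
      annotations <- structure(annotations,
                               class = c("nterm_go", class(annotations)))
    }
    list(
      proteome = as_proteome(tibble::tibble(accession = acc, sequence = seqs)),
      annotations = annotations,
      truth = list(seed = seed, background = background,
                   planted = dplyr::bind_rows(truth_rows))
    )
  })
}

#' Simulate an MTS cohort, pseudo-species proteomes and ortholog groups
#'
#' Builds a proteome containing `n_mts` MTS-bearing precursors (position-2
#' residue drawn from the NatC-type class with probability `natc_frac`,
#' arginine planted with probability `arg_prob` at `arg_positions`),
#' `n_mito_no_mts` mitochondrial proteins without MTS, and `n_other`
#' background proteins. For each of `n_species` pseudo-species an ortholog
#' proteome is derived by point substitution (`substitution_prob` per
#' residue from position 3 on) while the position-2 residue is retained with
#' probability `retention_prob`; an ortholog-group table links them.
#'
#' @param n_mts,n_mito_no_mts,n_other Cohort sizes.
#' @param natc_frac Probability that an MTS position-2 residue comes from
#'   \{L, F, I, W\} (drawn within the class proportionally to the
#'   background).
#' @param arg_positions,arg_prob Positions and per-position probability of
#'   the planted arginine enrichment in MTS members.
#' @param n_species Number of pseudo-species (>= 1).
#' @param retention_prob Probability an ortholog keeps the source
#'   position-2 residue.
#' @param substitution_prob Per-residue substitution probability from
#'   position 3 onwards.
#' @param background Named residue probability vector.
#' @param length_mean,length_min Length model.
#' @param seed Integer seed.
#' @return A list with `proteome`, `mito` (annotation table),
#'   `species_proteomes` (named list), `groups` (`nterm_orthogroups`) and
#'   `truth`.
#' @export
simulate_mts_cohort <- function(n_mts = 361, n_mito_no_mts = 365,
                                n_other = 5000, natc_frac = 0.6,
                                arg_positions = 3:20, arg_prob = 0.2,
                                n_species = 3, retention_prob = 0.9,
                                substitution_prob = 0.05,
                                background = yeast_background_frequencies(),
                                length_mean = 450, length_min = 30,
                                seed = 1) {
  if (n_species < 1) abort("n_species must be >= 1")
  with_local_seed(seed, {
    n_total <- n_mts + n_mito_no_mts + n_other
    acc <- sprintf("SYN%05d", seq_len(n_total))
    seqs <- random_sequences(sample_lengths(n_total, length_mean, length_min),
                             background)
    mts_idx <- seq_len(n_mts)
    # position-2 class mix
    natc <- c("L", "F", "I", "W")
    in_class <- runif(n_mts) < natc_frac
    p_natc <- background[natc] / sum(background[natc])
    r2 <- character(n_mts)
    r2[in_class] <- sample(natc, sum(in_class), replace = TRUE, prob = p_natc)
    r2[!in_class] <- draw_residues(sum(!in_class), background, exclude = natc)
    substr(seqs[mts_idx], 2, 2) <- r2
    # arginine enrichment at the planted positions
    for (pos in arg_positions) {
      covered <- mts_idx[nchar(seqs[mts_idx]) >= pos]
      hit <- runif(length(covered)) < arg_prob
      repl <- ifelse(hit, "R", draw_residues(length(covered), background, exclude = "R"))
      substr(seqs[covered], pos, pos) <- repl
    }
    mito <- tibble::tibble(
      accession = acc[seq_len(n_mts + n_mito_no_mts)],
      is_mito = TRUE,
      has_mts = c(rep(TRUE, n_mts), rep(FALSE, n_mito_no_mts)),
      compartment = sample(c("matrix", "inner_membrane", "outer_membrane",
                             "intermembrane_space"),
                           n_mts + n_mito_no_mts, replace = TRUE))
    proteome <- as_proteome(tibble::tibble(accession = acc, sequence = seqs),
                            species_tag = "source")
    species_tags <- sprintf("sp%02d", seq_len(n_species))
    species_proteomes <- list()
    group_cols <- list(sc_accession = acc)
    for (s in seq_along(species_tags)) {
      tag <- species_tags[s]
      orth_acc <- sprintf("%s_%05d", toupper(tag), seq_len(n_total))
      orth_seq <- vapply(seq_len(n_total), function(i) {
        chars <- strsplit(seqs[i], "")[[1]]
        L <- length(chars)
        if (L >= 2 && runif(1) >= retention_prob) {
          chars[2] <- draw_residues(1, background)
        }
        if (L >= 3) {
          sub <- which(runif(L - 2) < substitution_prob) + 2L
          if (length(sub)) chars[sub] <- draw_residues(length(sub), background)
        }
        paste(chars, collapse = "")
      }, character(1))
      species_proteomes[[tag]] <- as_proteome(
        tibble::tibble(accession = orth_acc, sequence = orth_seq),
        species_tag = tag)
      group_cols[[tag]] <- orth_acc
    }
    groups_wide <- tibble::as_tibble(group_cols)
    groups <- tidyr::pivot_longer(groups_wide, -"sc_accession",
                                  names_to = "species", values_to = "ortholog") |>
      dplyr::mutate(n_listed = 1L)
    groups <- structure(groups, species_tags = species_tags,
                        class = c("nterm_orthogroups", class(groups)))
    list(proteome = proteome, mito = mito,
         species_proteomes = species_proteomes, groups = groups,
         truth = list(seed = seed, natc_frac = natc_frac,
                      arg_prob = arg_prob, arg_positions = arg_positions,
                      retention_prob = retention_prob,
                      substitution_prob = substitution_prob,
                      mts_accessions = acc[mts_idx],
                      realized_natc = mean(substr(seqs[mts_idx], 2, 2) %in% natc)))
  })
}

#' Simulate sel-TRAP bait and reference enrichment tables
#'
#' Per replicate, bait enrichment is `shift * 1[class == planted_class] +
#' Normal(0, noise_sd)`; the reference (canonical-ribosome) enrichment is
#' `Normal(0, reference_sd)`. Gene classes are sampled from `class_probs`.
#'
#' @param n_genes Number of genes.
#' @param class_probs Named probability vector over class labels (must
#'   include `planted_class`).
#' @param planted_class Label receiving the shift.
#' @param shift Planted mean log2 shift.
#' @param noise_sd,reference_sd Gaussian noise standard deviations.
#' @param n_replicates Number of replicates (>= 1).
#' @param seed Integer seed.
#' @return A list with `bait` and `reference` (tibbles `gene_id`,
#'   `replicate`, `log2_ratio`) and `truth` (per-gene classes and planted
#'   flags).
#' @export
simulate_seltrap <- function(n_genes = 1000,
                             class_probs = c(ML = 0.05, other = 0.95),
                             planted_class = "ML", shift = 1.5,
                             noise_sd = 0.5, reference_sd = 0.1,
                             n_replicates = 2, seed = 1) {
  if (!planted_class %in% names(class_probs)) {
    abort("planted_class must appear among the class labels")
  }
  with_local_seed(seed, {
    gene_id <- sprintf("GENE%05d", seq_len(n_genes))
    cls <- sample(names(class_probs), n_genes, replace = TRUE, prob = class_probs)
    bait <- purrr::map_dfr(seq_len(n_replicates), function(r) {
      tibble::tibble(gene_id = gene_id, replicate = r,
                     log2_ratio = shift * (cls == planted_class) +
                       rnorm(n_genes, 0, noise_sd))
    })
    reference <- purrr::map_dfr(seq_len(n_replicates), function(r) {
      tibble::tibble(gene_id = gene_id, replicate = r,
                     log2_ratio = rnorm(n_genes, 0, reference_sd))
    })
    list(bait = bait, reference = reference,
         truth = tibble::tibble(gene_id = gene_id, class = cls,
                                planted = cls == planted_class))
  })
}

#' Generate a synthetic curated-mitochondrial annotation table
#'
#' Emulates the structure of a curated mitochondrial protein table:
#' `n_mito` curated proteins of which the first `n_mts` are MTS-flagged,
#' with deterministic synthetic accessions (`SYNMT0001`, ...).
#'
#' @param n_mito Number of curated mitochondrial proteins (default 726).
#' @param n_mts Number of MTS-flagged proteins (default 361).
#' @param seed Integer seed (controls only the compartment labels).
#' @return A tibble with `accession`, `is_mito`, `has_mts`, `compartment`.
#' @export
simulate_mito_table <- function(n_mito = 726, n_mts = 361, seed = 1) {
  stopifnot(n_mts <= n_mito)
  with_local_seed(seed, {
    tibble::tibble(
      accession = sprintf("SYNMT%04d", seq_len(n_mito)),
      is_mito = TRUE,
      has_mts = c(rep(TRUE, n_mts), rep(FALSE, n_mito - n_mts)),
      compartment = sample(c("matrix", "inner_membrane", "outer_membrane",
                             "intermembrane_space"), n_mito, replace = TRUE)
    )
  })
}
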