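write_fasta_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("FASTA proteomes parse, flag exclusions and reject bad input", {
  f <- write_fasta_lines(c(">sp|P1|A", "MSTAAA", ">sp|P2|B", "MLRTPT"))
  p <- read_fasta_proteome(f)
  expect_equal(nrow(p), 2)
  expect_equal(p$accession, c("P1", "P2"))
  expect_equal(substr(p$sequence, 2, 2), c("S", "L"))
  expect_equal(p$nterm_key, c("MSTAAA", "MLRTPT"))

  p2 <- read_fasta_proteome(f, exclusion_ids = "P2")
  expect_equal(sum(!p2$is_excluded), 1)

  fd <- write_fasta_lines(c(">sp|P1|A", "MSTAAA", ">sp|P1|A", "MLRTPT"))
  expect_error(read_fasta_proteome(fd), "P1")
  fe <- write_fasta_lines(character())
  expect_error(read_fasta_proteome(fe), "no FASTA")
  expect_error(
    as_proteome(data.frame(accession = "P1", sequence = "MST8AA")),
    "non-amino-acid")
})

test_that("row order of the FASTA never changes downstream results", {
  lines1 <- c(">A1", "MSTAAAGGGG", ">A2", "MLDERTYAAA", ">A3", "MSQQPLMNAA")
  lines2 <- lines1[c(5, 6, 1, 2, 3, 4)]
  p1 <- read_fasta_proteome(write_fasta_lines(lines1))
  p2 <- read_fasta_proteome(write_fasta_lines(lines2))
  b1 <- position_bias_table(position_profile(p1, 5), background_frequencies(p1))
  b2 <- position_bias_table(position_profile(p2, 5), background_frequencies(p2))
  expect_equal(tibble::as_tibble(b1), tibble::as_tibble(b2))
  expect_equal(nterm_dedup(p1), nterm_dedup(p2))
})

test_that("N-terminal dedup groups identical prefixes deterministically", {
  p <- as_proteome(data.frame(
    accession = c("B", "A", "C"),
    sequence = c("MSTAAAXXXXQQ", "MSTAAAXXXX", "MSTAAAXXXY")))
  dd <- nterm_dedup(p)
  expect_equal(dd$dedup_id[dd$accession %in% c("A", "B")], c("A", "A"))
  expect_equal(dplyr::n_distinct(dd$dedup_id), 2)

  # 50 random proteins with 5 planted prefix-duplicates -> 45 groups,
  # verified against brute-force prefix comparison
  set.seed(7)
  base <- toy_proteome(sample(c("S", "L", "D"), 50, replace = TRUE))
  seqs <- base$sequence
  seqs[46:50] <- paste0(substr(seqs[1:5], 1, 10), "KKK")
  p50 <- as_proteome(tibble::tibble(accession = base$accession, sequence = seqs))
  dd50 <- nterm_dedup(p50)
  expect_equal(dplyr::n_distinct(dd50$dedup_id),
               length(unique(substr(seqs, 1, 10))))
  expect_equal(dplyr::n_distinct(dd50$dedup_id), 45)
})

test_that("positional profiles count only covering, canonical residues", {
  p <- as_proteome(data.frame(accession = c("a", "b"), sequence = c("MST", "MLD")))
  prof <- position_profile(p, 3)
  at2 <- dplyr::filter(prof, position == 2)
  expect_equal(at2$count[at2$residue %in% c("S", "L")], c(1, 1))
  expect_equal(unique(at2$n_at_position), 2)

  # a protein too short for the position drops out of the denominator
  p2 <- as_proteome(data.frame(accession = c("a", "b"),
                               sequence = c("MST", "MLDERT")))
  prof2 <- position_profile(p2, 4)
  expect_equal(unique(prof2$n_at_position[prof2$position == 4]), 1)

  # ambiguity codes are excluded from numerator and denominator
  p3 <- as_proteome(data.frame(accession = c("a", "b", "c"),
                               sequence = c("MXT", "MLD", "MSD")))
  at2x <- dplyr::filter(position_profile(p3, 2), position == 2)
  expect_equal(unique(at2x$n_at_position), 2)
  expect_equal(sum(at2x$count), 2)

  # conservation: counts always sum to n_at_position
  set.seed(11)
  sim <- simulate_proteome(n_proteins = 120, seed = 3)
  profs <- position_profile(sim$proteome, 30)
  sums <- dplyr::summarise(dplyr::group_by(profs, position),
                           s = sum(count), n = unique(n_at_position))
  expect_equal(sums$s, sums$n)
  expect_error(position_profile(p[0, ], 2), "non-excluded")
})

test_that("planted position-2 frequencies are recovered within binomial noise", {
  sim <- simulate_proteome(
    n_proteins = 1000,
    planted = data.frame(term_id = "GO:S", residue = "S",
                         prob = 0.25, n_proteins = 1000),
    seed = 5)
  prof <- position_profile(sim$proteome, 2)
  f <- prof$freq[prof$position == 2 & prof$residue == "S"]
  se <- sqrt(0.25 * 0.75 / 1000)
  expect_lt(abs(f - 0.25), 3 * se)
})

test_that("background frequencies pool all residues of all proteins", {
  p1 <- as_proteome(data.frame(accession = "a", sequence = "MMMM"))
  bg1 <- background_frequencies(p1)
  expect_equal(bg1$freq[bg1$residue == "M"], 1)
  p2 <- as_proteome(data.frame(accession = c("a", "b"), sequence = c("MA", "MG")))
  bg <- background_frequencies(p2)
  expect_equal(bg$freq[match(c("M", "A", "G"), bg$residue)], c(0.5, 0.25, 0.25))
  expect_equal(sum(bg$freq), 1, tolerance = 1e-12)

  # simulated proteome recovers the generating table within 3 SD per residue
  want <- yeast_background_frequencies()
  sim <- simulate_proteome(n_proteins = 400, seed = 9)
  got <- background_frequencies(sim$proteome)
  total <- attr(got, "total")
  # position 1 is always M, a small known distortion; exclude M from the check
  for (r in setdiff(names(want), "M")) {
    se <- sqrt(want[[r]] * (1 - want[[r]]) / total)
    expect_lt(abs(got$freq[got$residue == r] - want[[r]]), 3 * se + 1e-3)
  }
})

test_that("GAF parsing honours qualifiers, aspects and the proteome", {
  gaf <- withr::local_tempfile(fileext = ".gaf")
  row <- function(acc, term, aspect, qual = "") {
    paste(c("SGD", acc, "GENE", qual, term, "PMID:1", "IDA", "", aspect,
            "", "", "protein", "taxon:559292", "20230101", "SGD", "", ""),
          collapse = "\t")
  }
  writeLines(c("!gaf-version: 2.2",
               row("P1", "GO:0005739", "C"),
               row("P2", "GO:0005739", "C"),
               row("P2", "GO:0005739", "C"),          # duplicate pair
               row("P1", "GO:0006412", "P"),
               row("P3", "GO:0005739", "C", "NOT|located_in"),
               row("PX", "GO:0005739", "C")), gaf)
  prot <- toy_proteome(c("S", "L", "D"))
  prot$accession <- c("P1", "P2", "P3")
  expect_warning(ann <- read_gaf(gaf, prot), "1 annotation")
  comp <- dplyr::filter(ann, domain == "component")
  expect_setequal(comp$accession, c("P1", "P2"))   # NOT row and PX dropped
  expect_equal(nrow(comp), 2)                      # duplicate collapsed
  expect_equal(dplyr::filter(ann, domain == "process")$accession, "P1")

  bad <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c("!gaf", "onlyonecolumn"), bad)
  expect_error(read_gaf(bad), "malformed|columns")
})

test_that("ortholog group tables parse with coverage and guard rails", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sc_accession\tsp1\tsp2\tsp3",
               "YAL001C\tA1\tB1\tC1",
               "YAL002W\tA2\t\tC2,C9"), tsv)
  g <- read_ortholog_groups(tsv)
  expect_equal(attr(g, "species_tags"), c("sp1", "sp2", "sp3"))
  cov <- orthogroup_coverage(g)
  expect_equal(sort(cov$n_species), c(2, 3))
  # first-listed ortholog is used; multiplicity recorded
  expect_equal(g$ortholog[g$sc_accession == "YAL002W" & g$species == "sp3"], "C2")
  expect_equal(g$n_listed[g$sc_accession == "YAL002W" & g$species == "sp3"], 2L)

  empty_row <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sc_accession\tsp1", "YAL003W\t"), empty_row)
  cov0 <- orthogroup_coverage(read_ortholog_groups(empty_row))
  expect_equal(cov0$n_species, 0)

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sc_accession\tsp1", "YAL001C\tA1", "YAL001C\tA9"), dup)
  expect_error(read_ortholog_groups(dup), "YAL001C")
})
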