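make_records <- function(means, classes, has_mts = NULL) {
  out <- tibble::tibble(
    gene_id = sprintf("G%04d", seq_along(means)),
    mean_enrichment = means,
    n_replicates = 2L,
    nterm_class = classes)
  if (!is.null(has_mts)) {
    out$has_mts <- has_mts
    out$is_mito <- has_mts
    out$residue2 <- ifelse(classes == "ML", "L", "S")
  }
  structure(out, class = c("nterm_enrichment", class(out)))
}

test_that("reference correction subtracts gene- and replicate-matched values", {
  b <- tibble::tibble(gene_id = c("g1", "g1", "g2"), replicate = c(1L, 2L, 1L),
                      log2_ratio = c(2, 1, 0.5))
  r <- tibble::tibble(gene_id = c("g1", "g1", "g3"), replicate = c(1L, 2L, 1L),
                      log2_ratio = c(0.5, 0.25, 9))
  out <- correct_enrichment(b, r)
  expect_equal(out$log2_ratio, c(1.5, 0.75))
  expect_equal(attr(out, "n_dropped"), 2L)
  expect_equal(correct_enrichment(b, b)$log2_ratio, c(0, 0, 0))
  expect_error(correct_enrichment(b, dplyr::mutate(r, gene_id = "zz")), "share")

  # random tables equal the element-wise subtraction oracle
  set.seed(6)
  genes <- sprintf("g%03d", 1:50)
  b2 <- tidyr::expand_grid(gene_id = genes, replicate = 1:2) |>
    dplyr::mutate(log2_ratio = rnorm(100))
  r2 <- dplyr::mutate(b2, log2_ratio = rnorm(100))
  got <- correct_enrichment(b2, r2) |> dplyr::arrange(gene_id, replicate)
  want <- dplyr::arrange(b2, gene_id, replicate)$log2_ratio -
    dplyr::arrange(r2, gene_id, replicate)$log2_ratio
  expect_equal(got$log2_ratio, want)
})

test_that("replicate combination averages complete genes only", {
  x <- tibble::tibble(gene_id = c("g1", "g1", "g2"), replicate = c(1L, 2L, 1L),
                      log2_ratio = c(1.0, 0.6, 5))
  out <- combine_replicates(x)
  expect_equal(out$gene_id, "g1")
  expect_equal(out$mean_enrichment, 0.8)
  expect_equal(attr(out, "n_dropped_incomplete"), 1L)

  set.seed(2)
  sim <- simulate_seltrap(n_genes = 100, seed = 9)
  corrected <- correct_enrichment(sim$bait, sim$reference)
  comb <- combine_replicates(corrected)
  want <- tapply(corrected$log2_ratio, corrected$gene_id, mean)
  expect_equal(comb$mean_enrichment, as.numeric(want[comb$gene_id]))
})

test_that("annotation columns join from the proteome and mito table", {
  prot <- toy_proteome(c("L", "S"))
  mito <- tibble::tibble(accession = prot$accession[1], is_mito = TRUE,
                         has_mts = TRUE, compartment = "matrix")
  x <- tibble::tibble(gene_id = rep(prot$accession, 2),
                      replicate = rep(1:2, each = 2),
                      log2_ratio = c(1, 0, 1, 0))
  out <- combine_replicates(x, proteome = prot, mito = mito)
  expect_equal(as.character(out$nterm_class),
               c("natc_type", "metap_type")[match(out$gene_id, prot$accession)])
  expect_equal(out$has_mts, out$gene_id == prot$accession[1])
})

test_that("the threshold sweep reduces to background at the grid minimum", {
  set.seed(10)
  means <- runif(400, -1, 2)   # all above the grid minimum of -3
  classes <- sample(c("ML", "MS", "MD"), 400, replace = TRUE,
                    prob = c(0.2, 0.5, 0.3))
  sw <- threshold_sweep(make_records(means, classes))
  first <- dplyr::filter(sw, threshold == min(threshold))
  bg <- table(classes) / length(classes)
  expect_equal(first$proportion, unname(as.vector(bg[first$class])))
  expect_identical(first$hgt, rep(0, nrow(first)))

  # n(t) is non-increasing and class counts partition each selection
  n_by_t <- dplyr::distinct(sw, threshold, n_selected)
  expect_true(all(diff(n_by_t$n_selected) <= 0))
  sums <- dplyr::summarise(dplyr::group_by(sw, threshold), s = sum(k),
                           n = unique(n_selected))
  expect_equal(sums$s, sums$n)
  # thresholds beyond every value give empty selections flagged as NA
  tail_rows <- dplyr::filter(sw, threshold > max(means))
  expect_true(all(is.na(tail_rows$proportion)))
})

test_that("target calling applies an inclusive threshold", {
  rec <- make_records(c(0.79, 0.80, 0.81), rep("ML", 3))
  expect_equal(nrow(call_targets(rec, 0.8)), 2)
  expect_equal(nrow(call_targets(rec, 5)), 0)
  set.seed(3)
  rec2 <- make_records(rnorm(200), sample(c("a", "b"), 200, TRUE))
  expect_equal(call_targets(rec2, 0.4)$gene_id,
               rec2$gene_id[rec2$mean_enrichment >= 0.4])
})

test_that("composition reports recover planted target structure", {
  # targets drawn 50% from the MTS class against a 6% background
  set.seed(8)
  n <- 2000
  has_mts <- runif(n) < 0.06
  means <- rnorm(n, 0, 0.3)
  rec <- make_records(means, ifelse(has_mts, "ML", "MS"), has_mts = has_mts)
  target_idx <- c(sample(which(has_mts), 100, replace = TRUE),
                  sample(which(!has_mts), 100))
  target_idx <- unique(target_idx)[1:150]
  tg <- rec[target_idx, ]
  rep_out <- composition_report(rec, tg)
  mts_row <- dplyr::filter(rep_out, category == "mts_status", level == "mts")
  expect_gt(mts_row$fraction_targets, 0.2)
  expect_gt(mts_row$hgt, 10)
  expect_equal(mts_row$hgt,
               oracle_hgt(mts_row$k, mts_row$K, mts_row$n, mts_row$N),
               tolerance = 1e-6 * max(1, mts_row$hgt))

  # targets = all records: every fraction equals background, all scores zero
  full <- composition_report(rec, rec)
  expect_equal(full$fraction_targets, full$fraction_background)
  expect_true(all(full$hgt == 0))
  expect_error(composition_report(rec[1:10, ], rec), "subset")
})

test_that("mass-spec partner filtering applies the score rules per replicate", {
  tagged <- tibble::tibble(
    protein_id = c("kept", "ctrl_hi", "low_ratio", "weak", "kept"),
    bait = "NatC",
    replicate = c(1L, 1L, 1L, 1L, 2L),
    score = c(300, 300, 400, 200, 400))
  control <- tibble::tibble(protein_id = c("ctrl_hi", "low_ratio"),
                            score = c(260, 210))
  out <- filter_ms_partners(tagged, control)
  v <- setNames(out$records$verdict, paste(out$records$protein_id,
                                           out$records$replicate))
  expect_equal(unname(v["kept 1"]), "kept")
  expect_equal(unname(v["ctrl_hi 1"]), "excluded_control")
  expect_equal(unname(v["low_ratio 1"]), "excluded_ratio")
  expect_equal(unname(v["weak 1"]), "below_cutoff")
  # 'kept' passes in both replicates -> reproducible partner
  expect_equal(out$partners$protein_id, "kept")
})

test_that("cross-bait specificity requires a five-fold score margin", {
  tagged <- tibble::tibble(
    protein_id = rep(c("spec", "shared"), each = 2),
    bait = rep(c("NatC", "NatA"), 2),
    replicate = 1L,
    score = c(2000, 300, 600, 400))
  out <- filter_ms_partners(tagged, tibble::tibble(protein_id = character(),
                                                   score = numeric()))
  sp <- setNames(out$specificity$assignment, out$specificity$protein_id)
  expect_equal(unname(sp["spec"]), "NatC")     # 2000 >= 5 x 300
  expect_equal(unname(sp["shared"]), "shared") # 600 < 5 x 400
})

test_that("a planted class shift is recovered by the sweep", {
  hits <- 0L
  for (seed in 1:4) {
    sim <- simulate_seltrap(
      n_genes = 1000,
      class_probs = c(ML = 0.05, MS = 0.45, MD = 0.25, MA = 0.25),
      planted_class = "ML", shift = 1.5, noise_sd = 0.5, seed = 300 + seed)
    rec <- combine_replicates(correct_enrichment(sim$bait, sim$reference))
    rec$nterm_class <- sim$truth$class[match(rec$gene_id, sim$truth$gene_id)]
    sw <- threshold_sweep(rec)
    peak <- glance(sw)
    hits <- hits + (peak$class[which.max(peak$peak_hgt)] == "ML")
  }
  expect_equal(hits, 4L)
})
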