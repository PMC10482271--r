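#' Analysis configuration
#'
#' Collects every numeric threshold used by the scanning, selection and
#' enrichment analyses in one auditable place. Defaults follow the published
#' analysis of the S. cerevisiae N-terminome.
#'
#' @param hgt_screen_min Minimum signed HGT score for a (GO term, residue)
#'   pair to be retained by [screen_go_terms()] (strict `>`). Default 4,
#'   i.e. hypergeometric p < 1e-4.
#' @param fold_change_min Minimum position-2 fold change (observed over
#'   proteome frequency) for a screened term to survive
#'   [filter_generic_terms()] (inclusive `>=`). Default 1.8.
#' @param bestN_overlap_max Maximum pairwise protein-set overlap
#'   (`|A & B| / min(|A|, |B|)`) tolerated between selected BestN terms.
#'   Default 0.40.
#' @param bestF_containment_min Minimum containment (`|F & B| / |F|`) of a
#'   BestF candidate in its BestN parent. Default 0.40.
#' @param bestF_overlap_max Maximum overlap tolerated among accepted BestF
#'   terms. Default 0.30.
#' @param bestF_bias_gain Minimum ratio of a BestF candidate's best fold
#'   change to its parent's. Default 1.30.
#' @param aspecificity_window Sliding-window length (positions) for the
#'   aspecificity score. Default 100.
#' @param aspecificity_span Number of leading proteome positions scanned by
#'   the aspecificity score. Default 500.
#' @param aspecificity_exclude Positions excluded from the aspecificity scan;
#'   defaults to 1:2 (position 1 is the constant initiator methionine and
#'   position 2 is the tested position itself).
#' @param sweep_min,sweep_max,sweep_step Enrichment-threshold grid for
#'   [threshold_sweep()]: defaults -3 to +4 in steps of 0.1.
#' @param target_threshold Mean corrected enrichment at or above which a gene
#'   is called a target. Default 0.8.
#' @param mascot_cutoff Minimum Mascot score for a mass-spec partner
#'   (strict `>`). Default 250.
#' @param mascot_ratio_min Minimum tagged/control Mascot score ratio.
#'   Default 2.
#' @param mascot_specificity_fold Fold difference in Mascot score assigning a
#'   shared partner as specific to one bait. Default 5.
#' @param dedup_prefix_len N-terminal prefix length used to collapse proteins
#'   sharing the same N-terminus. Default 10.
#'
#' @return A list of class `nterm_config`.
#' @examples
#' cfg <- nterm_config()
#' cfg$hgt_screen_min
#' @export
nterm_config <- function(hgt_screen_min = 4,
                         fold_change_min = 1.8,
                         bestN_overlap_max = 0.40,
                         bestF_containment_min = 0.40,
                         bestF_overlap_max = 0.30,
                         bestF_bias_gain = 1.30,
                         aspecificity_window = 100,
                         aspecificity_span = 500,
                         aspecificity_exclude = c(1L, 2L),
                         sweep_min = -3.0,
                         sweep_max = 4.0,
                         sweep_step = 0.1,
                         target_threshold = 0.8,
                         mascot_cutoff = 250,
                         mascot_ratio_min = 2,
                         mascot_specificity_fold = 5,
                         dedup_prefix_len = 10L) {
  cfg <- list(
    hgt_screen_min = hgt_screen_min,
    fold_change_min = fold_change_min,
    bestN_overlap_max = bestN_overlap_max,
    bestF_containment_min = bestF_containment_min,
    bestF_overlap_max = bestF_overlap_max,
    bestF_bias_gain = bestF_bias_gain,
    aspecificity_window = as.integer(aspecificity_window),
    aspecificity_span = as.integer(aspecificity_span),
    aspecificity_exclude = as.integer(aspecificity_exclude),
    sweep_min = sweep_min,
    sweep_max = sweep_max,
    sweep_step = sweep_step,
    target_threshold = target_threshold,
    mascot_cutoff = mascot_cutoff,
    mascot_ratio_min = mascot_ratio_min,
    mascot_specificity_fold = mascot_specificity_fold,
    dedup_prefix_len = as.integer(dedup_prefix_len)
  )
  num <- unlist(cfg[setdiff(names(cfg), c("sweep_min", "aspecificity_exclude"))])
  if (any(!is.finite(num)) || any(num <= 0)) {
    abort("all configuration thresholds must be finite and positive")
  }
  if (cfg$sweep_min >= cfg$sweep_max) abort("sweep_min must be < sweep_max")
  frac <- c(cfg$bestN_overlap_max, cfg$bestF_containment_min,
            cfg$bestF_overlap_max, cfg$target_threshold)
  if (any(frac[1:3] > 1)) abort("overlap/containment thresholds must lie in (0, 1]")
  if (cfg$aspecificity_window > cfg$aspecificity_span) {
    abort("aspecificity_window must not exceed aspecificity_span")
  }
  structure(cfg, class = "nterm_config")
}

#' @export
print.nterm_config <- function(x, ...) {
  cat("<nterm_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
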