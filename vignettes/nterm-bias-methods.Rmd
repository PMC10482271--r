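---
title: "Methods: statistical mapping of N-terminal residue usage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistical mapping of N-terminal residue usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntermatlas)
library(dplyr)
```

## The question and the statistic

The residue at position 2 of a protein — the one immediately after the
initiator methionine (iMet) — decides much of the protein's early fate:
small-radius residues (A, C, G, P, S, T, V) trigger iMet removal by
methionine aminopeptidase and expose a NatA-type N-terminus; D, E, N and Q
retain the iMet and define NatB-type substrates; the large hydrophobic
residues L, F, I and W retain the iMet and define NatC-type substrates.
`ntermatlas` asks whether groups of proteins that share a function, a
compartment or a targeting signal also share a *statistical preference* for
particular residues at this position, and whether that preference is
confined to position 2 or spread along the N-terminal region.

Every comparison in the package is scored with the same statistic, the
**signed HGT score**. For an observed count $k$ of a residue among $n$
sampled proteins, against a background of $K$ occurrences among $N$, the
one-sided hypergeometric tail $p$ is computed and reported as

$$\mathrm{HGT} = \pm\,|\log_{10} p|,$$

positive when $k/n \ge K/N$ (upper tail, over-representation) and negative
otherwise (lower tail, under-representation). A score of 3 corresponds to
$p = 10^{-3}$. Proteome-scale biases can be extreme — a quarter of a
proteome carrying one residue at one position yields $p$-values around
$10^{-268}$, far below the smallest positive double — so all tails are
computed in log space (`stats::phyper(log.p = TRUE)`); scores of magnitude
260 and beyond remain finite and accurate, which the test suite verifies
against independent PMF-enumeration oracles to 1e-9 (absolute, exhaustive
for all urns with $N \le 60$) and 1e-6 (relative, random large urns).

Two background constructions are used, and it matters which one applies:

* **Pooled-residue background** (`position_bias_table()`): the usage of a
  residue at position 2 is compared with its average usage anywhere in the
  proteome ($F_{mean}$). The background frequency is materialised as a
  finite urn whose population is the pool of all residues of all analysed
  proteins ($N$ = total residue count, $K$ = the residue's pooled count).
  This keeps a single hypergeometric family instead of introducing a
  binomial special case.
* **Positional background** (`positional_hgt_matrix()` and everything built
  on it): a protein subset is compared with a reference proteome *at the
  same position*; the urn is the set of reference proteins that cover the
  position with a canonical residue.

Ties ($F_{obs} = F_{ref}$) are scored on the upper tail with a positive
sign. Raw scores are reported without multiple-testing correction; the
screening threshold (HGT > 4) is deliberately strict instead.

## Aspecificity: is the bias really about position 2?

A residue can be frequent at position 2 simply because it is frequent in
some broader N-terminal context. The **aspecificity score** quantifies
this. From $F_2$ (frequency at position 2) and $F_{mean}$ a reference

$$F_{2ref} = \begin{cases} 0.9\,F_2 & F_2 > F_{mean}\\ 1.1\,F_2 & F_2 \le F_{mean}\end{cases}$$

is derived, and a window of 100 consecutive analysed positions slides over
the first 500 proteome positions. The local score of a window is the
percentage of its positions whose frequency crosses $F_{2ref}$ (exceeds it
for over-represented residues, stays at or below it for under-represented
ones — the `<=` convention is used for the second branch); the reported
aspecificity is the maximum local score. 0% means no 100-position stretch
of the proteome ever mimics the position-2 usage: the bias is strictly
positional.

Positions 1 and 2 are excluded from the scan by default
(`aspecificity_exclude`): position 1 is the constant iMet and position 2 is
the tested position itself, so including either would only dilute the
score. Positions covered by no protein are dropped and the window
denominator shrinks accordingly; if fewer than 100 analysed positions
remain, a single window over all of them is used.

## The GO scan and BestN/BestF reduction

`build_go_contingency()` counts, for every GO term of one domain, the
proteins carrying each residue at position 2. Counting is done on
**deduplicated identifiers**: proteins sharing their first 10 residues
(`dedup_prefix_len`) collapse to one representative — the lexicographically
smallest accession, a deterministic choice — so a recently expanded paralog
family with one shared N-terminus counts once, not twenty times. The
proteome margins $K$ and $N$ use the same deduplicated universe, and
annotations are never propagated along the GO hierarchy (an intentionally
annotation-driven, topology-free design).

Screening keeps (term, residue) pairs with HGT > 4; a second filter removes
entries with fold change below 1.8 (boundary inclusive: exactly 1.8
passes), which in practice removes very large generic terms whose sheer
size makes small biases significant. The surviving list is still highly
redundant, and the reduction works on the protein sets themselves rather
than on GO topology:

1. **BestN** (coverage pass): iteratively select the admissible term
   covering the most not-yet-covered *bias proteins* (deduplicated members
   carrying a qualifying residue at position 2). A term is admissible if
   its overlap with every selected BestN — $|A \cap B| / \min(|A|, |B|)$ —
   stays below 40%. Selection stops when no admissible term adds a new
   bias protein. Ties break on coverage gain, then HGT, then smaller term
   size, then term id; the chain makes the whole selection a deterministic
   function of the input, which the tests verify by permuting input rows.
2. **BestF** (selectivity pass): non-BestN terms contained at $\ge$ 40% in
   a BestN (the maximum-containment BestN becomes the parent) and whose
   best fold change beats the parent's by at least 1.3x. Candidates are
   processed in decreasing fold order; a candidate overlapping an accepted
   BestF by $\ge$ 30% replaces it only when it is enriched for more
   distinct residues (then higher fold, then term id) — otherwise it is
   marked redundant. The 30% overlap rule is applied among accepted BestF
   terms; whether it should also constrain against all larger terms is
   genuinely open, and the narrower reading was chosen because BestN
   redundancy is already handled by the containment rule.

The overlap metric itself ($|A \cap B|$ over the smaller set) and the
interpretation of "frequency bias" as the position-2 fold change of the
term's best residue are design choices the selection procedure needs but
that a verbal description underdetermines; both are fixed here and exposed
in `nterm_config()`. `positional_specificity_check()` closes the loop by
scanning the first 100 positions of a selected term's proteins: the term
is flagged non-specific when any other position reaches the position-2
score for the same residue (a flat, all-zero profile is trivially
specific).

## MTS signatures within and across species

Curated mitochondrial annotation (which proteins are mitochondrial with
high confidence; which carry an N-terminal mitochondrial targeting
sequence, MTS) is an *input*, read from a table — the package never
predicts MTSs. `mts_positional_bias()` contrasts MTS-bearing and MTS-less
precursors with the proteome across positions 1–20: the MTS hallmark is
strong arginine over-representation (and acidic depletion) at positions
3–20, with a hydrophobic NatC-type preference confined to position 2.
`mts_position2_table()` adds the per-class composition (NatC-type /
MetAP-cleaved / NatB-type / other) of the cohort.

For cross-species conservation, ortholog groups transfer the
*S. cerevisiae* MTS set to each species; MTS status is inherited from the
S. cerevisiae member, not re-annotated per species. Each species is scored
against **its own** proteome at the same position (not against the
orthogroup universe), so species-specific composition differences cannot
masquerade as signature loss. When a species lists several orthologs the
first is used and the multiplicity recorded; missing orthologs are skipped
and counted. A pseudo-species that is an exact copy of the source proteome
reproduces the within-species scores bit-identically — a property the test
suite asserts.

## sel-TRAP enrichment analysis

Selective translating-ribosome affinity purification (sel-TRAP) measures,
per gene, log2(IP/input) of mRNAs co-purified with a tagged nascent-chain-
associated factor. The analysis chain is:

1. `correct_enrichment()` — subtract, gene by gene and replicate by
   replicate, the enrichment of the canonical ribosomal bait (Rpl16A-type),
   removing the shared translating-ribosome component.
2. `combine_replicates()` — average; a gene must be present in every
   replicate. Targets are defined on the mean (a per-replicate strict mode
   is a trivial filter away, but the mean matches how the replicate lists
   are validated downstream).
3. `threshold_sweep()` — for every threshold $t$ from −3 to +4 in steps of
   0.1, the proportion and HGT score of each N-terminus class within
   $\{$mean $\ge t\}$. The grid is generated from integer steps to avoid
   floating-point drift; endpoints are inclusive; empty selections yield
   `NA` cells rather than fabricated zeros. The sweep makes the
   composition signal visible without committing to a cutoff; the default
   target threshold of 0.8 is where these curves peak for a specific bait.
4. `call_targets()` (inclusive $\ge$) and `composition_report()` —
   compartments, MTS status, N-terminus classes and position-2 residues
   among MTS targets, each with target fraction, background fraction and
   signed HGT. The background universe is the combined enrichment table
   (genes measured on the array with a defined class), not the whole
   proteome: genes absent from the array could never have been enriched,
   and using them would inflate every score.

`filter_ms_partners()` implements the companion proteomics filter: Mascot
score > 250 in every tagged replicate, control score ≤ 250, tagged/control
ratio ≥ 2 (a protein absent from the control counts as score 0 — absence
of evidence of background is treated as background absence), and a 5-fold
cross-bait margin, computed on per-bait mean replicate scores, for
assigning a shared partner as bait-specific.

## What the synthetic generators emulate — and what they do not

The generators produce data with exactly the statistical structure the
analyses assume, plus machine-readable ground truth:

* `simulate_proteome()` — i.i.d. residues from a documented yeast-like
  background table (uniform available for null tests), iMet fixed at
  position 1, geometric length model (mean 450, floor 30 — typical of a
  yeast proteome), planted position-2 biases inside disjoint GO groups,
  decoy annotations.
* `simulate_mts_cohort()` — position-2 class mix (default 60% NatC-type,
  matching the real cohort's composition), arginine planted at positions
  3–20 (probability 0.2 against a 4.4% background), pseudo-species derived
  by per-residue point substitution with a position-2 retention
  probability.
* `simulate_seltrap()` — planted mean log2 shift (default 1.5, about 3
  noise SDs) on a planted class (default 5% of genes), Gaussian replicate
  noise (SD 0.5) and reference noise (SD 0.1), two replicates — the
  dimensions of a typical two-replicate microarray sel-TRAP experiment.

Each generator uses one seeded RNG stream, restores the global RNG state,
and is byte-reproducible. What they deliberately do **not** model:
phylogenetic covariance or realistic substitution matrices (pseudo-species
are i.i.d. point-mutated copies), codon- or GC-driven residue correlations
along sequences, compositional differences between abundant and rare
proteins, microarray normalisation artefacts, or dependence between GO
terms beyond explicit nesting. Passing recovery tests on these fixtures
therefore shows that the statistics detect what they claim under their own
assumptions — not that real proteomes satisfy those assumptions.

## Numerical choices and degenerate inputs

* All p-values live as log10 values end to end; linear p is only ever
  formed for display and only above 1e-300.
* Ambiguity codes (X, B, Z, J, U, O) are excluded from numerators *and*
  denominators of every count, so per-position counts always sum to the
  number of analysed proteins.
* `-0` from a p = 1 lower tail is normalised to `0`; impossible tails
  (probability exactly zero) return `-Inf` rather than a pseudo-finite
  value.
* Empty proteomes, empty annotation sets, a subset not contained in its
  reference, a species without a loaded proteome, and bait/reference
  tables with no shared genes all raise immediate errors naming the
  offender.

## Problem sizes

The bundled tests and the acceptance script run at desk scale, chosen so
the statistical claims are sharp while the whole suite stays lightweight:
exhaustive tail verification for all urns with $N \le 60$ plus 200 random
urns up to $N = 5\times10^6$; GO recovery on 20 seeded ontologies of 700
proteins with three planted groups (40–50 proteins, planted position-2
probability 0.45); null screening on 20 ontologies of 50 decoy terms;
sel-TRAP recovery on 20 seeded tables of 1,000 genes; MTS cohorts of
200–361 precursors against proteomes of a few thousand. The GO recovery
claim addresses planted biases whose fold change is at least 3; with
high-background residues such as serine (whose position-2 margin sits near
0.12 once a group is planted), a planted probability of 0.6 keeps the
*realized* fold above 3 against binomial fluctuation at group sizes of
40–50, so every simulated run actually instantiates the regime the claim
is about. Scaling any of
these up is a matter of changing the generator arguments.

## Known limitations

* GAF term names are not resolved (a GAF carries no term names; joining an
  OBO file is out of scope), so `term_name` is `NA` for file-read
  annotations.
* The BestN/BestF procedure is one faithful, deterministic instantiation
  of a greedy family; published verbal descriptions underdetermine the
  score composition, and alternative tie-break chains can select different
  but equally valid term sets. All knobs live in `nterm_config()`.
* Whether $F_{mean}$ should be the pooled residue frequency (used here) or
  a mean of per-position frequencies is a genuinely open reading; the two
  coincide asymptotically and the pooled form keeps the urn construction
  exact.
* Cross-species scoring inherits MTS status from the source species;
  lineage-specific MTS gain or loss is invisible to it.
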