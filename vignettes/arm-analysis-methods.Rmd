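---
title: "Methods: arm-resolved miRNA evolution and isomiR expression analysis"
author: "armiso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arm-resolved miRNA evolution and isomiR expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armiso)
```

## The problem

A pre-miRNA hairpin can release a mature miRNA from either of its two arms.
The product of the 5′ arm is called miR-#-5p, the product of the 3′ arm
miR-#-3p; many hairpins release both, as a duplex, and which arm dominates
can change across tissues, conditions and species (*arm selection* and *arm
switching*). On top of this, each mature miRNA locus is expressed not as a
single sequence but as a population of *isomiRs* — variants with shifted 5′
and/or 3′ ends and occasional non-template 3′ additions.

`armiso` provides the analysis chain for studying mature miRNAs by arm:

1. **Arm classification** — locating matures on hairpins and labelling them
   5p/3p (`parse_mirbase_fasta()`, `assign_arm()`, `pair_arms()`);
2. **Composition statistics** — length, overall/positional nucleotide and
   homopolymer-run composition of arm-defined groups, with the corresponding
   two-group tests (`length_compare()`, `chi_square_compare()`);
3. **Cross-species evolution** — shared-family discovery, consensus
   inference of unannotated arms, reference-anchored alignment, per-position
   transition/transversion/indel divergence, and population-style diversity
   statistics π, Hd, k (`family_divergence()`, `diversity_stats()`);
4. **IsomiR expression** — extraction of end-variants from collapsed
   small-RNA reads, RPM and within-locus relative expression, cross-sample
   dispersion contrasts (`extract_isomirs()`, `profile_summary()`,
   `dispersion_compare()`);
5. **Seed-level function** — seed extraction (positions 2–8), seed-shift
   detection, and exact seed-match target-overlap statistics
   (`scan_targets()`, `overlap_stats()`);
6. **Synthetic data** — a fully seeded generator reproducing the statistical
   structure all of the above assume (`synthetic_config()` and the
   `generate_*()` functions), so the complete pipeline is testable without
   any database or cohort download.

## Arm classification

Existing annotation wins: an id ending in `-5p`/`-3p` is classified by name.
Otherwise the mature is located by exact substring search on the hairpin
(first occurrence; multiple hits are logged) and classified by position: with
mature midpoint $m=(start+end)/2$ and hairpin length $L$, the arm is 5p when
$m < L/2$ and 3p when $m > L/2$. Matures whose midpoint falls within 1 nt of
the hairpin midpoint are reported as `ambiguous` rather than forced to a
call: they straddle the loop, and a silent misclassification there would
contaminate both arm groups. Matures carried by several hairpins (multicopy
precursors) are placed on the first listed hairpin only. These rules are
deliberately simple, deterministic string/coordinate operations; an explicit
coordinate table can override the search.

## Composition statistics

Group statistics are computed on pooled counts. Homopolymer runs (`AA`,
`GGG`, ...) are counted **with overlap** — a run of $m$ identical bases
contributes $m-k+1$ $k$-mers — which is the simplest deterministic rule and
makes counts monotone across $k$ (count(`XXX`) ≤ count(`XX`), a property the
test suite asserts). Homopolymer percentages are normalised over the four
homopolymer labels only, so each group's column totals 100. Positional
composition is 5′-anchored (position 1 is the 5′ end); each position is
normalised over the sequences long enough to cover it.

Tests are all two-tailed: Student's pooled-variance t for independent arm
groups, the paired t test for miR-#-5p/miR-#-3p pairs (equivalent to a
one-sample t on the difference vector, which the tests verify), and the
uncorrected Pearson χ² on the groups × labels count contingency. For
positional input, the position × nucleotide counts are stacked into one
pooled contingency; whether one pooled statistic or per-position tests is
preferable is genuinely open, and we chose the pooled form because it yields
a single decision per comparison. Cells empty in both groups are dropped
(they carry no information); a zero expected count elsewhere raises an error
suggesting category merging rather than silently continuing.

## Alignment

Cross-species mature miRNAs are ~22 nt and highly similar, so a full MSA
program is unnecessary; `armiso` uses a deterministic Needleman–Wunsch star
alignment around the reference species (human by default): match +1,
mismatch −1, gap −2, terminal gaps free, fixed tie-breaks (diagonal, then
gap-in-subject, then gap-in-pattern). Pairwise alignments to the reference
are merged on reference coordinates, insertions opening shared gap columns.
Pre-aligned FASTA is accepted everywhere an alignment is consumed, so any
external aligner can be substituted when exact agreement with a particular
program matters. The aligner's scores are cross-checked in the test suite
against an independent implementation (`Biostrings::pairwiseAlignment`,
overlap mode) on random sequence pairs.

Because terminal length differences between species are common and
uninformative, analyses run on the **core**: leading and trailing alignment
columns containing any gap are removed (`trim_core()`); internal gap columns
are retained.

## Divergence and diversity

`divergence_profile()` compares every non-reference row to the reference
(human) at each core column: same-class difference (purine↔purine,
pyrimidine↔pyrimidine) is a transition, cross-class a transversion, a gap on
exactly one side an indel. The per-position substitution rate is
(transitions + transversions)/n_compared. Arm contrasts use the Wilcoxon
signed-rank test paired on **per-family mean substitution percentages** —
positionwise pairing across arms of different core lengths is ill-defined —
with the Z statistic computed by the normal approximation with tie
correction and zero-difference removal (all-zero differences give Z = 0,
p = 1 by convention), plus a Spearman rank correlation.

`diversity_stats()` treats a family's cross-species sequences as a small
population: k is the mean pairwise difference count (positions where both
members of a pair are non-gap and differ; gap–gap columns contribute neither
differences nor comparisons), π = k/L over the core length L, and haplotype
diversity Hd = n/(n−1)·(1 − Σp²) over distinct aligned sequences. The
reported "±" values are the Nei (1987) sampling SDs: eq. 10.7 for π (no
recombination) and eq. 8.12 for Hd, the quantities population-genetics
software conventionally prints. The implementation is checked against a
brute-force pairwise oracle on hundreds of random inputs and against an
independent distance-based computation of π.

`infer_missing_arm()` predicts an unannotated arm by aligning the target
hairpin to the human hairpin and reading off the segment under the human
mature's columns. Prediction fails if the segment is shorter than 15 nt,
more than half gaps, less than 60% identical to the human mature, or not
nearly colinear (>25% of window columns gapped on either side). The last two
guards matter: with free end gaps, an alignment can absorb a deleted arm
plus a short flank into a cost-free terminal overhang whose optimally-gapped
"identity" is inflated, and the colinearity test rejects exactly those
scrambles. Consensus inference is only meaningful while the arm is
conserved, so these bars are loose for any realistic input.

## IsomiR extraction and quantification

A read is assigned to a locus when, after removing the **shortest** 3′
suffix (≤ `max_tail`, default 3 nt) that leaves an exact substring of the
hairpin, the remainder starts within `window` (default 5 nt) of the
canonical start. Minimal trimming is the only consistent reading of
"non-template addition": trimming more than necessary would reclassify
templated 3′ ends as tails. Offsets are signed shifts of the templated ends
relative to the canonical mature (negative `offset5` = 5′ extension); the
removed suffix is recorded as `tail3` and not analysed further. When the
remainder matches the hairpin at several positions, the hit closest to the
canonical start wins (ties: 5′-most). The defaults cover the observed
behaviour of isomiR populations — abundant variants sit within 1–2 nt of the
dominant sequence — with margin; both are configuration, not contract.

Expression is reported as RPM (count × 10⁶ / library total; the library
total defaults to the read-set sum when no external total is supplied) and
as the within-locus relative expression percentage, which always sums
to 100 within a sample — an invariant asserted on every extraction in the
test suite. Cross-sample summaries drop samples whose locus RPM total is
below `min_rpm` (default 1), treat an isomiR absent from a retained sample
as 0%, pool isomiRs seen in fewer than `min_samples` samples (default 10%)
into an `other` row, use the sample (n−1) SD, and rank by mean percentage.
Percentages are computed per arm locus; computing them per hairpin (both
arms pooled) is a defensible alternative we did not take, because arm
totals differ by orders of magnitude and would drown the minor arm's
structure.

`dispersion_compare()` contrasts the distributions of per-isomiR SDs between
condition groups with box statistics (quartiles, 1.5×IQR whiskers) and a
two-tailed rank-sum test; fully tied SD distributions are reported as p = 1.

## Seed-level analysis

The seed is mature positions 2–8. A 5′ end shift relocates this window and
usually — not always (homopolymeric 5′ ends) — changes the seed; both facts
are reported. Target scanning is a deliberate simplification of dedicated
target-prediction tools: a UTR is a target iff it contains an exact
occurrence of the seed's reverse complement (no 7mer-m8/8mer/A1 site types,
no context or conservation scoring). Overlap between target sets is plain
set arithmetic on UTR ids. Results must not be read as equivalent to a
dedicated prediction pipeline; they exist so that overlap structure between
arms, and between canonical matures and their 5′ isomiRs, is computable and
testable end to end.

## The synthetic-data generator

The generator produces the inputs the pipeline assumes, with known truth:

* **Phylogeny** (`generate_phylo_families()`): per family, a root hairpin
  with embedded 5p and 3p matures; human is the root haplotype and every
  other species derives from it by i.i.d. per-position substitution —
  `sub_rate_5p` within the 5p mature, `sub_rate_3p` within the 3p mature,
  1.5× the larger rate elsewhere (non-mature hairpin sequence evolves
  faster) — plus ≤2 nt terminal length jitter. Making human the root is
  deliberate: divergence is profiled against the human reference, so the
  reference-vs-row mismatch probability equals the planted rate and
  parameter recovery is unbiased; with a latent ancestor both lineages
  would mutate and the observable mismatch rate would be ≈ 2s(1−s) + s²·⅓.
  The default in-mature deletion rate is 0 — mature miRNAs diverge almost
  exclusively by substitution, and length variation is terminal, which the
  jitter plus core trimming already model — with `indel_rate` exposed for
  robustness experiments.
* **IsomiR read sets** (`generate_isomir_readsets()`): per sample, isomiR
  proportions are Dirichlet-distributed around a template (70% canonical by
  default, the remainder over end-shift variants on the [−2, 2]² square
  with weights 2^−(|Δ5|+|Δ3|)), counts multinomial at a lognormal library
  size (default median 2×10⁴ reads per locus), and non-template tails
  appended to a binomial share of reads (default 10%, first tail base
  forced off-template). The Dirichlet concentration is the single
  dispersion knob — smaller = more between-sample dispersion — which is the
  simplest model producing condition-dependent percent dispersion; the
  default concentration 50 gives the visually "stable with scatter"
  profiles typical of abundant loci, and disease-like dispersion is modelled
  by dividing it.
* **UTRs** (`generate_utrs()`): random-composition UTRs with
  reverse-complement seed sites planted independently per seed at a chosen
  rate, at non-overlapping positions.

Everything is deterministic given (config, seed); per-generator substreams
are derived from the seed by fixed offsets so the generators do not perturb
each other. Truth tables (mutations, coordinates, per-sample proportions,
planted sites) are returned and written alongside outputs.

What the generator does **not** emulate: sequencing error, adapters and
quality profiles; genuine phylogenetic tree structure (species are
independent draws from the root, so there is no shared branch history);
RNA editing or SNP-derived isomiRs; and the skewed, heavy-tailed locus
abundance distributions of real small-RNA libraries. Passing tests on this
generator therefore demonstrate correctness of the statistics and the
pipeline plumbing under the stated model, not robustness to real-data
artefacts.

## Numerical choices and problem sizes

Ties in the alignment are broken in a fixed order; the Wilcoxon Z uses the
tie-corrected normal approximation without continuity correction; χ² is
uncorrected Pearson; quantiles are R's default type 7. Degenerate inputs are
defined explicitly: identical groups give t = 0/p = 1, all-zero difference
vectors give Z = 0/p = 1, a zero locus total yields an empty result with a
warning, a zero library size an empty read set.

The shipped experiments use desk-scale problem sizes chosen to estimate
their quantities stably: 40 families × 10 species for divergence recovery
(≈7,700 compared cells per arm, binomial SE ≈ 0.004 at rate 0.12), 200
replicates for the Wilcoxon power estimate, 100 replicates each for the
dominance and dispersion experiments, 20 samples per condition, and 100–400
UTRs of 300 nt for target scanning. The acceptance script
(`scripts/acceptance.R`) re-runs all of them from scratch from a single
command-line seed.

## Known limitations

* The positional χ² pools positions into one contingency; per-position
  testing with multiplicity correction is a reasonable alternative.
* Star alignment around the reference is not a full progressive MSA; for
  strongly diverged families (rates ≫ 0.2/site) a small fraction of
  substitutions is re-explained as compensating gaps, slightly deflating
  substitution rates. Pre-aligned input bypasses this.
* Loop-spanning (`ambiguous`) matures are exposed, not resolved.
* Target scanning is exact 7-mer matching only, by design.
* Arm classification of name-suffixed entries trusts the annotation even
  where a positional call would disagree.
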