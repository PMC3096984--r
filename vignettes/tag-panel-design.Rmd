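---
title: "Designing tag SNP panels under assay constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing tag SNP panels under assay constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagpanel)
```

## The problem

LD bin-tagging reduces a dense SNP map to bins of mutually correlated SNPs
(r² above a threshold), each representable by any of its candidate tag SNPs.
Tag choice within a bin is free from the LD point of view but very much not
free experimentally: a tag 40 bp from another assayed SNP can fail on a
hybridization platform, a tag with a poor vendor design score may not
genotype at all, an A/T or C/G tag costs twice the bead budget on the
Infinium platform, and in a multi-population study a tag that covers bins in
two populations halves the assay cost of those bins. `tagpanel` optimizes tag
selection over all of these at once, plus the user's own constraints
(obligates, exclusions, previously genotyped SNPs, functional preferences,
multiple panels).

## Model

### Genotyping probability

Each SNP's probability of assay success is taken from a user-configurable
discrete map: (vendor score interval) × (confidence class) → probability.
Intervals are left-closed and right-open; a score below the lowest interval
of its class (including the `-99` missing-score sentinel when the minimum
score filter is disabled) takes the lowest interval's value, while an unknown
class or an interior gap is an error — silent extrapolation of a calibration
table is worse than a failure. The probabilities must be a small discrete set:
ties in probability are exactly where functional-class preference is allowed
to act, so a continuous score would make functional prioritization vacuous.
The map shipped as `default_prob_map()` (levels 0.95/0.85/0.7/0.5) is a
placeholder shape; projects should calibrate their own from retrospective
genotyping results.

### Bin, cluster and panel scores

A bin with selected tag probabilities $p_1,\dots,p_m$ is tagged with
probability $P_i = 1 - \prod_l (1 - p_l)$, treating tag successes as
independent. Independence is an idealization: correlated failure modes (e.g.
a deleted region) will make $P_i$ optimistic, but the ranking of selections
is insensitive to this as long as the miscalibration is monotone.

A cluster of bins $k$ scores

$$S_k = \frac{\sum_{i \in k} n_i^{\mathrm{tagSnps}} \, P_i}{n_k^{\mathrm{tags}}},$$

where $n_i^{\mathrm{tagSnps}}$ weights bins by their number of candidate tag
SNPs (bins with more tag SNPs stand for more genetic variation and more
statistical power) and the denominator — the number of distinct selected
tags, or the bead-type total in Infinium mode — penalizes panel size. A tag
shared by bins of two populations is assayed once: it appears once in the
denominator and contributes to every bin containing it. The panel score is
the sum over clusters, which is what makes per-cluster optimization exact.

Two conventions are configurable because the weight is genuinely ambiguous:
`candidate_count` chooses whether $n_i^{\mathrm{tagSnps}}$ counts candidates
before or after the score/exclusion filter (default: after — the weight then
reflects what the panel can actually capture), and `bin_weight =
"bin_members"` switches to weighting by the bin's total SNP membership, which
better matches the power rationale when bins carry many non-tag SNPs.

### Lexicographic objective

Score only ranks selections after coverage is settled. The full comparator,
all criteria maximized in order: bins tagged ≥ 1 tag (or covered by an
existing genotype), obligates included, negative tag deficit, $S_k$,
functional-rank sum. The tag deficit compares actual tags per bin with
$\min(\text{max\_tags}, \text{n candidates}, \text{tags needed to reach the
probability cap})$ — so a bin is never penalized for having too few
candidates or for stopping early once `max_bin_probability` is reached. The
deficit is computed per cluster, keeping the objective additive across
clusters. Numeric comparisons of the score criterion use a $10^{-9}$
tolerance so floating-point noise cannot masquerade as an improvement.

## Search

Each cluster is optimized independently, deterministically (no randomness;
fixed enumeration orders, SNP-id tie-breaks):

1. **Greedy start.** Obligates are seeded first; two obligates in mutual
   conflict are resolved by comparing the two alternative objectives
   (earlier-ranked wins ties). The greedy fill then considers only tags with
   no conflict edge (and single-bead tags in Infinium mode), repeatedly
   taking the candidate that tags the most bins still needing tags,
   re-counting after every pick, with the pre-computed rank (probability
   desc, functional rank desc, id asc) as tie-break. For a single population
   this degenerates to the per-bin greedy fill.
2. **Swap-in of deferred tags.** Conflict-involved and two-bead tags are
   tried in ranked order, each together with removal subsets drawn from the
   selected tags it interacts with (conflict partners or bin mates). Only
   strictly improving moves are accepted; passes repeat to a fixed point.
   Strict improvement on a finite lattice guarantees termination.
3. **Exhaustive swap under a time budget.** All moves (remove ≤ 20 selected
   tags, add any subset of the remaining pool) are enumerated in ranked
   order; on any improvement the enumeration restarts from the new baseline.
   The search ends exhausted (the returned solution is the cluster optimum)
   or at the wall-clock deadline.

Pools larger than 31 candidates skip phase 3 for an **approximate search**:
single-in/multi-out moves plus pure removals, iterated to a fixed point. A
phase-3 deadline hit is followed by the same approximate polish — it is the
cheap fallback for over-budget clusters, and the run log records which
clusters took it (`exhausted = FALSE`, `phase_reached = "approximate"`).
`time_limit_s = 0` is special: the swap search is disabled entirely and the
phase-2 solution is returned, which gives a well-defined zero-budget
semantics and a clean baseline for budget-monotonicity checks. The deadline
is checked between move evaluations, so emitted solutions are always
constraint-valid; a longer budget can only improve the objective.

Hard constraints hold at every step: no two selected tags in conflict within
a panel (with `n_panels > 1`, feasibility is relaxed to the selection's
conflict subgraph being `n_panels`-colorable — exact bipartite test for two
panels, greedy with a small exact-backtracking rescue beyond), per-bin tag
counts within `max_tags_per_bin`, no excluded or filtered SNP selected.
Panel identifiers are assigned afterwards by coloring the selected conflict
subgraph; a pair that cannot be separated (e.g. a conflict triangle on two
panels) falls back to ordinary conflict resolution and one member is dropped.

### Degenerate inputs and edge conventions

* Conflict definition: same chromosome and $|\Delta\mathrm{pos}| \le$
  `distance_cutoff_bp` (cutoff 60 ⇔ "closer than 61 bp" conflicts). Ties in
  position are fine; positions are 1-based.
* A cluster with zero selected tags scores 0 (the $0/0$ case).
* Bins whose candidates were all filtered remain in the accounting as
  untagged and appear in the untagged report with one reason per candidate
  (`below_min_score`, `user_excluded`, `proximity_conflict`, `superseded`,
  `bin_probability_reached`).
* Previously genotyped SNPs are never re-assayed: they are removed from
  candidate lists and their bins are marked covered ($P_i = 1$, expected
  tags 0, counted as tagged). A covered bin keeps only candidates that also
  serve an uncovered bin; otherwise the $S_k = 0$ convention would let a
  covered singleton cluster reward a useless tag (score jumping from 0 to
  $w_i$ for a tag nobody needs).
* `conflict_all_snps` extends the proximity rule to the whole annotation
  table: a candidate within the cutoff of *any* supplied SNP is filtered
  out before the search, since the interfering DNA is present whether or not
  that SNP is assayed.
* Missing vendor scores (`-99`) fail the minimum-score filter; with the
  filter disabled they map through the lowest probability interval.
* An obligate that is excluded, filtered, or not a candidate of any bin is a
  hard input error rather than a silent decision.

## What the synthetic generator emulates

`synth_spec()`/`generate_instance()` produce the combinatorial structure the
optimizer faces, not population genetics: loci spaced far apart on one
chromosome, per-locus candidate tags (a skewed count distribution in which
roughly 70% of bins have a single candidate), cross-population tag sharing
(default 42% of tags shared between two populations), planted proximity
conflicts between adjacent loci (default rate 0.21), A/T-or-C/G alleles at
12%, uniform vendor scores with 2% missing, and a probability map realizing a
requested set of discrete levels. These defaults mirror the regime of a
large two-population candidate set over ~160 genes. Deterministic given the
seed; written instances are byte-identical across runs.

What it deliberately does **not** emulate: LD structure (bins arrive as
given), realistic score distributions, intra-bin proximity conflicts, more
than two populations, and correlated assay failures. Green tests therefore
demonstrate the correctness of the combinatorial optimization under the
stated model — not that the probability model is well calibrated for any
particular chemistry.

## Validation strategy

Three independent routes check the optimizer, at sizes chosen so the whole
suite runs in a couple of minutes on one CPU:

* **Brute-force oracle.** `brute_force_optimum()` enumerates every feasible
  selection per cluster (vectorized over subset incidence matrices — a
  different code path from the phase search) and applies the same
  lexicographic order. On 200+ seeded clusters (≤ 8 bins, ≤ 12 candidates,
  conflict densities up to 0.3, one or two populations) the full optimizer
  with an ample budget reproduces the oracle objective exactly, in
  GoldenGate and Infinium modes. Pools above 20 candidates are refused by
  the oracle.
* **Randomization dominance.** The harness builds random constrained
  solutions (random bin order, random conflict-free candidate, never more
  tags than the reference panel) and counts how many beat the optimizer on
  coverage, or on score at equal coverage. Twenty instances × 10⁴ random
  solutions yield zero better solutions on either criterion; the detector
  itself is checked to fire on deliberately wasteful reference panels.
* **Hard-constraint audit.** Every emitted panel is checked directly from
  coordinates: zero same-panel pairs within the cutoff, per-bin caps,
  exclusions, obligate presence, and exact bead accounting
  (`one-bead + 2 × two-bead`).

## Known limitations

* Phase 3 truncated by the deadline loses the optimality guarantee (the
  returned solution may still be optimal, but this is not certified); the
  run log makes the affected clusters visible.
* Budget monotonicity is guaranteed against the zero-budget baseline and
  holds empirically for longer budgets, but a truncated phase 3 followed by
  the approximate polish is a heuristic composition: pathological instances
  could in principle order two truncated runs non-monotonically.
* The randomization harness validates single-panel designs only.
* Functional prioritization acts only within probability ties by design;
  users who want functional class to outrank success probability should
  encode it in the probability map instead.
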