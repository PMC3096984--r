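# tagpanel

Design custom SNP genotyping panels from linkage-disequilibrium (LD)
bin-tagging output.

LD bin-tagging programs (ldSelect, TagZilla, Tagger, Snagger) group correlated
SNPs into bins and report, for each bin, the set of candidate *tag SNPs* that
can represent it — any one of them captures the bin's variation. Which
candidate to genotype is then an engineering decision, not an LD decision:
assay chemistry and study constraints make some choices far better than
others. `tagpanel` is a post-processor that picks the tags, accounting for:

- **proximity conflicts** — on hybridization assays (Illumina GoldenGate),
  SNPs closer than 61 bp interfere and must not share a panel;
- **genotyping probability** — each SNP's vendor design score and empirical
  confidence class map to a discrete probability of assay success;
- **Infinium bead types** — A/T and C/G SNPs consume two bead types instead
  of one, and panel cost scales with bead count;
- **multi-population sharing** — a tag serving bins in several populations is
  assayed once and should be preferred;
- **user constraints** — obligate (forced) SNPs, excluded SNPs, previously
  genotyped SNPs, functional-class preferences, multiple panels, per-bin tag
  caps.

## The objective

Bins whose candidates interact (shared tags across populations, or conflicting
pairs) are grouped into *bin clusters* by single-linkage; each cluster is
optimized independently. Within a cluster, selections are compared
lexicographically:

1. most bins tagged by at least one tag SNP;
2. most obligates included;
3. smallest deviation from the expected number of tags (with exemptions for
   bins that simply have too few candidates or that already reach the
   probability cap);
4. highest cluster score

   *S<sub>k</sub>* = Σ<sub>i</sub> *n<sub>i</sub><sup>tagSnps</sup>* ·
   *P<sub>i</sub><sup>tagged_bin</sup>* / *n<sub>k</sub><sup>tags</sup>*,

   where *P<sub>i</sub><sup>tagged_bin</sup>* = 1 − Π(1 −
   *p<sub>l</sub>*) is the probability that bin *i* gets at least one
   successful tag, the weight *n<sub>i</sub><sup>tagSnps</sup>* favors bins
   representing more variation, and the denominator (tag count, or bead-type
   count with `infinium = TRUE`) favors smaller panels;
5. highest sum of functional ranks (probabilities are discrete, so ties are
   common and functional preference acts only within them).

The panel score *S<sub>P</sub>* is the sum of cluster scores. Each cluster is
searched in three phases: a greedy start on conflict-free single-bead tags
(re-ranking by the number of populations still needing coverage), a swap-in
pass for the deferred conflict-involved/two-bead tags, and a time-budgeted
exhaustive swap (any-out/any-in, restarting from each improvement) that falls
back to a single-in/multi-out approximate search for oversized pools (more
than 31 candidates) or when the budget is exhausted.

## Worked example

```r
library(tagpanel)

inst  <- generate_instance(synth_spec(n_bins = 12, seed = 42))
panel <- pick_panel(inst$bins, inst$snps, inst$config)
panel
#> <tag_panel>
#>   bins: 12 | tagged: 11 | untagged: 1
#>   tag SNPs: 7 | obligates: 0 | bead types: 8
#>   panel score: 12.3 | tag deficit: 0 | same-panel conflicts: 0
#>   clusters: 7 ( 7 searched exhaustively, 0 approximate )
```

Eleven of the twelve bins are tagged with seven tag SNPs (shared tags cover
two populations at once); the twelfth bin lost its only candidates to the
score filter and is reported untagged with per-candidate reasons. Zero
selected pairs violate the 60 bp proximity rule. `tidy()` returns the final
report — obligates first, then tags by their incremental contribution to the
panel score:

```r
tidy(panel)[1:4, c("snp_id", "bin_id", "populations", "probability",
                   "incremental_score")]
#>   snp_id  bin_id          populations probability incremental_score
#> 1 rs00006 bin0003,bin0003 CEU,YRI            0.7               3.5
#> 2 rs00014 bin0006,bin0006 CEU,YRI            0.85              2.55
#> 3 rs00002 bin0001,bin0001 CEU,YRI            0.5               2
#> 4 rs00017 bin0007         CEU                0.85              1.7
```

The method's own quality check — many random constrained panels, none of
which may beat the optimized one on coverage, nor on score at equal
coverage:

```r
random_solutions(inst$bins, inst$snps, inst$config, panel,
                 n = 10000, seed = 7)
#>       n better_coverage equal_coverage better_score_at_equal_coverage
#> 1 10000               0           1784                              0
```

`glance(panel)` gives the one-row summary, `autoplot(panel)` the
probability-enrichment or per-tag-contribution plot, and
`brute_force_optimum()` an exhaustive oracle for small instances.

## Command line

```sh
tagpanel synth    --out inst_dir --seed 7 --n-bins 50
tagpanel optimize --bins inst_dir/bins.tsv --scores inst_dir/snps.tsv \
                  --config inst_dir/config.yaml --time-limit 50 --out run_dir
tagpanel validate --bins inst_dir/bins.tsv --scores inst_dir/snps.tsv \
                  --config inst_dir/config.yaml --n 10000 --seed 7
```

`optimize` accepts `--infinium`, `--panels N`, `--min-score X`,
`--distance-cutoff BP`, `--max-tags-per-bin K`, `--obligates FILE`,
`--exclude FILE`, `--pregenotyped FILE`, `--dialect ldselect`,
`--per-chromosome`. Input errors exit with status 2. The executable lives at
`inst/exec/tagpanel`; the same entry point is callable as
`tagpanel_run(args)`.

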