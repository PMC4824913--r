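# morphpars

Maximum parsimony analysis of discrete morphological character matrices in
R, built around the kind of dataset palaeontologists actually publish:
20–30 taxa, a few dozen unordered multistate characters, heavy missing
data (`?`), and occasional polymorphic cells (`[01]`).

The package ships the complete cranial character matrix from a capitosaur
(Triassic temnospondyl amphibian) study — 29 species × 56 characters, with
the newly erected *Yuanansuchus maopingchangensis* coded in two variants
(holotype only vs. all known specimens) — and reproduces that analysis end
to end: tree search, consensus, homoplasy indices, and synapomorphy
diagnosis.

## What it computes

**Criterion.** Equal-weights unordered (Fitch) parsimony: the score of a
tree is the minimum number of character-state changes needed to explain
the matrix,

    L(T) = sum_i s_i(T),

minimised over ancestral state assignments per character. Missing cells
enter as the full observed state set of their character and never force
changes; polymorphic cells are scored as state sets.

**Searches.** Exhaustive enumeration (≤ 9 taxa), branch-and-bound with
lower-bound pruning (≤ 16 taxa), and a seeded heuristic — random-addition
starting trees followed by NNI/SPR/TBR branch swapping that pools and
swaps *all* equally short trees, so the full MPT set is recovered, not
just one tree. Zero-minimum-length branches (edges that need carry no
change in any character under any optimal reconstruction) are collapsed
before distinct topologies are counted.

**Statistics.** Per-character step minima `m_i`, observed steps `s_i`,
maxima `g_i`, and the ensemble indices

    CI = Σm / Σs        RI = (Σg − Σs) / (Σg − Σm)

**Diagnosis.** `map_synapomorphies()` enumerates all most-parsimonious
reconstructions on every optimal tree and reports the character-state
changes that appear, with the same states on the same clade's branch, in
every one of them ("unambiguous synapomorphies").

**Validation.** An Mk-model simulator (`simulate_tree()`,
`simulate_matrix()`, `degrade_matrix()`) generates matrices with known
true trees, known per-character change counts, and configurable
missingness/polymorphism, so the whole pipeline can be tested against
ground truth.

## Worked example

```r
library(morphpars)
out <- reproduce_analysis("composite", seed = 1)
#> reproduce (composite coding):
#>   [PASS] best length 186 (expected 186)
#>   [PASS] Yuanansuchus sister-pair in all MPTs and consensus
#>   [PASS] 3 distinct MPTs after collapsing (published: 3)
```

The composite coding yields three most-parsimonious trees of 186 steps
(the holotype-only coding: two trees of 185 steps). In every optimal tree
the two Yuanan species are sister taxa, and the branch uniting them
carries four unambiguous changes:

```r
syn <- out$synapomorphies
syn[syn$clade == "Yuanansuchus laticeps + Yuanansuchus maopingchangensis" &
      syn$unambiguous, c("character", "from", "to")]
#>     character from to
#> 172         4    1  2     # tabular horn directed laterally
#> 314         7    0  1     # lateral line sulci continuous, well impressed
#> 8          10    0  1     # supraorbital canal enters the lacrimal
#> 17         13    1  0     # preorbital jugal projection < half snout length
print(out$score)
#> <tree_score> length 186 steps; CI = 0.36, RI = 0.67
```

General-purpose entry points: `read_matrix()` / `parse_matrix()` for
TNT-style and NEXUS files, `heuristic_search()` / `branch_and_bound()` /
`exhaustive_search()`, `strict_consensus()`, `rf_distance()`,
`tree_score()`, `collapse_min_zero()`, and `run_analysis()` for the whole
pipeline on any matrix. A thin command-line front end lives at
`inst/cli/morphpars.R` (subcommands `reproduce`, `run`, `score`,
`consensus`, `simulate`).

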