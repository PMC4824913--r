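---
title: "Maximum parsimony for morphological matrices: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum parsimony for morphological matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(morphpars)
```

# The inference problem

Discrete morphological matrices of the kind published in vertebrate
palaeontology — here, 29 capitosaur temnospondyl species scored for 56
cranial and mandibular characters — are analysed under maximum parsimony:
the preferred trees are those requiring the fewest character-state
changes. All characters are equally weighted and unordered (any state may
change to any other at cost one), which is both the convention of the
source analysis and the least-assuming model for characters whose states
have no natural ordering.

For one character on one tree, the minimum number of changes over all
ancestral state assignments is computed by the Fitch set operations
(intersection where possible, otherwise union, at cost one), implemented
here as bitmasks over state digits. Three cell types need conventions:

* **Missing (`?`)** — the cell enters the pass as the full set of states
  observed in that character's column. A missing cell therefore never
  forces a change. This is the standard convention of parsimony programs;
  it also means an all-missing character is scored as constant.
* **Polymorphic (`[01]`)** — scored as the state set {0, 1}: any member
  state satisfies the cell at no cost. Whether the original observation
  meant true polymorphism or uncertainty is not recoverable from the
  matrix and makes no difference to the score, so the two are treated
  identically (the distinction is recorded only in prose).
* **Gap (`-`)** — accepted on input and treated as missing.

Character indices are 1-based everywhere user-facing, matching how such
analyses cite characters ("character 4", "character 13").

# Tree search

`heuristic_search()` follows the classic two-phase strategy: a
random-addition-sequence (RAS) starting tree — taxa are inserted in random
order, each at its currently cheapest position, ties broken by the seeded
random stream — followed by branch swapping to a local optimum. The
default neighbourhood is TBR (tree bisection–reconnection), with SPR and
NNI available; the implementation scores an entire TBR neighbourhood by
precomputing, for each bisection, the per-edge "virtual root" state sets
of both components, so a candidate reconnection costs one vectorised
mask-intersection per character.

Because the *number* of equally most-parsimonious trees (MPTs) is itself a
result, equal-length trees are not discarded: every tree at the best known
length joins a pool, each pool member is itself fully swapped to
enumerate its island of equal-length neighbours, and the pool is
deduplicated by bipartition-set identity. Defaults — 100 RAS replicates,
TBR, a 10,000-tree cap — are deliberately generous for matrices of this
size: on the bundled 29-taxon matrix a full search takes well under a
second, and the best length is stable across seeds. The seed fully
determines the trajectory (the RNG is a self-contained 64-bit stream, so
results are identical across platforms); `stop_no_improve` can terminate
replicates early and is off by default.

Two exact searches serve as internal oracles and as practical tools for
small matrices: `exhaustive_search()` enumerates every unrooted binary
topology (up to 9 taxa), and `branch_and_bound()` inserts taxa stepwise,
pruning a partial tree when its per-character steps — each raised to the
character's global minimum — already exceed the best complete tree (the
initial bound comes from a greedy addition). The bound is monotone, so
branch-and-bound is exact and returns the complete MPT set.

# Counting distinct trees: the collapse rule

Binary search output can contain spurious resolutions: internal branches
that no character need support. Before counting MPTs, we contract every
internal edge whose *minimum* number of changes over all
most-parsimonious reconstructions is zero (`collapse_min_zero()`). This
is the stricter, reconstruction-independent rule; the per-edge test is an
exact conditional-cost computation (a Sankoff-style up/down pass per
character), not a heuristic.

The original analysis was run in a program whose collapsing convention is
not stated in the text, so reproduction of printed MPT *counts* is
checked under the rule above and treated as a soft check: the pipeline
reports and flags a mismatch rather than failing, while tree *lengths*
are hard checks. Under this rule the bundled matrix yields exactly the
published counts (3 composite, 2 holotype), stable across seeds.

# Scoring trees with polytomies

Consensus and collapsed trees contain polytomies, and scoring them forces
a semantic choice that implementation made concrete:

* `fitch_length(..., polytomies = "refine")` (default) scores each
  character as its minimum over binary refinements of the multifurcations
  — an exact dynamic programme that optimises over merge trees at each
  polytomy (subset DP, practical to degree 12; beyond that the function
  asks you to resolve the polytomy). Each character is minimised
  independently, so the total is a lower bound on what any single
  refinement achieves.
* `fitch_length(..., polytomies = "hard")` treats a polytomy as a
  simultaneous divergence and scores the multifurcating tree as given
  (multi-child Sankoff).

The two differ in general — a star over cells {0},{0},{1},{1} scores 1
under refinement but 2 hard — and the difference matters for invariants
one might expect of collapsing. Contracting a *single* zero-minimum edge
preserves the hard length exactly (and contracting a supported edge
increases it: this "iff" is asserted in the test suite against an
enumeration oracle). But after contracting *several* such edges at once,
no single reconstruction need be changeless on all of them
simultaneously, so the hard score of a fully collapsed tree can exceed
the binary length, while the refinement score can fall below it (different
characters re-resolving the polytomy differently). The only universally
safe statement, also asserted in the suite, is that the refinement score
of the collapsed tree never exceeds the binary length. Users comparing a
collapsed consensus against binary MPT lengths should score it with
`polytomies = "hard"` if they want "the tree as drawn", and remember that
neither convention makes a polytomous tree's length comparable to a
binary search optimum.

# Homoplasy indices

`tree_score()` reports, per character, the observed steps `s`, the
minimum conceivable steps `m` (one less than the smallest set of states
hitting every non-missing cell), and the maximum `g` (the star-tree
worst case: non-missing cells minus the best achievable single-state
count, with polymorphic cells resolved favourably). The ensemble indices
are CI = Σm/Σs and RI = (Σg−Σs)/(Σg−Σm); degenerate denominators give
`NA` rather than an error. Both sums include parsimony-uninformative
characters by default — the common default of the era's software, and the
convention under which the bundled matrix's indices match an independent
reference implementation — with `exclude_uninformative = TRUE` exposing
the adjusted variants. (As it happens, every character in the bundled
matrix is parsimony-informative, so the two variants coincide there.)

# Synapomorphy mapping

A claim of the form "this clade is supported by characters 4, 7, 10 and
13 in all shortest trees" is a statement about *all* most-parsimonious
reconstructions on *all* optimal trees. `map_synapomorphies()` therefore
computes, per character and per branch, the full set of
(parent-state, child-state) pairs realised at optimality — again via
exact conditional costs, not by committing to ACCTRAN or DELTRAN — and
flags a change as unambiguous only when the same single changing pair
appears on the branch subtending the same clade in every supplied tree.
Changes present in some but not all reconstructions are reported too,
flagged ambiguous. Branches are read against an outgroup
(*Rhineceps nyasaensis* by default when present: it carries the most
plesiomorphic, near-all-zero coding in the matrix; the source analysis
does not state its rooting, so this is configurable). The function
requires binary trees — reconstruction sets are well defined there —
and is run on the binary MPT pool, with records keyed by clade so they
aggregate across trees.

# The simulator and what passing tests mean

`simulate_tree()` draws either uniform unrooted topologies (by uniform
random edge insertion; the uniform model is restricted to ten taxa) or
Yule-style trees grown by splitting a random extant leaf. Characters
evolve under the symmetric k-state Mk model: change events are Poisson on
every branch with equal intensity, scaled so the expected number of
events per character equals `expected_changes_per_character`; every event
jumps to a uniformly chosen different state, and the true event counts
are retained. `degrade_matrix()` then knocks cells out uniformly at
random and widens others into two-state sets containing the true state.

Defaults mirror the shape of the bundled matrix (29 taxa, 56 characters,
up to 3 states, ~3 expected changes per character, 20% missing, a small
polymorphic fraction). The parameter-recovery check in the test suite
uses 12 taxa, 3 states and 2 expected changes per character — a moderate
rate at which characters are informative but rarely saturated — and
verifies that the Robinson–Foulds distance from the strict consensus of
recovered MPTs to the true tree shrinks as characters grow through 14,
56 and 224, vanishing for at least 90% of seeds at 224.

Two caveats on external validity. Missingness in real matrices is
phylogenetically and anatomically clustered (fragmentary taxa lose whole
suites of characters); the simulator's uniform missingness is a
deliberate simplification, so recovery results under it say nothing about
the biases clustered missing data can introduce. And the Mk model's
equal rates and independent characters are the generative counterpart of
equal-weights unordered parsimony, not a claim about morphological
evolution; passing recovery tests validates the machinery, not the
inference model.

# Numerical and engineering choices

* State sets are fixed-width bitmasks; the per-character state universe
  is column-local. Matrix I/O accepts digits 0–9; the reconstruction
  machinery (collapse, synapomorphies) supports state digits up to 4,
  ample for morphological data.
* All tie-breaking in search (addition order, insertion ties) is driven
  by the seeded stream; scan order within a swap neighbourhood is fixed
  by the tree structure, so searches are bit-reproducible.
* Problem sizes in the test suite are chosen so the whole suite runs in
  about a minute: brute-force oracles at ≤ 7 taxa, 40–50 random
  replicates for exact-search equivalences, 100-replicate full searches
  for the bundled matrix, and a 20-seed recovery experiment.
* Trees are `ape::phylo` objects throughout; Newick I/O is delegated to
  ape with added validation (balanced parentheses, duplicate labels).
  MPT identity is bipartition-set equality.
* The fixture preserves the source's printed taxon labels verbatim,
  including one evident misprint ("Cherninis denwai"), with the corrected
  binomial recorded as an alias in the matrix metadata; the two
  alternative coding rows of *Y. maopingchangensis* are stored under
  disambiguated labels and resolved to a single 29-taxon matrix by
  `load_fixture()`.

# Known limitations

Ordered/additive characters, step matrices, character weights, and
implied weighting are out of scope (the bundled analysis used none of
them). Polytomy refinement scoring is exponential in polytomy degree and
capped at 12. Branch lengths are never estimated; trees are topologies.
The heuristic search, like all heuristics, guarantees optimality only
where the exact searches can check it — which the test suite does
systematically for subsamples of the bundled matrix.
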