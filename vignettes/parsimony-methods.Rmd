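---
title: "Parsimony methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimony methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphparsimony)
```

## The problem this package addresses

`morphparsimony` implements an equal-weights maximum parsimony workflow for
small discrete morphological matrices, of the kind used to revise fossil
insect classifications from wing venation. It ships one such dataset: a
13-taxon, 24-character matrix of hagloid forewing characters (states 0–3,
`?` for missing) covering all analysable species of a Jurassic–Cretaceous
katydid subfamily plus two outgroups, *Euhagla saurensis* (Haglinae) and
*Liassophyllum caii* (Tuphellidae). Eleven of the thirteen known species of
the study group are in the matrix (85% coverage); two are too poorly
preserved to code. The matrix is bundled as a plain-text NEXUS fixture and
re-parsed on every call of `bundled_matrix()`, with its transcription pinned
by an MD5 checksum in the test suite.

The package is organised as an analysis workflow: the numbered scripts under
`analysis/` re-run the study end to end (exact search and indices, bootstrap
support, simulation-based validation) on top of the functions documented
here, and write their tables under `results/`.

## Model and optimality criterion

A tree's score is the minimum number of state changes it requires,

$$L(T) = \sum_j s_j(T),$$

where $s_j$ is the Fitch length of character $j$: all characters unordered
(any state can change to any other at unit cost) and equally weighted, as is
conventional for matrices of this kind. $s_j$ is computed by the Fitch
bottom-up pass over a binary tree rooted, for traversal only, at a leaf;
the score is independent of that rooting, which the tests assert for every
possible rooting.

**Missing data.** A `?` cell enters the Fitch pass as the *set of states
observed among the non-missing leaves of that character*, not as the full
symbol alphabet. The two choices give identical tree lengths (an unobserved
state never helps a minimisation), but the observed-set convention makes an
all-missing character contribute exactly zero steps without special-casing,
and keeps the per-character bounds $m_j$ (distinct observed states − 1) and
$g_j$ (non-missing leaves − modal state frequency) consistent with the step
counts they bracket: $m_j \le s_j \le g_j$ is a tested invariant.

## Exact search

`branch_and_bound()` enumerates topologies by stepwise leaf insertion.
Partial-tree length is monotone under leaf addition, so a branch is pruned
as soon as its length plus a lower bound on the cost of the remaining taxa
exceeds the best complete score. Two ingredients keep the bound tight:

* **Addition order.** Taxa are added in a max-divergence order (seeded with
  the most dissimilar pair by Hamming mismatch, then greedily by summed
  distance to the chosen set), so conflicts surface early.
* **Remaining-state bound.** For each character, every state seen only among
  not-yet-added taxa must cost at least one further step (a character with
  no state placed yet gets one state free, its effective root state). These
  per-level constants are precomputed once.

The recursion runs in C++ and returns *every* binary topology attaining the
optimum (capped by `max_trees`, with a flag when the cap is hit). On the
bundled matrix it visits roughly twenty thousand partial trees and finishes
in well under a second; the practical guard is 16 taxa. Correctness is
tested against full enumeration (`enumerate_topologies()`, $(2n-5)!!$
trees) on dozens of random matrices.

## Heuristic search

`heuristic_search()` mirrors the classic strategy of the parsimony programs
used for matrices like this one: random-addition-sequence starting trees
(taxa shuffled by the seeded RNG, each inserted at its currently best edge,
ties broken by a seeded draw) refined by hill-climbing with NNI, SPR or TBR
rearrangements (TBR default; the neighborhoods nest, which is property
tested). Replicates are pooled at the best score, deduplicated by
bipartition sets, and a final sweep absorbs equally optimal neighbors of
the pooled trees until closure or the tree cap. Everything is deterministic
given the configuration, including its seed, and the search can never beat
the exact optimum — both are tested.

Defaults are desk-scale (20 replicates) because this 13-taxon landscape
converges almost immediately; production-scale settings (1000 replicates,
10,000 kept trees) remain reachable through `search_config()`. On the
bundled matrix 20 TBR replicates find the exact optimum and, through the
closure sweep, the complete optimal set.

## Fit indices and their conventions

With per-character $(m_j, s_j, g_j)$ the ensemble indices are

$$\mathrm{CI} = \frac{\sum_j m_j}{\sum_j s_j}, \qquad
  \mathrm{RI} = \frac{\sum_j g_j - \sum_j s_j}{\sum_j g_j - \sum_j m_j}.$$

By default *all* characters enter the sums, matching the convention of the
classic programs; `informative_only = TRUE` restricts them to
parsimony-informative characters ($g_j > m_j$). Unrounded values are kept
internally; the report layer rounds half-up to two decimals
(`round_half_up()`), since half-to-even rounding would misrepresent
conventionally rounded published numbers.

On the bundled matrix every optimal tree gives $L = 42$,
$\mathrm{CI} = 34/42 = 0.8095 \rightarrow 0.81$ and
$\mathrm{RI} = 32/40 = 0.8000 \rightarrow 0.80$ under the all-characters
convention, and $\mathrm{CI} = 0.78$, $\mathrm{RI} = 0.80$ under the
informative-only convention. The analyses this matrix originally
accompanied printed the pair as CI 0.80 / RI 0.81 — the same two numbers
with the labels interchanged, a pairing that no convention computable from
the data reproduces. The package reports its computed values and both
conventions rather than adopting the transposition; the corresponding
acceptance check is deliberately left failing as a faithful record of the
discrepancy.

## How many most parsimonious trees?

Tree counts are convention-laden, so `reproduce_analysis()` reports two
numbers. The binary census — every fully resolved topology at the optimum —
is 54 for the bundled matrix. Two of its taxa have identical rows, and
several characters are uninformative about parts of the tree, so many of
those 54 differ only in edges that no character actually demands;
`collapse_min_length_zero()` contracts every internal edge whose minimum
number of changes over all most-parsimonious reconstructions is zero, and
deduplication under that rule leaves 4 collapsed classes. Programs that
reduce duplicate taxa before searching, cap their tree buffers, or collapse
under different rules will report other numbers for the same data (the
original runs printed one and two trees, respectively); exposing the pair
of counts, rather than imitating any one program, is the package's answer,
and the acceptance check tied to the historically printed count is left
failing rather than redefined.

## Ancestral states and synapomorphies

Per character the engine runs a unit-cost dynamic program over the
display-rooted tree: subtree-optimal costs down, rest-of-tree costs up.
Their sum identifies the MPR set of every node (states attainable in at
least one most-parsimonious reconstruction — the `"unambiguous"` policy
reports these sets). `"acctran"` resolves by the classic downpass-set rule
(keep the parent state when the downpass set allows it), pulling changes
rootward; `"deltran"` backtracks the dynamic program preferring the parent
state among optimal continuations, pushing changes tipward. Both policies
realize exactly the Fitch step count on every character, which is tested on
random instances.

`synapomorphies()` asks which characters place a change on a given branch.
Its default policy `"any"` lists a character when *some* most-parsimonious
reconstruction puts a change there (computed exactly from the two-sided
costs), because reconstruction-policy choices of the original graphical
output are not recoverable; `"acctran"`/`"deltran"` restrict to the named
reconstruction. On optimal trees of the bundled matrix the branch uniting
the ten ingroup species minus *Cyrtophyllites rogeri* carries the derived
states that diagnose the new subfamily (characters 1, 7, 12, 15 → state 1,
with 24 alongside), the *C. rogeri* + *L. caii* pair is supported by
characters 2, 5 and 8, and the core *Archaboilus* clade by character 20
state 1 — these are asserted as existence statements over the optimal set,
since not every optimal topology places *Tasgorosailus* (the one ingroup
taxon scored 0 for character 7) in a position that lets the change sit on
the subfamily branch.

**Display rooting.** Queries root on the pendant edge of *Euhagla
saurensis* alone, not on a two-outgroup clade: the analysis itself places
the second outgroup *L. caii* inside a clade with *C. rogeri*, so the two
outgroups cannot jointly root the tree. This is the package's convention,
exposed as the `root_taxon` argument.

## Bootstrap support

`run_bootstrap()` resamples the character columns with replacement, re-runs
the heuristic search on each pseudo-replicate, takes the strict consensus
of that replicate's equally best trees, and tallies bipartition
frequencies. Tallying from the consensus rather than one arbitrary best
tree keeps tie-breaking order out of the frequencies. All randomness flows
from one seed (per-replicate sub-seeds are derived below $2^{31}$), and
identical inputs give bit-identical results.

Within-replicate searches default to 10 random-addition replicates with
TBR and a deliberately small tree cap (16, hard-capped at 64): resampled
matrices can have extremely flat landscapes, and chasing a complete tie set
inside every replicate would cost much and change the consensus little.
The desk-scale run in `analysis/02_bootstrap_support.R` uses 100 replicates
with a 2-start SPR climb, which this landscape saturates; support for the
subfamily clade is high, as the original 1000-replicate analysis also
found, and the script prints the exact frequencies it computes.

## The simulator, and what passing tests do and do not show

`simulate_matrix()` emulates the *shape* of matrices like the bundled one:
a known generating topology (`random_tree()`, uniform over unrooted binary
topologies by sequential random edge insertion — chi-square tested), 2–4
unordered states per character, a per-branch per-character probability
`change_prob` of switching to a uniformly chosen different state (a
branch-length-free Mk-style process), and independent masking of leaf cells
with probability `missing_frac`. `perfect_matrix()` is the homoplasy-free
limit: one binary character per internal edge, making the generating tree
the unique optimum with CI = RI = 1.

Real morphological data violate these assumptions in known ways the
simulator does not model: characters are correlated (venation characters
share developmental pathways), missingness is concentrated in poorly
preserved taxa rather than independent across cells (compare the bundled
matrix, where three fragmentary taxa hold most of the 36 `?` cells), state
frequencies are uneven, and rates vary across characters and branches.
Passing recovery tests therefore demonstrate that the inference machinery
is correct and consistent — signal in, tree out — not that equal-weights
parsimony is statistically sufficient for any particular fossil dataset.
Scaled-down study conditions (10 taxa, 60 characters, `change_prob` 0.05,
5 search replicates; bootstrap with tens of replicates) are the package's
test sizes; the same functions accept larger settings unchanged.

## Numerical and interface choices

* **Tie-breaking.** Equal-score insertion points during random addition are
  resolved by a seeded RNG draw; hill-climbing takes the best neighbor with
  the first-found winning ties in generation order (`steepest = FALSE`
  accepts the first improvement instead).
* **Degenerate inputs.** All-missing characters cost zero steps and are
  flagged by `validate_matrix()`, as are constant characters and duplicate
  rows (findings, never errors — the bundled matrix itself has a duplicate
  pair). A zero-variation matrix reports CI = 1 with a warning.
* **Labels.** Taxon labels keep their printed spelling, including one
  published misspelling, with the corrected form as an alias in
  `taxon_metadata()`; whitespace is normalized, and the NEXUS/TNT/Newick
  layer swaps spaces and underscores reversibly (labels that already
  contain underscores or dialect-reserved characters are refused rather
  than emitted ambiguously).
* **Canonical identity.** Two trees are equal exactly when their
  non-trivial bipartition sets are equal; bipartitions are keyed by the
  side not containing the alphabetically first leaf, which makes hashes
  independent of tip order and rooting.
* **Rounding.** Only the report layer rounds (half-up, two decimals for
  indices; half-up integer percentages for coverage, so 11/13 → 85).

## Limitations

No generalized (Sankoff) step-matrix costs, character ordering or weights;
no ratchet, sectorial or genetic search strategies; no Bremer support or
rescaled consistency index; no likelihood or Bayesian models. The exact
search is for small matrices (≤ 16 taxa) by design. These bounds match the
package's purpose: complete, reproducible reanalysis of compact
morphological datasets.
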