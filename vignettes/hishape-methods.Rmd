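---
title: "Coarse-grained RNA folding spaces and kinetics with hishapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained RNA folding spaces and kinetics with hishapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hishapes)
```

## The problem

An RNA molecule does not simply fall into its minimum-free-energy (MFE)
structure: it explores an exponentially large landscape of secondary
structures, and for regulatory RNAs such as riboswitches the *order* in which
conformations are visited matters as much as their equilibrium weights.
Exact kinetic treatments (full enumeration plus a master equation over all
structures, or exact saddle computations) are limited to very short
sequences, and computing globally optimal folding pathways between two
structures is NP-hard. This package implements a three-part strategy:

1. **Abstraction.** Partition the folding space into *hishapes* — classes of
   structures sharing the same decorated helix indices — so that the state
   space shrinks from structures to classes while remaining a complete,
   non-heuristic partition.
2. **Pathways.** Estimate energy barriers between class representatives with
   a heuristic that anchors direct-path searches at *fuzzy related* hishapes
   and combines segments with a minimax (widest-bottleneck) Dijkstra search.
3. **Kinetics.** Treat the classes as states of a continuous-time Markov
   chain with Arrhenius rates derived from the estimated barriers and the
   classes' ensemble free energies, and propagate the master equation.

## Hishapes

A helix is a maximal run of stacked base pairs. Its innermost pair $(i,j)$
closes the helix's terminating loop, and the *helix index* is the central
position $(i+j)/2$ of that closing pair — a position-specific label that is
robust to helix extension or shortening at the outer end, and possibly
half-integral. Indices carry a marker for the terminating loop type: none
for hairpin loops, `m`, `b`, `i` for multiloops, bulges and internal loops.

Four abstraction levels form a refinement chain:

| level | retains |
|-------|---------|
| `h`   | hairpin helices only, flat list |
| `h+`  | adds multiloop nesting (parentheses) |
| `m`   | adds multiloop helices (`m` marker) |
| `a`   | adds bulge/internal helices (`b`, `i` markers) |

The canonical text form is a bracketed list such as `[4]` or
`[9.5m(6,13)]`; the open chain is `[_]`. Class counts grow monotonically
along `h` → `h+` → `m` → `a` on every input, since each level refines the
previous one.

For each class $\alpha$ the package computes the partition-function
contribution and ensemble energy
$$Z_\alpha = \sum_{x \in \alpha} e^{-\Delta G(x)/kT}, \qquad
  \Delta G(\alpha) = -kT \ln Z_\alpha,$$
the class probability $P(\alpha) = Z_\alpha / \sum_\beta Z_\beta$, and the
*hishrep*, the minimum-free-energy member that represents the class.

```{r}
classify("GGAAACC")
```

### Strictly negative structures

Suboptimal enumeration retains many structures containing helices whose
formation costs energy. The *strictly negative* (SN) filter demands that
every closed substructure whose parent loop is the exterior loop or a
multiloop has energy $\le 0$ kcal/mol (zero is allowed; the filter rejects
strictly positive substructures only). This prunes the space substantially
while keeping thermodynamically sensible conformations, at the known cost
that for some sequences the MFE structure itself is removed. Growth-law fits
with `growth_curve_fit()` (the abstract-shape asymptotics
$a \cdot b^n \cdot n^{-3/2}$) show a smaller exponential base $b$ for SN
hishapes than for the unrestricted space.

## The energy model

All algorithms here are energy-model-agnostic; the package ships a compact,
dangle-free nearest-neighbor table
(`system.file("extdata", "nn_compact.par", package = "hishapes")`) rather
than a full published parameter set:

* stacking free energies for all 36 ordered combinations of the canonical
  pairs AU, UA, GC, CG, GU, UG, obeying the thermodynamic symmetry
  $\Delta G(P/Q) = \Delta G(\overline{Q}/\overline{P})$;
* hairpin, bulge and internal loop initiations tabulated to size 30 with
  logarithmic extrapolation $\Delta G(s) = \Delta G(30) + \mathrm{lxc}
  \ln(s/30)$ beyond;
* an affine multiloop model (offset + per-branch + per-unpaired terms) and a
  terminal AU/GU penalty applied at helix ends abutting hairpin, bulge,
  internal and multiloops;
* the exterior loop contributes exactly 0 kcal/mol.

Defaults: $R = 0.0019872$ kcal/(mol K), $T = 310.15$ K, minimum hairpin loop
3 nt. The file format is documented in the file header and any table in the
same grammar can be supplied via `energy_parameters(file = ...)`, so results
can be recomputed under a different parameterization without touching the
algorithms. Under the bundled table an isolated 2-stack hairpin helix (e.g.
on `GGAAACC`) costs +2.44 kcal/mol — short helices are penalized, long GC
helices are strongly stabilizing, which is the qualitative shape real
parameter sets have.

## Structure space and moves

Structures are pseudoknot-free, lonely-pair-free (noLP: every pair stacks on
a neighbor), with canonical pairs only and hairpin loops of at least three
unpaired bases. `enumerate_structures()` generates the complete space by a
memoized interval recursion over *maximal* helices, which yields each
structure exactly once; the test suite cross-checks it against an
independent single-pair recursion that enumerates all pair sets and filters
for noLP.

The move set connecting structures adds or removes one pair, with a repair
rule that keeps the space lonely-pair-free:

* removal leaving exactly one lonely pair also deletes that pair;
* removal leaving two lonely remnants (the middle of a 3-stack) is
  discarded;
* an addition creating a lonely pair closes an adjacent pair
  ($(i{-}1,j{+}1)$ or $(i{+}1,j{-}1)$) when possible, else is discarded.

**Design choice.** When *both* adjacent completions of a lonely addition are
closable, this package emits both results as neighbors rather than picking
one by a fixed preference order. A fixed order looks harmless but makes the
relation asymmetric (a structure $A + \{p, q\}$ may be constructible from
$A$ only through one of the two orders), and symmetry is load-bearing: the
landscape graph used by the exact barrier oracle is undirected, and detailed
balance of the kinetic model presumes that if a move is possible so is its
reverse. The symmetry of the implemented relation is verified exhaustively
on enumerated fixtures.

A structure is *locally optimal* if no neighbor has strictly lower energy;
equal-energy neighbors do not disqualify a local optimum. The `localopt`
CLI subcommand tabulates, per abstraction level and for the unrestricted and
SN spaces, the fraction of hishreps that are locally optimal.

## Barrier estimation

The exact barrier between $S$ and $T$ is
$$\Delta G[S,T] = \min_{\text{paths } S \to T}\ \max_{x \in \text{path}}
  \Delta G(x)\; -\; \Delta G(S),$$
computable only on fully enumerated landscapes; `exact_barrier()` does this
with a best-first minimax sweep (default limit 30 nt) and serves as the
testing oracle. The heuristic stack consists of:

* **`direct_path_bfs()`** — width-$k$ beam search over *direct* paths
  (intermediates use only pairs of $S \cup T$). Every move strictly reduces
  the base-pair distance to the target; per level the $k$ best candidates
  are kept, ranked by running path maximum, then current energy, then
  dot-bracket (a deterministic tie-break). A state is re-expanded only when
  reached with a strictly better running maximum, and the search keeps going
  after the first complete path so a wider beam can only improve the result.
  Default $k = 10$.
* **`fuzzy_related_hishapes()`** — candidate anchors: hishapes all of whose
  hairpin indices lie within $\theta$ of some hairpin index of the two
  endpoint hishapes ($\theta = 0$ reduces to exact related hishapes; the
  open chain always qualifies). Default $\theta = 1$ helix-index unit; the
  threshold is user-defined by design and 1.0 admits single-position helix
  slippage, which is the phenomenon the fuzziness exists to capture.
* **`auto_k()`** — how many anchors to keep:
  $k = \mathrm{round}(124000 \cdot n^{-3/2})$, floored at 1. The constant is
  an empirical budget rule tied to the growth asymptotics of shape spaces;
  note that at $n = 500$ the formula gives 11.09, i.e. "approximately 10" —
  the formula is implemented literally with round-to-nearest.
* **`hipath2()`** — builds the node list $\{S, T\} \cup$ anchors (hishreps
  of the $N$ lowest-energy fuzzy related classes at level `h`), fills a
  symmetric matrix of segment saddle heights by running the BFS in both
  directions per pair and keeping the smaller saddle, then runs
  `minimax_dijkstra()` and concatenates the winning segments (junction
  hishreps deduplicated). Edge weights are *absolute* saddle heights, so the
  route bottleneck minus $\Delta G(S)$ is the reported barrier and the
  stitched path reproduces it exactly.

Because the direct $S$–$T$ edge is always in the graph, the anchored
estimate never exceeds the plain direct-path estimate, and every reported
path is a genuine neighbor chain, so it never beats the exact barrier:
exact $\le$ anchored $\le$ direct. This sandwich is asserted on every
oracle-checkable fixture.

## Kinetics

States are hishape classes; transitions use Arrhenius rates
$$r_{\beta\alpha} = A\, e^{-(\Delta G[\alpha,\beta] -
  \Delta G(\alpha))/kT},$$
with the saddle height $\Delta G[\alpha,\beta]$ estimated between the two
hishreps and the *ensemble* energy $\Delta G(\alpha)$ of the departing
class. Using ensemble energies weights transitions by class size: leaving a
large class is slower, entering it is faster. The prefactor default is
$A = 1.0\ \mu s^{-1}$, the literature calibration against experimental
folding rates; all times are in microseconds. The formula is applied
literally — no capping at $A$ when a saddle lies below the ensemble energy.

Storing one saddle height per unordered pair makes the barrier matrix
symmetric, which together with the rate formula yields exact detailed
balance $r_{\beta\alpha} Z_\alpha = r_{\alpha\beta} Z_\beta$; the stationary
distribution is therefore the Boltzmann distribution over ensemble energies,
matching `classify()` probabilities — asserted to $10^{-6}$ in the tests.
The generator (columns summing to zero) is propagated as
$p(t) = e^{tR} p(0)$:

* when detailed balance holds (always, by construction) the generator is
  symmetrized with $D = \mathrm{diag}(\sqrt{\pi})$ and solved by a symmetric
  eigendecomposition; eigenvalues within $10^{-10}$ of zero (relative) are
  clamped to exactly zero so that $e^{\lambda t}$ does not drift at
  $t = 10^8\ \mu s$;
* otherwise a dense scaling-and-squaring matrix exponential is used; both
  routes agree with a reference exponential to $10^{-8}$.

States with no finite-barrier connection are retained with zero rates and a
warning. The default time grid is 200 log-spaced points over
$10^{-2}$–$10^8\ \mu s$, mirroring the log-time axes customary for folding
kinetics. `simulate_kinetics()` runs the full pipeline; the initial
distribution is a unit vector on a chosen hishape (default the open chain
`[_]`), and the open chain and the initial state are always added to the
`k_best` states simulated.

## Synthetic fixtures

`random_sequences()` draws i.i.d. bases at a target GC fraction with a
seeded Mersenne-Twister, leaving the caller's RNG untouched. Fixture
defaults used across the tests: GC 0.5 for space-counting protocols
(agnostic random sequences), GC 0.6–0.65 for barrier and kinetics fixtures
(at desk scale, equal-GC random 20–25-mers frequently have an unstructured
MFE under the bundled table; mildly GC-rich draws give structured optima
while keeping spaces in the hundreds of structures). Enumeration-bound sizes
used in the tests: 20–30 nt for space enumeration, ≤ 25 nt for landscape
oracles, chosen so the complete landscape stays in the hundreds-to-thousands
of nodes.

`bistable_sequence()` builds `L AAA M AAA R` with `M = revcomp(L)` and `R`
a one-position mutant of `L`: the central segment can pair upstream or
downstream but not both. Candidates are drawn (boundedly, deterministically
from the seed) until the two best non-open classes are within 1 kcal/mol,
mutually exclusive, both stabilizing, and — the operational signature of a
kinetic switch — the class with the lower nucleation saddle from the open
chain is *not* the thermodynamically preferred one. With that construction
the master equation started from `[_]` shows the metastable class rising
first and being overtaken by the equilibrium winner, the occupancy-crossing
phenomenology of natural bistable RNAs.

What the fixtures do *not* emulate: natural sequence composition and length
(real switches are 50–400 nt), pseudoknots, modified bases,
co-transcriptional folding, and the published Turner parameterization.
Passing tests demonstrate internal correctness of enumeration,
classification, barriers and kinetics at desk scale — not quantitative
agreement with wet-lab kinetics of any particular RNA.

## Numerical choices and degenerate inputs

* Boltzmann sums are computed relative to the space minimum to avoid
  overflow; partition conservation is asserted at relative error
  $< 10^{-9}$.
* All orderings (enumeration output, class ranking, beam candidates,
  Dijkstra ties) break ties lexicographically on dot-bracket or hishape
  text, making every result deterministic.
* Energy comparisons use a $10^{-12}$ kcal/mol slack; "strictly negative"
  means $\le 0$ (a zero-energy substructure is allowed).
* The open chain is always a valid structure, its own hishape `[_]`, and
  vacuously strictly negative, so classification never returns an empty
  state set.
* Exhaustive enumeration refuses sequences beyond 60 nt unless an energy
  band is supplied (banding filters the exhaustive space; it does not change
  the backend's cost, which is why the limit exists).
* `minimax_dijkstra()` and `exact_barrier()` raise an explicit
  "unreachable" error for disconnected inputs; `hipath2()` converts that
  into an infinite-barrier path object.

## Known limitations

* Classification is by explicit enumeration, not a grammar-based dynamic
  program: exact and fully testable at desk scale, but not usable at the
  hundreds-of-nucleotides scale where a DP backend would be required.
* The bundled energy table is compact by design; absolute energies differ
  from published parameter sets even though the model shape matches.
* Direct-path search explores only direct paths per segment; indirect
  detours are captured only through anchoring, as in the heuristic this
  package implements.
* The Arrhenius prefactor sets an arbitrary global timescale; occupancy
  *orderings* and equilibria are meaningful, absolute times only relative to
  $1/A$.
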