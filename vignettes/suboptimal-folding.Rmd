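---
title: "Complete enumeration of suboptimal RNA secondary structures"
author: "wuchtyfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complete enumeration of suboptimal RNA secondary structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wuchtyfold)
```

# The problem

Free-energy minimization yields one structure per RNA sequence, but for many
sequences very different secondary structures lie within a narrow band of
free energy, and chemical probing data rarely pin down a unique fold.
`wuchtyfold` enumerates *every* non-pseudoknotted secondary structure whose
free energy lies within a chosen window above the minimum free energy (MFE),
so that the density and diversity of structures near the bottom of the
folding funnel can be examined directly rather than sampled.  With an
infinite window the enumeration is combinatorially complete — every pair set
satisfying the pairing rules is produced exactly once.

# The enumeration model

A *state* is a pair $(\sigma, P)$: a list of unevaluated closed intervals
$\sigma$ and a set of fixed base pairs $P$.  The root state holds the single
interval $[1, n]$ and no pairs — the completely undetermined structure of
free energy zero.  Refining a state removes its last interval $[i, j]$ and
produces children: one in which $j$ is unpaired (interval $[i, j-1]$
retained), and one per admissible pair involving $j$.  Each child carries

* $\Delta G_P$ — the exactly accumulated free energy of the determined
  portion (stacks, closed loops, terminal AU/GU charges), and
* $\Delta G_\sigma$ — the sum over its intervals of a dynamic-programming
  lower bound on the best achievable energy inside each interval.

A child survives only while $\Delta G_P + \Delta G_\sigma \le
\mathrm{MFE} + W$.  Because the bounds are exact minima from the Zuker fill
step, every surviving state leads to at least one in-window structure and no
in-window structure is lost: states with empty $\sigma$ are leaves, emitted
exactly once each.

Internally the intervals are typed by the refinement grammar (exterior-like,
closed-by-boundary-pair, multibranch component), mirroring the three fill
arrays `W`/`V`/`WM`; the closed type additionally records whether the
enclosing pair is Watson–Crick, which the probing rule below needs.  The
grammar is unambiguous — every structure has exactly one derivation — which
is what guarantees duplicate-free output and makes parallel partitioning of
the tree safe.

## Energies

All energies are handled as integer tenths of kcal/mol so that window
comparisons are exact; energies are converted to kcal/mol at the interface.
The shipped parameter set (`loadEnergyParams()`) is a compact Turner-style
nearest-neighbor table: stacking energies for all 36 ordered combinations of
the six pair types (AU, CG, GC, UA, GU, UG), hairpin/bulge/internal loop
initiations tabulated to length 30 with the standard $1.75\,RT
\ln(\mathrm{len}/30)$ logarithmic extension beyond, an affine multibranch
model $a + b\cdot\mathrm{branches} + c\cdot\mathrm{unpaired}$ (defaults 3.4,
0.4, 0.0 kcal/mol), and a 0.5 kcal/mol terminal penalty charged once per
helix end closed by AU/UA/GU/UG.  Dangling ends and coaxial stacking are
deliberately excluded; every quantitative claim the package tests is either
energy-independent (the combinatorial counts) or internally consistent
(window membership, oracle equivalence), so bit-exact agreement with any
published table is not required and not claimed.  Users can supply their own
tables in the documented plain-text dialect.

Two conventions are worth stating precisely because they make the evaluator,
the DP and the enumerator mutually consistent:

* **Terminal AU/GU charges** are attributed to loops: a hairpin, internal
  loop, bulge of length ≥ 2, multibranch loop or the exterior loop charges
  the penalty for each adjacent AU/UA/GU/UG closing pair; stacks and 1-nt
  bulges (which continue a helix) charge none.  A pair in mid-helix is
  therefore never charged and an isolated pair is charged twice — i.e. once
  per helix end.
* **Interior loops are not capped at 30 nt.**  The Vienna lineage caps loop
  *generation* at 30; a generation cap would make the combinatorial
  enumeration incomplete (and the exact counts wrong), so this package only
  caps the *tables* and extrapolates the energy logarithmically beyond.

## No-lonely-pairs pruning (energy-independent)

The classical way to suppress isolated pairs is a large energy penalty, which
silently fails once the window grows past the penalty.  Here the option is a
pure pruning rule: a pair can acquire a stacked neighbor only through an
outer pair already present when it is created, or through the stack child of
its own closed interval.  Hence when a closed interval $(i,j)$ is refined
into any non-stack child (hairpin, bulge, internal, multibranch) and
$(i{-}1, j{+}1) \notin P$, the pair $(i,j)$ is permanently lonely and that
child is discarded instead of being pushed.  The rule is exact: the output
with the flag equals the unpruned output minus exactly the structures
containing an isolated pair (property-tested against the brute-force
oracle).  The window stays referenced to the MFE of the *unpruned* model, so
the flag is a filter, not a re-centering of the window.

## Constraints

Hard constraints: `x` forces a nucleotide unpaired; `(`/`)` force a pair
(structures incompatible with it — crossing pairs, other partners, either
position unpaired — are pruned); an optional maximum pair span bounds
$j - i$ (implemented but off by default, since the headline computations do
not use it).

Context-dependent probing (`m`): a chemically modified nucleotide may sit in
a Watson–Crick pair at a helix end, adjacent to a loop or bulge, or
in/adjacent to a GU pair — but never as a Watson–Crick pair flanked on both
sides by Watson–Crick pairs.  Because refinement adds pairs strictly
outside-in, the full triple (outer, probed, inner) is only known when the
innermost pair of the sandwich is proposed; the engine therefore rejects
*that proposal*, preserving the tree-pruning formulation.  Sequence-terminal
pairs count as helix ends (no outer pair can exist).  A probed nucleotide in
a GU pair is always admissible, and a Watson–Crick pair next to a GU pair is
admissible even when its other neighbor is Watson–Crick — the reading of the
probing chemistry adopted here and isolated behind `allowPair()` so it can
be revisited.

## Optional multibranch loops

With `noMultibranch`, the fill step grants no multibranch energies to pairs
(so bounds stay valid) and the refinement never generates a second branch
directly inside a closed pair: structures become series of stem-loop
hairpins, while the exterior loop may still hold arbitrarily many stems.
Enabling multiloops can only lower the MFE, and the package asserts that
direction on every test sequence.

## Helix filter

`findHelices()` partitions the pair set into maximal runs where consecutive
pairs either stack directly or skip one position on both sides (a 1×1
internal loop, counted as one mismatch); bulges and anything larger start a
new helix.  `helixFilterPass()` requires a minimum number of helices of a
minimum pair length under a per-helix mismatch budget.  Helix sizes are
unknowable before a structure is complete, so the filter applies at emission
(pruning earlier on remaining-nucleotide arithmetic buys little and is not
attempted).  "Mismatch" = single 1×1 internal loop is the minimal reading of
helix-counting conventions in the literature; the definition is isolated
behind `findHelices()` so it can be swapped.

## Counting

`countStructures()` is an independent dynamic program (not the enumeration
grammar): it counts, with exact big-integer arithmetic, all structures
compatible with the pairing rules, minimum hairpin loop and constraints —
including the context-dependent probing rule, which is handled by splitting
the paired-interval count on whether the enclosing pair is Watson–Crick.
Counts up to $2^{53}$ return as numerics, larger counts as decimal strings.
For the printed 14-mer `GCUCUAAAAGAGAG` and its 2× and 3× concatenations the
count (and the enumerator, and the brute-force oracle) give 119, 124,926 and
197,316,085 structures.  The crude growth estimate $1.8^N$ is exposed as
`estimateStructureCount()`; at $N = 247$ it evaluates to $1.128\times
10^{63}$ (often quoted, truncated, as $1.12\times 10^{63}$).

## Low-memory mode

The direct implementation pushes all children of a node, so the memory held
before the first structure can be written is on the order of depth ×
branching factor.  `lowMemory = TRUE` instead stores one branch per level
plus the iteration cursor needed to resume the parent exactly where it left
off; the retained state count before the first emission is then linear in
sequence length (asserted ≤ 3N + 5 in the tests).  The two modes produce
byte-identical sorted output.

## Parallel driver

`runParallel()` implements a master–worker scheme: the master seeds its
stack with the root state, workers start empty and send `need_work`; the
master answers with `grant_state` (one state) or `terminate`.  A worker
whose stack exceeds the share threshold sends the *oldest* (shallowest) half
back (`share_states`) — shallow states carry the most remaining work, which
is what balances load without estimating work per branch.  Since state
refinements are independent and the grammar is unambiguous, sharing one
refinement stack yields a complete, non-duplicating exploration: sorted
parallel output is byte-identical to serial for every worker count and
threshold, which the acceptance tests assert on a 4 × 3 grid.

Two transports ship behind one protocol: a deterministic in-process
scheduler (the default — it makes the message flow fully instrumentable and
testable, and desk-scale runs gain nothing from extra processes), and a
fork-based backend in which each grant runs in a child process and all
states cross the process boundary through `stateSerialize()`.  Every
process recomputes its own fill tables from the run parameters rather than
receiving them, which keeps messages small.  A cluster MPI transport is out
of scope.

# The synthetic fixtures

`generateFixture("random_seq", n, seed)` draws uniform ACGU sequences — the
regime in which the brute-force oracle is feasible (lengths 8–16 for the
oracle-equivalence suite, 20 for the parallel grid, windows 0–8 kcal/mol and
infinite).  `generateFixture("planted_probing")` returns a fixed designed
16-nt hairpin, `GGCAGGAAAACUUGCC`, whose single helix instantiates every
context case of the probing rule at a known position: a helix-end pair
(1,16), a Watson–Crick pair sandwiched by Watson–Crick pairs (2,15), a
Watson–Crick pair adjacent to a GU pair (4,13), the GU pair itself (5,12),
and a loop-adjacent pair (6,11) — with the expected admissibility of probing
each position recorded for post-hoc verification of every emitted structure.

What the generator does *not* emulate: base composition bias, modified
nucleotides beyond the probed mark, pseudoknots, tertiary or protein
contacts, and the scale of natural test cases (a 1,058-nt viral genome,
billions of structures).  Passing tests therefore demonstrate algorithmic
correctness — set equality with an exhaustive oracle under every option —
not biological accuracy of the shipped energy table on long natural
sequences.

# Numerical and design choices

* Integer tenths of kcal/mol internally; window membership uses `<=` in
  integers, so float accumulation can never flip a structure across the
  window edge.
* Refinement order is fixed (interval from the tail of σ; unpaired-j child
  first, then pairing candidates with ascending 5' position) purely for
  reproducibility; output order is unspecified unless `sortOutput`, which
  orders by energy then lexicographic dot-bracket.
* Minimum hairpin loop is an option but validated ≥ 3: the shipped tables
  are undefined below 3 and all printed counts use 3.
* The counting DP ignores `noLonelyPairs` by design (it counts the
  enumerator's leaves with an infinite window and no lonely-pair pruning)
  but honors `noMultibranch`, constraints and the span bound.
* Degenerate inputs: a sequence with no pairable nucleotides yields the
  open chain (count 1, MFE 0); infeasible constraint systems yield an empty
  enumeration; a safety cap (`maxStructures`, default 10^7) stops runaway
  combinatorial runs with a structured warning.
* Problem sizes in the shipped tests: oracle equivalence over 200 random
  8–16-mers; the parallel grid on the 14-mer and five random 20-mers at a
  5 kcal/mol window; counts up to the 42-mer (197,316,085) via the DP and
  up to the 28-mer (124,926) by full enumeration.

# Known limitations

* The energy model is a compact Turner-style set: no dangles, no coaxial
  stacks, no temperature rescaling, no sequence-specific loop corrections
  (tetraloop boni, asymmetry penalties).  Published free energies from other
  packages will differ; windows are self-consistent, not transferable.
* No pseudoknots, no partition function, no Boltzmann sampling.
* The probing rule is the qualitative helix-context rule, not
  reactivity-valued pseudo-energies.
* The parallel driver targets desk scale; it demonstrates and tests the
  protocol, not cluster throughput.

# A worked example

```{r example}
res <- enumerateSuboptimal("GCUCUAAAAGAGAG")
length(res)                 # 119 combinatorially possible structures
res@mfe
ls <- landscapeSummary(res)
str(ls[c("count", "energySpan", "maxDistance", "meanDistance")])

# context-dependent vs hard probing constraint at position 2
n <- 14
soft <- countStructures("GCUCUAAAAGAGAG",
                        constraints = parseConstraintString(".m............", n))
hard <- countStructures("GCUCUAAAAGAGAG",
                        constraints = parseConstraintString(".x............", n))
c(soft = soft, hard = hard)
```
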