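# wuchtyfold

Combinatorially complete enumeration of non-pseudoknotted RNA secondary
structures within a free-energy window — with energy-independent
no-lonely-pair pruning, hard and context-dependent chemical-probing
constraints, optional multibranch loops, a post-hoc helix filter, a
low-memory depth-first mode, exact big-integer structure counting, landscape
metrics, and a master–worker parallel driver that reproduces the serial
result set.

The package is for structural-RNA researchers who need *all* structures near
a free-energy minimum — to test whether probing data define a unique fold, to
model encapsidated viral RNA against crystallographic helix counts, or to
characterize the shape (funnel vs. basin) of a folding landscape — rather
than samples from it.

## The algorithm

A state is a pair (σ, P): unevaluated intervals σ and fixed base pairs P.
The root state is ([1, n], ∅), the undetermined structure of free energy
zero.  Refining a state removes an interval [i, j] from σ and branches on
the fate of j: unpaired, giving (σ + [i, j−1], P), or paired with k, giving
(σ + [i, k−1] + [k+1, j−1], P + (k, j)).  Each child carries ΔG_P — the
exact nearest-neighbor energy of its determined portion — and ΔG_σ — the sum
of Zuker dynamic-programming lower bounds over its intervals — and survives
only while

    ΔG_P + ΔG_σ  ≤  MFE + W

for the chosen window W.  Leaves (σ = ∅) are completely determined
structures, emitted exactly once each; with W = ∞ the enumeration is
combinatorially complete.  Energies are integer tenths of kcal/mol
internally, so window membership is exact.

On top of the classic scheme the package adds:

* **No lonely pairs, energy-independent** — a branch is discarded (not
  penalized) the moment a pair has permanently lost the possibility of a
  stacked neighbor, so isolated pairs never leak into large windows.
* **Probing constraints** — `x` forces a nucleotide unpaired; `m` marks a
  chemically modified nucleotide that may sit in a Watson–Crick pair only at
  a helix end, adjacent to a loop/bulge, or in/adjacent to a GU pair — never
  Watson–Crick-sandwiched.  Forced pairs `(`…`)` prune everything
  incompatible with them.
* **Optional multibranch loops** — series-of-hairpin structures only, the
  cotranscriptional-folding picture.
* **Helix filter** — keep only structures with ≥ COUNT helices of ≥ LEN
  pairs under a per-helix 1×1-mismatch budget (e.g. `30:9:3` for
  crystallography-constrained encapsidated RNA).
* **Exact counting** — an independent big-integer DP over the same structure
  space, plus the 1.8^N growth estimate.
* **Parallel driver** — master–worker work sharing with a configurable
  share threshold; sorted output is byte-identical to serial for any worker
  count.

## A worked example

The 14-mer `GCUCUAAAAGAGAG` is small enough to check by hand and designed so
that every context case of the probing rule occurs:

```r
library(wuchtyfold)

res <- enumerateSuboptimal("GCUCUAAAAGAGAG",
                           options = foldOptions(sortOutput = TRUE))
res
#> SuboptResult 'seq': 119 structures over 14 nt; energies [-0.70, 12.80] kcal/mol
#>   GCUCUAAAAGAGAG
#>   .((((...))))..  -0.70
#>   .((((.....))))  -0.40
#>   ..............   0.00
#>   .(((.....)))..   1.20
#>   .(((.......)))   1.50
#>   ...
```

119 is the complete combinatorial count for this sequence (the open chain
included); the first line is the MFE structure at −0.70 kcal/mol under the
shipped parameter set.  The landscape summary compares every structure to
the MFE structure by base-pair distance:

```r
unlist(landscapeSummary(res)[c("count", "energySpan", "maxDistance", "meanDistance")])
#>        count   energySpan  maxDistance meanDistance
#>   119.000000    13.500000     8.000000     4.773109
```

Context-dependent probing constraints prune less than hard single-strand
constraints on the same position — here probing position 3:

```r
cs_soft <- parseConstraintString("..m...........", 14)
cs_hard <- parseConstraintString("..x...........", 14)
c(soft = countStructures("GCUCUAAAAGAGAG", constraints = cs_soft),
  hard = countStructures("GCUCUAAAAGAGAG", constraints = cs_hard))
#> soft hard
#>  113   40
```

Counting scales far beyond what enumeration should attempt — the 3×
concatenation of the 14-mer has

```r
countStructures(strrep("GCUCUAAAAGAGAG", 3))
#> [1] 197316085
```

structures, computed exactly in milliseconds.  A parallel run reproduces the
serial set while spreading the refinement tree over workers:

```r
par <- runParallel("GCUCUAAAAGAGAG", config = runConfig(nWorkers = 4, shareThreshold = 8))
length(par)
#> [1] 119
```

A command-line interface wrapping these functions ships in
`inst/scripts/wuchtyfold` (subcommands `fold`, `count`, `eval`, `distance`,
`fixtures`; see `--help` of each).

## Parameter files

`loadEnergyParams()` reads plain-text blocks in kcal/mol — `[stack]` (6×6,
pair order AU CG GC UA GU UG), `[hairpin]`, `[bulge]`, `[internal]` (loop
tables from length 1; `Inf` for forbidden lengths), `[multiloop]` (closing,
per-branch, per-unpaired), `[misc]` (terminal AU/GU penalty, logarithmic
loop-extrapolation coefficient, temperature in K).  The shipped default is
`inst/extdata/params/default.par`, reproduced in full there; see the
vignette for the model's conventions and limitations.

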