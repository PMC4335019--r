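#' Folding run options
#'
#' @param window energy window above the MFE in kcal/mol (`Inf` enumerates the
#'   complete combinatorial space).
#' @param noLonelyPairs prune branches in which a pair has permanently lost
#'   the possibility of a stacked neighbor (energy-independent).
#' @param noMultibranch disallow multibranch loops inside closed pairs,
#'   forcing series-of-hairpin structures (the exterior loop may still hold
#'   many stems).
#' @param lowMemory use the depth-first single-branch iterator.
#' @param minHairpin minimum unpaired hairpin-loop length (>= 3).
#' @param maxStructures safety cap on emitted structures; exceeding it stops
#'   the enumeration with a warning.
#' @param sortOutput sort output by energy, then lexicographically by
#'   dot-bracket.
#' @param helixFilter optional [HelixFilterSpec-class] applied post hoc to
#'   completed structures.
#' @return a [FoldOptions-class].
#' @export
foldOptions <- function(window = Inf, noLonelyPairs = FALSE,
                        noMultibranch = FALSE, lowMemory = FALSE,
                        minHairpin = 3L, maxStructures = 1e7,
                        sortOutput = FALSE, helixFilter = NULL) {
  new("FoldOptions", window = as.numeric(window),
      noLonelyPairs = isTRUE(noLonelyPairs),
      noMultibranch = isTRUE(noMultibranch),
      lowMemory = isTRUE(lowMemory),
      minHairpin = as.integer(minHairpin),
      maxStructures = as.numeric(maxStructures),
      sortOutput = isTRUE(sortOutput),
      helixFilter = helixFilter)
}

# plain-list form consumed by the C++ core
.optsList <- function(options) {
  validObject(options)
  list(window = options@window,
       noLonelyPairs = options@noLonelyPairs,
       noMultibranch = options@noMultibranch,
       minHairpin = options@minHairpin,
       maxStructures = options@maxStructures)
}

#' Fill the Zuker dynamic-programming tables
#'
#' Computes the minimum-free-energy tables used both to report the MFE and as
#' admissible lower bounds on unevaluated intervals during the refinement
#' backtrack.  Pairs disallowed by the constraints have `V = Inf`; with
#' `noMultibranch` the multibranch contribution is omitted from `V`, so pairs
#' that could only close multiloops are not granted those energies.
#'
#' @param seq RNA sequence (character or Biostrings object).
#' @param params an [EnergyParams-class]; default the shipped set.
#' @param constraints a [ConstraintSet-class] or `NULL`.
#' @param options a [FoldOptions-class].
#' @return a [FoldMatrices-class].
#' @examples
#' fm <- fillMatrices("GGGGAAAACCCC")
#' fm@mfe
#' @export
fillMatrices <- function(seq, params = loadEnergyParams(), constraints = NULL,
                         options = foldOptions()) {
  s <- .normalizeSeq(seq)
  n <- nchar(s)
  enc <- .encodeSeq(s)
  tb <- .wf_fill(enc, .modelTenths(params), .consList(constraints, n),
                 .optsList(options))
  toK <- function(m) { m[m >= .INF_E] <- Inf; m / 10 }
  # externally visible V includes the terminal AU/GU charge seen from the
  # exterior, so that W[i,j] <= V[i,j] holds as stated
  au <- matrix(0, n, n)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    t <- .pairTypeMatrix[ch[i], ch[j]]
    if (t %in% c(1L, 4L, 5L, 6L)) au[i, j] <- params@terminalAU
  }
  V <- toK(tb$Vn) + au
  mfe <- if (tb$mfeT >= .INF_E) NA_real_ else tb$mfeT / 10
  new("FoldMatrices", seq = s, V = V, W = toK(tb$F), WM = toK(tb$M),
      mfe = mfe,
      tablesT = list(Vn = tb$Vn, Vw = tb$Vw, M = tb$M, F = tb$F,
                     mfeT = tb$mfeT))
}

#' Minimum free energy of a sequence
#'
#' @inheritParams fillMatrices
#' @return numeric, kcal/mol (0 for a sequence that cannot pair).
#' @export
mfe <- function(seq, params = loadEnergyParams(), constraints = NULL,
                options = foldOptions()) {
  fillMatrices(seq, params, constraints, options)@mfe
}

#' Count secondary structures exactly
#'
#' Energy-free exact count of every structure satisfying the pairing rules
#' (Watson-Crick plus GU wobble), the minimum hairpin loop, and the
#' constraints -- i.e. the number of leaves the enumerator emits with an
#' infinite energy window and no lonely-pair pruning.  The open-chain
#' (empty) structure is included.  The dynamic program is independent of the
#' enumeration grammar and uses exact big-integer arithmetic; counts beyond
#' 2^53 are returned as decimal strings.
#'
#' @inheritParams fillMatrices
#' @param as `"auto"` returns numeric when exactly representable, otherwise a
#'   decimal string; `"character"` always returns the string.
#' @return numeric count, or decimal string for very large counts.
#' @examples
#' countStructures("GCUCUAAAAGAGAG")   # 119
#' @export
countStructures <- function(seq, constraints = NULL, options = foldOptions(),
                            as = c("auto", "character")) {
  as <- match.arg(as)
  s <- .normalizeSeq(seq)
  n <- nchar(s)
  cnt <- .wf_count(.encodeSeq(s), .consList(constraints, n),
                   .optsList(options))
  if (as == "character" || nchar(cnt) > 15) cnt else as.numeric(cnt)
}

#' Estimate the number of secondary structures from sequence length
#'
#' The standard asymptotic estimate `1.8^N` for the number of combinatorially
#' feasible secondary structures of an N-nucleotide sequence.
#'
#' @param n sequence length, >= 1.
#' @return numeric, `1.8^n`.
#' @examples
#' estimateStructureCount(14)
#' signif(estimateStructureCount(247), 3)   # 1.12e63
#' @export
estimateStructureCount <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1)
    stop("validation error: n must be a single number >= 1")
  1.8^n
}
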