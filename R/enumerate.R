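#' Enumerate all suboptimal structures within an energy window
#'
#' Stack-based refinement of partially determined structures: a state is a
#' list of unevaluated intervals plus a set of fixed pairs; refining an
#' interval either leaves its 3' nucleotide unpaired or pairs it, and a child
#' survives only while the exactly-known energy of its determined portion
#' plus the table lower bound on its intervals stays within `mfe + window`.
#' Every structure with energy at most `mfe + window` that satisfies the
#' constraints is emitted exactly once.  With an infinite window the
#' enumeration is combinatorially complete.
#'
#' Options: `noLonelyPairs` discards (rather than penalizes) any branch in
#' which a pair has permanently lost the possibility of a stacked neighbor,
#' so isolated pairs never appear regardless of window size;
#' `noMultibranch` never places more than one helix directly inside a closed
#' pair; `lowMemory` switches to the depth-first single-branch iterator,
#' which stores one branch per tree level so the retained state count before
#' the first emitted structure grows linearly with sequence length;
#' `helixFilter` drops completed structures that do not meet the helix
#' count/length/mismatch criteria (applied at the last stage, since helix
#' sizes are only known once the structure is complete).
#'
#' @inheritParams fillMatrices
#' @param name sequence name used in output files.
#' @return a [SuboptResult-class] with one dot-bracket and energy per
#'   structure, the run MFE, and enumeration diagnostics (states processed,
#'   peak stored states, peak stored states before the first emission).
#' @examples
#' res <- enumerateSuboptimal("GCUCUAAAAGAGAG")
#' length(res)   # 119 combinatorially possible structures
#' @export
enumerateSuboptimal <- function(seq, constraints = NULL,
                                options = foldOptions(),
                                params = loadEnergyParams(),
                                name = "seq") {
  s <- .normalizeSeq(seq)
  n <- nchar(s)
  validObject(options)
  windowT <- if (is.finite(options@window)) round(options@window * 10) else Inf
  raw <- .wf_enumerate(.encodeSeq(s), .modelTenths(params),
                       .consList(constraints, n), .optsList(options),
                       options@lowMemory, as.numeric(windowT))
  if (isTRUE(raw$truncated))
    warning(sprintf("enumeration truncated at the safety cap of %g structures; raise maxStructures to continue",
                    options@maxStructures))
  db <- raw$db
  energy <- raw$energyT / 10
  if (!is.null(options@helixFilter) && length(db)) {
    keep <- vapply(db, function(d)
      helixFilterPass(secondaryStructure(s, d), options@helixFilter),
      logical(1), USE.NAMES = FALSE)
    db <- db[keep]
    energy <- energy[keep]
  }
  if (options@sortOutput && length(db)) {
    o <- order(energy, db, method = "radix")
    db <- db[o]
    energy <- energy[o]
  }
  new("SuboptResult", name = name, seq = s, db = db, energy = energy,
      mfe = if (is.na(raw$mfeT) || raw$mfeT >= .INF_E) NA_real_
            else raw$mfeT / 10,
      options = options,
      diagnostics = list(statesProcessed = raw$processed,
                         maxStatesBeforeFirst = raw$maxStatesBeforeFirst,
                         maxStates = raw$maxStates,
                         truncated = isTRUE(raw$truncated)))
}

#' Sort an ensemble by energy, then dot-bracket
#'
#' @param x a [SuboptResult-class].
#' @return the sorted ensemble.
#' @export
sortStructures <- function(x) {
  if (!length(x@db)) return(x)
  o <- order(x@energy, x@db, method = "radix")
  initialize(x, db = x@db[o], energy = x@energy[o])
}

#' Brute-force enumeration oracle
#'
#' Recursively enumerates every pair set satisfying the structural
#' invariants (Watson-Crick plus GU pairs, minimum hairpin loop,
#' non-crossing) and the constraint set, with no energy model, no
#' thermodynamic tables and no pruning heuristics shared with the refinement
#' engine.  Intended as an independent oracle for testing; refuses sequences
#' longer than `maxLen`.
#'
#' @inheritParams fillMatrices
#' @param maxLen refusal guard against combinatorial explosion.
#' @return character vector of dot-bracket strings (the open chain included).
#' @examples
#' length(bruteForceEnumerate("GCUCUAAAAGAGAG"))   # 119
#' @export
bruteForceEnumerate <- function(seq, constraints = NULL,
                                options = foldOptions(), maxLen = 25) {
  s <- .normalizeSeq(seq)
  n <- nchar(s)
  if (n > maxLen)
    stop(sprintf("refusal: brute-force enumeration guarded at %d nt (got %d)",
                 maxLen, n))
  .wf_brute(.encodeSeq(s), .consList(constraints, n), .optsList(options))
}

# ---------------------------------------------------------------------------
# partial states at the R level
# ---------------------------------------------------------------------------

.stateFromList <- function(lst) {
  new("PartialState",
      sigma = matrix(as.integer(lst$sigma), ncol = 3,
                     dimnames = list(NULL, c("i", "j", "type"))),
      pairs = matrix(as.integer(lst$pairs), ncol = 2),
      dgP = as.integer(lst$dgP), dgSig = as.integer(lst$dgSig))
}

.stateToList <- function(state) {
  list(sigma = matrix(as.integer(state@sigma), ncol = 3),
       pairs = matrix(as.integer(state@pairs), ncol = 2),
       dgP = as.numeric(state@dgP), dgSig = as.numeric(state@dgSig))
}

#' The completely unrefined root state
#'
#' A single unevaluated interval spanning the whole sequence with no fixed
#' pairs: the undetermined secondary structure whose free energy is zero.
#'
#' @param matrices a [FoldMatrices-class] from [fillMatrices()].
#' @return a [PartialState-class].
#' @export
rootState <- function(matrices) {
  n <- nchar(matrices@seq)
  bound <- matrices@tablesT$mfeT
  new("PartialState",
      sigma = matrix(c(1L, n, 0L), 1, 3,
                     dimnames = list(NULL, c("i", "j", "type"))),
      pairs = matrix(integer(), 0, 2),
      dgP = 0L, dgSig = as.integer(bound))
}

#' Is a state a leaf (completely determined structure)?
#'
#' @param state a [PartialState-class].
#' @return logical.
#' @export
isLeafState <- function(state) nrow(state@sigma) == 0

#' The structure determined by a leaf state
#'
#' @param state a leaf [PartialState-class].
#' @param seq the sequence the state refers to.
#' @return a [SecondaryStructure-class] carrying the state's accumulated
#'   energy.
#' @export
leafStructure <- function(state, seq) {
  if (!isLeafState(state)) stop("state still has unevaluated intervals")
  secondaryStructure(seq, state@pairs, energy = state@dgP / 10)
}

#' Refine a partial state
#'
#' Removes the last unevaluated interval `[i, j]` and produces the viable
#' children: the state in which j is unpaired, and one state per admissible
#' pair involving j (or, inside a closed pair, per admissible loop closed by
#' the boundary pair).  A child is kept only while its determined energy plus
#' the table lower bound on its remaining intervals stays within
#' `mfe + window`; with `noMultibranch` children creating a second branch
#' inside a closed pair are not generated, and with `noLonelyPairs` children
#' in which a pair has become permanently isolated are discarded.
#'
#' @param state a non-leaf [PartialState-class].
#' @param matrices a [FoldMatrices-class] for the same sequence/constraints/
#'   options.
#' @inheritParams fillMatrices
#' @return list of [PartialState-class] children (possibly empty).
#' @export
refineState <- function(state, matrices, constraints = NULL,
                        options = foldOptions(),
                        params = loadEnergyParams()) {
  if (isLeafState(state))
    stop("state is a leaf; use leafStructure() to extract its structure")
  s <- matrices@seq
  n <- nchar(s)
  windowT <- if (is.finite(options@window)) round(options@window * 10) else Inf
  out <- .wf_refine(.stateToList(state), matrices@tablesT, .encodeSeq(s),
                    .modelTenths(params), .consList(constraints, n),
                    .optsList(options), as.numeric(windowT))
  lapply(out$children, .stateFromList)
}

#' Can a state be pruned because a pair is permanently lonely?
#'
#' True when some fixed pair (i, j) has no stacked neighbor among the fixed
#' pairs and no unevaluated interval could still provide one: the inner
#' neighbor (i+1, j-1) is rescuable only while both its positions lie in one
#' remaining interval, the outer neighbor (i-1, j+1) likewise.  When `seq`
#' is given, neighbor formability additionally requires a chemically legal
#' pair type at legal distance (and admissibility under `constraints`).
#'
#' @param state a [PartialState-class].
#' @param seq optional sequence for pair-type legality checks.
#' @param constraints optional [ConstraintSet-class].
#' @param minHairpin minimum hairpin loop used for the distance test.
#' @return logical.
#' @examples
#' # a pair with a stacked neighbor is never lonely:
#' st <- new("PartialState", sigma = matrix(integer(), 0, 3),
#'           pairs = rbind(c(1L, 10L), c(2L, 9L)), dgP = 0L, dgSig = 0L)
#' lonelyPairPrunable(st)
#' @export
lonelyPairPrunable <- function(state, seq = NULL, constraints = NULL,
                               minHairpin = 3L) {
  prs <- state@pairs
  if (!nrow(prs)) return(FALSE)
  sig <- state@sigma
  hasPair <- function(a, b) any(prs[, 1] == a & prs[, 2] == b)
  inOneInterval <- function(a, b) {
    if (a > b || nrow(sig) == 0) return(FALSE)
    any(sig[, 1] <= a & b <= sig[, 2])
  }
  formable <- function(a, b) {
    if (a < 1 || b - a < minHairpin + 1) return(FALSE)
    if (!inOneInterval(a, b)) return(FALSE)
    if (!is.null(seq)) {
      s <- .normalizeSeq(seq)
      if (b > nchar(s)) return(FALSE)
      if (.pairType(s, a, b) == 0L) return(FALSE)
      if (!is.null(constraints) && !allowPair(a, b, state, s, constraints))
        return(FALSE)
    }
    TRUE
  }
  for (r in seq_len(nrow(prs))) {
    i <- prs[r, 1]; j <- prs[r, 2]
    if (hasPair(i + 1, j - 1) || hasPair(i - 1, j + 1)) next
    if (formable(i + 1, j - 1) || formable(i - 1, j + 1)) next
    return(TRUE)
  }
  FALSE
}
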