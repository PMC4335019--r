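#' Nearest-neighbor energy parameters
#'
#' Holds a complete nearest-neighbor thermodynamic parameter set: stacking
#' energies for all 36 ordered combinations of the six allowed pair types
#' (AU, CG, GC, UA, GU, UG), loop-initiation tables for hairpin, bulge and
#' internal loops up to a tabulated maximum length, the affine multibranch
#' terms, the terminal AU/GU penalty, and the logarithmic loop-extrapolation
#' coefficient applied beyond the tabulated lengths.  All energies are free
#' energies at the stated temperature in kcal/mol.
#'
#' @slot stack 6x6 numeric matrix of stacking free energies; rows index the
#'   closing (outer) pair type, columns the stacked (inner) pair type, in the
#'   order AU, CG, GC, UA, GU, UG.
#' @slot hairpin numeric vector of hairpin-loop initiation energies indexed by
#'   loop length; entries below length 3 are `Inf` (such loops are sterically
#'   forbidden).
#' @slot bulge numeric vector of bulge-loop energies indexed by loop length.
#' @slot internal numeric vector of internal-loop energies indexed by total
#'   loop length (sum of both sides); length 1 is `Inf` (a 1-nt interruption
#'   on one side only is a bulge).
#' @slot multiloop numeric vector `c(closing, branch, unpaired)`: the affine
#'   multibranch model `a + b * branches + c * unpaired`.
#' @slot terminalAU numeric, penalty charged once per helix end closed by an
#'   AU, UA, GU or UG pair.
#' @slot loopExtrapolation numeric, coefficient of the `log(len/maxTab)`
#'   extension applied to loop tables beyond the tabulated maximum.
#' @slot temperature numeric, kelvin.
#' @slot source character, provenance label of the parameter set.
#' @seealso [loadEnergyParams()]
#' @export
setClass("EnergyParams", representation(
  stack = "matrix",
  hairpin = "numeric",
  bulge = "numeric",
  internal = "numeric",
  multiloop = "numeric",
  terminalAU = "numeric",
  loopExtrapolation = "numeric",
  temperature = "numeric",
  source = "character"
))

setValidity("EnergyParams", function(object) {
  msg <- character()
  if (!identical(dim(object@stack), c(6L, 6L)))
    msg <- c(msg, "stack table must be 6x6 (pair types AU,CG,GC,UA,GU,UG)")
  if (any(!is.finite(object@stack)))
    msg <- c(msg, "stack table must be finite for all pair-type combinations")
  nt <- length(object@hairpin)
  if (nt < 3 || length(object@bulge) != nt || length(object@internal) != nt)
    msg <- c(msg, "loop tables must share one tabulated maximum length >= 3")
  if (any(is.finite(object@hairpin[seq_len(min(2, nt))])))
    msg <- c(msg, "hairpin loops shorter than 3 must have infinite energy")
  if (length(object@multiloop) != 3)
    msg <- c(msg, "multiloop must be c(closing, branch, unpaired)")
  if (length(msg)) msg else TRUE
})

#' @describeIn EnergyParams compact display
#' @param object an `EnergyParams` object
#' @export
setMethod("show", "EnergyParams", function(object) {
  cat("EnergyParams (", object@source, ")\n", sep = "")
  cat("  stacks: 6x6, range [", min(object@stack), ", ", max(object@stack),
      "] kcal/mol\n", sep = "")
  cat("  loop tables to length ", length(object@hairpin),
      ", log extrapolation coefficient ", object@loopExtrapolation,
      " kcal/mol\n", sep = "")
  cat("  multiloop a,b,c = ", paste(object@multiloop, collapse = ", "),
      "; terminal AU/GU penalty ", object@terminalAU, " kcal/mol\n", sep = "")
})

#' Per-nucleotide folding constraints
#'
#' Per-position constraint codes (none / forced-unpaired / member of a forced
#' pair / chemically probed), the forced pairs themselves, and the optional
#' maximum pair span.  Forced-unpaired positions ("x") model S1
#' nuclease or chemical probing hits that are treated as hard single-strand
#' constraints; probed positions ("m") carry the context-dependent rule that
#' such a nucleotide may sit in a Watson-Crick pair only at a helix end,
#' adjacent to a loop or bulge, or in/adjacent to a GU pair -- never as a
#' Watson-Crick pair flanked on both sides by Watson-Crick pairs.
#'
#' @slot n integer, sequence length.
#' @slot code integer vector of length `n`: 0 none, 1 forced unpaired,
#'   2 member of a forced pair, 3 probed (context-dependent).
#' @slot forcedPairs two-column integer matrix of forced pairs (i < j).
#' @slot maxPairSpan integer, maximum allowed `j - i` for any pair;
#'   `NA` disables the bound (the default).
#' @seealso [parseConstraintString()], [emptyConstraints()]
#' @export
setClass("ConstraintSet", representation(
  n = "integer",
  code = "integer",
  forcedPairs = "matrix",
  maxPairSpan = "integer"
))

setValidity("ConstraintSet", function(object) {
  msg <- character()
  if (length(object@code) != object@n)
    msg <- c(msg, "code vector length must equal n")
  if (any(!object@code %in% 0:3))
    msg <- c(msg, "constraint codes must be in 0:3")
  fp <- object@forcedPairs
  if (ncol(fp) != 2) msg <- c(msg, "forcedPairs must have two columns")
  if (nrow(fp)) {
    if (any(fp < 1) || any(fp > object@n) || any(fp[, 1] >= fp[, 2]))
      msg <- c(msg, "forced pairs must satisfy 1 <= i < j <= n")
    pos <- as.vector(fp)
    if (anyDuplicated(pos))
      msg <- c(msg, "forced pairs overlap: a position may appear once only")
    if (any(object@code[pos] == .C_UNPAIRED))
      msg <- c(msg, sprintf(
        "position %d is both forced-unpaired and in a forced pair",
        pos[which(object@code[pos] == .C_UNPAIRED)[1]]))
    if (nrow(fp) > 1) {
      for (a in seq_len(nrow(fp) - 1)) for (b in (a + 1):nrow(fp)) {
        i <- fp[a, 1]; j <- fp[a, 2]; k <- fp[b, 1]; l <- fp[b, 2]
        if ((i < k && k < j && j < l) || (k < i && i < l && l < j))
          msg <- c(msg, sprintf("forced pairs (%d,%d) and (%d,%d) cross",
                                i, j, k, l))
      }
    }
  }
  if (!is.na(object@maxPairSpan) && object@maxPairSpan < 4)
    msg <- c(msg, "maxPairSpan must be at least minimum-hairpin-loop + 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn ConstraintSet compact display
#' @param object a `ConstraintSet` object
#' @export
setMethod("show", "ConstraintSet", function(object) {
  cat("ConstraintSet over", object@n, "nt:",
      sum(object@code == .C_UNPAIRED), "forced unpaired,",
      nrow(object@forcedPairs), "forced pairs,",
      sum(object@code == .C_PROBED), "probed\n")
  if (!is.na(object@maxPairSpan))
    cat("  maximum pair span:", object@maxPairSpan, "\n")
})

#' Folding run options
#'
#' @slot window numeric, energy window above the MFE in kcal/mol; `Inf`
#'   enumerates the complete combinatorial space.
#' @slot noLonelyPairs logical, prune branches in which a base pair has
#'   permanently lost the possibility of a stacked neighbor
#'   (energy-independent; no penalty term is involved).
#' @slot noMultibranch logical, disallow multibranch loops: at most one helix
#'   directly inside any closed pair (the exterior loop may still hold many
#'   stems), yielding series-of-hairpin structures.
#' @slot lowMemory logical, use the depth-first single-branch iterator whose
#'   retained state count before the first emitted structure grows linearly
#'   with sequence length.
#' @slot minHairpin integer, minimum unpaired length of a hairpin loop
#'   (>= 3; the shipped tables are undefined below 3).
#' @slot maxStructures numeric, safety cap on emitted structures.
#' @slot sortOutput logical, sort output by energy then dot-bracket.
#' @slot helixFilter a [HelixFilterSpec-class] or `NULL`.
#' @seealso [foldOptions()]
#' @export
setClass("FoldOptions", representation(
  window = "numeric",
  noLonelyPairs = "logical",
  noMultibranch = "logical",
  lowMemory = "logical",
  minHairpin = "integer",
  maxStructures = "numeric",
  sortOutput = "logical",
  helixFilter = "ANY"
))

setValidity("FoldOptions", function(object) {
  msg <- character()
  if (is.na(object@window) || object@window < 0)
    msg <- c(msg, "window must be >= 0 (Inf for combinatorial mode)")
  if (object@minHairpin < 3)
    msg <- c(msg, "minHairpin must be >= 3")
  if (object@maxStructures < 1)
    msg <- c(msg, "maxStructures must be >= 1")
  if (!is.null(object@helixFilter) && !is(object@helixFilter, "HelixFilterSpec"))
    msg <- c(msg, "helixFilter must be NULL or a HelixFilterSpec")
  if (length(msg)) msg else TRUE
})

#' @describeIn FoldOptions compact display
#' @param object a `FoldOptions` object
#' @export
setMethod("show", "FoldOptions", function(object) {
  cat("FoldOptions: window =", object@window, "kcal/mol;",
      "noLonelyPairs =", object@noLonelyPairs, ";",
      "noMultibranch =", object@noMultibranch, ";",
      "lowMemory =", object@lowMemory, ";",
      "minHairpin =", object@minHairpin, "\n")
})

#' Helix filter specification
#'
#' Pass/fail test applied to completed structures: the structure must contain
#' at least `minHelixCount` helices of at least `minHelixLength` pairs, where
#' a helix may extend across single 1x1 internal-loop interruptions up to
#' `maxMismatches` per helix (bulges and larger loops terminate a helix).
#'
#' @slot minHelixCount integer >= 0
#' @slot minHelixLength integer >= 1, in base pairs
#' @slot maxMismatches integer >= 0, tolerated 1x1 interruptions per helix
#' @seealso [helixFilterSpec()], [helixFilterPass()]
#' @export
setClass("HelixFilterSpec", representation(
  minHelixCount = "integer",
  minHelixLength = "integer",
  maxMismatches = "integer"
))

setValidity("HelixFilterSpec", function(object) {
  msg <- character()
  if (object@minHelixCount < 0) msg <- c(msg, "minHelixCount must be >= 0")
  if (object@minHelixLength < 1) msg <- c(msg, "minHelixLength must be >= 1")
  if (object@maxMismatches < 0) msg <- c(msg, "maxMismatches must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn HelixFilterSpec compact display
#' @param object a `HelixFilterSpec` object
#' @export
setMethod("show", "HelixFilterSpec", function(object) {
  cat("HelixFilterSpec:", object@minHelixCount, "helices of >=",
      object@minHelixLength, "pairs, <=", object@maxMismatches,
      "mismatches per helix\n")
})

#' A single RNA secondary structure
#'
#' A set of base pairs over a sequence.  Pairs are non-crossing
#' (pseudoknot-free), each nucleotide pairs at most once, and every hairpin
#' loop encloses at least 3 unpaired nucleotides.
#'
#' @slot seq character, the RNA sequence (ACGUN).
#' @slot pairs two-column integer matrix of pairs (i, j), i < j, sorted by i.
#' @slot energy numeric, free energy in kcal/mol, or `NA` when unset.
#' @seealso [secondaryStructure()], [evalStructure()], [dotBracket()]
#' @export
setClass("SecondaryStructure", representation(
  seq = "character",
  pairs = "matrix",
  energy = "numeric"
))

setValidity("SecondaryStructure", function(object) {
  msg <- character()
  n <- nchar(object@seq)
  p <- object@pairs
  if (ncol(p) != 2) return("pairs must be a two-column matrix")
  if (nrow(p)) {
    if (any(p < 1) || any(p > n))
      msg <- c(msg, "pair positions outside the sequence")
    if (any(p[, 1] >= p[, 2]))
      msg <- c(msg, "pairs must satisfy i < j")
    if (anyDuplicated(as.vector(p)))
      msg <- c(msg, "a nucleotide appears in more than one pair")
    if (any(p[, 2] - p[, 1] < 4))
      msg <- c(msg, "hairpin loop shorter than 3 unpaired nucleotides (j - i < 4)")
    if (nrow(p) > 1) {
      o <- order(p[, 1])
      p <- p[o, , drop = FALSE]
      for (a in seq_len(nrow(p) - 1)) for (b in (a + 1):nrow(p)) {
        if (p[a, 1] < p[b, 1] && p[b, 1] < p[a, 2] && p[a, 2] < p[b, 2])
          msg <- c(msg, sprintf("pairs (%d,%d) and (%d,%d) cross (pseudoknot)",
                                p[a, 1], p[a, 2], p[b, 1], p[b, 2]))
      }
    }
  }
  if (length(msg)) msg[1] else TRUE
})

#' @describeIn SecondaryStructure compact display
#' @param object a `SecondaryStructure` object
#' @export
setMethod("show", "SecondaryStructure", function(object) {
  cat("SecondaryStructure,", nchar(object@seq), "nt,", nrow(object@pairs),
      "pairs\n")
  cat(" ", object@seq, "\n")
  cat(" ", dotBracket(object))
  if (!is.na(object@energy)) cat(sprintf("  (%.2f kcal/mol)", object@energy))
  cat("\n")
})

#' Zuker dynamic-programming tables
#'
#' The fill-step tables used to compute the minimum free energy and to
#' lower-bound the energy of unevaluated intervals during backtracking.
#' `V[i,j]` is the minimum energy of the substructure on `[i,j]` given that
#' (i,j) pair (including the terminal AU/GU charge seen from the enclosing
#' loop); `W[i,j]` the minimum energy of any substructure on `[i,j]`;
#' `WM[i,j]` the minimum energy of `[i,j]` as a multibranch-loop component.
#'
#' @slot seq character, the folded sequence.
#' @slot V,W,WM numeric matrices in kcal/mol (`Inf` = impossible).
#' @slot mfe numeric, minimum free energy `W[1, N]` in kcal/mol.
#' @slot tablesT list of integer matrices in tenths kcal/mol used internally
#'   by the refinement engine (`Vn`, `Vw`, `M`, `F`, and `mfeT`).
#' @seealso [fillMatrices()]
#' @export
setClass("FoldMatrices", representation(
  seq = "character",
  V = "matrix",
  W = "matrix",
  WM = "matrix",
  mfe = "numeric",
  tablesT = "list"
))

#' @describeIn FoldMatrices compact display
#' @param object a `FoldMatrices` object
#' @export
setMethod("show", "FoldMatrices", function(object) {
  cat("FoldMatrices over", nchar(object@seq), "nt; MFE =",
      sprintf("%.2f", object@mfe), "kcal/mol\n")
})

#' A partially determined structure (refinement state)
#'
#' The enumeration state: a list of unevaluated intervals (sigma) and a set
#' of fixed pairs (P), together with the exactly accumulated energy of the
#' determined portion and the table lower bound on the remainder.  Interval
#' types track the refinement grammar: 0 = exterior-like, 1 = closed by its
#' boundary pair (outer context not Watson-Crick), 2 = closed with a
#' Watson-Crick outer pair (needed by the probing rule), 3 = multibranch
#' component.
#'
#' @slot sigma three-column integer matrix (i, j, type) of unevaluated
#'   intervals; the last row is refined next.
#' @slot pairs two-column integer matrix of fixed pairs.
#' @slot dgP integer, energy of the determined portion in tenths kcal/mol.
#' @slot dgSig integer, table lower bound on the unevaluated intervals in
#'   tenths kcal/mol.
#' @seealso [rootState()], [refineState()], [stateSerialize()]
#' @export
setClass("PartialState", representation(
  sigma = "matrix",
  pairs = "matrix",
  dgP = "integer",
  dgSig = "integer"
))

#' @describeIn PartialState compact display
#' @param object a `PartialState` object
#' @export
setMethod("show", "PartialState", function(object) {
  cat("PartialState:", nrow(object@sigma), "unevaluated intervals,",
      nrow(object@pairs), "fixed pairs, dgP =",
      sprintf("%.2f", object@dgP / 10), "kcal/mol, bound =",
      sprintf("%.2f", (object@dgP + object@dgSig) / 10), "kcal/mol\n")
})

#' An enumerated ensemble of suboptimal structures
#'
#' @slot name character, sequence name.
#' @slot seq character, the folded sequence.
#' @slot db character vector of dot-bracket strings, one per structure.
#' @slot energy numeric vector of free energies in kcal/mol.
#' @slot mfe numeric, minimum free energy of the run in kcal/mol.
#' @slot options the [FoldOptions-class] used.
#' @slot diagnostics list: states processed, peak stored states, truncation
#'   flag, and (for parallel runs) per-process counters.
#' @seealso [enumerateSuboptimal()], [runParallel()], [writeSubopt()]
#' @export
setClass("SuboptResult", representation(
  name = "character",
  seq = "character",
  db = "character",
  energy = "numeric",
  mfe = "numeric",
  options = "FoldOptions",
  diagnostics = "list"
))

#' @describeIn SuboptResult number of structures in the ensemble
#' @param x a `SuboptResult`
#' @export
setMethod("length", "SuboptResult", function(x) length(x@db))

#' @describeIn SuboptResult compact display
#' @param object a `SuboptResult` object
#' @export
setMethod("show", "SuboptResult", function(object) {
  cat("SuboptResult '", object@name, "': ", length(object@db),
      " structures over ", nchar(object@seq), " nt", sep = "")
  if (length(object@energy))
    cat(sprintf("; energies [%.2f, %.2f] kcal/mol", min(object@energy),
                max(object@energy)))
  cat("\n")
  k <- min(5L, length(object@db))
  if (k > 0) {
    cat(" ", object@seq, "\n")
    for (r in seq_len(k))
      cat(sprintf("  %s %6.2f\n", object@db[r], object@energy[r]))
    if (length(object@db) > k) cat("  ...\n")
  }
})

#' @describeIn SuboptResult subset the ensemble
#' @param i indices
#' @param j,...,drop ignored
#' @export
setMethod("[", "SuboptResult", function(x, i, j, ..., drop = TRUE) {
  initialize(x, db = x@db[i], energy = x@energy[i])
})

#' Convert an ensemble to a data.frame
#'
#' @param x a [SuboptResult-class]
#' @param row.names,optional,... passed through conventions; unused
#' @return data.frame with columns `structure` (dot-bracket) and `energy`
#' @export
as.data.frame.SuboptResult <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  data.frame(structure = x@db, energy = x@energy, stringsAsFactors = FALSE)
}
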