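#' Construct a secondary structure
#'
#' @param seq RNA sequence (character or Biostrings object).
#' @param structure either a dot-bracket string or a two-column matrix of
#'   pairs (i, j).
#' @param energy optional free energy in kcal/mol.
#' @return a validated [SecondaryStructure-class].
#' @examples
#' secondaryStructure("GGGGAAAACCCC", "((((....))))")
#' @export
secondaryStructure <- function(seq, structure = NULL, energy = NA_real_) {
  s <- .normalizeSeq(seq)
  if (is.null(structure)) {
    pairs <- matrix(integer(), 0, 2)
  } else if (is.character(structure)) {
    if (nchar(structure) != nchar(s))
      stop("validation error: dot-bracket length differs from sequence length")
    pairs <- .wf_db2pairs(structure)
  } else {
    pairs <- matrix(as.integer(structure), ncol = 2)
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  new("SecondaryStructure", seq = s, pairs = pairs,
      energy = as.numeric(energy))
}

#' Dot-bracket rendering / extraction
#'
#' @param x a [SecondaryStructure-class] or [SuboptResult-class].
#' @return character: one dot-bracket string (or the vector of them).
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))

#' @describeIn dotBracket render one structure
#' @export
setMethod("dotBracket", "SecondaryStructure", function(x) {
  db <- rep(".", nchar(x@seq))
  if (nrow(x@pairs)) {
    db[x@pairs[, 1]] <- "("
    db[x@pairs[, 2]] <- ")"
  }
  paste(db, collapse = "")
})

#' @describeIn dotBracket extract the vector of dot-bracket strings
#' @export
setMethod("dotBracket", "SuboptResult", function(x) x@db)

#' Base pairs of a structure
#'
#' @param x a [SecondaryStructure-class].
#' @return two-column integer matrix of pairs, sorted by the 5' position.
#' @export
basePairs <- function(x) x@pairs

#' Evaluate the free energy of a complete structure
#'
#' Sums the loop decomposition: stacking terms, hairpin/bulge/internal loop
#' initiations, the affine multibranch terms (`a + b * branches +
#' c * unpaired`), and terminal AU/GU penalties charged once per helix end.
#' The exterior loop contributes nothing beyond the terminal penalties of the
#' stems it holds; the open chain has free energy zero.
#'
#' @param seq RNA sequence; ignored (may be `NULL`) when `structure` is a
#'   [SecondaryStructure-class], which carries its own sequence.
#' @param structure a [SecondaryStructure-class], a dot-bracket string, or a
#'   two-column pair matrix.
#' @param params an [EnergyParams-class].
#' @param options a [FoldOptions-class]; `minHairpin` participates in
#'   validation.
#' @return numeric free energy in kcal/mol.
#' @examples
#' evalStructure("GGGGAAAACCCC", "((((....))))")
#' evalStructure("GGGGAAAACCCC", "............")   # open chain: 0
#' @export
evalStructure <- function(seq, structure, params = loadEnergyParams(),
                          options = foldOptions()) {
  if (is(structure, "SecondaryStructure")) {
    s <- structure@seq
    pairs <- structure@pairs
  } else {
    s <- .normalizeSeq(seq)
    st <- secondaryStructure(s, structure)   # runs validity
    pairs <- st@pairs
  }
  if (nrow(pairs) && any(pairs[, 2] - pairs[, 1] - 1 < options@minHairpin))
    stop(sprintf("validation error: hairpin loop shorter than %d unpaired nucleotides",
                 options@minHairpin))
  eT <- .wf_eval(.encodeSeq(s), matrix(as.integer(pairs), ncol = 2),
                 .modelTenths(params), .optsList(options))
  if (eT >= .INF_E)
    stop("validation error: structure contains a loop with undefined energy")
  eT / 10
}

#' Evaluate many structures at once
#'
#' Vectorized form of [evalStructure()] over dot-bracket strings; used for
#' ensemble re-evaluation and as the cross-check that the enumerator's
#' incrementally accumulated energies match an independent re-evaluation.
#'
#' @param seq RNA sequence.
#' @param db character vector of dot-bracket strings.
#' @inheritParams evalStructure
#' @return numeric vector of free energies in kcal/mol.
#' @export
evalStructures <- function(seq, db, params = loadEnergyParams(),
                           options = foldOptions()) {
  s <- .normalizeSeq(seq)
  if (!length(db)) return(numeric())
  .wf_eval_batch(.encodeSeq(s), db, .modelTenths(params),
                 .optsList(options)) / 10
}
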