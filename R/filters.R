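#' Helix filter specification
#'
#' @param minHelixCount required number of qualifying helices.
#' @param minHelixLength minimum helix length in base pairs.
#' @param maxMismatches tolerated 1x1 internal-loop interruptions per helix.
#' @return a [HelixFilterSpec-class].
#' @examples
#' helixFilterSpec(30, 9, 3)   # the encapsidated-virus use case
#' @export
helixFilterSpec <- function(minHelixCount, minHelixLength, maxMismatches = 0L) {
  new("HelixFilterSpec", minHelixCount = as.integer(minHelixCount),
      minHelixLength = as.integer(minHelixLength),
      maxMismatches = as.integer(maxMismatches))
}

#' Parse a COUNT:LEN:MISMATCH helix-filter string
#'
#' @param text e.g. `"30:9:3"`.
#' @return a [HelixFilterSpec-class].
#' @export
parseHelixFilter <- function(text) {
  parts <- suppressWarnings(as.integer(strsplit(text, ":", fixed = TRUE)[[1]]))
  if (length(parts) != 3 || anyNA(parts))
    stop("parse error: helix filter must be COUNT:LEN:MISMATCH")
  helixFilterSpec(parts[1], parts[2], parts[3])
}

#' Partition a structure's pairs into helices
#'
#' Walks the pairs in 5' order and greedily extends the current helix: a pair
#' (i+1, j-1) continues it as a perfect stack, a pair (i+2, j-2) continues it
#' across a single 1x1 internal loop counted as one mismatch, as long as the
#' helix's accumulated mismatches stay within `maxMismatches`.  Bulges and
#' any larger loop terminate the helix and start a new one.
#'
#' @param structure a [SecondaryStructure-class] (or dot-bracket string with
#'   `seq`).
#' @param maxMismatches tolerated 1x1 interruptions per helix.
#' @param seq sequence, only needed when `structure` is a dot-bracket string.
#' @return data.frame with one row per helix: `start5`, `start3` (outermost
#'   pair), `length` (pairs), `mismatches`; the attribute `"assignment"`
#'   maps each pair (row of `basePairs`) to its helix.
#' @examples
#' s <- secondaryStructure("GGGGAAAACCCC", "((((....))))")
#' findHelices(s, 0)
#' @export
findHelices <- function(structure, maxMismatches = 0L, seq = NULL) {
  if (is.character(structure)) structure <- secondaryStructure(seq, structure)
  p <- structure@pairs
  if (!nrow(p)) {
    out <- data.frame(start5 = integer(), start3 = integer(),
                      length = integer(), mismatches = integer())
    attr(out, "assignment") <- integer()
    return(out)
  }
  o <- order(p[, 1])
  p <- p[o, , drop = FALSE]
  helix <- integer(nrow(p))
  start5 <- start3 <- len <- mm <- integer()
  h <- 0L
  for (r in seq_len(nrow(p))) {
    i <- p[r, 1]; j <- p[r, 2]
    extend <- FALSE
    if (h > 0L) {
      li <- lastI; lj <- lastJ
      if (i == li + 1L && j == lj - 1L) {
        extend <- TRUE; add <- 0L
      } else if (i == li + 2L && j == lj - 2L && mm[h] < maxMismatches) {
        extend <- TRUE; add <- 1L
      }
    }
    if (extend) {
      len[h] <- len[h] + 1L
      mm[h] <- mm[h] + add
    } else {
      h <- h + 1L
      start5 <- c(start5, i); start3 <- c(start3, j)
      len <- c(len, 1L); mm <- c(mm, 0L)
    }
    helix[r] <- h
    lastI <- i; lastJ <- j
  }
  out <- data.frame(start5 = start5, start3 = start3, length = len,
                    mismatches = mm)
  assignment <- integer(nrow(p))
  assignment[o] <- helix
  attr(out, "assignment") <- assignment
  out
}

#' Does a structure pass a helix filter?
#'
#' True when at least `minHelixCount` helices of at least `minHelixLength`
#' pairs are found under the filter's mismatch tolerance.  Applied to
#' completed structures only (helix sizes are unknowable before a structure
#' is fully determined).
#'
#' @param structure a [SecondaryStructure-class].
#' @param spec a [HelixFilterSpec-class].
#' @return logical.
#' @export
helixFilterPass <- function(structure, spec) {
  hx <- findHelices(structure, spec@maxMismatches)
  sum(hx$length >= spec@minHelixLength) >= spec@minHelixCount
}

#' Base-pair distance between two structures
#'
#' `type = "pairs"` (the default) counts base pairs present in one structure
#' and not the other (the symmetric difference of the two pair sets).
#' `type = "nucleotides"` counts nucleotides whose pairing partner differs
#' between the two structures (each rearranged pair contributes its two
#' positions).
#'
#' @param a,b [SecondaryStructure-class] objects, dot-bracket strings, or
#'   two-column pair matrices; both over the same length.
#' @param type distance flavor, see above.
#' @param n sequence length, required only when both inputs are bare pair
#'   matrices.
#' @return integer distance; 0 iff the structures are identical.
#' @examples
#' basePairDistance("((((....))))", ".(((....))).")
#' @export
basePairDistance <- function(a, b, type = c("pairs", "nucleotides"), n = NULL) {
  type <- match.arg(type)
  get <- function(x) {
    if (is(x, "SecondaryStructure"))
      list(p = x@pairs, n = nchar(x@seq))
    else if (is.character(x))
      list(p = .wf_db2pairs(x), n = nchar(x))
    else
      list(p = matrix(as.integer(x), ncol = 2), n = n)
  }
  A <- get(a); B <- get(b)
  if (!is.null(A$n) && !is.null(B$n) && A$n != B$n)
    stop("validation error: structures have different lengths")
  keyA <- paste(A$p[, 1], A$p[, 2])
  keyB <- paste(B$p[, 1], B$p[, 2])
  if (type == "pairs")
    return(length(setdiff(keyA, keyB)) + length(setdiff(keyB, keyA)))
  len <- if (!is.null(A$n)) A$n else max(A$p, B$p, 0L)
  pa <- integer(len); pb <- integer(len)
  if (nrow(A$p)) { pa[A$p[, 1]] <- A$p[, 2]; pa[A$p[, 2]] <- A$p[, 1] }
  if (nrow(B$p)) { pb[B$p[, 1]] <- B$p[, 2]; pb[B$p[, 2]] <- B$p[, 1] }
  sum(pa != pb)
}

#' Summarize an ensemble against a reference structure
#'
#' Reports the structure count, the energy range and span, and the maximum
#' and mean base-pair distance of ensemble members to the reference (by
#' default the minimum-free-energy member, ties broken by lexicographic
#' dot-bracket order).
#'
#' @param ensemble a [SuboptResult-class] or character vector of dot-bracket
#'   strings.
#' @param reference a [SecondaryStructure-class] or dot-bracket string;
#'   `NULL` selects the minimum-energy member.
#' @param energies energies for a bare character ensemble (optional).
#' @return list with `count`, `minEnergy`, `maxEnergy`, `energySpan`,
#'   `maxDistance`, `meanDistance`, `reference` (dot-bracket).
#' @export
landscapeSummary <- function(ensemble, reference = NULL, energies = NULL) {
  if (is(ensemble, "SuboptResult")) {
    db <- ensemble@db
    en <- ensemble@energy
  } else {
    db <- as.character(ensemble)
    en <- if (is.null(energies)) rep(NA_real_, length(db)) else energies
  }
  if (!length(db)) stop("validation error: empty ensemble")
  if (is.null(reference)) {
    if (all(is.na(en)))
      stop("validation error: no energies available to pick the MFE reference")
    cand <- which(en == min(en, na.rm = TRUE))
    reference <- db[cand[order(db[cand])][1]]
  } else if (is(reference, "SecondaryStructure")) {
    reference <- dotBracket(reference)
  }
  d <- vapply(db, basePairDistance, numeric(1), b = reference,
              USE.NAMES = FALSE)
  list(count = length(db),
       minEnergy = if (all(is.na(en))) NA_real_ else min(en, na.rm = TRUE),
       maxEnergy = if (all(is.na(en))) NA_real_ else max(en, na.rm = TRUE),
       energySpan = if (all(is.na(en))) NA_real_
                    else diff(range(en, na.rm = TRUE)),
       maxDistance = as.integer(max(d)),
       meanDistance = mean(d),
       reference = reference)
}
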