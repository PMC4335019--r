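#' Create an empty constraint set
#'
#' @param n sequence length.
#' @return a [ConstraintSet-class] with no constraints.
#' @export
emptyConstraints <- function(n) {
  new("ConstraintSet", n = as.integer(n), code = integer(n),
      forcedPairs = matrix(integer(), 0, 2), maxPairSpan = NA_integer_)
}

#' Parse a constraint string
#'
#' One character per nucleotide: `.` no constraint, `x` forced unpaired (hard
#' single-strand constraint, e.g. from S1 nuclease probing), `(` and `)` a
#' forced pair (matched like brackets), `m` chemically probed/modified
#' (context-dependent: the nucleotide may sit in a Watson-Crick pair only at
#' a helix end, adjacent to a loop or bulge, or in/adjacent to a GU pair).
#'
#' @param text the constraint string.
#' @param n expected sequence length.
#' @param maxPairSpan optional maximum `j - i` for any pair (`NA` = off).
#' @return a [ConstraintSet-class].
#' @examples
#' parseConstraintString("..x...", 6)
#' parseConstraintString("((...))", 7)
#' @export
parseConstraintString <- function(text, n, maxPairSpan = NA) {
  if (!is.character(text) || length(text) != 1)
    stop("validation error: constraint string must be a single string")
  if (nchar(text) != n)
    stop(sprintf("validation error: constraint string length %d != sequence length %d",
                 nchar(text), n))
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), c(".", "x", "(", ")", "m"))
  if (length(bad))
    stop(sprintf("parse error: illegal constraint character '%s' (alphabet . x ( ) m)",
                 bad[1]))
  code <- integer(n)
  code[ch == "x"] <- .C_UNPAIRED
  code[ch == "m"] <- .C_PROBED
  stack <- integer()
  fp <- matrix(integer(), 0, 2)
  for (p in seq_len(n)) {
    if (ch[p] == "(") stack <- c(stack, p)
    else if (ch[p] == ")") {
      if (!length(stack))
        stop("parse error: unbalanced brackets in constraint string")
      fp <- rbind(fp, c(stack[length(stack)], p))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack))
    stop("parse error: unbalanced brackets in constraint string")
  code[as.vector(fp)] <- .C_PAIRMEM
  new("ConstraintSet", n = as.integer(n), code = code,
      forcedPairs = matrix(as.integer(fp), ncol = 2),
      maxPairSpan = as.integer(maxPairSpan))
}

# plain-list form consumed by the C++ core
.consList <- function(constraints, n) {
  if (is.null(constraints)) constraints <- emptyConstraints(n)
  if (constraints@n != n)
    stop("validation error: constraint set length does not match the sequence")
  validObject(constraints)
  list(code = constraints@code,
       forcedPairs = matrix(as.integer(constraints@forcedPairs), ncol = 2),
       maxSpan = if (is.na(constraints@maxPairSpan)) 0L
                 else constraints@maxPairSpan)
}

#' Is a candidate pair admissible under the constraints?
#'
#' Pure predicate used by the refinement engine.  A pair (i, j) is rejected
#' when i or j is forced unpaired, when a forced pair names a different
#' partner for i or j, when it crosses a forced pair, or when the maximum
#' pair span is exceeded.  When i or j is chemically probed, the pair is
#' admissible only if it is not a Watson-Crick pair flanked on both sides by
#' Watson-Crick pairs: a GU/UG pair is always admissible, and so is a
#' Watson-Crick pair whose outer neighbor (i-1, j+1) or inner neighbor
#' (i+1, j-1) is absent from `state` or is GU/UG.  Because refinement adds
#' pairs outside-in, the inner neighbor is usually still undecided when
#' (i, j) is proposed; the engine re-applies this test whenever a
#' neighboring pair is added, rejecting the later proposal that would
#' complete a forbidden Watson-Crick sandwich.
#'
#' @param i,j candidate pair positions, i < j.
#' @param state a [PartialState-class] carrying the pairs fixed so far, or
#'   `NULL` for no context.
#' @param seq the RNA sequence (character).
#' @param constraints a [ConstraintSet-class].
#' @return `TRUE` if the pair is admissible.
#' @export
allowPair <- function(i, j, state = NULL, seq, constraints) {
  s <- .normalizeSeq(seq)
  n <- nchar(s)
  stopifnot(i >= 1, j <= n, i < j)
  code <- constraints@code
  if (code[i] == .C_UNPAIRED || code[j] == .C_UNPAIRED) return(FALSE)
  fp <- constraints@forcedPairs
  if (nrow(fp)) {
    partner <- integer(n)
    partner[fp[, 1]] <- fp[, 2]
    partner[fp[, 2]] <- fp[, 1]
    if (partner[i] != 0 && partner[i] != j) return(FALSE)
    if (partner[j] != 0 && partner[j] != i) return(FALSE)
    for (r in seq_len(nrow(fp))) {
      a <- fp[r, 1]; b <- fp[r, 2]
      if ((i < a && a < j && j < b) || (a < i && i < b && b < j)) return(FALSE)
    }
  }
  if (!is.na(constraints@maxPairSpan) && j - i > constraints@maxPairSpan)
    return(FALSE)
  if (code[i] == .C_PROBED || code[j] == .C_PROBED) {
    t <- .pairType(s, i, j)
    if (t == 0L) return(FALSE)
    if (!.isWCType(t)) return(TRUE)            # GU/UG always admissible
    prs <- if (is.null(state)) matrix(integer(), 0, 2) else state@pairs
    hasPair <- function(a, b) {
      a >= 1 && b <= n && nrow(prs) > 0 &&
        any(prs[, 1] == a & prs[, 2] == b)
    }
    outerWC <- hasPair(i - 1, j + 1) && .isWCType(.pairType(s, i - 1, j + 1))
    innerWC <- hasPair(i + 1, j - 1) && .isWCType(.pairType(s, i + 1, j - 1))
    if (outerWC && innerWC) return(FALSE)
  }
  TRUE
}
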