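#' Read a single RNA sequence from FASTA
#'
#' Reads the first record (with a warning if more follow), uppercases,
#' converts T to U, and validates the ACGUN alphabet.  N positions never
#' pair.
#'
#' @param path FASTA file path.
#' @return named character vector of length 1: the sequence, named by the
#'   FASTA header word.
#' @export
readFastaRNA <- function(path) {
  if (!file.exists(path)) stop(sprintf("I/O error: '%s' not found", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop(sprintf("I/O error: cannot parse FASTA '%s': %s",
                                 path, conditionMessage(e))))
  if (length(set) == 0) stop("validation error: empty FASTA file")
  if (length(set) > 1)
    warning("multiple FASTA records; using the first")
  nm <- strsplit(names(set)[1], "[[:space:]]+")[[1]][1]
  s <- .normalizeSeq(as.character(set[[1]]))
  stats::setNames(s, nm)
}

#' Read an extended FASTA with a constraint line
#'
#' The constraint string sits on the line(s) following the sequence, written
#' in the dialect of [parseConstraintString()]; alternatively a standalone
#' single-line constraint file may accompany a plain FASTA.
#'
#' @param path extended-FASTA path.
#' @return list with `seq` (named sequence) and `constraints`
#'   (a [ConstraintSet-class], or `NULL` when no constraint line is present).
#' @export
readExtendedFasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("I/O error: '%s' not found", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[1], ">"))
    stop("validation error: not a FASTA file")
  nm <- strsplit(sub("^>", "", lines[1]), "[[:space:]]+")[[1]][1]
  body <- lines[-1]
  isCons <- grepl("^[.x()m]+$", body)
  # a line of only dots could be sequence in no alphabet; sequence lines
  # match ACGUTN
  isSeq <- grepl("^[ACGUTNacgutn]+$", body)
  seqLines <- body[isSeq & !isCons]
  consLines <- body[isCons & !isSeq]
  if (!length(seqLines)) stop("validation error: no sequence line found")
  s <- .normalizeSeq(paste(seqLines, collapse = ""))
  cons <- NULL
  if (length(consLines)) {
    cons <- parseConstraintString(paste(consLines, collapse = ""), nchar(s))
  }
  list(seq = stats::setNames(s, nm), constraints = cons)
}

#' Write an ensemble in the subopt dialect
#'
#' Header line `> name`, the sequence, then one line per structure:
#' dot-bracket, a single space, and the energy with two decimals.  Sorted
#' mode orders by energy then lexicographic dot-bracket.
#'
#' @param x a [SuboptResult-class].
#' @param path destination file (or `""` for stdout).
#' @param sorted sort before writing.
#' @return invisibly, the number of structure lines written.
#' @export
writeSubopt <- function(x, path, sorted = FALSE) {
  if (sorted) x <- sortStructures(x)
  con <- if (identical(path, "")) stdout() else {
    ok <- tryCatch(file(path, "w"), error = function(e)
      stop(sprintf("I/O error: cannot write '%s'", path)))
    on.exit(close(ok))
    ok
  }
  writeLines(c(paste(">", x@name), x@seq,
               sprintf("%s %.2f", x@db, x@energy)), con)
  invisible(length(x@db))
}

#' Read an ensemble written by [writeSubopt()]
#'
#' @param path subopt file path.
#' @return a [SuboptResult-class] (default fold options; mfe = minimum energy
#'   present).
#' @export
readSubopt <- function(path) {
  if (!file.exists(path)) stop(sprintf("I/O error: '%s' not found", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2 || !startsWith(lines[1], ">"))
    stop("validation error: not a subopt file")
  nm <- trimws(sub("^>", "", lines[1]))
  s <- .normalizeSeq(lines[2])
  body <- lines[-(1:2)]
  db <- sub(" .*$", "", body)
  energy <- as.numeric(sub("^[^ ]+ ", "", body))
  if (anyNA(energy)) stop("validation error: malformed structure line")
  new("SuboptResult", name = nm, seq = s, db = db, energy = energy,
      mfe = if (length(energy)) min(energy) else NA_real_,
      options = foldOptions(), diagnostics = list())
}

#' Write a run manifest
#'
#' Key=value text that fully reconstructs the run configuration: sequence
#' name and length, option settings, parameter-set identifier, and the
#' structure count.
#'
#' @param x a [SuboptResult-class].
#' @param path destination; `""` for stdout.
#' @param params the [EnergyParams-class] used (for its identifier).
#' @return invisibly, the manifest lines.
#' @export
writeRunManifest <- function(x, path = "", params = NULL) {
  o <- x@options
  lines <- c(
    paste0("name=", x@name),
    paste0("length=", nchar(x@seq)),
    paste0("window=", o@window),
    paste0("noLonelyPairs=", o@noLonelyPairs),
    paste0("noMultibranch=", o@noMultibranch),
    paste0("lowMemory=", o@lowMemory),
    paste0("minHairpin=", o@minHairpin),
    paste0("helixFilter=", if (is.null(o@helixFilter)) "none" else
      paste(o@helixFilter@minHelixCount, o@helixFilter@minHelixLength,
            o@helixFilter@maxMismatches, sep = ":")),
    paste0("parameters=", if (is.null(params)) "default" else params@source),
    paste0("mfe=", sprintf("%.2f", x@mfe)),
    paste0("structures=", length(x@db)))
  if (identical(path, "")) writeLines(lines) else writeLines(lines, path)
  invisible(lines)
}

#' Generate test fixtures
#'
#' `random_seq` draws a uniform ACGU sequence of length `n` under the given
#' seed.  `planted_probing` returns a designed 16-nt hairpin whose single
#' helix instantiates each context case of the chemical-probing rule at a
#' known position -- a helix-end pair, a Watson-Crick pair sandwiched between
#' Watson-Crick pairs, a GU wobble pair, a Watson-Crick pair adjacent to the
#' GU pair, and a loop-adjacent pair -- together with the expected
#' admissibility of marking each position as probed while keeping the full
#' helix (`n` and `seed` are ignored: the construct is fixed by design).
#'
#' @param kind `"random_seq"` or `"planted_probing"`.
#' @param n sequence length for `random_seq`.
#' @param seed RNG seed for `random_seq`.
#' @return list with `seq`, `constraints` (a [ConstraintSet-class]), and for
#'   the planted fixture `helixDb` (the full-helix structure) and `cases`
#'   (data.frame of position, pair, context case, and whether the full helix
#'   remains admissible when that position is probed).
#' @export
generateFixture <- function(kind = c("random_seq", "planted_probing"),
                            n = 14, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "random_seq") {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    s <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
               collapse = "")
    return(list(kind = kind, seq = s, constraints = emptyConstraints(n)))
  }
  # planted probing construct: helix (1,16)(2,15)(3,14)(4,13)(5,12)(6,11),
  # loop 7..10; (5,12) is the GU wobble
  s <- "GGCAGGAAAACUUGCC"
  helix <- cbind(1:6, 16:11)
  cases <- data.frame(
    position = c(1L, 2L, 4L, 5L, 6L),
    i = c(1L, 2L, 4L, 5L, 6L),
    j = c(16L, 15L, 13L, 12L, 11L),
    case = c("helix_end", "wc_sandwiched", "gu_adjacent", "gu_pair",
             "loop_adjacent"),
    admissibleInHelix = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  db <- paste(c(rep("(", 6), rep(".", 4), rep(")", 6)), collapse = "")
  list(kind = kind, seq = s, constraints = emptyConstraints(nchar(s)),
       helixDb = db, helixPairs = helix, cases = cases)
}
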