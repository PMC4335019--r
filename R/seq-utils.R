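# sequence normalization and encoding shared across the package

# Accepts a character string or a Biostrings XString/XStringSet; returns a
# single uppercase ACGUN string (T converted to U).
.normalizeSeq <- function(seq) {
  if (is(seq, "XStringSet")) {
    if (length(seq) > 1)
      warning("multiple sequences supplied; using the first")
    seq <- as.character(seq[[1]])
  } else if (is(seq, "XString")) {
    seq <- as.character(seq)
  }
  if (!is.character(seq) || length(seq) != 1)
    stop("validation error: `seq` must be a single sequence")
  s <- chartr("t", "u", toupper(seq))
  s <- chartr("T", "U", s)
  if (nchar(s) < 1) stop("validation error: empty sequence")
  bad <- gsub("[ACGUN]", "", s)
  if (nchar(bad) > 0)
    stop(sprintf("validation error: illegal character(s) '%s' in sequence (alphabet ACGU/T, N)",
                 substr(bad, 1, 5)))
  s
}

# base codes for the C++ core: A=0 C=1 G=2 U=3 N=4
.encodeSeq <- function(seq) {
  m <- c(A = 0L, C = 1L, G = 2L, U = 3L, N = 4L)
  unname(m[strsplit(seq, "", fixed = TRUE)[[1]]])
}

.pairTypeMatrix <- local({
  pt <- matrix(0L, 5, 5, dimnames = list(c("A","C","G","U","N"),
                                         c("A","C","G","U","N")))
  pt["A","U"] <- 1L; pt["C","G"] <- 2L; pt["G","C"] <- 3L
  pt["U","A"] <- 4L; pt["G","U"] <- 5L; pt["U","G"] <- 6L
  pt
})

# pair type code of positions i, j (0 if not pairable)
.pairType <- function(seq, i, j) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  .pairTypeMatrix[ch[i], ch[j]]
}

.isWCType <- function(t) t >= 1L & t <= 4L
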