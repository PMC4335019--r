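# shared helpers: independent oracles built on the brute-force enumerator

THE_14MER <- "GCUCUAAAAGAGAG"

randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# brute-force reference: all structures within `window` of the brute-force
# minimum (evaluated independently of the enumerator's accumulation)
bruteWindowSet <- function(seq, window, constraints = NULL,
                           params = loadEnergyParams()) {
  bf <- bruteForceEnumerate(seq, constraints)
  en <- evalStructures(seq, bf, params)
  bf[en <= min(en) + window + 1e-9]
}

# does a dot-bracket contain an isolated (lonely) pair?
hasLonelyPair <- function(db) {
  p <- wuchtyfold:::.wf_db2pairs(db)
  if (!nrow(p)) return(FALSE)
  key <- paste(p[, 1], p[, 2])
  any(!(paste(p[, 1] + 1, p[, 2] - 1) %in% key |
          paste(p[, 1] - 1, p[, 2] + 1) %in% key))
}

# does any closed pair directly enclose >= 2 branches?
hasInnerMultibranch <- function(db) {
  p <- wuchtyfold:::.wf_db2pairs(db)
  if (nrow(p) < 3) return(FALSE)
  n <- nchar(db)
  partner <- integer(n)
  partner[p[, 1]] <- p[, 2]
  partner[p[, 2]] <- p[, 1]
  for (r in seq_len(nrow(p))) {
    k <- p[r, 1] + 1
    nb <- 0
    while (k < p[r, 2]) {
      if (partner[k] > k) { nb <- nb + 1; k <- partner[k] + 1 } else k <- k + 1
    }
    if (nb >= 2) return(TRUE)
  }
  FALSE
}

# canonical sorted "db energy" lines for byte-identity comparisons
sortedLines <- function(res) {
  rs <- sortStructures(res)
  sprintf("%s %.2f", dotBracket(rs), rs@energy)
}

mkState <- function(pairs, sigma = matrix(integer(), 0, 3)) {
  new("PartialState",
      sigma = matrix(as.integer(sigma), ncol = 3),
      pairs = matrix(as.integer(pairs), ncol = 2),
      dgP = 0L, dgSig = 0L)
}

constraintAt <- function(n, pos, char) {
  ch <- rep(".", n)
  ch[pos] <- char
  parseConstraintString(paste(ch, collapse = ""), n)
}
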