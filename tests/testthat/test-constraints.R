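test_that("constraint strings parse to the documented codes", {
  cs <- parseConstraintString("..x...", 6)
  expect_identical(cs@code, c(0L, 0L, 1L, 0L, 0L, 0L))
  cs2 <- parseConstraintString("((...))", 7)
  expect_setequal(split(cs2@forcedPairs, row(cs2@forcedPairs)),
                  list(c(2L, 6L), c(1L, 7L)))
  expect_identical(cs2@code[c(1, 2, 6, 7)], rep(2L, 4))
  cs3 <- parseConstraintString(".m.", 3)
  expect_identical(cs3@code[2], 3L)
})

test_that("malformed constraint strings are rejected", {
  expect_error(parseConstraintString("(....", 5), "unbalanced")
  expect_error(parseConstraintString("))((", 4), "unbalanced")
  expect_error(parseConstraintString("...", 5), "length")
  expect_error(parseConstraintString("..q..", 5), "illegal")
})

test_that("conflicting constraints are rejected with positions named", {
  cs <- emptyConstraints(8)
  cs@code[2] <- 1L
  cs@forcedPairs <- rbind(c(2L, 7L))
  cs@code[7] <- 2L
  expect_error(validObject(cs), "position 2")
  crossing <- emptyConstraints(14)
  crossing@forcedPairs <- rbind(c(1L, 8L), c(4L, 12L))
  crossing@code[c(1, 8, 4, 12)] <- 2L
  expect_error(validObject(crossing), "cross")
})

test_that("allowPair implements the hard constraints", {
  s <- "GGCAGGAAAACUUGCC"
  n <- nchar(s)
  expect_false(allowPair(3, 14, NULL, s, constraintAt(n, 3, "x")))
  expect_false(allowPair(3, 14, NULL, s, constraintAt(n, 14, "x")))
  expect_true(allowPair(3, 14, NULL, s, emptyConstraints(n)))
  cs <- parseConstraintString("(..........)....", n)  # forces (1,12)
  expect_false(allowPair(1, 16, NULL, s, cs))          # wrong partner
  spanned <- emptyConstraints(n)
  spanned@maxPairSpan <- 6L
  expect_false(allowPair(1, 16, NULL, s, spanned))
  expect_true(allowPair(6, 11, NULL, s, spanned))
})

test_that("allowPair implements the context-dependent probing rule", {
  s <- "GGCAGGAAAACUUGCC"
  n <- nchar(s)
  # probed GU pair between Watson-Crick neighbors: admissible
  stG <- mkState(rbind(c(4L, 13L), c(6L, 11L)))
  expect_true(allowPair(5, 12, stG, s, constraintAt(n, 5, "m")))
  # probed WC pair flanked by WC pairs on both sides: inadmissible
  stS <- mkState(rbind(c(1L, 16L), c(3L, 14L)))
  expect_false(allowPair(2, 15, stS, s, constraintAt(n, 2, "m")))
  # same pair at a helix end (no outer neighbor): admissible
  stE <- mkState(rbind(c(3L, 14L)))
  expect_true(allowPair(2, 15, stE, s, constraintAt(n, 2, "m")))
  # WC pair with a GU inner neighbor: admissible
  stA <- mkState(rbind(c(3L, 14L), c(5L, 12L)))
  expect_true(allowPair(4, 13, stA, s, constraintAt(n, 4, "m")))
})

test_that("every emitted structure satisfies its constraints", {
  set.seed(21)
  for (rep in 1:6) {
    n <- sample(12:16, 1)
    s <- randomSeq(n)
    cstr <- paste(sample(c(".", ".", "x", "m"), n, replace = TRUE),
                  collapse = "")
    cs <- parseConstraintString(cstr, n)
    r <- enumerateSuboptimal(s, constraints = cs)
    xpos <- which(cs@code == 1L)
    mpos <- which(cs@code == 3L)
    for (db in dotBracket(r)) {
      ch <- strsplit(db, "")[[1]]
      expect_true(all(ch[xpos] == "."))
      p <- wuchtyfold:::.wf_db2pairs(db)
      if (!nrow(p) || !length(mpos)) next
      partner <- integer(n)
      partner[p[, 1]] <- p[, 2]; partner[p[, 2]] <- p[, 1]
      for (q in seq_len(nrow(p))) {
        i <- p[q, 1]; j <- p[q, 2]
        if (!(i %in% mpos || j %in% mpos)) next
        wc <- function(a, b) a >= 1 && b <= n &&
          wuchtyfold:::.isWCType(wuchtyfold:::.pairType(s, a, b))
        sandwiched <- wc(i, j) &&
          partner[i] == j &&
          i > 1 && j < n && partner[i - 1] == j + 1 && wc(i - 1, j + 1) &&
          partner[i + 1] == j - 1 && wc(i + 1, j - 1)
        expect_false(sandwiched)
      }
    }
  }
})

test_that("probing constraints are weaker than hard constraints in count", {
  set.seed(22)
  for (rep in 1:10) {
    n <- sample(10:16, 1)
    s <- randomSeq(n)
    k <- sample(n, 1)
    soft <- countStructures(s, constraints = constraintAt(n, k, "m"))
    hard <- countStructures(s, constraints = constraintAt(n, k, "x"))
    expect_gte(soft, hard)
  }
})

test_that("forced pairs prune conformational space at least as hard as single-strand constraints", {
  set.seed(23)
  tried <- 0
  for (rep in 1:20) {
    n <- sample(10:16, 1)
    s <- randomSeq(n)
    bf <- bruteForceEnumerate(s)
    withPairs <- bf[vapply(bf, function(d) grepl("(", d, fixed = TRUE),
                           logical(1))]
    if (!length(withPairs)) next
    p <- wuchtyfold:::.wf_db2pairs(withPairs[1])
    i <- p[1, 1]; j <- p[1, 2]
    ch <- rep(".", n); ch[i] <- "("; ch[j] <- ")"
    forced <- countStructures(s, constraints = parseConstraintString(
      paste(ch, collapse = ""), n))
    ch2 <- rep(".", n); ch2[c(i, j)] <- "x"
    ss <- countStructures(s, constraints = parseConstraintString(
      paste(ch2, collapse = ""), n))
    expect_lte(forced, ss)
    tried <- tried + 1
  }
  expect_gte(tried, 5)
})

test_that("the counting DP honors constraints exactly (brute-force cross-check)", {
  set.seed(24)
  for (rep in 1:8) {
    n <- sample(10:16, 1)
    s <- randomSeq(n)
    cstr <- paste(sample(c(".", ".", "x", "m"), n, replace = TRUE),
                  collapse = "")
    cs <- parseConstraintString(cstr, n)
    expect_identical(countStructures(s, constraints = cs),
                     as.numeric(length(bruteForceEnumerate(s, cs))),
                     info = paste(s, cstr))
  }
})
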