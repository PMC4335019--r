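test_that("sequences without pairable nucleotides fold to the open chain", {
  fm <- fillMatrices("AAAA")
  expect_identical(fm@mfe, 0)
  expect_true(all(!is.finite(fm@V[upper.tri(fm@V)])))
  expect_identical(countStructures("AAAA"), 1)
})

test_that("the MFE equals the brute-force minimum on small sequences", {
  p <- loadEnergyParams()
  for (s in c("GGGGAAAACCCC", "GCUCUAAAAGAGAG", "GGCAGGAAAACUUGCC")) {
    bf <- bruteForceEnumerate(s)
    expect_equal(mfe(s), min(evalStructures(s, bf, p)), tolerance = 0.005,
                 info = s)
  }
  set.seed(77)
  for (rep in 1:10) {
    s <- randomSeq(sample(8:16, 1))
    bf <- bruteForceEnumerate(s)
    expect_equal(mfe(s), min(evalStructures(s, bf, p)), tolerance = 0.005,
                 info = s)
  }
})

test_that("forcing every position unpaired leaves only the open chain", {
  s <- "GGGGAAAACCCC"
  cs <- parseConstraintString(strrep("x", nchar(s)), nchar(s))
  expect_identical(mfe(s, constraints = cs), 0)
  expect_identical(countStructures(s, constraints = cs), 1)
  r <- enumerateSuboptimal(s, constraints = cs)
  expect_identical(dotBracket(r), strrep(".", nchar(s)))
})

test_that("the counting DP matches the brute-force cardinality", {
  expect_identical(countStructures(THE_14MER), 119)
  set.seed(5)
  for (rep in 1:12) {
    n <- sample(8:20, 1)
    s <- randomSeq(n)
    expect_identical(countStructures(s),
                     as.numeric(length(bruteForceEnumerate(s))), info = s)
  }
})

test_that("counts are monotone non-decreasing under constraint removal", {
  set.seed(6)
  for (rep in 1:8) {
    n <- sample(10:16, 1)
    s <- randomSeq(n)
    cstr <- paste(sample(c(".", ".", "x", "m"), n, replace = TRUE),
                  collapse = "")
    cs <- parseConstraintString(cstr, n)
    full <- countStructures(s)
    constrained <- countStructures(s, constraints = cs)
    expect_lte(constrained, full)
    # removing one constraint can only grow the count
    pos <- which(cs@code != 0L)
    if (length(pos)) {
      relaxed <- cs
      relaxed@code[pos[1]] <- 0L
      expect_lte(constrained, countStructures(s, constraints = relaxed))
    }
  }
})

test_that("very long sequences count exactly through big integers", {
  s <- strrep(THE_14MER, 6)             # 84 nt, count far beyond 2^53
  cnt <- countStructures(s, as = "character")
  expect_type(cnt, "character")
  expect_gt(nchar(cnt), 15)
  # leading digits must agree with the 1.8^N order of magnitude, roughly
  expect_gt(nchar(cnt), floor(84 * log10(1.65)))
})

test_that("the 1.8^N estimate behaves as documented", {
  expect_equal(estimateStructureCount(1), 1.8)
  expect_equal(estimateStructureCount(14), 1.8^14)
  # 1.8^247 = 1.128e63; truncated to three significant digits: 1.12e63
  expect_identical(trunc(estimateStructureCount(247) / 1e61), 112)
  expect_error(estimateStructureCount(0), "validation")
})

test_that("the fill tables satisfy their defining inequalities", {
  set.seed(8)
  s <- randomSeq(18)
  fm <- fillMatrices(s)
  n <- nchar(s)
  for (i in 1:n) for (j in 1:n) {
    if (j <= i) next
    if (is.finite(fm@V[i, j]))
      expect_lte(fm@W[i, j], fm@V[i, j] + 1e-9)
    if (j - 1 >= i) expect_lte(fm@W[i, j], fm@W[i, j - 1] + 1e-9)
    if (i + 1 <= j) expect_lte(fm@W[i, j], fm@W[i + 1, j] + 1e-9)
  }
  expect_identical(fm@mfe, fm@W[1, n])
})

test_that("disabling multibranch loops never lowers the MFE", {
  set.seed(9)
  seqs <- c("GGCAGGAAAACUUGCC", replicate(8, randomSeq(sample(12:20, 1))))
  for (s in seqs) {
    expect_gte(mfe(s, options = foldOptions(noMultibranch = TRUE)),
               mfe(s) - 1e-9)
  }
})
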