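test_that("the printed 14-mer enumerates its complete combinatorial space", {
  r <- enumerateSuboptimal(THE_14MER)
  expect_identical(length(r), 119L)
  expect_identical(anyDuplicated(dotBracket(r)), 0L)
  expect_setequal(dotBracket(r), bruteForceEnumerate(THE_14MER))
})

test_that("a window of zero yields exactly the minimum-energy structures", {
  set.seed(31)
  for (rep in 1:8) {
    s <- randomSeq(sample(8:14, 1))
    r <- enumerateSuboptimal(s, options = foldOptions(window = 0))
    bf <- bruteForceEnumerate(s)
    en <- evalStructures(s, bf)
    expect_setequal(dotBracket(r), bf[en <= min(en) + 1e-9])
  }
})

test_that("enumeration equals the brute-force enumerate-evaluate-filter set", {
  set.seed(32)
  for (rep in 1:25) {
    s <- randomSeq(sample(8:16, 1))
    w <- sample(c(0, 1, 2, 5, Inf), 1)
    r <- enumerateSuboptimal(s, options = foldOptions(window = w))
    expect_setequal(dotBracket(r), bruteWindowSet(s, w))
    expect_identical(anyDuplicated(dotBracket(r)), 0L)
  }
})

test_that("no-lonely-pairs pruning removes exactly the isolated-pair structures", {
  set.seed(33)
  sawLonely <- FALSE
  for (rep in 1:15) {
    s <- randomSeq(sample(8:16, 1))
    w <- sample(c(2, 5, Inf), 1)
    want <- bruteWindowSet(s, w)
    lonely <- vapply(want, hasLonelyPair, logical(1))
    if (any(lonely)) sawLonely <- TRUE
    # without the flag, a large window admits lonely-pair structures
    r0 <- enumerateSuboptimal(s, options = foldOptions(window = w))
    expect_setequal(dotBracket(r0), want)
    # with the flag they are pruned, and nothing else is lost
    r1 <- enumerateSuboptimal(s, options = foldOptions(
      window = w, noLonelyPairs = TRUE))
    expect_setequal(dotBracket(r1), want[!lonely])
    expect_false(any(vapply(dotBracket(r1), hasLonelyPair, logical(1))))
  }
  expect_true(sawLonely)   # the regression actually exercised the pruning
})

test_that("no-multibranch restricts closed pairs to a single enclosed branch", {
  set.seed(34)
  for (rep in 1:10) {
    s <- randomSeq(sample(10:16, 1))
    r <- enumerateSuboptimal(s, options = foldOptions(noMultibranch = TRUE))
    expect_false(any(vapply(dotBracket(r), hasInnerMultibranch, logical(1))))
    bf <- bruteForceEnumerate(s)
    want <- bf[!vapply(bf, hasInnerMultibranch, logical(1))]
    expect_setequal(dotBracket(r), want)
  }
})

test_that("structure counts grow monotonically (and fast) with the window", {
  s <- THE_14MER
  counts <- vapply(c(0, 1, 2, 4, 8, 16), function(w)
    length(enumerateSuboptimal(s, options = foldOptions(window = w))),
    integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[length(counts)], 10 * counts[1])
})

test_that("low-memory mode reproduces the standard output with linear prefix memory", {
  for (s in c(THE_14MER, strrep(THE_14MER, 2))) {
    std <- enumerateSuboptimal(s, options = foldOptions(sortOutput = TRUE))
    low <- enumerateSuboptimal(s, options = foldOptions(
      sortOutput = TRUE, lowMemory = TRUE))
    expect_identical(sprintf("%s %.2f", dotBracket(low), low@energy),
                     sprintf("%s %.2f", dotBracket(std), std@energy))
    expect_lte(low@diagnostics$maxStatesBeforeFirst, 3 * nchar(s) + 5)
  }
})

test_that("refinement states behave per the state-tree contract", {
  fm <- fillMatrices("AAAA")
  root <- rootState(fm)
  kids <- refineState(root, fm)
  expect_length(kids, 1)              # only the j-unpaired chain
  st <- kids[[1]]
  while (!isLeafState(st)) {
    ks <- refineState(st, fm)
    expect_length(ks, 1)
    st <- ks[[1]]
  }
  expect_identical(dotBracket(leafStructure(st, "AAAA")), "....")
  expect_error(refineState(st, fm), "leaf")
})

test_that("lonely-pair prunability follows the rescue rule", {
  expect_false(lonelyPairPrunable(mkState(rbind(c(1, 10), c(2, 9)))))
  expect_true(lonelyPairPrunable(mkState(rbind(c(1, 10)))))
  expect_false(lonelyPairPrunable(
    mkState(rbind(c(3, 12)), sigma = matrix(c(4L, 11L, 1L), 1, 3))))
})

test_that("the brute-force oracle refuses oversized inputs", {
  expect_error(bruteForceEnumerate(strrep("A", 30)), "refusal")
  expect_identical(bruteForceEnumerate("AAAA"), "....")
})

test_that("the emission safety cap triggers a structured warning", {
  expect_warning(
    enumerateSuboptimal(strrep(THE_14MER, 2),
                        options = foldOptions(maxStructures = 50)),
    "safety cap")
})

test_that("the post-hoc helix filter drops structures below the helix criteria", {
  s <- "GGGGGAAAACCCCC"
  spec <- helixFilterSpec(1, 5, 0)
  r <- enumerateSuboptimal(s, options = foldOptions(helixFilter = spec))
  expect_true(all(vapply(dotBracket(r), function(d)
    helixFilterPass(secondaryStructure(s, d), spec), logical(1))))
  rAll <- enumerateSuboptimal(s)
  expect_lt(length(r), length(rAll))
  expect_gte(length(r), 1)
})
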