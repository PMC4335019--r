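test_that("helix finding follows the stack/mismatch extension rules", {
  s <- strrep("A", 14)   # helix rules are sequence-independent
  perfect <- new("SecondaryStructure", seq = "GGGGAAAACCCC",
                 pairs = cbind(1:4, 12:9), energy = NA_real_)
  hx <- findHelices(perfect, 0)
  expect_identical(nrow(hx), 1L)
  expect_identical(hx$length, 4L)
  expect_identical(hx$mismatches, 0L)

  mm <- new("SecondaryStructure", seq = s,
            pairs = rbind(c(1L, 14L), c(2L, 13L), c(4L, 11L), c(5L, 10L)),
            energy = NA_real_)
  hx1 <- findHelices(mm, 1)
  expect_identical(nrow(hx1), 1L)
  expect_identical(hx1$length, 4L)
  expect_identical(hx1$mismatches, 1L)
  # with no mismatch budget the 1x1 interruption splits the helix
  hx0 <- findHelices(mm, 0)
  expect_identical(nrow(hx0), 2L)
  expect_identical(hx0$length, c(2L, 2L))

  empty <- new("SecondaryStructure", seq = s,
               pairs = matrix(integer(), 0, 2), energy = NA_real_)
  expect_identical(nrow(findHelices(empty, 3)), 0L)
})

test_that("bulges terminate helices regardless of mismatch budget", {
  s <- strrep("A", 16)
  bulged <- new("SecondaryStructure", seq = s,
                pairs = rbind(c(1L, 16L), c(2L, 15L), c(4L, 14L), c(5L, 13L)),
                energy = NA_real_)   # 1-nt bulge on the 5' side
  hx <- findHelices(bulged, 3)
  expect_identical(nrow(hx), 2L)
})

test_that("helix partition covers each pair exactly once", {
  set.seed(41)
  for (rep in 1:10) {
    s <- randomSeq(sample(12:18, 1))
    bf <- bruteForceEnumerate(s)
    db <- bf[which.max(nchar(gsub("[.]", "", bf)))]
    st <- secondaryStructure(s, db)
    hx <- findHelices(st, sample(0:3, 1))
    a <- attr(hx, "assignment")
    expect_length(a, nrow(st@pairs))
    if (nrow(hx)) {
      expect_setequal(unique(a), seq_len(nrow(hx)))
      expect_identical(as.integer(table(a)), hx$length)
    }
  }
})

test_that("helix filter passes and fails per the count/length criteria", {
  s <- "GGGGGGGGGAAAACCCCCCCCC"   # 9-pair perfect helix
  st <- secondaryStructure(s, paste(c(rep("(", 9), rep(".", 4), rep(")", 9)),
                                    collapse = ""))
  expect_true(helixFilterPass(st, helixFilterSpec(1, 9, 0)))
  expect_false(helixFilterPass(st, helixFilterSpec(2, 9, 0)))
  expect_false(helixFilterPass(st, helixFilterSpec(1, 10, 0)))
})

test_that("a short third helix fails a three-helix specification", {
  # three hairpins with helices of 9, 9 and 8 pairs
  mkHairpin <- function(len) c(rep("(", len), rep(".", 4), rep(")", len))
  db <- paste(c(mkHairpin(9), ".", mkHairpin(9), ".", mkHairpin(8)),
              collapse = "")
  s <- paste(c(rep(c(rep("G", 9), "AAAA", rep("C", 9)), 1), "A",
               rep("G", 9), "AAAA", rep("C", 9), "A",
               rep("G", 8), "AAAA", rep("C", 8)), collapse = "")
  st <- secondaryStructure(s, db)
  expect_true(helixFilterPass(st, helixFilterSpec(2, 9, 3)))
  expect_false(helixFilterPass(st, helixFilterSpec(3, 9, 3)))
  expect_true(helixFilterPass(st, helixFilterSpec(3, 8, 3)))
})

test_that("helix filter acceptance is monotone in the specification", {
  set.seed(42)
  for (rep in 1:10) {
    s <- randomSeq(16)
    bf <- bruteForceEnumerate(s)
    db <- sample(bf, 1)
    st <- secondaryStructure(s, db)
    spec <- helixFilterSpec(sample(1:3, 1), sample(1:4, 1), sample(0:2, 1))
    if (helixFilterPass(st, spec)) {
      expect_true(helixFilterPass(st, helixFilterSpec(
        spec@minHelixCount - 1L, spec@minHelixLength, spec@maxMismatches)))
      expect_true(helixFilterPass(st, helixFilterSpec(
        spec@minHelixCount, max(1L, spec@minHelixLength - 1L),
        spec@maxMismatches)))
      expect_true(helixFilterPass(st, helixFilterSpec(
        spec@minHelixCount, spec@minHelixLength, spec@maxMismatches + 1L)))
    }
  }
})

test_that("base-pair distance is the symmetric difference of pair sets", {
  expect_identical(basePairDistance("((((....))))", "((((....))))"), 0L)
  expect_identical(basePairDistance(rbind(c(1, 7), c(2, 6)), rbind(c(2, 6)),
                                    n = 7), 1L)
  # independent oracle: sorted-key set difference
  set.seed(43)
  for (rep in 1:15) {
    s <- randomSeq(16)
    bf <- bruteForceEnumerate(s)
    a <- sample(bf, 1); b <- sample(bf, 1)
    pa <- wuchtyfold:::.wf_db2pairs(a); pb <- wuchtyfold:::.wf_db2pairs(b)
    ka <- sort(paste(pa[, 1], pa[, 2], sep = "-"))
    kb <- sort(paste(pb[, 1], pb[, 2], sep = "-"))
    expect_identical(basePairDistance(a, b),
                     sum(!ka %in% kb) + sum(!kb %in% ka))
  }
})

test_that("base-pair distance is a metric", {
  set.seed(44)
  s <- randomSeq(16)
  bf <- bruteForceEnumerate(s)
  for (rep in 1:10) {
    x <- sample(bf, 1); y <- sample(bf, 1); z <- sample(bf, 1)
    expect_identical(basePairDistance(x, y), basePairDistance(y, x))
    expect_identical(basePairDistance(x, x), 0L)
    if (x != y) expect_gt(basePairDistance(x, y), 0)
    expect_lte(basePairDistance(x, z),
               basePairDistance(x, y) + basePairDistance(y, z))
  }
})

test_that("the nucleotide-distance variant counts differently paired nucleotides", {
  a <- "((((....))))"
  b <- ".(((....)))."
  expect_identical(basePairDistance(a, b, type = "nucleotides"), 2L)
  expect_identical(basePairDistance(a, a, type = "nucleotides"), 0L)
})

test_that("landscape summaries report count, span and distances to the MFE reference", {
  one <- landscapeSummary("((((....))))", reference = "((((....))))")
  expect_identical(one$count, 1L)
  expect_identical(one$maxDistance, 0L)
  expect_identical(one$meanDistance, 0)

  r <- enumerateSuboptimal(THE_14MER)
  ls <- landscapeSummary(r)
  expect_identical(ls$count, 119L)
  expect_equal(ls$minEnergy, r@mfe, tolerance = 1e-9)
  expect_equal(ls$energySpan, max(r@energy) - min(r@energy))
  # mean distance equals direct arithmetic on a small hand-built ensemble
  small <- c("((((....))))", ".(((....))).", "............")
  ref <- "((((....))))"
  d <- c(0, basePairDistance(small[2], ref), basePairDistance(small[3], ref))
  ls2 <- landscapeSummary(small, reference = ref)
  expect_equal(ls2$meanDistance, mean(d))
  expect_identical(ls2$maxDistance, as.integer(max(d)))
  expect_error(landscapeSummary(character()), "empty")
})
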