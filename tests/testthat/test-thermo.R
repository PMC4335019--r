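test_that("the shipped parameter set is well-formed", {
  p <- loadEnergyParams()
  expect_s4_class(p, "EnergyParams")
  expect_lt(p@stack["CG", "CG"], 0)           # stacking is stabilizing
  expect_true(all(p@stack < 2))
  expect_identical(p@hairpin[2], Inf)          # loops shorter than 3 forbidden
  expect_identical(p@hairpin[1], Inf)
  expect_true(all(is.finite(p@hairpin[3:30])))
  expect_length(p@multiloop, 3)
})

test_that("parameter loading reports I/O and parse errors", {
  expect_error(loadEnergyParams("nonexistent.par"), "I/O error")
  bad <- tempfile(fileext = ".par")
  writeLines(c("[stack]", "1 2 three"), bad)
  expect_error(loadEnergyParams(bad), "\\[stack\\]")
  short <- tempfile(fileext = ".par")
  writeLines(c("[stack]", paste(rep("-1", 36), collapse = " "),
               "[hairpin]", "Inf Inf 5"), short)
  expect_error(loadEnergyParams(short), "missing block|tables")
})

test_that("a parameter file round-trips through the documented dialect", {
  p <- loadEnergyParams()
  f <- tempfile(fileext = ".par")
  writeLines(c(
    "[stack]",
    apply(p@stack, 1, paste, collapse = " "),
    "[hairpin]", paste(p@hairpin, collapse = " "),
    "[bulge]", paste(p@bulge, collapse = " "),
    "[internal]", paste(p@internal, collapse = " "),
    "[multiloop]", paste(p@multiloop, collapse = " "),
    "[misc]", paste(p@terminalAU, p@loopExtrapolation, p@temperature)), f)
  q <- loadEnergyParams(f)
  expect_equal(unname(q@stack), unname(p@stack))
  expect_equal(q@hairpin, p@hairpin)
  expect_equal(q@multiloop, p@multiloop)
})

test_that("the open chain has zero free energy", {
  expect_identical(evalStructure("GGGGAAAACCCC", "............"), 0)
  expect_identical(evalStructure("AAAA", "...."), 0)
})

test_that("a perfect GC helix evaluates to its stack and hairpin terms", {
  p <- loadEnergyParams()
  # three GC-on-GC stacks plus a hairpin of 4; GC ends carry no AU penalty
  expected <- 3 * p@stack["GC", "GC"] + p@hairpin[4]
  expect_equal(evalStructure("GGGGAAAACCCC", "((((....))))", p), expected,
               tolerance = 1e-9)
})

test_that("terminal AU/GU penalties are charged once per helix end", {
  p <- loadEnergyParams()
  # UAUA...UAUA helix of AU/UA pairs: both helix ends charged once
  s <- "UAUAAAAAUAUA"
  db <- "((((....))))"
  types <- c("UA", "AU", "UA", "AU")
  stacks <- sum(vapply(1:3, function(k)
    p@stack[types[k], types[k + 1]], numeric(1)))
  expected <- stacks + p@hairpin[4] + 2 * p@terminalAU
  expect_equal(evalStructure(s, db, p), expected, tolerance = 1e-9)
})

test_that("inserting a stacked pair changes the energy by one stack minus the loop terms", {
  p <- loadEnergyParams()
  s <- "GGGGAAAACCCC"
  with2 <- evalStructure(s, rbind(c(1, 12), c(2, 11), c(3, 10), c(4, 9)), p)
  # remove (2,11): (1,12)-(3,10) becomes a 1x1 internal loop; both closing
  # pairs are GC so no AU charges move
  without <- evalStructure(s, rbind(c(1, 12), c(3, 10), c(4, 9)), p)
  delta <- (p@stack["GC", "GC"] + p@stack["GC", "GC"]) - p@internal[2]
  expect_equal(with2 - without, delta, tolerance = 1e-9)
})

test_that("structure validation rejects illegal structures", {
  expect_error(evalStructure("GGGAAACCC", rbind(c(1, 3))), "hairpin")
  expect_error(secondaryStructure("GGGAAAUCC", rbind(c(1, 9), c(1, 8))),
               "more than one pair")
  expect_error(secondaryStructure("GGGAAAAUCCAAAUU", rbind(c(1, 10), c(5, 15))),
               "cross")
  expect_error(evalStructure("GGGG", "((((....))))"), "length")
})

test_that("the enumerator's accumulated energies match independent re-evaluation", {
  set.seed(101)
  for (rep in 1:8) {
    s <- randomSeq(sample(10:15, 1))
    r <- enumerateSuboptimal(s)
    if (!length(r)) next
    expect_equal(r@energy, evalStructures(s, dotBracket(r)),
                 tolerance = 0.005)
  }
})
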