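test_that("a single-worker parallel run reproduces the serial enumeration", {
  serial <- enumerateSuboptimal(THE_14MER)
  par1 <- runParallel(THE_14MER, config = runConfig(nWorkers = 1))
  expect_identical(sortedLines(par1), sortedLines(serial))
})

test_that("worker count and share threshold never change the result set", {
  set.seed(51)
  cases <- list(
    list(seq = THE_14MER, options = foldOptions()),
    list(seq = randomSeq(18), options = foldOptions(window = 5)),
    list(seq = randomSeq(16), options = foldOptions(noLonelyPairs = TRUE)))
  for (cs in cases) {
    ref <- sortedLines(enumerateSuboptimal(cs$seq, options = cs$options))
    for (nw in c(2, 4)) for (th in c(1, 16)) {
      r <- runParallel(cs$seq, options = cs$options,
                       config = runConfig(nWorkers = nw, shareThreshold = th))
      expect_identical(sortedLines(r), ref,
                       info = sprintf("%s workers=%d threshold=%d",
                                      cs$seq, nw, th))
    }
  }
})

test_that("each state is processed exactly once across all processes", {
  serial <- enumerateSuboptimal(THE_14MER)
  for (th in c(1, 16)) {
    r <- runParallel(THE_14MER, config = runConfig(nWorkers = 3,
                                                   shareThreshold = th))
    expect_identical(r@diagnostics$statesProcessed,
                     serial@diagnostics$statesProcessed)
  }
})

test_that("workers shed their excess and the master redistributes it", {
  r <- runParallel(THE_14MER, config = runConfig(nWorkers = 2,
                                                 shareThreshold = 1))
  expect_gt(r@diagnostics$messages$share_states, 0)
  expect_gt(r@diagnostics$messages$grant_state, 2)
  per <- r@diagnostics$perProcess
  expect_gte(sum(per[-1] > 0), 2)   # both workers actually worked
})

test_that("state serialization round-trips and rejects corrupt payloads", {
  fm <- fillMatrices(THE_14MER)
  root <- rootState(fm)
  kids <- refineState(root, fm)
  st <- kids[[length(kids)]]
  blob <- stateSerialize(st)
  back <- stateDeserialize(blob)
  expect_identical(back@sigma, st@sigma)
  expect_identical(back@pairs, st@pairs)
  expect_identical(back@dgP, st@dgP)
  expect_identical(back@dgSig, st@dgSig)
  expect_error(stateDeserialize(blob[1:8]), "deserialize error")
  expect_error(stateDeserialize(as.raw(c(1, 2, 3))), "deserialize error")
})

test_that("per-worker spill files merge to the full result set", {
  dir <- tempfile("spill")
  r <- runParallel(THE_14MER,
                   config = runConfig(nWorkers = 2, shareThreshold = 4,
                                      spillDir = dir))
  files <- list.files(dir, full.names = TRUE)
  expect_gte(length(files), 3)   # master + 2 workers
  lines <- unlist(lapply(files, readLines))
  lines <- lines[nzchar(lines)]
  expect_identical(sort(lines), sort(sprintf("%s %.2f", r@db, r@energy)))
})

test_that("the fork backend reproduces the serial set across process boundaries", {
  ref <- sortedLines(enumerateSuboptimal(THE_14MER))
  r <- runParallel(THE_14MER, config = runConfig(nWorkers = 2,
                                                 shareThreshold = 8,
                                                 backend = "fork"))
  expect_identical(sortedLines(r), ref)
})

test_that("invalid run configurations are rejected", {
  expect_error(runConfig(nWorkers = 0), "nWorkers")
  expect_error(runConfig(shareThreshold = 0), "shareThreshold")
})
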