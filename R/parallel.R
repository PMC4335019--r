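#' Parallel run configuration
#'
#' @param nWorkers number of worker processes (the master is additional).
#' @param shareThreshold a worker whose stack exceeds this many states sends
#'   the oldest (shallowest) half of its stack back to the master for
#'   redistribution.
#' @param backend `"inproc"` runs the master-worker message protocol inside
#'   one process with a deterministic round-robin scheduler; `"fork"` runs
#'   each granted state in a forked child process (unix only), with states
#'   crossing the process boundary through [stateSerialize()].
#' @param spillDir optional directory: each worker spills its structures to
#'   `worker-<k>.subopt` there instead of keeping them in memory; files are
#'   merged at the end of the run.
#' @return a list of class `"RunConfig"`.
#' @export
runConfig <- function(nWorkers = 2L, shareThreshold = 16L,
                      backend = c("inproc", "fork"), spillDir = NULL) {
  backend <- match.arg(backend)
  nWorkers <- as.integer(nWorkers)
  shareThreshold <- as.integer(shareThreshold)
  if (nWorkers < 1) stop("validation error: nWorkers must be >= 1")
  if (shareThreshold < 1) stop("validation error: shareThreshold must be >= 1")
  structure(list(nWorkers = nWorkers, shareThreshold = shareThreshold,
                 backend = backend, spillDir = spillDir),
            class = "RunConfig")
}

#' Serialize a refinement state for message passing
#'
#' Round-trip safe: `stateDeserialize(stateSerialize(s))` reproduces the
#' state including energies.  The payload is a tagged binary blob; corrupt or
#' truncated payloads raise a deserialize error.
#'
#' @param state a [PartialState-class].
#' @return raw vector.
#' @export
stateSerialize <- function(state) {
  stopifnot(is(state, "PartialState"))
  body <- serialize(.stateToList(state), NULL, xdr = TRUE)
  c(charToRaw("WFST"), body)
}

#' @rdname stateSerialize
#' @param bytes raw vector produced by [stateSerialize()].
#' @return `stateDeserialize`: the reconstructed [PartialState-class].
#' @export
stateDeserialize <- function(bytes) {
  if (!is.raw(bytes) || length(bytes) < 5 ||
      !identical(rawToChar(bytes[1:4]), "WFST"))
    stop("deserialize error: not a serialized refinement state")
  lst <- tryCatch(unserialize(bytes[-(1:4)]),
                  error = function(e)
                    stop("deserialize error: corrupt state payload"))
  if (!is.list(lst) || !all(c("sigma", "pairs", "dgP", "dgSig") %in% names(lst)))
    stop("deserialize error: corrupt state payload")
  .stateFromList(lst)
}

# a work message: kind in {need_work, share_states, grant_state, terminate}
.workMessage <- function(kind, from, payload = list()) {
  if (kind == "grant_state" && length(payload) != 1)
    stop("grant_state carries exactly one state")
  if (kind == "share_states" && length(payload) < 1)
    stop("share_states carries a non-empty state list")
  list(kind = kind, from = from, payload = payload)
}

# shed policy: when a stack exceeds the threshold, the oldest (shallowest)
# half leaves; shallow states carry the most remaining work
.shedStates <- function(stack, threshold) {
  if (length(stack) <= threshold) return(list(keep = stack, shed = list()))
  nShed <- ceiling(length(stack) / 2)
  list(shed = stack[seq_len(nShed)],
       keep = stack[-seq_len(nShed)])
}

# one worker refinement step over the shared run context
.workerRefine <- function(stack, ctx) {
  state <- stack[[length(stack)]]
  stack[[length(stack)]] <- NULL
  out <- .wf_refine(state, ctx$tablesT, ctx$enc, ctx$modelT, ctx$consL,
                    ctx$optsL, ctx$windowT)
  if (isTRUE(out$isLeaf))
    return(list(stack = stack, leafDb = out$db, leafEnergy = out$energyT))
  for (ch in out$children) stack[[length(stack) + 1L]] <- ch
  list(stack = stack, leafDb = NULL, leafEnergy = NULL)
}

# shared run context: every process recomputes the fill tables from the run
# parameters rather than receiving them, which keeps messages small
.runContext <- function(seq, constraints, options, params) {
  s <- .normalizeSeq(seq)
  n <- nchar(s)
  enc <- .encodeSeq(s)
  modelT <- .modelTenths(params)
  consL <- .consList(constraints, n)
  optsL <- .optsList(options)
  tb <- .wf_fill(enc, modelT, consL, optsL)
  windowT <- if (is.finite(options@window)) round(options@window * 10) else Inf
  list(seq = s, n = n, enc = enc, modelT = modelT, consL = consL,
       optsL = optsL,
       tablesT = list(Vn = tb$Vn, Vw = tb$Vw, M = tb$M, F = tb$F,
                      mfeT = tb$mfeT),
       mfeT = tb$mfeT, windowT = as.numeric(windowT))
}

#' Master-worker parallel enumeration
#'
#' Runs the enumeration as one master plus `nWorkers` workers.  The master
#' seeds its stack with the completely unrefined root state; workers start
#' with empty stacks and request work (`need_work`), which the master answers
#' with a single granted state (`grant_state`) or, once no work remains, with
#' `terminate`.  A worker whose stack exceeds `shareThreshold` states sends
#' the excess back to the master (`share_states`) for redistribution, which
#' keeps otherwise-idle workers busy.  Because state refinements are
#' independent, sharing one refinement stack this way yields a complete,
#' non-duplicating exploration: the merged output is always the same set the
#' serial enumeration produces.
#'
#' @inheritParams enumerateSuboptimal
#' @param config a [runConfig()] list.
#' @return a [SuboptResult-class]; diagnostics carry per-process state
#'   counters and message counts.
#' @examples
#' res <- runParallel("GCUCUAAAAGAGAG", config = runConfig(nWorkers = 2))
#' length(res)   # 119, identical to the serial enumeration
#' @export
runParallel <- function(seq, constraints = NULL, options = foldOptions(),
                        params = loadEnergyParams(),
                        config = runConfig(), name = "seq") {
  validObject(options)
  ctx <- .runContext(seq, constraints, options, params)
  res <- switch(config$backend,
                inproc = .runInproc(ctx, config),
                fork = .runFork(ctx, config))
  db <- res$db
  energy <- res$energyT / 10
  if (!is.null(options@helixFilter) && length(db)) {
    keep <- vapply(db, function(d)
      helixFilterPass(secondaryStructure(ctx$seq, d), options@helixFilter),
      logical(1), USE.NAMES = FALSE)
    db <- db[keep]; energy <- energy[keep]
  }
  if (options@sortOutput && length(db)) {
    o <- order(energy, db, method = "radix")
    db <- db[o]; energy <- energy[o]
  }
  new("SuboptResult", name = name, seq = ctx$seq, db = db, energy = energy,
      mfe = if (ctx$mfeT >= .INF_E) NA_real_ else ctx$mfeT / 10,
      options = options, diagnostics = res$diagnostics)
}

# deterministic in-process scheduler: workers are stepped round-robin, one
# refinement per tick; all protocol messages go through an explicit queue
.runInproc <- function(ctx, config) {
  P <- config$nWorkers
  rootL <- .wf_root_state(ctx$enc, ctx$tablesT, ctx$modelT, ctx$consL,
                          ctx$optsL)
  masterStack <- if (ctx$mfeT >= .INF_E) list() else list(rootL)
  workers <- lapply(seq_len(P), function(k)
    list(stack = list(), db = character(), energyT = integer(),
         processed = 0, terminated = FALSE))
  masterDb <- character(); masterEnergyT <- integer(); masterProcessed <- 0
  queue <- lapply(seq_len(P), function(k) .workMessage("need_work", k))
  waiting <- integer()
  msgCount <- c(need_work = P, share_states = 0, grant_state = 0,
                terminate = 0)

  repeat {
    processedMsg <- length(queue) > 0
    while (length(queue)) {
      msg <- queue[[1]]; queue[[1]] <- NULL
      if (msg$kind == "need_work") {
        waiting <- c(waiting, msg$from)
      } else if (msg$kind == "share_states") {
        for (b in msg$payload)
          masterStack[[length(masterStack) + 1L]] <- .stateToList(stateDeserialize(b))
      }
    }
    while (length(waiting) && length(masterStack)) {
      w <- waiting[1]; waiting <- waiting[-1]
      st <- masterStack[[length(masterStack)]]
      masterStack[[length(masterStack)]] <- NULL
      # grant travels through the serialization layer like any message
      blob <- stateSerialize(.stateFromList(st))
      workers[[w]]$stack <- list(.stateToList(stateDeserialize(blob)))
      msgCount["grant_state"] <- msgCount["grant_state"] + 1
    }
    busy <- vapply(workers, function(w) length(w$stack) > 0, logical(1))
    if (!length(masterStack) && !any(busy) && !length(queue)) {
      msgCount["terminate"] <- msgCount["terminate"] + P
      break
    }
    if (!processedMsg && length(masterStack)) {
      # no worker messages: the master works its own next state
      step <- .workerRefine(masterStack, ctx)
      masterStack <- step$stack
      masterProcessed <- masterProcessed + 1
      if (!is.null(step$leafDb)) {
        masterDb <- c(masterDb, step$leafDb)
        masterEnergyT <- c(masterEnergyT, step$leafEnergy)
      }
    }
    for (w in which(busy)) {
      step <- .workerRefine(workers[[w]]$stack, ctx)
      workers[[w]]$stack <- step$stack
      workers[[w]]$processed <- workers[[w]]$processed + 1
      if (!is.null(step$leafDb)) {
        workers[[w]]$db <- c(workers[[w]]$db, step$leafDb)
        workers[[w]]$energyT <- c(workers[[w]]$energyT, step$leafEnergy)
      }
      if (length(workers[[w]]$stack) > config$shareThreshold) {
        sh <- .shedStates(workers[[w]]$stack, config$shareThreshold)
        workers[[w]]$stack <- sh$keep
        blobs <- lapply(sh$shed, function(st)
          stateSerialize(.stateFromList(st)))
        queue[[length(queue) + 1L]] <- .workMessage("share_states", w, blobs)
        msgCount["share_states"] <- msgCount["share_states"] + 1
      }
      if (!length(workers[[w]]$stack)) {
        queue[[length(queue) + 1L]] <- .workMessage("need_work", w)
        msgCount["need_work"] <- msgCount["need_work"] + 1
      }
    }
  }

  spill <- .maybeSpill(ctx, config, workers, masterDb, masterEnergyT)
  list(db = spill$db, energyT = spill$energyT,
       diagnostics = list(
         backend = "inproc",
         nWorkers = P,
         shareThreshold = config$shareThreshold,
         statesProcessed = masterProcessed +
           sum(vapply(workers, function(w) w$processed, numeric(1))),
         perProcess = c(master = masterProcessed,
                        vapply(workers, function(w) w$processed, numeric(1))),
         messages = as.list(msgCount)))
}

# optional per-worker spill files, merged at the end of the run
.maybeSpill <- function(ctx, config, workers, masterDb, masterEnergyT) {
  allDb <- masterDb
  allEn <- masterEnergyT
  if (!is.null(config$spillDir)) {
    dir.create(config$spillDir, showWarnings = FALSE, recursive = TRUE)
    writeLines(sprintf("%s %.2f", masterDb, masterEnergyT / 10),
               file.path(config$spillDir, "worker-master.subopt"))
  }
  for (k in seq_along(workers)) {
    allDb <- c(allDb, workers[[k]]$db)
    allEn <- c(allEn, workers[[k]]$energyT)
    if (!is.null(config$spillDir))
      writeLines(sprintf("%s %.2f", workers[[k]]$db,
                         workers[[k]]$energyT / 10),
                 file.path(config$spillDir,
                           sprintf("worker-%d.subopt", k)))
  }
  list(db = allDb, energyT = allEn)
}

# fork backend: each grant becomes a forked job that refines its granted
# state, shedding the shallow half of its stack into a return pile whenever
# the threshold is exceeded; the master redistributes returned states
.runFork <- function(ctx, config) {
  if (!requireNamespace("parallel", quietly = TRUE) ||
      .Platform$OS.type != "unix")
    stop("fork backend requires the parallel package on a unix platform")
  P <- config$nWorkers
  threshold <- config$shareThreshold
  rootL <- .wf_root_state(ctx$enc, ctx$tablesT, ctx$modelT, ctx$consL,
                          ctx$optsL)
  masterStack <- if (ctx$mfeT >= .INF_E) list() else list(rootL)
  jobs <- list()
  allDb <- character(); allEn <- integer()
  processed <- 0; grants <- 0; shares <- 0

  workerJob <- function(blob) {
    stack <- list(.stateToList(stateDeserialize(blob)))
    db <- character(); en <- integer(); shed <- list(); done <- 0
    while (length(stack)) {
      step <- .workerRefine(stack, ctx)
      stack <- step$stack
      done <- done + 1
      if (!is.null(step$leafDb)) {
        db <- c(db, step$leafDb); en <- c(en, step$leafEnergy)
      }
      if (length(stack) > threshold) {
        sh <- .shedStates(stack, threshold)
        stack <- sh$keep
        shed <- c(shed, lapply(sh$shed, function(st)
          stateSerialize(.stateFromList(st))))
      }
    }
    list(db = db, energyT = en, shed = shed, processed = done)
  }

  while (length(masterStack) || length(jobs)) {
    while (length(jobs) < P && length(masterStack)) {
      st <- masterStack[[length(masterStack)]]
      masterStack[[length(masterStack)]] <- NULL
      blob <- stateSerialize(.stateFromList(st))
      job <- parallel::mcparallel(workerJob(blob))
      jobs[[as.character(job$pid)]] <- job
      grants <- grants + 1
    }
    got <- parallel::mccollect(jobs, wait = FALSE, timeout = 0.02)
    if (!is.null(got)) {
      for (pid in names(got)) {
        if (is.null(got[[pid]])) next
        res <- got[[pid]]
        jobs[[pid]] <- NULL
        if (inherits(res, "try-error") || !is.list(res))
          stop("worker failure: a forked enumeration job did not return a result; run aborted")
        allDb <- c(allDb, res$db)
        allEn <- c(allEn, res$energyT)
        processed <- processed + res$processed
        if (length(res$shed)) {
          shares <- shares + 1
          for (b in res$shed)
            masterStack[[length(masterStack) + 1L]] <-
              .stateToList(stateDeserialize(b))
        }
      }
    }
  }
  list(db = allDb, energyT = allEn,
       diagnostics = list(backend = "fork", nWorkers = P,
                          shareThreshold = threshold,
                          statesProcessed = processed,
                          messages = list(grant_state = grants,
                                          share_states = shares)))
}
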