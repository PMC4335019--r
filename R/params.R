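#' Load a nearest-neighbor thermodynamic parameter set
#'
#' Reads a parameter file in the plain-text block dialect documented below,
#' or the compact Turner-style default set shipped with the package
#' (`source = "default"`).  The shipped set covers stacking energies for all
#' 36 ordered pair-type combinations, hairpin/bulge/internal loop tables to
#' length 30, the affine multibranch terms, the terminal AU/GU penalty and
#' the logarithmic loop extrapolation; it reproduces the qualitative shape of
#' the 2004 Turner rules without claiming bit-exactness.
#'
#' The file dialect consists of blocks introduced by a `[name]` header with
#' whitespace-separated numbers in kcal/mol (`Inf` allowed):
#' \preformatted{
#'   [stack]     6 rows x 6 columns, pair order AU CG GC UA GU UG
#'   [hairpin]   loop energies for lengths 1..max (first two Inf)
#'   [bulge]     loop energies for lengths 1..max
#'   [internal]  loop energies for total lengths 1..max (first Inf)
#'   [multiloop] closing  branch  unpaired
#'   [misc]      terminalAU  loopExtrapolation  temperatureK
#' }
#' Lines starting with `#` are comments.
#'
#' @param source `"default"` or the path of a parameter file.
#' @return an [EnergyParams-class] object.
#' @examples
#' p <- loadEnergyParams()
#' p@stack["CG", "CG"]    # stacking is stabilizing
#' @export
loadEnergyParams <- function(source = "default") {
  if (identical(source, "default")) {
    path <- system.file("extdata", "params", "default.par",
                        package = "wuchtyfold")
    if (!nzchar(path)) stop("I/O error: shipped default parameter set not found")
  } else {
    path <- source
    if (!file.exists(path))
      stop(sprintf("I/O error: parameter file '%s' not found", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  heads <- grep("^\\[", lines)
  if (!length(heads)) stop("parse error: no [block] headers in parameter file")
  blocks <- list()
  for (h in seq_along(heads)) {
    name <- gsub("^\\[|\\]$", "", lines[heads[h]])
    from <- heads[h] + 1
    to <- if (h < length(heads)) heads[h + 1] - 1 else length(lines)
    body <- if (from > to) character() else lines[from:to]
    vals <- suppressWarnings(as.numeric(unlist(strsplit(paste(body, collapse = " "),
                                                        "[[:space:]]+"))))
    if (anyNA(vals))
      stop(sprintf("parse error in block [%s]: non-numeric entry", name))
    blocks[[name]] <- vals
  }
  need <- c("stack", "hairpin", "bulge", "internal", "multiloop", "misc")
  miss <- setdiff(need, names(blocks))
  if (length(miss))
    stop(sprintf("parse error: missing block [%s]", miss[1]))
  if (length(blocks$stack) != 36)
    stop("parse error in block [stack]: expected 36 numbers (6x6)")
  st <- matrix(blocks$stack, 6, 6, byrow = TRUE,
               dimnames = list(.PAIR_TYPES, .PAIR_TYPES))
  nt <- length(blocks$hairpin)
  if (nt < 3 || length(blocks$bulge) != nt || length(blocks$internal) != nt)
    stop("parse error in block [hairpin]/[bulge]/[internal]: tables must share one length >= 3")
  if (length(blocks$multiloop) != 3)
    stop("parse error in block [multiloop]: expected closing, branch, unpaired")
  if (length(blocks$misc) != 3)
    stop("parse error in block [misc]: expected terminalAU, loopExtrapolation, temperature")
  new("EnergyParams",
      stack = st,
      hairpin = blocks$hairpin,
      bulge = blocks$bulge,
      internal = blocks$internal,
      multiloop = blocks$multiloop,
      terminalAU = blocks$misc[1],
      loopExtrapolation = blocks$misc[2],
      temperature = blocks$misc[3],
      source = if (identical(source, "default")) "default" else basename(path))
}

# convert kcal/mol parameters to the integer tenths representation consumed
# by the C++ core
.modelTenths <- function(params) {
  toT <- function(x) {
    y <- round(x * 10)
    y[!is.finite(y)] <- .INF_E
    storage.mode(y) <- "integer"
    y
  }
  list(stack = toT(params@stack),
       hairpin = toT(params@hairpin),
       bulge = toT(params@bulge),
       internal = toT(params@internal),
       maxTab = length(params@hairpin),
       multiA = toT(params@multiloop[1]),
       multiB = toT(params@multiloop[2]),
       multiC = toT(params@multiloop[3]),
       terminalAU = toT(params@terminalAU),
       logCoef = toT(params@loopExtrapolation))
}
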