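#' Monoisotopic mass table
#'
#' Residue and constant masses rooting every mass computation in the package.
#' Masses are monoisotopic, in Daltons, stated to five decimals. Isoleucine
#' and leucine share a mass but remain distinct symbols.
#'
#' @return A named list with components `residue_mass` (named numeric vector
#'   over the 20 standard one-letter residue codes), `water_mass` and
#'   `proton_mass`.
#' @examples
#' mt <- massTable()
#' mt$residue_mass[["G"]]
#' @export
massTable <- function() {
  list(
    residue_mass = c(
      G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
      T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
      N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
      E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
      R = 156.10111, Y = 163.06333, W = 186.07931
    ),
    water_mass = 18.01056,
    proton_mass = 1.00728
  )
}

#' @rdname Modification-class
#' @export
setClass("Modification",
  representation(
    name = "character",
    deltaMass = "numeric",
    targets = "character",
    fixed = "logical"
  )
)

setValidity("Modification", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@deltaMass) != 1L || !is.finite(object@deltaMass))
    msg <- c(msg, "'deltaMass' must be a single finite number")
  if (length(object@targets) < 1L)
    msg <- c(msg, "'targets' must name at least one residue")
  if (!all(object@targets %in% names(massTable()$residue_mass)))
    msg <- c(msg, "'targets' must be standard one-letter residue codes")
  if (length(object@fixed) != 1L || is.na(object@fixed))
    msg <- c(msg, "'fixed' must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Residue modification
#'
#' A post-translational modification: a signed monoisotopic mass delta tied to
#' a set of target residues. A fixed modification is applied to every
#' occurrence of its targets; a variable modification is enumerated over site
#' subsets up to a per-peptide cap.
#'
#' @param name modification name.
#' @param deltaMass signed mass delta in Da.
#' @param targets character vector of one-letter residue codes.
#' @param fixed logical; fixed (always applied) or variable.
#' @return A `Modification` object.
#' @examples
#' Modification("oxidation", 15.99491, "M", fixed = FALSE)
#' @export
Modification <- function(name, deltaMass, targets, fixed = FALSE) {
  new("Modification", name = as.character(name),
      deltaMass = as.numeric(deltaMass),
      targets = toupper(as.character(targets)), fixed = as.logical(fixed))
}

setMethod("show", "Modification", function(object) {
  cat(sprintf("Modification '%s': %+0.5f Da on %s (%s)\n",
              object@name, object@deltaMass,
              paste(object@targets, collapse = ""),
              if (object@fixed) "fixed" else "variable"))
})

#' @describeIn Modification modification name.
#' @param object,x a `Modification`.
#' @export
modName <- function(x) x@name

#' @describeIn Modification mass delta in Da.
#' @export
deltaMass <- function(x) x@deltaMass

#' @describeIn Modification target residues.
#' @export
modTargets <- function(x) x@targets

#' @describeIn Modification whether the modification is fixed.
#' @export
isFixed <- function(x) x@fixed

#' Built-in modification definitions
#'
#' Carbamidomethylation of cysteine (fixed), oxidation of methionine,
#' deamidation of asparagine/glutamine, and phosphorylation of
#' serine/threonine/tyrosine.
#'
#' @return Named list of [Modification] objects.
#' @export
builtinModifications <- function() {
  list(
    carbamidomethyl = Modification("carbamidomethyl", 57.02146, "C", fixed = TRUE),
    oxidation       = Modification("oxidation", 15.99491, "M", fixed = FALSE),
    deamidation     = Modification("deamidation", 0.98402, c("N", "Q"), fixed = FALSE),
    phospho         = Modification("phospho", 79.96633, c("S", "T", "Y"), fixed = FALSE)
  )
}

#' @rdname buildLogFactorialTable
#' @export
setClass("LogFactorialTable",
  representation(values = "numeric", nMax = "integer", logBase = "numeric")
)

setValidity("LogFactorialTable", function(object) {
  if (length(object@values) != object@nMax + 1L)
    return("'values' must have length nMax + 1")
  if (!all(is.finite(object@values)))
    return("all table values must be finite")
  TRUE
})

setMethod("show", "LogFactorialTable", function(object) {
  cat(sprintf("LogFactorialTable: log(n!) for n = 0..%d, base %s\n",
              object@nMax,
              if (abs(object@logBase - 10) < 1e-12) "10" else "e"))
})

#' Memoized log-factorial table
#'
#' Precomputes `log(n!)` for `n = 0..nMax` by the recurrence
#' `log(n!) = log(n) + log((n-1)!)`, keeping hyperscore evaluation free of
#' factorial overflow (64-bit integer `n!` already overflows at n >= 21).
#'
#' @param nMax largest `n` tabulated (default 120).
#' @param logBase base of the logarithm, 10 or `exp(1)`.
#' @return A `LogFactorialTable` object.
#' @examples
#' lft <- buildLogFactorialTable()
#' logFactorial(lft, 5)  # log10(120)
#' @export
buildLogFactorialTable <- function(nMax = 120L, logBase = 10) {
  if (!is.numeric(nMax) || length(nMax) != 1L || nMax < 1)
    stop("'nMax' must be a single integer >= 1")
  nMax <- as.integer(nMax)
  if (!(isTRUE(all.equal(logBase, 10)) || isTRUE(all.equal(logBase, exp(1)))))
    stop("'logBase' must be 10 or exp(1)")
  vals <- c(0, cumsum(log(seq_len(nMax), base = logBase)))
  new("LogFactorialTable", values = vals, nMax = nMax, logBase = logBase)
}

#' @describeIn buildLogFactorialTable look up `log(n!)`; errors past `nMax`
#'   rather than computing on the fly.
#' @param table a `LogFactorialTable`.
#' @param n non-negative integer count (vectorized).
#' @export
logFactorial <- function(table, n) {
  stopifnot(is(table, "LogFactorialTable"))
  if (any(n < 0)) stop("'n' must be non-negative")
  if (any(n > table@nMax))
    stop(sprintf("count %d exceeds table capacity nMax = %d",
                 max(n), table@nMax))
  table@values[n + 1L]
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus one water plus any modification deltas.
#'
#' @param sequence peptide string of one-letter residue codes.
#' @param mods optional list of `c(position, delta)` pairs or a two-column
#'   matrix; positions are 0-based residue indexes.
#' @param mt mass table, defaults to [massTable()].
#' @return Neutral mass in Da.
#' @examples
#' peptideNeutralMass("PEPTIDE")   # 799.35994
#' @export
peptideNeutralMass <- function(sequence, mods = NULL, mt = massTable()) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  m <- mt$residue_mass[res]
  if (anyNA(m)) {
    bad <- unique(res[is.na(m)])
    stop(sprintf("invalid residue(s): %s", paste(bad, collapse = ", ")))
  }
  delta <- 0
  if (!is.null(mods) && length(mods)) {
    mm <- if (is.matrix(mods)) mods else do.call(rbind, mods)
    if (any(mm[, 1] < 0 | mm[, 1] >= length(res)))
      stop("modification position out of range")
    delta <- sum(mm[, 2])
  }
  sum(m) + mt$water_mass + delta
}
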