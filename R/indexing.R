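#' @rdname buildIndex
#' @export
setClass("FragmentIonIndex",
  representation(
    peptides = "data.frame",   # mass-sorted; peptideId = 0-based rank
    fragments = "data.frame",  # mz-sorted, stable; mz/peptideId/series/charge
    params = "list"
  )
)

setValidity("FragmentIonIndex", function(object) {
  msg <- character()
  p <- object@peptides; f <- object@fragments
  if (nrow(p) == 0L) msg <- c(msg, "index must contain at least one peptide")
  if (is.unsorted(p$neutralMass)) msg <- c(msg, "peptide masses must be non-decreasing")
  if (!identical(p$peptideId, seq_len(nrow(p)) - 1L))
    msg <- c(msg, "peptideId must be the dense 0-based mass rank")
  if (nrow(f) && is.unsorted(f$mz)) msg <- c(msg, "fragment m/z must be non-decreasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FragmentIonIndex", function(object) {
  cat(sprintf(paste0("FragmentIonIndex: %d peptide forms (%.2f-%.2f Da), ",
                     "%d fragment entries (series %s, charge <= %d)\n"),
              nrow(object@peptides),
              min(object@peptides$neutralMass), max(object@peptides$neutralMass),
              nrow(object@fragments),
              paste(object@params$series, collapse = "/"),
              object@params$maxCharge))
})

#' @describeIn buildIndex mass-sorted peptide table of an index.
#' @export
peptides <- function(index) index@peptides

#' @describeIn buildIndex m/z-sorted fragment-entry table of an index.
#' @export
fragments <- function(index) index@fragments

#' @describeIn buildIndex generation settings stored with an index.
#' @export
indexParams <- function(index) index@params

#' Theoretical b/y fragment ions of one peptide form
#'
#' For each prefix length `k = 1..len-1`: the b-ion neutral mass is the sum
#' of the first `k` residue masses plus modification deltas on those sites;
#' the y-ion neutral mass is the sum of the last `k` residues plus their
#' modifications plus water. m/z at charge z is `(neutral + z * proton)/z`.
#' Theoretical fragments carry no intensity.
#'
#' @param sequence peptide string (length >= 2).
#' @param modSites two-column matrix of (0-based position, delta) rows, or NULL.
#' @param series character subset of `c("b", "y")`.
#' @param maxCharge fragments generated for charges `1..maxCharge`.
#' @param mt mass table.
#' @return `data.frame` with columns `mz`, `series`, `charge`, `k`, in
#'   generation order (series, then k, then charge);
#'   `(len-1) * |series| * maxCharge` rows.
#' @examples
#' generateIons("AG")  # b1 = 72.04439, y1 = 76.03930
#' @export
generateIons <- function(sequence, modSites = NULL, series = c("b", "y"),
                         maxCharge = 1L, mt = massTable()) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  if (n < 2L) stop("peptide too short to fragment (length < 2)")
  if (maxCharge < 1L) stop("'maxCharge' must be >= 1")
  m <- mt$residue_mass[res]
  if (anyNA(m)) stop("invalid residue in peptide")
  delta <- numeric(n)
  if (!is.null(modSites) && nrow(modSites))
    delta[modSites[, 1] + 1L] <- delta[modSites[, 1] + 1L] + modSites[, 2]
  site <- unname(m) + delta
  bneut <- cumsum(site)[seq_len(n - 1L)]
  yneut <- rev(cumsum(rev(site)))[2:n] + mt$water_mass  # suffix sums, k=n-1..1
  yneut <- rev(yneut)                                   # k = 1..n-1
  out <- list()
  for (s in series) {
    neut <- if (s == "b") bneut else yneut
    for (k in seq_len(n - 1L)) {
      z <- seq_len(maxCharge)
      out[[length(out) + 1L]] <- data.frame(
        mz = (neut[k] + z * mt$proton_mass) / z,
        series = s, charge = z, k = k, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build the fragment-ion index
#'
#' Stably sorts the peptide forms by neutral mass and assigns dense 0-based
#' `peptideId` ranks (ties keep the canonical input order, so the
#' smaller-index tie rule is well defined), then generates all theoretical
#' fragments in peptide-id order and stably sorts them by m/z — entries with
#' equal m/z that originate from the same peptide stay at adjacent locations.
#' The index is immutable; tolerance windows are applied only at query time.
#'
#' @param entries `data.frame` of peptide-form precursors as produced by
#'   [digestProteins()] / [enumerateModforms()] (columns `sequence`, `mods`,
#'   `neutralMass`, `modSites`, optionally `protein`/`proteins`).
#' @param series fragment series to generate (default b and y).
#' @param maxCharge maximum fragment charge (default 3).
#' @return A `FragmentIonIndex`.
#' @export
buildIndex <- function(entries, series = c("b", "y"), maxCharge = 3L) {
  if (is.null(entries) || nrow(entries) == 0L)
    stop("cannot build an index from an empty peptide list")
  ord <- order(entries$neutralMass, method = "radix")  # stable
  pep <- entries[ord, , drop = FALSE]
  pep$peptideId <- seq_len(nrow(pep)) - 1L
  rownames(pep) <- NULL
  frag <- vector("list", nrow(pep))
  for (i in seq_len(nrow(pep))) {
    g <- generateIons(pep$sequence[i], pep$modSites[[i]], series, maxCharge)
    g$peptideId <- pep$peptideId[i]
    frag[[i]] <- g
  }
  frag <- do.call(rbind, frag)
  frag <- frag[order(frag$mz, method = "radix"), , drop = FALSE]  # stable
  rownames(frag) <- NULL
  new("FragmentIonIndex", peptides = pep, fragments = frag,
      params = list(series = series, maxCharge = as.integer(maxCharge)))
}

# half-open [lo, hi) 1-based row range of sorted values v with
# |v - q| <= delta; boundaries inclusive on both sides, membership decided
# by the absolute-difference predicate itself so floating-point boundary
# cases match a linear scan exactly
.windowRange <- function(v, q, delta) {
  n <- length(v)
  lo <- findInterval(q - delta, v) # count of v <= q - delta
  hi <- findInterval(q + delta, v) # count of v <= q + delta
  # fix edges against the canonical predicate
  while (lo >= 1L && abs(v[lo] - q) <= delta) lo <- lo - 1L
  lo <- lo + 1L
  while (lo <= n && abs(v[lo] - q) > delta) lo <- lo + 1L
  while (hi < n && abs(v[hi + 1L] - q) <= delta) hi <- hi + 1L
  while (hi >= 1L && abs(v[hi] - q) > delta) hi <- hi - 1L
  if (hi < lo) hi <- lo - 1L
  c(lo, hi + 1L)
}

#' Precursor-mass candidate window
#'
#' Peptide ids whose neutral mass lies within `deltaM` of the query mass;
#' both boundaries inclusive. `deltaM` compares neutral monoisotopic masses,
#' not m/z.
#'
#' @param index a `FragmentIonIndex`.
#' @param queryMass query neutral mass (Da).
#' @param deltaM precursor tolerance (Da), >= 0.
#' @return Integer vector `c(lo, hi)`: the half-open 0-based peptide-id
#'   range `[lo, hi)`; empty when `lo == hi`.
#' @export
precursorWindow <- function(index, queryMass, deltaM) {
  if (deltaM < 0) stop("'deltaM' must be >= 0")
  r <- .windowRange(index@peptides$neutralMass, queryMass, deltaM)
  c(r[1] - 1L, r[2] - 1L)
}

#' Fragment-m/z window
#'
#' Row range of the fragment table with `|mz - queryMz| <= deltaF`;
#' comparisons are done in floating point (no integer binning).
#'
#' @param index a `FragmentIonIndex`.
#' @param queryMz query fragment m/z (Da).
#' @param deltaF fragment tolerance (Da), >= 0.
#' @return Integer vector `c(lo, hi)`: half-open 1-based row range into
#'   `fragments(index)`.
#' @export
fragmentWindow <- function(index, queryMz, deltaF) {
  if (deltaF < 0) stop("'deltaF' must be >= 0")
  .windowRange(index@fragments$mz, queryMz, deltaF)
}

#' Save / load a fragment-ion index
#'
#' The on-disk form is a versioned binary payload with a magic header; the
#' loader validates the magic, the format version, and (optionally) that the
#' stored generation parameters match the expected ones.
#'
#' @param index a `FragmentIonIndex`.
#' @param path file path.
#' @export
saveIndex <- function(index, path) {
  stopifnot(is(index, "FragmentIonIndex"))
  saveRDS(list(magic = "FIONIDX", version = 1L, params = index@params,
               peptides = index@peptides, fragments = index@fragments),
          path)
  invisible(path)
}

#' @rdname saveIndex
#' @param expectedParams if non-NULL, a list like `indexParams()` output that
#'   the stored parameters must equal.
#' @export
loadIndex <- function(path, expectedParams = NULL) {
  x <- readRDS(path)
  if (!identical(x$magic, "FIONIDX")) stop("not a fragment-ion index file")
  if (!identical(x$version, 1L))
    stop(sprintf("unsupported index version %s", x$version))
  if (!is.null(expectedParams) && !identical(x$params, expectedParams))
    stop("index parameters do not match the requested settings")
  new("FragmentIonIndex", peptides = x$peptides, fragments = x$fragments,
      params = x$params)
}
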