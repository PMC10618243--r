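#' Hyperscore
#'
#' Similarity between a theoretical and an experimental spectrum:
#' `log(n_b!) + log(n_y!) + log(sum i_b) + log(sum i_y)`, where `n_b`/`n_y`
#' are the counts of shared b/y ions and the sums run over the matched
#' experimental intensities. A log term whose intensity sum is zero
#' contributes 0, keeping scores finite when one series is absent. The
#' factorial logs come from the memoized table; counts beyond its capacity
#' raise an error rather than being computed on the fly.
#'
#' @param nB,nY matched b- and y-ion counts.
#' @param sumIb,sumIy summed matched experimental intensities (normalized
#'   units), >= 0.
#' @param lft a [buildLogFactorialTable()] table; its base sets the base of
#'   all four log terms.
#' @return The hyperscore (vectorized over the four arguments).
#' @examples
#' hyperscore(2, 1, 10, 5)  # 2 in base 10
#' @export
hyperscore <- function(nB, nY, sumIb, sumIy, lft = buildLogFactorialTable()) {
  if (any(sumIb < 0) || any(sumIy < 0)) stop("intensity sums must be >= 0")
  lg <- function(x) ifelse(x > 0, log(x, base = .lftBase(lft)), 0)
  logFactorial(lft, nB) + logFactorial(lft, nY) + lg(sumIb) + lg(sumIy)
}

.lftBase <- function(lft) lft@logBase

#' Search one preprocessed spectrum against the index
#'
#' Candidate peptides are those whose neutral mass lies within `deltaM` of
#' the query's neutral mass. Every experimental peak is looked up in the
#' m/z-sorted fragment index with tolerance `deltaF`; each
#' (peak, fragment-entry) pair whose peptide is a candidate counts once,
#' incrementing that candidate's b- or y-series count and adding the peak's
#' normalized intensity to the series sum. Candidates sharing at least
#' `minShared` fragment ions (b+y jointly) are scored with the hyperscore
#' and accumulated into the null histogram at unit-width bins
#' `max(0, floor(h))`. The reported match is the maximal hyperscore, ties
#' resolved to the smaller peptide id. The e-value slot is left `NA` here
#' and is filled by postprocessing only when at least `minHits` candidates
#' were scored.
#'
#' @param q a `PreprocessedSpectrum` (excluded spectra yield no match).
#' @param index a `FragmentIonIndex`.
#' @param deltaM precursor tolerance in Da (~1 closed, 100-500 open).
#' @param deltaF fragment tolerance in Da (default 0.01).
#' @param minShared minimum shared fragment ions for candidacy (default 4).
#' @param minHits minimum scored candidates for statistical scoring
#'   (default 4; recorded for postprocessing).
#' @param lft log-factorial table used by the hyperscore.
#' @return List with `psm` (one-row `data.frame` or NULL), `null` (integer
#'   histogram of scored-candidate hyperscores, bins 0..len-1), and
#'   `numCandidates` (scored-candidate count).
#' @export
searchSpectrum <- function(q, index, deltaM, deltaF = 0.01,
                           minShared = 4L, minHits = 4L,
                           lft = buildLogFactorialTable()) {
  stopifnot(is(index, "FragmentIonIndex"))
  if (deltaM < 0 || deltaF < 0) stop("tolerances must be >= 0")
  empty <- list(psm = NULL, null = integer(0), numCandidates = 0L)
  if (isExcluded(q)) return(empty)
  win <- precursorWindow(index, q@neutralMass, deltaM)
  if (win[2] <= win[1]) return(empty)
  idLo <- win[1]; nCand <- win[2] - win[1]      # candidate ids idLo..win[2]-1
  nb <- integer(nCand); ny <- integer(nCand)
  sib <- numeric(nCand); siy <- numeric(nCand)
  pk <- q@peaks
  fr <- index@fragments
  for (p in seq_len(nrow(pk))) {
    r <- fragmentWindow(index, pk[p, 1], deltaF)
    if (r[2] <= r[1]) next
    rows <- r[1]:(r[2] - 1L)
    pid <- fr$peptideId[rows]
    inWin <- pid >= idLo & pid < win[2]
    if (!any(inWin)) next
    rows <- rows[inWin]
    slot <- fr$peptideId[rows] - idLo + 1L
    isB <- fr$series[rows] == "b"
    if (any(isB)) {
      tb <- tabulate(slot[isB], nCand)
      nb <- nb + tb
      sib <- sib + tb * pk[p, 2]
    }
    if (any(!isB)) {
      ty <- tabulate(slot[!isB], nCand)
      ny <- ny + ty
      siy <- siy + ty * pk[p, 2]
    }
  }
  scored <- which(nb + ny >= minShared)
  if (!length(scored)) return(empty)
  h <- hyperscore(nb[scored], ny[scored], sib[scored], siy[scored], lft)
  bins <- pmax(0L, as.integer(floor(h)))
  null <- tabulate(bins + 1L, max(bins) + 1L)
  top <- scored[which.max(h)]                   # which.max: first max = smaller id
  hTop <- max(h)
  pepRow <- index@peptides[idLo + top, , drop = FALSE]  # 1-based row = id + 1
  psm <- data.frame(
    scanId = q@scanId,
    peptideId = pepRow$peptideId,
    sequence = pepRow$sequence,
    mods = pepRow$mods,
    peptideMass = pepRow$neutralMass,
    queryMass = q@neutralMass,
    deltaMassDa = q@neutralMass - pepRow$neutralMass,
    charge = q@charge,
    hyperscore = hTop,
    nB = nb[top], nY = ny[top],
    numCandidates = length(scored),
    eValue = NA_real_,
    stringsAsFactors = FALSE)
  list(psm = psm, null = null, numCandidates = length(scored))
}

#' Search a batch of spectra
#'
#' Streams the batch through [searchSpectrum()] in chunks. The chunk size is
#' a scheduling knob only: results are element-wise identical to searching
#' each spectrum independently, whatever the chunking.
#'
#' @param batch list of `PreprocessedSpectrum` objects.
#' @param index a `FragmentIonIndex`.
#' @param chunkSize spectra per chunk (default 512).
#' @inheritParams searchSpectrum
#' @return List of [searchSpectrum()] results, same order as the input.
#' @export
searchBatch <- function(batch, index, deltaM, deltaF = 0.01,
                        minShared = 4L, minHits = 4L,
                        lft = buildLogFactorialTable(), chunkSize = 512L) {
  if (!length(batch)) return(list())
  starts <- seq(1L, length(batch), by = chunkSize)
  out <- vector("list", length(batch))
  for (s in starts) {
    idx <- s:min(s + chunkSize - 1L, length(batch))
    out[idx] <- lapply(batch[idx], searchSpectrum, index = index,
                       deltaM = deltaM, deltaF = deltaF,
                       minShared = minShared, minHits = minHits, lft = lft)
  }
  out
}
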