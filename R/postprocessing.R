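#' Tail-fit parameters
#'
#' Settings for the expectation-value fit. The fitted tail is the run of
#' histogram bins strictly above the histogram mode that still have nonzero
#' survival; at least `minTailPoints` usable bins are required and the
#' fitted slope must be negative, otherwise the e-value is undefined with a
#' reason code.
#'
#' @param minTailPoints minimum usable tail bins (default 4, must be >= 2).
#' @param minHits minimum scored candidates for statistical scoring
#'   (default 4).
#' @return A validated list of class `TailFitParams`.
#' @export
tailFitParams <- function(minTailPoints = 4L, minHits = 4L) {
  if (minTailPoints < 2L) stop("'minTailPoints' must be >= 2")
  structure(list(minTailPoints = as.integer(minTailPoints),
                 minHits = as.integer(minHits)),
            class = "TailFitParams")
}

#' Expectation value by linear tail fit
#'
#' From the null histogram of candidate hyperscores, the survival function
#' `S(s) = sum_{b >= s} counts[b]` is computed and `log10 S` is fitted by
#' least squares over the tail bins (strictly above the histogram mode, with
#' `S > 0`), giving slope `a` and intercept `c`. The e-value of the top hit
#' is the extrapolation `10^(c + a * hTop)`: the expected number of random
#' candidates scoring at least `hTop`.
#'
#' @param null numeric histogram over unit score bins `0..length-1`.
#' @param hTop hyperscore of the top hit, >= 0.
#' @param params a [tailFitParams()].
#' @return List with `eValue` (number or NA), `slope`, `intercept`, and
#'   `reason` (empty when defined; otherwise one of
#'   `"insufficient_hits"`, `"degenerate_tail"`, `"nonnegative_slope"`).
#' @examples
#' s <- 10^(5 - 0.5 * (0:9)); counts <- -diff(c(s, 0))
#' tailFitEvalue(counts, 12)$eValue  # 0.1
#' @export
tailFitEvalue <- function(null, hTop, params = tailFitParams()) {
  if (hTop < 0) stop("'hTop' must be >= 0")
  undef <- function(reason) list(eValue = NA_real_, slope = NA_real_,
                                 intercept = NA_real_, reason = reason)
  if (!length(null) || sum(null) < params$minHits)
    return(undef("insufficient_hits"))
  s <- seq_along(null) - 1L                      # bin scores
  surv <- rev(cumsum(rev(null)))                 # S(s)
  mode <- s[which.max(null)]                     # ties -> smallest bin
  tail <- which(s > mode & surv > 0)
  if (length(tail) < params$minTailPoints) return(undef("degenerate_tail"))
  fit <- stats::lm.fit(cbind(1, s[tail]), log10(surv[tail]))
  cc <- unname(fit$coefficients[1]); a <- unname(fit$coefficients[2])
  if (!is.finite(a) || a >= 0) return(undef("nonnegative_slope"))
  list(eValue = 10^(cc + a * hTop), slope = a, intercept = cc, reason = "")
}

#' Write peptide-spectrum matches to TSV
#'
#' One row per searched spectrum, stable column order, `NA` for undefined
#' e-values; the file round-trips through [readResults()].
#'
#' @param psms `data.frame` of PSM rows (as assembled by [runPipeline()] or
#'   bound from [searchSpectrum()] results).
#' @param path output file path.
#' @export
writeResults <- function(psms, path) {
  cols <- c("scanId", "sequence", "mods", "peptideMass", "deltaMassDa",
            "charge", "hyperscore", "nB", "nY", "numCandidates", "eValue")
  if (is.null(psms) || nrow(psms) == 0L) {
    psms <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  } else {
    for (cl in setdiff(cols, names(psms))) psms[[cl]] <- NA
    psms <- psms[, cols, drop = FALSE]
  }
  utils::write.table(psms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "NA")
}

#' Run the full search pipeline
#'
#' Digest -> modification forms -> fragment-ion index (reusing a stored
#' index when its parameters match) -> MS2 preprocessing (dataset cache) ->
#' database search -> e-values -> TSV, with per-stage counters in the
#' returned log.
#'
#' @param fasta FASTA file of protein sequences.
#' @param ms2 MS2 file of experimental spectra.
#' @param outPath output TSV path.
#' @param digest a [digestParams()].
#' @param fixedMods,variableMods,maxVarMods modification setup.
#' @param deltaM,deltaF search tolerances (Da).
#' @param minShared,minHits candidacy / statistical-scoring gates.
#' @param k,normalization preprocessing settings.
#' @param series,maxCharge theoretical fragment generation settings.
#' @param indexPath optional path to store/reuse the index.
#' @param cacheDir preprocessing cache directory (default: alongside `ms2`).
#' @param tailFit a [tailFitParams()].
#' @return List with `results` (the PSM `data.frame`), `log` (named stage
#'   counters), and `outPath`.
#' @export
runPipeline <- function(fasta, ms2, outPath,
                        digest = digestParams(),
                        fixedMods = list(builtinModifications()$carbamidomethyl),
                        variableMods = list(), maxVarMods = 5L,
                        deltaM = 1, deltaF = 0.01,
                        minShared = 4L, minHits = 4L,
                        k = 100L, normalization = "basepeak",
                        series = c("b", "y"), maxCharge = 3L,
                        indexPath = NULL, cacheDir = dirname(ms2),
                        tailFit = tailFitParams(minHits = minHits)) {
  log <- list()
  idxParams <- list(series = series, maxCharge = as.integer(maxCharge))
  index <- NULL
  if (!is.null(indexPath) && file.exists(indexPath)) {
    index <- tryCatch(loadIndex(indexPath, expectedParams = idxParams),
                      error = function(e) NULL)
    log$indexReused <- !is.null(index)
  }
  if (is.null(index)) {
    proteins <- readFasta(fasta)
    log$proteins <- length(proteins)
    entries <- digestProteins(proteins, digest, fixedMods, variableMods,
                              maxVarMods)
    log$peptideForms <- nrow(entries)
    index <- buildIndex(entries, series, maxCharge)
    if (!is.null(indexPath)) saveIndex(index, indexPath)
    log$indexReused <- FALSE
  }
  log$fragments <- nrow(fragments(index))

  pre <- preprocessFile(ms2, cacheDir = cacheDir, k = k,
                        normalization = normalization)
  log$preprocessCacheHit <- pre$cacheHit
  log$spectraRead <- length(pre$spectra)
  kept <- Filter(Negate(isExcluded), pre$spectra)
  log$spectraKept <- length(kept)
  log$spectraExcluded <- log$spectraRead - log$spectraKept

  lft <- buildLogFactorialTable()
  res <- searchBatch(kept, index, deltaM, deltaF, minShared, minHits, lft)
  rows <- list()
  for (i in seq_along(res)) {
    r <- res[[i]]
    if (is.null(r$psm)) {
      rows[[i]] <- data.frame(
        scanId = scanId(kept[[i]]), peptideId = NA_integer_,
        sequence = NA_character_, mods = NA_character_,
        peptideMass = NA_real_, queryMass = neutralMass(kept[[i]]),
        deltaMassDa = NA_real_, charge = precursorCharge(kept[[i]]),
        hyperscore = NA_real_, nB = NA_integer_, nY = NA_integer_,
        numCandidates = r$numCandidates, eValue = NA_real_,
        stringsAsFactors = FALSE)
    } else {
      psm <- r$psm
      if (r$numCandidates >= minHits) {
        ev <- tailFitEvalue(r$null, psm$hyperscore, tailFit)
        psm$eValue <- ev$eValue
      }
      rows[[i]] <- psm
    }
  }
  results <- do.call(rbind, rows)
  if (is.null(results)) results <- data.frame()
  log$psms <- if (nrow(results)) sum(!is.na(results$sequence)) else 0L
  writeResults(results, outPath)
  list(results = results, log = log, outPath = outPath)
}
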