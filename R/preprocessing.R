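#' @rdname readMS2
#' @export
setClass("Spectrum",
  representation(
    scanId = "integer",
    precursorMz = "numeric",
    charge = "integer",
    neutralMass = "numeric",
    peaks = "matrix"           # columns mz, intensity
  )
)

setValidity("Spectrum", function(object) {
  msg <- character()
  pk <- object@peaks
  if (ncol(pk) != 2L) msg <- c(msg, "'peaks' must have columns mz, intensity")
  if (nrow(pk) && any(pk[, 2] < 0)) msg <- c(msg, "intensities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname preprocessSpectrum
#' @export
setClass("PreprocessedSpectrum",
  contains = "Spectrum",
  representation(
    k = "integer",
    normalization = "character",
    excluded = "logical",
    exclusionReason = "character"
  )
)

setValidity("PreprocessedSpectrum", function(object) {
  if (!object@excluded && nrow(object@peaks) > object@k)
    return("a preprocessed spectrum holds at most K peaks")
  TRUE
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum scan %d: z=%d, neutral mass %.4f Da, %d peaks\n",
              object@scanId, object@charge, object@neutralMass,
              nrow(object@peaks)))
})

setMethod("show", "PreprocessedSpectrum", function(object) {
  cat(sprintf(
    "PreprocessedSpectrum scan %d: z=%d, %.4f Da, %d/%d peaks (%s)%s\n",
    object@scanId, object@charge, object@neutralMass, nrow(object@peaks),
    object@k, object@normalization,
    if (object@excluded) paste0(" [excluded: ", object@exclusionReason, "]")
    else ""))
})

#' @describeIn readMS2 scan identifier accessor.
#' @param s a `Spectrum`.
#' @export
scanId <- function(s) s@scanId

#' @describeIn readMS2 neutral (uncharged) precursor mass accessor.
#' @export
neutralMass <- function(s) s@neutralMass

#' @describeIn readMS2 precursor charge accessor.
#' @export
precursorCharge <- function(s) s@charge

#' @describeIn readMS2 peak matrix accessor (columns mz, intensity).
#' @export
peaks <- function(s) s@peaks

#' @describeIn preprocessSpectrum whether the spectrum was flagged excluded.
#' @export
isExcluded <- function(s) is(s, "PreprocessedSpectrum") && s@excluded

.PROTON <- 1.00728

#' Construct a spectrum
#'
#' @param scanId integer scan number.
#' @param precursorMz precursor m/z.
#' @param charge precursor charge state.
#' @param peaks two-column matrix (mz, intensity).
#' @param neutralMass neutral mass; computed as
#'   `(precursorMz - proton) * charge` when missing.
#' @return A `Spectrum`.
#' @export
spectrum <- function(scanId, precursorMz, charge, peaks,
                     neutralMass = NULL) {
  peaks <- matrix(as.numeric(peaks), ncol = 2,
                  dimnames = list(NULL, c("mz", "intensity")))
  if (is.null(neutralMass)) neutralMass <- (precursorMz - .PROTON) * charge
  new("Spectrum", scanId = as.integer(scanId),
      precursorMz = as.numeric(precursorMz), charge = as.integer(charge),
      neutralMass = as.numeric(neutralMass), peaks = peaks)
}

#' Read / write spectra in MS2 format
#'
#' Parses the MSConvert MS2 dialect: `H` header lines (ignored), `S` lines
#' (scan number and precursor m/z), `Z` lines (charge and M+H), then peak
#' lines `mz intensity`. The neutral mass is `(M+H) - proton` when a Z line
#' is present; a spectrum with several Z lines yields one `Spectrum` per
#' charge state. Scans with no Z line are skipped with a warning.
#'
#' @param path MS2 file path.
#' @return List of [Spectrum][spectrum] objects.
#' @export
readMS2 <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  out <- list()
  scan <- NULL; pmz <- NULL; zs <- NULL; mhs <- NULL; pk <- NULL
  flush <- function() {
    if (is.null(scan)) return()
    if (is.null(zs)) {
      warning(sprintf("scan %s has no Z line; skipped", scan))
      return()
    }
    pkm <- if (is.null(pk)) matrix(numeric(0), ncol = 2) else do.call(rbind, pk)
    for (j in seq_along(zs)) {
      out[[length(out) + 1L]] <<- spectrum(
        scan, pmz, zs[j], pkm, neutralMass = mhs[j] - .PROTON)
    }
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "H")) next
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (f[1] == "S") {
      flush()
      if (length(f) < 3L) stop(sprintf("malformed S line at line %d", i))
      scan <- as.integer(f[2]); pmz <- as.numeric(f[length(f)])
      zs <- NULL; mhs <- NULL; pk <- NULL
      if (is.na(scan) || is.na(pmz))
        stop(sprintf("malformed S line at line %d", i))
    } else if (f[1] == "Z") {
      if (length(f) < 3L || anyNA(suppressWarnings(as.numeric(f[2:3]))))
        stop(sprintf("malformed Z line at line %d", i))
      zs <- c(zs, as.integer(f[2])); mhs <- c(mhs, as.numeric(f[3]))
    } else if (f[1] %in% c("I", "D")) {
      next  # per-scan metadata, ignored
    } else {
      v <- suppressWarnings(as.numeric(f))
      if (length(v) < 2L || anyNA(v[1:2]))
        stop(sprintf("malformed peak line at line %d", i))
      if (is.null(scan)) stop(sprintf("peak line before any S line (line %d)", i))
      pk[[length(pk) + 1L]] <- v[1:2]
    }
  }
  flush()
  out
}

#' @rdname readMS2
#' @param spectra list of `Spectrum` objects.
#' @param header optional character vector of H-line comments.
#' @export
writeMS2 <- function(spectra, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("H\t", h), con)
  for (s in spectra) {
    writeLines(sprintf("S\t%d\t%d\t%.5f", s@scanId, s@scanId, s@precursorMz),
               con)
    writeLines(sprintf("Z\t%d\t%.5f", s@charge, s@neutralMass + .PROTON), con)
    pk <- s@peaks
    if (nrow(pk))
      writeLines(sprintf("%.5f %.5f", pk[, 1], pk[, 2]), con)
  }
  invisible(path)
}

.normalizeIntensity <- function(intensity, rule) {
  switch(rule,
    basepeak = intensity / max(intensity) * 100,
    sqrt = { v <- sqrt(intensity); v / max(v) * 100 },
    identity = intensity,
    stop(sprintf("unknown normalization rule '%s'", rule)))
}

#' Normalize and extract the top-K peaks of a spectrum
#'
#' Intensities are normalized (default: linear scaling so the base peak is
#' 100), the K highest-intensity peaks are retained — an intensity tie at
#' the K-th rank is broken toward the lower-m/z peak — and the result is
#' re-sorted by m/z. Spectra outside the acceptance bounds (precursor
#' neutral mass 500-5000 Da, charge +1..+4) or with all-zero intensity are
#' flagged excluded with a reason instead of being dropped.
#'
#' @param s a [Spectrum][spectrum].
#' @param k number of peaks to retain (default 100).
#' @param normalization `"basepeak"`, `"sqrt"` or `"identity"`.
#' @param massRange,chargeRange acceptance bounds for the precursor.
#' @return A `PreprocessedSpectrum`.
#' @export
preprocessSpectrum <- function(s, k = 100L, normalization = "basepeak",
                               massRange = c(500, 5000),
                               chargeRange = c(1L, 4L)) {
  if (k < 1L) stop("'k' must be >= 1")
  mk <- function(pk, excluded = FALSE, reason = "") {
    new("PreprocessedSpectrum", scanId = s@scanId,
        precursorMz = s@precursorMz, charge = s@charge,
        neutralMass = s@neutralMass, peaks = pk, k = as.integer(k),
        normalization = normalization, excluded = excluded,
        exclusionReason = reason)
  }
  if (s@neutralMass < massRange[1] || s@neutralMass > massRange[2])
    return(mk(s@peaks, TRUE, "precursor mass out of range"))
  if (s@charge < chargeRange[1] || s@charge > chargeRange[2])
    return(mk(s@peaks, TRUE, "precursor charge out of range"))
  pk <- s@peaks
  if (nrow(pk) == 0L || all(pk[, 2] == 0))
    return(mk(pk, TRUE, "no nonzero-intensity peaks"))
  pk[, 2] <- .normalizeIntensity(pk[, 2], normalization)
  # rank by intensity desc, ties toward lower mz; keep top K
  keep <- order(-pk[, 2], pk[, 1], method = "radix")[seq_len(min(k, nrow(pk)))]
  pk <- pk[keep, , drop = FALSE]
  pk <- pk[order(pk[, 1], method = "radix"), , drop = FALSE]
  mk(pk)
}

#' Preprocess a batch of spectra
#'
#' The contract is element-wise equivalence with mapping
#' [preprocessSpectrum()] over the batch independently; batching never
#' changes any individual result.
#'
#' @param batch list of `Spectrum` objects.
#' @inheritParams preprocessSpectrum
#' @return List of `PreprocessedSpectrum` objects, same order as the input.
#' @export
preprocessBatch <- function(batch, k = 100L, normalization = "basepeak",
                            massRange = c(500, 5000),
                            chargeRange = c(1L, 4L)) {
  lapply(batch, preprocessSpectrum, k = k, normalization = normalization,
         massRange = massRange, chargeRange = chargeRange)
}

#' Preprocess an MS2 file with a dataset-level cache
#'
#' Runs [preprocessBatch()] over a whole MS2 file and writes the kept
#' spectra back as MS2 plus a JSON sidecar recording K, the normalization
#' rule, a format version and the input's content hash. A second invocation
#' with the same input and settings is a no-op cache hit; changing any
#' setting (or the input file) forces re-processing.
#'
#' @param path input MS2 file.
#' @param cacheDir directory for the preprocessed MS2 + sidecar.
#' @inheritParams preprocessSpectrum
#' @return List with `spectra` (preprocessed, exclusions flagged),
#'   `cacheHit` (logical), and `cachedPath`.
#' @export
preprocessFile <- function(path, cacheDir = tempdir(), k = 100L,
                           normalization = "basepeak",
                           massRange = c(500, 5000),
                           chargeRange = c(1L, 4L)) {
  hash <- unname(tools::md5sum(path))
  dir.create(cacheDir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(cacheDir,
                    paste0(tools::file_path_sans_ext(basename(path)),
                           ".preprocessed"))
  ms2out <- paste0(base, ".ms2"); sidecar <- paste0(base, ".json")
  meta <- list(version = 1L, k = as.integer(k), normalization = normalization,
               massRange = massRange, chargeRange = chargeRange,
               sourceHash = hash)
  if (file.exists(sidecar) && file.exists(ms2out)) {
    old <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (identical(as.integer(old$version), meta$version) &&
        identical(as.integer(old$k), meta$k) &&
        identical(old$normalization, meta$normalization) &&
        identical(as.numeric(old$massRange), as.numeric(meta$massRange)) &&
        identical(as.integer(old$chargeRange), as.integer(meta$chargeRange)) &&
        identical(old$sourceHash, hash)) {
      sp <- readMS2(ms2out)
      pp <- lapply(sp, function(s)
        new("PreprocessedSpectrum", scanId = s@scanId,
            precursorMz = s@precursorMz, charge = s@charge,
            neutralMass = s@neutralMass, peaks = s@peaks,
            k = meta$k, normalization = normalization,
            excluded = FALSE, exclusionReason = ""))
      return(list(spectra = pp, cacheHit = TRUE, cachedPath = ms2out))
    }
  }
  pp <- preprocessBatch(readMS2(path), k, normalization, massRange, chargeRange)
  kept <- Filter(Negate(isExcluded), pp)
  writeMS2(kept, ms2out)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  list(spectra = pp, cacheHit = FALSE, cachedPath = ms2out)
}
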