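# run expr with a private RNG stream seeded from `seed`, restoring the
# caller's RNG state afterwards
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic-dataset specification
#'
#' Controls the seeded generators for proteins and spectra. Identical specs
#' (including the seed) produce byte-identical outputs.
#'
#' @param nProteins number of proteins to generate.
#' @param proteinLenRange approximate protein length bounds (residues).
#' @param seed RNG seed.
#' @param spectraPerPeptide spectra generated per selected peptide.
#' @param noisePeaks uniform-random noise peaks added per spectrum, placed
#'   at least `2 * deltaF` from every signal peak.
#' @param intensityModel `"rank"` (signal intensity 100/rank) or `"flat"`.
#' @param chargeRange precursor charge states sampled uniformly.
#' @param ptmMenu list of [Modification] objects available to the
#'   generators.
#' @return A validated list of class `FixtureSpec`.
#' @export
fixtureSpec <- function(nProteins = 20L, proteinLenRange = c(60L, 200L),
                        seed = 1L, spectraPerPeptide = 1L,
                        noisePeaks = 10L, intensityModel = "rank",
                        chargeRange = c(2L, 3L),
                        ptmMenu = builtinModifications()) {
  if (nProteins < 1L) stop("'nProteins' must be >= 1")
  if (proteinLenRange[1] < 7L)
    stop("proteins shorter than 7 residues cannot hold a length-6 tryptic peptide")
  if (!intensityModel %in% c("rank", "flat"))
    stop("unknown intensity model")
  structure(list(nProteins = as.integer(nProteins),
                 proteinLenRange = as.integer(proteinLenRange),
                 seed = as.integer(seed),
                 spectraPerPeptide = as.integer(spectraPerPeptide),
                 noisePeaks = as.integer(noisePeaks),
                 intensityModel = intensityModel,
                 chargeRange = as.integer(chargeRange),
                 ptmMenu = ptmMenu),
            class = "FixtureSpec")
}

#' Generate a synthetic protein FASTA
#'
#' Proteins are concatenations of tryptic segments: a run of non-K/R
#' residues capped by K or R, with segment lengths drawn so that every
#' protein digests to at least one peptide in the 6-46 residue window.
#' Deterministic under the spec's seed.
#'
#' @param spec a [fixtureSpec()].
#' @param path optional FASTA output path; omitted = not written.
#' @return List with `proteins` (named character vector) and `path`.
#' @export
generateFasta <- function(spec = fixtureSpec(), path = NULL) {
  aa <- setdiff(names(massTable()$residue_mass), c("K", "R", "P"))
  proteins <- .withSeed(spec$seed, {
    out <- character(spec$nProteins)
    for (i in seq_len(spec$nProteins)) {
      target <- sample(spec$proteinLenRange[1]:spec$proteinLenRange[2], 1L)
      segs <- character()
      len <- 0L
      while (len < target) {
        core <- sample(5:40, 1L)   # +1 terminator -> peptide length 6..41
        seg <- paste0(paste(sample(aa, core, replace = TRUE), collapse = ""),
                      sample(c("K", "R"), 1L))
        segs <- c(segs, seg)
        len <- len + nchar(seg)
      }
      out[i] <- paste(segs, collapse = "")
    }
    names(out) <- sprintf("synthetic_protein_%03d", seq_len(spec$nProteins))
    out
  })
  if (!is.null(path)) {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins), path)
  }
  list(proteins = proteins, path = path)
}

#' Generate synthetic MS2 spectra with ground truth
#'
#' Each spectrum's signal peaks are the generating peptide form's singly
#' charged b/y ions, with rank-decaying intensities (100/rank in generation
#' order) by default. `noisePeaks` uniform-random peaks are added, rejected
#' within `2 * deltaF` of any signal peak so ground-truth matched-ion counts
#' stay exact. The precursor neutral mass is the peptide mass plus an
#' optional `precursorShift` (e.g. an unsearched PTM delta for open-search
#' truth). Deterministic under the spec's seed.
#'
#' @param entries peptide-form `data.frame` (from [digestProteins()]); one
#'   spectrum set is generated per row.
#' @param spec a [fixtureSpec()].
#' @param deltaF fragment tolerance the noise placement must respect.
#' @param precursorShift added to every precursor neutral mass (Da).
#' @param path optional MS2 output path.
#' @return List with `spectra` (list of `Spectrum`), `truth` (`data.frame`
#'   scanId/sequence/mods/neutralMass/shift), and `path`.
#' @export
generateSpectra <- function(entries, spec = fixtureSpec(), deltaF = 0.01,
                            precursorShift = 0, path = NULL) {
  if (is.null(entries) || nrow(entries) == 0L) stop("no peptides supplied")
  gen <- .withSeed(spec$seed + 1L, {
    spectra <- list(); truth <- list(); scan <- 0L
    for (i in seq_len(nrow(entries))) {
      ions <- generateIons(entries$sequence[i], entries$modSites[[i]],
                           series = c("b", "y"), maxCharge = 1L)
      sig <- ions$mz
      inten <- if (spec$intensityModel == "rank")
        100 / seq_along(sig) else rep(100, length(sig))
      for (r in seq_len(spec$spectraPerPeptide)) {
        scan <- scan + 1L
        noise <- numeric(0)
        lo <- max(min(sig) - 50, 1); hi <- max(sig) + 50
        while (length(noise) < spec$noisePeaks) {
          cand <- stats::runif(spec$noisePeaks, lo, hi)
          ok <- vapply(cand, function(x) all(abs(x - sig) > 2 * deltaF), TRUE)
          noise <- c(noise, cand[ok])
        }
        noise <- noise[seq_len(spec$noisePeaks)]
        nInt <- if (spec$noisePeaks)
          stats::runif(spec$noisePeaks, 1, 40) else numeric(0)
        pk <- cbind(c(sig, noise), c(inten, nInt))
        pk <- pk[order(pk[, 1]), , drop = FALSE]
        z <- if (spec$chargeRange[1] == spec$chargeRange[2])
          spec$chargeRange[1] else
          sample(spec$chargeRange[1]:spec$chargeRange[2], 1L)
        neutral <- entries$neutralMass[i] + precursorShift
        spectra[[scan]] <- spectrum(
          scan, precursorMz = (neutral + z * .PROTON) / z, charge = z,
          peaks = pk, neutralMass = neutral)
        truth[[scan]] <- data.frame(
          scanId = scan, sequence = entries$sequence[i],
          mods = entries$mods[i], neutralMass = neutral,
          shift = precursorShift, stringsAsFactors = FALSE)
      }
    }
    list(spectra = spectra, truth = do.call(rbind, truth))
  })
  if (!is.null(path)) writeMS2(gen$spectra, path)
  list(spectra = gen$spectra, truth = gen$truth, path = path)
}

#' Emit a complete synthetic dataset to a directory
#'
#' FASTA, MS2 and a truth TSV, all seeded; convenience wrapper used by the
#' command-line `fixtures` subcommand.
#'
#' @param dir output directory (created if needed).
#' @param spec a [fixtureSpec()].
#' @param digest a [digestParams()] used to pick the generating peptides.
#' @param precursorShift optional open-search mass shift (Da).
#' @return Named list of written paths plus the truth table.
#' @export
generateFixtureSet <- function(dir, spec = fixtureSpec(),
                               digest = digestParams(),
                               precursorShift = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- generateFasta(spec, file.path(dir, "proteins.fasta"))
  entries <- digestProteins(fa$proteins, digest)
  sp <- generateSpectra(entries, spec, precursorShift = precursorShift,
                        path = file.path(dir, "spectra.ms2"))
  truthPath <- file.path(dir, "truth.tsv")
  utils::write.table(sp$truth, truthPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fasta = fa$path, ms2 = sp$path, truth = truthPath,
       truthTable = sp$truth, entries = entries)
}
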