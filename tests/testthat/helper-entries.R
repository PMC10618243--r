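# Build a peptide-form entries table (as digestProteins would emit) from
# bare sequences, optionally with explicit modification-site matrices.
makeEntries <- function(sequences, modSites = NULL) {
  if (is.null(modSites))
    modSites <- rep(list(matrix(numeric(0), ncol = 2)), length(sequences))
  mass <- vapply(seq_along(sequences), function(i)
    peptideNeutralMass(sequences[i], modSites[[i]]), 0)
  out <- data.frame(sequence = sequences,
                    mods = vapply(modSites, function(m)
                      if (nrow(m)) paste(sprintf("%d%+0.5f", m[, 1] + 1, m[, 2]),
                                         collapse = ";") else "",
                      ""),
                    nMods = vapply(modSites, nrow, 0L),
                    neutralMass = mass, stringsAsFactors = FALSE)
  out$modSites <- modSites
  out
}

randomPeptide <- function(len) {
  paste(sample(names(massTable()$residue_mass), len, replace = TRUE),
        collapse = "")
}

# Random entries table of n peptide forms, lengths 6..12.
randomEntries <- function(n, lenRange = c(6L, 12L)) {
  makeEntries(vapply(seq_len(n), function(i)
    randomPeptide(sample(lenRange[1]:lenRange[2], 1L)), ""))
}

# A preprocessed query spectrum with given peaks (already normalized units).
makeQuery <- function(scan, nmass, peaks, charge = 2L, k = 1000L) {
  methods::new("PreprocessedSpectrum", scanId = as.integer(scan),
               precursorMz = (nmass + charge * 1.00728) / charge,
               charge = as.integer(charge), neutralMass = nmass,
               peaks = matrix(peaks, ncol = 2,
                              dimnames = list(NULL, c("mz", "intensity"))),
               k = as.integer(k), normalization = "identity",
               excluded = FALSE, exclusionReason = "")
}

# Random query: a spectrum seeded with some of a random entry's ions plus
# random peaks, precursor near (or shifted from) that entry's mass.
randomQuery <- function(scan, entries, shift = 0) {
  i <- sample(nrow(entries), 1L)
  ions <- generateIons(entries$sequence[i], entries$modSites[[i]],
                       maxCharge = 1L)
  keep <- sample(nrow(ions), max(2L, rbinom(1, nrow(ions), 0.7)))
  mz <- c(ions$mz[keep] + runif(length(keep), -0.008, 0.008),
          runif(sample(0:10, 1L), 150, 1500))
  pk <- cbind(mz, runif(length(mz), 1, 100))
  pk <- pk[order(pk[, 1]), , drop = FALSE]
  makeQuery(scan, entries$neutralMass[i] + shift + runif(1, -0.3, 0.3), pk)
}
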