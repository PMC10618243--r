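#' Digestion parameters
#'
#' Settings for in-silico enzymatic digestion. Defaults follow common
#' tryptic search practice: up to 2 missed cleavages, peptide lengths 6-46
#' residues, peptide masses 500-5000 Da. The length filter applies to the
#' unmodified sequence; the mass filter is applied downstream to each
#' modified form.
#'
#' @param enzyme cleavage rule identifier; only `"trypsin"` is implemented
#'   (cleave C-terminal to K/R).
#' @param maxMissedCleavages maximum internal cleavage sites retained.
#' @param minLen,maxLen peptide length bounds (residues).
#' @param minMass,maxMass peptide neutral-mass bounds (Da), applied to
#'   modified forms.
#' @param prolineRule suppress cleavage when the following residue is
#'   proline (default TRUE).
#' @return A validated list of class `DigestParams`.
#' @export
digestParams <- function(enzyme = "trypsin", maxMissedCleavages = 2L,
                         minLen = 6L, maxLen = 46L,
                         minMass = 500, maxMass = 5000,
                         prolineRule = TRUE) {
  if (!identical(enzyme, "trypsin"))
    stop("only the trypsin rule is implemented")
  if (maxMissedCleavages < 0) stop("'maxMissedCleavages' must be >= 0")
  if (minLen > maxLen) stop("'minLen' must be <= 'maxLen'")
  if (minMass > maxMass) stop("'minMass' must be <= 'maxMass'")
  structure(list(enzyme = enzyme,
                 maxMissedCleavages = as.integer(maxMissedCleavages),
                 minLen = as.integer(minLen), maxLen = as.integer(maxLen),
                 minMass = minMass, maxMass = maxMass,
                 prolineRule = prolineRule),
            class = "DigestParams")
}

#' In-silico tryptic digestion of one protein
#'
#' Cleaves C-terminal to K/R (optionally suppressed before proline) and
#' enumerates every peptide with at most `maxMissedCleavages` retained
#' internal sites, filtered by the length bounds. Offsets are 0-based and
#' peptide intervals are half-open on the protein.
#'
#' @param sequence protein residue string.
#' @param params a [digestParams()] object.
#' @return `data.frame` with columns `peptide`, `start` (0-based offset),
#'   `missed`, ordered by start then length.
#' @examples
#' digestProtein("AAKGGRCC", digestParams(maxMissedCleavages = 0, minLen = 1))
#' @export
digestProtein <- function(sequence, params = digestParams()) {
  if (!nzchar(sequence)) stop("empty protein sequence")
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(res %in% names(massTable()$residue_mass))) {
    bad <- unique(res[!res %in% names(massTable()$residue_mass)])
    stop(sprintf("invalid residue(s) in protein: %s", paste(bad, collapse = ", ")))
  }
  n <- length(res)
  # cleavage points: after position i (1-based) when res[i] in K/R,
  # unless proline follows and the rule is on; protein ends are boundaries
  cut <- which(res %in% c("K", "R"))
  if (params$prolineRule)
    cut <- cut[!(cut < n & res[cut + 1L] == "P")]
  cut <- cut[cut < n]
  bounds <- c(0L, cut, n)                      # half-open segment boundaries
  nseg <- length(bounds) - 1L
  out <- vector("list", nseg)
  for (i in seq_len(nseg)) {
    jmax <- min(nseg, i + params$maxMissedCleavages)
    for (j in i:jmax) {
      len <- bounds[j + 1L] - bounds[i]
      if (len >= params$minLen && len <= params$maxLen) {
        out[[i]] <- rbind(out[[i]], data.frame(
          peptide = substr(sequence, bounds[i] + 1L, bounds[j + 1L]),
          start = bounds[i], missed = j - i,
          stringsAsFactors = FALSE))
      }
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(peptide = character(), start = integer(),
                      missed = integer(), stringsAsFactors = FALSE))
  out <- out[order(out$start, nchar(out$peptide)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read protein sequences from FASTA
#'
#' Multi-record FASTA via Biostrings; '*' stop codons are stripped, any other
#' non-residue character is rejected with the record name.
#'
#' @param path FASTA file path.
#' @return Named character vector of protein sequences.
#' @export
readFasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- gsub("*", "", as.character(aa), fixed = TRUE)
  ok <- names(massTable()$residue_mass)
  for (i in seq_along(seqs)) {
    res <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    if (!all(res %in% ok))
      stop(sprintf("record '%s': invalid residue(s) %s", names(seqs)[i],
                   paste(unique(res[!res %in% ok]), collapse = ", ")))
  }
  seqs
}

# all site subsets of total size <= maxVar, at most one mod per site;
# returns list of integer vectors of row indexes into the site table
.siteSubsets <- function(nsites, maxVar) {
  subs <- list(integer(0))
  if (nsites == 0L || maxVar == 0L) return(subs)
  for (k in seq_len(min(nsites, maxVar))) {
    cmb <- utils::combn(nsites, k)
    subs <- c(subs, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  subs
}

#' Enumerate fixed/variable modification forms of a peptide
#'
#' Fixed modifications are applied to every occurrence of their targets.
#' Variable forms are all site subsets of total size `<= maxVarMods`, at most
#' one variable modification per site; site positions occupied by a fixed
#' modification are not eligible. Forms come out in canonical order: the
#' fixed-only form first, then ascending site tuples. Each form's neutral
#' mass is computed and the `minMass`/`maxMass` filter (if `params` given)
#' applies to the modified mass.
#'
#' @param peptide peptide residue string.
#' @param fixedMods,variableMods lists of [Modification] objects.
#' @param maxVarMods cap on variable modifications per peptide (default 5).
#' @param params optional [digestParams()] supplying the mass window.
#' @return `data.frame` with columns `sequence`, `mods` (compact text like
#'   `"C2+57.02146;M3+15.99491"`, 1-based display positions), `nMods`,
#'   `neutralMass`, plus list column `modSites` of (0-based position, delta)
#'   matrices.
#' @examples
#' bm <- builtinModifications()
#' enumerateModforms("ACM", list(bm$carbamidomethyl), list(bm$oxidation))
#' @export
enumerateModforms <- function(peptide, fixedMods = list(),
                              variableMods = list(), maxVarMods = 5L,
                              params = NULL) {
  if (maxVarMods < 0) stop("'maxVarMods' must be >= 0")
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  n <- length(res)
  fixed <- NULL                               # (pos0, delta) rows
  for (m in fixedMods) {
    hit <- which(res %in% modTargets(m)) - 1L
    if (length(hit)) fixed <- rbind(fixed, cbind(hit, deltaMass(m)))
  }
  fixedPos <- if (is.null(fixed)) integer(0) else fixed[, 1]
  # variable site table: one row per (position, mod)
  sites <- NULL
  for (m in variableMods) {
    hit <- which(res %in% modTargets(m)) - 1L
    hit <- setdiff(hit, fixedPos)
    if (length(hit)) sites <- rbind(sites, data.frame(
      pos = hit, delta = deltaMass(m), name = modName(m),
      stringsAsFactors = FALSE))
  }
  if (!is.null(sites)) {
    sites <- sites[order(sites$pos, sites$name), , drop = FALSE]
    # at most one variable mod per site within a subset is enforced below
  }
  nsites <- if (is.null(sites)) 0L else nrow(sites)
  subs <- .siteSubsets(nsites, as.integer(maxVarMods))
  if (nsites > 0L)  # drop subsets placing two mods on one site
    subs <- Filter(function(s) !anyDuplicated(sites$pos[s]), subs)
  # canonical order: fixed-only first, then ascending (size-lex) site tuples
  keys <- vapply(subs, function(s)
    paste(sprintf("%06d", c(length(s), sites$pos[s])), collapse = ","), "")
  subs <- subs[order(keys)]

  rows <- lapply(subs, function(s) {
    ms <- fixed
    if (length(s)) ms <- rbind(ms, cbind(sites$pos[s], sites$delta[s]))
    if (!is.null(ms)) ms <- ms[order(ms[, 1]), , drop = FALSE]
    mass <- peptideNeutralMass(peptide, ms)
    lab <- if (is.null(ms) || nrow(ms) == 0L) "" else
      paste(sprintf("%s%d%+0.5f", res[ms[, 1] + 1L], ms[, 1] + 1L, ms[, 2]),
            collapse = ";")
    list(mods = lab, nMods = length(s), neutralMass = mass,
         modSites = if (is.null(ms)) matrix(numeric(0), ncol = 2) else
           unname(ms))
  })
  out <- data.frame(
    sequence = rep(peptide, length(rows)),
    mods = vapply(rows, `[[`, "", "mods"),
    nMods = vapply(rows, `[[`, 0L, "nMods"),
    neutralMass = vapply(rows, `[[`, 0, "neutralMass"),
    stringsAsFactors = FALSE)
  out$modSites <- lapply(rows, `[[`, "modSites")
  if (!is.null(params))
    out <- out[out$neutralMass >= params$minMass &
               out$neutralMass <= params$maxMass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Digest a protein set into modified peptide entries
#'
#' Full digestion of every protein, modification-form enumeration, and
#' deduplication by (sequence, modification set) keeping the first parent
#' protein; the full parent list is retained for reporting.
#'
#' @param proteins named character vector of protein sequences.
#' @param params a [digestParams()].
#' @param fixedMods,variableMods lists of [Modification] objects.
#' @param maxVarMods variable-modification cap per peptide.
#' @return `data.frame` of peptide-form precursors (columns as in
#'   [enumerateModforms()] plus `protein` and `proteins`).
#' @export
digestProteins <- function(proteins, params = digestParams(),
                           fixedMods = list(), variableMods = list(),
                           maxVarMods = 5L) {
  peps <- list()
  for (pn in names(proteins)) {
    d <- digestProtein(proteins[[pn]], params)
    if (nrow(d)) peps[[pn]] <- data.frame(peptide = d$peptide, protein = pn,
                                          stringsAsFactors = FALSE)
  }
  peps <- do.call(rbind, peps)
  if (is.null(peps)) stop("digestion produced no peptides")
  parents <- split(peps$protein, peps$peptide)
  uniq <- peps[!duplicated(peps$peptide), , drop = FALSE]
  forms <- lapply(seq_len(nrow(uniq)), function(i) {
    f <- enumerateModforms(uniq$peptide[i], fixedMods, variableMods,
                           maxVarMods, params)
    if (nrow(f)) {
      f$protein <- uniq$protein[i]
      f$proteins <- paste(unique(parents[[uniq$peptide[i]]]), collapse = ",")
    }
    f
  })
  out <- do.call(rbind, forms[vapply(forms, nrow, 0L) > 0])
  if (is.null(out) || nrow(out) == 0L) stop("no peptide forms within bounds")
  rownames(out) <- NULL
  out
}
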