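# Independent brute-force oracles. These deliberately avoid the package's
# index/search path: theoretical fragment masses are recomputed from plain
# residue-mass cumulative sums, candidate filtering is a linear scan, and
# scoring loops over all (peak, fragment) pairs.

.oracleMT <- massTable()

# b/y fragment m/z values of one peptide form, computed from scratch
oracleIons <- function(sequence, modSites, maxCharge) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  site <- unname(.oracleMT$residue_mass[res])
  if (nrow(modSites)) site[modSites[, 1] + 1] <- site[modSites[, 1] + 1] + modSites[, 2]
  n <- length(site)
  rows <- list()
  for (s in c("b", "y")) {
    for (k in 1:(n - 1)) {
      neutral <- if (s == "b") sum(site[1:k]) else
        sum(site[(n - k + 1):n]) + .oracleMT$water_mass
      for (z in 1:maxCharge)
        rows[[length(rows) + 1]] <- data.frame(
          mz = (neutral + z * .oracleMT$proton_mass) / z, series = s,
          stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# all-pairs search of one query against an entries table; mirrors the
# documented scoring conventions but none of the index machinery
oracleSearch <- function(q, entries, deltaM, deltaF, minShared = 4L,
                         maxCharge = 3L, lft = buildLogFactorialTable()) {
  ord <- order(entries$neutralMass, method = "radix")
  mass <- entries$neutralMass[ord]          # peptideId = position - 1
  pk <- peaks(q)
  base <- 10
  scores <- list()
  for (id in seq_along(mass) - 1L) {
    if (abs(mass[id + 1] - neutralMass(q)) > deltaM) next
    e <- entries[ord[id + 1], , drop = FALSE]
    frag <- oracleIons(e$sequence, e$modSites[[1]], maxCharge)
    nb <- 0L; ny <- 0L; sib <- 0; siy <- 0
    for (p in seq_len(nrow(pk))) {
      hit <- abs(frag$mz - pk[p, 1]) <= deltaF
      cb <- sum(hit & frag$series == "b"); cy <- sum(hit & frag$series == "y")
      nb <- nb + cb; ny <- ny + cy
      sib <- sib + cb * pk[p, 2]; siy <- siy + cy * pk[p, 2]
    }
    if (nb + ny >= minShared) {
      h <- sum(log(seq_len(nb), base = base)) +
        sum(log(seq_len(ny), base = base)) +
        (if (sib > 0) log(sib, base = base) else 0) +
        (if (siy > 0) log(siy, base = base) else 0)
      scores[[length(scores) + 1]] <- list(id = id, h = h, nb = nb, ny = ny)
    }
  }
  if (!length(scores))
    return(list(psm = NULL, null = integer(0), numCandidates = 0L))
  hs <- vapply(scores, `[[`, 0, "h")
  bins <- pmax(0L, as.integer(floor(hs)))
  null <- tabulate(bins + 1L, max(bins) + 1L)
  best <- scores[[which.max(hs)]]           # first max = smallest id
  list(psm = data.frame(peptideId = best$id, hyperscore = best$h,
                        nB = best$nb, nY = best$ny,
                        numCandidates = length(scores)),
       null = null, numCandidates = length(scores))
}

# linear-scan window oracle over a sorted (or unsorted) numeric vector
oracleWindow <- function(v, q, delta) which(abs(v - q) <= delta)

# exhaustive tryptic digestion by enumerating all cleavage-site subsets
oracleDigest <- function(sequence, missed, prolineRule = TRUE) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  cut <- which(res %in% c("K", "R"))
  if (prolineRule) cut <- cut[!(cut < n & res[cut + 1] == "P")]
  cut <- cut[cut < n]
  bounds <- c(0L, cut, n)
  peps <- character()
  for (i in seq_len(length(bounds) - 1)) {
    for (j in i:length(bounds[-1])) {
      if (j - i > missed) next
      peps <- c(peps, substr(sequence, bounds[i] + 1, bounds[j + 1]))
    }
  }
  sort(unique(peps))
}
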