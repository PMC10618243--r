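writeTempMS2 <- function(lines) {
  p <- tempfile(fileext = ".ms2")
  writeLines(lines, p)
  p
}

test_that("MS2 parsing derives neutral mass from Z lines", {
  p <- writeTempMS2(c(
    "H\tCreationDate test",
    "S\t1\t1\t501.01092",
    "Z\t2\t1001.00728",
    "100.0 10.0",
    "200.0 20.0"))
  sp <- readMS2(p)
  expect_length(sp, 1L)
  expect_equal(neutralMass(sp[[1]]), 1000.0, tolerance = 1e-6)
  expect_equal(precursorCharge(sp[[1]]), 2L)
  expect_equal(unname(peaks(sp[[1]])[, 1]), c(100, 200))
  # multiple Z lines -> one spectrum per charge state
  p2 <- writeTempMS2(c("S\t7\t7\t501.0", "Z\t2\t1001.00728",
                       "Z\t3\t1501.00728", "100.0 5.0"))
  sp2 <- readMS2(p2)
  expect_length(sp2, 2L)
  expect_equal(vapply(sp2, precursorCharge, 0L), c(2L, 3L))
  expect_equal(vapply(sp2, neutralMass, 0), c(1000, 1500), tolerance = 1e-6)
  # empty file, missing charge, malformed lines
  expect_length(readMS2(writeTempMS2(character(0))), 0L)
  expect_warning(readMS2(writeTempMS2(c("S\t1\t1\t500.0", "100.0 1.0"))),
                 "no Z line")
  expect_error(readMS2(writeTempMS2(c("S\t1\t1\t500.0", "Z\tx\ty"))),
               "line 2")
})

test_that("MS2 writing round-trips through the reader", {
  set.seed(23)
  sp <- lapply(1:5, function(i) {
    pk <- cbind(sort(runif(20, 100, 1500)), runif(20, 1, 100))
    spectrum(i, 500 + i, 2L, round(pk, 5))
  })
  path <- tempfile(fileext = ".ms2")
  writeMS2(sp, path, header = "test set")
  back <- readMS2(path)
  expect_length(back, 5L)
  for (i in 1:5) {
    expect_equal(scanId(back[[i]]), scanId(sp[[i]]))
    expect_equal(neutralMass(back[[i]]), neutralMass(sp[[i]]), tolerance = 1e-5)
    expect_equal(peaks(back[[i]]), peaks(sp[[i]]), tolerance = 1e-5)
  }
})

test_that("top-K extraction keeps the K most intense peaks, m/z-sorted", {
  pk <- cbind(c(100, 200, 300, 400, 500), c(5, 50, 20, 80, 1))
  s <- spectrum(1, 600, 2L, pk)
  out <- preprocessSpectrum(s, k = 3, normalization = "identity")
  expect_equal(unname(peaks(out)), cbind(c(200, 300, 400), c(50, 20, 80)))
  # oracle: sort-by-intensity
  set.seed(29)
  for (i in 1:20) {
    n <- sample(5:200, 1); k <- sample(1:150, 1)
    pk <- cbind(runif(n, 100, 2000), sample(seq_len(10 * n), n))  # distinct
    s <- spectrum(1, 600, 2L, pk)
    out <- peaks(preprocessSpectrum(s, k = k, normalization = "identity"))
    expect_equal(nrow(out), min(k, n))
    keep <- pk[order(-pk[, 2])[seq_len(min(k, n))], , drop = FALSE]
    expect_equal(out, keep[order(keep[, 1]), , drop = FALSE],
                 ignore_attr = TRUE)
    expect_false(is.unsorted(out[, 1]))
  }
})

test_that("base-peak normalization scales to 100 and is idempotent", {
  pk <- cbind(c(100, 200, 300), c(10, 40, 20))
  s <- spectrum(1, 600, 2L, pk)
  out <- preprocessSpectrum(s, k = 10)
  expect_equal(max(peaks(out)[, 2]), 100)
  expect_equal(unname(peaks(out)[, 2]), c(25, 100, 50))
  # idempotence at the same settings
  again <- preprocessSpectrum(out, k = 10)
  expect_equal(peaks(again), peaks(out))
  # fewer than K peaks: only normalized
  expect_equal(nrow(peaks(preprocessSpectrum(s, k = 10))), 3L)
})

test_that("an intensity tie at the K-th rank keeps the lower-m/z peak", {
  pk <- cbind(c(100, 150, 200), c(30, 10, 10))
  s <- spectrum(1, 600, 2L, pk)
  out <- peaks(preprocessSpectrum(s, k = 2, normalization = "identity"))
  expect_equal(unname(out[, 1]), c(100, 150))
})

test_that("out-of-bounds spectra are flagged excluded with a reason", {
  pk <- cbind(c(100, 200), c(1, 2))
  tooLight <- preprocessSpectrum(spectrum(1, 200, 2L, pk))
  expect_true(isExcluded(tooLight))
  expect_match(tooLight@exclusionReason, "mass")
  highZ <- preprocessSpectrum(spectrum(1, 300, 5L, pk))
  expect_true(isExcluded(highZ))
  expect_match(highZ@exclusionReason, "charge")
  allZero <- preprocessSpectrum(spectrum(1, 600, 2L, cbind(c(100, 200), c(0, 0))))
  expect_true(isExcluded(allZero))
  ok <- preprocessSpectrum(spectrum(1, 600, 2L, pk))
  expect_false(isExcluded(ok))
})

test_that("batch preprocessing equals the per-spectrum loop", {
  set.seed(31)
  batch <- lapply(1:100, function(i) {
    n <- sample(3:120, 1)
    spectrum(i, runif(1, 300, 2000), sample(1:5, 1),
             cbind(runif(n, 100, 2000), runif(n, 0, 1000)))
  })
  b <- preprocessBatch(batch, k = 50)
  l <- lapply(batch, preprocessSpectrum, k = 50)
  expect_equal(b, l)
  # shuffling the batch permutes but does not change per-scan results
  perm <- sample(length(batch))
  bs <- preprocessBatch(batch[perm], k = 50)
  expect_equal(bs, l[perm])
})

test_that("the dataset cache makes the second preprocessing run a no-op", {
  set.seed(37)
  sp <- lapply(1:10, function(i)
    spectrum(i, 800, 2L, cbind(runif(30, 100, 1500), runif(30, 1, 100))))
  ms2 <- tempfile(fileext = ".ms2"); writeMS2(sp, ms2)
  cache <- tempfile(); dir.create(cache)
  r1 <- preprocessFile(ms2, cache, k = 20)
  expect_false(r1$cacheHit)
  r2 <- preprocessFile(ms2, cache, k = 20)
  expect_true(r2$cacheHit)
  expect_equal(length(r2$spectra), sum(!vapply(r1$spectra, isExcluded, TRUE)))
  # changed settings invalidate the cache
  r3 <- preprocessFile(ms2, cache, k = 25)
  expect_false(r3$cacheHit)
})
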