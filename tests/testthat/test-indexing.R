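test_that("b/y ion generation matches residue-sum arithmetic", {
  g <- generateIons("AG")
  expect_equal(nrow(g), 2L)
  expect_equal(g$mz[g$series == "b"], 72.04439, tolerance = 1e-7)
  expect_equal(g$mz[g$series == "y"], 76.03930, tolerance = 1e-7)
  # count law: (len-1) * |series| * maxCharge
  p10 <- randomPeptide(10)
  expect_equal(nrow(generateIons(p10, maxCharge = 3L)), 54L)
  # charge scaling: mz(z) = (neutral + z*proton)/z
  g3 <- generateIons("PEPTIDER", maxCharge = 3L)
  b1 <- g3[g3$series == "b" & g3$k == 3, ]
  neutral <- b1$mz[b1$charge == 1] - 1.00728
  expect_equal(b1$mz[b1$charge == 2], (neutral + 2 * 1.00728) / 2)
  expect_equal(b1$mz[b1$charge == 3], (neutral + 3 * 1.00728) / 3)
  # modifications shift exactly the fragments containing the site
  gm <- generateIons("PEPTIDER", modSites = cbind(0, 79.96633))
  g0 <- generateIons("PEPTIDER")
  bshift <- gm$series == "b"
  expect_equal(gm$mz[bshift], g0$mz[bshift] + 79.96633)       # all b contain site 0
  yk <- gm$series == "y" & gm$k < 8                           # y_k, k<8 exclude site 0
  expect_equal(gm$mz[yk], g0$mz[yk])
  expect_error(generateIons("A"), "too short")
  # randomized agreement with the independent fragment oracle
  set.seed(13)
  for (i in 1:10) {
    pep <- randomPeptide(sample(6:12, 1))
    g <- generateIons(pep, maxCharge = 2L)
    o <- oracleIons(pep, matrix(numeric(0), ncol = 2), 2L)
    expect_equal(sort(g$mz), sort(o$mz), tolerance = 1e-12)
  }
})

test_that("index build sorts peptides by mass and fragments stably by m/z", {
  e <- makeEntries(c("VVVVVVVVVV", "AAAAAA", "GGGGGGGG"))
  # masses: V10 ~ 1008, A6 ~ 444, G8 ~ 474
  idx <- buildIndex(e, maxCharge = 1L)
  p <- peptides(idx)
  expect_equal(p$peptideId, 0:2)
  expect_equal(p$sequence, c("AAAAAA", "GGGGGGGG", "VVVVVVVVVV"))
  expect_false(is.unsorted(p$neutralMass))
  f <- fragments(idx)
  expect_false(is.unsorted(f$mz))
  expect_equal(nrow(f), sum((nchar(e$sequence) - 1) * 2))
  # single peptide: 2 * maxCharge * (len-1) fragments
  i1 <- buildIndex(makeEntries("AG"), maxCharge = 2L)
  expect_equal(nrow(fragments(i1)), 4L)
})

test_that("equal-m/z fragments from one peptide stay adjacent (stable sort)", {
  # two copies of the same peptide share every fragment m/z; stability keeps
  # generation order, so entries alternate by series/k but each m/z group
  # lists peptide 0's entry before peptide 1's
  e <- makeEntries(c("AGAR", "AGAR"))
  idx <- buildIndex(e, maxCharge = 1L)
  f <- fragments(idx)
  grp <- split(f$peptideId, format(f$mz, digits = 12))
  for (g in grp) expect_equal(g, sort(g))
  # determinism: two builds are element-wise identical
  idx2 <- buildIndex(e, maxCharge = 1L)
  expect_identical(fragments(idx), fragments(idx2))
  expect_identical(peptides(idx), peptides(idx2))
})

test_that("window queries agree with a linear scan", {
  masses <- c(500, 999, 1000, 1001, 1500)
  idx <- buildIndex(makeEntries(rep("AG", 5)))
  idx@peptides$neutralMass <- masses           # direct fixture for the query
  expect_equal(precursorWindow(idx, 1000, 1), c(1L, 4L))
  expect_equal(precursorWindow(idx, 2000, 1), c(5L, 5L))
  expect_equal(precursorWindow(idx, 1500, 0), c(4L, 5L))

  # fragment windows on a hand fixture
  idx@fragments <- data.frame(mz = c(100.005, 100.012, 100.030),
                              series = "b", charge = 1L, k = 1L,
                              peptideId = 0L)
  expect_equal(fragmentWindow(idx, 100.010, 0.01), c(1L, 3L))
  expect_equal(fragmentWindow(idx, 100.030, 0), c(3L, 4L))
  expect_equal(fragmentWindow(idx, 200, 0.01), c(4L, 4L))

  # randomized property: both windows match the O(n) oracle
  set.seed(17)
  for (i in 1:25) {
    e <- randomEntries(sample(5:40, 1))
    ix <- buildIndex(e, maxCharge = sample(1:3, 1))
    for (j in 1:40) {
      q <- runif(1, 300, 1600); d <- sample(c(0, 0.01, 0.5, 1, 10), 1)
      w <- precursorWindow(ix, q, d)
      hits <- oracleWindow(peptides(ix)$neutralMass, q, d)
      rows <- if (w[2] > w[1]) (w[1]:(w[2] - 1)) + 1L else integer(0)
      expect_equal(rows, hits)
      fw <- fragmentWindow(ix, q, d)
      fh <- oracleWindow(fragments(ix)$mz, q, d)
      expect_equal(if (fw[2] > fw[1]) fw[1]:(fw[2] - 1) else integer(0), fh)
    }
  }
})

test_that("every generated fragment is found by a zero-tolerance window", {
  set.seed(19)
  e <- randomEntries(10)
  idx <- buildIndex(e, maxCharge = 2L)
  f <- fragments(idx)
  for (r in sample(nrow(f), 50)) {
    w <- fragmentWindow(idx, f$mz[r], 0)
    expect_true(w[1] <= r && r < w[2])
  }
})

test_that("index serialization round-trips and validates its header", {
  e <- randomEntries(8)
  idx <- buildIndex(e, maxCharge = 2L)
  path <- tempfile(fileext = ".idx")
  saveIndex(idx, path)
  back <- loadIndex(path, expectedParams = indexParams(idx))
  expect_identical(peptides(back), peptides(idx))
  expect_identical(fragments(back), fragments(idx))
  expect_error(loadIndex(path, expectedParams = list(series = "b", maxCharge = 1L)),
               "parameters")
  bad <- tempfile(); saveRDS(list(magic = "nope"), bad)
  expect_error(loadIndex(bad), "not a fragment-ion index")
  expect_error(buildIndex(makeEntries(character(0))), "empty")
})
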