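test_that("column classification follows pairwise-deletion rules", {
  s <- classifyColumns("ACGT", "ACGT")
  expect_equal(s@comparedSites, 4L)
  expect_equal(s@transitions + s@transversions, 0L)

  s <- classifyColumns("ACGT", "GCGT")          # A<->G
  expect_equal(s@transitions, 1L)
  expect_equal(s@transversions, 0L)

  s <- classifyColumns("AC-GT", "ACCGT")
  expect_equal(s@comparedSites, 4L)
  expect_equal(s@indelColumns, 1L)
  expect_equal(s@indelEvents, 1L)

  # N excluded from all counts, tallied as ambiguous; gap-gap ignored
  s <- classifyColumns("ANG-T", "AAG-T")
  expect_equal(s@comparedSites, 3L)
  expect_equal(s@ambiguousColumns, 1L)
  expect_equal(s@indelColumns, 0L)

  # totals invariant to swapping rows
  a <- "ACGTAC--GTNNACGTTTAC"
  b <- "ACGAACTTGT--ACGNTTGC"
  s1 <- classifyColumns(a, b); s2 <- classifyColumns(b, a)
  for (sl in c("comparedSites", "transitions", "transversions",
               "indelColumns", "indelEvents", "ambiguousColumns"))
    expect_equal(methods::slot(s1, sl), methods::slot(s2, sl), info = sl)
})

test_that("K2P matches the closed form and flags undefined cases", {
  expect_equal(k2pDistance(list(L = 100L, nP = 0L, nQ = 0L)), 0)
  expect_equal(k2pDistance(list(L = 100L, nP = 10L, nQ = 0L)),
               -0.5 * log(0.8), tolerance = 1e-12)
  u <- k2pDistance(list(L = 0L, nP = 0L, nQ = 0L))
  expect_true(is.na(u))
  expect_match(attr(u, "reason"), "no comparable sites")
  sat <- k2pDistance(list(L = 10L, nP = 6L, nQ = 0L))   # 1-2P-Q <= 0
  expect_true(is.na(sat))
  expect_match(attr(sat, "reason"), "saturated")
})

test_that("K2P agrees with an independent evaluation over a (P,Q) grid", {
  # independent route: log1p-based evaluation of the same closed form
  for (P in seq(0, 0.4, by = 0.04)) for (Q in seq(0, 0.3, by = 0.03)) {
    if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) next
    L <- 1000L
    ref <- -0.5 * (log1p(-2 * P - Q) + 0.5 * log1p(-2 * Q))
    got <- k2pDistance(list(L = L, nP = as.integer(P * L),
                            nQ = as.integer(Q * L)))
    expect_equal(got, ref, tolerance = 1e-9,
                 info = sprintf("P=%.2f Q=%.2f", P, Q))
    # K2P >= p-distance, equality only at zero
    expect_true(got >= P + Q - 1e-12)
    if (P + Q > 0) expect_gt(got, P + Q - 1e-9 + 0)
  }
})

test_that("K2P agrees with ape's K80 distance on sequence pairs", {
  set.seed(9)
  for (k in 1:5) {
    a <- randomDnaString(300)
    v <- strsplit(a, "")[[1L]]
    pos <- sample(300, 12)
    ts <- c(A = "G", G = "A", C = "T", T = "C")
    v[pos] <- ifelse(runif(12) < 0.7, ts[v[pos]],
                     sample(c("A", "C", "G", "T"), 12, replace = TRUE))
    b <- paste(v, collapse = "")
    m <- do.call(rbind, strsplit(c(a = a, b = b), ""))
    db <- ape::dist.dna(ape::as.DNAbin(matrix(tolower(m), nrow = 2,
                                              dimnames = list(c("a", "b")))),
                        model = "K80", pairwise.deletion = TRUE)
    expect_equal(as.numeric(k2pDistance(classifyColumns(a, b))),
                 as.numeric(db), tolerance = 1e-12)
  }
})

test_that("difference counts distinguish events from columns", {
  expect_equal(differenceCount("ACGT", "ACGT"), 0L)
  a <- "ACGTTTACG"
  b <- "AGGT---CG"   # 1 substitution (C->G transversion is col 2) + 3-col gap
  expect_equal(differenceCount(a, b, mode = "columns"), 4L)
  expect_equal(differenceCount(a, b, mode = "events"), 2L)
  # 10 substitutions count 10 in both modes
  x <- strsplit("ACGTACGTACGTACGTACGT", "")[[1L]]
  y <- x; y[seq(1, 20, by = 2)] <- c("G", "A", "T", "C", "G", "A", "T", "C",
                                     "G", "A")
  expect_equal(differenceCount(paste(x, collapse = ""),
                               paste(y, collapse = ""), "columns"), 10L)
  expect_equal(differenceCount(paste(x, collapse = ""),
                               paste(y, collapse = ""), "events"), 10L)
})

test_that("distance matrices are consistent with per-pair recomputation", {
  set.seed(21)
  base <- randomDnaString(200)
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1L]]
    p <- sample(length(v), k)
    v[p] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    paste(v, collapse = "")
  }
  rows <- c(r1 = base, r2 = mut(base, 6), r3 = mut(base, 15), r4 = base)
  aln <- methods::new("HaploAlignment",
                      seqs = Biostrings::DNAStringSet(rows),
                      provenance = "test")
  d <- k2pMatrix(aln)
  expect_equal(distValues(d)["r1", "r4"], 0)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(distValues(d)[i, j],
                 as.numeric(k2pDistance(classifyColumns(rows[i], rows[j]))),
                 tolerance = 1e-12)
  }
  expect_identical(distValues(d), t(distValues(d)))
  # permutation equivariance
  perm <- c(3, 1, 4, 2)
  aln2 <- methods::new("HaploAlignment",
                       seqs = Biostrings::DNAStringSet(rows[perm]),
                       provenance = "test")
  d2 <- k2pMatrix(aln2)
  expect_equal(distValues(d2)[names(rows), names(rows)], distValues(d))
})

test_that("mean distance with bootstrap SE is seeded and degenerates to 0", {
  rows <- c(a = "ACGTACGTGT", b = "ACGTACGTGT", c = "ACGTACGTGT")
  aln <- methods::new("HaploAlignment",
                      seqs = Biostrings::DNAStringSet(rows),
                      provenance = "test")
  r <- meanDistanceWithSE(aln, B = 100L, seed = 4L)
  expect_equal(r$mean, 0)
  expect_equal(r$se, 0)
  set.seed(77)
  base <- randomDnaString(400)
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1L]]; p <- sample(length(v), k)
    v[p] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    paste(v, collapse = "")
  }
  trio <- c(x = base, y = mut(base, 8), z = mut(base, 10))
  aln2 <- methods::new("HaploAlignment",
                       seqs = Biostrings::DNAStringSet(trio),
                       provenance = "test")
  r1 <- meanDistanceWithSE(aln2, B = 300L, seed = 10L)
  r2 <- meanDistanceWithSE(aln2, B = 300L, seed = 10L)
  expect_identical(r1, r2)
  expect_gt(r1$se, 0)
})

test_that("bootstrap SE is stable across seeds (CV < 15% at B = 1000)", {
  set.seed(123)
  base <- randomDnaString(500)
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1L]]; p <- sample(length(v), k)
    ts <- c(A = "G", G = "A", C = "T", T = "C")
    v[p] <- ts[v[p]]
    paste(v, collapse = "")
  }
  trio <- c(x = base, y = mut(base, 10), z = mut(base, 14))
  aln <- methods::new("HaploAlignment",
                      seqs = Biostrings::DNAStringSet(trio),
                      provenance = "test")
  ses <- vapply(1:6, function(s)
    meanDistanceWithSE(aln, B = 1000L, seed = s)$se, numeric(1))
  expect_lt(stats::sd(ses) / mean(ses), 0.15)
})
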