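test_that("an empty template pool leaves only the genuine sequence", {
  cfg <- simConfig("coding", nHeteroplasmic = 0L, nNumtLoci = 0L, seed = 1L)
  tt <- generateTruth(cfg)
  expect_equal(length(truthTemplates(tt)), 1L)
  expect_equal(truthClasses(tt), "genuine")
  expect_equal(truthWeights(tt), 1)
})

test_that("the genuine coding template carries no internal stop in frame 0", {
  for (s in 1:5) {
    tt <- generateTruth(simConfig("coding", seed = s))
    g <- as.character(truthTemplates(tt))[["genuine"]]
    expect_equal(countStops(g, frame = 0L), 0L, info = paste("seed", s))
  }
})

test_that("heteroplasmic templates sit 3-10 substitutions from the genuine", {
  for (s in 1:5) {
    tt <- generateTruth(simConfig("coding", seed = s))
    tpl <- as.character(truthTemplates(tt))
    for (nm in names(tpl)[truthClasses(tt) == "heteroplasmic"]) {
      d <- differenceCount(tpl[["genuine"]], tpl[[nm]])
      expect_true(d >= 3L && d <= 10L, info = paste(s, nm, d))
    }
  }
})

test_that("NUMT realized K2P tracks the drawn target divergence", {
  devs <- c()
  k <- 0L
  for (s in 1:14) {
    cfg <- simConfig("coding", seed = s, numtIndelRate = 0,
                     numtDivergenceRange = c(0.07, 0.24))
    tt <- generateTruth(cfg)
    tpl <- as.character(truthTemplates(tt))
    mc <- S4Vectors::mcols(truthTemplates(tt))
    for (nm in names(tpl)[truthClasses(tt) == "numt"]) {
      al <- pairwiseAlign(tpl[["genuine"]], tpl[[nm]])
      rows <- as.character(alnSeqs(al$alignment))
      kk <- k2pDistance(classifyColumns(rows[1L], rows[2L]))
      devs <- c(devs, as.numeric(kk) - mc$targetDivergence[match(nm, names(tpl))])
      k <- k + 1L
    }
  }
  expect_gte(k, 40L)
  expect_lt(abs(mean(devs)), 0.02)
})

test_that("coding NUMTs at high divergence are disrupted or flagged", {
  for (s in 1:4) {
    cfg <- simConfig("coding", seed = s,
                     numtDivergenceRange = c(0.12, 0.24))
    tt <- generateTruth(cfg)
    tpl <- as.character(truthTemplates(tt))
    mc <- S4Vectors::mcols(truthTemplates(tt))
    for (i in which(truthClasses(tt) == "numt")) {
      if (mc$flaggedClean[i]) next
      nm <- names(tpl)[i]
      disrupted <- countStops(tpl[[nm]], frame = 0L) > 0L ||
        nchar(tpl[[nm]]) %% 3L != nchar(tpl[["genuine"]]) %% 3L ||
        length(tt@ledger[[nm]]) > 0L &&
          any(vapply(tt@ledger[[nm]], function(op)
            op$type %in% c("ins", "del") &&
              (if (op$type == "ins") nchar(op$seq) else op$len) %% 3L != 0L,
            logical(1)))
      expect_true(disrupted, info = paste(s, nm))
    }
  }
})

test_that("mutation ledgers replay to the exact template sequences", {
  for (s in c(2, 9)) {
    tt <- generateTruth(simConfig("coding", seed = s))
    tpl <- as.character(truthTemplates(tt))
    for (nm in names(tpl)) {
      expect_identical(applyMutationLedger(tpl[["genuine"]], tt@ledger[[nm]]),
                       tpl[[nm]], info = paste(s, nm))
    }
  }
})

test_that("error-free amplification reproduces the templates verbatim", {
  cfg <- simConfig("coding", taqErrorRate = 0, seed = 6L)
  tt <- generateTruth(cfg)
  lib <- simulatePcrLibrary(tt)
  tpl <- as.character(truthTemplates(tt))
  for (i in seq_along(lib$clones)) {
    expect_identical(unname(as.character(lib$clones)[i]),
                     unname(tpl[[lib$provenance$template[i]]]))
  }
  expect_true(all(lib$provenance$errorCount == 0L))
})

test_that("binomial-model error burden matches the analytic expectation", {
  cfg <- simConfig("coding", amplificationModel = "binomial",
                   nClones = 10000L, nHeteroplasmic = 0L, nNumtLoci = 0L,
                   seed = 8L)
  tt <- generateTruth(cfg)
  lib <- simulatePcrLibrary(tt)
  expected <- 807 * 1e-4 * 35 / 2           # L * mu * E[depth]
  got <- mean(lib$provenance$errorCount)
  expect_lt(abs(got - expected) / expected, 0.05)
})

test_that("genealogy and binomial models agree at efficiency 1", {
  base <- simConfig("coding", nClones = 2000L, nHeteroplasmic = 0L,
                    nNumtLoci = 0L, seed = 12L, efficiency = 1)
  tt <- generateTruth(base)
  mG <- mean(simulatePcrLibrary(tt, base)$provenance$errorCount)
  cfgB <- simConfig("coding", nClones = 2000L, nHeteroplasmic = 0L,
                    nNumtLoci = 0L, seed = 12L,
                    amplificationModel = "binomial")
  mB <- mean(simulatePcrLibrary(tt, cfgB)$provenance$errorCount)
  expect_lt(abs(mG - mB) / mB, 0.15)
})

test_that("the modal clone haplotype is the genuine template", {
  for (s in c(3, 21, 33)) {
    sim <- simulatedRegion(seed = s)
    txt <- as.character(sim$lib$clones)
    modal <- names(sort(table(txt), decreasing = TRUE))[1L]
    expect_identical(modal,
                     as.character(truthTemplates(sim$truth))[["genuine"]],
                     info = paste("seed", s))
  }
})

test_that("fixtures are deterministic and complete", {
  cfg <- simConfig("coding", seed = 5L)
  tt <- generateTruth(cfg)
  lib <- simulatePcrLibrary(tt)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- emitFixture(tt, lib, d1)
  tt2 <- generateTruth(simConfig("coding", seed = 5L))
  lib2 <- simulatePcrLibrary(tt2)
  p2 <- emitFixture(tt2, lib2, d2)
  for (nm in names(p1))
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]), info = nm)
  truthTab <- utils::read.delim(p1[["truth"]])
  expect_equal(nrow(truthTab), cfg@nClones)
  # the fixture feeds the pipeline unchanged
  res <- runRegion(p1[["clones"]], direct = p1[["direct"]], region = "COI",
                   B = 100L, seed = 1L)
  expect_equal(nrow(cloneTable(res$report)), cfg@nClones)
})

test_that("simulator configs can be read from key:value files", {
  tmp <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("regionKind: noncoding", "nClones: 12", "seed: 9",
               "heteroplasmyDiffRange: [4, 6]"), tmp)
  cfg <- simConfigFromFile(tmp)
  expect_equal(cfg@regionKind, "noncoding")
  expect_equal(cfg@nClones, 12L)
  expect_equal(cfg@heteroplasmyDiffRange, c(4L, 6L))
  writeLines("bogusKey: 1", tmp)
  expect_error(simConfigFromFile(tmp), "unknown simulator config key")
})

test_that("infeasible template weights are rejected", {
  expect_error(simConfig("coding", nNumtLoci = 30L, numtWeight = 0.05),
               "weights exceed 1")
})
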