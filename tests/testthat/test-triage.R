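.mkAln <- function(rows)
  methods::new("HaploAlignment", seqs = Biostrings::DNAStringSet(rows),
               provenance = "test")

.mut <- function(s, pos, to) {
  v <- strsplit(s, "")[[1L]]
  v[pos] <- to
  paste(v, collapse = "")
}

test_that("genuine determination follows the direct-match rule", {
  set.seed(14)
  g <- randomDnaString(60)
  rows <- c(direct = g, c1 = g, c2 = g, c3 = .mut(g, 5, "N"),
            c4 = .mut(g, c(2, 9), c("T", "T")))
  rows["c3"] <- g                      # three identical to direct
  rows["c4"] <- .mut(g, 2, if (substr(g, 2, 2) == "A") "G" else "A")
  aln <- .mkAln(rows)
  r <- identifyGenuine(aln, paste0("c", 1:4), directId = "direct")
  expect_equal(r$status, "ok")
  expect_setequal(r$supportIds, c("c1", "c2", "c3"))
  expect_equal(r$genuineId, "c1")
  # no clone identical to the direct read -> error
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  rows2 <- rows
  rows2[c("c1", "c2", "c3")] <- vapply(11:13, function(i)
    .mut(g, i, ts[substr(g, i, i)]), character(1))
  expect_error(identifyGenuine(.mkAln(rows2), paste0("c", 1:4),
                               directId = "direct"), "no genuine match")
})

test_that("without a direct read the dominant identical haplotype wins", {
  set.seed(15)
  g <- randomDnaString(60)
  alt <- .mut(g, 3, if (substr(g, 3, 3) == "C") "T" else "C")
  rows <- c(c1 = g, c2 = g, c3 = g, c4 = alt, c5 = alt,
            c6 = .mut(g, 20, if (substr(g, 20, 20) == "A") "C" else "A"))
  r <- identifyGenuine(.mkAln(rows), names(rows))
  expect_equal(r$status, "ok")
  expect_setequal(r$supportIds, c("c1", "c2", "c3"))
  # all clones unique -> undetermined
  uniq <- vapply(1:4, function(i) .mut(g, i, "N"), character(1))
  uniq <- c(u1 = g, u2 = .mut(g, 1, if (substr(g, 1, 1) == "A") "G" else "A"),
            u3 = .mut(g, 2, if (substr(g, 2, 2) == "A") "G" else "A"))
  r2 <- identifyGenuine(.mkAln(uniq), names(uniq))
  expect_equal(r2$status, "undetermined")
  expect_true(is.na(r2$genuineId))
})

test_that("distance-based grouping separates haplotypes at the cutoff", {
  # two tight clusters: within 0, between ~ 8%
  ids <- c("g1", "v1", "n1", "n2")
  D <- matrix(0, 4, 4, dimnames = list(ids, ids))
  D["g1", "v1"] <- D["v1", "g1"] <- 0.002
  for (i in c("g1", "v1")) for (j in c("n1", "n2")) {
    D[i, j] <- D[j, i] <- 0.08
  }
  D["n1", "n2"] <- D["n2", "n1"] <- 0.004
  dm <- methods::new("DistMatrix", labels = ids, values = D,
                     undefinedPairs = matrix(character(), 0, 2))
  cfg <- triageConfig(useTreeClades = FALSE)
  gr <- assignGroups(dm, "g1", cfg = cfg, region = "COI")
  expect_setequal(gr$id[gr$group == "A"], c("g1", "v1"))
  expect_setequal(gr$id[gr$group == "B"], c("n1", "n2"))
  # everything within 1% -> a single group A
  D2 <- D; D2[D2 > 0.01] <- 0.005
  dm2 <- methods::new("DistMatrix", labels = ids, values = D2,
                      undefinedPairs = matrix(character(), 0, 2))
  gr2 <- assignGroups(dm2, "g1", cfg = cfg, region = "COI")
  expect_true(all(gr2$group == "A"))
})

test_that("undefined distances push haplotypes into their own far group", {
  ids <- c("g1", "v1", "d1")
  D <- matrix(0.001, 3, 3, dimnames = list(ids, ids))
  diag(D) <- 0
  D["g1", "d1"] <- D["d1", "g1"] <- NA
  D["v1", "d1"] <- D["d1", "v1"] <- NA
  dm <- methods::new("DistMatrix", labels = ids, values = D,
                     undefinedPairs = rbind(c("g1", "d1"), c("v1", "d1")))
  gr <- assignGroups(dm, "g1", cfg = triageConfig(useTreeClades = FALSE),
                     region = "Dloop")
  expect_equal(gr$group[gr$id == "d1"], "B")
  expect_setequal(gr$id[gr$group == "A"], c("g1", "v1"))
})

test_that("non-A groups are lettered by increasing divergence from A", {
  ids <- c("g1", "far1", "near1")
  D <- matrix(0, 3, 3, dimnames = list(ids, ids))
  D["g1", "far1"] <- D["far1", "g1"] <- 0.20
  D["g1", "near1"] <- D["near1", "g1"] <- 0.08
  D["far1", "near1"] <- D["near1", "far1"] <- 0.15
  dm <- methods::new("DistMatrix", labels = ids, values = D,
                     undefinedPairs = matrix(character(), 0, 2))
  gr <- assignGroups(dm, "g1", cfg = triageConfig(useTreeClades = FALSE),
                     region = "COI")
  expect_equal(gr$group[gr$id == "near1"], "B")
  expect_equal(gr$group[gr$id == "far1"], "C")
})

test_that("clone labels follow the difference-count and group rules", {
  set.seed(16)
  g <- randomDnaString(120)
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  sub1 <- .mut(g, 7, ts[substr(g, 7, 7)])
  v <- strsplit(g, "")[[1L]]
  p10 <- sample(120, 10)
  v[p10] <- ts[v[p10]]
  het <- paste(v, collapse = "")
  w <- strsplit(g, "")[[1L]]
  pn <- sample(120, 12)
  w[pn] <- ts[w[pn]]
  numt <- paste(w, collapse = "")
  rows <- c(direct = g, cg = g, cv = sub1, ch = het, cn = numt)
  aln <- .mkAln(rows)
  cfg <- triageConfig(useTreeClades = FALSE)
  genuine <- list(ind1 = list(status = "ok", genuineId = "cg",
                              supportIds = "cg"))
  groups <- data.frame(id = c("cg", "cv", "ch", "cn"),
                       group = c("A", "A", "A", "B"))
  info <- data.frame(id = c("cg", "cv", "ch", "cn"),
                     individual = "ind1", stringsAsFactors = FALSE)
  rep <- classifyClones(aln, info, genuine, groups, cfg = cfg,
                        region = "COI")
  lab <- stats::setNames(cloneTable(rep)$label, cloneTable(rep)$id)
  expect_equal(unname(lab["cg"]), "genuine")
  expect_equal(unname(lab["cv"]), "pcr_error_variant")
  expect_equal(unname(lab["ch"]), "heteroplasmy")
  expect_equal(unname(lab["cn"]), "numt")
  expect_equal(cloneTable(rep)$diffsEvents[cloneTable(rep)$id == "ch"], 10L)
  # every clone gets exactly one label
  expect_equal(nrow(cloneTable(rep)), 4L)
  expect_false(any(is.na(cloneTable(rep)$label)))
})

test_that("undetermined genuine labels all clones ambiguous", {
  set.seed(17)
  g <- randomDnaString(60)
  rows <- c(c1 = g, c2 = .mut(g, 2, "N"))
  genuine <- list(ind1 = list(status = "undetermined",
                              genuineId = NA_character_,
                              supportIds = character()))
  groups <- data.frame(id = c("c1", "c2"), group = c("A", "A"))
  info <- data.frame(id = c("c1", "c2"), individual = "ind1")
  rep <- classifyClones(.mkAln(rows), info, genuine, groups,
                        region = "COI", coding = FALSE)
  expect_true(all(cloneTable(rep)$label == "ambiguous"))
})

test_that("raising the polymerase-error threshold only absorbs heteroplasmy labels", {
  sim <- simulatedRegion(seed = 31)
  lib <- sim$lib
  prevLabels <- NULL
  for (t in 1:4) {
    cfg <- triageConfig(taqMaxDiffs = t, heteroplasmyMinDiffs = t + 1L,
                        useTreeClades = FALSE)
    res <- runRegion(lib$clones, direct = sim$direct, region = "COI",
                     cfg = cfg, B = 100L, seed = 2L)
    lab <- stats::setNames(cloneTable(res$report)$label,
                           cloneTable(res$report)$id)
    if (!is.null(prevLabels)) {
      was <- names(prevLabels)[prevLabels == "pcr_error_variant"]
      expect_true(all(lab[was] %in% c("pcr_error_variant", "genuine")),
                  info = paste("t =", t))
    }
    prevLabels <- lab
  }
})

test_that("divergence summaries match the cross-group cells", {
  set.seed(18)
  g <- randomDnaString(200)
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  v <- strsplit(g, "")[[1L]]
  p <- sample(200, 16)
  v[p] <- ts[v[p]]
  far <- paste(v, collapse = "")
  rows <- c(a1 = g, a2 = g, b1 = far, b2 = far)
  aln <- .mkAln(rows)
  groups <- data.frame(id = names(rows), group = c("A", "A", "B", "B"))
  ds <- divergenceSummary(aln, groups, B = 100L, seed = 1L)
  expect_equal(nrow(ds), 1L)
  # identical-within groups at a fixed distance: min = max = mean
  expect_equal(ds$min, ds$max)
  expect_equal(ds$mean, ds$min)
  d <- k2pMatrix(aln)
  expect_equal(ds$mean, mean(distValues(d)[c("a1", "a2"), c("b1", "b2")]) * 100,
               tolerance = 1e-9)
  expect_gt(ds$se, 0)
  expect_equal(ds$undefinedFraction, 0)
})
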