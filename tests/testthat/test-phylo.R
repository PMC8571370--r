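test_that("NJ solves the three-taxon case in closed form", {
  D <- matrix(c(0, 3, 5,
                3, 0, 4,
                5, 4, 0), 3, 3, dimnames = list(c("A", "B", "C"),
                                                c("A", "B", "C")))
  tr <- neighborJoining(D)
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(tr$Nnode, 1L)
  el <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  # three-point formulas: a = (dAB + dAC - dBC)/2 etc.
  expect_equal(unname(el[c("A", "B", "C")]), c(2, 1, 3))
})

test_that("NJ recovers the 4-taxon additive example exactly", {
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):0);")
  D <- ape::cophenetic.phylo(ref)
  ord <- c("A", "B", "C", "D")
  tr <- neighborJoining(D[ord, ord])
  expect_equal(phangorn::RF.dist(tr, ape::unroot(ref)), 0)
  expect_equal(ape::cophenetic.phylo(tr)[ord, ord], D[ord, ord],
               tolerance = 1e-9)
  # the clade query on the known topology
  expect_setequal(smallestContainingClade(tr, c("A", "B")), c("A", "B"))
  expect_setequal(smallestContainingClade(tr, "A"), "A")
  expect_setequal(smallestContainingClade(tr, c("A", "C"), outgroup = NULL),
                  tr$tip.label)
})

test_that("NJ recovers random additive trees up to 12 taxa", {
  set.seed(2024)
  for (k in 1:10) {
    n <- sample(4:12, 1)
    ref <- ape::rtree(n, rooted = FALSE)
    D <- ape::cophenetic.phylo(ref)
    ord <- sort(rownames(D))
    tr <- neighborJoining(D[ord, ord])
    expect_equal(phangorn::RF.dist(tr, ref), 0, info = paste("n =", n))
    expect_equal(ape::cophenetic.phylo(tr)[ord, ord], D[ord, ord],
                 tolerance = 1e-8, info = paste("n =", n))
  }
})

test_that("NJ is deterministic on tie-rich matrices and rejects NAs", {
  D <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(D) <- 0
  t1 <- neighborJoining(D)
  t2 <- neighborJoining(D)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  Dna <- D; Dna[1, 2] <- Dna[2, 1] <- NA
  expect_error(neighborJoining(Dna), "undefined")
  dm <- methods::new("DistMatrix", labels = letters[1:5], values = Dna,
                     undefinedPairs = matrix(c("a", "b"), 1, 2))
  expect_error(neighborJoining(dm), "a/b")
})

test_that("negative branch lengths are clamped with a logged deficit", {
  # a matrix violating the four-point condition produces a negative NJ edge
  D <- matrix(c(0, 2, 3, 4,
                2, 0, 2.6, 3.2,
                3, 2.6, 0, 1.2,
                4, 3.2, 1.2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighborJoining(D)
  expect_true(all(tr$edge.length >= 0))
  expect_true(is.numeric(attr(tr, "clampedDeficit")))
})

test_that("bootstrap support is 100 for forced bipartitions and bounded", {
  set.seed(55)
  a <- randomDnaString(300)
  v <- strsplit(a, "")[[1L]]
  flip <- c(A = "G", C = "T", G = "A", T = "C")
  w <- v; w[seq(1, 300, by = 4)] <- flip[v[seq(1, 300, by = 4)]]
  b <- paste(w, collapse = "")
  rows <- c(a1 = a, a2 = a, a3 = a, a4 = a, b1 = b, b2 = b, b3 = b, b4 = b)
  aln <- methods::new("HaploAlignment",
                      seqs = Biostrings::DNAStringSet(rows),
                      provenance = "test")
  tr <- bootstrapSupport(aln, B = 100L, seed = 3L)
  supp <- suppressWarnings(as.numeric(tr$node.label))
  supp <- supp[!is.na(supp)]
  expect_true(all(supp >= 0 & supp <= 100))
  # the a-cluster vs b-cluster split is present in every replicate
  part <- ape::prop.part(tr)
  labs <- attr(part, "labels")
  sizes <- vapply(part, length, integer(1))
  # find the internal edge splitting the two quartets
  splitNode <- which(vapply(part, function(p)
    setequal(labs[p], c("a1", "a2", "a3", "a4")) ||
      setequal(labs[p], c("b1", "b2", "b3", "b4")), logical(1)))
  expect_true(length(splitNode) >= 1L)
  expect_true(all(suppressWarnings(
    as.numeric(tr$node.label[splitNode])) == 100))
  # reproducible under the same seed
  tr2 <- bootstrapSupport(aln, B = 100L, seed = 3L)
  expect_identical(tr$node.label, tr2$node.label)
})

test_that("Newick serialization round-trips and applies the support threshold", {
  d <- matrix(c(0, 1, 4, 5,
                1, 0, 5, 6,
                4, 5, 0, 1.5,
                5, 6, 1.5, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighborJoining(d)
  tr$node.label <- c("", "59", "87")[seq_len(tr$Nnode)]
  txt <- toNewick(tr, supportThreshold = 60)
  expect_false(grepl("59", txt, fixed = TRUE))
  back <- ape::read.tree(text = toNewick(tr))
  expect_equal(phangorn::RF.dist(back, tr), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  expect_match(toNewick(cherry), "^\\(A:1,B:1\\);?$")
})
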