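# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the aligner oracle enumerates alignments, the
# genetic-code oracle is a hand-typed table, and additive test trees come
# from ape.

# exhaustive global-alignment optimum with affine gap costs
# (gap of length k costs open + k * extend); enumerates every path
bruteForceAlignScore <- function(a, b, match, mismatch, open, extend) {
  va <- strsplit(a, "", fixed = TRUE)[[1L]]
  vb <- strsplit(b, "", fixed = TRUE)[[1L]]
  na <- length(va); nb <- length(vb)
  rec <- function(i, j, last) {
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb) {
      s <- if (va[i] == vb[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "m"))
    }
    if (i <= na) {
      cost <- extend + if (last == "x") 0 else open
      best <- max(best, -cost + rec(i + 1L, j, "x"))
    }
    if (j <= nb) {
      cost <- extend + if (last == "y") 0 else open
      best <- max(best, -cost + rec(i, j + 1L, "y"))
    }
    best
  }
  rec(1L, 1L, "m")
}

# hand-typed standard genetic code, then the invertebrate mitochondrial
# (table 5) differences applied
.standardCode <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

table5Oracle <- function() {
  tbl <- .standardCode
  tbl[c("ATA", "TGA", "AGA", "AGG")] <- c("M", "W", "S", "S")
  tbl
}

randomDnaString <- function(n, prob = c(0.31, 0.18, 0.17, 0.34)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# a synthetic circular mitogenome carrying one forward primer site and one
# reverse footprint placed so that the amplicon has exactly `productLen`
# bases (optionally spanning the origin); the backbone is screened so no
# second site exists
syntheticCircularTemplate <- function(primers, productLen, genomeLen = 3000L,
                                      forwardAt = 100L) {
  fwd <- primers@forward
  rev <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(primers@reverse)))
  repeat {
    g <- strsplit(randomDnaString(genomeLen), "", fixed = TRUE)[[1L]]
    insert <- function(g, site, at) {
      v <- strsplit(site, "", fixed = TRUE)[[1L]]
      pos <- ((at - 1L + seq_along(v) - 1L) %% genomeLen) + 1L
      g[pos] <- v
      g
    }
    g <- insert(g, fwd, forwardAt)
    revStart <- forwardAt + productLen - nchar(rev)
    g <- insert(g, rev, revStart)
    seq <- paste(g, collapse = "")
    doubled <- paste0(seq, seq)
    nf <- length(Biostrings::start(Biostrings::matchPattern(fwd, doubled)))
    nr <- length(Biostrings::start(Biostrings::matchPattern(rev, doubled)))
    if (nf == 2L && nr == 2L) return(seq)   # one site each, seen twice
  }
}

# small simulated library + direct read, shared by triage/pipeline tests
simulatedRegion <- function(seed, regionKind = "coding", ...) {
  cfg <- simConfig(regionKind, seed = seed, ...)
  truth <- generateTruth(cfg)
  lib <- simulatePcrLibrary(truth)
  direct <- HaploSet(
    stats::setNames(as.character(truthTemplates(truth))["genuine"],
                    "sim1-direct"),
    region = if (regionKind == "coding") "COI" else "Dloop",
    individual = "sim1", role = "direct")
  list(cfg = cfg, truth = truth, lib = lib, direct = direct)
}

depositedDir <- function() {
  system.file("extdata", "deposited", package = "numtriage")
}
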