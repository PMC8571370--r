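# Sanger-style peak prediction for a weighted mixture of co-amplified
# haplotypes: per alignment column the template weight reaching each
# nucleotide, the above-threshold peak set, and the miscall risk when
# pseudogene weight outvotes the genuine template. The signal model is
# linear in template fraction with a flat detection threshold; indel
# disruption is flagged, not physically modeled.

#' Predict per-site peak signals for a haplotype mixture
#'
#' Weights are summed by nucleotide within each column; nucleotides whose
#' summed weight reaches the detection threshold form the peak set.
#' Columns where gap mass itself reaches the threshold are flagged
#' gap-disrupted (a frame slip wrecking the downstream trace).
#'
#' @param alignment a \linkS4class{HaploAlignment}.
#' @param weights nonnegative per-row mixture fractions (normalized to sum
#'   to 1).
#' @param threshold detection threshold in (0, 0.5].
#' @return a \linkS4class{PeakProfile}.
#' @examples
#' aln <- progressiveAlign(HaploSet(c(g = "ACGTACGT", n1 = "ACGTACTT",
#'                                    n2 = "ACGTACTT")))
#' predictSiteSignals(aln, c(0.7, 0.15, 0.15), threshold = 0.1)
#' @export
predictSiteSignals <- function(alignment, weights, threshold = 0.10) {
  m <- .alnMatrix(alignment)
  if (length(weights) != nrow(m))
    stop("weights length (", length(weights), ") must match row count (",
         nrow(m), ")")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (threshold <= 0 || threshold > 0.5)
    stop("threshold must lie in (0, 0.5]")
  w <- weights / sum(weights)
  sym <- c("A", "C", "G", "T", "-")
  wb <- matrix(0, 5L, ncol(m), dimnames = list(sym, NULL))
  for (s in sym) wb[s, ] <- colSums((m == s) * w)
  eps <- 1e-9   # guard against float summation at the threshold boundary
  peakSets <- lapply(seq_len(ncol(wb)), function(col) {
    v <- wb[1:4, col]
    v[v >= threshold - eps]
  })
  mult <- vapply(peakSets, length, integer(1))
  gapDis <- wb["-", ] >= threshold - eps
  topRow <- which.max(w)
  methods::new("PeakProfile", weightsByBase = wb, peaks = peakSets,
               multiplicity = as.integer(mult),
               gapDisrupted = unname(gapDis), threshold = threshold,
               topRowBase = unname(m[topRow, ]))
}

#' Count multi-peak and gap-disrupted sites
#'
#' @param profile a \linkS4class{PeakProfile}.
#' @return named integer vector: \code{nDouble} (multiplicity exactly 2),
#'   \code{nTriple} (exactly 3), \code{nGapDisrupted}.
#' @export
multipeakCounts <- function(profile) {
  c(nDouble = sum(profile@multiplicity == 2L),
    nTriple = sum(profile@multiplicity == 3L),
    nGapDisrupted = sum(profile@gapDisrupted))
}

#' Call the strongest signal per column
#'
#' Mimics adopting the stronger peak during base calling: per column the
#' maximum-weight nucleotide; ties are broken toward the highest-weight
#' single row's base, then alphabetically. Columns with no nucleotide
#' weight (all-gap) are called "-".
#'
#' @param profile a \linkS4class{PeakProfile}.
#' @return the called sequence (character string; compare it with the true
#'   genuine haplotype to quantify miscalls).
#' @export
callStrongest <- function(profile) {
  wb <- profile@weightsByBase[1:4, , drop = FALSE]
  calls <- vapply(seq_len(ncol(wb)), function(col) {
    v <- wb[, col]
    if (all(v == 0)) return("-")
    mx <- max(v)
    top <- names(v)[v >= mx - 1e-12]
    if (length(top) > 1L) {
      pref <- profile@topRowBase[col]
      if (pref %in% top) return(pref)
      top <- sort(top)
    }
    top[1L]
  }, character(1))
  paste(calls, collapse = "")
}

#' Constructed mixture mimicking a multi-peak electropherogram window
#'
#' Builds a synthetic 10-haplotype alignment (one genuine + nine
#' pseudogene rows over a 60-column window) whose sharing pattern yields,
#' at the default weights and a 0.10 threshold, exactly seven double-peak
#' and five triple-peak sites: at a double-peak column two pseudogenes
#' share one alternative base; at a triple-peak column two pseudogene
#' pairs each share a distinct alternative base.
#'
#' @return list with \code{alignment} (a \linkS4class{HaploAlignment}),
#'   \code{weights} (genuine 0.55, 0.05 per pseudogene row), and
#'   \code{genuine} (the genuine row string).
#' @export
multipeakExample <- function() {
  L <- 60L
  base <- rep(c("A", "C", "G", "T"), length.out = L)
  alt <- c(A = "G", C = "T", G = "A", T = "C")   # transition partner
  alt2 <- c(A = "C", C = "A", G = "T", T = "G")  # a transversion partner
  rows <- matrix(rep(base, each = 10L), nrow = 10L)
  doubleCols <- c(5L, 11L, 18L, 25L, 33L, 41L, 52L)
  tripleCols <- c(8L, 20L, 29L, 44L, 57L)
  # nine pseudogene rows are rows 2..10; rotate which disjoint row pairs
  # share the alternative base(s)
  for (k in seq_along(doubleCols)) {
    col <- doubleCols[k]
    pair <- c(2L, 3L) + ((k - 1L) %% 4L) * 2L
    rows[pair, col] <- alt[[base[col]]]
  }
  for (k in seq_along(tripleCols)) {
    col <- tripleCols[k]
    pairA <- c(2L, 3L) + ((k - 1L) %% 2L) * 2L
    pairB <- c(6L, 7L) + ((k - 1L) %% 2L) * 2L
    rows[pairA, col] <- alt[[base[col]]]
    rows[pairB, col] <- alt2[[base[col]]]
  }
  ids <- c("genuine", paste0("numt", 1:9))
  seqs <- stats::setNames(apply(rows, 1L, paste, collapse = ""), ids)
  aln <- methods::new("HaploAlignment",
                      seqs = Biostrings::DNAStringSet(seqs),
                      provenance = "constructed multi-peak example")
  list(alignment = aln, weights = c(0.55, rep(0.05, 9L)),
       genuine = seqs[["genuine"]])
}
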