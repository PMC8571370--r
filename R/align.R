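# Pairwise and progressive multiple alignment with affine gap costs, and
# the trim-to-window rule (fit all rows to the shortest direct-sequencing
# anchor). The DP kernels live in src/align.cpp.

.seqText <- function(x) {
  if (methods::is(x, "XStringSet")) as.character(x)
  else toupper(as.character(x))
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman--Wunsch--Gotoh alignment; a gap of length k costs
#' \code{gapOpen + k * gapExtend}. Traceback is deterministic (diagonal
#' preferred over up over left).
#'
#' @param a,b sequences (character strings or single-element sets).
#' @param params an \linkS4class{AlignParams}.
#' @return list with \code{alignment} (a 2-row
#'   \linkS4class{HaploAlignment}) and \code{score}.
#' @examples
#' pairwiseAlign("ACGT", "AGT", alignParams(1, -1, 2, 1))$score
#' @export
pairwiseAlign <- function(a, b, params = alignParams()) {
  ta <- .seqText(a)[[1L]]; tb <- .seqText(b)[[1L]]
  if (!nzchar(ta) || !nzchar(tb)) stop("sequences must be nonempty")
  na <- if (!is.null(names(a))) names(a)[1L] else "a"
  nb <- if (!is.null(names(b))) names(b)[1L] else "b"
  if (identical(na, nb)) nb <- paste0(nb, ".2")
  res <- .nwAffine(ta, tb, params@match, params@mismatch,
                   params@gapOpen, params@gapExtend)
  seqs <- Biostrings::DNAStringSet(stats::setNames(c(res$a, res$b), c(na, nb)))
  aln <- methods::new("HaploAlignment", seqs = seqs,
                      provenance = "pairwise affine-gap alignment")
  list(alignment = aln, score = res$score)
}

# fraction identity between the two rows of a pairwise alignment,
# excluding terminal-gap columns of either row (read-length artifacts are
# not divergence); internal gap columns count as non-identity.
.pairIdentity <- function(ra, rb) {
  va <- strsplit(ra, "", fixed = TRUE)[[1L]]
  vb <- strsplit(rb, "", fixed = TRUE)[[1L]]
  core <- function(v) {
    ng <- which(v != "-")
    c(ng[1L], ng[length(ng)])
  }
  ca <- core(va); cb <- core(vb)
  lo <- max(ca[1L], cb[1L]); hi <- min(ca[2L], cb[2L])
  if (hi < lo) return(0)
  va <- va[lo:hi]; vb <- vb[lo:hi]
  sum(va == vb & va != "-") / length(va)
}

#' Guide tree for progressive alignment
#'
#' Neighbor-joining tree over all records, built on pairwise distances
#' d = 1 - identity from \code{\link{pairwiseAlign}} (terminal gaps
#' excluded from the identity).
#'
#' @param records a \linkS4class{HaploSet} (>= 2 sequences).
#' @param params an \linkS4class{AlignParams}.
#' @return an \code{ape} \code{phylo} tree whose leaves are the record
#'   ids.
#' @export
buildGuideTree <- function(records, params = alignParams()) {
  n <- length(records)
  if (n < 2L) stop("need at least 2 records")
  ids <- names(records)
  txt <- as.character(records)
  if (n == 2L) {
    al <- pairwiseAlign(records[1L], records[2L], params)
    d <- 1 - .pairIdentity(as.character(al$alignment@seqs)[1L],
                           as.character(al$alignment@seqs)[2L])
    return(ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                         ids[1L], d / 2, ids[2L], d / 2)))
  }
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    al <- pairwiseAlign(txt[i], txt[j], params)
    rows <- as.character(al$alignment@seqs)
    D[i, j] <- D[j, i] <- 1 - .pairIdentity(rows[1L], rows[2L])
  }
  neighborJoining(methods::new("DistMatrix", labels = ids, values = D,
                               undefinedPairs = matrix(character(), 0, 2)))
}

# 5 x L column-frequency profile (rows A, C, G, T, gap)
.profileOf <- function(rows) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  L <- ncol(m)
  p <- matrix(0, 5L, L)
  sym <- c("A", "C", "G", "T", "-")
  for (k in 1:5) p[k, ] <- colMeans(m == sym[k])
  p
}

.expandRows <- function(rows, idx) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  out <- matrix("-", nrow(m), length(idx))
  out[, idx > 0L] <- m[, idx[idx > 0L], drop = FALSE]
  stats::setNames(apply(out, 1L, paste, collapse = ""), names(rows))
}

.mergeProfiles <- function(rowsA, rowsB, params) {
  res <- .profileAlign(.profileOf(rowsA), .profileOf(rowsB),
                       params@match, params@mismatch,
                       params@gapOpen, params@gapExtend)
  c(.expandRows(rowsA, res$a), .expandRows(rowsB, res$b))
}

#' Progressive multiple alignment
#'
#' Profiles are merged in guide-tree post-order with profile-profile
#' global alignment (column score = expected pairwise substitution score).
#' Row order follows the input; gap-only columns are never produced.
#'
#' @param records a \linkS4class{HaploSet} (>= 2 sequences).
#' @param params an \linkS4class{AlignParams}.
#' @return a \linkS4class{HaploAlignment}.
#' @examples
#' hs <- HaploSet(c(x = "ACGT", y = "ACG", z = "CGT"))
#' alnWidth(progressiveAlign(hs))
#' @export
progressiveAlign <- function(records, params = alignParams()) {
  n <- length(records)
  if (n < 2L) stop("need at least 2 records")
  txt <- stats::setNames(as.character(records), names(records))
  if (n == 2L) {
    al <- pairwiseAlign(records[1L], records[2L], params)$alignment
    rows <- stats::setNames(as.character(al@seqs), names(records))
  } else {
    guide <- buildGuideTree(records, params)
    guide <- ape::reorder.phylo(guide, "postorder")
    nnode <- max(guide$edge)
    rowsAt <- vector("list", nnode)
    for (i in seq_along(guide$tip.label))
      rowsAt[[i]] <- txt[guide$tip.label[i]]
    for (e in seq_len(nrow(guide$edge))) {
      par <- guide$edge[e, 1L]; chd <- guide$edge[e, 2L]
      rowsAt[[par]] <- if (is.null(rowsAt[[par]])) rowsAt[[chd]]
        else .mergeProfiles(rowsAt[[par]], rowsAt[[chd]], params)
    }
    root <- guide$edge[nrow(guide$edge), 1L]
    rows <- rowsAt[[root]][names(txt)]
  }
  m <- .alnMatrix(Biostrings::DNAStringSet(rows))
  keep <- colSums(m != "-") > 0L
  if (!all(keep))
    rows <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  seqs <- Biostrings::DNAStringSet(rows)
  S4Vectors::mcols(seqs) <- S4Vectors::mcols(records)
  methods::new("HaploAlignment", seqs = seqs,
               provenance = sprintf(
                 "progressive alignment of %d sequences (match %g, mismatch %g, open %g, extend %g)",
                 n, params@match, params@mismatch, params@gapOpen,
                 params@gapExtend))
}

#' Trim an alignment to the window of its shortest anchor row
#'
#' Columns outside the first..last non-gap column of the shortest anchor
#' row (fewest non-gap symbols) are removed from every row; this fits all
#' sequences to the shortest direct-sequencing read before distances are
#' computed.
#'
#' @param alignment a \linkS4class{HaploAlignment}.
#' @param anchorIds row ids of the anchor (direct) sequences.
#' @return the trimmed \linkS4class{HaploAlignment}.
#' @export
trimToWindow <- function(alignment, anchorIds) {
  labs <- alnLabels(alignment)
  if (!all(anchorIds %in% labs))
    stop("unknown anchor id(s): ",
         paste(setdiff(anchorIds, labs), collapse = ", "))
  m <- .alnMatrix(alignment)
  nongap <- rowSums(m[anchorIds, , drop = FALSE] != "-")
  anchor <- anchorIds[which.min(nongap)]
  ng <- which(m[anchor, ] != "-")
  lo <- ng[1L]; hi <- ng[length(ng)]
  rows <- apply(m[, lo:hi, drop = FALSE], 1L, paste, collapse = "")
  seqs <- Biostrings::DNAStringSet(rows)
  S4Vectors::mcols(seqs) <- S4Vectors::mcols(alignment@seqs)
  methods::new("HaploAlignment", seqs = seqs,
               provenance = paste0(alignment@provenance,
                                   sprintf("; trimmed to columns %d-%d (anchor %s)",
                                           lo, hi, anchor)))
}
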