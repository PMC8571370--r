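# Neighbor-joining with a deterministic tie-break, column-bootstrap
# bipartition support, rooted clade queries, and Newick output. Trees are
# ape "phylo" objects throughout.

.nwkEscape <- function(x) gsub("[ ():;,\\[\\]]", "_", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration on the Q-criterion. Ties in Q are broken
#' deterministically by the lexicographically smallest label pair.
#' Negative branch lengths are clamped to 0; the clamped deficit is
#' attached as attribute \code{"clampedDeficit"}.
#'
#' @param d a \linkS4class{DistMatrix} or a symmetric numeric matrix with
#'   dimnames; must contain no undefined (NA) distances.
#' @return an unrooted \code{ape} \code{phylo} tree (trifurcating root for
#'   >= 3 taxa).
#' @export
neighborJoining <- function(d) {
  if (methods::is(d, "DistMatrix")) {
    if (nrow(d@undefinedPairs) > 0L)
      stop("undefined distances for pair(s): ",
           paste(apply(d@undefinedPairs, 1L, paste, collapse = "/"),
                 collapse = ", "),
           "; prune these labels first")
    D <- d@values
  } else D <- as.matrix(d)
  if (any(is.na(D)))
    stop("undefined distances present; prune the offending labels first")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 labels")
  labs <- rownames(D)
  nwk <- .nwkEscape(labs)         # newick fragment per active node
  key <- labs                     # tie-break key per active node
  deficit <- 0
  fmt <- function(x) sprintf("%.12g", x)
  while (n > 3L) {
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    # lexicographically smallest (sorted) label pair
    k1 <- pmin(key[cand[, 1L]], key[cand[, 2L]])
    k2 <- pmax(key[cand[, 1L]], key[cand[, 2L]])
    pick <- order(k1, k2)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    vi <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { deficit <- deficit - vi; vi <- 0 }
    if (vj < 0) { deficit <- deficit - vj; vj <- 0 }
    newNwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(vi), nwk[j], fmt(vj))
    newKey <- min(key[i], key[j])
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    nwk <- c(nwk[keep], newNwk)
    key <- c(key[keep], newKey)
    n <- n - 1L
  }
  # final three-taxon star: three-point formulas
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- c(v1, v2, v3)
  deficit <- deficit + sum(-pmin(v, 0))
  v <- pmax(v, 0)
  text <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(v[1]),
                  nwk[2], fmt(v[2]), nwk[3], fmt(v[3]))
  tr <- ape::read.tree(text = text)
  attr(tr, "clampedDeficit") <- deficit
  tr
}

#' Column-bootstrap support for a neighbor-joining tree
#'
#' Builds the NJ tree from the alignment's K2P matrix, then resamples
#' alignment columns with replacement B times; each replicate's K2P matrix
#' feeds NJ, and the support of an internal edge is the percentage of
#' usable replicates containing the same leaf bipartition. Replicates with
#' undefined distances are discarded and counted (a warning is raised if
#' more than 10\% are lost).
#'
#' @param alignment a \linkS4class{HaploAlignment} with >= 4 rows.
#' @param B replicates (>= 100; figure-style default 1000).
#' @param seed integer seed.
#' @return the original-data NJ \code{phylo} tree with integer percentage
#'   supports in \code{node.label} (root label empty), plus attribute
#'   \code{"discardedReplicates"}.
#' @export
bootstrapSupport <- function(alignment, B = 1000L, seed = 1L) {
  codes <- .alnCodes(alignment)
  if (nrow(codes) < 4L) stop("need at least 4 rows")
  if (B < 100L) stop("B must be >= 100")
  d0 <- .k2pMatrixFromCodes(codes)
  tree <- neighborJoining(d0)
  L <- ncol(codes)
  reps <- .withSeed(seed, {
    out <- vector("list", B)
    for (b in seq_len(B)) {
      cb <- codes[, sample.int(L, L, replace = TRUE), drop = FALSE]
      db <- .k2pMatrixFromCodes(cb)
      out[[b]] <- if (nrow(db@undefinedPairs) > 0L) NULL
        else neighborJoining(db)
    }
    out
  })
  ok <- !vapply(reps, is.null, logical(1))
  dropped <- sum(!ok)
  if (dropped > 0.1 * B)
    warning(dropped, " of ", B,
            " bootstrap replicates discarded (undefined distances)")
  used <- reps[ok]
  counts <- ape::prop.clades(tree, used, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supp <- round(100 * counts / length(used))
  supp <- pmin(pmax(supp, 0L), 100L)
  tree$node.label <- as.character(supp)
  tree$node.label[1L] <- ""   # root of the unrooted representation
  attr(tree, "discardedReplicates") <- dropped
  tree
}

.rootTree <- function(tree, outgroup = NULL) {
  if (!is.null(outgroup)) {
    if (!all(outgroup %in% tree$tip.label))
      stop("outgroup not among leaves: ",
           paste(setdiff(outgroup, tree$tip.label), collapse = ", "))
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
              edgelabel = TRUE)
  } else {
    phangorn::midpoint(tree)
  }
}

#' Leaves of the smallest clade containing a set of ids
#'
#' The tree is rooted on the outgroup when one is given, otherwise
#' midpoint-rooted; the result is the leaf set of the minimal rooted clade
#' containing all the query ids.
#'
#' @param tree a \code{phylo} tree.
#' @param ids leaf labels that must be contained.
#' @param outgroup optional leaf label(s) to root on.
#' @return character vector of leaf labels.
#' @export
smallestContainingClade <- function(tree, ids, outgroup = NULL) {
  if (!all(ids %in% tree$tip.label))
    stop("unknown leaf id(s): ",
         paste(setdiff(ids, tree$tip.label), collapse = ", "))
  if (length(ids) == 1L) return(ids)
  rt <- .rootTree(tree, outgroup)
  mrca <- ape::getMRCA(rt, ids)
  if (is.null(mrca)) return(rt$tip.label)
  ape::extract.clade(rt, mrca)$tip.label
}

#' Serialize a tree to Newick with a support display threshold
#'
#' Branch lengths are written in full precision; internal-node supports
#' below the threshold are omitted (the figure-style "show supports >
#' 60\%" rule).
#'
#' @param tree a \code{phylo} tree, optionally with numeric supports in
#'   \code{node.label}.
#' @param supportThreshold supports strictly below this percentage are
#'   blanked.
#' @return a single Newick string.
#' @export
toNewick <- function(tree, supportThreshold = 0) {
  if (!is.null(tree$node.label) && supportThreshold > 0) {
    s <- suppressWarnings(as.numeric(tree$node.label))
    tree$node.label[!is.na(s) & s < supportThreshold] <- ""
  }
  ape::write.tree(tree, digits = 12)
}
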