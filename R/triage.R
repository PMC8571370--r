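# The decision procedure: determine each individual's genuine haplotype,
# group haplotypes (tree clade and/or single-linkage K2P), and label every
# clone genuine / pcr_error_variant / heteroplasmy / numt / ambiguous with
# its supporting evidence.

#' Determine the genuine haplotype of one individual
#'
#' With a direct-sequencing read, the genuine haplotype is the clone
#' haplotype identical to it (zero differences, events mode, over the
#' shared trimmed window). Without one, it is the haplotype shared
#' identically by the largest number of clones, requiring multiplicity >=
#' \code{minGenuineSupport}; ties go to the haplotype whose smallest clone
#' id sorts first.
#'
#' @param alignment a trimmed \linkS4class{HaploAlignment} containing the
#'   individual's clones (and the direct read, if any).
#' @param cloneIds row ids of this individual's clones.
#' @param directId row id of the direct read, or NULL.
#' @param cfg a \linkS4class{TriageConfig}.
#' @return list with \code{status} ("ok" or "undetermined"),
#'   \code{genuineId} (representative clone id or NA), and
#'   \code{supportIds} (clones carrying the genuine haplotype).
#' @export
identifyGenuine <- function(alignment, cloneIds, directId = NULL,
                            cfg = triageConfig()) {
  m <- .alnMatrix(alignment)
  if (!all(cloneIds %in% rownames(m)))
    stop("unknown clone id(s): ",
         paste(setdiff(cloneIds, rownames(m)), collapse = ", "))
  rowStr <- apply(m[cloneIds, , drop = FALSE], 1L, paste, collapse = "")
  if (!is.null(directId)) {
    if (!directId %in% rownames(m)) stop("unknown direct id: ", directId)
    dRow <- paste(m[directId, ], collapse = "")
    hit <- cloneIds[vapply(rowStr, function(r)
      differenceCount(r, dRow, mode = "events") == 0L, logical(1))]
    if (length(hit) == 0L)
      stop("no genuine match: no clone haplotype identical to the direct read")
    hit <- sort(hit)
    return(list(status = "ok", genuineId = hit[1L], supportIds = hit))
  }
  classes <- split(cloneIds, rowStr)
  sizes <- lengths(classes)
  best <- max(sizes)
  if (best < cfg@minGenuineSupport)
    return(list(status = "undetermined", genuineId = NA_character_,
                supportIds = character()))
  top <- classes[sizes == best]
  firsts <- vapply(top, function(x) min(sort(x)), character(1))
  members <- sort(top[[order(firsts)[1L]]])
  list(status = "ok", genuineId = members[1L], supportIds = members)
}

# single-linkage groups at a K2P-percent cutoff; undefined distances are
# "far"
.singleLinkGroups <- function(Dpct, cutoff) {
  n <- nrow(Dpct)
  if (n == 1L) return(stats::setNames(1L, rownames(Dpct)))
  big <- max(c(Dpct[!is.na(Dpct)], cutoff)) * 2 + 100
  Dp <- Dpct
  Dp[is.na(Dp)] <- big
  hc <- stats::hclust(stats::as.dist(Dp), method = "single")
  stats::cutree(hc, h = cutoff)
}

#' Group haplotypes around the genuine clade
#'
#' Primary assignment (when the config enables tree clades and a tree is
#' supplied): group A is the leaf set of the smallest rooted clade that
#' contains every genuine haplotype and is supported at >= 60\% (walking
#' from their MRCA toward the root; the root counts as supported); the
#' remaining haplotypes are grouped by single-linkage at the region's K2P
#' cutoff. Without a tree, single-linkage grouping covers all haplotypes
#' and the cluster(s) containing the genuine haplotypes form group A.
#' Groups are labeled A, then B, C, ... by increasing mean K2P from A.
#'
#' @param d a \linkS4class{DistMatrix} over the haplotypes (percent scale
#'   not required; substitutions/site are converted internally).
#' @param genuineIds ids of the genuine haplotypes (all individuals).
#' @param cfg a \linkS4class{TriageConfig}.
#' @param region region name used to pick the cutoff.
#' @param tree optional \code{phylo} tree with bootstrap supports in
#'   \code{node.label}.
#' @param outgroup optional leaf id(s) to root on (reference sequences);
#'   excluded from group membership.
#' @return data.frame with columns \code{id}, \code{group} and
#'   \code{assignmentConflict} (TRUE where the tree-based and
#'   distance-based assignments of group A disagree); attribute
#'   \code{"ambiguousGrouping"} is TRUE when the genuine haplotypes fell
#'   into different single-linkage groups.
#' @export
assignGroups <- function(d, genuineIds, cfg = triageConfig(),
                         region = "COI", tree = NULL, outgroup = NULL) {
  ids <- setdiff(d@labels, outgroup)
  if (!all(genuineIds %in% ids)) stop("genuine ids must be in the matrix")
  cutoff <- cfg@groupLinkCutoff[[region]]
  if (is.null(cutoff) || is.na(cutoff)) cutoff <- cfg@groupLinkCutoff[["other"]]
  keep <- match(ids, d@labels)
  Dpct <- d@values[keep, keep, drop = FALSE] * 100
  ambiguous <- FALSE
  # distance-based assignment: single-linkage cluster(s) holding the
  # genuine haplotypes
  cl <- .singleLinkGroups(Dpct, cutoff)
  gcl <- unique(cl[genuineIds])
  if (length(gcl) > 1L) {
    warning("genuine haplotypes fall into different single-linkage groups")
    ambiguous <- TRUE
  }
  linkA <- names(cl)[cl %in% gcl]
  radius <- cfg@genuineRadius[[region]]
  if (is.null(radius) || is.na(radius)) radius <- cfg@genuineRadius[["other"]]
  treeA <- NULL
  if (cfg@useTreeClades && !is.null(tree)) {
    rt <- .rootTree(tree, outgroup)
    supp <- suppressWarnings(as.numeric(rt$node.label))
    supp[is.na(supp)] <- 100
    ntip <- length(rt$tip.label)
    rootNode <- ntip + 1L
    node <- if (length(genuineIds) == 1L)
      rt$edge[rt$edge[, 2L] == match(genuineIds, rt$tip.label), 1L]
    else ape::getMRCA(rt, genuineIds)
    while (node != rootNode && supp[node - ntip] < 60) {
      node <- rt$edge[rt$edge[, 2L] == node, 1L]
    }
    treeA <- intersect(ape::extract.clade(rt, node)$tip.label, ids)
    # the clade can extend group A only within the region's genuine
    # radius: independently integrated pseudogene loci need not form a
    # joint clade, so the smallest supported clade around the genuine
    # haplotypes may legitimately engulf the nearest locus
    minToGenuine <- apply(Dpct[treeA, genuineIds, drop = FALSE], 1L,
                          function(x) if (all(is.na(x))) Inf
                            else min(x, na.rm = TRUE))
    treeA <- treeA[minToGenuine <= radius]
  }
  # group A = radius-bounded supported genuine clade plus the genuine
  # linkage cluster (variants cluster cohesively with their genuine
  # haplotype even when a short supported edge would cut them off the
  # clade); members carried by only one assignment are flagged
  aMembers <- union(treeA, linkA)
  rest <- setdiff(ids, aMembers)
  grp <- stats::setNames(rep("A", length(aMembers)), aMembers)
  if (length(rest) > 0L) {
    sub <- .singleLinkGroups(Dpct[rest, rest, drop = FALSE], cutoff)
    grp[rest] <- paste0("g", sub[rest])
  }
  disagree <- if (is.null(treeA)) character()
    else c(setdiff(treeA, linkA), setdiff(linkA, treeA))
  # order non-A groups by increasing mean K2P from A
  others <- setdiff(unique(grp), "A")
  if (length(others) > 0L) {
    aIdx <- names(grp)[grp == "A"]
    meanToA <- vapply(others, function(g) {
      cells <- Dpct[names(grp)[grp == g], aIdx, drop = FALSE]
      if (all(is.na(cells))) Inf else mean(cells, na.rm = TRUE)
    }, numeric(1))
    newNames <- stats::setNames(LETTERS[1L + seq_along(others)],
                                others[order(meanToA)])
    grp[grp != "A"] <- newNames[grp[grp != "A"]]
  }
  out <- data.frame(id = ids, group = unname(grp[ids]),
                    assignmentConflict = ids %in% disagree,
                    stringsAsFactors = FALSE)
  attr(out, "ambiguousGrouping") <- ambiguous
  out
}

#' Label every clone with evidence
#'
#' Per clone, with d the difference count to its own individual's genuine
#' haplotype (mode from the config): d = 0 is genuine; 1 <= d <= t inside
#' group A is a Taq polymerase error variant; d >= the heteroplasmy
#' minimum inside group A is heteroplasmy; any clone outside group A is a
#' NUMT. Stop codons or frameshifts inside group A add a pseudogene-like
#' note without changing the label; in non-A clones they corroborate the
#' NUMT call. Clones of an individual whose genuine haplotype is
#' undetermined are ambiguous.
#'
#' @param alignment trimmed \linkS4class{HaploAlignment} containing all
#'   clones and direct reads.
#' @param cloneInfo data.frame with columns \code{id} and
#'   \code{individual} (one row per clone).
#' @param genuineByIndividual named list (by individual) of
#'   \code{\link{identifyGenuine}} results.
#' @param groups data.frame from \code{\link{assignGroups}} (haplotype
#'   representative per clone id, or per haplotype plus a
#'   \code{haplotypeOf} mapping in \code{cloneInfo$haplotype}).
#' @param cfg a \linkS4class{TriageConfig}.
#' @param region region name (codon diagnostics are computed for COI).
#' @param coding compute codon evidence (stops, nonsynonymous counts).
#' @return a \linkS4class{TriageReport} (divergence table empty; see
#'   \code{\link{divergenceSummary}}).
#' @export
classifyClones <- function(alignment, cloneInfo, genuineByIndividual,
                           groups, cfg = triageConfig(), region = "COI",
                           coding = region == "COI") {
  m <- .alnMatrix(alignment)
  grpOf <- stats::setNames(groups$group, groups$id)
  radius <- cfg@genuineRadius[[region]]
  if (is.null(radius) || is.na(radius)) radius <- cfg@genuineRadius[["other"]]
  hapCol <- if ("haplotype" %in% colnames(cloneInfo)) cloneInfo$haplotype
    else cloneInfo$id
  frames <- list()
  rows <- vector("list", nrow(cloneInfo))
  for (k in seq_len(nrow(cloneInfo))) {
    id <- cloneInfo$id[k]
    ind <- cloneInfo$individual[k]
    gen <- genuineByIndividual[[ind]]
    hap <- hapCol[k]
    grp <- if (hap %in% names(grpOf)) unname(grpOf[hap]) else NA_character_
    if (is.null(gen) || is.na(gen$genuineId)) {
      rows[[k]] <- data.frame(
        id = id, individual = ind, label = "ambiguous",
        diffsEvents = NA_integer_, diffsColumns = NA_integer_,
        k2pToGenuine = NA_real_, group = grp, inGenuineClade = NA,
        stopCodons = NA_integer_, nonsynonymous = NA_integer_,
        aaDifferences = NA_integer_,
        notes = "genuine haplotype undetermined", stringsAsFactors = FALSE)
      next
    }
    gRow <- paste(m[gen$genuineId, ], collapse = "")
    cRow <- paste(m[hap, ], collapse = "")   # clone row = its haplotype's row
    dEv <- differenceCount(cRow, gRow, mode = "events")
    dCol <- differenceCount(cRow, gRow, mode = "columns")
    d <- if (cfg@diffMode == "events") dEv else dCol
    k2p <- as.numeric(k2pDistance(classifyColumns(cRow, gRow)))
    inA <- !is.na(grp) && grp == "A"
    label <- if (d == 0L) "genuine"
      else if (is.na(grp)) "ambiguous"
      else if (!inA) "numt"
      else if (d <= cfg@taqMaxDiffs) "pcr_error_variant"
      else if (d >= cfg@heteroplasmyMinDiffs) "heteroplasmy"
      else "ambiguous"
    notes <- character()
    stops <- NA_integer_; nonsyn <- NA_integer_; aaDiff <- NA_integer_
    if (coding) {
      if (is.null(frames[[gen$genuineId]])) {
        gUngap <- gsub("-", "", gRow, fixed = TRUE)
        frames[[gen$genuineId]] <- inferFrame(gUngap)$frame
      }
      ann <- annotateSubstitutions(gRow, cRow,
                                   frame = frames[[gen$genuineId]])
      stops <- ann$cloneStopCount
      nonsyn <- ann$nonsynonymousCount
      aaDiff <- ann$aaDifferences
      if (inA && (stops > 0L || ann$frameshift))
        notes <- c(notes, "pseudogene-like (stop codon or frameshift in group A)")
      if (!inA && !is.na(grp) && stops > 0L)
        notes <- c(notes, sprintf("%d stop codon(s) corroborate NUMT", stops))
    }
    if (inA && !is.na(k2p) && k2p * 100 > radius)
      notes <- c(notes, sprintf("K2P %.3f%% exceeds genuine radius %.1f%%",
                                k2p * 100, radius))
    rows[[k]] <- data.frame(
      id = id, individual = ind, label = label, diffsEvents = dEv,
      diffsColumns = dCol, k2pToGenuine = k2p, group = grp,
      inGenuineClade = inA, stopCodons = stops, nonsynonymous = nonsyn,
      aaDifferences = aaDiff,
      notes = paste(notes, collapse = "; "), stringsAsFactors = FALSE)
  }
  clones <- do.call(rbind, rows)
  gtab <- as.data.frame(table(group = groups$group),
                        stringsAsFactors = FALSE)
  colnames(gtab) <- c("group", "nHaplotypes")
  methods::new("TriageReport", clones = clones, groups = gtab,
               divergence = data.frame(), region = region, config = cfg,
               notes = character())
}

# column-bootstrap SE of the mean cross-group K2P
.bootCrossMean <- function(codes, idxA, idxB, B, seed) {
  sub <- codes[c(idxA, idxB), , drop = FALSE]
  na <- length(idxA)
  crossMean <- function(cd) {
    D <- .k2pMatrixFromCodes(cd)@values
    cells <- D[seq_len(na), na + seq_along(idxB), drop = FALSE]
    if (all(is.na(cells))) NA_real_ else mean(cells, na.rm = TRUE)
  }
  L <- ncol(sub)
  bm <- .withSeed(seed, {
    out <- numeric(B)
    for (b in seq_len(B))
      out[b] <- crossMean(sub[, sample.int(L, L, replace = TRUE),
                              drop = FALSE])
    out
  })
  stats::sd(bm[!is.na(bm)])
}

#' Between-group K2P divergence summary
#'
#' For every pair of groups: min, max and mean of the defined cross-group
#' K2P distances (in percent), a column-bootstrap SE of the mean, and the
#' fraction of undefined pairs.
#'
#' @param alignment trimmed \linkS4class{HaploAlignment}.
#' @param groups data.frame from \code{\link{assignGroups}}.
#' @param d optional precomputed \linkS4class{DistMatrix}.
#' @param B,seed bootstrap replicates and seed for the SE.
#' @return data.frame with one row per group pair.
#' @export
divergenceSummary <- function(alignment, groups, d = NULL, B = 200L,
                              seed = 1L) {
  gs <- sort(unique(groups$group))
  if (length(gs) < 2L) stop("need at least 2 groups")
  if (is.null(d)) d <- k2pMatrix(alignment)
  codes <- .alnCodes(alignment)
  Dpct <- d@values * 100
  out <- list()
  for (i in seq_len(length(gs) - 1L)) for (j in (i + 1L):length(gs)) {
    ga <- groups$id[groups$group == gs[i]]
    gb <- groups$id[groups$group == gs[j]]
    cells <- Dpct[ga, gb, drop = FALSE]
    def <- cells[!is.na(cells)]
    se <- if (length(def)) .bootCrossMean(codes,
                                          match(ga, rownames(codes)),
                                          match(gb, rownames(codes)),
                                          B, seed) * 100 else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      groupA = gs[i], groupB = gs[j],
      min = if (length(def)) min(def) else NA_real_,
      max = if (length(def)) max(def) else NA_real_,
      mean = if (length(def)) mean(def) else NA_real_,
      se = se,
      undefinedFraction = mean(is.na(cells)), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
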