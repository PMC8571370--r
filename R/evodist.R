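# Pairwise-deletion site classification, Kimura two-parameter distances,
# the difference counts behind the polymerase-error / heteroplasmy
# thresholds, and distance matrices with column-bootstrap standard errors.

# run expr under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# encode a row (string or char vector) as integer codes
.rowCodes <- function(x) {
  if (length(x) == 1L && nchar(x[1L]) > 1L)
    x <- strsplit(x, "", fixed = TRUE)[[1L]]
  out <- rep.int(5L, length(x))
  out[x == "-"] <- 0L
  out[x == "A"] <- 1L
  out[x == "C"] <- 2L
  out[x == "G"] <- 3L
  out[x == "T"] <- 4L
  out
}

# core pair counting on integer codes; gap-gap columns ignored, N columns
# excluded from all counts but tallied as ambiguous
.pairCounts <- function(xa, xb) {
  gapgap <- xa == 0L & xb == 0L
  xa <- xa[!gapgap]; xb <- xb[!gapgap]
  amb <- xa == 5L | xb == 5L
  baseA <- xa >= 1L & xa <= 4L
  baseB <- xb >= 1L & xb <= 4L
  both <- baseA & baseB & !amb
  L <- sum(both)
  diffs <- both & xa != xb
  purA <- xa == 1L | xa == 3L
  purB <- xb == 1L | xb == 3L
  nP <- sum(diffs & purA == purB)   # A<->G, C<->T
  nQ <- sum(diffs) - nP
  indelCols <- sum(((xa == 0L) != (xb == 0L)) & !amb)
  runsOf <- function(g) {
    if (!any(g)) return(0L)
    r <- rle(g)
    sum(r$values)
  }
  indelEv <- runsOf(xa == 0L) + runsOf(xb == 0L)
  list(L = L, nP = nP, nQ = nQ, indelCols = indelCols,
       indelEvents = indelEv, ambiguous = sum(amb))
}

#' Classify aligned columns for one pair of rows
#'
#' Pairwise deletion: gap-gap columns are ignored; columns with N in
#' either row are excluded from all counts and reported as ambiguous.
#' Transitions are A<->G and C<->T; transversions all other base
#' mismatches; indel columns have exactly one row gapped, and indel events
#' are maximal gap runs in either row.
#'
#' @param a,b equal-length gapped rows (strings or character vectors).
#' @return a \linkS4class{PairDiff}.
#' @examples
#' classifyColumns("ACGT", "GCGT")
#' @export
classifyColumns <- function(a, b) {
  xa <- .rowCodes(a); xb <- .rowCodes(b)
  if (length(xa) != length(xb)) stop("rows must have equal length")
  k <- .pairCounts(xa, xb)
  methods::new("PairDiff", comparedSites = as.integer(k$L),
               transitions = as.integer(k$nP),
               transversions = as.integer(k$nQ),
               indelColumns = as.integer(k$indelCols),
               indelEvents = as.integer(k$indelEvents),
               ambiguousColumns = as.integer(k$ambiguous))
}

#' Kimura two-parameter distance
#'
#' K = -(1/2) ln[(1 - 2P - Q) sqrt(1 - 2Q)], with P and Q the transition
#' and transversion proportions over the compared sites. Returns
#' \code{NA} with a \code{"reason"} attribute when no sites are
#' comparable or the logarithm's argument is not positive (saturation) --
#' flagged, never silently dropped.
#'
#' @param s a \linkS4class{PairDiff} (or a list with elements \code{L},
#'   \code{nP}, \code{nQ}).
#' @return distance in substitutions/site, or \code{NA}.
#' @examples
#' k2pDistance(classifyColumns("ACGT", "GCGT"))
#' @export
k2pDistance <- function(s) {
  if (methods::is(s, "PairDiff")) {
    L <- s@comparedSites; nP <- s@transitions; nQ <- s@transversions
  } else {
    L <- s$L; nP <- s$nP; nQ <- s$nQ
  }
  if (L == 0L)
    return(structure(NA_real_, reason = "no comparable sites"))
  P <- nP / L; Q <- nQ / L
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0)
    return(structure(NA_real_, reason = "saturated (log argument <= 0)"))
  -0.5 * log(a1 * sqrt(a2))
}

#' Count differences between two aligned rows
#'
#' The threshold currency of the triage rules. In \code{"events"} mode (the
#' default) a contiguous indel counts once (substitution columns + indel
#' events); in \code{"columns"} mode every indel column counts
#' (substitution columns + indel columns).
#'
#' @param a,b equal-length gapped rows.
#' @param mode "events" or "columns".
#' @return integer difference count.
#' @examples
#' differenceCount("AC---GT", "ACTTTGT", mode = "events")   # 1
#' differenceCount("AC---GT", "ACTTTGT", mode = "columns")  # 3
#' @export
differenceCount <- function(a, b, mode = c("events", "columns")) {
  mode <- match.arg(mode)
  s <- classifyColumns(a, b)
  n <- s@transitions + s@transversions
  n + if (mode == "events") s@indelEvents else s@indelColumns
}

#' Pairwise K2P distance matrix under pairwise deletion
#'
#' @param alignment a \linkS4class{HaploAlignment} (>= 2 rows).
#' @return a \linkS4class{DistMatrix}; undefined pairs hold \code{NA} and
#'   are listed in \code{undefinedPairs}.
#' @export
k2pMatrix <- function(alignment) {
  codes <- .alnCodes(alignment)
  .k2pMatrixFromCodes(codes)
}

.k2pMatrixFromCodes <- function(codes) {
  n <- nrow(codes)
  if (n < 2L) stop("need at least 2 rows")
  ids <- rownames(codes)
  k <- .pairCountsAll(codes)
  L <- k$L; P <- k$nP / pmax(k$L, 1L); Q <- k$nQ / pmax(k$L, 1L)
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  D <- -0.5 * log(a1 * sqrt(a2))
  D[L == 0L | a1 <= 0 | a2 <= 0] <- NA_real_
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  bad <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
  up <- if (nrow(bad)) cbind(ids[bad[, 1L]], ids[bad[, 2L]])
    else matrix(character(), 0, 2)
  methods::new("DistMatrix", labels = ids, values = D, undefinedPairs = up)
}

#' Mean pairwise distance with a column-bootstrap standard error
#'
#' The mean is taken over the defined pairwise K2P distances among the
#' selected rows; the SE is the standard deviation of that mean across B
#' column resamples of the alignment (columns drawn with replacement,
#' distances recomputed).
#'
#' @param alignment a \linkS4class{HaploAlignment}.
#' @param labels row ids to include (default: all rows).
#' @param B bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @return list with \code{mean}, \code{se}, \code{nPairs},
#'   \code{nUndefined} (on the original alignment) and
#'   \code{nDiscardedReplicates} (replicates whose mean was undefined).
#' @export
meanDistanceWithSE <- function(alignment, labels = NULL, B = 1000L,
                               seed = 1L) {
  if (B < 100L) stop("B must be >= 100")
  codes <- .alnCodes(alignment)
  if (!is.null(labels)) {
    if (!all(labels %in% rownames(codes)))
      stop("unknown labels: ",
           paste(setdiff(labels, rownames(codes)), collapse = ", "))
    codes <- codes[labels, , drop = FALSE]
  }
  if (nrow(codes) < 2L) stop("need at least 2 rows")
  pairMean <- function(cd) {
    D <- .k2pMatrixFromCodes(cd)@values
    v <- D[upper.tri(D)]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  D0 <- .k2pMatrixFromCodes(codes)
  v0 <- D0@values[upper.tri(D0@values)]
  m0 <- if (all(is.na(v0))) NA_real_ else mean(v0, na.rm = TRUE)
  L <- ncol(codes)
  bm <- .withSeed(seed, {
    out <- numeric(B)
    for (b in seq_len(B)) {
      cols <- sample.int(L, L, replace = TRUE)
      out[b] <- pairMean(codes[, cols, drop = FALSE])
    }
    out
  })
  dropped <- sum(is.na(bm))
  list(mean = m0, se = stats::sd(bm[!is.na(bm)]),
       nPairs = length(v0), nUndefined = sum(is.na(v0)),
       nDiscardedReplicates = dropped)
}

#' Write a distance matrix as square TSV
#'
#' Header row and column of ids; undefined distances written as "NA".
#'
#' @param d a \linkS4class{DistMatrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDistMatrix <- function(d, path) {
  m <- d@values
  df <- data.frame(id = d@labels, m, check.names = FALSE)
  colnames(df) <- c("id", d@labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
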