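#' Accessors for triage data objects
#'
#' Small accessor family: \code{seqIds}, \code{seqRegion},
#' \code{seqIndividual}, \code{seqRole} read a \linkS4class{HaploSet}'s
#' metadata; \code{alnSeqs}, \code{alnWidth}, \code{alnLabels} read a
#' \linkS4class{HaploAlignment}; \code{distLabels}, \code{distValues},
#' \code{undefinedPairs} read a \linkS4class{DistMatrix};
#' \code{cloneTable}, \code{groupTable}, \code{divergenceTable} read a
#' \linkS4class{TriageReport}; \code{truthTemplates} and
#' \code{truthClasses} read a \linkS4class{SimTruth}.
#'
#' @param x the object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
seqIds <- function(x) names(x)

#' @rdname accessors
#' @export
seqRegion <- function(x) S4Vectors::mcols(x)$region

#' @rdname accessors
#' @export
seqIndividual <- function(x) S4Vectors::mcols(x)$individual

#' @rdname accessors
#' @export
seqRole <- function(x) S4Vectors::mcols(x)$role

#' @rdname accessors
#' @export
alnSeqs <- function(x) x@seqs

#' @rdname accessors
#' @export
alnWidth <- function(x) Biostrings::width(x@seqs)[1L]

#' @rdname accessors
#' @export
alnLabels <- function(x) names(x@seqs)

#' @rdname accessors
#' @export
distLabels <- function(x) x@labels

#' @rdname accessors
#' @export
distValues <- function(x) x@values

#' @rdname accessors
#' @export
undefinedPairs <- function(x) x@undefinedPairs

#' @rdname accessors
#' @export
cloneTable <- function(x) x@clones

#' @rdname accessors
#' @export
groupTable <- function(x) x@groups

#' @rdname accessors
#' @export
divergenceTable <- function(x) x@divergence

#' @rdname accessors
#' @export
truthTemplates <- function(x) x@templates

#' @rdname accessors
#' @export
truthClasses <- function(x) S4Vectors::mcols(x@templates)$class

#' @rdname accessors
#' @export
truthWeights <- function(x) S4Vectors::mcols(x@templates)$weight

# character matrix view of an alignment (rows = sequences)
.alnMatrix <- function(aln) {
  seqs <- if (methods::is(aln, "HaploAlignment")) aln@seqs else aln
  m <- do.call(rbind, strsplit(as.character(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

# integer-coded alignment: A=1 C=2 G=3 T=4, gap=0, N/other=5
.alnCodes <- function(aln) {
  m <- .alnMatrix(aln)
  codes <- matrix(5L, nrow(m), ncol(m), dimnames = dimnames(m))
  codes[m == "-"] <- 0L
  codes[m == "A"] <- 1L
  codes[m == "C"] <- 2L
  codes[m == "G"] <- 3L
  codes[m == "T"] <- 4L
  codes
}

setMethod("show", "HaploSet", function(object) {
  cat("HaploSet of", length(object), "sequences (",
      paste(unique(seqRegion(object)), collapse = "/"), ")\n")
  roles <- table(seqRole(object))
  cat("  roles:", paste(names(roles), roles, sep = "=", collapse = ", "), "\n")
  cat("  widths:", paste(range(Biostrings::width(object)), collapse = "-"),
      "nt\n")
})

setMethod("show", "HaploAlignment", function(object) {
  cat("HaploAlignment:", length(object@seqs), "rows x", alnWidth(object),
      "columns\n")
  if (length(object@provenance) && nzchar(object@provenance[1L]))
    cat("  provenance:", object@provenance[1L], "\n")
})

setMethod("show", "PairDiff", function(object) {
  cat("PairDiff: L =", object@comparedSites,
      "| transitions =", object@transitions,
      "| transversions =", object@transversions,
      "| indel columns =", object@indelColumns,
      "| indel events =", object@indelEvents,
      "| ambiguous =", object@ambiguousColumns, "\n")
})

setMethod("show", "DistMatrix", function(object) {
  cat("DistMatrix:", length(object@labels), "labels,",
      nrow(object@undefinedPairs), "undefined pair(s)\n")
})

setMethod("show", "TriageReport", function(object) {
  cat("TriageReport (", object@region, "): ", nrow(object@clones),
      " clones\n", sep = "")
  print(table(object@clones$label))
})

setMethod("show", "SimTruth", function(object) {
  cls <- table(truthClasses(object))
  cat("SimTruth:", length(object@templates), "templates (",
      paste(names(cls), cls, sep = "=", collapse = ", "), ")\n")
})

setMethod("show", "PeakProfile", function(object) {
  cat("PeakProfile:", length(object@multiplicity), "columns, threshold",
      object@threshold, "\n")
  cat("  multiplicity:",
      paste(names(table(object@multiplicity)), table(object@multiplicity),
            sep = "x", collapse = ", "), "\n")
})
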