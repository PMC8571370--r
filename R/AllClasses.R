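#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom Biostrings DNAStringSet
NULL

#' Sequence collection with clone-library metadata
#'
#' A \code{HaploSet} is a \linkS4class{DNAStringSet} whose element metadata
#' carry the fields the triage pipeline needs: a free-text
#' \code{description}, the mitochondrial \code{region} (\code{"COI"},
#' \code{"12S"}, \code{"Dloop"} or \code{"other"}), the source
#' \code{individual}, and the \code{role} of each sequence
#' (\code{"direct"}, \code{"clone"}, \code{"genuine"}, \code{"reference"}
#' or \code{"simulated"}).
#'
#' Sequence names are the record ids and must be unique; residues are
#' restricted to \code{A,C,G,T,N,-}.
#'
#' @export
setClass("HaploSet", contains = "DNAStringSet")

.REGIONS <- c("COI", "12S", "Dloop", "other")
.ROLES   <- c("direct", "clone", "genuine", "reference", "simulated")

setValidity("HaploSet", function(object) {
  msg <- character()
  if (length(object) == 0L)
    msg <- c(msg, "HaploSet must contain at least one sequence")
  nm <- names(object)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    msg <- c(msg, "all sequences must be named (ids)")
  else if (anyDuplicated(nm))
    msg <- c(msg, paste0("duplicate ids: ",
                         paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  if (any(Biostrings::width(object) == 0L))
    msg <- c(msg, "sequences must be nonempty")
  mc <- S4Vectors::mcols(object)
  need <- c("description", "region", "individual", "role")
  if (is.null(mc) || !all(need %in% colnames(mc))) {
    msg <- c(msg, paste0("metadata columns required: ",
                         paste(need, collapse = ", ")))
  } else {
    if (!all(mc$region %in% .REGIONS))
      msg <- c(msg, "region must be one of COI, 12S, Dloop, other")
    if (!all(mc$role %in% .ROLES))
      msg <- c(msg, "role must be one of direct, clone, genuine, reference, simulated")
  }
  bad <- .illegalLetters(object)
  if (length(bad))
    msg <- c(msg, paste0("illegal symbols in: ", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a HaploSet
#'
#' @param x a named character vector of sequences or a
#'   \linkS4class{DNAStringSet}.
#' @param region,individual,role metadata, recycled across sequences.
#' @param description free-text per-sequence description (defaults to the
#'   ids).
#' @return a \linkS4class{HaploSet}.
#' @examples
#' hs <- HaploSet(c(a = "ACGT", b = "ACGA"), region = "COI", role = "clone")
#' seqIds(hs)
#' @export
HaploSet <- function(x, region = "other", individual = "",
                     role = "clone", description = NULL) {
  if (is.character(x)) {
    x <- toupper(x)
    x <- Biostrings::DNAStringSet(chartr("U", "T", x))
  }
  if (is.null(description)) description <- names(x)
  if (is.null(description)) description <- character(length(x))
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(
    description = rep_len(as.character(description), length(x)),
    region = rep_len(as.character(region), length(x)),
    individual = rep_len(as.character(individual), length(x)),
    role = rep_len(as.character(role), length(x)))
  methods::new("HaploSet", x)
}

.illegalLetters <- function(x) {
  ok <- c("A", "C", "G", "T", "N", "-")
  freq <- Biostrings::alphabetFrequency(x)
  bad <- rowSums(freq[, setdiff(colnames(freq), ok), drop = FALSE])
  names(x)[bad > 0]
}

#' Alignment parameters
#'
#' Scoring scheme for the affine-gap aligner: a gap of length k costs
#' \code{gapOpen + k * gapExtend}.
#'
#' @slot match,mismatch per-column substitution scores (match > mismatch).
#' @slot gapOpen,gapExtend nonnegative gap penalties.
#' @export
setClass("AlignParams", representation(
  match = "numeric", mismatch = "numeric",
  gapOpen = "numeric", gapExtend = "numeric"))

setValidity("AlignParams", function(object) {
  msg <- character()
  if (object@gapOpen < 0 || object@gapExtend < 0)
    msg <- c(msg, "gap penalties must be >= 0")
  if (object@match <= object@mismatch)
    msg <- c(msg, "match score must exceed mismatch score")
  if (length(msg)) msg else TRUE
})

#' @param match,mismatch,gapOpen,gapExtend see slots. Defaults are
#'   ClustalW-like DNA settings (+2/-1, open 5, extend 2); fragments that
#'   are >90\% identical are insensitive to them, but divergent noncoding
#'   pseudogene groups may need gentler gap costs.
#' @return an \code{AlignParams} object.
#' @rdname AlignParams-class
#' @export
alignParams <- function(match = 2, mismatch = -1, gapOpen = 5, gapExtend = 2) {
  methods::new("AlignParams", match = match, mismatch = mismatch,
               gapOpen = gapOpen, gapExtend = gapExtend)
}

#' Multiple sequence alignment of haplotypes
#'
#' Equal-length gapped sequences plus a provenance note. Row metadata are
#' inherited from the input \linkS4class{HaploSet}.
#'
#' @slot seqs gapped \linkS4class{DNAStringSet}, equal widths.
#' @slot provenance free text describing how the alignment was built.
#' @export
setClass("HaploAlignment", representation(
  seqs = "DNAStringSet", provenance = "character"))

setValidity("HaploAlignment", function(object) {
  w <- Biostrings::width(object@seqs)
  msg <- character()
  if (length(w) == 0L || any(w < 1L)) msg <- c(msg, "alignment must be nonempty")
  if (length(unique(w)) > 1L) msg <- c(msg, "all rows must have equal length")
  nm <- names(object@seqs)
  if (is.null(nm) || anyDuplicated(nm)) msg <- c(msg, "rows must have unique names")
  if (length(msg)) msg else TRUE
})

#' Pairwise site-difference summary
#'
#' Column classification for one pair of aligned rows under pairwise
#' deletion: \code{comparedSites} is the number of columns where both rows
#' carry an unambiguous base, \code{transitions}/\code{transversions} count
#' the substituted ones, \code{indelColumns} the columns where exactly one
#' row is gapped, \code{indelEvents} the maximal gap runs in either row,
#' and \code{ambiguousColumns} the columns dropped because either row is N.
#'
#' @export
setClass("PairDiff", representation(
  comparedSites = "integer", transitions = "integer",
  transversions = "integer", indelColumns = "integer",
  indelEvents = "integer", ambiguousColumns = "integer"))

setValidity("PairDiff", function(object) {
  s <- object@transitions + object@transversions
  if (s > object@comparedSites)
    return("transitions + transversions cannot exceed compared sites")
  if (any(c(object@comparedSites, object@transitions, object@transversions,
            object@indelColumns, object@indelEvents,
            object@ambiguousColumns) < 0L))
    return("all counts must be nonnegative")
  TRUE
})

#' Pairwise distance matrix with undefined-pair bookkeeping
#'
#' Symmetric matrix of evolutionary distances (substitutions/site); pairs
#' where the distance formula is inapplicable (saturation, no comparable
#' sites) hold \code{NA} and are listed in \code{undefinedPairs}.
#'
#' @export
setClass("DistMatrix", representation(
  labels = "character", values = "matrix", undefinedPairs = "matrix"))

setValidity("DistMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v) || nrow(v) != length(object@labels))
    msg <- c(msg, "label count must equal matrix dimension")
  if (!isTRUE(all.equal(v, t(v))) && !all(is.na(v) == is.na(t(v))))
    msg <- c(msg, "matrix must be symmetric")
  if (any(diag(v) != 0, na.rm = TRUE)) msg <- c(msg, "diagonal must be zero")
  if (any(v < 0, na.rm = TRUE)) msg <- c(msg, "distances must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Triage thresholds and switches
#'
#' @slot taqMaxDiffs maximal difference count t attributed to polymerase
#'   error (default 2: clones at 1--2 differences from their genuine
#'   haplotype are called \code{pcr_error_variant}).
#' @slot heteroplasmyMinDiffs minimal difference count for a heteroplasmy
#'   call (default 3).
#' @slot genuineRadius per-region K2P percentage within which group-A
#'   clones are expected to sit (COI 2.5, 12S 2.5, Dloop 5.0); exceeding
#'   it adds an evidence note.
#' @slot groupLinkCutoff per-region single-linkage K2P percentage cutoff
#'   for grouping haplotypes (COI 5.0, 12S 1.0, Dloop 10.0).
#' @slot minGenuineSupport clone multiplicity required to call a genuine
#'   haplotype without a direct sequence (default 2).
#' @slot useTreeClades when TRUE the genuine group is read off the
#'   bootstrap-supported clade containing the genuine haplotypes.
#' @slot diffMode "events" (a contiguous indel counts once; default) or
#'   "columns".
#' @export
setClass("TriageConfig", representation(
  taqMaxDiffs = "integer", heteroplasmyMinDiffs = "integer",
  genuineRadius = "numeric", groupLinkCutoff = "numeric",
  minGenuineSupport = "integer", useTreeClades = "logical",
  diffMode = "character"))

setValidity("TriageConfig", function(object) {
  msg <- character()
  if (object@taqMaxDiffs < 0L ||
      object@taqMaxDiffs >= object@heteroplasmyMinDiffs)
    msg <- c(msg, "need 0 <= taqMaxDiffs < heteroplasmyMinDiffs")
  if (any(object@genuineRadius <= 0) || any(object@groupLinkCutoff <= 0))
    msg <- c(msg, "radii and cutoffs must be > 0")
  if (!object@diffMode %in% c("events", "columns"))
    msg <- c(msg, "diffMode must be 'events' or 'columns'")
  if (length(msg)) msg else TRUE
})

#' @param taqMaxDiffs,heteroplasmyMinDiffs,genuineRadius,groupLinkCutoff,minGenuineSupport,useTreeClades,diffMode
#'   see the class slots.
#' @return a \code{TriageConfig}.
#' @rdname TriageConfig-class
#' @export
triageConfig <- function(taqMaxDiffs = 2L, heteroplasmyMinDiffs = 3L,
                         genuineRadius = c(COI = 2.5, `12S` = 2.5, Dloop = 5.0,
                                           other = 2.5),
                         groupLinkCutoff = c(COI = 5.0, `12S` = 1.0,
                                             Dloop = 10.0, other = 5.0),
                         minGenuineSupport = 2L, useTreeClades = TRUE,
                         diffMode = "events") {
  methods::new("TriageConfig",
               taqMaxDiffs = as.integer(taqMaxDiffs),
               heteroplasmyMinDiffs = as.integer(heteroplasmyMinDiffs),
               genuineRadius = genuineRadius,
               groupLinkCutoff = groupLinkCutoff,
               minGenuineSupport = as.integer(minGenuineSupport),
               useTreeClades = useTreeClades,
               diffMode = diffMode)
}

#' Per-clone triage report
#'
#' @slot clones one row per input clone: label (genuine |
#'   pcr_error_variant | heteroplasmy | numt | ambiguous), difference
#'   counts to the individual's genuine haplotype (events and columns),
#'   K2P distance, group id, clade membership, stop-codon and
#'   nonsynonymous counts, and free-text evidence notes.
#' @slot groups per-haplotype group assignment with member counts.
#' @slot divergence between-group K2P summaries (min/max/mean +/- SE, in
#'   percent).
#' @export
setClass("TriageReport", representation(
  clones = "data.frame", groups = "data.frame", divergence = "data.frame",
  region = "character", config = "TriageConfig", notes = "character"))

#' Electropherogram peak profile
#'
#' Per alignment column, the summed template weight reaching each symbol,
#' the set of nucleotides at or above the detection threshold, the
#' resulting peak multiplicity (1--4), and a gap-disruption flag where gap
#' mass itself reaches the threshold (frame-slip wrecking downstream
#' signal).
#'
#' @export
setClass("PeakProfile", representation(
  weightsByBase = "matrix", peaks = "list", multiplicity = "integer",
  gapDisrupted = "logical", threshold = "numeric", topRowBase = "character"))

setValidity("PeakProfile", function(object) {
  if (length(object@multiplicity) != ncol(object@weightsByBase))
    return("multiplicity length must equal column count")
  if (any(object@multiplicity < 0L | object@multiplicity > 4L))
    return("multiplicity must lie in 0..4")
  TRUE
})

#' Simulator configuration
#'
#' Study-condition defaults for the synthetic clone-library generator: a
#' coding fragment of 807 bp (the genuine COI haplotype length) or a
#' noncoding one of 820 bp; base composition A .31 / C .18 / G .17 / T .34
#' (AT-rich arthropod mtDNA); two heteroplasmic templates at 3--10
#' substitutions and 5\% copy fraction each; three NUMT loci at 7--24\%
#' (coding) or 7--70\% (noncoding) expected divergence with indels, 2\%
#' weight each; transition bias kappa = 4; Taq error rate 1e-4 per base
#' per synthesis (documented range 7.2e-5--1e-4) over 35 cycles; 30
#' sampled clones.
#'
#' @export
setClass("SimConfig", representation(
  regionKind = "character", fragmentLength = "integer",
  baseComposition = "numeric", nHeteroplasmic = "integer",
  heteroplasmyDiffRange = "integer", heteroplasmyFraction = "numeric",
  nNumtLoci = "integer", numtDivergenceRange = "numeric",
  numtIndelRate = "numeric", indelMeanLength = "numeric",
  numtWeight = "numeric", kappa = "numeric", taqErrorRate = "numeric",
  cycles = "integer", amplificationModel = "character",
  efficiency = "numeric", nClones = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  rates <- c(object@heteroplasmyFraction, object@numtIndelRate,
             object@numtWeight, object@taqErrorRate, object@efficiency)
  if (any(rates < 0 | rates > 1)) msg <- c(msg, "rates must lie in [0,1]")
  wt <- object@nHeteroplasmic * object@heteroplasmyFraction +
    object@nNumtLoci * object@numtWeight
  if (wt > 1) msg <- c(msg, "template weights exceed 1; nothing left for the genuine template")
  if (diff(object@heteroplasmyDiffRange) < 0 ||
      diff(object@numtDivergenceRange) < 0)
    msg <- c(msg, "ranges must be ordered low..high")
  if (!object@regionKind %in% c("coding", "noncoding"))
    msg <- c(msg, "regionKind must be 'coding' or 'noncoding'")
  if (!object@amplificationModel %in% c("genealogy", "binomial"))
    msg <- c(msg, "amplificationModel must be 'genealogy' or 'binomial'")
  if (length(msg)) msg else TRUE
})

#' @param regionKind "coding" or "noncoding".
#' @param fragmentLength template length in bp (default 807 coding, 820
#'   noncoding).
#' @param baseComposition named A/C/G/T frequencies.
#' @param nHeteroplasmic,heteroplasmyDiffRange,heteroplasmyFraction
#'   heteroplasmic template count, substitution-count range, copy fraction
#'   per template.
#' @param nNumtLoci,numtDivergenceRange,numtIndelRate,indelMeanLength,numtWeight
#'   NUMT locus count, expected substitutions/site range, per-site indel
#'   rate, geometric mean indel length, copy fraction per locus.
#' @param kappa transition bias (relative rate of the transition vs each
#'   transversion).
#' @param taqErrorRate,cycles polymerase substitution rate per base per
#'   synthesis and PCR cycle count.
#' @param amplificationModel "genealogy" (reference) or "binomial" (fast
#'   approximation).
#' @param efficiency per-cycle copying probability (genealogy model).
#' @param nClones clones sampled from the final pool.
#' @param seed integer seed; all randomness flows from it.
#' @return a \code{SimConfig}.
#' @rdname SimConfig-class
#' @export
simConfig <- function(regionKind = c("coding", "noncoding"),
                      fragmentLength = NULL,
                      baseComposition = c(A = 0.31, C = 0.18, G = 0.17, T = 0.34),
                      nHeteroplasmic = 2L,
                      heteroplasmyDiffRange = c(3L, 10L),
                      heteroplasmyFraction = 0.05,
                      nNumtLoci = 3L,
                      numtDivergenceRange = NULL,
                      numtIndelRate = NULL,
                      indelMeanLength = 2,
                      numtWeight = 0.02,
                      kappa = 4,
                      taqErrorRate = 1e-4,
                      cycles = 35L,
                      amplificationModel = c("genealogy", "binomial"),
                      efficiency = 0.8,
                      nClones = 30L,
                      seed = 1L) {
  regionKind <- match.arg(regionKind)
  coding <- regionKind == "coding"
  if (is.null(fragmentLength)) fragmentLength <- if (coding) 807L else 820L
  if (is.null(numtDivergenceRange))
    numtDivergenceRange <- if (coding) c(0.07, 0.24) else c(0.07, 0.70)
  if (is.null(numtIndelRate)) numtIndelRate <- if (coding) 0.001 else 0.005
  methods::new("SimConfig", regionKind = regionKind,
               fragmentLength = as.integer(fragmentLength),
               baseComposition = baseComposition / sum(baseComposition),
               nHeteroplasmic = as.integer(nHeteroplasmic),
               heteroplasmyDiffRange = as.integer(heteroplasmyDiffRange),
               heteroplasmyFraction = heteroplasmyFraction,
               nNumtLoci = as.integer(nNumtLoci),
               numtDivergenceRange = numtDivergenceRange,
               numtIndelRate = numtIndelRate,
               indelMeanLength = indelMeanLength,
               numtWeight = numtWeight, kappa = kappa,
               taqErrorRate = taqErrorRate, cycles = as.integer(cycles),
               amplificationModel = match.arg(amplificationModel),
               efficiency = efficiency, nClones = as.integer(nClones),
               seed = as.integer(seed))
}

#' Simulator ground truth
#'
#' Template sequences with class labels (genuine | heteroplasmic | numt)
#' and copy-fraction weights, the per-template mutation ledger (replayable
#' operation list), and the genuine reading frame for coding fragments.
#'
#' @export
setClass("SimTruth", representation(
  templates = "DNAStringSet", ledger = "list", frame = "integer",
  config = "SimConfig"))
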