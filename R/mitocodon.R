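# Invertebrate mitochondrial code (NCBI translation table 5) diagnostics:
# translation, reading-frame inference by stop-codon scan, and per-
# substitution codon-position / synonymy annotation against a genuine row.

.geneticCode <- function(id = "5") Biostrings::getGeneticCode(id)

# translate one codon (character of length 3) under the table; codons
# containing N (or gap) -> "X"
.translateCodons <- function(codons, code) {
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Translate under the invertebrate mitochondrial code
#'
#' NCBI translation table 5 (ATA -> M, TGA -> W, AGA/AGG -> S; stops TAA
#' and TAG only). The trailing partial codon is ignored; codons containing
#' N translate to X; stops appear as \code{*}.
#'
#' @param seq ungapped nucleotide text.
#' @param frame 0, 1 or 2 (offset from the fragment start).
#' @param codeId NCBI genetic-code id (default "5").
#' @return amino-acid string.
#' @examples
#' translateMito("ATATGATAA")  # "MW*"
#' @export
translateMito <- function(seq, frame = 0L, codeId = "5") {
  seq <- toupper(as.character(seq)[[1L]])
  if (grepl("-", seq, fixed = TRUE)) stop("sequence must be ungapped")
  if (nchar(seq) < frame + 3L) stop("sequence too short for frame ", frame)
  s <- substr(seq, frame + 1L, nchar(seq))
  ncod <- nchar(s) %/% 3L
  starts <- (seq_len(ncod) - 1L) * 3L + 1L
  codons <- substring(s, starts, starts + 2L)
  paste(.translateCodons(codons, .geneticCode(codeId)), collapse = "")
}

#' Infer the reading frame by minimizing internal stop codons
#'
#' Scans all three frames and returns the one with the fewest internal
#' stops (ties go to the smallest offset). When every frame contains a
#' stop the result is flagged pseudogene-like.
#'
#' @param seq ungapped nucleotide text (>= 30 nt).
#' @param codeId NCBI genetic-code id (default "5").
#' @return list with \code{frame}, \code{stopCounts} (all three frames),
#'   and \code{pseudogeneLike}.
#' @export
inferFrame <- function(seq, codeId = "5") {
  seq <- toupper(as.character(seq)[[1L]])
  if (nchar(seq) < 30L) stop("sequence too short to infer a frame")
  stops <- vapply(0:2, function(f) {
    aa <- translateMito(seq, f, codeId)
    sum(strsplit(aa, "", fixed = TRUE)[[1L]] == "*")
  }, integer(1))
  frame <- which.min(stops) - 1L
  list(frame = frame, stopCounts = stats::setNames(stops, paste0("frame", 0:2)),
       pseudogeneLike = all(stops > 0L))
}

#' Annotate substitutions between a genuine row and a clone row
#'
#' Codon bookkeeping runs on the genuine row's coordinates in the given
#' frame; clone indels never re-frame the genuine row. Each substituted
#' column is annotated with its codon position (1--3), a transition flag,
#' and a synonymy flag (the genuine codon vs the codon carrying the
#' clone's aligned bases; NA when the clone codon is incomplete).
#' Frameshifting indels (gap-run length not divisible by 3) mark the
#' clone's translation unreliable.
#'
#' @param genuine,clone equal-length gapped rows; \code{genuine} sets the
#'   codon frame.
#' @param frame frame offset of the genuine row (0/1/2).
#' @param codeId NCBI genetic-code id (default "5").
#' @return list with \code{substitutions} (data.frame: column,
#'   codonPosition, transition, synonymous), \code{nonsynonymousCount},
#'   \code{aaDifferences} (differing residues between the two
#'   translations over complete codons), \code{cloneStopCount},
#'   \code{frameshift} flag.
#' @export
annotateSubstitutions <- function(genuine, clone, frame = 0L, codeId = "5") {
  vg <- strsplit(as.character(genuine)[[1L]], "", fixed = TRUE)[[1L]]
  vc <- strsplit(as.character(clone)[[1L]], "", fixed = TRUE)[[1L]]
  if (length(vg) != length(vc)) stop("rows must have equal length")
  code <- .geneticCode(codeId)
  # genuine coordinates: codon index/position per alignment column
  gpos <- cumsum(vg != "-")            # genuine residue index per column
  inFrame <- gpos > frame & vg != "-"
  codonIdx <- ifelse(inFrame, (gpos - frame - 1L) %/% 3L + 1L, NA_integer_)
  codonPos <- ifelse(inFrame, (gpos - frame - 1L) %% 3L + 1L, NA_integer_)
  bases <- c("A", "C", "G", "T")
  subCols <- which(vg %in% bases & vc %in% bases & vg != vc)
  pur <- c(A = TRUE, C = FALSE, G = TRUE, T = FALSE)
  ann <- lapply(subCols, function(col) {
    ci <- codonIdx[col]
    syn <- NA
    if (!is.na(ci)) {
      cols3 <- which(codonIdx == ci)            # alignment columns of codon
      if (length(cols3) == 3L) {
        gcod <- paste(vg[cols3], collapse = "")
        ccod <- paste(vc[cols3], collapse = "")
        if (!grepl("[^ACGT]", ccod))
          syn <- identical(unname(code[gcod]), unname(code[ccod]))
      }
    }
    data.frame(column = col, codonPosition = codonPos[col],
               transition = pur[vg[col]] == pur[vc[col]],
               synonymous = syn)
  })
  subs <- if (length(ann)) do.call(rbind, ann)
    else data.frame(column = integer(), codonPosition = integer(),
                    transition = logical(), synonymous = logical())
  # full-codon translations for amino-acid difference count
  ncod <- max(c(0L, codonIdx), na.rm = TRUE)
  aaDiff <- 0L; stopCount <- 0L
  if (ncod > 0L) {
    gAA <- cAA <- character(ncod)
    for (ci in seq_len(ncod)) {
      cols3 <- which(codonIdx == ci)
      if (length(cols3) != 3L) { gAA[ci] <- cAA[ci] <- "X"; next }
      gcod <- paste(vg[cols3], collapse = "")
      ccod <- paste(vc[cols3], collapse = "")
      gAA[ci] <- if (grepl("[^ACGT]", gcod)) "X" else unname(code[gcod])
      cAA[ci] <- if (grepl("[^ACGT]", ccod)) "X" else unname(code[ccod])
    }
    comp <- gAA != "X" & cAA != "X"
    aaDiff <- sum(gAA[comp] != cAA[comp])
    stopCount <- sum(cAA == "*")
  }
  # frameshift: any single-row gap run with length not divisible by 3
  frameshift <- FALSE
  for (v in list(vg, vc)) {
    r <- rle(v == "-")
    runs <- r$lengths[r$values]
    if (any(runs %% 3L != 0L)) { frameshift <- TRUE; break }
  }
  nonsyn <- sum(!subs$synonymous, na.rm = TRUE)
  list(substitutions = subs, nonsynonymousCount = nonsyn,
       aaDifferences = aaDiff, cloneStopCount = stopCount,
       frameshift = frameshift)
}

#' Stop-codon scan of an ungapped sequence in a given frame
#'
#' @param seq ungapped nucleotide text.
#' @param frame 0/1/2.
#' @param codeId NCBI genetic-code id.
#' @return integer count of internal stop codons.
#' @export
countStops <- function(seq, frame = 0L, codeId = "5") {
  aa <- translateMito(seq, frame, codeId)
  sum(strsplit(aa, "", fixed = TRUE)[[1L]] == "*")
}
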