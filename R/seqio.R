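#' Primer pair
#'
#' Both primers are written 5'->3' on their own strands, 15--30 bases of
#' A/C/G/T.
#'
#' @slot forward,reverse primer sequences.
#' @slot name label for the pair.
#' @export
setClass("PrimerPair", representation(
  forward = "character", reverse = "character", name = "character"))

setValidity("PrimerPair", function(object) {
  msg <- character()
  for (p in c(object@forward, object@reverse)) {
    if (!nzchar(p)) msg <- c(msg, "primers must be nonempty")
    else if (grepl("[^ACGT]", p)) msg <- c(msg, "primers must be A/C/G/T only")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' @param forward,reverse,name see slots.
#' @return a \code{PrimerPair}.
#' @rdname PrimerPair-class
#' @export
primerPair <- function(forward, reverse, name = "") {
  methods::new("PrimerPair", forward = toupper(forward),
               reverse = toupper(reverse), name = name)
}

#' The spiny-lobster primer set
#'
#' The six semi-species-specific primers used to amplify the COI, 12S and
#' Dloop regions of *Panulirus japonicus* mtDNA; expected product sizes on
#' the reference mitogenome are 935, 802 and 863 bp.
#'
#' @return named list of three \linkS4class{PrimerPair} objects
#'   (\code{COI}, \code{12S}, \code{Dloop}).
#' @examples
#' panulirusPrimers()$COI
#' @export
panulirusPrimers <- function() {
  list(
    COI = primerPair("ACGCAACGATGATTTTTCTCTAC", "ACAGCAATAATTATGGTTGCCG",
                     "PanJCOIF/PanJCOIR"),
    `12S` = primerPair("TTAATGAAAGCGACGGGCAA", "CCTATAGTTTGATTCTTGCTA",
                       "PanJ12SF/PanJ12SR"),
    Dloop = primerPair("TAGCAAGAATCAAACTATAG", "ACATTACTTGCTCTATCAAA",
                       "PanJ12SF2/PanJtRNAR"))
}

#' Read sequences from a FASTA file
#'
#' Headers are split at the first whitespace into id and description;
#' lowercase residues are upper-cased and U is mapped to T. Symbols outside
#' \code{A,C,G,T,N,-} raise an error naming the sequence and offset, and
#' duplicate ids raise an error naming them.
#'
#' @param path FASTA file.
#' @param region,role,individual metadata attached to every record.
#' @return a \linkS4class{HaploSet}.
#' @export
readFastaRecords <- function(path, region = "other", role = "clone",
                             individual = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids))
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  txt <- chartr("u", "t", toupper(as.character(raw)))
  txt <- chartr("U", "T", txt)
  bad <- regexpr("[^ACGTN-]", txt)
  if (any(bad > 0)) {
    k <- which(bad > 0)[1L]
    stop("illegal symbol '", substr(txt[k], bad[k], bad[k]), "' in entry '",
         ids[k], "' at position ", bad[k])
  }
  names(txt) <- ids
  HaploSet(txt, region = region, individual = individual, role = role,
           description = headers)
}

#' Write sequences to a FASTA file
#'
#' Round-trip safe with \code{\link{readFastaRecords}}: ids and residues
#' are preserved exactly.
#'
#' @param records a \linkS4class{HaploSet} (or any named
#'   \linkS4class{DNAStringSet}).
#' @param path output file.
#' @param width line width for the sequence body.
#' @return \code{path}, invisibly.
#' @export
writeFastaRecords <- function(records, path, width = 60L) {
  if (length(records) == 0L) stop("no records to write")
  out <- Biostrings::DNAStringSet(
    stats::setNames(as.character(records), names(records)))
  Biostrings::writeXStringSet(out, path, width = as.integer(width))
  invisible(path)
}

.hamming <- function(a, b) {
  # N anywhere counts as mismatch (conservative primer matching)
  va <- strsplit(a, "", fixed = TRUE)[[1L]]
  vb <- strsplit(b, "", fixed = TRUE)[[1L]]
  sum(va != vb | va == "N" | vb == "N")
}

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# all start positions where `pattern` sits in `subject` within maxMismatch,
# ungapped. N in the subject never matches (fixed = TRUE + N mismatch rule).
.primerSites <- function(pattern, subject, maxMismatch) {
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject),
                                   max.mismatch = maxMismatch,
                                   with.indels = FALSE, fixed = TRUE)
  Biostrings::start(hits)
}

#' Locate a primer-defined amplicon in a template
#'
#' In-silico PCR: the forward primer is matched on the plus strand and the
#' reverse complement of the reverse primer downstream of it; the product
#' runs from the forward primer's 5' end through the reverse footprint,
#' inclusive of both footprints. Primer matching is ungapped Hamming
#' matching; N in the template counts as a mismatch. Circular templates
#' are searched across the origin.
#'
#' @param template a single-sequence \linkS4class{HaploSet} or a character
#'   string.
#' @param primers a \linkS4class{PrimerPair}.
#' @param maxMismatch mismatches tolerated per primer site.
#' @param circular treat the template as circular (reference mitogenomes).
#' @return a list with \code{product} (a \linkS4class{HaploSet} record
#'   including both primer footprints), \code{start}, \code{end} (1-based
#'   template coordinates; \code{end} exceeds the template length when the
#'   product spans the origin) and \code{length}.
#' @export
findAmplicon <- function(template, primers, maxMismatch = 0L,
                         circular = FALSE) {
  stopifnot(methods::is(primers, "PrimerPair"))
  if (methods::is(template, "XStringSet") || methods::is(template, "HaploSet")) {
    stopifnot(length(template) == 1L)
    id <- names(template)[1L]
    seq <- as.character(template)[[1L]]
  } else {
    seq <- toupper(as.character(template)[[1L]])
    id <- "template"
  }
  L <- nchar(seq)
  rcrev <- .revcomp(primers@reverse)
  search <- if (circular) paste0(seq, seq) else seq
  fstarts <- .primerSites(primers@forward, search, maxMismatch)
  if (circular) fstarts <- fstarts[fstarts <= L]
  rstarts <- .primerSites(rcrev, search, maxMismatch)
  if (length(fstarts) == 0L || length(rstarts) == 0L)
    stop("no amplicon: primer site(s) not found within ", maxMismatch,
         " mismatch(es)")
  rend <- rstarts + nchar(rcrev) - 1L
  cand <- list()
  for (f in fstarts) {
    e <- rend[rend >= f + nchar(primers@forward) & rend - f + 1L <= L]
    if (length(e)) cand[[length(cand) + 1L]] <- cbind(start = f, end = e)
  }
  if (length(cand) == 0L)
    stop("no amplicon: no reverse footprint downstream of a forward site")
  cand <- do.call(rbind, cand)
  if (nrow(cand) > 1L)
    stop("multiple candidate products at [",
         paste(sprintf("%d-%d", cand[, "start"], cand[, "end"]),
               collapse = ", "), "]")
  f <- cand[1L, "start"]; e <- cand[1L, "end"]
  prod <- substr(search, f, e)
  out <- HaploSet(stats::setNames(prod, paste0(id, "_amplicon")),
                  region = "other", role = "reference",
                  description = sprintf("%s amplicon %d-%d (%s)", id, f, e,
                                        primers@name))
  list(product = out, start = unname(f), end = unname(e),
       length = nchar(prod))
}

#' Trim primer footprints from amplicon sequences
#'
#' Removes the forward primer from the 5' end and the reverse-complemented
#' reverse primer from the 3' end of each record, when each footprint is
#' recognizable within \code{maxMismatch} (ungapped Hamming).
#'
#' @param records a \linkS4class{HaploSet}.
#' @param primers a \linkS4class{PrimerPair}.
#' @param maxMismatch mismatches tolerated per footprint.
#' @param strict if TRUE a missing footprint is an error; otherwise the
#'   record is left untrimmed at that end with a warning.
#' @return the trimmed \linkS4class{HaploSet}.
#' @export
trimPrimers <- function(records, primers, maxMismatch = 0L, strict = FALSE) {
  stopifnot(methods::is(primers, "PrimerPair"))
  fwd <- primers@forward
  rcrev <- .revcomp(primers@reverse)
  nf <- nchar(fwd); nr <- nchar(rcrev)
  txt <- as.character(records)
  for (i in seq_along(txt)) {
    s <- txt[[i]]
    hasF <- nchar(s) >= nf && .hamming(substr(s, 1L, nf), fwd) <= maxMismatch
    hasR <- nchar(s) >= nr &&
      .hamming(substr(s, nchar(s) - nr + 1L, nchar(s)), rcrev) <= maxMismatch
    if (!hasF || !hasR) {
      what <- paste(c(if (!hasF) "forward", if (!hasR) "reverse"),
                    collapse = " and ")
      if (strict)
        stop("primer footprint (", what, ") not found in '",
             names(records)[i], "'")
      warning("primer footprint (", what, ") not found in '",
              names(records)[i], "'; left untrimmed at that end")
    }
    if (hasR) s <- substr(s, 1L, nchar(s) - nr)
    if (hasF) s <- substr(s, nf + 1L, nchar(s))
    txt[[i]] <- s
  }
  mc <- S4Vectors::mcols(records)
  HaploSet(txt, region = mc$region, individual = mc$individual,
           role = mc$role, description = mc$description)
}
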