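# Synthetic clone-library generator: ground-truth template pools
# (genuine / heteroplasmic / NUMT) and PCR amplification with per-cycle
# polymerase error, so every pipeline stage is testable without any
# external data.

.BASES <- c("A", "C", "G", "T")

# kappa-biased point change: the transition partner has relative rate
# kappa, each of the two transversion partners rate 1
.mutateBase <- function(base, kappa) {
  ts <- c(A = "G", G = "A", C = "T", T = "C")[[base]]
  tv <- setdiff(.BASES, c(base, ts))
  sample(c(ts, tv), 1L, prob = c(kappa, 1, 1))
}

#' Read a simulator configuration from a key:value text file
#'
#' The file holds \code{key: value} lines (YAML subset) whose keys are
#' the arguments of \code{\link{simConfig}}, e.g. \code{regionKind:
#' coding}, \code{nClones: 30}, \code{seed: 1}; vector-valued arguments
#' take YAML lists. Unknown keys raise an error.
#'
#' @param path config file.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfigFromFile <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown simulator config key(s): ", paste(bad, collapse = ", "))
  do.call(simConfig, lapply(vals, function(v)
    if (is.list(v)) unlist(v) else v))
}

#' Replay a mutation ledger
#'
#' Applies the recorded operations (substitutions, insertions, deletions)
#' in order to a sequence; replaying a template's ledger on the genuine
#' sequence reproduces the template exactly.
#'
#' @param seq character string.
#' @param ops list of operations, each a list with \code{type}
#'   ("sub"/"ins"/"del") and its fields (\code{pos}, \code{from},
#'   \code{to}, \code{seq}, \code{len}).
#' @return the mutated sequence.
#' @export
applyMutationLedger <- function(seq, ops) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (op in ops) {
    if (op$type == "sub") {
      if (!is.null(op$from) && v[op$pos] != op$from)
        stop("ledger mismatch at position ", op$pos)
      v[op$pos] <- op$to
    } else if (op$type == "ins") {
      v <- append(v, strsplit(op$seq, "", fixed = TRUE)[[1L]], after = op$pos)
    } else if (op$type == "del") {
      v <- v[-(op$pos:(op$pos + op$len - 1L))]
    } else stop("unknown ledger op: ", op$type)
  }
  paste(v, collapse = "")
}

.randomSeq <- function(L, comp) {
  paste(sample(.BASES, L, replace = TRUE, prob = comp), collapse = "")
}

.internalStops <- function(seq) {
  if (nchar(seq) < 3L) return(0L)
  countStops(seq, frame = 0L)
}

# u distinct-site substitutions, kappa-biased; returns list(seq, ops)
.substituteSites <- function(seq, u, kappa) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sort(sample.int(length(v), u))
  ops <- vector("list", u)
  for (k in seq_along(pos)) {
    to <- .mutateBase(v[pos[k]], kappa)
    ops[[k]] <- list(type = "sub", pos = pos[k], from = v[pos[k]], to = to)
    v[pos[k]] <- to
  }
  list(seq = paste(v, collapse = ""), ops = ops)
}

# divergence-d mutation: Binomial(L, d) substitution events placed with
# replacement (multiple hits allowed, so the K2P-corrected distance
# estimates d), then Poisson indel events with geometric lengths
.numtMutate <- function(seq, d, cfg) {
  L0 <- nchar(seq)
  nSub <- stats::rbinom(1L, L0, d)
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ops <- list()
  if (nSub > 0L) for (k in seq_len(nSub)) {
    p <- sample.int(length(v), 1L)
    to <- .mutateBase(v[p], cfg@kappa)
    ops[[length(ops) + 1L]] <- list(type = "sub", pos = p, from = v[p], to = to)
    v[p] <- to
  }
  nInd <- stats::rpois(1L, L0 * cfg@numtIndelRate)
  frameshift <- FALSE
  if (nInd > 0L) for (k in seq_len(nInd)) {
    len <- stats::rgeom(1L, 1 / cfg@indelMeanLength) + 1L
    if (len %% 3L != 0L) frameshift <- TRUE
    if (stats::runif(1L) < 0.5 && length(v) > len + 1L) {
      p <- sample.int(length(v) - len, 1L)
      ops[[length(ops) + 1L]] <- list(type = "del", pos = p, len = len)
      v <- v[-(p:(p + len - 1L))]
    } else {
      p <- sample.int(length(v) + 1L, 1L) - 1L
      ins <- paste(sample(.BASES, len, replace = TRUE,
                          prob = cfg@baseComposition), collapse = "")
      ops[[length(ops) + 1L]] <- list(type = "ins", pos = p, seq = ins)
      v <- append(v, strsplit(ins, "", fixed = TRUE)[[1L]], after = p)
    }
  }
  list(seq = paste(v, collapse = ""), ops = ops, frameshift = frameshift,
       nIndels = nInd)
}

#' Generate ground-truth templates
#'
#' Draws the genuine sequence from the configured base composition (for
#' coding fragments, codons are resampled until frame 0 carries no
#' internal stop under the invertebrate mitochondrial code); builds
#' heteroplasmic templates at a uniform 3--10 substitutions (distinct
#' sites, transition-biased) and NUMT templates mutated to a drawn target
#' divergence (Binomial(L, d) substitution events with multiple hits
#' allowed) plus Poisson indel events. Coding NUMTs at divergence >= 0.10
#' are redrawn (up to 100 times) until they carry a frameshift or an
#' internal stop, then flagged if still clean. Every mutation is
#' ledgered and replayable.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return a \linkS4class{SimTruth}.
#' @export
generateTruth <- function(cfg) {
  methods::validObject(cfg)
  .withSeed(cfg@seed, {
    L <- cfg@fragmentLength
    coding <- cfg@regionKind == "coding"
    genuine <- .randomSeq(L, cfg@baseComposition)
    if (coding) {
      v <- strsplit(genuine, "", fixed = TRUE)[[1L]]
      repeat {
        ncod <- L %/% 3L
        starts <- (seq_len(ncod) - 1L) * 3L + 1L
        codons <- substring(paste(v, collapse = ""), starts, starts + 2L)
        bad <- which(codons %in% c("TAA", "TAG"))
        if (length(bad) == 0L) break
        for (b in bad)
          v[starts[b]:(starts[b] + 2L)] <-
            sample(.BASES, 3L, replace = TRUE, prob = cfg@baseComposition)
      }
      genuine <- paste(v, collapse = "")
    }
    seqs <- c(genuine = genuine)
    classes <- "genuine"
    ledger <- list(genuine = list())
    targetDiv <- NA_real_
    if (cfg@nHeteroplasmic > 0L) for (k in seq_len(cfg@nHeteroplasmic)) {
      u <- sample(seq(cfg@heteroplasmyDiffRange[1L],
                      cfg@heteroplasmyDiffRange[2L]), 1L)
      r <- .substituteSites(genuine, u, cfg@kappa)
      nm <- paste0("het", k)
      seqs[nm] <- r$seq
      classes <- c(classes, "heteroplasmic")
      ledger[[nm]] <- r$ops
      targetDiv <- c(targetDiv, NA_real_)
    }
    flagged <- character()
    if (cfg@nNumtLoci > 0L) for (k in seq_len(cfg@nNumtLoci)) {
      d <- stats::runif(1L, cfg@numtDivergenceRange[1L],
                        cfg@numtDivergenceRange[2L])
      r <- NULL
      for (try in seq_len(100L)) {
        r <- .numtMutate(genuine, d, cfg)
        if (!coding || d < 0.10) break
        if (r$frameshift || .internalStops(r$seq) > 0L) break
        r <- NULL
      }
      if (is.null(r)) {     # no disrupted draw found; accept and flag
        r <- .numtMutate(genuine, d, cfg)
        flagged <- c(flagged, paste0("numt", k))
      }
      nm <- paste0("numt", k)
      seqs[nm] <- r$seq
      classes <- c(classes, "numt")
      ledger[[nm]] <- r$ops
      targetDiv <- c(targetDiv, d)
    }
    w <- c(1 - cfg@nHeteroplasmic * cfg@heteroplasmyFraction -
             cfg@nNumtLoci * cfg@numtWeight,
           rep(cfg@heteroplasmyFraction, cfg@nHeteroplasmic),
           rep(cfg@numtWeight, cfg@nNumtLoci))
    tpl <- Biostrings::DNAStringSet(seqs)
    S4Vectors::mcols(tpl) <- S4Vectors::DataFrame(
      class = classes, weight = w, targetDivergence = targetDiv,
      flaggedClean = names(seqs) %in% flagged)
    methods::new("SimTruth", templates = tpl, ledger = ledger,
                 frame = if (coding) 0L else NA_integer_, config = cfg)
  })
}

# one synthesis round: Binomial(L, mu) substitutions at distinct sites
.taqRound <- function(v, mu, kappa) {
  k <- stats::rbinom(1L, length(v), mu)
  pos <- if (k > 0L) sample.int(length(v), k) else integer()
  for (p in pos) v[p] <- .mutateBase(v[p], kappa)
  list(v = v, pos = pos)
}

#' Simulate a PCR clone library from ground truth
#'
#' The genealogy model (reference) tracks the molecule pool forward --
#' 1000 template molecules drawn by weight, each cycle every molecule
#' copied with the per-cycle efficiency -- and samples each sequenced
#' clone's synthesis history backward through the recorded pool sizes;
#' every synthesis event adds Binomial(length, mu) substitutions. The
#' binomial model is the fast approximation: template by weight, synthesis
#' depth s ~ Binomial(cycles, 1/2), then s error rounds. Every clone
#' carries its true template label and error count.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param cfg its \linkS4class{SimConfig} (or an override).
#' @return list with \code{clones} (a \linkS4class{HaploSet}) and
#'   \code{provenance} (data.frame: id, template, class, synthesisDepth,
#'   errorCount).
#' @export
simulatePcrLibrary <- function(truth, cfg = truth@config) {
  tpl <- truth@templates
  labels <- names(tpl)
  classes <- S4Vectors::mcols(tpl)$class
  w <- S4Vectors::mcols(tpl)$weight
  txt <- as.character(tpl)
  .withSeed((cfg@seed + 1L) %% .Machine$integer.max, {
    n <- cfg@nClones
    if (cfg@amplificationModel == "genealogy") {
      poolInit <- 1000L
      counts <- stats::rmultinom(1L, poolInit, w)[, 1L]
      N <- numeric(cfg@cycles + 1L)
      births <- numeric(cfg@cycles)
      N[1L] <- poolInit
      for (cyc in seq_len(cfg@cycles)) {
        if (cfg@efficiency == 0 && n > N[cyc])
          stop("pool extinction: cannot sample ", n, " from ", N[cyc])
        births[cyc] <- stats::rbinom(1L, N[cyc], cfg@efficiency)
        N[cyc + 1L] <- N[cyc] + births[cyc]
      }
      depth <- vapply(seq_len(n), function(i) {
        s <- 0L
        for (cyc in rev(seq_len(cfg@cycles)))
          if (stats::runif(1L) < births[cyc] / N[cyc + 1L]) s <- s + 1L
        s
      }, integer(1))
      tmplIdx <- sample(seq_along(labels), n, replace = TRUE,
                        prob = counts / sum(counts))
    } else {
      depth <- stats::rbinom(n, cfg@cycles, 0.5)
      tmplIdx <- sample(seq_along(labels), n, replace = TRUE, prob = w)
    }
    seqs <- character(n)
    errs <- integer(n)
    for (i in seq_len(n)) {
      v <- strsplit(txt[tmplIdx[i]], "", fixed = TRUE)[[1L]]
      e <- 0L
      if (depth[i] > 0L) for (s in seq_len(depth[i])) {
        r <- .taqRound(v, cfg@taqErrorRate, cfg@kappa)
        v <- r$v
        e <- e + length(r$pos)
      }
      seqs[i] <- paste(v, collapse = "")
      errs[i] <- e
    }
    ids <- sprintf("clone%03d", seq_len(n))
    region <- if (cfg@regionKind == "coding") "COI" else "Dloop"
    clones <- HaploSet(stats::setNames(seqs, ids), region = region,
                       individual = "sim1", role = "clone")
    prov <- data.frame(id = ids, template = labels[tmplIdx],
                       class = classes[tmplIdx], synthesisDepth = depth,
                       errorCount = errs, stringsAsFactors = FALSE)
    list(clones = clones, provenance = prov)
  })
}

#' Write a simulated fixture to disk
#'
#' Emits \code{direct.fasta} (the genuine template standing in for the
#' direct-sequencing read), \code{clones.fasta}, and \code{truth.tsv}
#' (clone id, template, class, error count) -- enough to run the full
#' pipeline. Identical configurations produce byte-identical files.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param library result of \code{\link{simulatePcrLibrary}}.
#' @param outDir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
emitFixture <- function(truth, library, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  region <- if (truth@config@regionKind == "coding") "COI" else "Dloop"
  direct <- HaploSet(
    stats::setNames(as.character(truth@templates)["genuine"], "sim1-direct"),
    region = region, individual = "sim1", role = "direct")
  paths <- c(direct = file.path(outDir, "direct.fasta"),
             clones = file.path(outDir, "clones.fasta"),
             truth = file.path(outDir, "truth.tsv"))
  writeFastaRecords(direct, paths["direct"])
  writeFastaRecords(library$clones, paths["clones"])
  utils::write.table(library$provenance, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
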