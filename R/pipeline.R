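# Per-region orchestration: ingest -> primer trim -> length filter ->
# dedupe haplotypes -> progressive alignment -> trim-to-window -> K2P
# matrix -> NJ + bootstrap -> codon diagnostics (COI) -> genuine
# determination -> grouping -> clone labels -> divergence summary ->
# electropherogram peak prediction -> reports.

.asHaploSet <- function(x, region, role) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L)
    readFastaRecords(x, region = region, role = role)
  else x
}

#' Run the full analysis for one region
#'
#' Executes the whole triage workflow on a set of clones plus optional
#' direct-sequencing reads and reference/outgroup sequences. Clones whose
#' insert length deviates more than \code{lengthTolerance} from the
#' region's expected size (the direct read's length, or the median clone
#' length) are excluded up front and listed. Identical clone sequences
#' are collapsed to one haplotype before alignment; every clone is still
#' reported individually.
#'
#' @param clones a \linkS4class{HaploSet} or FASTA path (clone library).
#' @param direct optional \linkS4class{HaploSet}/path of direct reads
#'   (one per individual; ids must differ from clone ids).
#' @param references optional \linkS4class{HaploSet}/path of reference or
#'   outgroup sequences (excluded from grouping; first id used to root).
#' @param region region name ("COI", "12S", "Dloop", "other").
#' @param primers optional \linkS4class{PrimerPair} for primer trimming.
#' @param cfg a \linkS4class{TriageConfig}.
#' @param params an \linkS4class{AlignParams}.
#' @param B bootstrap replicates for tree support and divergence SEs.
#' @param seed integer seed for all resampling.
#' @param lengthTolerance relative insert-length deviation tolerated.
#' @param peakThreshold detection threshold for the electropherogram
#'   model.
#' @param outDir optional output directory (reports written when given).
#' @param formats report formats, subset of c("tsv", "json").
#' @return list with \code{report} (a \linkS4class{TriageReport}),
#'   \code{alignment}, \code{dist}, \code{tree}, \code{peaks},
#'   \code{genuine} (per-individual results), \code{haplotypeOf}
#'   (clone -> haplotype map), \code{excluded} (length-filtered clone
#'   ids) and \code{log} (decision log lines).
#' @export
runRegion <- function(clones, direct = NULL, references = NULL,
                      region = "COI", primers = NULL,
                      cfg = triageConfig(), params = alignParams(),
                      B = 200L, seed = 1L, lengthTolerance = 0.2,
                      peakThreshold = 0.10, outDir = NULL,
                      formats = c("tsv", "json")) {
  logLines <- character()
  say <- function(...) {
    line <- sprintf(...)
    logLines <<- c(logLines, line)
    invisible(line)
  }
  clones <- .asHaploSet(clones, region, "clone")
  direct <- .asHaploSet(direct, region, "direct")
  references <- .asHaploSet(references, region, "reference")
  if (is.null(clones) || length(clones) == 0L) stop("no clones supplied")
  # individuals must be non-empty keys for per-individual bookkeeping
  fixInd <- function(x) {
    ind <- S4Vectors::mcols(x)$individual
    ind[is.na(ind) | ind == ""] <- "unspecified"
    S4Vectors::mcols(x)$individual <- ind
    x
  }
  clones <- fixInd(clones)
  if (!is.null(direct)) direct <- fixInd(direct)
  say("region %s: %d clones, %d direct, %d references", region,
      length(clones), length(direct), length(references))
  if (!is.null(primers)) {
    clones <- trimPrimers(clones, primers)
    if (!is.null(direct)) direct <- trimPrimers(direct, primers)
    say("primers trimmed (%s)", primers@name)
  }
  # length filter against the expected insert size
  expected <- if (!is.null(direct))
    stats::median(Biostrings::width(direct))
  else stats::median(Biostrings::width(clones))
  dev <- abs(Biostrings::width(clones) - expected) / expected
  excluded <- names(clones)[dev > lengthTolerance]
  if (length(excluded)) {
    say("excluded %d clone(s) with insert length deviating > %.0f%% from %d bp: %s",
        length(excluded), lengthTolerance * 100, round(expected),
        paste(excluded, collapse = ", "))
    clones <- clones[!names(clones) %in% excluded]
  }
  if (length(clones) == 0L) stop("all clones removed by the length filter")
  # collapse identical clone sequences to haplotypes
  txt <- as.character(clones)
  firstOf <- tapply(names(clones), txt, function(ids) sort(ids)[1L])
  haplotypeOf <- stats::setNames(unname(firstOf[txt]), names(clones))
  hapIds <- sort(unique(unname(haplotypeOf)))
  say("%d clones collapse to %d haplotypes", length(clones), length(hapIds))
  haps <- clones[hapIds]
  pool <- haps
  if (!is.null(direct)) pool <- .bindSets(pool, direct)
  if (!is.null(references)) pool <- .bindSets(pool, references)
  if (length(pool) < 2L) stop("need at least 2 sequences to align")
  aln <- progressiveAlign(pool, params)
  if (!is.null(direct)) {
    aln <- trimToWindow(aln, names(direct))
    say("alignment trimmed to the window of the shortest direct read")
  }
  d <- k2pMatrix(aln)
  if (nrow(d@undefinedPairs))
    say("%d sequence pair(s) have undefined K2P (saturation)",
        nrow(d@undefinedPairs))
  tree <- NULL
  if (length(pool) >= 4L) {
    tree <- tryCatch(bootstrapSupport(aln, B = max(B, 100L), seed = seed),
                     error = function(e) {
                       say("tree skipped: %s", conditionMessage(e))
                       NULL
                     })
    if (!is.null(tree)) say("NJ tree with %d bootstrap replicates", max(B, 100L))
  }
  # genuine haplotype per individual
  inds <- unique(seqIndividual(clones))
  genuine <- list()
  for (ind in inds) {
    cIds <- unique(haplotypeOf[names(clones)[seqIndividual(clones) == ind]])
    dId <- if (!is.null(direct)) {
      cand <- names(direct)[seqIndividual(direct) == ind]
      if (length(cand)) cand[1L] else NULL
    } else NULL
    genuine[[ind]] <- tryCatch(
      identifyGenuine(aln, cIds, directId = dId, cfg = cfg),
      error = function(e) {
        say("individual %s: %s", ind, conditionMessage(e))
        list(status = "undetermined", genuineId = NA_character_,
             supportIds = character())
      })
    if (!is.na(genuine[[ind]]$genuineId))
      say("individual %s: genuine haplotype %s (supported by %d clone haplotype match(es))",
          ind, genuine[[ind]]$genuineId, length(genuine[[ind]]$supportIds))
  }
  genuineIds <- unlist(lapply(genuine, function(g) g$genuineId))
  genuineIds <- unique(genuineIds[!is.na(genuineIds)])
  outgroup <- if (!is.null(references)) names(references) else NULL
  nonRef <- setdiff(d@labels, c(if (!is.null(direct)) names(direct), outgroup))
  dHap <- .subsetDist(d, c(nonRef, outgroup))
  groups <- if (length(genuineIds)) {
    assignGroups(dHap, genuineIds, cfg = cfg, region = region,
                 tree = tree, outgroup = outgroup)
  } else data.frame(id = nonRef, group = NA_character_)
  say("groups: %s", paste(sprintf("%s=%d", names(table(groups$group)),
                                  table(groups$group)), collapse = ", "))
  cloneInfo <- data.frame(id = names(clones),
                          individual = seqIndividual(clones),
                          haplotype = unname(haplotypeOf[names(clones)]),
                          stringsAsFactors = FALSE)
  report <- classifyClones(aln, cloneInfo, genuine, groups, cfg = cfg,
                           region = region, coding = region == "COI")
  say("labels: %s", paste(sprintf("%s=%d", names(table(report@clones$label)),
                                  table(report@clones$label)),
                          collapse = ", "))
  say("thresholds applied: taqMaxDiffs=%d heteroplasmyMinDiffs=%d groupLinkCutoff=%.1f%% diffMode=%s",
      cfg@taqMaxDiffs, cfg@heteroplasmyMinDiffs,
      cfg@groupLinkCutoff[[if (region %in% names(cfg@groupLinkCutoff))
        region else "other"]], cfg@diffMode)
  if (length(unique(groups$group[!is.na(groups$group)])) >= 2L) {
    report@divergence <- divergenceSummary(aln, groups, d = d,
                                           B = max(B, 100L), seed = seed)
  }
  # electropherogram prediction: clone-frequency weights per haplotype
  hapCounts <- table(factor(haplotypeOf, levels = alnLabels(aln)))
  weights <- as.numeric(hapCounts) / sum(hapCounts)
  peaks <- predictSiteSignals(aln, weights, threshold = peakThreshold)
  mp <- multipeakCounts(peaks)
  say("predicted peaks: %d double, %d triple, %d gap-disrupted sites",
      mp["nDouble"], mp["nTriple"], mp["nGapDisrupted"])
  report@notes <- logLines
  out <- list(report = report, alignment = aln, dist = d, tree = tree,
              peaks = peaks, genuine = genuine, haplotypeOf = haplotypeOf,
              excluded = excluded, log = logLines)
  if (!is.null(outDir)) writeReports(out, outDir, formats = formats)
  out
}

.bindSets <- function(a, b) {
  seqs <- c(stats::setNames(as.character(a), names(a)),
            stats::setNames(as.character(b), names(b)))
  mc <- rbind(as.data.frame(S4Vectors::mcols(a)),
              as.data.frame(S4Vectors::mcols(b)))
  HaploSet(seqs, region = mc$region, individual = mc$individual,
           role = mc$role, description = mc$description)
}

.subsetDist <- function(d, ids) {
  keep <- match(ids, d@labels)
  up <- d@undefinedPairs
  if (nrow(up))
    up <- up[up[, 1L] %in% ids & up[, 2L] %in% ids, , drop = FALSE]
  methods::new("DistMatrix", labels = ids,
               values = d@values[keep, keep, drop = FALSE],
               undefinedPairs = up)
}

#' Write the artifacts of a region run
#'
#' Emits, per requested format, the clone report (TSV and/or JSON), the
#' group and divergence tables, the Newick tree (supports >= 60 shown),
#' the trimmed alignment as FASTA, the distance matrix as TSV, and a run
#' log echoing every threshold applied plus the package version.
#'
#' @param result the list returned by \code{\link{runRegion}}.
#' @param outDir output directory (created if needed).
#' @param formats subset of c("tsv", "json").
#' @return character vector of written paths, invisibly.
#' @export
writeReports <- function(result, outDir, formats = c("tsv", "json")) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  report <- result$report
  region <- report@region
  paths <- character()
  put <- function(p) { paths <<- c(paths, p); p }
  if ("tsv" %in% formats) {
    utils::write.table(report@clones,
                       put(file.path(outDir, paste0(region, "_clones.tsv"))),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report@groups,
                       put(file.path(outDir, paste0(region, "_groups.tsv"))),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(report@divergence))
      utils::write.table(report@divergence,
                         put(file.path(outDir,
                                       paste0(region, "_divergence.tsv"))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    writeDistMatrix(result$dist,
                    put(file.path(outDir, paste0(region, "_k2p.tsv"))))
  }
  if ("json" %in% formats) {
    js <- list(region = region,
               clones = report@clones,
               groups = report@groups,
               divergence = report@divergence,
               excluded = result$excluded)
    jsonlite::write_json(js,
                         put(file.path(outDir, paste0(region, "_report.json"))),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(result$tree))
    writeLines(toNewick(result$tree, supportThreshold = 60),
               put(file.path(outDir, paste0(region, "_nj.nwk"))))
  writeFastaRecords(result$alignment@seqs,
                    put(file.path(outDir, paste0(region, "_alignment.fasta"))))
  ver <- tryCatch(as.character(utils::packageVersion("numtriage")),
                  error = function(e) "dev")
  writeLines(c(sprintf("numtriage %s", ver), result$log),
             put(file.path(outDir, paste0(region, "_run.log"))))
  invisible(paths)
}

#' Run several regions, isolating failures
#'
#' Each element of \code{regions} is a named list of arguments for
#' \code{\link{runRegion}} (the region name is taken from the element
#' name). A failing region is reported and skipped; the others proceed.
#'
#' @param regions named list of argument lists.
#' @param ... shared arguments forwarded to every region.
#' @return named list of per-region results (or \code{try-error}s).
#' @export
runPipeline <- function(regions, ...) {
  shared <- list(...)
  out <- list()
  for (rg in names(regions)) {
    args <- c(regions[[rg]], list(region = rg), shared)
    out[[rg]] <- tryCatch(do.call(runRegion, args), error = function(e) {
      warning("region ", rg, " failed: ", conditionMessage(e))
      e
    })
  }
  out
}
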