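# End-to-end orchestration: genome QC -> clustering -> core selection ->
# alignment -> consensus -> candidate design -> degeneracy filter ->
# two-stage specificity screen -> report.

#' Filter genomes on assembly quality metadata
#'
#' Applies the standard genome QC rule: keep genomes with completeness of at
#' least \code{minCompleteness} percent and contamination of at most
#' \code{maxContamination} percent (boundary values are retained; the
#' filtered side is completeness below 90 or contamination above 5).
#' QC metrics are consumed as metadata (e.g. CheckM output), not computed.
#'
#' @param qc \code{data.frame} with columns \code{genomeId},
#'   \code{completeness}, \code{contamination} (percent).
#' @param minCompleteness minimum completeness, percent (default 90).
#' @param maxContamination maximum contamination, percent (default 5).
#' @return Character vector of retained genome ids.
#' @export
filterGenomesByQC <- function(qc, minCompleteness = 90,
                              maxContamination = 5) {
  need <- c("genomeId", "completeness", "contamination")
  if (!all(need %in% names(qc)))
    stop("qc table needs columns genomeId, completeness, contamination",
         call. = FALSE)
  if (anyDuplicated(qc$genomeId))
    stop("one QC record per genome required", call. = FALSE)
  keep <- qc$completeness >= minCompleteness &
    qc$contamination <= maxContamination
  as.character(qc$genomeId[keep])
}

# deterministic quality penalty used to rank candidate pairs before
# screening (smaller is better): distance of both primers from the Tm
# optimum, pair Tm difference, length deviation from the optimum, and the
# log2 pool sizes
.pair_penalty <- function(pairs, constraints) {
  abs(pairs$fwdTm - constraints$tmOpt) +
    abs(pairs$revTm - constraints$tmOpt) +
    abs(pairs$fwdTm - pairs$revTm) +
    0.25 * (abs(pairs$fwdLen - constraints$lenOpt) +
            abs(pairs$revLen - constraints$lenOpt)) +
    0.5 * (log2(pmax(pairs$fwdDegeneracy, 1L)) +
           log2(pmax(pairs$revDegeneracy, 1L)))
}

#' Run configuration for the primer design pipeline
#'
#' Reads a YAML run configuration. Recognised keys mirror the arguments of
#' \code{\link{runPipeline}}; \code{constraints} and \code{conditions}
#' sub-maps override individual \code{\link{designConstraints}} /
#' \code{\link{reactionConditions}} defaults.
#'
#' @param path path to a YAML file.
#' @return A named list suitable for \code{do.call(runPipeline, .)}.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  for (key in c("ntFasta", "aaFasta", "nonTargetFasta", "qcTable", "outDir",
                "headerDelim", "minIdentity", "minCoverage",
                "maxMismatches", "minHitCoverage", "designProbes",
                "maxWindowsPerCluster", "maxPairsPerCluster",
                "keepRejected"))
    if (!is.null(cfg[[key]])) args[[key]] <- cfg[[key]]
  if (!is.null(cfg$offTargetWindow))
    args$offTargetWindow <- as.integer(unlist(cfg$offTargetWindow))
  if (!is.null(cfg$constraints))
    args$constraints <- do.call(designConstraints, cfg$constraints)
  if (!is.null(cfg$conditions))
    args$conditions <- do.call(reactionConditions, cfg$conditions)
  args
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Design clade-specific degenerate primers end to end
#'
#' Executes the full pipeline on a target-clade gene catalogue: optional
#' genome QC filtering, protein clustering into gene families, single-copy
#' core selection, per-cluster protein alignment, codon-aware
#' back-translation, majority consensus, candidate pair enumeration,
#' degeneracy injection and filtering, optional internal-probe design, and
#' the two-stage off-target screen (target gene catalogue, then non-target
#' sequences). Candidate pairs are ranked by a deterministic quality
#' penalty and at most \code{maxPairsPerCluster} pairs per cluster are
#' carried into screening.
#'
#' The run is fully deterministic: the same inputs and parameters give a
#' byte-identical report. All internal coordinates are 0-based half-open;
#' report coordinates are 1-based inclusive.
#'
#' @param catalog a \code{\linkS4class{GeneCatalog}}, or \code{NULL} to read
#'   one from \code{ntFasta}/\code{aaFasta}.
#' @param ntFasta,aaFasta paths to the target CDS/protein FASTA (used when
#'   \code{catalog} is \code{NULL}).
#' @param nonTarget named sequences (character or \code{DNAStringSet}) for
#'   stage-2 screening, or \code{NULL}.
#' @param nonTargetFasta path to a non-target multi-FASTA (used when
#'   \code{nonTarget} is \code{NULL}).
#' @param qc optional QC \code{data.frame} (see
#'   \code{\link{filterGenomesByQC}}); \code{qcTable} a TSV path
#'   alternative. Genomes without a QC record are retained with a warning.
#' @param qcTable path to a QC TSV.
#' @param outDir output directory, or \code{NULL} to skip writing. Writes
#'   \code{primer_report.tsv}, \code{clusters.tsv},
#'   \code{off_target_amplicons.tsv}, per-cluster alignment FASTA under
#'   \code{alignments/}, and \code{run.log}.
#' @param constraints a \code{\link{designConstraints}} object.
#' @param conditions a \code{\link{reactionConditions}} object.
#' @param minIdentity,minCoverage clustering thresholds (fractions).
#' @param offTargetWindow off-target product size window, bp.
#' @param maxMismatches,minHitCoverage in-silico PCR hit viability.
#' @param designProbes also design internal probes (logical).
#' @param maxWindowsPerCluster best single-primer windows per cluster that
#'   enter pairing (see \code{\link{enumerateCandidates}}; default 60).
#' @param maxPairsPerCluster candidate pairs per cluster carried into
#'   screening (ranked by penalty; default 500).
#' @param keepRejected include rejected pairs in the report (default TRUE).
#' @param headerDelim FASTA header delimiter between genome and gene id.
#' @return (Invisibly) a list with \code{report} (data.frame),
#'   \code{retained}, \code{rejected}, \code{clusters}, \code{coreClusters},
#'   \code{status} (\code{"ok"} or \code{"no_candidates"}) and
#'   \code{params}.
#' @export
runPipeline <- function(catalog = NULL, ntFasta = NULL, aaFasta = NULL,
                        nonTarget = NULL, nonTargetFasta = NULL,
                        qc = NULL, qcTable = NULL, outDir = NULL,
                        constraints = designConstraints(),
                        conditions = reactionConditions(),
                        minIdentity = 0.80, minCoverage = 0.90,
                        offTargetWindow = c(30L, 2000L),
                        maxMismatches = 3L, minHitCoverage = 0.8,
                        designProbes = FALSE,
                        maxWindowsPerCluster = 60L,
                        maxPairsPerCluster = 500L,
                        keepRejected = TRUE,
                        headerDelim = "|") {
  if (is.null(catalog)) {
    if (is.null(ntFasta) || is.null(aaFasta))
      stop("provide a GeneCatalog or ntFasta + aaFasta paths", call. = FALSE)
    catalog <- readGeneCatalog(ntFasta, aaFasta, delim = headerDelim)
  }
  if (is.null(nonTarget) && !is.null(nonTargetFasta)) {
    nonTarget <- readDNAStringSet(nonTargetFasta)
    names(nonTarget) <- sub("\\s.*$", "", names(nonTarget))
  }
  if (is.null(qc) && !is.null(qcTable))
    qc <- utils::read.delim(qcTable, stringsAsFactors = FALSE)

  params <- list(minIdentity = minIdentity, minCoverage = minCoverage,
                 offTargetWindow = offTargetWindow,
                 maxMismatches = maxMismatches,
                 minHitCoverage = minHitCoverage,
                 designProbes = designProbes,
                 maxWindowsPerCluster = maxWindowsPerCluster,
                 maxPairsPerCluster = maxPairsPerCluster,
                 keepRejected = keepRejected,
                 constraints = unclass(constraints),
                 conditions = unclass(conditions))
  log_lines <- c("cladePrimers run",
                 yaml::as.yaml(params))

  # --- genome QC -----------------------------------------------------------
  genomes <- unique(genomeIds(catalog))
  if (!is.null(qc)) {
    keep <- filterGenomesByQC(qc)
    missing_qc <- setdiff(genomes, qc$genomeId)
    if (length(missing_qc)) {
      warning(sprintf("no QC record for genome(s) %s; retained",
                      paste(missing_qc, collapse = ", ")), call. = FALSE)
      keep <- c(keep, missing_qc)
    }
    drop <- setdiff(genomes, keep)
    if (length(drop)) {
      catalog <- catalog[genomeIds(catalog) %in% keep]
      genomes <- unique(genomeIds(catalog))
      log_lines <- c(log_lines,
                     sprintf("qc: dropped %d genome(s): %s", length(drop),
                             paste(drop, collapse = ",")))
    }
  }

  # --- clustering and core selection ---------------------------------------
  clusters <- clusterGenes(catalog, minIdentity, minCoverage)
  core_ids <- selectCoreClusters(clusters, genomes)
  log_lines <- c(log_lines,
                 sprintf("clusters: %d total, %d single-copy core",
                         length(unique(clusters$clusterId)),
                         length(core_ids)))

  finish <- function(report, retained, rejected, status, alignments) {
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      hdr <- "# coordinates are 1-based inclusive on the cluster consensus"
      writeLines(c(hdr, capture_tsv(report)),
                 file.path(outDir, "primer_report.tsv"))
      .write_tsv(clusters, file.path(outDir, "clusters.tsv"))
      # off-target amplicons behind every rejection, one row per pair
      amp <- data.frame(clusterId = integer(0), pairId = character(0),
                        stage = character(0), subjectId = character(0),
                        productLen = integer(0), fwdSeq = character(0),
                        revSeq = character(0), stringsAsFactors = FALSE)
      if ("status" %in% names(report) &&
          any(report$status == "rejected")) {
        rej <- report[report$status == "rejected", , drop = FALSE]
        amp <- data.frame(clusterId = rej$clusterId, pairId = rej$pairId,
                          stage = rej$rejectionStage,
                          subjectId = rej$rejectionSubject,
                          productLen = rej$offTargetLen,
                          fwdSeq = rej$fwdSeq, revSeq = rej$revSeq,
                          stringsAsFactors = FALSE)
      }
      .write_tsv(amp, file.path(outDir, "off_target_amplicons.tsv"))
      if (length(alignments)) {
        adir <- file.path(outDir, "alignments")
        dir.create(adir, showWarnings = FALSE)
        for (cid in names(alignments))
          writeXStringSet(alignments[[cid]],
                          file.path(adir, sprintf("cluster_%s.aln.fna", cid)))
      }
      writeLines(log_lines, file.path(outDir, "run.log"))
    }
    invisible(list(report = report, retained = retained,
                   rejected = rejected, clusters = clusters,
                   coreClusters = core_ids, status = status,
                   params = params))
  }

  empty_report <- data.frame()
  if (!length(core_ids))
    return(finish(empty_report, NULL, NULL, "no_candidates", list()))

  # --- per-cluster design --------------------------------------------------
  all_pairs <- list()
  alignments <- list()
  for (cid in core_ids) {
    members <- clusters$geneId[clusters$clusterId == cid]
    sub_cat <- catalog[members]
    aln <- alignProteinCluster(setNames(as.character(aaSeqs(sub_cat)),
                                        geneIds(sub_cat)))
    cdn <- backTranslateAlignment(aln, sub_cat)
    alignments[[as.character(cid)]] <- codonRows(cdn)
    track <- majorityConsensus(cdn)
    cand <- enumerateCandidates(track, constraints, conditions,
                                maxWindows = maxWindowsPerCluster)
    if (!nrow(cand)) next
    cand <- addDegeneracies(cand, track, constraints$threePrimeWindow)
    cand <- filterDegeneracy(cand, constraints)
    if (!nrow(cand)) next
    if (designProbes)
      cand <- designInternalProbes(cand, track, constraints, conditions)
    cand <- cand[order(.pair_penalty(cand, constraints),
                       cand$fwdStart, cand$productLen,
                       method = "radix"), , drop = FALSE]
    if (nrow(cand) > maxPairsPerCluster)
      cand <- cand[seq_len(maxPairsPerCluster), , drop = FALSE]
    cand$clusterId <- cid
    # mean Tm over the degenerate pool, computed once per unique primer
    pool_tm <- function(seqs) {
      u <- unique(seqs)
      tm <- vapply(u, meanPrimerTm, numeric(1), cond = conditions,
                   max.expansions = constraints$maxExpansions)
      unname(tm[match(seqs, u)])
    }
    cand$fwdMeanTm <- pool_tm(cand$fwdDegSeq)
    cand$revMeanTm <- pool_tm(cand$revDegSeq)
    all_pairs[[as.character(cid)]] <- cand
  }
  if (!length(all_pairs))
    return(finish(empty_report, NULL, NULL, "no_candidates", alignments))
  pairs <- do.call(rbind, all_pairs)
  rownames(pairs) <- NULL

  # --- two-stage specificity screen ---------------------------------------
  screened <- screenPrimerPairs(pairs, catalog, clusters, nonTarget,
                                offTargetWindow, maxMismatches,
                                minHitCoverage)
  log_lines <- c(log_lines,
                 sprintf("screening: %d retained, %d rejected",
                         nrow(screened$retained), nrow(screened$rejected)))

  report <- .build_report(screened, keepRejected)
  status <- if (nrow(screened$retained)) "ok" else "no_candidates"
  finish(report, screened$retained, screened$rejected, status, alignments)
}

# serialize a data.frame as TSV lines (header + rows)
capture_tsv <- function(df) {
  if (!nrow(df)) return(paste(names(df), collapse = "\t"))
  tc <- textConnection("out", "w", local = TRUE)
  utils::write.table(df, tc, sep = "\t", quote = FALSE, row.names = FALSE)
  close(tc)
  out
}

.build_report <- function(screened, keepRejected) {
  fmt <- function(df, status) {
    if (is.null(df) || !nrow(df)) return(NULL)
    out <- data.frame(
      clusterId = df$clusterId,
      pairId = sprintf("c%s_p%d", df$clusterId,
                       stats::ave(seq_len(nrow(df)), df$clusterId,
                                  FUN = seq_along)),
      fwdSeq = df$fwdDegSeq, revSeq = df$revDegSeq,
      fwdLen = df$fwdLen, revLen = df$revLen,
      fwdStart = df$fwdStart + 1L,                 # 1-based inclusive
      fwdEnd = df$fwdStart + df$fwdLen,
      revStart = df$revStart + 1L,
      revEnd = df$revStart + df$revLen,
      productLen = df$productLen,
      fwdMeanTm = round(df$fwdMeanTm, 2), revMeanTm = round(df$revMeanTm, 2),
      fwdDegeneracy = df$fwdDegeneracy, revDegeneracy = df$revDegeneracy,
      fwdDeg3p = df$fwdDeg3p, revDeg3p = df$revDeg3p,
      status = status,
      rejectionStage = if ("stage" %in% names(df)) df$stage
                       else NA_character_,
      rejectionSubject = if ("subjectId" %in% names(df)) df$subjectId
                         else NA_character_,
      offTargetLen = if ("offTargetLen" %in% names(df)) df$offTargetLen
                     else NA_integer_,
      stringsAsFactors = FALSE)
    if ("probeSeq" %in% names(df)) {
      out$probeSeq <- df$probeSeq
      out$probeStart <- ifelse(is.na(df$probeStart), NA_integer_,
                               df$probeStart + 1L)
      out$probeLen <- df$probeLen
    }
    out
  }
  rep_ret <- fmt(screened$retained, "retained")
  rep_rej <- if (keepRejected) fmt(screened$rejected, "rejected") else NULL
  out <- rbind(rep_ret, rep_rej)
  if (is.null(out)) out <- data.frame()
  out
}
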