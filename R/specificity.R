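# In-silico PCR: degenerate-primer binding-site search, amplicon prediction
# and two-stage off-target screening of candidate pairs.

.empty_hits <- function() {
  data.frame(subjectId = character(), strand = character(),
             start = integer(), end = integer(),
             length = integer(), coverage = numeric(),
             mismatches = integer(), stringsAsFactors = FALSE)
}

# mismatch counts of a placement of primer-mask suffix (3'-anchored) at every
# anchor of a subject-mask vector; masks are IUPAC bitmasks.  Returns, for
# allowed placement length l, the vector of mismatch counts at anchors
# (3'-end positions) l..S.  Implemented incrementally: extending a placement
# 5'-ward only adds mismatches.
.scan_anchor_mm <- function(primer_masks, subject_masks, lengths) {
  L <- length(primer_masks)
  S <- length(subject_masks)
  lengths <- sort(lengths)
  out <- vector("list", length(lengths))
  names(out) <- as.character(lengths)
  l0 <- lengths[1L]
  if (l0 > S) return(out)
  # mm[e] for anchors e = l..S, built from the shortest length up
  mm <- rep(0L, S)   # index = anchor position (1-based 3' end)
  for (j in seq_len(l0)) {
    # primer position (from 3' end): offset j-1 upstream of the anchor
    p <- primer_masks[L - j + 1L]
    idx <- seq.int(l0, S)
    mm[idx] <- mm[idx] + as.integer(bitwAnd(p, subject_masks[idx - j + 1L]) == 0L)
  }
  if (l0 > 1L) mm[seq_len(l0 - 1L)] <- NA_integer_
  out[[1L]] <- mm
  prev <- l0
  for (k in seq_along(lengths)[-1L]) {
    l <- lengths[k]
    if (l > S) break
    for (j in seq.int(prev + 1L, l)) {
      p <- primer_masks[L - j + 1L]
      idx <- seq.int(l, S)
      mm[idx] <- mm[idx] + as.integer(bitwAnd(p, subject_masks[idx - j + 1L]) == 0L)
    }
    mm[seq_len(l - 1L)] <- NA_integer_
    out[[k]] <- mm
    prev <- l
  }
  out
}

#' Find viable binding sites of a degenerate primer on a subject
#'
#' Scans both strands of a subject sequence for primer placements under
#' IUPAC compatibility (a primer code matches a subject base when their
#' concrete-base sets intersect). Placements are 3'-anchored: only the 5'
#' end may be truncated (extension by the polymerase requires an intact 3'
#' end), down to the coverage floor -- a placement must cover strictly more
#' than \code{minCoverage} of the primer length to be viable. For every
#' (strand, 3'-anchor) the single longest placement with at most
#' \code{maxMismatches} mismatches is reported (mismatch count can only grow
#' as a placement is extended 5'-ward, so this is well defined). Hits are
#' returned in deterministic order: strand \code{+} before \code{-}, then
#' by start position.
#'
#' @param primer degenerate primer sequence (character scalar, 5'->3').
#' @param subject subject sequence (character scalar or \code{DNAString});
#'   IUPAC codes in the subject are matched compatibly.
#' @param maxMismatches maximum mismatches per placement (default 3).
#' @param minCoverage strict lower bound on covered primer fraction
#'   (default 0.8: a 16/20 placement is not viable, 17/20 is).
#' @return A \code{data.frame} with columns \code{subjectId, strand, start,
#'   end} (0-based half-open on the plus strand), \code{length, coverage,
#'   mismatches}.
#' @export
findPrimerHits <- function(primer, subject, maxMismatches = 3L,
                           minCoverage = 0.8) {
  subject_id <- if (!is.null(names(subject)) && length(subject) == 1L)
    names(subject) else "subject"
  subject <- as.character(subject)
  sm <- .iupac_masks(subject)
  sm_rc <- rev(.complement_masks(sm))
  .find_hits_masks(.iupac_masks(primer), sm, sm_rc, subject_id,
                   maxMismatches, minCoverage)
}

# complement of a bitmask vector: swap A<->T (1<->8) and C<->G (2<->4)
.complement_masks <- function(m) {
  bitwOr(bitwOr(bitwShiftL(bitwAnd(m, 1L), 3L),      # A -> T
                bitwShiftR(bitwAnd(m, 8L), 3L)),     # T -> A
         bitwOr(bitwShiftL(bitwAnd(m, 2L), 1L),      # C -> G
                bitwShiftR(bitwAnd(m, 4L), 1L)))     # G -> C
}

# scanner core over precomputed subject masks (plus strand and reverse
# complement); used by findPrimerHits and, with cached masks, by the
# screening loop
.find_hits_masks <- function(pm, sm, sm_rc, subject_id,
                             maxMismatches = 3L, minCoverage = 0.8) {
  L <- length(pm)
  S <- length(sm)
  if (L > S) return(.empty_hits())
  l_min <- floor(minCoverage * L) + 1L    # strictly > minCoverage
  if (l_min > L) l_min <- L
  lengths <- seq.int(l_min, L)

  hits <- list()
  collect <- function(mm_by_len, strand) {
    # per anchor, the longest viable length
    best_len <- rep(0L, S)
    best_mm <- rep(NA_integer_, S)
    for (l in lengths) {
      mm <- mm_by_len[[as.character(l)]]
      if (is.null(mm)) next
      viable <- !is.na(mm) & mm <= maxMismatches
      best_len[viable] <- l
      best_mm[viable] <- mm[viable]
    }
    anchors <- which(best_len > 0L)
    if (!length(anchors)) return()
    if (strand == "+") {
      start0 <- anchors - best_len[anchors]       # 0-based
      end0 <- anchors
    } else {
      # minus-strand scan was done on rc(primer) prefixes anchored at the
      # *left* end; translate back to plus coordinates
      start0 <- S - anchors
      end0 <- start0 + best_len[anchors]
    }
    hits[[length(hits) + 1L]] <<- data.frame(
      subjectId = subject_id, strand = strand,
      start = as.integer(start0), end = as.integer(end0),
      length = best_len[anchors],
      coverage = best_len[anchors] / L,
      mismatches = best_mm[anchors], stringsAsFactors = FALSE)
  }
  collect(.scan_anchor_mm(pm, sm, lengths), "+")
  # minus strand: match rc(primer) prefixes = reversed-complemented suffixes.
  # Scan on the reversed subject-complement so the same suffix machinery
  # applies: align primer suffixes to rc(subject), then map anchors back.
  collect(.scan_anchor_mm(pm, sm_rc, lengths), "-")
  if (!length(hits)) return(.empty_hits())
  out <- do.call(rbind, hits)
  out <- out[order(match(out$strand, c("+", "-")), out$start,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict PCR products from forward and reverse primer hits
#'
#' Pairs every plus-strand forward hit with every minus-strand reverse hit
#' downstream of it on the same subject and reports products whose
#' outer-edge-to-outer-edge length falls within the size window. The
#' product spans from the forward hit's start to the reverse hit's end
#' (both primers included).
#'
#' @param fwdHits,revHits hit tables from \code{\link{findPrimerHits}} for
#'   the forward and reverse primer on the same subject.
#' @param sizeMin,sizeMax product size window (bp).
#' @return A \code{data.frame} with columns \code{subjectId, start, end,
#'   productLen, fwdMismatches, revMismatches}.
#' @export
predictAmplicons <- function(fwdHits, revHits, sizeMin = 30L,
                             sizeMax = 2000L) {
  empty <- data.frame(subjectId = character(), start = integer(),
                      end = integer(), productLen = integer(),
                      fwdMismatches = integer(), revMismatches = integer(),
                      stringsAsFactors = FALSE)
  f <- fwdHits[fwdHits$strand == "+", , drop = FALSE]
  r <- revHits[revHits$strand == "-", , drop = FALSE]
  if (!nrow(f) || !nrow(r)) return(empty)
  res <- list()
  for (i in seq_len(nrow(f))) {
    same <- which(r$subjectId == f$subjectId[i] &
                  r$start >= f$end[i])          # reverse fully downstream
    if (!length(same)) next
    len <- r$end[same] - f$start[i]
    okl <- len >= sizeMin & len <= sizeMax
    if (!any(okl)) next
    res[[length(res) + 1L]] <- data.frame(
      subjectId = f$subjectId[i],
      start = f$start[i], end = r$end[same][okl],
      productLen = as.integer(len[okl]),
      fwdMismatches = f$mismatches[i],
      revMismatches = r$mismatches[same][okl],
      stringsAsFactors = FALSE)
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$subjectId, out$start, out$end, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# memoised per-(primer, subject) hit lookup over a subject mask cache;
# candidate pairs share windows heavily, so each unique primer is scanned
# over each subject at most once per screening run
.hit_memoiser <- function(cache, maxMismatches, minCoverage) {
  hits_env <- new.env(hash = TRUE, parent = emptyenv())
  masks_env <- new.env(hash = TRUE, parent = emptyenv())
  function(primer, sid) {
    key <- paste0(primer, "\r", sid)
    h <- hits_env[[key]]
    if (is.null(h)) {
      pm <- masks_env[[primer]]
      if (is.null(pm)) {
        pm <- .iupac_masks(primer)
        masks_env[[primer]] <- pm
      }
      cs <- cache[[sid]]
      h <- .find_hits_masks(pm, cs$sm, cs$rc, sid, maxMismatches,
                            minCoverage)
      hits_env[[key]] <- h
    }
    h
  }
}

# precompute plus-strand and reverse-complement masks for a set of subjects
.subject_mask_cache <- function(subjects) {
  lapply(subjects, function(s) {
    sm <- .iupac_masks(s)
    list(sm = sm, rc = rev(.complement_masks(sm)))
  })
}

# all amplicons of one primer pair over a cache of subject masks
.pair_amplicons <- function(fwd, rev, cache, sizeMin, sizeMax,
                            maxMismatches, minCoverage,
                            memo = NULL) {
  if (is.null(memo)) memo <- .hit_memoiser(cache, maxMismatches, minCoverage)
  res <- list()
  for (sid in names(cache)) {
    fh <- memo(fwd, sid)
    if (!nrow(fh)) next
    rh <- memo(rev, sid)
    if (!nrow(rh)) next
    # a product needs the forward primer on + and the reverse on -, or the
    # pair annealing in the flipped orientation (fwd on -, rev on +)
    a1 <- predictAmplicons(fh, rh, sizeMin, sizeMax)
    a2 <- predictAmplicons(rh, fh, sizeMin, sizeMax)
    if (nrow(a2)) a2$subjectId <- sid
    res[[length(res) + 1L]] <- rbind(a1, a2)
  }
  if (!length(res)) return(predictAmplicons(.empty_hits(), .empty_hits()))
  do.call(rbind, res)
}

#' Two-stage off-target screening of primer pairs
#'
#' Implements the specificity filter: a candidate pair is rejected if it can
#' produce an amplicon within the off-target size window (default 30-2000
#' bp) on (stage 1) any gene of the target-clade catalogue that is not in
#' the pair's own cluster, or (stage 2) any non-target sequence. Amplicons
#' on the pair's own cluster members are classified as target products and
#' never cause rejection. Every rejection records the stage, the subject
#' and the offending product length; \code{retained} plus \code{rejected}
#' partition the input.
#'
#' @param pairs candidate table (needs \code{fwdDegSeq}/\code{revDegSeq}, or
#'   \code{fwdSeq}/\code{revSeq} if degeneracies were not injected) with a
#'   \code{clusterId} column.
#' @param catalog the target-clade \code{\linkS4class{GeneCatalog}}.
#' @param clusters clustering table from \code{\link{clusterGenes}} mapping
#'   genes to clusters.
#' @param nonTarget named character vector or \code{DNAStringSet} of
#'   non-target sequences (may be empty).
#' @param offTargetWindow off-target product size window, bp (default
#'   \code{c(30, 2000)}).
#' @param maxMismatches,minCoverage hit viability (see
#'   \code{\link{findPrimerHits}}).
#' @return A list with elements \code{retained} (subset of \code{pairs}) and
#'   \code{rejected} (subset with added \code{stage, subjectId,
#'   offTargetLen} columns).
#' @export
screenPrimerPairs <- function(pairs, catalog, clusters, nonTarget = NULL,
                              offTargetWindow = c(30L, 2000L),
                              maxMismatches = 3L, minCoverage = 0.8) {
  stopifnot(is(catalog, "GeneCatalog"), "clusterId" %in% names(pairs))
  target_seqs <- setNames(as.character(ntSeqs(catalog)), geneIds(catalog))
  cluster_of <- setNames(clusters$clusterId, clusters$geneId)
  if (is.null(nonTarget)) nonTarget <- character(0)
  nt_names <- names(nonTarget)
  nonTarget <- setNames(as.character(nonTarget), nt_names)
  target_cache <- .subject_mask_cache(target_seqs)
  non_target_cache <- .subject_mask_cache(nonTarget)
  memo_target <- .hit_memoiser(target_cache, maxMismatches, minCoverage)
  memo_non <- .hit_memoiser(non_target_cache, maxMismatches, minCoverage)
  n <- nrow(pairs)
  stage <- rep(NA_character_, n)
  subj <- rep(NA_character_, n)
  offlen <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    fwd <- if ("fwdDegSeq" %in% names(pairs) && !is.na(pairs$fwdDegSeq[i]))
      pairs$fwdDegSeq[i] else pairs$fwdSeq[i]
    rev <- if ("revDegSeq" %in% names(pairs) && !is.na(pairs$revDegSeq[i]))
      pairs$revDegSeq[i] else pairs$revSeq[i]
    # stage 1: genes of the target genomes outside the pair's own cluster
    own <- names(cluster_of)[cluster_of == pairs$clusterId[i]]
    others <- target_cache[setdiff(names(target_seqs), own)]
    amp <- .pair_amplicons(fwd, rev, others, offTargetWindow[1L],
                           offTargetWindow[2L], maxMismatches, minCoverage,
                           memo = memo_target)
    if (nrow(amp)) {
      stage[i] <- "target_genome_off_target"
      subj[i] <- amp$subjectId[1L]
      offlen[i] <- amp$productLen[1L]
      next
    }
    # stage 2: non-target clade sequences
    if (length(nonTarget)) {
      amp <- .pair_amplicons(fwd, rev, non_target_cache, offTargetWindow[1L],
                             offTargetWindow[2L], maxMismatches, minCoverage,
                             memo = memo_non)
      if (nrow(amp)) {
        stage[i] <- "non_target_clade"
        subj[i] <- amp$subjectId[1L]
        offlen[i] <- amp$productLen[1L]
      }
    }
  }
  rejected <- pairs[!is.na(stage), , drop = FALSE]
  if (nrow(rejected)) {
    rejected$stage <- stage[!is.na(stage)]
    rejected$subjectId <- subj[!is.na(stage)]
    rejected$offTargetLen <- offlen[!is.na(stage)]
  } else {
    rejected$stage <- character(0)
    rejected$subjectId <- character(0)
    rejected$offTargetLen <- integer(0)
  }
  retained <- pairs[is.na(stage), , drop = FALSE]
  rownames(retained) <- rownames(rejected) <- NULL
  list(retained = retained, rejected = rejected)
}
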