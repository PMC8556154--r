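# Candidate primer-pair enumeration on the consensus, degeneracy injection
# from alignment variation, and degeneracy-budget filtering.

#' Primer design constraints
#'
#' All tunable thermodynamic and structural constraints for candidate
#' enumeration and filtering. Defaults follow common qPCR design practice:
#' 18-25 nt primers (optimum 20), Tm 57-63 degC (optimum 60) with at most
#' 3 degC difference within a pair, GC 30-70\%, homopolymer runs of at most
#' 4, products of 70-1000 bp. Degeneracy budgets: a primer pool of at most
#' 32 expansions and no degenerate code in the 3'-terminal window (final 5
#' nt), where ambiguity most impairs extension.
#'
#' @param lenMin,lenOpt,lenMax primer length bounds (nt).
#' @param tmMin,tmOpt,tmMax melting temperature bounds (degC).
#' @param maxPairTmDiff maximum within-pair Tm difference (degC).
#' @param gcMin,gcMax GC-content bounds (fraction).
#' @param maxHomopolymer longest allowed single-base run.
#' @param productMin,productMax target product size bounds (bp).
#' @param maxDegeneracy maximum total degeneracy per primer.
#' @param max3PrimeDegeneracy maximum degenerate positions in the 3' window.
#' @param threePrimeWindow length of the 3' window (nt).
#' @param maxSelfComplementRun reject primers containing a self-complementary
#'   run longer than this (simple hairpin/self-dimer heuristic).
#' @param probeTmOffset internal-probe Tm target offset above \code{tmOpt}.
#' @param maxExpansions cap on pool size for mean-Tm computation.
#' @return A named list of class \code{"DesignConstraints"}.
#' @export
designConstraints <- function(lenMin = 18L, lenOpt = 20L, lenMax = 25L,
                              tmMin = 57, tmOpt = 60, tmMax = 63,
                              maxPairTmDiff = 3,
                              gcMin = 0.30, gcMax = 0.70,
                              maxHomopolymer = 4L,
                              productMin = 70L, productMax = 1000L,
                              maxDegeneracy = 32L,
                              max3PrimeDegeneracy = 0L,
                              threePrimeWindow = 5L,
                              maxSelfComplementRun = 8L,
                              probeTmOffset = 8,
                              maxExpansions = 512L) {
  cons <- list(lenMin = as.integer(lenMin), lenOpt = as.integer(lenOpt),
               lenMax = as.integer(lenMax),
               tmMin = tmMin, tmOpt = tmOpt, tmMax = tmMax,
               maxPairTmDiff = maxPairTmDiff,
               gcMin = gcMin, gcMax = gcMax,
               maxHomopolymer = as.integer(maxHomopolymer),
               productMin = as.integer(productMin),
               productMax = as.integer(productMax),
               maxDegeneracy = as.integer(maxDegeneracy),
               max3PrimeDegeneracy = as.integer(max3PrimeDegeneracy),
               threePrimeWindow = as.integer(threePrimeWindow),
               maxSelfComplementRun = as.integer(maxSelfComplementRun),
               probeTmOffset = probeTmOffset,
               maxExpansions = as.integer(maxExpansions))
  with(cons, {
    if (!(lenMin <= lenOpt && lenOpt <= lenMax))
      stop("need lenMin <= lenOpt <= lenMax", call. = FALSE)
    if (!(tmMin <= tmOpt && tmOpt <= tmMax))
      stop("need tmMin <= tmOpt <= tmMax", call. = FALSE)
    if (!(gcMin <= gcMax) || gcMin < 0 || gcMax > 1)
      stop("GC bounds must satisfy 0 <= gcMin <= gcMax <= 1", call. = FALSE)
    if (productMin > productMax || productMin < 1)
      stop("bad product size bounds", call. = FALSE)
  })
  structure(cons, class = c("DesignConstraints", "list"))
}

#' @export
print.DesignConstraints <- function(x, ...) {
  cat(sprintf(
    paste0("DesignConstraints: len %d/%d/%d nt, Tm %g/%g/%g degC ",
           "(pair dTm <= %g), GC %g-%g, product %d-%d bp,\n",
           "  degeneracy <= %d with <= %d degenerate in final %d nt\n"),
    x$lenMin, x$lenOpt, x$lenMax, x$tmMin, x$tmOpt, x$tmMax,
    x$maxPairTmDiff, x$gcMin, x$gcMax, x$productMin, x$productMax,
    x$maxDegeneracy, x$max3PrimeDegeneracy, x$threePrimeWindow))
  invisible(x)
}

# TRUE if the sequence contains a self-complementary run longer than k
# (some substring of length k+1 whose reverse complement also occurs)
.has_selfcomp_run <- function(seq, k) {
  n <- nchar(seq)
  if (n <= k) return(FALSE)
  for (s in seq_len(n - k)) {
    w <- substr(seq, s, s + k)
    if (grepl(reverseComplementIupac(w), seq, fixed = TRUE)) return(TRUE)
  }
  FALSE
}

# all single-primer windows on the consensus that satisfy the constraints;
# returns a data.frame of windows (0-based start, length, sequence, Tm).
# Vectorized over starts with cumulative sums: nearest-neighbor dH/dS,
# GC counts and long-homopolymer flags accumulate along the consensus, so
# each window is O(1).  The Tm computed here equals meltingTemperature()
# exactly (same NN parameters, salt correction and C_T/4 term).
.valid_windows <- function(track, constraints, cond) {
  cons <- consensusSequence(track)
  cons_chars <- strsplit(cons, "")[[1L]]
  usable <- usableColumns(track)
  L <- length(cons_chars)
  if (L < constraints$lenMin)
    return(data.frame(start = integer(), len = integer(),
                      seq = character(), tm = numeric(),
                      stringsAsFactors = FALSE))
  cum_ok <- c(0L, cumsum(usable))
  is_gc <- cons_chars %in% c("G", "C")
  cum_gc <- c(0L, cumsum(is_gc))
  # homopolymer runs: r[i] = length of the single-base run ending at i
  run <- integer(L); run[1L] <- 1L
  if (L > 1L) for (i in 2:L)
    run[i] <- if (cons_chars[i] == cons_chars[i - 1L] &&
                  cons_chars[i] != "-") run[i - 1L] + 1L else 1L
  bad_run <- run > constraints$maxHomopolymer
  cum_bad <- c(0L, cumsum(bad_run))
  # nearest-neighbor stacks along the consensus (gap steps contribute 0;
  # windows containing gaps are excluded by the usability test anyway)
  steps <- paste0(cons_chars[-L], cons_chars[-1L])
  known <- steps %in% names(.NN_DH)
  dh_step <- ifelse(known, .NN_DH[steps], 0)
  ds_step <- ifelse(known, .NN_DS[steps], 0)
  cum_dh <- c(0, cumsum(dh_step))
  cum_ds <- c(0, cumsum(ds_step))
  init_at <- cons_chars %in% c("A", "T")
  mon_M <- .monovalent_equivalent(cond) / 1000
  rlogct <- .R_GAS * log(cond$oligo_nM * 1e-9 / 4)

  res <- list()
  for (len in seq.int(constraints$lenMin, min(constraints$lenMax, L))) {
    starts0 <- 0:(L - len)
    ok <- (cum_ok[starts0 + len + 1L] - cum_ok[starts0 + 1L]) == len
    gc <- (cum_gc[starts0 + len + 1L] - cum_gc[starts0 + 1L]) / len
    ok <- ok & gc >= constraints$gcMin & gc <= constraints$gcMax
    # a long run overlaps the window by > max iff it extends > max beyond
    # the window start: check flags in (start + max + 1) .. (start + len)
    lo <- pmin(starts0 + constraints$maxHomopolymer + 1L, starts0 + len)
    ok <- ok & (cum_bad[starts0 + len + 1L] - cum_bad[lo]) == 0L
    dh <- cum_dh[starts0 + len] - cum_dh[starts0 + 1L] +
      ifelse(init_at[starts0 + 1L], 2.3, 0.1) +
      ifelse(init_at[starts0 + len], 2.3, 0.1)
    ds <- cum_ds[starts0 + len] - cum_ds[starts0 + 1L] +
      ifelse(init_at[starts0 + 1L], 4.1, -2.8) +
      ifelse(init_at[starts0 + len], 4.1, -2.8) +
      0.368 * (len - 1L) * log(mon_M)
    tm <- 1000 * dh / (ds + rlogct) - 273.15
    ok <- ok & tm >= constraints$tmMin & tm <= constraints$tmMax
    keep <- starts0[ok]
    if (!length(keep)) next
    seqs <- substring(cons, keep + 1L, keep + len)
    sc_ok <- !vapply(seqs, .has_selfcomp_run, logical(1),
                     k = constraints$maxSelfComplementRun,
                     USE.NAMES = FALSE)
    if (!any(sc_ok)) next
    res[[length(res) + 1L]] <- data.frame(
      start = keep[sc_ok], len = len, seq = seqs[sc_ok],
      tm = tm[ok][sc_ok], stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(start = integer(), len = integer(),
                      seq = character(), tm = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$len, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_pairs <- function() {
  data.frame(fwdStart = integer(), fwdLen = integer(),
             revStart = integer(), revLen = integer(),
             fwdSeq = character(), revSeq = character(),
             productLen = integer(), fwdTm = numeric(), revTm = numeric(),
             stringsAsFactors = FALSE)
}

#' Enumerate candidate primer pairs on a consensus
#'
#' Finds every (forward window, reverse window) pair on the majority
#' consensus whose concrete subsequences satisfy the length, Tm, GC,
#' homopolymer, self-complementarity, pair-Tm-difference and product-size
#' constraints, and whose windows avoid masked or gap-variant columns.
#' Coordinates are 0-based half-open on the consensus; the forward primer is
#' the consensus window itself and the reverse primer is the reverse
#' complement of its window (both written 5'->3'). Product length is
#' reverse-window end minus forward-window start. Pairs are returned in
#' deterministic order (forward start, then product length).
#'
#' Degeneracies are not yet injected here: Tm values are those of the
#' concrete consensus windows (see \code{\link{addDegeneracies}}).
#'
#' @param track a \code{\linkS4class{ConsensusTrack}}.
#' @param constraints a \code{\link{designConstraints}} object.
#' @param cond a \code{\link{reactionConditions}} object.
#' @param maxWindows optionally restrict pairing to the best
#'   \code{maxWindows} single-primer windows, ranked by closeness to the Tm
#'   and length optima and by pool size (the pick-best-then-pair strategy of
#'   conventional primer designers). \code{Inf} (the default) pairs all
#'   valid windows.
#' @return A \code{data.frame} of candidate pairs (possibly empty) with
#'   columns \code{fwdStart, fwdLen, revStart, revLen, fwdSeq, revSeq,
#'   productLen, fwdTm, revTm}.
#' @export
enumerateCandidates <- function(track, constraints = designConstraints(),
                                cond = reactionConditions(),
                                maxWindows = Inf) {
  stopifnot(is(track, "ConsensusTrack"))
  if (nchar(consensusSequence(track)) < constraints$productMin)
    return(.empty_pairs())
  win <- .valid_windows(track, constraints, cond)
  if (is.finite(maxWindows) && nrow(win) > maxWindows) {
    # degenerate pool size per window from the per-column variant unions
    cards <- vapply(columnVariants(track), function(v) {
      v <- setdiff(v, "-")
      if (!length(v)) return(NA_real_)
      .IUPAC_CARD[[iupacUnion(v)]]
    }, numeric(1))
    logdeg <- vapply(seq_len(nrow(win)), function(i) {
      cc <- cards[(win$start[i] + 1L):(win$start[i] + win$len[i])]
      if (anyNA(cc)) return(Inf)
      sum(log2(cc))
    }, numeric(1))
    score <- abs(win$tm - constraints$tmOpt) +
      0.25 * abs(win$len - constraints$lenOpt) + 0.5 * logdeg
    keep <- order(score, win$start, win$len,
                  method = "radix")[seq_len(maxWindows)]
    win <- win[sort(keep), , drop = FALSE]
  }
  if (nrow(win) < 2L) return(.empty_pairs())
  ends <- win$start + win$len
  rc <- vapply(win$seq, reverseComplementIupac, character(1),
               USE.NAMES = FALSE)
  # vectorized pair construction: for each forward window, the reverse
  # windows whose end lies in the allowed product span
  fi <- ri <- list()
  for (i in seq_len(nrow(win))) {
    sel <- which(ends >= win$start[i] + constraints$productMin &
                 ends <= win$start[i] + constraints$productMax &
                 win$start >= ends[i] &
                 abs(win$tm - win$tm[i]) <= constraints$maxPairTmDiff)
    if (!length(sel)) next
    fi[[length(fi) + 1L]] <- rep.int(i, length(sel))
    ri[[length(ri) + 1L]] <- sel
  }
  if (!length(fi)) return(.empty_pairs())
  fi <- unlist(fi); ri <- unlist(ri)
  out <- data.frame(
    fwdStart = win$start[fi], fwdLen = win$len[fi],
    revStart = win$start[ri], revLen = win$len[ri],
    fwdSeq = win$seq[fi], revSeq = rc[ri],
    productLen = ends[ri] - win$start[fi],
    fwdTm = win$tm[fi], revTm = win$tm[ri],
    stringsAsFactors = FALSE)
  out <- out[order(out$fwdStart, out$productLen, out$fwdLen, out$revStart,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Inject degeneracies from alignment variation into candidate pairs
#'
#' Each primer position is replaced by the minimal IUPAC code covering all
#' symbols observed in the corresponding alignment column
#' (\code{\link{iupacUnion}}); reverse-primer positions are complemented
#' accordingly. A candidate whose window touches a column with an indel
#' variant is rejected (flagged, not dropped). Degeneracy statistics are
#' computed for both primers.
#'
#' @param pairs candidate table from \code{\link{enumerateCandidates}}.
#' @param track the \code{\linkS4class{ConsensusTrack}} the candidates were
#'   enumerated on.
#' @param threePrimeWindow 3'-window length for the degeneracy statistics.
#' @return The table with added columns \code{fwdDegSeq, revDegSeq,
#'   fwdDegeneracy, revDegeneracy, fwdDeg3p, revDeg3p, degenerateOk}.
#' @export
addDegeneracies <- function(pairs, track, threePrimeWindow = 5L) {
  stopifnot(is(track, "ConsensusTrack"))
  vars <- columnVariants(track)
  # per-column union code and indel flag, computed once for the whole track
  col_gap <- vapply(vars, function(v) "-" %in% v, logical(1))
  col_code <- rep(NA_character_, length(vars))
  col_code[!col_gap] <- vapply(vars[!col_gap], iupacUnion, character(1))
  if (!nrow(pairs)) {
    for (col in c("fwdDegSeq", "revDegSeq")) pairs[[col]] <- character(0)
    for (col in c("fwdDegeneracy", "revDegeneracy", "fwdDeg3p", "revDeg3p"))
      pairs[[col]] <- integer(0)
    pairs$degenerateOk <- logical(0)
    return(pairs)
  }
  cum_gap <- cumsum(col_gap)
  # degenerate sequence and stats depend only on the window, so compute per
  # unique window and join back onto the (possibly much larger) pair table
  window_info <- function(starts, lens, reverse) {
    key <- paste(starts, lens)
    uk <- !duplicated(key)
    u_start <- starts[uk]; u_len <- lens[uk]
    ok <- (cum_gap[u_start + u_len] - c(0L, cum_gap)[u_start + 1L]) == 0L
    seqs <- rep(NA_character_, length(u_start))
    tot <- n3 <- rep(NA_integer_, length(u_start))
    for (i in which(ok)) {
      s <- paste0(col_code[(u_start[i] + 1L):(u_start[i] + u_len[i])],
                  collapse = "")
      if (reverse) s <- reverseComplementIupac(s)
      seqs[i] <- s
      st <- primerDegeneracy(s, min(threePrimeWindow, u_len[i]))
      tot[i] <- st$total; n3[i] <- st$n3prime
    }
    idx <- match(key, key[uk])
    list(seq = seqs[idx], tot = tot[idx], n3 = n3[idx], ok = ok[idx])
  }
  f <- window_info(pairs$fwdStart, pairs$fwdLen, reverse = FALSE)
  r <- window_info(pairs$revStart, pairs$revLen, reverse = TRUE)
  ok <- f$ok & r$ok
  pairs$fwdDegSeq <- ifelse(ok, f$seq, NA_character_)
  pairs$revDegSeq <- ifelse(ok, r$seq, NA_character_)
  pairs$fwdDegeneracy <- f$tot
  pairs$revDegeneracy <- r$tot
  pairs$fwdDeg3p <- f$n3
  pairs$revDeg3p <- r$n3
  pairs$degenerateOk <- ok
  pairs
}

#' Filter primer pairs on degeneracy budgets
#'
#' Retains pairs where both primers have total degeneracy at most
#' \code{maxDegeneracy} and at most \code{max3PrimeDegeneracy} degenerate
#' positions in the 3' window, and which were not rejected for indel
#' variants during degeneracy injection.
#'
#' @param pairs table from \code{\link{addDegeneracies}}.
#' @param constraints a \code{\link{designConstraints}} object.
#' @return The retained subset of \code{pairs}.
#' @export
filterDegeneracy <- function(pairs, constraints = designConstraints()) {
  if (!nrow(pairs)) return(pairs)
  keep <- pairs$degenerateOk &
    pairs$fwdDegeneracy <= constraints$maxDegeneracy &
    pairs$revDegeneracy <= constraints$maxDegeneracy &
    pairs$fwdDeg3p <= constraints$max3PrimeDegeneracy &
    pairs$revDeg3p <= constraints$max3PrimeDegeneracy
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Design an internal hydrolysis probe for each primer pair
#'
#' Searches the region strictly between the two primer binding sites for the
#' best probe window: same structural machinery as primer enumeration, with
#' the Tm band shifted up by \code{probeTmOffset} (probes should melt ~8 degC
#' above the primers). The window closest to the probe Tm target that also
#' passes the degeneracy budgets is reported; ties go to the leftmost
#' window. Pairs whose inter-primer region is too short get \code{NA}.
#'
#' @param pairs table from \code{\link{addDegeneracies}} (or
#'   \code{\link{filterDegeneracy}}).
#' @param track the \code{\linkS4class{ConsensusTrack}}.
#' @param constraints a \code{\link{designConstraints}} object.
#' @param cond a \code{\link{reactionConditions}} object.
#' @return \code{pairs} with added columns \code{probeSeq, probeStart,
#'   probeLen, probeTm} (NA where no probe exists).
#' @export
designInternalProbes <- function(pairs, track,
                                 constraints = designConstraints(),
                                 cond = reactionConditions()) {
  stopifnot(is(track, "ConsensusTrack"))
  probe_cons <- constraints
  probe_cons$tmMin <- constraints$tmMin + constraints$probeTmOffset
  probe_cons$tmOpt <- constraints$tmOpt + constraints$probeTmOffset
  probe_cons$tmMax <- constraints$tmMax + constraints$probeTmOffset
  win <- .valid_windows(track, probe_cons, cond)
  if (nrow(win)) {
    win <- addDegeneracies(
      data.frame(fwdStart = win$start, fwdLen = win$len,
                 revStart = win$start, revLen = win$len,
                 fwdSeq = win$seq, revSeq = win$seq,
                 productLen = win$len, fwdTm = win$tm, revTm = win$tm,
                 stringsAsFactors = FALSE),
      track, constraints$threePrimeWindow)
    win_keep <- win$degenerateOk &
      win$fwdDegeneracy <= constraints$maxDegeneracy &
      win$fwdDeg3p <= constraints$max3PrimeDegeneracy
    win <- win[win_keep, , drop = FALSE]
  }
  n <- nrow(pairs)
  probeSeq <- rep(NA_character_, n)
  probeStart <- probeLen <- rep(NA_integer_, n)
  probeTm <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- pairs$fwdStart[i] + pairs$fwdLen[i]   # first column after fwd
    hi <- pairs$revStart[i]                     # first column of rev
    if (!nrow(win) || hi - lo < constraints$lenMin) next
    cand <- which(win$fwdStart >= lo & win$fwdStart + win$fwdLen <= hi)
    if (!length(cand)) next
    target <- constraints$tmOpt + constraints$probeTmOffset
    best <- cand[order(abs(win$fwdTm[cand] - target), win$fwdStart[cand],
                       method = "radix")][1L]
    probeSeq[i] <- win$fwdDegSeq[best]
    probeStart[i] <- win$fwdStart[best]
    probeLen[i] <- win$fwdLen[best]
    probeTm[i] <- win$fwdTm[best]
  }
  pairs$probeSeq <- probeSeq
  pairs$probeStart <- probeStart
  pairs$probeLen <- probeLen
  pairs$probeTm <- probeTm
  pairs
}
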