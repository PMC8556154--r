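# Protein alignment of a core cluster, codon-aware back-translation, and the
# majority consensus track that primer design operates on.

#' Align the proteins of a gene cluster
#'
#' Center-star multiple alignment: the longest member is the center (ties
#' broken by input order); every other member is aligned to the center by
#' global pairwise alignment (BLOSUM62, affine gaps: open 11, extend 1), and
#' the pairwise alignments are merged by gap propagation. The result is a
#' set of equal-length gapped rows whose degapped content is exactly the
#' input. Exact for two sequences; a good, dependency-free approximation for
#' the high-identity clusters this package aligns.
#'
#' @param members named character vector or \code{AAStringSet} of amino-acid
#'   sequences (at least 2).
#' @return Named \code{AAStringSet} of equal-width gapped rows.
#' @export
alignProteinCluster <- function(members) {
  ids <- names(members)
  seqs <- as.character(members)
  names(seqs) <- if (is.null(ids)) paste0("seq", seq_along(seqs)) else ids
  if (length(seqs) < 2L)
    stop("a cluster alignment needs at least 2 sequences", call. = FALSE)
  if (any(!nzchar(seqs))) stop("empty member sequence", call. = FALSE)
  center <- which.max(nchar(seqs))
  others <- setdiff(seq_along(seqs), center)
  Lc <- nchar(seqs[[center]])
  sub <- .blosum62()

  # per-member: chars inserted between consecutive center positions
  # (slot j = insertions after center residue j; slot 0 = before the first),
  # plus the member char aligned to each center residue
  ins_list <- vector("list", length(seqs))
  at_list <- vector("list", length(seqs))
  for (i in others) {
    aln <- pairwiseAlignment(AAStringSet(seqs[[i]]),
                             AAStringSet(seqs[[center]]),
                             type = "global", substitutionMatrix = sub,
                             gapOpening = 11, gapExtension = 1)
    pc <- strsplit(as.character(alignedPattern(aln)[[1L]]), "")[[1L]]
    sc <- strsplit(as.character(alignedSubject(aln)[[1L]]), "")[[1L]]
    ins <- vector("list", Lc + 1L)
    at <- character(Lc)
    j <- 0L
    buf <- character(0)
    for (k in seq_along(sc)) {
      if (sc[k] == "-") {
        buf <- c(buf, pc[k])
      } else {
        ins[[j + 1L]] <- buf
        buf <- character(0)
        j <- j + 1L
        at[j] <- pc[k]
      }
    }
    ins[[Lc + 1L]] <- buf
    ins_list[[i]] <- ins
    at_list[[i]] <- at
  }
  ins_list[[center]] <- rep(list(character(0)), Lc + 1L)
  at_list[[center]] <- strsplit(seqs[[center]], "")[[1L]]

  master <- vapply(seq_len(Lc + 1L), function(j)
    max(vapply(ins_list, function(x) length(x[[j]]), integer(1))),
    integer(1))

  rows <- vapply(seq_along(seqs), function(i) {
    out <- character(0)
    for (j in seq_len(Lc + 1L)) {
      chars <- ins_list[[i]][[j]]
      out <- c(out, chars, rep("-", master[j] - length(chars)))
      if (j <= Lc) out <- c(out, at_list[[i]][j])
    }
    paste0(out, collapse = "")
  }, character(1))
  AAStringSet(setNames(rows, names(seqs)))
}

#' Codon alignment of a gene cluster
#'
#' Nucleotide alignment obtained by back-translating a protein alignment:
#' every residue is replaced by its source codon and every gap by
#' \code{"---"}, so the codon alignment is exactly three times the protein
#' alignment width and degapping any row recovers the member CDS.
#'
#' @slot nt gapped \code{DNAStringSet}, equal widths.
#' @slot aa the gapped protein alignment (\code{AAStringSet}).
#' @export
setClass("CodonAlignment", representation(
  nt = "DNAStringSet",
  aa = "AAStringSet"
))

setValidity("CodonAlignment", function(object) {
  wn <- Biostrings::width(object@nt)
  wa <- Biostrings::width(object@aa)
  msgs <- character()
  if (length(wn) != length(wa))
    msgs <- c(msgs, "nt and aa row counts differ")
  else {
    if (length(unique(wn)) > 1L) msgs <- c(msgs, "ragged nucleotide rows")
    if (any(wn != 3L * wa))
      msgs <- c(msgs, "codon rows must be 3x the protein alignment width")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf("CodonAlignment: %d rows x %d columns (%d codons)\n",
              length(object@nt),
              if (length(object@nt)) Biostrings::width(object@nt)[1L] else 0L,
              if (length(object@aa)) Biostrings::width(object@aa)[1L] else 0L))
})

#' @describeIn CodonAlignment-class number of rows.
#' @param x a \code{CodonAlignment}.
#' @export
setMethod("length", "CodonAlignment", function(x) length(x@nt))

#' Rows of a codon alignment
#' @param x a \code{\linkS4class{CodonAlignment}}.
#' @return Gapped \code{DNAStringSet}.
#' @export
codonRows <- function(x) { stopifnot(is(x, "CodonAlignment")); x@nt }

#' Back-translate a protein alignment into a codon alignment
#'
#' @param aln gapped protein alignment (\code{AAStringSet}, names = gene
#'   ids).
#' @param catalog a \code{\linkS4class{GeneCatalog}} supplying the source
#'   CDS of every row.
#' @return A \code{\linkS4class{CodonAlignment}}.
#' @export
backTranslateAlignment <- function(aln, catalog) {
  aln <- AAStringSet(aln)
  ids <- names(aln)
  if (is.null(ids) || !all(ids %in% geneIds(catalog)))
    stop("alignment rows must be named with catalogue gene ids",
         call. = FALSE)
  nt <- as.character(ntSeqs(catalog))[ids]
  rows <- vapply(seq_along(aln), function(i) {
    res <- strsplit(as.character(aln[[i]]), "")[[1L]]
    cds <- nt[[i]]
    n_res <- sum(res != "-")
    if (nchar(cds) != 3L * n_res)
      stop(sprintf("CDS of %s is %d nt but its aligned row has %d residues",
                   ids[i], nchar(cds), n_res), call. = FALSE)
    codons <- substring(cds, seq(1L, nchar(cds), by = 3L),
                        seq(3L, nchar(cds), by = 3L))
    out <- rep("---", length(res))
    out[res != "-"] <- codons
    paste0(out, collapse = "")
  }, character(1))
  new("CodonAlignment", nt = DNAStringSet(setNames(rows, ids)), aa = aln)
}

#' Per-column consensus and variation of a codon alignment
#'
#' The majority consensus is the input to primer candidate enumeration; the
#' per-column variant sets drive degeneracy injection. Columns whose
#' majority symbol is a gap are masked, and any column whose variant set
#' contains a gap is unusable for primers (a primer cannot reliably span an
#' indel polymorphism).
#'
#' @slot consensus character scalar over \code{A,C,G,T,-}.
#' @slot variants list of character vectors: symbols observed per column.
#' @slot masked logical: majority symbol is a gap.
#' @export
setClass("ConsensusTrack", representation(
  consensus = "character",
  variants = "list",
  masked = "logical"
))

setValidity("ConsensusTrack", function(object) {
  L <- nchar(object@consensus)
  if (length(object@variants) != L || length(object@masked) != L)
    return("variants and masked must have one entry per consensus column")
  TRUE
})

setMethod("show", "ConsensusTrack", function(object) {
  L <- nchar(object@consensus)
  nvar <- sum(lengths(object@variants) > 1L)
  cat(sprintf(
    "ConsensusTrack: %d columns, %d variable, %d masked, %d usable\n",
    L, nvar, sum(object@masked), sum(usableColumns(object))))
})

#' @rdname ConsensusTrack-class
#' @param x a \code{ConsensusTrack}.
#' @return \code{consensusSequence}: the consensus string;
#'   \code{columnVariants}: list of per-column symbol sets;
#'   \code{usableColumns}: logical, columns a primer may cover (not masked,
#'   no gap in the variant set).
#' @export
consensusSequence <- function(x) { stopifnot(is(x, "ConsensusTrack")); x@consensus }
#' @rdname ConsensusTrack-class
#' @export
columnVariants <- function(x) { stopifnot(is(x, "ConsensusTrack")); x@variants }
#' @rdname ConsensusTrack-class
#' @export
usableColumns <- function(x) {
  stopifnot(is(x, "ConsensusTrack"))
  !x@masked & !vapply(x@variants, function(v) "-" %in% v, logical(1))
}

#' Majority consensus of a codon alignment
#'
#' Per column, the most frequent symbol among \code{A,C,G,T,-}; ties are
#' broken by the fixed order A < C < G < T < \code{-}. The variant set of a
#' column records every symbol observed in it (and always contains the
#' consensus symbol). Row order does not affect the result.
#'
#' @param aln a \code{\linkS4class{CodonAlignment}} (or gapped
#'   \code{DNAStringSet}) with at least 2 rows.
#' @return A \code{\linkS4class{ConsensusTrack}}.
#' @export
majorityConsensus <- function(aln) {
  rows <- if (is(aln, "CodonAlignment")) aln@nt else DNAStringSet(aln)
  if (length(rows) < 2L)
    stop("consensus needs at least 2 rows", call. = FALSE)
  if (length(unique(Biostrings::width(rows))) != 1L)
    stop("ragged alignment", call. = FALSE)
  mat <- do.call(rbind, strsplit(as.character(rows), ""))
  symbols <- c("A", "C", "G", "T", "-")
  cons <- character(ncol(mat))
  vars <- vector("list", ncol(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    counts <- tabulate(match(col, symbols), nbins = 5L)
    cons[j] <- symbols[which.max(counts)]   # which.max = first max = tie order
    vars[[j]] <- symbols[counts > 0L]
  }
  new("ConsensusTrack", consensus = paste0(cons, collapse = ""),
      variants = vars, masked = cons == "-")
}
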