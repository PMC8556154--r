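#' @importFrom Biostrings DNAStringSet AAStringSet readDNAStringSet
#'   readAAStringSet writeXStringSet translate getGeneticCode width
#'   pairwiseAlignment alignedPattern alignedSubject nmatch subject pattern
#'   aligned
#' @importFrom S4Vectors metadata metadata<-
#' @importFrom IRanges start end
NULL

#' Catalogue of coding genes across genomes
#'
#' A \code{GeneCatalog} holds, for every coding gene of every genome in a
#' clade, the paired nucleotide CDS and its amino-acid translation, together
#' with the genome and gene identifiers. It is the input to pan-genome
#' clustering. CDSs are stored without a terminal stop codon, so
#' \code{width(nt) == 3 * width(aa)} for every record.
#'
#' @slot nt \code{DNAStringSet} of CDSs (no terminal stop codon).
#' @slot aa \code{AAStringSet} of translations.
#' @slot genomeId character vector, genome of each record.
#' @slot geneId character vector, unique gene identifiers.
#' @export
setClass("GeneCatalog", representation(
  nt = "DNAStringSet",
  aa = "AAStringSet",
  genomeId = "character",
  geneId = "character"
))

setValidity("GeneCatalog", function(object) {
  n <- length(object@nt)
  msgs <- character()
  if (length(object@aa) != n || length(object@genomeId) != n ||
      length(object@geneId) != n)
    msgs <- c(msgs, "nt, aa, genomeId and geneId must have equal length")
  else {
    if (any(Biostrings::width(object@nt) !=
            3L * Biostrings::width(object@aa)))
      msgs <- c(msgs, "every CDS must be exactly 3x its protein length")
    if (anyDuplicated(object@geneId))
      msgs <- c(msgs, "gene identifiers must be unique")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneCatalog
#'
#' Builds a \code{\linkS4class{GeneCatalog}} from paired nucleotide and
#' protein sequences. A terminal stop codon on any CDS is stripped before
#' pairing. Each CDS is checked against its stated translation under the
#' bacterial/archaeal genetic code (NCBI table 11); a mismatch raises a
#' warning, not an error, to tolerate annotation quirks.
#'
#' @param nt \code{DNAStringSet} (or named character) of CDSs.
#' @param aa \code{AAStringSet} (or named character) of translations.
#' @param genomeId,geneId character vectors; if missing, parsed from the
#'   sequence names as \code{"<genomeId><delim><geneId>"}.
#' @param delim delimiter between genome and gene id in FASTA headers.
#' @param checkTranslation verify nt/aa consistency (warning on mismatch).
#' @return A \code{GeneCatalog}.
#' @export
geneCatalog <- function(nt, aa, genomeId = NULL, geneId = NULL,
                        delim = "|", checkTranslation = TRUE) {
  if (!is(nt, "DNAStringSet")) nt <- DNAStringSet(nt)
  if (!is(aa, "AAStringSet")) aa <- AAStringSet(aa)
  if (is.null(geneId) || is.null(genomeId)) {
    if (is.null(names(nt)))
      stop("sequence names required to parse genome/gene identifiers",
           call. = FALSE)
    ids <- strsplit(names(nt), delim, fixed = TRUE)
    if (any(lengths(ids) < 2L))
      stop(sprintf("FASTA headers must look like 'genomeID%sgeneID'", delim),
           call. = FALSE)
    if (is.null(genomeId)) genomeId <- vapply(ids, `[[`, "", 1L)
    if (is.null(geneId)) geneId <- names(nt)
  }
  # strip terminal stop codons before pairing
  w <- Biostrings::width(nt)
  last_codon <- as.character(Biostrings::subseq(nt, start = pmax(w - 2L, 1L)))
  has_stop <- w >= 3L & last_codon %in% c("TAA", "TAG", "TGA") &
    w == 3L * Biostrings::width(aa) + 3L
  if (any(has_stop))
    nt[has_stop] <- Biostrings::subseq(nt[has_stop], end = w[has_stop] - 3L)
  if (checkTranslation) {
    tr <- suppressWarnings(as.character(
      Biostrings::translate(nt, genetic.code = getGeneticCode("11"),
                            if.fuzzy.codon = "X")))
    mism <- tr != as.character(aa)
    if (any(mism))
      warning(sprintf(
        "%d CDS(s) do not translate to their stated protein (e.g. %s)",
        sum(mism), geneId[which(mism)[1L]]), call. = FALSE)
  }
  names(nt) <- geneId
  names(aa) <- geneId
  new("GeneCatalog", nt = nt, aa = aa,
      genomeId = as.character(genomeId), geneId = as.character(geneId))
}

#' Read a GeneCatalog from FASTA files
#'
#' @param ntFasta path to the nucleotide CDS multi-FASTA.
#' @param aaFasta path to the protein multi-FASTA (same headers).
#' @param delim header delimiter between genome and gene id.
#' @param ... passed to \code{\link{geneCatalog}}.
#' @return A \code{\linkS4class{GeneCatalog}}.
#' @export
readGeneCatalog <- function(ntFasta, aaFasta, delim = "|", ...) {
  nt <- readDNAStringSet(ntFasta)
  aa <- readAAStringSet(aaFasta)
  names(nt) <- sub("\\s.*$", "", names(nt))
  names(aa) <- sub("\\s.*$", "", names(aa))
  if (!setequal(names(nt), names(aa)))
    stop("nucleotide and protein FASTA carry different gene identifiers",
         call. = FALSE)
  geneCatalog(nt, aa[names(nt)], delim = delim, ...)
}

#' @describeIn GeneCatalog-class number of gene records.
#' @param x a \code{GeneCatalog}.
#' @export
setMethod("length", "GeneCatalog", function(x) length(x@nt))

#' Accessors for GeneCatalog
#'
#' \code{ntSeqs} and \code{aaSeqs} return the sequence sets; \code{genomeIds}
#' and \code{geneIds} the identifier vectors.
#'
#' @param x a \code{\linkS4class{GeneCatalog}}.
#' @return The corresponding slot.
#' @name catalog-accessors
NULL

#' @rdname catalog-accessors
#' @export
ntSeqs <- function(x) { stopifnot(is(x, "GeneCatalog")); x@nt }
#' @rdname catalog-accessors
#' @export
aaSeqs <- function(x) { stopifnot(is(x, "GeneCatalog")); x@aa }
#' @rdname catalog-accessors
#' @export
genomeIds <- function(x) { stopifnot(is(x, "GeneCatalog")); x@genomeId }
#' @rdname catalog-accessors
#' @export
geneIds <- function(x) { stopifnot(is(x, "GeneCatalog")); x@geneId }

#' @export
setMethod("[", "GeneCatalog", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@geneId)
  new("GeneCatalog", nt = x@nt[i], aa = x@aa[i],
      genomeId = x@genomeId[i], geneId = x@geneId[i])
})

setMethod("show", "GeneCatalog", function(object) {
  cat(sprintf("GeneCatalog: %d genes from %d genome(s)\n",
              length(object), length(unique(object@genomeId))))
  if (length(object)) {
    w <- Biostrings::width(object@nt)
    cat(sprintf("  CDS length: %d-%d nt (median %d)\n",
                min(w), max(w), as.integer(stats::median(w))))
  }
})

#' Write a GeneCatalog to FASTA files
#'
#' @param x a \code{\linkS4class{GeneCatalog}}.
#' @param ntFasta,aaFasta output paths.
#' @return Invisibly, the two paths.
#' @export
writeGeneCatalog <- function(x, ntFasta, aaFasta) {
  writeXStringSet(ntSeqs(x), ntFasta)
  writeXStringSet(aaSeqs(x), aaFasta)
  invisible(c(ntFasta, aaFasta))
}
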