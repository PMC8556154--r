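# Pan-genome clustering: greedy centroid clustering of protein sequences at
# identity/coverage thresholds, and selection of single-copy core clusters.

.blosum62 <- function() {
  # lazy-load Biostrings' BLOSUM62 into the package namespace cache
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Pairwise identity and coverage of two protein sequences
#'
#' Aligns the shorter sequence against the longer one (global in the shorter,
#' local in the longer; BLOSUM62, affine gaps) and reports
#' \describe{
#'   \item{identity}{matching residues / aligned columns, gap columns
#'     excluded;}
#'   \item{coverage}{the aligned span on each sequence divided by its length,
#'     minimised over the two sequences (both must be covered -- a perfect
#'     fragment match to half of a longer gene has coverage 0.5).}
#' }
#'
#' @param a,b amino-acid sequences (character scalars or \code{AAString}).
#' @return Named numeric vector \code{c(identity=, coverage=)}, both in
#'   \code{[0, 1]}.
#' @export
pairwiseIdentityCoverage <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b))
    stop("empty sequence", call. = FALSE)
  swap <- nchar(a) > nchar(b)
  shorter <- if (swap) b else a
  longer <- if (swap) a else b
  aln <- pairwiseAlignment(AAStringSet(shorter), AAStringSet(longer),
                           type = "global-local",
                           substitutionMatrix = .blosum62(),
                           gapOpening = 11, gapExtension = 1)
  p <- as.character(alignedPattern(aln)[[1L]])
  s <- as.character(alignedSubject(aln)[[1L]])
  pc <- strsplit(p, "")[[1L]]
  sc <- strsplit(s, "")[[1L]]
  non_gap <- pc != "-" & sc != "-"
  identity <- if (any(non_gap)) sum(pc[non_gap] == sc[non_gap]) / sum(non_gap)
              else 0
  span_short <- sum(pc != "-")
  span_long <- sum(sc != "-")
  coverage <- min(span_short / nchar(shorter), span_long / nchar(longer))
  c(identity = identity, coverage = min(coverage, 1))
}

#' Cluster genes across genomes by protein similarity
#'
#' Greedy centroid clustering of the catalogue's protein sequences: genes are
#' sorted by decreasing length (ties broken lexicographically by gene id) and
#' each gene joins the first existing cluster whose centroid it matches at
#' \code{>= minIdentity} identity and \code{>= minCoverage} coverage
#' (\code{\link{pairwiseIdentityCoverage}}), otherwise it founds a new
#' cluster with itself as centroid. The result is a partition: every gene
#' belongs to exactly one cluster.
#'
#' The default thresholds (80\% identity, 90\% coverage) are the standard
#' cut-offs for pan-genome gene family clustering.
#'
#' @param catalog a \code{\linkS4class{GeneCatalog}}.
#' @param minIdentity minimum identity to the centroid (fraction).
#' @param minCoverage minimum bidirectional coverage (fraction).
#' @return A \code{data.frame} with one row per gene: \code{geneId},
#'   \code{genomeId}, \code{clusterId} (integer, 1-based, in order of
#'   foundation), \code{isCentroid}.
#' @export
clusterGenes <- function(catalog, minIdentity = 0.80, minCoverage = 0.90) {
  stopifnot(is(catalog, "GeneCatalog"))
  n <- length(catalog)
  if (n == 0L) stop("empty catalogue", call. = FALSE)
  aa <- as.character(aaSeqs(catalog))
  ord <- order(-nchar(aa), geneIds(catalog), method = "radix")
  centroid_idx <- integer(0)        # catalogue index of each centroid
  cluster_of <- integer(n)
  for (i in ord) {
    assigned <- FALSE
    for (k in seq_along(centroid_idx)) {
      ic <- pairwiseIdentityCoverage(aa[[i]], aa[[centroid_idx[k]]])
      if (ic[["identity"]] >= minIdentity &&
          ic[["coverage"]] >= minCoverage) {
        cluster_of[i] <- k
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      centroid_idx <- c(centroid_idx, i)
      cluster_of[i] <- length(centroid_idx)
    }
  }
  data.frame(
    geneId = geneIds(catalog),
    genomeId = genomeIds(catalog),
    clusterId = cluster_of,
    isCentroid = seq_len(n) %in% centroid_idx,
    stringsAsFactors = FALSE
  )
}

#' Select single-copy core clusters
#'
#' A cluster is single-copy core when it contains exactly one member from
#' every genome of the target clade -- no genome missing, no genome
#' contributing two members. These are the gene families primers are
#' designed on.
#'
#' @param clusters clustering table from \code{\link{clusterGenes}}.
#' @param genomeIdSet character vector of target genome identifiers.
#' @return Integer vector of single-copy core \code{clusterId}s (sorted).
#' @export
selectCoreClusters <- function(clusters, genomeIdSet) {
  if (length(genomeIdSet) == 0L)
    stop("genomeIdSet must be non-empty", call. = FALSE)
  genomeIdSet <- unique(as.character(genomeIdSet))
  keep <- vapply(split(clusters$genomeId, clusters$clusterId), function(g) {
    setequal(unique(g), genomeIdSet) && !anyDuplicated(g) &&
      length(g) == length(genomeIdSet)
  }, logical(1))
  sort(as.integer(names(keep)[keep]))
}
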