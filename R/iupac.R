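#' @import methods
#' @importFrom stats setNames
NULL

# IUPAC nucleotide codes as bitmasks: A=1, C=2, G=4, T=8.  The bitmask algebra
# is the backbone of the whole package: union of observed bases is bitwOr,
# primer/template compatibility is bitwAnd > 0.
.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)
.BITS_IUPAC <- setNames(names(.IUPAC_BITS), .IUPAC_BITS)

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

.IUPAC_CARD <- vapply(.IUPAC_SETS, length, integer(1))

# split a sequence string into single characters, normalized to upper case
# with U -> T (defensive I/O; RNA-style input is accepted and canonicalized)
.seq_chars <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  chars <- strsplit(chartr("u", "T", toupper(x)), "", fixed = TRUE)[[1]]
  chars[chars == "U"] <- "T"
  chars
}

.check_iupac <- function(chars, allow_gap = FALSE, what = "sequence") {
  ok <- chars %in% names(.IUPAC_BITS)
  if (allow_gap) ok <- ok | chars == "-"
  if (!all(ok)) {
    bad <- unique(chars[!ok])
    stop(sprintf("invalid symbol(s) in %s: %s", what,
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(chars)
}

#' Encode an IUPAC sequence as base bitmasks
#'
#' Internal workhorse: each symbol becomes an integer bitmask over
#' \{A=1, C=2, G=4, T=8\}; gaps (if permitted) become \code{NA}.
#' @noRd
.iupac_masks <- function(x, allow_gap = FALSE) {
  chars <- .seq_chars(x)
  .check_iupac(chars, allow_gap = allow_gap)
  m <- unname(.IUPAC_BITS[chars])
  if (allow_gap) m[chars == "-"] <- NA_integer_
  m
}

#' Minimal IUPAC code covering a set of codes
#'
#' Returns the single IUPAC nucleotide code whose concrete-base set equals the
#' union of the concrete-base sets of the inputs. This is the operation used
#' to inject degeneracies into a primer so that it covers all sequence
#' variation observed at an alignment column.
#'
#' @param bases character vector of IUPAC codes (case-insensitive; \code{U}
#'   is normalized to \code{T}). Must be non-empty and gap-free.
#' @return A single upper-case IUPAC code.
#' @examples
#' iupacUnion(c("A", "C"))        # "M"
#' iupacUnion(c("A", "C", "G", "T"))  # "N"
#' iupacUnion("t")                # "T"
#' @export
iupacUnion <- function(bases) {
  if (length(bases) == 0L)
    stop("iupacUnion() requires a non-empty set of codes", call. = FALSE)
  chars <- .seq_chars(paste0(bases, collapse = ""))
  .check_iupac(chars, allow_gap = FALSE, what = "code set")
  .BITS_IUPAC[[as.character(Reduce(bitwOr, .IUPAC_BITS[chars]))]]
}

#' Expand a degenerate sequence into all concrete sequences
#'
#' Enumerates every A/C/G/T-only sequence compatible with a degenerate
#' (IUPAC) sequence. The number of expansions equals the total degeneracy
#' (product over positions of code cardinalities).
#'
#' @param x a single degenerate sequence (character scalar), gap-free.
#' @param max.expansions refuse to enumerate beyond this pool size
#'   (guards against runaway \code{N}-rich input).
#' @return Character vector of concrete sequences, in lexicographic order of
#'   the per-position base choices.
#' @examples
#' iupacExpand("TM")    # "TA" "TC"
#' iupacExpand("ACGT")  # "ACGT"
#' @export
iupacExpand <- function(x, max.expansions = 65536L) {
  chars <- .seq_chars(x)
  if (length(chars) == 0L)
    stop("cannot expand an empty sequence", call. = FALSE)
  if (any(chars == "-"))
    stop("gap symbol '-' is not part of the IUPAC algebra; degap first",
         call. = FALSE)
  .check_iupac(chars)
  total <- prod(.IUPAC_CARD[chars])
  if (total > max.expansions)
    stop(sprintf("degeneracy %d exceeds expansion cap %d", total,
                 max.expansions), call. = FALSE)
  sets <- .IUPAC_SETS[chars]
  # build the pool column by column; columns vary slowest-first so the
  # output order is deterministic
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  sort(out)
}

#' Degeneracy statistics of a primer
#'
#' Computes the total degeneracy (pool size), the number of degenerate
#' positions, and the number of degenerate positions within the 3' window --
#' the quantities on which candidate primers are filtered. Primers are
#' written 5'->3', so the 3' window is the final \code{threePrimeWindow}
#' symbols.
#'
#' @param x degenerate sequence (character scalar), gap-free.
#' @param threePrimeWindow length of the 3'-terminal window (default 5 nt).
#' @return A list with components \code{total}, \code{nDegenerate} and
#'   \code{n3prime}.
#' @examples
#' primerDegeneracy("TMARRACMCACTGCAGGGAC")  # total 16, 4 positions, 0 in 3'
#' @export
primerDegeneracy <- function(x, threePrimeWindow = 5L) {
  chars <- .seq_chars(x)
  if (any(chars == "-"))
    stop("gap symbol '-' not allowed in a primer", call. = FALSE)
  .check_iupac(chars)
  if (threePrimeWindow > length(chars))
    stop("3' window longer than the primer", call. = FALSE)
  card <- .IUPAC_CARD[chars]
  deg <- card > 1L
  tail_idx <- seq.int(length(chars) - threePrimeWindow + 1L, length(chars))
  list(total = prod(card),
       nDegenerate = sum(deg),
       n3prime = if (threePrimeWindow > 0L) sum(deg[tail_idx]) else 0L)
}

.COMPLEMENT_MAP <- c(
  A = "T", C = "G", G = "C", T = "A",
  M = "K", K = "M", R = "Y", Y = "R", W = "W", S = "S",
  V = "B", B = "V", H = "D", D = "H", N = "N", `-` = "-"
)

#' IUPAC-aware reverse complement
#'
#' Reverse complement of a degenerate sequence: each code is replaced by the
#' code of the complements of its concrete bases (M<->K, R<->Y, N<->N, ...),
#' then the sequence is reversed. Gaps are preserved in place, so alignment
#' rows can be flipped too. The operation is an involution and preserves
#' total degeneracy.
#'
#' @param x degenerate sequence (character scalar); gaps allowed.
#' @return The reverse-complemented sequence (upper case).
#' @examples
#' reverseComplementIupac("ACGT")  # "ACGT"
#' reverseComplementIupac("M")     # "K"
#' @export
reverseComplementIupac <- function(x) {
  chars <- .seq_chars(x)
  .check_iupac(chars, allow_gap = TRUE)
  paste0(rev(unname(.COMPLEMENT_MAP[chars])), collapse = "")
}

#' Compatibility of two IUPAC codes
#'
#' Two codes are compatible when their concrete-base sets intersect -- the
#' match predicate used by the in-silico PCR scanner (a degenerate primer
#' base can pair at a template position iff some expansion matches it).
#'
#' @param a,b IUPAC codes (vectorized, recycled).
#' @return Logical vector.
#' @examples
#' iupacCompatible("M", "A")  # TRUE
#' iupacCompatible("Y", "A")  # FALSE
#' @export
iupacCompatible <- function(a, b) {
  ma <- .IUPAC_BITS[.check_iupac(.seq_chars(paste0(a, collapse = "")),
                                 what = "codes")]
  mb <- .IUPAC_BITS[.check_iupac(.seq_chars(paste0(b, collapse = "")),
                                 what = "codes")]
  unname(bitwAnd(ma, mb) > 0L)
}

# GC content of a degenerate sequence: mean over the pool equals the mean of
# per-position P(G or C), which for a code with k bases of which g are G/C is
# g/k.  Used by the design constraints.
.gc_fraction <- function(chars) {
  gc_bits <- bitwAnd(.IUPAC_BITS[chars], 6L)  # C=2 | G=4
  frac <- vapply(gc_bits, function(b) sum(bitwAnd(b, c(2L, 4L)) > 0L),
                 numeric(1)) / .IUPAC_CARD[chars]
  mean(frac)
}

# longest homopolymer run over concrete positions (degenerate codes break a
# run only if they exclude the running base)
.max_homopolymer <- function(chars) {
  n <- length(chars)
  if (n == 0L) return(0L)
  masks <- .IUPAC_BITS[chars]
  best <- 1L
  for (base_bit in c(1L, 2L, 4L, 8L)) {
    run <- 0L
    for (i in seq_len(n)) {
      if (bitwAnd(masks[i], base_bit) > 0L && .IUPAC_CARD[chars[i]] == 1L) {
        run <- run + 1L
        if (run > best) best <- run
      } else run <- 0L
    }
  }
  best
}
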