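# Independent brute-force oracles used to cross-check the package's
# implementations.  These deliberately avoid the package's internal bitmask
# machinery: codes are literal base sets, matching is set intersection, and
# searches rescan from scratch.

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A")

# enumerate all concrete sequences by explicit cartesian product
oracle_expand <- function(seq) {
  sets <- ORACLE_SETS[strsplit(seq, "")[[1]]]
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  sort(apply(grid[, rev(seq_len(ncol(grid))), drop = FALSE], 1, paste0,
             collapse = ""))
}

# reverse complement through the concrete-base sets (direct lookup for
# concrete sequences, set logic for ambiguity codes)
oracle_revcomp <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  if (all(chars %in% names(ORACLE_COMP)))
    return(paste0(rev(unname(ORACLE_COMP[chars])), collapse = ""))
  comp <- vapply(rev(chars), function(ch) {
    if (ch == "-") return("-")
    set <- sort(unname(ORACLE_COMP[ORACLE_SETS[[ch]]]))
    names(Filter(function(s) setequal(s, set), ORACLE_SETS))[1]
  }, character(1))
  paste0(comp, collapse = "")
}

oracle_compatible <- function(a, b) {
  length(intersect(ORACLE_SETS[[a]], ORACLE_SETS[[b]])) > 0
}

# exhaustive position-by-position binding-site scanner.  For every strand,
# allowed placement length and 3'-anchor it recounts mismatches from scratch
# by set-membership lookups, then reports per anchor the longest placement
# with <= maxMismatches (coverage strictly > minCoverage).
oracle_find_hits <- function(primer, subject, maxMismatches = 3,
                             minCoverage = 0.8) {
  pr <- strsplit(toupper(primer), "")[[1]]
  L <- length(pr)
  l_min <- min(floor(minCoverage * L) + 1, L)
  scan_strand <- function(chars, strand) {
    S <- length(chars)
    if (S < l_min) return(list())
    # compat[[j]][i]: does primer position j match subject position i?
    compat <- lapply(seq_len(L), function(j)
      chars %in% ORACLE_SETS[[pr[j]]])
    best_l <- integer(S); best_mm <- rep(NA_integer_, S)
    for (l in seq(l_min, min(L, S))) {
      anchors <- seq.int(l, S)
      mm <- rep(0L, length(anchors))
      for (j in seq_len(l))               # j counts from the 3' end
        mm <- mm + !compat[[L - j + 1]][anchors - j + 1]
      ok <- mm <= maxMismatches
      best_l[anchors[ok]] <- l            # ascending l: longest wins
      best_mm[anchors[ok]] <- mm[ok]
    }
    lapply(which(best_l > 0), function(a) c(a, best_l[a], best_mm[a]))
  }
  chars <- strsplit(toupper(subject), "")[[1]]
  S <- length(chars)
  out <- list()
  for (r in scan_strand(chars, "+"))
    out[[length(out) + 1]] <- data.frame(
      strand = "+", start = r[1] - r[2], end = r[1], length = r[2],
      coverage = r[2] / L, mismatches = r[3], stringsAsFactors = FALSE)
  rc_chars <- strsplit(oracle_revcomp(toupper(subject)), "")[[1]]
  for (r in scan_strand(rc_chars, "-"))
    out[[length(out) + 1]] <- data.frame(
      strand = "-", start = S - r[1], end = S - r[1] + r[2], length = r[2],
      coverage = r[2] / L, mismatches = r[3], stringsAsFactors = FALSE)
  if (!length(out))
    return(data.frame(strand = character(), start = integer(),
                      end = integer(), length = integer(),
                      coverage = numeric(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[order(match(df$strand, c("+", "-")), df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# random degenerate primer with bounded pool size
random_degenerate_primer <- function(len = 20, max_degeneracy = 64) {
  repeat {
    codes <- sample(names(ORACLE_SETS), len, replace = TRUE,
                    prob = c(rep(10, 4), rep(1, 6), rep(0.2, 4), 0.1))
    deg <- prod(lengths(ORACLE_SETS[codes]))
    if (deg <= max_degeneracy) return(paste0(codes, collapse = ""))
  }
}

random_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

random_aa <- function(n) paste0(sample(strsplit(
  "ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE), collapse = "")

# small catalogue built directly from aa sequences (CDS synthesized by
# reverse-translating each residue through a fixed codon choice)
catalog_from_aa <- function(aa, genomeId, geneId) {
  code <- Biostrings::getGeneticCode("11")
  codon_of <- vapply(unique(code), function(a)
    names(code)[code == a][1], character(1))
  nt <- vapply(aa, function(s) {
    paste0(codon_of[strsplit(s, "")[[1]]], collapse = "")
  }, character(1), USE.NAMES = FALSE)
  geneCatalog(Biostrings::DNAStringSet(setNames(nt, geneId)),
              Biostrings::AAStringSet(setNames(aa, geneId)),
              genomeId = genomeId, geneId = geneId,
              checkTranslation = FALSE)
}
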