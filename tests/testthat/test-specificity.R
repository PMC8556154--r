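test_that("exact and reverse-complement planted sites are each one hit", {
  set.seed(51)
  primer <- "TCGCCGTTGCCTAAACCTAT"
  subj <- paste0(random_dna(200), primer, random_dna(200))
  hits <- findPrimerHits(primer, setNames(subj, "s1"))
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$strand, "+")
  expect_identical(hits$start, 200L)
  expect_identical(hits$end, 220L)
  expect_equal(hits$coverage, 1)
  expect_identical(hits$mismatches, 0L)

  subj2 <- paste0(random_dna(150), reverseComplementIupac(primer),
                  random_dna(100))
  hits2 <- findPrimerHits(primer, setNames(subj2, "s2"))
  expect_identical(nrow(hits2), 1L)
  expect_identical(hits2$strand, "-")
  expect_identical(hits2$start, 150L)
  expect_identical(hits2$end, 170L)
  expect_identical(substr(subj2, 151, 170), reverseComplementIupac(primer))
})

test_that("the 80% coverage rule is strict", {
  primer <- "ACGTTGCATGCGTAACGGTA"        # 20-mer
  # a subject starting with only the final 16 primer nt: best placement
  # covers 16/20 = 0.80, not strictly above the floor -> no viable hit
  subj16 <- paste0(substr(primer, 5, 20), random_dna(100))
  expect_identical(nrow(findPrimerHits(primer, subj16)), 0L)
  # 17/20 = 0.85 > 0.80 -> viable
  subj17 <- paste0(substr(primer, 4, 20), random_dna(100))
  h <- findPrimerHits(primer, subj17)
  expect_identical(nrow(h), 1L)
  expect_equal(h$coverage, 0.85)
  expect_identical(h$start, 0L)
  # a primer longer than the subject yields an empty table
  expect_identical(nrow(findPrimerHits(primer, "ACGT")), 0L)
})

test_that("degenerate primer hits match the brute-force scanner", {
  set.seed(61)
  for (rep in 1:8) {
    primer <- random_degenerate_primer(len = sample(18:21, 1))
    subj <- random_dna(800)
    # plant a mutated copy so some replicates have true hits
    if (rep %% 2 == 0) {
      site <- iupacExpand(primer, 4096L)[1]
      pos <- sample(100:600, 1)
      substr(subj, pos, pos + nchar(site) - 1) <- site
    }
    mine <- findPrimerHits(primer, subj)
    ref <- oracle_find_hits(primer, subj)
    expect_identical(nrow(mine), nrow(ref))
    if (nrow(ref)) {
      expect_identical(mine$strand, ref$strand)
      expect_identical(mine$start, as.integer(ref$start))
      expect_identical(mine$end, as.integer(ref$end))
      expect_identical(mine$mismatches, as.integer(ref$mismatches))
    }
  }
})

test_that("amplicon prediction applies the size window on outer edges", {
  fwd <- data.frame(subjectId = "s", strand = "+", start = 0L, end = 20L,
                    length = 20L, coverage = 1, mismatches = 0L,
                    stringsAsFactors = FALSE)
  rev <- data.frame(subjectId = "s", strand = "-", start = 380L, end = 400L,
                    length = 20L, coverage = 1, mismatches = 1L,
                    stringsAsFactors = FALSE)
  amp <- predictAmplicons(fwd, rev, 30L, 2000L)
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$productLen, 400L)
  # outside the window -> nothing
  far <- rev; far$start <- 2480L; far$end <- 2500L
  expect_identical(nrow(predictAmplicons(fwd, far, 30L, 2000L)), 0L)
  # reverse hit upstream of the forward hit -> nothing
  up <- rev; up$start <- 0L; up$end <- 20L
  fwd2 <- fwd; fwd2$start <- 300L; fwd2$end <- 320L
  expect_identical(nrow(predictAmplicons(fwd2, up, 30L, 2000L)), 0L)
})

screen_fixture <- function() {
  set.seed(71)
  fwd <- "TCGCCGTTGCCTAAACCTAT"
  rev <- "TTGAAGGAGTCTAGCAGCCG"
  own_gene <- paste0(random_dna(60), fwd, random_dna(260),
                     reverseComplementIupac(rev), random_dna(60))
  other_clean <- random_dna(420)
  # an off-target gene carrying both sites 450 bp apart
  other_hot <- paste0(random_dna(20), fwd, random_dna(388),
                      reverseComplementIupac(rev), random_dna(20))
  cat <- geneCatalog(
    Biostrings::DNAStringSet(c("g1|own" = substr(own_gene, 1, 420),
                               "g1|clean" = other_clean,
                               "g1|hot" = other_hot)),
    Biostrings::AAStringSet(c("g1|own" = strrep("X", 140),
                              "g1|clean" = strrep("X", 140),
                              "g1|hot" = strrep("X", 156))),
    genomeId = rep("g1", 3), geneId = c("g1|own", "g1|clean", "g1|hot"),
    checkTranslation = FALSE)
  clusters <- data.frame(geneId = c("g1|own", "g1|clean", "g1|hot"),
                         genomeId = "g1", clusterId = 1:3,
                         isCentroid = TRUE, stringsAsFactors = FALSE)
  pair <- data.frame(clusterId = 1L, fwdStart = 60L, fwdLen = 20L,
                     revStart = 340L, revLen = 20L,
                     fwdSeq = fwd, revSeq = rev, productLen = 300L,
                     fwdTm = 60, revTm = 60,
                     fwdDegSeq = fwd, revDegSeq = rev,
                     fwdDegeneracy = 1L, revDegeneracy = 1L,
                     fwdDeg3p = 0L, revDeg3p = 0L, degenerateOk = TRUE,
                     stringsAsFactors = FALSE)
  list(cat = cat, clusters = clusters, pair = pair, fwd = fwd, rev = rev)
}

test_that("two-stage screening rejects off-target amplification", {
  fx <- screen_fixture()
  # stage 1: the pair amplifies a different target gene at ~450 bp
  scr <- screenPrimerPairs(fx$pair, fx$cat, fx$clusters)
  expect_identical(nrow(scr$retained), 0L)
  expect_identical(scr$rejected$stage, "target_genome_off_target")
  expect_identical(scr$rejected$subjectId, "g1|hot")
  expect_gt(scr$rejected$offTargetLen, 30L)
  expect_lt(scr$rejected$offTargetLen, 2000L)

  # remove the hot gene: stage 1 passes; a decoy non-target then rejects at
  # stage 2, and without any decoy the pair is retained
  cat2 <- fx$cat[c("g1|own", "g1|clean")]
  cl2 <- fx$clusters[1:2, ]
  set.seed(72)
  decoy <- paste0(random_dna(100), fx$fwd, random_dna(480),
                  reverseComplementIupac(fx$rev), random_dna(100))
  scr2 <- screenPrimerPairs(fx$pair, cat2, cl2,
                            nonTarget = c(nt1 = decoy))
  expect_identical(scr2$rejected$stage, "non_target_clade")
  expect_identical(scr2$rejected$subjectId, "nt1")
  expect_identical(scr2$rejected$offTargetLen, 520L)
  scr3 <- screenPrimerPairs(fx$pair, cat2, cl2)
  expect_identical(nrow(scr3$retained), 1L)
  expect_identical(nrow(scr3$rejected), 0L)
  # retained and rejected partition the input
  expect_identical(nrow(scr2$retained) + nrow(scr2$rejected), nrow(fx$pair))
})

test_that("screening is subject-order independent and window-monotone", {
  fx <- screen_fixture()
  cat2 <- fx$cat[c("g1|own", "g1|clean")]
  cl2 <- fx$clusters[1:2, ]
  set.seed(73)
  decoys <- c(nt1 = random_dna(800),
              nt2 = paste0(random_dna(50), fx$fwd, random_dna(300),
                           reverseComplementIupac(fx$rev), random_dna(50)))
  a <- screenPrimerPairs(fx$pair, cat2, cl2, nonTarget = decoys)
  b <- screenPrimerPairs(fx$pair, cat2, cl2, nonTarget = decoys[c(2, 1)])
  expect_identical(nrow(a$rejected), nrow(b$rejected))
  expect_identical(a$rejected$stage, b$rejected$stage)
  # narrowing the window below the product length un-rejects; widening
  # never moves a rejected pair back to retained
  narrow <- screenPrimerPairs(fx$pair, cat2, cl2, nonTarget = decoys,
                              offTargetWindow = c(30L, 200L))
  expect_identical(nrow(narrow$retained), 1L)
  wide <- screenPrimerPairs(fx$pair, cat2, cl2, nonTarget = decoys,
                            offTargetWindow = c(30L, 5000L))
  expect_identical(nrow(wide$retained), 0L)
})
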