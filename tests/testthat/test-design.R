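# a conserved track (no variation) straight from a consensus string
conserved_track <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  new("ConsensusTrack", consensus = seq,
      variants = as.list(chars), masked = chars == "-")
}

test_that("candidate enumeration recovers a planted pair", {
  sim <- simulatePangenome(simulationConfig(substitutionProb = 0,
                                            seed = 3L))
  fam <- sim$planted$pairA$geneFamily
  ids <- sim$truth$geneId[sim$truth$family == fam]
  sub <- sim$catalog[ids]
  aln <- alignProteinCluster(setNames(as.character(aaSeqs(sub)), ids))
  track <- majorityConsensus(backTranslateAlignment(aln, sub))
  cand <- enumerateCandidates(track)
  pa <- sim$planted$pairA
  f0 <- pa$fwdStart - 1L
  r0 <- pa$revSiteStart - 1L
  hit <- cand$fwdStart == f0 & cand$fwdLen == 20L &
    cand$revStart == r0 & cand$revLen == 20L
  expect_true(any(hit))
  expect_identical(unique(cand$productLen[hit]), pa$productLen)
  expect_identical(cand$fwdSeq[hit][1], pa$fwd)
  expect_identical(cand$revSeq[hit][1], pa$rev)
  # deterministic order and the documented coordinate arithmetic
  expect_identical(cand$productLen,
                   cand$revStart + cand$revLen - cand$fwdStart)
  expect_true(all(diff(order(cand$fwdStart, cand$productLen)) > 0) ||
                !is.unsorted(cand$fwdStart))
})

test_that("degenerate or impossible constraints give an empty candidate set", {
  tr <- conserved_track(random_dna(50))
  expect_identical(nrow(enumerateCandidates(tr)), 0L)   # < productMin
  sim_tr <- conserved_track(random_dna(400))
  impossible <- designConstraints(tmMin = 95, tmOpt = 96, tmMax = 97)
  expect_identical(nrow(enumerateCandidates(sim_tr, impossible)), 0L)
})

test_that("window Tm from enumeration equals meltingTemperature", {
  set.seed(13)
  tr <- conserved_track(random_dna(300))
  cand <- enumerateCandidates(tr, designConstraints(productMin = 70L,
                                                    productMax = 300L))
  skip_if(nrow(cand) == 0L, "no candidate on this random consensus")
  i <- which.max(cand$productLen)
  expect_equal(cand$fwdTm[i], meltingTemperature(cand$fwdSeq[i]))
  expect_equal(cand$revTm[i],
               meltingTemperature(reverseComplementIupac(cand$revSeq[i])))
})

test_that("degeneracy injection unions column variants per position", {
  # alignment of three rows differing at two positions inside the windows
  base <- "ATGGCTACCGGTTACGCTGAAGCTTTCGGTATGGCTACCGGTTACGCTGGTAAAGAACGT"
  r2 <- base; substr(r2, 5, 5) <- "A"     # C -> A at column 5
  r3 <- base; substr(r3, 44, 44) <- "G"   # A -> G at column 44
  tr <- majorityConsensus(Biostrings::DNAStringSet(
    c(a = base, b = r2, c = r3)))
  pairs <- data.frame(fwdStart = 0L, fwdLen = 20L,
                      revStart = 40L, revLen = 20L,
                      fwdSeq = substr(base, 1, 20),
                      revSeq = reverseComplementIupac(substr(base, 41, 60)),
                      productLen = 60L, fwdTm = 60, revTm = 60,
                      stringsAsFactors = FALSE)
  out <- addDegeneracies(pairs, tr)
  expect_true(out$degenerateOk)
  expect_identical(substr(out$fwdDegSeq, 5, 5), "M")      # {A,C}
  # column 44 (A/G -> R) is offset 4 into the reverse window, so position
  # 20-4+1 = 17 of the 5'->3' reverse primer, complemented to Y
  expect_identical(substr(out$revDegSeq, 17, 17), "Y")
  expect_identical(out$fwdDegeneracy, 2)
  expect_identical(out$revDegeneracy, 2)
  # fully conserved windows come back unchanged
  tr0 <- conserved_track(base)
  out0 <- addDegeneracies(pairs, tr0)
  expect_identical(out0$fwdDegSeq, pairs$fwdSeq)
  expect_identical(out0$revDegSeq, pairs$revSeq)
})

test_that("windows over indel-variant columns are rejected, not thrown", {
  rows <- c(a = "ATGGCTACCGGTTACGCTGAAGCTTTCGGT",
            b = "ATG-CTACCGGTTACGCTGAAGCTTTCGGT",
            c = "ATGGCTACCGGTTACGCTGAAGCTTTCGGT")
  tr <- majorityConsensus(Biostrings::DNAStringSet(rows))
  pairs <- data.frame(fwdStart = 0L, fwdLen = 10L, revStart = 20L,
                      revLen = 10L, fwdSeq = "x", revSeq = "x",
                      productLen = 30L, fwdTm = 60, revTm = 60,
                      stringsAsFactors = FALSE)
  out <- addDegeneracies(pairs, tr)
  expect_false(out$degenerateOk)
  expect_true(is.na(out$fwdDegSeq))
})

test_that("degeneracy filtering enforces both budgets and is monotone", {
  mk <- function(fwd, rev) {
    df <- data.frame(fwdStart = 0L, fwdLen = nchar(fwd), revStart = 100L,
                     revLen = nchar(rev), fwdSeq = fwd, revSeq = rev,
                     productLen = 120L, fwdTm = 60, revTm = 60,
                     stringsAsFactors = FALSE)
    df$fwdDegSeq <- fwd; df$revDegSeq <- rev
    fs <- primerDegeneracy(fwd); rs <- primerDegeneracy(rev)
    df$fwdDegeneracy <- fs$total; df$revDegeneracy <- rs$total
    df$fwdDeg3p <- fs$n3prime; df$revDeg3p <- rs$n3prime
    df$degenerateOk <- TRUE
    df
  }
  # the printed worked-example pair passes the default budgets
  paper <- mk("TMARRACMCACTGCAGGGAC", "TCCGTGYTCAACYTTYTTCCT")
  expect_identical(nrow(filterDegeneracy(paper)), 1L)
  # one degenerate code inside the final five nucleotides -> removed
  tail_deg <- mk("ACGTTGCATGCGTAACGYTA", "ACGTTGCATGCGTAACGGTA")
  expect_identical(nrow(filterDegeneracy(tail_deg)), 0L)
  expect_identical(nrow(filterDegeneracy(
    tail_deg, designConstraints(max3PrimeDegeneracy = 1L))), 1L)
  # over-degenerate primer -> removed; relaxing the cap readmits it
  heavy <- mk("NNNRACMCACTGCAGGGAC", "TCCGTGTCAACTTTTTCCT")
  expect_identical(nrow(filterDegeneracy(heavy)), 0L)
  expect_identical(nrow(filterDegeneracy(
    heavy, designConstraints(maxDegeneracy = 256L))), 1L)
  # zero-degeneracy pairs always survive
  clean <- mk("ACGTTGCATGCGTAACGGTA", "TGCAACGTACGCATTGCCAT")
  expect_identical(nrow(filterDegeneracy(clean)), 1L)
})

test_that("emitted degenerate primers cover exactly the observed variation", {
  sim <- simulatePangenome(simulationConfig(seed = 17L))
  fam <- sim$planted$pairA$geneFamily
  ids <- sim$truth$geneId[sim$truth$family == fam]
  sub <- sim$catalog[ids]
  aln <- alignProteinCluster(setNames(as.character(aaSeqs(sub)), ids))
  cdn <- backTranslateAlignment(aln, sub)
  track <- majorityConsensus(cdn)
  cand <- filterDegeneracy(addDegeneracies(
    enumerateCandidates(track, maxWindows = 20), track))
  skip_if(nrow(cand) == 0L)
  rows <- as.character(codonRows(cdn))
  for (i in seq_len(min(5L, nrow(cand)))) {
    fwd <- cand$fwdDegSeq[i]
    # the concrete consensus window is one of the expansions
    expect_true(cand$fwdSeq[i] %in% iupacExpand(fwd))
    # every position's code is attained by some alignment row (degeneracy is
    # the union of observed symbols, never more)
    win <- substring(rows, cand$fwdStart[i] + 1L,
                     cand$fwdStart[i] + cand$fwdLen[i])
    for (p in seq_len(nchar(fwd))) {
      obs <- unique(substr(win, p, p))
      expect_identical(iupacUnion(obs), substr(fwd, p, p))
    }
  }
})

test_that("internal probes stay between the primers and meet their Tm band", {
  # conserved consensus with a planted GC-rich probe window between sites
  set.seed(23)
  fwd <- "TCGCCGTTGCCTAAACCTAT"
  rev <- "TTGAAGGAGTCTAGCAGCCG"
  probe <- "CCGCTGGCAGGCATCGTGGTGA"   # 22-mer, Tm ~ primer band + 8
  cons <- paste0(random_dna(30), fwd, random_dna(60), probe,
                 random_dna(60), reverseComplementIupac(rev),
                 random_dna(30))
  tr <- conserved_track(cons)
  cand <- enumerateCandidates(tr, maxWindows = 40)
  pairs <- addDegeneracies(cand, tr)
  pairs <- designInternalProbes(pairs, tr)
  wp <- !is.na(pairs$probeSeq)
  skip_if(!any(wp), "no probe-compatible pair on this fixture")
  expect_true(all(pairs$probeStart[wp] >=
                    pairs$fwdStart[wp] + pairs$fwdLen[wp]))
  expect_true(all(pairs$probeStart[wp] + pairs$probeLen[wp] <=
                    pairs$revStart[wp]))
  expect_true(all(pairs$probeTm[wp] >= designConstraints()$tmMin + 8))
  # a pair whose insert is too short gets no probe
  short <- data.frame(fwdStart = 0L, fwdLen = 20L, revStart = 25L,
                      revLen = 20L, fwdSeq = "x", revSeq = "x",
                      productLen = 45L, fwdTm = 60, revTm = 60,
                      fwdDegSeq = "x", revDegSeq = "x",
                      fwdDegeneracy = 1L, revDegeneracy = 1L,
                      fwdDeg3p = 0L, revDeg3p = 0L, degenerateOk = TRUE,
                      stringsAsFactors = FALSE)
  out <- designInternalProbes(short, tr)
  expect_true(is.na(out$probeSeq))
})
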