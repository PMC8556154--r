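test_that("identical configuration and seed give byte-identical output", {
  cfg <- simulationConfig(seed = 12L)
  s1 <- simulatePangenome(cfg)
  s2 <- simulatePangenome(cfg)
  expect_identical(as.character(ntSeqs(s1$catalog)),
                   as.character(ntSeqs(s2$catalog)))
  expect_identical(as.character(s1$genomes), as.character(s2$genomes))
  expect_identical(as.character(s1$nonTarget), as.character(s2$nonTarget))
  expect_identical(s1$truth, s2$truth)
  # writing the fixture twice gives identical files
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  writeSimulatedPangenome(s1, d1)
  writeSimulatedPangenome(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("zero divergence reproduces the ancestor in every genome", {
  sim <- simulatePangenome(simulationConfig(substitutionProb = 0,
                                            seed = 4L))
  nt <- setNames(as.character(ntSeqs(sim$catalog)), geneIds(sim$catalog))
  for (fam in unique(sim$truth$family)) {
    copies <- nt[sim$truth$geneId[sim$truth$family == fam]]
    expect_identical(length(unique(copies)), 1L)
  }
})

test_that("observed substitution counts match the configured rate", {
  # 50 replicate one-genome simulations; the p = 0 twin of each replicate
  # recovers the ancestor, so substitutions can be counted exactly
  p <- 0.02
  n_sub <- 0L; n_sites <- 0L
  for (seed in 1:50) {
    mk <- function(prob) simulatePangenome(simulationConfig(
      nTargetGenomes = 1L, nCoreGenes = 1L,
      geneLengthRange = c(120L, 120L), substitutionProb = prob,
      plantPrimerSites = FALSE, plantDecoy = FALSE,
      nOffTargetGenomes = 0L, seed = seed))
    anc <- strsplit(as.character(ntSeqs(mk(0)$catalog))[[1]], "")[[1]]
    obs <- strsplit(as.character(ntSeqs(mk(p)$catalog))[[1]], "")[[1]]
    n_sub <- n_sub + sum(anc != obs)
    n_sites <- n_sites + length(anc)
  }
  ci <- qbinom(c(0.005, 0.995), n_sites, p)
  expect_gte(n_sub, ci[1])
  expect_lte(n_sub, ci[2])
})

test_that("planted windows are conserved and ground truth matches identity", {
  sim <- simulatePangenome(simulationConfig(seed = 8L))
  nt <- setNames(as.character(ntSeqs(sim$catalog)), geneIds(sim$catalog))
  for (nm in c("pairA", "pairB")) {
    pl <- sim$planted[[nm]]
    ids <- sim$truth$geneId[sim$truth$family == pl$geneFamily]
    fwd_windows <- substring(nt[ids], pl$fwdStart, pl$fwdStart + 19L)
    expect_identical(unique(unname(fwd_windows)), pl$fwd)
    rev_windows <- substring(nt[ids], pl$revSiteStart, pl$revSiteStart + 19L)
    expect_identical(unique(unname(rev_windows)),
                     reverseComplementIupac(pl$rev))
  }
  # decoy near-match carries the configured number of mismatches
  d <- as.character(sim$nonTarget[[sim$planted$decoy$subject]])
  pb <- sim$planted$pairB
  dec_f <- substr(d, sim$planted$decoy$fwdStart,
                  sim$planted$decoy$fwdStart + 19L)
  expect_identical(sum(strsplit(dec_f, "")[[1]] !=
                         strsplit(pb$fwd, "")[[1]]),
                   sim$config$decoyMismatches)

  # truth families agree with brute-force all-vs-all identity grouping
  small <- simulatePangenome(simulationConfig(
    nTargetGenomes = 3L, nCoreGenes = 3L, geneLengthRange = c(60L, 90L),
    plantPrimerSites = FALSE, plantDecoy = FALSE, nOffTargetGenomes = 0L,
    seed = 14L))
  aa <- setNames(as.character(aaSeqs(small$catalog)),
                 geneIds(small$catalog))
  n <- length(aa)
  same <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    if (i == j) return(TRUE)
    pairwiseIdentityCoverage(aa[[i]], aa[[j]])[["identity"]] >= 0.8
  }))
  fam <- small$truth$family[match(names(aa), small$truth$geneId)]
  expect_identical(unname(same), outer(fam, fam, "=="))
})

test_that("plantPrimerSite validates geometry and collisions", {
  gene <- strrep("ACGT", 30)
  out <- plantPrimerSite(gene, "TTTTT", 10L)
  expect_identical(substr(as.character(out), 10, 14), "TTTTT")
  expect_identical(nchar(out), nchar(gene))
  expect_error(plantPrimerSite(gene, "TTTTT", 118L), "fit")
  expect_error(plantPrimerSite(as.character(out), "GGGGG", 12L,
                               occupied = attr(out, "planted")),
               "collides")
  expect_error(simulationConfig(plantedProductLen = 400L,
                                geneLengthRange = c(100L, 120L)),
               "fit")
  expect_error(simulationConfig(substitutionProb = 1.5), "\\[0, 1\\]")
})
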