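# Synthetic pan-genome generator: a star-phylogeny clade of genomes sharing
# planted single-copy core genes at controlled divergence, with optional
# planted primer sites (conserved windows) and off-target decoys carrying
# near-matches to a planted site.  Every stage of the pipeline is testable
# against the generator's ground truth.

# planted 20-mers chosen once to satisfy the default design constraints
# (Tm ~60 degC at default conditions, GC 40-60%, homopolymer <= 4)
.PLANTED_PRIMERS <- list(
  pairA = c(fwd = "TCGCCGTTGCCTAAACCTAT", rev = "TTGAAGGAGTCTAGCAGCCG"),
  pairB = c(fwd = "TCCGTGTTACCAGACCAAAC", rev = "CGCGTGAATGAAGCGCTTAA")
)

#' Configuration of a synthetic pan-genome simulation
#'
#' The defaults define the standard fixture: a clade of 5 genomes carrying 8
#' single-copy core genes of 120-250 codons, diverged from a common ancestor
#' at 2\% substitutions per site (biased 3:1 toward third codon positions so
#' amino-acid identity stays high while nucleotide variation -- the regime
#' degenerate primers must absorb -- is exercised), plus one off-target
#' decoy genome. Two primer-site pairs are planted in different core genes:
#' a clean pair, and a pair whose binding sites also occur in the decoy with
#' 2 mismatches per primer (so specificity screening must reject it).
#'
#' @param nTargetGenomes number of target-clade genomes.
#' @param nCoreGenes number of planted single-copy core gene families.
#' @param geneLengthRange gene length range in codons (min, max).
#' @param substitutionProb mean per-site nucleotide substitution probability
#'   per genome.
#' @param nOffTargetGenomes number of off-target decoy genomes.
#' @param plantPrimerSites plant the two primer-site pairs (logical).
#' @param plantDecoy give the first decoy genome near-matches (at
#'   \code{decoyMismatches} mismatches per primer site) to the second
#'   planted pair (logical).
#' @param decoyMismatches mismatches per planted site in the decoy.
#' @param plantedProductLen planted amplicon length, bp.
#' @param spacerLengthRange intergenic spacer length range, bp.
#' @param seed integer RNG seed; identical config + seed gives byte-identical
#'   output.
#' @return A named list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nTargetGenomes = 5L, nCoreGenes = 8L,
                             geneLengthRange = c(120L, 250L),
                             substitutionProb = 0.02,
                             nOffTargetGenomes = 1L,
                             plantPrimerSites = TRUE,
                             plantDecoy = TRUE,
                             decoyMismatches = 2L,
                             plantedProductLen = 299L,
                             spacerLengthRange = c(50L, 500L),
                             seed = 1L) {
  cfg <- list(nTargetGenomes = as.integer(nTargetGenomes),
              nCoreGenes = as.integer(nCoreGenes),
              geneLengthRange = as.integer(geneLengthRange),
              substitutionProb = substitutionProb,
              nOffTargetGenomes = as.integer(nOffTargetGenomes),
              plantPrimerSites = isTRUE(plantPrimerSites),
              plantDecoy = isTRUE(plantDecoy),
              decoyMismatches = as.integer(decoyMismatches),
              plantedProductLen = as.integer(plantedProductLen),
              spacerLengthRange = as.integer(spacerLengthRange),
              seed = as.integer(seed))
  if (cfg$nTargetGenomes < 1L || cfg$nCoreGenes < 1L ||
      cfg$nOffTargetGenomes < 0L)
    stop("counts must be positive", call. = FALSE)
  if (cfg$substitutionProb < 0 || cfg$substitutionProb > 1)
    stop("substitutionProb must be in [0, 1]", call. = FALSE)
  if (cfg$plantPrimerSites && cfg$nCoreGenes < 2L && cfg$plantDecoy)
    stop("planting the decoy pair needs at least 2 core genes", call. = FALSE)
  if (cfg$plantPrimerSites &&
      cfg$plantedProductLen + 6L > 3L * cfg$geneLengthRange[1L])
    stop("planted amplicon does not fit inside the shortest gene",
         call. = FALSE)
  structure(cfg, class = c("SimulationConfig", "list"))
}

.SENSE_CODONS <- NULL  # filled on first use

.sense_codons <- function() {
  code <- Biostrings::getGeneticCode("11")
  names(code)[code != "*"]
}

#' Overwrite a window of a gene with a planted primer site
#'
#' Replaces the subsequence at \code{start} (1-based) with \code{site}. Used
#' by the simulator to plant conserved, constraint-satisfying primer
#' binding windows; exposed so tests can build fixtures by construction.
#'
#' @param gene nucleotide sequence (character scalar).
#' @param site sequence to plant.
#' @param start 1-based start position.
#' @param occupied optional integer vector of already-planted positions; a
#'   collision is an error.
#' @return The modified gene, with attribute \code{"planted"} giving the
#'   occupied positions.
#' @export
plantPrimerSite <- function(gene, site, start, occupied = integer(0)) {
  n <- nchar(gene); L <- nchar(site)
  if (start < 1L || start + L - 1L > n)
    stop("planted window does not fit inside the gene", call. = FALSE)
  span <- seq.int(start, start + L - 1L)
  if (length(intersect(span, occupied)))
    stop("planted window collides with an existing planted site",
         call. = FALSE)
  out <- paste0(substr(gene, 1L, start - 1L), site,
                substr(gene, start + L, n))
  attr(out, "planted") <- c(occupied, span)
  out
}

.random_seq <- function(n) paste0(sample(c("A", "C", "G", "T"), n,
                                         replace = TRUE), collapse = "")

# introduce k mismatches into a concrete site (never at the same position
# twice); used for decoy construction
.mutate_site <- function(site, k) {
  chars <- strsplit(site, "")[[1L]]
  pos <- sample(seq_along(chars), k)
  for (p in pos)
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  paste0(chars, collapse = "")
}

#' Simulate a pan-genome with planted ground truth
#'
#' Draws ancestral CDSs (random sense codons, no internal stops), plants
#' primer sites per the configuration, then evolves each target genome
#' independently (star phylogeny): every unprotected site mutates i.i.d.
#' with the configured probability, 3:1 biased toward third codon
#' positions; a substitution that would create an internal stop codon is
#' reverted. Genomes are concatenations of the genes with random intergenic
#' spacers. Off-target genomes are random sequence, the first optionally
#' carrying decoy near-matches to the second planted primer pair.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return A list with components:
#'   \describe{
#'     \item{catalog}{\code{\linkS4class{GeneCatalog}} of all target-clade
#'       CDSs (gene ids \code{"<genome>|gene<k>"});}
#'     \item{genomes}{\code{DNAStringSet} of target genome sequences;}
#'     \item{nonTarget}{\code{DNAStringSet} of off-target genomes;}
#'     \item{truth}{\code{data.frame}: one row per gene with its true
#'       family, plus planted-site annotations;}
#'     \item{planted}{list describing the planted primer pairs (sequences
#'       and host gene families), or \code{NULL};}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulatePangenome <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)

  sense <- .sense_codons()
  n_genes <- config$nCoreGenes
  gene_len <- sample(seq.int(config$geneLengthRange[1L],
                             config$geneLengthRange[2L]),
                     n_genes, replace = TRUE)
  ancestors <- vapply(gene_len, function(l)
    paste0(sample(sense, l, replace = TRUE), collapse = ""), character(1))

  protected <- rep(list(integer(0)), n_genes)
  planted <- NULL
  if (config$plantPrimerSites) {
    planted <- list()
    hosts <- seq_len(min(2L, n_genes))
    for (k in seq_along(hosts)) {
      g <- hosts[k]
      pr <- .PLANTED_PRIMERS[[k]]
      amp <- config$plantedProductLen
      glen <- nchar(ancestors[g])
      f_start <- max(1L, (glen - amp) %/% 2L)
      f_start <- f_start - (f_start - 1L) %% 3L   # codon-aligned
      r_site <- reverseComplementIupac(pr[["rev"]])
      r_start <- f_start + amp - nchar(r_site)
      gene <- plantPrimerSite(ancestors[g], pr[["fwd"]], f_start)
      occ <- attr(gene, "planted")
      gene <- plantPrimerSite(gene, r_site, r_start, occupied = occ)
      protected[[g]] <- attr(gene, "planted")
      ancestors[g] <- as.character(gene)
      codons <- substring(ancestors[g], seq(1L, nchar(ancestors[g]), 3L),
                          seq(3L, nchar(ancestors[g]), 3L))
      if (!all(codons %in% sense))
        stop("planted site introduces an in-frame stop codon; choose a ",
             "different planted sequence or position", call. = FALSE)
      planted[[names(.PLANTED_PRIMERS)[k]]] <- list(
        geneFamily = g, fwd = unname(pr[["fwd"]]), rev = unname(pr[["rev"]]),
        fwdStart = f_start, revSiteStart = r_start, productLen = amp)
    }
  }

  # per-site substitution probabilities: positions 1,2 at 0.6p, position 3
  # at 1.8p, so the mean over a codon is p with a 3:1 third-position bias
  site_probs <- function(n_nt) {
    p <- config$substitutionProb
    rep(c(0.6, 0.6, 1.8), length.out = n_nt) * p
  }

  genome_names <- sprintf("tg%02d", seq_len(config$nTargetGenomes))
  nt_all <- character(0); genome_all <- character(0); gene_all <- character(0)
  family_all <- integer(0)
  genomes <- setNames(character(length(genome_names)), genome_names)
  for (gi in seq_along(genome_names)) {
    gname <- genome_names[gi]
    parts <- character(0)
    for (g in seq_len(n_genes)) {
      chars <- strsplit(ancestors[g], "")[[1L]]
      probs <- site_probs(length(chars))
      probs[protected[[g]]] <- 0
      hit <- which(stats::runif(length(chars)) < probs)
      for (p in hit) {
        old <- chars[p]
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        codon_i <- (p - 1L) %/% 3L
        codon <- paste0(chars[(codon_i * 3L + 1L):(codon_i * 3L + 3L)],
                        collapse = "")
        if (!codon %in% sense) chars[p] <- old   # no internal stops
      }
      cds <- paste0(chars, collapse = "")
      gene_id <- sprintf("%s|gene%02d", gname, g)
      nt_all <- c(nt_all, cds)
      genome_all <- c(genome_all, gname)
      gene_all <- c(gene_all, gene_id)
      family_all <- c(family_all, g)
      parts <- c(parts, .random_seq(sample(
        seq.int(config$spacerLengthRange[1L], config$spacerLengthRange[2L]),
        1L)), cds)
    }
    genomes[gname] <- paste0(c(parts, .random_seq(sample(
      seq.int(config$spacerLengthRange[1L], config$spacerLengthRange[2L]),
      1L))), collapse = "")
  }

  nt <- DNAStringSet(setNames(nt_all, gene_all))
  aa <- Biostrings::translate(nt, genetic.code = getGeneticCode("11"))
  catalog <- geneCatalog(nt, aa, genomeId = genome_all, geneId = gene_all,
                         checkTranslation = FALSE)

  non_target <- DNAStringSet()
  if (config$nOffTargetGenomes > 0L) {
    nt_names <- sprintf("decoy%02d", seq_len(config$nOffTargetGenomes))
    seqs <- vapply(nt_names, function(x) .random_seq(3000L), character(1))
    if (config$plantDecoy && !is.null(planted) && length(planted) >= 2L) {
      pb <- planted[[2L]]
      f_site <- .mutate_site(pb$fwd, config$decoyMismatches)
      r_site <- .mutate_site(reverseComplementIupac(pb$rev),
                             config$decoyMismatches)
      d <- seqs[[1L]]
      d_f <- 500L
      d_r <- d_f + pb$productLen - nchar(r_site)
      d <- plantPrimerSite(d, f_site, d_f)
      d <- plantPrimerSite(as.character(d), r_site, d_r,
                           occupied = attr(d, "planted"))
      seqs[[1L]] <- as.character(d)
      planted$decoy <- list(subject = nt_names[1L], fwdStart = d_f,
                            revSiteStart = d_r, productLen = pb$productLen,
                            mismatchesPerSite = config$decoyMismatches)
    }
    non_target <- DNAStringSet(setNames(seqs, nt_names))
  }

  truth <- data.frame(geneId = gene_all, genomeId = genome_all,
                      family = family_all, stringsAsFactors = FALSE)
  list(catalog = catalog, genomes = DNAStringSet(genomes),
       nonTarget = non_target, truth = truth, planted = planted,
       config = config)
}

#' Write a simulated pan-genome fixture to disk
#'
#' Emits the genome FASTA, CDS nucleotide FASTA, protein FASTA, non-target
#' FASTA and ground-truth TSV for a simulation result.
#'
#' @param sim result of \code{\link{simulatePangenome}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
writeSimulatedPangenome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genomes = file.path(dir, "target_genomes.fna"),
             nt = file.path(dir, "target_genes.fna"),
             aa = file.path(dir, "target_genes.faa"),
             nonTarget = file.path(dir, "non_target.fna"),
             truth = file.path(dir, "truth.tsv"))
  writeXStringSet(sim$genomes, paths[["genomes"]])
  writeXStringSet(ntSeqs(sim$catalog), paths[["nt"]])
  writeXStringSet(aaSeqs(sim$catalog), paths[["aa"]])
  writeXStringSet(sim$nonTarget, paths[["nonTarget"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
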