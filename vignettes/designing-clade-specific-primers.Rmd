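---
title: "Designing clade-specific degenerate qPCR primers from single-copy core genes"
author: "cladePrimers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing clade-specific degenerate qPCR primers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladePrimers)
```

## The problem

Quantifying one microbial clade in a complex community by qPCR needs a
primer pair that (i) amplifies **every** member of the clade despite
sequence variation among its genomes, and (ii) amplifies **nothing else**.
`cladePrimers` solves this by designing primers on single-copy core genes of
the clade's pan-genome:

1. **Pan-genome clustering.** All protein sequences from the target genomes
   are clustered greedily at 80% identity / 90% coverage (centroid
   clustering, longest-first). Clusters with exactly one member in every
   genome are the *single-copy core* — present everywhere, and free of the
   copy-number ambiguity that would distort quantification.
2. **Codon alignment and consensus.** Each core cluster is aligned at the
   protein level (center-star, BLOSUM62, affine gaps 11/1), back-translated
   codon-by-codon into a nucleotide alignment, and summarized as a majority
   consensus with per-column variant sets.
3. **Candidate enumeration.** All primer-pair windows on the consensus that
   satisfy thermodynamic and structural constraints are enumerated.
4. **Degeneracy injection.** Each primer position is widened to the minimal
   IUPAC code covering *all* bases observed in its alignment column, so the
   primer pool matches every genome. Pairs exceeding the degeneracy budgets
   are discarded.
5. **In-silico PCR screening.** Pairs that could produce an off-target
   product — first on any other gene of the target genomes, then on any
   non-target sequence — are removed.

The deliverable is a ranked table of degenerate primer pairs with lengths,
mean melting temperatures, degeneracy statistics and screening outcomes.

## The melting-temperature model

Primer Tm is computed with the unified nearest-neighbor thermodynamic
parameters (SantaLucia 1998): duplex initiation terms with terminal A/T
penalties, dinucleotide stacking enthalpies and entropies, and

$$T_m = \frac{\Delta H^\circ}{\Delta S^\circ + 0.368\,(N-1)\ln[\mathrm{Mon}^+] + R \ln(C_T/4)} - 273.15$$

with the oligonucleotide at $C_T$ = 50 nM (neither strand in excess,
non-self-complementary, hence $C_T/4$). Divalent cations are converted to a
monovalent equivalent as $[\mathrm{Mon}^+] = \mathrm{monovalent} +
120\sqrt{[\mathrm{Mg}^{2+}]}$ (concentrations in mM). dNTP chelation of
Mg²⁺ is *not* modeled by default — the package's worked examples are
calibrated to this total-divalent dialect, which reproduces published
reference values for degenerate primer pairs to within 0.3 °C; the
chelation-correcting variant ($120\sqrt{\mathrm{Mg}-\mathrm{dNTP}}$) is
available via `chelateDntp = TRUE` and lowers a typical 20-mer by roughly
0.9 °C.

A degenerate primer is a *pool* of concrete oligos; its reported Tm is the
arithmetic mean over all expansions:

```{r}
meanPrimerTm("TMARRACMCACTGCAGGGAC")    # pool of 16
primerDegeneracy("TMARRACMCACTGCAGGGAC")
```

## Design constraints and their defaults

| Constraint | Default | Why |
|---|---|---|
| primer length | 18/20/25 nt (min/opt/max) | standard qPCR primer range |
| Tm | 57/60/63 °C, pair ΔTm ≤ 3 | both primers efficient at one annealing temperature |
| GC | 30–70% | stable but not kinetically trapped annealing |
| homopolymer | ≤ 4 | avoids slippage and synthesis artifacts |
| product size | 70–1000 bp | spans qPCR (short) through endpoint PCR |
| total degeneracy | ≤ 32 per primer | pool dilution: each expansion is at 1/pool of the nominal concentration |
| 3′ degeneracy | 0 in the final 5 nt | 3′ mismatches and ambiguity impair polymerase extension most |
| self-complementary run | ≤ 8 nt | coarse hairpin/self-dimer guard (no ΔG folding) |

Degeneracy is taken from the raw column variant sets with no
minor-allele-frequency floor: a base seen in a single genome still widens
the primer, because the goal is amplification of *all* clade members. Any
column whose variant set contains a gap disqualifies overlapping windows —
a primer cannot reliably span an indel polymorphism.

## In-silico PCR semantics

Binding sites are searched under IUPAC compatibility (a primer code matches
a template base when their concrete-base sets intersect). Placements are
3′-anchored: only the 5′ end may be truncated, because polymerase extension
requires a paired 3′ terminus. A placement is *viable* when it covers
strictly more than 80% of the primer (a 16/20 alignment is not viable;
17/20 is) and carries at most 3 mismatches (the mismatch cap is a
configurable stand-in for the short-word local-alignment search of
BLAST-style screening, which does not publish equivalent thresholds). Per
strand and 3′ anchor the single longest viable placement is reported;
mismatch count is monotone under 5′ extension, so this is well defined.

Two hits on opposite strands within 30–2000 bp (outer edge to outer edge)
constitute a predicted product. A candidate pair is rejected if it predicts
a product on any target-clade gene outside its own cluster (stage 1) or on
any non-target sequence (stage 2); products on its own cluster's genes are
the intended target and never cause rejection.

## Candidate ranking

Enumerating every valid window pair on a ~500 bp consensus yields $10^5$–
$10^6$ pairs, almost all of them near-duplicates shifted by a few bases.
Following the pick-best-then-pair strategy of conventional primer
designers, the pipeline (i) keeps the best `maxWindowsPerCluster = 60`
single-primer windows per cluster (closest to the Tm and length optima,
lowest degeneracy), then (ii) ranks the resulting pairs by a deterministic
penalty — $|T_m^{fwd}-T_{opt}| + |T_m^{rev}-T_{opt}| + \Delta T_m +
0.25\,|\ell-\ell_{opt}|\text{-terms} + 0.5\log_2(\text{pool sizes})$ — and
carries the top `maxPairsPerCluster = 500` into screening. Ties break on
coordinates, so a rerun is byte-identical. Both caps are exposed as
parameters; `enumerateCandidates()` itself returns the complete set when
called with `maxWindows = Inf`.

## The synthetic pan-genome

`simulatePangenome()` provides fixtures with known ground truth. Defaults
describe the standard study conditions: 5 target genomes sharing 8
single-copy core genes of 120–250 codons, diverged independently from a
common ancestor (star phylogeny) at 2% substitutions per site, biased 3:1
toward third codon positions so amino-acid identity stays high while
nucleotide variation — the regime degenerate primers must absorb — is
exercised. Substitutions that would create an in-frame stop are reverted.
Two primer-site pairs are planted as mutation-protected windows: a clean
pair, and a pair mirrored into an off-target decoy genome at 2 mismatches
per site, which the stage-2 screen must reject. Planted sequences were
chosen once by filtering random 20-mers through the default constraints
(Tm ≈ 60 °C, GC 40–60%, homopolymer ≤ 4); the planted product length is
299 bp so both sites sit on codon boundaries without creating stops.

What the simulator does *not* emulate — and what passing tests therefore do
not establish about real data: tree-structured (non-star) evolution, indels
inside genes, horizontal transfer, annotation errors, fragmented
assemblies, and compositional bias. The real application of this design
approach used 16 dereplicated genomes of a target genus; the 5-genome
default keeps the fixture desk-scale. Genome quality metrics
(completeness/contamination) are consumed as metadata and thresholded at
≥ 90% / ≤ 5% — the package never computes them, and expects dereplicated
genomes as input.

## Numerical and degenerate-input choices

* Consensus ties break by the fixed order A < C < G < T < gap; columns with
  a gap majority are masked.
* All internal coordinates are 0-based half-open; report files are 1-based
  inclusive (stated in their header).
* Clustering sorts by length then gene id, so the partition is
  reproducible; coverage is bidirectional (both sequences ≥ threshold).
* An empty candidate list, a cluster set without single-copy core members,
  or a screen that rejects everything are all clean "no candidates"
  outcomes, not errors.
* `meanPrimerTm()` refuses pools above 512 expansions rather than silently
  averaging an enormous pool.

## Problem sizes used by the test suite

The suite validates the scanner against a brute-force oracle on 50 random
5 kb subjects × 20 degenerate primers, round-trips back-translation over
100 simulated clusters, and runs the full pipeline twice on the default
5-genome fixture to check planted-pair recovery, decoy rejection and
byte-determinism. These sizes exercise every code path at desk scale; the
algorithms are quadratic at worst in gene length and linear in subject
length, so scaling to dozens of genomes is a matter of minutes, not design
changes.

## Known limitations

* The center-star aligner is exact for 2 sequences and a good approximation
  at the high identities (≥ 85% amino acid) of core-gene clusters; an
  external MSA tool can be substituted upstream by importing a gapped FASTA.
* Hairpin/self-dimer screening is a complementary-run heuristic, not a
  thermodynamic folding calculation.
* Off-target screening is exhaustive scanning, appropriate for gene
  catalogues and small genome sets rather than nr-scale databases.
* Stage outputs (clusters, alignments, report) are written as re-loadable
  TSV/FASTA artifacts, but there is no single-command resume; re-running a
  stage means calling its module function on the saved artifact.
* Cluster annotation (e.g. BLAST against external databases) is out of
  scope; the report carries cluster ids and coordinates only.
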