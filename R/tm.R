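# Nearest-neighbor duplex melting temperature, SantaLucia (1998) unified
# parameters.  dH in kcal/mol, dS in cal/(mol K), for the 5'->3' dinucleotide
# on the top strand (each entry equals its reverse complement's).
.NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
.NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)
.R_GAS <- 1.987  # cal/(mol K)

#' PCR reaction conditions for melting-temperature estimation
#'
#' Container for the solution conditions under which primer melting
#' temperatures are computed. Defaults mirror common primer-design practice:
#' 50 nM annealing oligo, 50 mM monovalent cation, 1.5 mM divalent cation
#' and 0.6 mM total dNTP.
#'
#' @param oligo_nM annealing oligonucleotide concentration (nM).
#' @param monovalent_mM monovalent cation concentration (mM).
#' @param divalent_mM divalent cation (Mg2+) concentration (mM).
#' @param dntp_mM total dNTP concentration (mM).
#' @return A named list of class \code{"ReactionConditions"}.
#' @examples
#' reactionConditions()
#' @export
reactionConditions <- function(oligo_nM = 50, monovalent_mM = 50,
                               divalent_mM = 1.5, dntp_mM = 0.6) {
  vals <- c(oligo_nM, monovalent_mM, divalent_mM, dntp_mM)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("reaction conditions must be finite and non-negative", call. = FALSE)
  structure(list(oligo_nM = oligo_nM, monovalent_mM = monovalent_mM,
                 divalent_mM = divalent_mM, dntp_mM = dntp_mM),
            class = "ReactionConditions")
}

#' @export
print.ReactionConditions <- function(x, ...) {
  cat(sprintf(
    "ReactionConditions: %g nM oligo, %g mM monovalent, %g mM divalent, %g mM dNTP\n",
    x$oligo_nM, x$monovalent_mM, x$divalent_mM, x$dntp_mM))
  invisible(x)
}

# monovalent-equivalent cation concentration (mM).  Divalent cations are
# converted with the 120*sqrt([Mg2+]) equivalence; by default the total
# divalent pool is used (dNTP chelation of Mg2+ not modeled), which is the
# dialect this package's worked examples are calibrated to.  chelateDntp =
# TRUE subtracts the dNTP concentration (clamped at zero) before converting.
.monovalent_equivalent <- function(cond, chelateDntp = FALSE) {
  dv <- cond$divalent_mM
  if (chelateDntp) dv <- max(dv - cond$dntp_mM, 0)
  cond$monovalent_mM + 120 * sqrt(dv)
}

#' Nearest-neighbor melting temperature of a concrete primer
#'
#' Duplex melting temperature of a non-degenerate (A/C/G/T-only)
#' oligonucleotide against its perfect complement, from the unified
#' nearest-neighbor thermodynamic parameters (SantaLucia 1998) with duplex
#' initiation and terminal A/T penalties, an entropy-based salt correction
#' (0.368 (N-1) ln[Mon+]) and divalent cations converted to a monovalent
#' equivalent. The annealing concentration enters as C_T/4 (non-self-
#' complementary duplex, neither strand in excess).
#'
#' @param x concrete sequence (character scalar), length >= 8.
#' @param cond a \code{\link{reactionConditions}} object.
#' @param chelateDntp subtract the dNTP concentration from the divalent pool
#'   before the monovalent-equivalence step (default \code{FALSE}).
#' @return Melting temperature in degrees Celsius.
#' @examples
#' meltingTemperature("ACGTACGTACGTACGTACGT")
#' @export
meltingTemperature <- function(x, cond = reactionConditions(),
                               chelateDntp = FALSE) {
  chars <- .seq_chars(x)
  .check_iupac(chars)
  if (any(.IUPAC_CARD[chars] > 1L))
    stop("sequence contains degenerate codes; use meanPrimerTm()",
         call. = FALSE)
  n <- length(chars)
  if (n < 8L)
    stop("sequence too short for the nearest-neighbor model (need >= 8 nt)",
         call. = FALSE)
  dh <- 0; ds <- 0
  for (end_base in chars[c(1L, n)]) {      # duplex initiation
    if (end_base %in% c("A", "T")) { dh <- dh + 2.3; ds <- ds + 4.1 }
    else                           { dh <- dh + 0.1; ds <- ds - 2.8 }
  }
  steps <- paste0(chars[-n], chars[-1L])
  dh <- dh + sum(.NN_DH[steps])
  ds <- ds + sum(.NN_DS[steps])
  mon_M <- .monovalent_equivalent(cond, chelateDntp) / 1000
  ds <- ds + 0.368 * (n - 1L) * log(mon_M)
  ct <- cond$oligo_nM * 1e-9 / 4
  1000 * dh / (ds + .R_GAS * log(ct)) - 273.15
}

#' Mean melting temperature of a degenerate primer
#'
#' The melting temperature reported for a degenerate primer is the arithmetic
#' mean of \code{\link{meltingTemperature}} over all of its concrete
#' expansions (every non-degenerate sequence combination in the pool).
#'
#' @param x degenerate sequence (character scalar).
#' @param cond a \code{\link{reactionConditions}} object.
#' @param max.expansions refuse primers whose pool exceeds this size
#'   (default 512).
#' @param chelateDntp see \code{\link{meltingTemperature}}.
#' @return Mean melting temperature in degrees Celsius.
#' @examples
#' meanPrimerTm("TMARRACMCACTGCAGGGAC")
#' @export
meanPrimerTm <- function(x, cond = reactionConditions(),
                         max.expansions = 512L, chelateDntp = FALSE) {
  deg <- primerDegeneracy(x, threePrimeWindow = 0L)$total
  if (deg > max.expansions)
    stop(sprintf("primer degeneracy %d exceeds the expansion cap %d",
                 deg, max.expansions), call. = FALSE)
  pool <- iupacExpand(x, max.expansions = max.expansions)
  mean(vapply(pool, meltingTemperature, numeric(1), cond = cond,
              chelateDntp = chelateDntp))
}
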