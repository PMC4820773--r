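# Nearest-neighbor melting temperature for probe arms.
#
# Unified NN parameters (duplex DNA, 1 M NaCl reference state), with an
# entropic monovalent-salt correction and the usual non-self-complementary
# strand-concentration term CT/4. Values: dH in kcal/mol, dS in cal/(mol K).

.nn_dh <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
.nn_ds <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
# initiation terms by terminal base
.init_dh <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
.init_ds <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)

.nn_canonical <- function(dinuc) {
  # each NN stack equals its reverse complement; map onto the 10 unique keys
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ifelse(dinuc %in% names(.nn_dh), dinuc,
         paste0(comp[substr(dinuc, 2, 2)], comp[substr(dinuc, 1, 1)]))
}

#' Nearest-neighbor melting temperature of a probe arm
#'
#' Computes the duplex melting temperature of a DNA oligo against its perfect
#' complement using unified nearest-neighbor thermodynamics: summed stack
#' enthalpies/entropies plus terminal initiation terms, an entropic salt
#' correction `0.368 (N-1) ln[Na+]`, and
#' `Tm = 1000 dH / (dS + R ln(CT/4)) - 273.15`.
#'
#' @param arm DNA string over `A,C,G,T`, length >= 8.
#' @param na_molar Monovalent cation concentration in mol/L (default 0.05,
#'   i.e. 50 mM).
#' @param conc_molar Total oligo concentration in mol/L (default 2.5e-7,
#'   i.e. 0.25 uM).
#' @return Melting temperature in degrees Celsius.
#' @export
melting_temp <- function(arm, na_molar = 0.05, conc_molar = 0.25e-6) {
  arm <- toupper(as.character(arm))
  if (nchar(arm) < 8L) stop("arm shorter than 8 nt")
  if (grepl("[^ACGT]", arm)) stop("arm contains non-ACGT characters: ", arm)
  bases <- strsplit(arm, "")[[1]]
  n <- length(bases)
  stacks <- .nn_canonical(paste0(bases[-n], bases[-1]))
  dh <- sum(.nn_dh[stacks]) + .init_dh[bases[1]] + .init_dh[bases[n]]
  ds <- sum(.nn_ds[stacks]) + .init_ds[bases[1]] + .init_ds[bases[n]]
  ds <- ds + 0.368 * (n - 1) * log(na_molar)
  R <- 1.9872
  unname(1000 * dh / (ds + R * log(conc_molar / 4)) - 273.15)
}

# Cumulative NN sums along a sequence, giving O(1) melting temperature for
# any window [a, b) of the plus strand. A probe arm is the reverse
# complement of its plus-strand site, and duplex Tm is strand-symmetric,
# so Tm(window) equals melting_temp() of the arm.
tm_profile <- function(seq, na_molar = 0.05, conc_molar = 0.25e-6) {
  bases <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]]
  n <- length(bases)
  stacks <- .nn_canonical(paste0(bases[-n], bases[-1]))
  cum_dh <- c(0, cumsum(.nn_dh[stacks]))
  cum_ds <- c(0, cumsum(.nn_ds[stacks]))
  init_dh <- .init_dh[bases]
  init_ds <- .init_ds[bases]
  denom_const <- 1.9872 * log(conc_molar / 4)
  salt <- 0.368 * log(na_molar)
  function(a0, b0) {
    # window [a0, b0) 0-based half-open; vectorized
    dh <- cum_dh[b0] - cum_dh[a0 + 1L] + init_dh[a0 + 1L] + init_dh[b0]
    ds <- cum_ds[b0] - cum_ds[a0 + 1L] + init_ds[a0 + 1L] + init_ds[b0] +
      salt * (b0 - a0 - 1L)
    unname(1000 * dh / (ds + denom_const) - 273.15)
  }
}
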