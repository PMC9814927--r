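# Physical constants and element tables. Units throughout the package:
# kJ mol^-1 (energy), Angstrom (length), degrees (angles), GPa (pressure),
# electron charge e (charges).

# Coulomb constant e^2/(4 pi eps0) in kJ mol^-1 Angstrom e^-2
KE_COULOMB <- 1389.35457644382

# 1 GPa * Angstrom^3 expressed in kJ mol^-1
GPA_A3_TO_KJMOL <- 0.6022140857

# Covalent radii [Angstrom] (Cordero-style consensus values)
COVALENT_RADII <- c(
  H = 0.31, He = 0.28, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Ne = 0.58, Na = 1.66, Mg = 1.41, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
  Ar = 1.06, K = 2.03, Br = 1.20, I = 1.39
)

# van der Waals radii [Angstrom] (Bondi)
VDW_RADII <- c(
  H = 1.20, He = 1.40, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  Ne = 1.54, Na = 2.27, Mg = 1.73, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75,
  Ar = 1.88, K = 2.75, Br = 1.85, I = 1.98
)

# Atomic masses [amu]
ATOMIC_MASSES <- c(
  H = 1.008, He = 4.0026, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974,
  S = 32.06, Cl = 35.45, Ar = 39.948, K = 39.098, Br = 79.904, I = 126.90
)

ATOMIC_NUMBERS <- c(
  H = 1, He = 2, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10, Na = 11, Mg = 12,
  Si = 14, P = 15, S = 16, Cl = 17, Ar = 18, K = 19, Br = 35, I = 53
)

# Cromer-Mann X-ray form factor coefficients (a1..a4, b1..b4, c) for the
# elements the package's powder screen supports directly; other elements fall
# back to a constant f = Z, which is adequate for a screening-grade pattern.
CROMER_MANN <- list(
  H  = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
            b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C  = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
            b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N  = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
            b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O  = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
            b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  F  = list(a = c(3.53920, 2.64120, 1.51700, 1.02430),
            b = c(10.2825, 4.29440, 0.261500, 26.1476), c = 0.277600),
  S  = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
            b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900),
  Cl = list(a = c(11.4604, 7.19640, 6.25560, 1.64550),
            b = c(0.010400, 1.16620, 18.5194, 47.7784), c = -9.5574)
)

lookup_table <- function(table, keys, what) {
  out <- table[keys]
  if (anyNA(out)) {
    stop("no ", what, " tabulated for element(s): ",
         paste(unique(keys[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Error function
#'
#' Gauss error function, used by the Ewald self/intramolecular corrections.
#' @param x numeric vector
#' @return erf(x)
#' @keywords internal
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
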