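# Monoisotopic constants used throughout. All masses in Da.

#' @keywords internal
PROTON_MASS <- 1.007276

#' @keywords internal
WATER_MASS <- 18.010565

# Residue (dehydro) monoisotopic masses of the four monosaccharides of
# complex-type N-glycans.
.MONOSACCHARIDES <- c(
  HexNAc = 203.079373,
  Hex    = 162.052824,
  Fuc    = 146.057909,
  NeuAc  = 291.095417
)

# Amino-acid residue monoisotopic masses (20 canonical residues).
.AA_RESIDUE_MASS <- c(
  G = 57.021464,  A = 71.037114,  S = 87.032028,  P = 97.052764,
  V = 99.068414,  T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

# Common modification deltas.
.MOD_MASS <- c(
  carbamidomethyl = 57.021464,
  oxidation       = 15.994915,
  deamidation     = 0.984016
)

#' Monosaccharide residue masses
#'
#' Monoisotopic residue masses of the four monosaccharides that make up the
#' complex-type N-glycan compositions handled by this package.
#'
#' @param name optional character vector of monosaccharide names to look up.
#'   Unknown names are an error.
#' @return Named numeric vector of residue masses in Da.
#' @examples
#' monosaccharide_masses()
#' monosaccharide_masses("Fuc")
#' @export
monosaccharide_masses <- function(name = NULL) {
  if (is.null(name)) return(.MONOSACCHARIDES)
  bad <- setdiff(name, names(.MONOSACCHARIDES))
  if (length(bad) > 0L) {
    stop("unknown monosaccharide(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(names(.MONOSACCHARIDES), collapse = ", "), ")")
  }
  .MONOSACCHARIDES[name]
}

#' Mass constants table
#'
#' The machine-readable table of all mass constants shipped with the package
#' (monosaccharide residues, atomic constants, modification deltas, and the
#' fixed published m/z values of the two HexNAc secondary oxonium fragments).
#'
#' @return A data.frame with columns `name`, `kind`, `value_da` and `note`.
#' @export
glyco_constants <- function() {
  path <- system.file("extdata", "glyco_constants.csv", package = "glycoPRM",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Fragment ion m/z from neutral mass
#'
#' @param neutral_mass neutral monoisotopic mass in Da.
#' @param charge positive integer charge.
#' @return m/z = (neutral_mass + charge * proton) / charge.
#' @export
ion_mz <- function(neutral_mass, charge) {
  stopifnot(all(charge >= 1L), all(charge == as.integer(charge)))
  (neutral_mass + charge * PROTON_MASS) / charge
}

# Constructor for the flat fragment-ion record used across modules.
fragment_ion <- function(kind, label, neutral_mass, charge) {
  neutral_mass <- unname(neutral_mass)
  data.frame(
    kind = unname(kind), label = unname(label), neutral_mass = neutral_mass,
    charge = as.integer(charge), mz = ion_mz(neutral_mass, charge),
    stringsAsFactors = FALSE
  )
}
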