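# Intact-mass bookkeeping for autoproteolysis and conjugation.  Average
# (not monoisotopic) masses are the default, matching intact-protein ESI
# deconvolution; one water (18.0153 Da average) is released per peptide/
# amide bond formed and gained per bond hydrolysed.

WATER_AVG <- 18.0153
WATER_MONO <- 18.010565

# average residue masses, ExPASy values (Da)
RESIDUE_MASS_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

# monoisotopic residue masses (Da)
RESIDUE_MASS_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Average molecular mass of a protein sequence
#'
#' Sum of residue masses plus one water.  With `remove_fmet = TRUE` a
#' leading methionine is dropped before summation, the convention for
#' bacterially expressed proteins whose initiator fMet is cleaved.
#'
#' @param sequence One-letter amino acid string (canonical 20 letters).
#' @param remove_fmet Drop a leading `M` before summation.
#' @param monoisotopic Use monoisotopic instead of average masses.
#' @return Mass in Da.
#' @examples
#' average_mass("G")                        # glycine, 75.07 Da
#' average_mass("MG", remove_fmet = TRUE)   # equals average_mass("G")
#' @export
average_mass <- function(sequence, remove_fmet = FALSE, monoisotopic = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(gsub("\\s", "", sequence))
  if (remove_fmet && startsWith(sequence, "M")) {
    sequence <- substr(sequence, 2, nchar(sequence))
  }
  tab <- if (monoisotopic) RESIDUE_MASS_MONO else RESIDUE_MASS_AVG
  water <- if (monoisotopic) WATER_MONO else WATER_AVG
  if (nchar(sequence) == 0) return(water)
  letters1 <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(letters1), names(tab))
  if (length(bad)) {
    abort(sprintf("non-canonical residue letter(s): %s",
                  paste(bad, collapse = ", ")))
  }
  sum(tab[letters1]) + water
}

resolve_mass <- function(x, remove_fmet = FALSE) {
  if (is.numeric(x)) {
    if (x <= 0) abort("mass must be positive")
    return(x)
  }
  if (is.character(x)) return(average_mass(x, remove_fmet = remove_fmet))
  if (is.list(x)) {
    if (!is.null(x$mass)) return(resolve_mass(x$mass))
    if (!is.null(x$sequence)) return(average_mass(x$sequence, remove_fmet = remove_fmet))
  }
  abort("cannot resolve a mass: give a number, a sequence, or a list with $mass/$sequence")
}

#' Cleavage-product masses
#'
#' Autoproteolysis at an internal peptide bond splits a precursor into an
#' N-terminal fragment bearing a C-terminal anhydride and a C-terminal
#' fragment.  The anhydride fragment weighs `precursor - c_fragment`; its
#' hydrolyzed (linear) form carries one additional water.
#'
#' @param precursor,c_fragment Masses in Da, sequences, or lists with
#'   `$mass`/`$sequence`.
#' @return One-row tibble: `n_fragment_anhydride`, `n_fragment_hydrolyzed`,
#'   `c_fragment`, `precursor`, `water`.
#' @examples
#' cleavage_masses(42024.7, 26415.1)  # hydrolyzed N-fragment 15627.6 Da
#' @export
cleavage_masses <- function(precursor, c_fragment) {
  mp <- resolve_mass(precursor)
  mc <- resolve_mass(c_fragment)
  if (mc >= mp) abort("c_fragment mass must be smaller than the precursor")
  tibble(
    n_fragment_anhydride = mp - mc,
    n_fragment_hydrolyzed = mp - mc + WATER_AVG,
    c_fragment = mc,
    precursor = mp,
    water = WATER_AVG
  )
}

#' Conjugate mass
#'
#' Mass of the covalent conjugate between the (hydrolyzed) binder fragment
#' and the target protein: the two masses are added and one water —
#' released on amide/ester bond formation — is subtracted.
#'
#' @param binder_fragment_hydrolyzed Mass in Da of the hydrolyzed cleaved
#'   binder fragment.
#' @param target Mass in Da of the target protein.
#' @return Conjugate mass in Da.
#' @examples
#' conjugate_mass(15627.6, 52929.9)
#' @export
conjugate_mass <- function(binder_fragment_hydrolyzed, target) {
  b <- resolve_mass(binder_fragment_hydrolyzed)
  t <- resolve_mass(target)
  b + t - WATER_AVG
}
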