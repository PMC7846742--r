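#' Scan configuration
#'
#' Bundles the tunable limits of the distance scan.  The defaults are the
#' operating conditions of the published screening protocol: structure files
#' of 10 MB or more are skipped, at most the first 10 coordinate models are
#' analysed, primary distances below 1.6 \eqn{\angstrom}{A} are treated as
#' existing covalent linkages (e.g. ubiquitination) and filtered from
#' shortlists, and per-structure minima are interrogated on \[0, 50)
#' \eqn{\angstrom}{A} in 0.1 \eqn{\angstrom}{A} steps binned to 1
#' \eqn{\angstrom}{A}.
#'
#' @param max_file_bytes Size gate in bytes applied to the input file before
#'   parsing; files of this size or larger are skipped.  Use `Inf` to disable.
#' @param max_models Maximum number of coordinate models analysed per
#'   structure; models beyond this are dropped in file order.
#' @param covalent_cutoff Distance in \eqn{\angstrom}{A} below which a primary
#'   distance is flagged as an existing covalent linkage.
#' @param histogram_range Closed-open interval in \eqn{\angstrom}{A} over
#'   which minima histograms and interrogation run.
#' @param fine_step Interrogation step in \eqn{\angstrom}{A}.
#' @param bin_width Histogram bin width in \eqn{\angstrom}{A}.
#' @param include_same_residue Keep records where the C-terminal residue is
#'   itself the target lysine of the same chain instance (flagged
#'   `same_residue`) in raw scans.  Shortlist queries always exclude them.
#' @param assembly_mode `"assemblies"` expands deposited assembly operators;
#'   `"asymmetric_unit"` analyses the untransformed deposited chains.
#' @param map_mse Treat selenomethionine (MSE) as standard methionine.
#' @param max_assembly_atoms Guard against pathological operator products:
#'   assemblies expanding to more atoms than this raise an error.
#'
#' @return A list of class `neiss_config`.
#' @examples
#' cfg <- scan_config(max_models = 5)
#' cfg$covalent_cutoff
#' @export
scan_config <- function(max_file_bytes = 10485760,
                        max_models = 10L,
                        covalent_cutoff = 1.6,
                        histogram_range = c(0, 50),
                        fine_step = 0.1,
                        bin_width = 1.0,
                        include_same_residue = TRUE,
                        assembly_mode = c("assemblies", "asymmetric_unit"),
                        map_mse = FALSE,
                        max_assembly_atoms = 500000L) {
  assembly_mode <- match.arg(assembly_mode)
  stopifnot(
    max_file_bytes > 0,
    max_models >= 1,
    covalent_cutoff > 0,
    covalent_cutoff < histogram_range[2],
    length(histogram_range) == 2, histogram_range[1] < histogram_range[2],
    fine_step <= bin_width, fine_step > 0
  )
  structure(
    list(
      max_file_bytes = max_file_bytes,
      max_models = as.integer(max_models),
      covalent_cutoff = covalent_cutoff,
      histogram_range = histogram_range,
      fine_step = fine_step,
      bin_width = bin_width,
      include_same_residue = include_same_residue,
      assembly_mode = assembly_mode,
      map_mse = map_mse,
      max_assembly_atoms = as.integer(max_assembly_atoms)
    ),
    class = "neiss_config"
  )
}

#' @export
print.neiss_config <- function(x, ...) {
  cat("<neiss_config>\n")
  cat(sprintf("  size gate        : < %s bytes\n", format(x$max_file_bytes, big.mark = ",")))
  cat(sprintf("  model cap        : %d\n", x$max_models))
  cat(sprintf("  covalent cutoff  : < %.2f A\n", x$covalent_cutoff))
  cat(sprintf("  histogram        : [%g, %g) A, %.1f A bins\n",
              x$histogram_range[1], x$histogram_range[2], x$bin_width))
  cat(sprintf("  assembly mode    : %s\n", x$assembly_mode))
  invisible(x)
}

# canonical 20 three-letter codes
AA_STANDARD <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

aa_one <- function(resname) {
  out <- unname(AA_STANDARD[resname])
  out[is.na(out)] <- "X"
  out
}

#' Category levels for distance records
#'
#' @return Character vector of the three distance categories.
#' @export
distance_categories <- function() {
  c("intramolecular", "intermolecular_homomeric", "intermolecular_heteromeric")
}
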