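#' Average residue-mass table
#'
#' Bundles the average masses used throughout the package: the four
#' monosaccharide residue masses (hexose, N-acetylhexosamine, fucose and
#' N-acetylneuraminic acid), water, the proton, and the twenty standard
#' amino-acid residue masses. Intact-protein AEX-MS of a ~34 kDa
#' glycoprotein works in average-mass space (isotopes are not resolved at
#' the protein level), so average masses are the default everywhere; a
#' monoisotopic table can be configured by overriding the fields, but is
#' never the default.
#'
#' @param hexose_Da average mass of a hexose residue (Da).
#' @param hexnac_Da average mass of an N-acetylhexosamine residue (Da).
#' @param fucose_Da average mass of a fucose (deoxyhexose) residue (Da).
#' @param neuac_Da average mass of an N-acetylneuraminic acid (sialic acid)
#'   residue (Da).
#' @param water_Da average mass of water (Da), added once per polypeptide
#'   chain.
#' @param proton_Da mass of a proton (Da), used for m/z arithmetic.
#' @param amino_acid_residues_Da named numeric vector of average residue
#'   masses keyed by one-letter amino-acid code.
#'
#' @return An object of class `ResidueMassTable` (a named list).
#' @examples
#' t <- residue_mass_table()
#' t$hexose_Da          # 162.14
#' 2 * t$fucose_Da - t$neuac_Da  # the ~1 Da two-fucose/one-sialic-acid gap
#' @export
residue_mass_table <- function(hexose_Da = 162.14,
                               hexnac_Da = 203.20,
                               fucose_Da = 146.14,
                               neuac_Da = 291.26,
                               water_Da = 18.01528,
                               proton_Da = 1.00728,
                               amino_acid_residues_Da = average_residue_masses()) {
  t <- list(hexose_Da = hexose_Da, hexnac_Da = hexnac_Da,
            fucose_Da = fucose_Da, neuac_Da = neuac_Da,
            water_Da = water_Da, proton_Da = proton_Da,
            amino_acid_residues_Da = amino_acid_residues_Da)
  scalars <- unlist(t[c("hexose_Da", "hexnac_Da", "fucose_Da", "neuac_Da",
                        "water_Da", "proton_Da")])
  if (any(!is.finite(scalars)) || any(scalars <= 0)) {
    stop("all residue masses must be finite and strictly positive", call. = FALSE)
  }
  if (any(!is.finite(amino_acid_residues_Da)) || any(amino_acid_residues_Da <= 0)) {
    stop("amino-acid residue masses must be finite and strictly positive",
         call. = FALSE)
  }
  structure(t, class = "ResidueMassTable")
}

#' Standard average amino-acid residue masses
#'
#' @return Named numeric vector (Da) keyed by one-letter code.
#' @export
average_residue_masses <- function() {
  c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
}

#' @export
print.ResidueMassTable <- function(x, ...) {
  cat("<ResidueMassTable>\n")
  cat(sprintf("  Hex %.2f  HexNAc %.2f  Fuc %.2f  NeuAc %.2f (Da, average)\n",
              x$hexose_Da, x$hexnac_Da, x$fucose_Da, x$neuac_Da))
  cat(sprintf("  water %.5f  proton %.5f  %d amino-acid residues\n",
              x$water_Da, x$proton_Da, length(x$amino_acid_residues_Da)))
  invisible(x)
}

#' Compute a polypeptide backbone average mass from its sequence
#'
#' Sum of average residue masses plus one water.
#'
#' @param seq amino-acid sequence, standard one-letter codes.
#' @param table a [residue_mass_table()].
#' @return Average mass in Da. The empty sequence returns the mass of water.
#' @examples
#' backbone_mass_from_sequence("G")   # 75.07
#' backbone_mass_from_sequence("GG")  # 132.12
#' @export
backbone_mass_from_sequence <- function(seq, table = residue_mass_table()) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  if (nchar(seq) == 0L) return(table$water_Da)
  aa <- strsplit(toupper(seq), "")[[1]]
  masses <- table$amino_acid_residues_Da[aa]
  if (anyNA(masses)) {
    bad <- which(is.na(masses))[1L]
    stop(sprintf("unknown residue code '%s' at position %d", aa[bad], bad),
         call. = FALSE)
  }
  sum(masses) + table$water_Da
}
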