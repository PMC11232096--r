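#' Protein-level glycan composition
#'
#' A glycan composition at the whole-protein level: counts of hexose (H),
#' N-acetylhexosamine (N), fucose (F) and N-acetylneuraminic acid / sialic
#' acid (S), summed over all glycosylation sites (five for AGP). The
#' canonical text form is `"H{H}N{N}F{F}S{S}"`, e.g. `"H29N24F1S14"`.
#'
#' @param H,N,F,S non-negative integer monosaccharide counts.
#' @return An object of class `GlycanComposition`.
#' @examples
#' glycan_composition(29, 24, 1, 14)
#' parse_composition("H32N27F0S16")
#' @export
glycan_composition <- function(H, N, F = 0L, S = 0L) {
  counts <- c(H = H, N = N, F = F, S = S)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("glycan composition counts must be non-negative integers",
         call. = FALSE)
  }
  structure(as.list(as.integer(counts)), names = c("H", "N", "F", "S"),
            class = "GlycanComposition")
}

#' @rdname glycan_composition
#' @param x canonical composition string such as `"H29N24F1S14"`.
#' @export
parse_composition <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec("^H([0-9]+)N([0-9]+)F([0-9]+)S([0-9]+)$", x))[[1]]
  if (length(m) != 5L) {
    stop(sprintf("'%s' is not a canonical composition string (H#N#F#S#)", x),
         call. = FALSE)
  }
  v <- as.integer(m[-1L])
  glycan_composition(v[1L], v[2L], v[3L], v[4L])
}

#' @export
format.GlycanComposition <- function(x, ...) {
  sprintf("H%dN%dF%dS%d", x$H, x$N, x$F, x$S)
}

#' @export
print.GlycanComposition <- function(x, ...) {
  cat("<GlycanComposition>", format(x), "\n")
  invisible(x)
}

#' @export
as.character.GlycanComposition <- function(x, ...) format(x)

#' @export
`==.GlycanComposition` <- function(e1, e2) {
  format(e1) == format(e2)
}

#' @export
`+.GlycanComposition` <- function(e1, e2) {
  glycan_composition(e1$H + e2$H, e1$N + e2$N, e1$F + e2$F, e1$S + e2$S)
}

#' Average mass of a glycan composition
#'
#' Linear in each count: `H * hexose + N * hexnac + F * fucose + S * neuac`.
#'
#' @param composition a [glycan_composition()] (or canonical string).
#' @param table a [residue_mass_table()].
#' @return mass in Da.
#' @examples
#' composition_mass(glycan_composition(1, 0, 0, 0))   # 162.14, one hexose
#' composition_mass(parse_composition("H29N24F1S14")) # 13802.64
#' @export
composition_mass <- function(composition, table = residue_mass_table()) {
  composition <- as_composition(composition)
  composition$H * table$hexose_Da + composition$N * table$hexnac_Da +
    composition$F * table$fucose_Da + composition$S * table$neuac_Da
}

as_composition <- function(x) {
  if (inherits(x, "GlycanComposition")) return(x)
  if (is.character(x)) return(parse_composition(x))
  stop("expected a GlycanComposition or canonical composition string",
       call. = FALSE)
}

#' Composition constraints for candidate enumeration and validation
#'
#' Encodes the structural rules for protein-level compositions of a protein
#' carrying `n_sites` complex N-glycans. Each core contributes
#' `hexnac_per_core` HexNAc and `hex_per_core` Hex, so with the defaults
#' (five sites, 2 HexNAc and 3 Hex per core) complex-type structures obey
#' the offset rule H = N + 5 and carry N - 10 antennae. Each antenna holds
#' at most one sialic acid, giving S <= N - 10 when
#' `enforce_sa_le_antennae` is on.
#'
#' @param n_sites number of N-glycosylation sites (default 5).
#' @param hexnac_per_core HexNAc residues per core (default 2).
#' @param hex_per_core Hex residues per core (default 3).
#' @param max_fucose maximum fucoses per protein (default 4).
#' @param sa_min,sa_max allowed range of sialic acids per protein.
#' @param n_min,n_max HexNAc enumeration bounds (defaults 10 and 40, a
#'   generous superset of observed compositions).
#' @param enforce_hex_hexnac_offset enforce H = N + n_sites *
#'   (hex_per_core - hexnac_per_core)?
#' @param enforce_sa_le_antennae enforce S <= antennae (= N - n_sites *
#'   hexnac_per_core)?
#' @return An object of class `CompositionConstraints`.
#' @export
composition_constraints <- function(n_sites = 5L,
                                    hexnac_per_core = 2L,
                                    hex_per_core = 3L,
                                    max_fucose = 4L,
                                    sa_min = 0L,
                                    sa_max = 25L,
                                    n_min = 10L,
                                    n_max = 40L,
                                    enforce_hex_hexnac_offset = TRUE,
                                    enforce_sa_le_antennae = TRUE) {
  k <- list(n_sites = as.integer(n_sites),
            hexnac_per_core = as.integer(hexnac_per_core),
            hex_per_core = as.integer(hex_per_core),
            max_fucose = as.integer(max_fucose),
            sa_min = as.integer(sa_min), sa_max = as.integer(sa_max),
            n_min = as.integer(n_min), n_max = as.integer(n_max),
            enforce_hex_hexnac_offset = isTRUE(enforce_hex_hexnac_offset),
            enforce_sa_le_antennae = isTRUE(enforce_sa_le_antennae))
  if (k$sa_min > k$sa_max) stop("sa_min must be <= sa_max", call. = FALSE)
  if (k$n_min > k$n_max) stop("n_min must be <= n_max", call. = FALSE)
  structure(k, class = "CompositionConstraints")
}

#' Hex-over-HexNAc offset implied by a constraint set
#' @param constraints a [composition_constraints()].
#' @return integer offset (5 with the defaults: H = N + 5).
#' @export
hex_offset <- function(constraints) {
  constraints$n_sites * (constraints$hex_per_core - constraints$hexnac_per_core)
}

#' Core HexNAc count implied by a constraint set
#' @param constraints a [composition_constraints()].
#' @return integer (10 with the defaults); antennae per protein = N - this.
#' @export
core_hexnac <- function(constraints) {
  constraints$n_sites * constraints$hexnac_per_core
}

#' Validate a glycan composition against structural constraints
#'
#' A total function: never errors, returns pass/fail plus every violated
#' rule as a reason code.
#'
#' @param composition a [glycan_composition()] or canonical string.
#' @param constraints a [composition_constraints()].
#' @return list with elements `pass` (logical) and `reasons` (character
#'   vector of violated-rule codes, empty on pass). Codes:
#'   `"hex_hexnac_offset"`, `"n_below_core"`, `"sa_exceeds_antennae"`,
#'   `"fucose_above_max"`, `"sa_out_of_range"`.
#' @examples
#' k <- composition_constraints()
#' validate_composition("H32N27F0S16", k)$pass        # TRUE
#' validate_composition("H32N26F0S16", k)$reasons     # offset rule violated
#' @export
validate_composition <- function(composition,
                                 constraints = composition_constraints()) {
  c0 <- as_composition(composition)
  reasons <- character(0)
  off <- hex_offset(constraints)
  core_n <- core_hexnac(constraints)
  if (constraints$enforce_hex_hexnac_offset && c0$H != c0$N + off) {
    reasons <- c(reasons, "hex_hexnac_offset")
  }
  if (c0$N < core_n) reasons <- c(reasons, "n_below_core")
  if (constraints$enforce_sa_le_antennae && c0$S > c0$N - core_n) {
    reasons <- c(reasons, "sa_exceeds_antennae")
  }
  if (c0$F > constraints$max_fucose) reasons <- c(reasons, "fucose_above_max")
  if (c0$S < constraints$sa_min || c0$S > constraints$sa_max) {
    reasons <- c(reasons, "sa_out_of_range")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}
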