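#' Proteoform candidates
#'
#' A proteoform candidate is one backbone variant plus one protein-level
#' glycan composition plus a set of modifications; its theoretical average
#' mass is the strict sum of the three parts.
#'
#' @param variant a [backbone_variant()] (or a variant name, resolved
#'   against `registry`).
#' @param composition a [glycan_composition()] or canonical string.
#' @param mods character vector of modification names.
#' @param registry optional [variant_registry()] used to resolve `variant`
#'   by name and to validate modification applicability.
#' @param table a [residue_mass_table()].
#' @return An object of class `ProteoformCandidate` with the
#'   `theoretical_mass_Da` field filled in.
#' @export
proteoform_candidate <- function(variant, composition, mods = NULL,
                                 registry = NULL,
                                 table = residue_mass_table()) {
  mod_registry <- if (!is.null(registry)) registry$modifications
                  else builtin_modifications()
  if (is.character(variant)) {
    if (is.null(registry)) {
      stop("a registry is required to resolve a variant by name",
           call. = FALSE)
    }
    v <- registry$variants[[variant]]
    if (is.null(v)) {
      stop(sprintf("variant '%s' is not in the registry", variant),
           call. = FALSE)
    }
    variant <- v
  }
  stopifnot(inherits(variant, "BackboneVariant"))
  if (is.null(mods)) mods <- variant$modifications
  composition <- as_composition(composition)
  p <- structure(list(variant = variant, composition = composition,
                      mods = mods, theoretical_mass_Da = NA_real_),
                 class = "ProteoformCandidate")
  p$theoretical_mass_Da <- proteoform_mass(p, table,
                                           mod_registry = mod_registry)
  p
}

#' Theoretical average mass of a proteoform candidate
#'
#' backbone mass + glycan composition mass + sum of modification deltas.
#' Additive and invariant to modification ordering.
#'
#' @param candidate a [proteoform_candidate()].
#' @param table a [residue_mass_table()].
#' @param mod_registry named list of [modification()] objects.
#' @return mass in Da.
#' @export
proteoform_mass <- function(candidate, table = residue_mass_table(),
                            mod_registry = builtin_modifications()) {
  stopifnot(inherits(candidate, "ProteoformCandidate"))
  v <- candidate$variant
  deltas <- vapply(candidate$mods, function(m) {
    mod <- mod_registry[[m]]
    if (is.null(mod)) {
      stop(sprintf("unknown modification '%s'", m), call. = FALSE)
    }
    if (!mod_applies(mod, v$name)) {
      stop(sprintf("modification '%s' is not applicable to variant '%s'",
                   m, v$name), call. = FALSE)
    }
    mod$delta_Da
  }, numeric(1))
  v$backbone_mass_Da + composition_mass(candidate$composition, table) +
    sum(deltas)
}

#' @export
print.ProteoformCandidate <- function(x, ...) {
  cat(sprintf("<ProteoformCandidate> %s %s [%s]  %.2f Da\n",
              x$variant$name, format(x$composition),
              paste(x$mods, collapse = "+"), x$theoretical_mass_Da))
  invisible(x)
}
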