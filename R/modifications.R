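#' Backbone modifications
#'
#' A modification is a named, signed average-mass delta with an
#' applicability rule. Two modifications are built in, both observed on
#' intact AGP:
#'
#' * `pyroglutamate`: cyclization of the N-terminal glutamine with loss of
#'   ammonia (NH3, 17.0265 Da average), so delta = -17.03 Da. Applies to
#'   every variant and is mandatory: all proteoforms carry it.
#' * `cysteinylation`: disulfide attachment of a free cysteine
#'   (C3H7NO2S, 121.158 Da average) with loss of two hydrogens, so
#'   delta = +119.14 Da. Applies only to variants declaring a free
#'   cysteine (AGP2) and is mandatory there.
#' * `none`: the identity modification, delta 0.
#'
#' @param name modification identifier.
#' @param delta_Da signed average-mass change in Da.
#' @param applicability character vector of variant names the modification
#'   may occur on, or `NULL` for all variants.
#' @param mandatory if `TRUE` the modification is applied to every
#'   enumerated candidate of an applicable variant.
#' @return An object of class `Modification`.
#' @export
modification <- function(name, delta_Da, applicability = NULL,
                         mandatory = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(delta_Da), length(delta_Da) == 1L,
            is.finite(delta_Da))
  structure(list(name = name, delta_Da = delta_Da,
                 applicability = applicability,
                 mandatory = isTRUE(mandatory)),
            class = "Modification")
}

#' @rdname modification
#' @export
builtin_modifications <- function() {
  list(
    pyroglutamate = modification("pyroglutamate", -17.0265,
                                 applicability = NULL, mandatory = TRUE),
    cysteinylation = modification("cysteinylation", 119.1423,
                                  applicability = "AGP2", mandatory = TRUE),
    none = modification("none", 0, applicability = NULL, mandatory = FALSE)
  )
}

#' Look up the mass delta of a registered modification
#'
#' @param name modification name.
#' @param registry a named list of [modification()] objects; defaults to the
#'   built-in registry.
#' @return signed mass delta in Da.
#' @examples
#' modification_delta("pyroglutamate")  # -17.03
#' modification_delta("cysteinylation") # +119.14
#' @export
modification_delta <- function(name, registry = builtin_modifications()) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- registry[[name]]
  if (is.null(m)) {
    stop(sprintf("unknown modification '%s' (registered: %s)", name,
                 paste(names(registry), collapse = ", ")), call. = FALSE)
  }
  m$delta_Da
}

mod_applies <- function(mod, variant_name) {
  is.null(mod$applicability) || variant_name %in% mod$applicability
}
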