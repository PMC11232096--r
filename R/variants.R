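#' Backbone genetic variants and the variant registry
#'
#' A `BackboneVariant` describes one genetic variant of the protein
#' backbone: its name, its average mass (optionally checked against a
#' supplied amino-acid sequence), the modifications it may carry, and an
#' optional prior relative abundance. A `VariantRegistry` is an ordered,
#' named collection of variants sharing one modification registry.
#'
#' @param name variant identifier, e.g. `"AGP1*F1"`.
#' @param backbone_mass_Da average mass of the unmodified polypeptide (Da).
#'   May be omitted when `sequence` is given.
#' @param sequence optional one-letter amino-acid sequence. When both
#'   `sequence` and `backbone_mass_Da` are given, they must agree within
#'   0.01 Da.
#' @param modifications character vector of modification names (resolved
#'   against the registry's modification list).
#' @param prior_abundance optional prior fraction in `[0, 1]`.
#' @param table a [residue_mass_table()] used when a sequence is supplied.
#' @return An object of class `BackboneVariant`.
#' @export
backbone_variant <- function(name, backbone_mass_Da = NULL, sequence = NULL,
                             modifications = "pyroglutamate",
                             prior_abundance = NULL,
                             table = residue_mass_table()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(backbone_mass_Da) && is.null(sequence)) {
    stop("either backbone_mass_Da or sequence must be given", call. = FALSE)
  }
  if (!is.null(sequence)) {
    seq_mass <- backbone_mass_from_sequence(sequence, table)
    if (is.null(backbone_mass_Da)) {
      backbone_mass_Da <- seq_mass
    } else if (abs(backbone_mass_Da - seq_mass) > 0.01) {
      stop(sprintf(paste0("backbone_mass_Da (%.4f) disagrees with the mass ",
                          "computed from the sequence (%.4f) by more than ",
                          "0.01 Da for variant '%s'"),
                   backbone_mass_Da, seq_mass, name), call. = FALSE)
    }
  }
  if (!is.finite(backbone_mass_Da) || backbone_mass_Da <= 0) {
    stop("backbone_mass_Da must be strictly positive", call. = FALSE)
  }
  if (!is.null(prior_abundance)) {
    stopifnot(is.numeric(prior_abundance), prior_abundance >= 0,
              prior_abundance <= 1)
  }
  structure(list(name = name, backbone_mass_Da = backbone_mass_Da,
                 sequence = sequence, modifications = modifications,
                 prior_abundance = prior_abundance),
            class = "BackboneVariant")
}

#' @rdname backbone_variant
#' @param variants list of [backbone_variant()] objects.
#' @param modification_registry named list of [modification()] objects.
#' @export
variant_registry <- function(variants,
                             modification_registry = builtin_modifications()) {
  if (length(variants) == 0L) {
    stop("variant registry must contain at least one variant", call. = FALSE)
  }
  stopifnot(all(vapply(variants, inherits, logical(1), "BackboneVariant")))
  nm <- vapply(variants, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate variant names", call. = FALSE)
  names(variants) <- nm
  for (v in variants) {
    unknown <- setdiff(v$modifications, names(modification_registry))
    if (length(unknown)) {
      stop(sprintf("variant '%s' refers to unregistered modification(s): %s",
                   v$name, paste(unknown, collapse = ", ")), call. = FALSE)
    }
    for (m in v$modifications) {
      if (!mod_applies(modification_registry[[m]], v$name)) {
        stop(sprintf("modification '%s' is not applicable to variant '%s'",
                     m, v$name), call. = FALSE)
      }
    }
  }
  structure(list(variants = variants,
                 modifications = modification_registry),
            class = "VariantRegistry")
}

#' @export
print.VariantRegistry <- function(x, ...) {
  cat(sprintf("<VariantRegistry> %d variant(s)\n", length(x$variants)))
  for (v in x$variants) {
    cat(sprintf("  %-10s %10.2f Da  mods: %s\n", v$name, v$backbone_mass_Da,
                paste(v$modifications, collapse = "+")))
  }
  invisible(x)
}

#' Default AGP variant registry (synthetic backbone masses)
#'
#' The four genetic variants of alpha-1-acid glycoprotein: the three AGP1
#' polymorphs (AGP1*F1, AGP1*F2, AGP1*S) and AGP2. All variants carry the
#' mandatory N-terminal pyroglutamate; AGP2 additionally carries mandatory
#' cysteinylation of its free cysteine. Prior abundances default to the
#' shares typical of pooled plasma from healthy donors (F1 0.56, S 0.32,
#' F2 0.03, AGP2 0.09).
#'
#' The backbone masses shipped here are synthetic stand-ins: distinct
#' values at the realistic ~21.5 kDa scale of the mature AGP polypeptide,
#' with inter-variant spacings of the order produced by the real
#' single-residue polymorphisms. They are configuration, not ground truth:
#' supply your own masses or sequences (via [backbone_variant()] or
#' [registry_from_json()]) for work on real data.
#'
#' @return A [variant_registry()].
#' @export
default_agp_registry <- function() {
  variant_registry(list(
    backbone_variant("AGP1*F1", 21540.00,
                     modifications = "pyroglutamate", prior_abundance = 0.56),
    backbone_variant("AGP1*F2", 21582.08,
                     modifications = "pyroglutamate", prior_abundance = 0.03),
    backbone_variant("AGP1*S", 21568.06,
                     modifications = "pyroglutamate", prior_abundance = 0.32),
    backbone_variant("AGP2", 21700.10,
                     modifications = c("pyroglutamate", "cysteinylation"),
                     prior_abundance = 0.09)
  ))
}

#' Read a variant registry from JSON or YAML
#'
#' The file holds a list of variant records with fields `name`,
#' `backbone_mass_Da` and/or `sequence`, `modifications` and optional
#' `prior_abundance`, plus an optional `residue_masses` block overriding
#' [residue_mass_table()] defaults and an optional `modifications_registry`
#' block of `{name, delta_Da, applicability, mandatory}` records.
#'
#' @param path path to a `.json`, `.yml` or `.yaml` file.
#' @return A [variant_registry()].
#' @export
registry_from_json <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("registry file not found: %s", path), call. = FALSE)
  }
  spec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  table <- do.call(residue_mass_table,
                   c(lapply(spec$residue_masses, as.numeric)))
  mods <- builtin_modifications()
  for (m in spec$modifications_registry) {
    mods[[m$name]] <- modification(m$name, as.numeric(m$delta_Da),
                                   applicability = unlist(m$applicability),
                                   mandatory = isTRUE(m$mandatory))
  }
  variants <- lapply(spec$variants, function(v) {
    backbone_variant(v$name,
                     backbone_mass_Da = if (!is.null(v$backbone_mass_Da))
                       as.numeric(v$backbone_mass_Da),
                     sequence = v$sequence,
                     modifications = if (!is.null(v$modifications))
                       unlist(v$modifications) else "pyroglutamate",
                     prior_abundance = v$prior_abundance,
                     table = table)
  })
  variant_registry(variants, modification_registry = mods)
}

#' Build a variant registry from a FASTA file of backbone sequences
#'
#' Sequence headers become variant names; masses are computed from the
#' sequences. Requires the Biostrings package.
#'
#' @param path FASTA file of amino-acid sequences.
#' @param modifications named list mapping variant name to its modification
#'   names; unlisted variants get `"pyroglutamate"`.
#' @param table a [residue_mass_table()].
#' @return A [variant_registry()].
#' @export
registry_from_fasta <- function(path, modifications = list(),
                                table = residue_mass_table()) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("registry_from_fasta() requires the Biostrings package",
         call. = FALSE)
  }
  seqs <- Biostrings::readAAStringSet(path)
  variants <- lapply(seq_along(seqs), function(i) {
    nm <- names(seqs)[i]
    backbone_variant(nm, sequence = as.character(seqs[[i]]),
                     modifications = modifications[[nm]] %||% "pyroglutamate",
                     table = table)
  })
  variant_registry(variants)
}
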