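#' Enumerate candidate proteoforms in a mass window
#'
#' Builds the full grid of constraint-valid proteoform candidates for every
#' variant in the registry — HexNAc from `n_min` to `n_max` with the
#' Hex = HexNAc + offset rule, fucose 0..`max_fucose`, sialic acids over
#' the allowed range — applies each variant's mandatory modifications, and
#' keeps exactly the candidates whose theoretical mass falls inside
#' `mass_window`. When `sa_count` is given (from the retention-time
#' calibration), only candidates with that sialic-acid count survive: this
#' is the chromatographic constraint that separates compositions that are
#' near-isobaric at the intact level, such as two extra fucoses versus one
#' extra sialic acid (~1 Da apart).
#'
#' @param registry a [variant_registry()].
#' @param constraints a [composition_constraints()].
#' @param mass_window numeric length-2, inclusive `[lo, hi]` window in Da.
#' @param sa_count optional integer; restrict to S == sa_count.
#' @param table a [residue_mass_table()].
#' @param expand_optional_mods if `TRUE`, each candidate is also emitted
#'   with every subset of its variant's non-mandatory modifications;
#'   by default only mandatory modifications are applied.
#' @return data.frame with columns `variant`, `H`, `N`, `F`, `S`,
#'   `composition`, `mods`, `theoretical_mass_Da`, ordered by variant name,
#'   then N, then F, then S.
#' @export
enumerate_candidates <- function(registry, constraints, mass_window,
                                 sa_count = NULL,
                                 table = residue_mass_table(),
                                 expand_optional_mods = FALSE) {
  stopifnot(inherits(registry, "VariantRegistry"),
            inherits(constraints, "CompositionConstraints"),
            is.numeric(mass_window), length(mass_window) == 2L)
  lo <- mass_window[1L]; hi <- mass_window[2L]
  if (lo > hi) stop("mass window must satisfy lo <= hi", call. = FALSE)
  if (!is.null(sa_count)) {
    stopifnot(length(sa_count) == 1L)
    if (is.na(sa_count)) sa_count <- NULL
  }

  off <- hex_offset(constraints)
  out <- lapply(registry$variants, function(v) {
    mods <- split_mods(v, registry$modifications)
    mod_sets <- list(mods$mandatory)
    if (expand_optional_mods && length(mods$optional)) {
      subsets <- all_subsets(mods$optional)
      mod_sets <- lapply(subsets, function(s) c(mods$mandatory, s))
    }
    s_range <- if (is.null(sa_count)) constraints$sa_min:constraints$sa_max
               else as.integer(sa_count)
    grid <- expand.grid(N = constraints$n_min:constraints$n_max,
                        F = 0:constraints$max_fucose,
                        S = s_range,
                        KEEP.OUT.ATTRS = FALSE)
    grid$H <- grid$N + off
    # vectorized form of validate_composition() over the grid (the offset
    # rule holds by construction); equivalence is property-tested
    core_n <- core_hexnac(constraints)
    keep <- grid$N >= core_n &
      grid$F <= constraints$max_fucose &
      grid$S >= constraints$sa_min & grid$S <= constraints$sa_max
    if (constraints$enforce_sa_le_antennae) {
      keep <- keep & grid$S <= grid$N - core_n
    }
    grid <- grid[keep, , drop = FALSE]
    if (!nrow(grid)) return(NULL)
    glyc <- grid$H * table$hexose_Da + grid$N * table$hexnac_Da +
      grid$F * table$fucose_Da + grid$S * table$neuac_Da
    do.call(rbind, lapply(mod_sets, function(ms) {
      delta <- if (length(ms)) {
        sum(vapply(ms, modification_delta, numeric(1),
                   registry = registry$modifications))
      } else 0
      mass <- v$backbone_mass_Da + glyc + delta
      inw <- mass >= lo & mass <= hi
      if (!any(inw)) return(NULL)
      data.frame(variant = v$name,
                 H = grid$H[inw], N = grid$N[inw],
                 F = grid$F[inw], S = grid$S[inw],
                 composition = sprintf("H%dN%dF%dS%d", grid$H[inw],
                                       grid$N[inw], grid$F[inw], grid$S[inw]),
                 mods = paste(ms, collapse = "+"),
                 theoretical_mass_Da = mass[inw],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) out <- empty_candidate_frame()
  rownames(out) <- NULL
  out[order(out$variant, out$N, out$F, out$S, out$mods), , drop = FALSE]
}

empty_candidate_frame <- function() {
  data.frame(variant = character(0), H = integer(0), N = integer(0),
             F = integer(0), S = integer(0), composition = character(0),
             mods = character(0), theoretical_mass_Da = numeric(0),
             stringsAsFactors = FALSE)
}

split_mods <- function(variant, mod_registry) {
  mand <- character(0); opt <- character(0)
  for (m in variant$modifications) {
    mod <- mod_registry[[m]]
    if (is.null(mod)) stop(sprintf("unknown modification '%s'", m),
                           call. = FALSE)
    if (mod$mandatory) mand <- c(mand, m) else opt <- c(opt, m)
  }
  list(mandatory = mand, optional = opt)
}

all_subsets <- function(x) {
  n <- length(x)
  lapply(seq_len(2^n) - 1L, function(mask) {
    x[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
  })
}

#' Match one observed feature against the candidate space
#'
#' Candidates are enumerated in `[mass - tol, mass + tol]`; the
#' sialic-acid-count constraint is applied when enabled and the feature
#' carries an `sa_count`. Candidates are ranked by absolute mass error.
#' If two or more candidates survive within the tolerance the feature is
#' declared `ambiguous` and all survivors are listed: on an intact ~34 kDa
#' protein a marginally smaller mass error is no basis for choosing
#' between near-isobaric compositions — retention time, not mass, is the
#' arbiter.
#'
#' @param feature a one-row data.frame or list with fields `mass_da`,
#'   and optionally `rt_min`, `area`, `sa_count`.
#' @param registry a [variant_registry()].
#' @param constraints a [composition_constraints()].
#' @param tol_Da mass tolerance in Da (> 0). Default 1.0 Da, the accuracy
#'   scale at which 1-2 Da compositional near-isobars are unresolvable by
#'   mass alone.
#' @param use_sa_constraint apply the feature's `sa_count` during
#'   enumeration?
#' @param table a [residue_mass_table()].
#' @return list of class `Assignment`: `feature`, `status` (`"assigned"`,
#'   `"ambiguous"` or `"unassigned"`), `candidates` (data.frame ordered by
#'   `abs(delta_mDa)` with a `rank` column), and for convenience `top`
#'   (best candidate row or `NULL`).
#' @export
match_feature <- function(feature, registry, constraints,
                          tol_Da = 1.0, use_sa_constraint = TRUE,
                          table = residue_mass_table()) {
  stopifnot(is.numeric(tol_Da), length(tol_Da) == 1L, tol_Da > 0)
  mass <- as.numeric(feature$mass_da)
  if (!is.finite(mass)) stop("feature mass_da must be finite", call. = FALSE)
  sa <- NULL
  if (use_sa_constraint && !is.null(feature$sa_count) &&
      !is.na(feature$sa_count)) {
    sa <- as.integer(feature$sa_count)
  }
  cand <- enumerate_candidates(registry, constraints,
                               mass_window = c(mass - tol_Da, mass + tol_Da),
                               sa_count = sa, table = table)
  if (nrow(cand)) {
    cand$delta_mDa <- (mass - cand$theoretical_mass_Da) * 1000
    cand <- cand[order(abs(cand$delta_mDa), cand$variant, cand$composition), ,
                 drop = FALSE]
    cand$rank <- seq_len(nrow(cand))
    rownames(cand) <- NULL
  } else {
    cand$delta_mDa <- numeric(0)
    cand$rank <- integer(0)
  }
  status <- if (nrow(cand) == 0L) "unassigned"
            else if (nrow(cand) == 1L) "assigned"
            else "ambiguous"
  structure(list(feature = feature, status = status, candidates = cand,
                 top = if (nrow(cand)) cand[1L, , drop = FALSE] else NULL),
            class = "Assignment")
}

#' @export
print.Assignment <- function(x, ...) {
  cat(sprintf("<Assignment> status=%s, %d candidate(s)\n", x$status,
              nrow(x$candidates)))
  if (nrow(x$candidates)) print(utils::head(x$candidates, 5L))
  invisible(x)
}

#' Assign a full run of observed features
#'
#' Applies [match_feature()] to every feature. When a retention-time to
#' sialic-acid-count calibration is supplied, each feature's `sa_count` is
#' filled from its retention time before matching (an already-present
#' `sa_count` column takes precedence). Features with non-finite mass are
#' rejected with a per-feature reason rather than dropped silently.
#'
#' @param features data.frame with columns `rt_min`, `mass_da`, `area` and
#'   optionally `sa_count`, `condition`, `feature_id`.
#' @param registry a [variant_registry()].
#' @param constraints a [composition_constraints()].
#' @param tol_Da mass tolerance in Da.
#' @param calibration optional [calibrate_rt_to_sa()] result.
#' @param use_sa_constraint apply sialic-acid counts during matching?
#' @param table a [residue_mass_table()].
#' @param verbose print the assigned/ambiguous/unassigned summary?
#' @return data.frame with one row per feature: the feature columns plus
#'   `status`, `variant`, `composition`, `mods`, `theoretical_mass_Da`,
#'   `delta_mDa`, `n_candidates`, `ambiguous_with` (pipe-separated
#'   co-matching candidates), `runner_up_mass_Da`, `runner_up_S`, `reason`.
#' @export
assign_run <- function(features, registry, constraints, tol_Da = 1.0,
                       calibration = NULL, use_sa_constraint = TRUE,
                       table = residue_mass_table(), verbose = TRUE) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  n <- nrow(features)
  if (is.null(features$feature_id)) {
    features$feature_id <- if (n) seq_len(n) else integer(0)
  }
  if (!is.null(calibration)) {
    sa_cal <- predict(calibration, features$rt_min)
    if (is.null(features$sa_count)) {
      features$sa_count <- sa_cal$sa_count
    } else {
      miss <- is.na(features$sa_count)
      features$sa_count[miss] <- sa_cal$sa_count[miss]
    }
  }
  res <- lapply(seq_len(n), function(i) {
    f <- features[i, , drop = FALSE]
    if (!is.finite(f$mass_da)) {
      return(assignment_row(f, status = "rejected",
                            reason = "non-finite mass"))
    }
    a <- match_feature(f, registry, constraints, tol_Da = tol_Da,
                       use_sa_constraint = use_sa_constraint, table = table)
    assignment_row(f, status = a$status, candidates = a$candidates)
  })
  out <- if (n) do.call(rbind, res) else assignment_row(NULL, empty = TRUE)
  rownames(out) <- NULL
  if (verbose && n) {
    tab <- table(factor(out$status, levels = c("assigned", "ambiguous",
                                               "unassigned", "rejected")))
    message(sprintf(
      "assign_run: %d features | %d assigned, %d ambiguous, %d unassigned, %d rejected",
      n, tab[["assigned"]], tab[["ambiguous"]], tab[["unassigned"]],
      tab[["rejected"]]))
  }
  out
}

assignment_row <- function(f, status = NA_character_, candidates = NULL,
                           reason = NA_character_, empty = FALSE) {
  base <- data.frame(feature_id = if (empty) integer(0) else f$feature_id,
                     rt_min = if (empty) numeric(0) else
                       (f$rt_min %||% NA_real_),
                     mass_da = if (empty) numeric(0) else f$mass_da,
                     area = if (empty) numeric(0) else (f$area %||% NA_real_),
                     sa_count = if (empty) integer(0) else
                       as.integer(f$sa_count %||% NA_integer_),
                     condition = if (empty) character(0) else
                       as.character(f$condition %||% NA_character_),
                     stringsAsFactors = FALSE)
  ann <- data.frame(status = character(0), variant = character(0),
                    composition = character(0), mods = character(0),
                    theoretical_mass_Da = numeric(0), delta_mDa = numeric(0),
                    n_candidates = integer(0), ambiguous_with = character(0),
                    runner_up_mass_Da = numeric(0), runner_up_S = integer(0),
                    reason = character(0), stringsAsFactors = FALSE)
  if (empty) return(cbind(base, ann))
  nc <- if (is.null(candidates)) 0L else nrow(candidates)
  top <- if (nc) candidates[1L, ] else NULL
  others <- if (nc > 1L) {
    paste(sprintf("%s %s (%.2f Da)", candidates$variant[-1L],
                  candidates$composition[-1L],
                  candidates$theoretical_mass_Da[-1L]), collapse = " | ")
  } else NA_character_
  cbind(base, data.frame(
    status = status,
    variant = if (nc) top$variant else NA_character_,
    composition = if (nc) top$composition else NA_character_,
    mods = if (nc) top$mods else NA_character_,
    theoretical_mass_Da = if (nc) top$theoretical_mass_Da else NA_real_,
    delta_mDa = if (nc) top$delta_mDa else NA_real_,
    n_candidates = nc,
    ambiguous_with = others,
    runner_up_mass_Da = if (nc > 1L) candidates$theoretical_mass_Da[2L]
                        else NA_real_,
    runner_up_S = if (nc > 1L) candidates$S[2L] else NA_integer_,
    reason = reason, stringsAsFactors = FALSE))
}

#' Assign a desialylated (sialidase-treated) run
#'
#' After sialidase treatment all sialic acids are removed and the
#' chromatographic proteoform separation collapses, so enumeration forces
#' S = 0 and no retention-to-sialic-acid calibration applies. Retention
#' time can instead be used to group features into variant clusters (the
#' adapted separation resolves the genetic variants): when `rt_clusters`
#' is given, a feature that matches several variants' candidate sets is
#' restricted to the variant of its retention cluster.
#'
#' @inheritParams assign_run
#' @param rt_clusters optional data.frame with columns `rt_lo`, `rt_hi`,
#'   `variant` mapping retention windows to variants.
#' @return As [assign_run()].
#' @export
assign_desialylated <- function(features, registry, constraints,
                                tol_Da = 1.0, rt_clusters = NULL,
                                table = residue_mass_table(),
                                verbose = TRUE) {
  k0 <- constraints
  k0$sa_min <- 0L; k0$sa_max <- 0L
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features)) features$sa_count <- NA_integer_
  out <- assign_run(features, registry, k0, tol_Da = tol_Da,
                    calibration = NULL, use_sa_constraint = FALSE,
                    table = table, verbose = FALSE)
  if (!is.null(rt_clusters) && nrow(out)) {
    stopifnot(all(c("rt_lo", "rt_hi", "variant") %in% names(rt_clusters)))
    for (i in which(out$status == "ambiguous")) {
      hit <- rt_clusters$variant[rt_clusters$rt_lo <= out$rt_min[i] &
                                   out$rt_min[i] <= rt_clusters$rt_hi]
      if (length(hit) != 1L) next
      f <- out[i, c("feature_id", "rt_min", "mass_da", "area", "sa_count",
                    "condition")]
      a <- match_feature(f, registry, k0, tol_Da = tol_Da,
                         use_sa_constraint = FALSE, table = table)
      cand <- a$candidates[a$candidates$variant == hit, , drop = FALSE]
      if (nrow(cand) == 1L) {
        out[i, ] <- assignment_row(f, status = "assigned", candidates = cand)
      } else if (nrow(cand) > 1L) {
        out[i, ] <- assignment_row(f, status = "ambiguous", candidates = cand)
      }
    }
  }
  if (verbose && nrow(out)) {
    tab <- table(factor(out$status, levels = c("assigned", "ambiguous",
                                               "unassigned", "rejected")))
    message(sprintf(
      "assign_desialylated: %d features | %d assigned, %d ambiguous, %d unassigned",
      nrow(out), tab[["assigned"]], tab[["ambiguous"]], tab[["unassigned"]]))
  }
  out
}

#' Report ambiguous assignments and how each could be resolved
#'
#' One row per ambiguous feature, with the mass gap between the top two
#' candidates and a resolution hint: `"sa_count"` when the candidates
#' differ in sialic-acid count (the chromatographic constraint resolves
#' them — the two-fucose/one-sialic-acid ~1 Da case), `"tighter tolerance"`
#' when they share a sialic-acid count but differ in mass, and
#' `"unresolvable isobar"` when the theoretical masses coincide exactly.
#'
#' @param assignments output of [assign_run()] or [assign_desialylated()].
#' @return data.frame with columns `feature_id`, `mass_da`, `top_candidate`,
#'   `runner_up`, `delta_pair_Da`, `hint`.
#' @export
ambiguity_report <- function(assignments) {
  amb <- assignments[assignments$status == "ambiguous", , drop = FALSE]
  if (!nrow(amb)) {
    return(data.frame(feature_id = integer(0), mass_da = numeric(0),
                      top_candidate = character(0), runner_up = character(0),
                      delta_pair_Da = numeric(0), hint = character(0),
                      stringsAsFactors = FALSE))
  }
  delta <- abs(amb$theoretical_mass_Da - amb$runner_up_mass_Da)
  top_s <- as.integer(sub(".*S([0-9]+)$", "\\1", amb$composition))
  hint <- ifelse(delta < 1e-6, "unresolvable isobar",
                 ifelse(top_s != amb$runner_up_S, "sa_count",
                        "tighter tolerance"))
  data.frame(feature_id = amb$feature_id, mass_da = amb$mass_da,
             top_candidate = paste(amb$variant, amb$composition),
             runner_up = amb$ambiguous_with,
             delta_pair_Da = delta, hint = hint, stringsAsFactors = FALSE)
}

#' Read / write observed-feature tables
#'
#' The feature dialect is a delimited text file with columns `rt_min`,
#' `mass_da`, `area` and optional `sa_count`, `condition`, `feature_id`.
#'
#' @param path file path. `.tsv` is tab-separated, anything else
#'   comma-separated.
#' @return `read_features()`: data.frame of features.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("feature file not found: %s", path), call. = FALSE)
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("rt_min", "mass_da", "area")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("feature file %s lacks column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' @rdname read_features
#' @param features data.frame of features (or assignments).
#' @export
write_features <- function(features, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(features, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
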