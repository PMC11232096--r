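#' Per-variant relative quantification
#'
#' Normalizes integrated areas to 100% within each (genetic variant,
#' condition) group, using only unambiguously assigned features.
#' Ambiguous features are excluded rather than split between their
#' candidates, and the excluded area fraction is always reported (as the
#' `excluded` attribute and in the log) so this bias stays visible.
#'
#' @param assignments output of [assign_run()] or [assign_desialylated()]
#'   with an `area` column.
#' @param by grouping column for conditions (default `"condition"`;
#'   missing or `NA` labels collapse to `"all"`).
#' @param verbose report the excluded-area fraction?
#' @return A `QuantTable`: data.frame with columns `variant`,
#'   `composition`, `H`, `N`, `F`, `S`, `area`,
#'   `relative_abundance_percent` (sums to 100 within each variant and
#'   condition), `variant_share_percent` (the variant's share of all
#'   assigned area in its condition) and `condition`. Attributes:
#'   `excluded` (data.frame of per-condition ambiguous/unassigned area
#'   fractions).
#' @export
relative_quant <- function(assignments, by = "condition", verbose = TRUE) {
  a <- as.data.frame(assignments, stringsAsFactors = FALSE)
  if (!nrow(a)) stop("no assignments to quantify", call. = FALSE)
  if (any(a$area < 0, na.rm = TRUE)) {
    stop("areas must be non-negative", call. = FALSE)
  }
  cond <- if (by %in% names(a)) as.character(a[[by]]) else
    rep(NA_character_, nrow(a))
  cond[is.na(cond)] <- "all"
  a$.cond <- cond

  excl <- do.call(rbind, lapply(split(a, a$.cond), function(g) {
    tot <- sum(g$area, na.rm = TRUE)
    amb <- sum(g$area[g$status == "ambiguous"], na.rm = TRUE)
    una <- sum(g$area[!g$status %in% c("assigned", "ambiguous")], na.rm = TRUE)
    data.frame(condition = g$.cond[1L],
               excluded_ambiguous_fraction = if (tot > 0) amb / tot else 0,
               excluded_other_fraction = if (tot > 0) una / tot else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(excl) <- NULL

  ok <- a[a$status == "assigned" & is.finite(a$area), , drop = FALSE]
  if (!nrow(ok)) stop("no unambiguously assigned features", call. = FALSE)

  agg <- stats::aggregate(area ~ .cond + variant + composition, data = ok,
                          FUN = sum)
  rows <- list()
  for (cd in unique(agg$.cond)) {
    g <- agg[agg$.cond == cd, , drop = FALSE]
    grand <- sum(g$area)
    for (v in unique(g$variant)) {
      gv <- g[g$variant == v, , drop = FALSE]
      tot <- sum(gv$area)
      if (tot <= 0) {
        warning(sprintf("variant %s has zero total area in condition %s; omitted",
                        v, cd))
        next
      }
      comp <- lapply(gv$composition, parse_composition)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, composition = gv$composition,
        H = vapply(comp, `[[`, integer(1), "H"),
        N = vapply(comp, `[[`, integer(1), "N"),
        F = vapply(comp, `[[`, integer(1), "F"),
        S = vapply(comp, `[[`, integer(1), "S"),
        area = gv$area,
        relative_abundance_percent = 100 * gv$area / tot,
        variant_share_percent = 100 * tot / grand,
        condition = cd, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$condition, out$variant, out$N, out$F, out$S), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (verbose) {
    for (i in seq_len(nrow(excl))) {
      message(sprintf(
        "relative_quant [%s]: excluded area fraction %.1f%% ambiguous, %.1f%% unassigned/rejected",
        excl$condition[i], 100 * excl$excluded_ambiguous_fraction[i],
        100 * excl$excluded_other_fraction[i]))
    }
  }
  structure(out, excluded = excl, class = c("QuantTable", "data.frame"))
}

#' Per-variant glycosylation summaries
#'
#' Abundance-weighted summaries of a [relative_quant()] table, per variant
#' and condition: mean sialic acids per protein, percent afucosylated,
#' the fucose-count distribution (0-4), and the HexHexNAc-unit
#' distribution, reported both as antenna-equivalents (HexNAc minus the
#' core HexNAc count) and as the Hex_n HexNAc_(n-5) composition label.
#'
#' @param quant a `QuantTable`.
#' @param core_hexnac core HexNAc residues per protein (10 for five
#'   diantennary cores); antenna-equivalents are `N - core_hexnac`.
#' @param fucose_sa_subset optional integer vector of sialic-acid counts:
#'   when given, the fucose distribution (and percent afucosylated) is
#'   computed only from glycoforms with those counts and renormalized —
#'   useful to avoid peak-overlap bias by restricting to well-resolved
#'   chromatographic peaks.
#' @return list of class `QuantSummary` with data.frames `summary`
#'   (`variant`, `condition`, `mean_sa`, `pct_afucosylated`,
#'   `mean_hexhexnac_units`, `variant_share_percent`), `fucose`
#'   (`variant`, `condition`, `fucose`, `percent`) and `hexhexnac`
#'   (`variant`, `condition`, `units`, `label`, `percent`).
#' @export
summarize_distributions <- function(quant, core_hexnac = 10L,
                                    fucose_sa_subset = NULL) {
  q <- as.data.frame(quant, stringsAsFactors = FALSE)
  groups <- unique(q[, c("variant", "condition")])
  summ <- list(); fuc <- list(); hhn <- list()
  for (i in seq_len(nrow(groups))) {
    v <- groups$variant[i]; cd <- groups$condition[i]
    g <- q[q$variant == v & q$condition == cd, , drop = FALSE]
    w <- g$relative_abundance_percent
    gf <- g; wf <- w
    if (!is.null(fucose_sa_subset)) {
      keep <- g$S %in% fucose_sa_subset
      gf <- g[keep, , drop = FALSE]
      wf <- if (any(keep)) 100 * w[keep] / sum(w[keep]) else numeric(0)
    }
    f_levels <- 0:4
    f_pct <- vapply(f_levels, function(k) sum(wf[gf$F == k]), numeric(1))
    units <- sort(unique(g$N - core_hexnac))
    u_pct <- vapply(units, function(u) sum(w[g$N - core_hexnac == u]),
                    numeric(1))
    summ[[i]] <- data.frame(
      variant = v, condition = cd,
      mean_sa = sum(w * g$S) / sum(w),
      pct_afucosylated = if (length(wf)) sum(wf[gf$F == 0]) else NA_real_,
      mean_hexhexnac_units = sum(w * (g$N - core_hexnac)) / sum(w),
      variant_share_percent = g$variant_share_percent[1L],
      stringsAsFactors = FALSE)
    fuc[[i]] <- data.frame(variant = v, condition = cd, fucose = f_levels,
                           percent = f_pct, stringsAsFactors = FALSE)
    hhn[[i]] <- data.frame(variant = v, condition = cd, units = units,
                           label = sprintf("H%dN%d",
                                           units + core_hexnac + 5L,
                                           units + core_hexnac),
                           percent = u_pct, stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, summ),
                 fucose = do.call(rbind, fuc),
                 hexhexnac = do.call(rbind, hhn)),
            class = "QuantSummary")
}

#' @export
print.QuantSummary <- function(x, ...) {
  cat("<QuantSummary>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Compare proteoform profiles between two conditions
#'
#' Per-variant differences of the [summarize_distributions()] summaries of
#' two quantification tables. Sign convention: condition1 - condition2
#' (stated in the `sign_convention` attribute and in written output).
#' A variant present in only one table yields a row flagged in
#' `missing_in` with `NA` deltas.
#'
#' @param q1,q2 `QuantTable`s for the two conditions.
#' @param labels length-2 condition labels used in reporting.
#' @param core_hexnac passed to [summarize_distributions()].
#' @param fucose_sa_subset passed to [summarize_distributions()].
#' @return data.frame with columns `variant`, `d_mean_sa`,
#'   `d_pct_afucosylated`, `d_mean_hexhexnac_units`,
#'   `d_variant_share_percent`, `missing_in`.
#' @export
compare_conditions <- function(q1, q2, labels = c("condition1", "condition2"),
                               core_hexnac = 10L, fucose_sa_subset = NULL) {
  s1 <- summarize_distributions(q1, core_hexnac, fucose_sa_subset)$summary
  s2 <- summarize_distributions(q2, core_hexnac, fucose_sa_subset)$summary
  s1 <- stats::aggregate(cbind(mean_sa, pct_afucosylated,
                               mean_hexhexnac_units, variant_share_percent)
                         ~ variant, data = s1, FUN = mean)
  s2 <- stats::aggregate(cbind(mean_sa, pct_afucosylated,
                               mean_hexhexnac_units, variant_share_percent)
                         ~ variant, data = s2, FUN = mean)
  variants <- union(s1$variant, s2$variant)
  rows <- lapply(variants, function(v) {
    a <- s1[s1$variant == v, ]; b <- s2[s2$variant == v, ]
    missing_in <- if (!nrow(a)) labels[1L] else if (!nrow(b)) labels[2L]
                  else NA_character_
    if (!is.na(missing_in)) {
      return(data.frame(variant = v, d_mean_sa = NA_real_,
                        d_pct_afucosylated = NA_real_,
                        d_mean_hexhexnac_units = NA_real_,
                        d_variant_share_percent = NA_real_,
                        missing_in = missing_in, stringsAsFactors = FALSE))
    }
    data.frame(variant = v,
               d_mean_sa = a$mean_sa - b$mean_sa,
               d_pct_afucosylated = a$pct_afucosylated - b$pct_afucosylated,
               d_mean_hexhexnac_units = a$mean_hexhexnac_units -
                 b$mean_hexhexnac_units,
               d_variant_share_percent = a$variant_share_percent -
                 b$variant_share_percent,
               missing_in = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "sign_convention") <- sprintf("%s - %s", labels[1L], labels[2L])
  out
}
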