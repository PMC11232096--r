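#' Ground-truth profile specification
#'
#' Describes the population of proteoforms a synthetic run is drawn from:
#' genetic-variant shares, and discrete distributions for the sialic-acid
#' count, fucose count and branching (HexNAc count). Defaults echo the
#' profile of pooled plasma from healthy donors: variant shares
#' F1 56% / S 32% / F2 3% / AGP2 9%; sialic acids supported on 10-19 with
#' mode 16 (triangular shape — the data constrain only range and mean);
#' afucosylated glycoforms most abundant with up to four fucoses; and a
#' broad HexNAc distribution peaking at N = 27 (the H32N27 composition).
#'
#' Distributions are named numeric weight vectors: names are the integer
#' values, weights are normalized internally.
#'
#' @param variant_shares named fractions per variant (normalized).
#' @param sa_distribution weights over sialic-acid counts.
#' @param fucose_distribution weights over fucose counts 0..4.
#' @param antenna_distribution weights over total HexNAc counts.
#' @param n_proteoforms number of proteoform draws.
#' @param seed integer seed for reproducible sampling.
#' @return An object of class `ProfileSpec`.
#' @export
profile_spec <- function(variant_shares = c("AGP1*F1" = 0.56,
                                            "AGP1*S" = 0.32,
                                            "AGP1*F2" = 0.03,
                                            "AGP2" = 0.09),
                         sa_distribution = triangular_weights(10, 19, 16),
                         fucose_distribution = c("0" = 0.47, "1" = 0.33,
                                                 "2" = 0.12, "3" = 0.05,
                                                 "4" = 0.03),
                         antenna_distribution = triangular_weights(22, 33, 27),
                         n_proteoforms = 200L,
                         seed = 1L) {
  norm <- function(w, what) {
    if (any(w < 0) || sum(w) <= 0) {
      stop(sprintf("%s weights must be non-negative with positive sum", what),
           call. = FALSE)
    }
    w / sum(w)
  }
  stopifnot(n_proteoforms >= 1L)
  structure(list(variant_shares = norm(variant_shares, "variant share"),
                 sa_distribution = norm(sa_distribution, "sialic acid"),
                 fucose_distribution = norm(fucose_distribution, "fucose"),
                 antenna_distribution = norm(antenna_distribution, "HexNAc"),
                 n_proteoforms = as.integer(n_proteoforms),
                 seed = seed),
            class = "ProfileSpec")
}

#' Triangular weights over an integer support
#'
#' @param min,max integer support bounds.
#' @param mode location of the peak.
#' @return named numeric weight vector.
#' @export
triangular_weights <- function(min, max, mode) {
  v <- min:max
  w <- ifelse(v <= mode,
              (v - min + 1) / (mode - min + 1),
              (max - v + 1) / (max - mode + 1))
  stats::setNames(w / sum(w), v)
}

dist_values <- function(w) as.integer(names(w))
dist_mean <- function(w) sum(dist_values(w) * w / sum(w))

#' Shift a discrete distribution's mean by exponential tilting
#'
#' Reweights `w` to `w * exp(lambda * v)` with `lambda` chosen so the mean
#' moves by `shift`, keeping the support fixed. Used by
#' [condition_shift()] to build condition contrasts.
#'
#' @param w named weight vector.
#' @param shift desired change in mean (must keep the mean inside the
#'   support).
#' @return tilted, normalized weight vector.
#' @export
tilt_distribution <- function(w, shift) {
  if (shift == 0) return(w / sum(w))
  v <- dist_values(w)
  target <- dist_mean(w) + shift
  if (target <= min(v) || target >= max(v)) {
    stop("shift moves the mean outside the distribution support",
         call. = FALSE)
  }
  f <- function(lam) {
    ww <- w * exp(lam * v)
    sum(v * ww) / sum(ww) - target
  }
  lam <- stats::uniroot(f, c(-20, 20), tol = 1e-12)$root
  ww <- w * exp(lam * v)
  ww / sum(ww)
}

#' Build a condition-contrast profile (pregnancy-like shift)
#'
#' Returns a copy of `spec` with the sialic-acid mean shifted by
#' `sa_mean_shift`, the HexNAc (branching) mean by `antenna_mean_shift`,
#' and the afucosylated fraction changed by `afucosylated_shift`
#' (redistributing weight proportionally over the fucosylated counts).
#' The directions typical of pregnancy are sialylation up, branching up,
#' afucosylated fraction down; the magnitudes are the caller's choice.
#'
#' @param spec a [profile_spec()].
#' @param sa_mean_shift change in mean sialic acids per protein.
#' @param antenna_mean_shift change in mean HexNAc count.
#' @param afucosylated_shift change in the fucose-0 fraction (e.g. -0.05).
#' @param seed optional new seed for the shifted spec.
#' @return A [profile_spec()].
#' @export
condition_shift <- function(spec, sa_mean_shift = 0, antenna_mean_shift = 0,
                            afucosylated_shift = 0, seed = spec$seed) {
  stopifnot(inherits(spec, "ProfileSpec"))
  sa <- tilt_distribution(spec$sa_distribution, sa_mean_shift)
  an <- tilt_distribution(spec$antenna_distribution, antenna_mean_shift)
  fu <- spec$fucose_distribution
  if (afucosylated_shift != 0) {
    p0 <- fu[["0"]] + afucosylated_shift
    if (p0 < 0 || p0 > 1) {
      stop("afucosylated_shift pushes the fucose-0 fraction outside [0, 1]",
           call. = FALSE)
    }
    rest <- fu[names(fu) != "0"]
    fu <- c("0" = p0, rest * (1 - p0) / sum(rest))
  }
  profile_spec(variant_shares = spec$variant_shares, sa_distribution = sa,
               fucose_distribution = fu, antenna_distribution = an,
               n_proteoforms = spec$n_proteoforms, seed = seed)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample a ground-truth proteoform profile
#'
#' Draws `n_proteoforms` proteoforms: the variant from the variant shares,
#' HexNAc from the branching distribution (Hex follows from the offset
#' rule), the sialic-acid count from its distribution conditioned on
#' S <= antennae (counts exceeding the antenna capacity of the drawn
#' HexNAc are renormalized away; if no HexNAc value in the support can
#' carry any allowed sialic-acid count, generation fails naming the
#' constraint), and the fucose count from its distribution. Identical
#' draws are aggregated; abundances are normalized to fractions within
#' each variant. Every emitted composition passes
#' [validate_composition()].
#'
#' @param spec a [profile_spec()].
#' @param registry a [variant_registry()].
#' @param constraints a [composition_constraints()].
#' @param table a [residue_mass_table()].
#' @return data.frame of class `TruthProfile`: `truth_id`, `variant`,
#'   `H`, `N`, `F`, `S`, `composition`, `mods`, `theoretical_mass_Da`,
#'   `abundance` (per-variant fraction), `variant_share` (empirical).
#' @export
sample_profile <- function(spec, registry = default_agp_registry(),
                           constraints = composition_constraints(),
                           table = residue_mass_table()) {
  stopifnot(inherits(spec, "ProfileSpec"))
  shares <- spec$variant_shares
  unknown <- setdiff(names(shares), names(registry$variants))
  if (length(unknown)) {
    stop(sprintf("profile names variants absent from the registry: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  core_n <- core_hexnac(constraints)
  n_vals <- dist_values(spec$antenna_distribution)
  sa_w <- spec$sa_distribution
  sa_vals <- dist_values(sa_w)
  # conditional S | N distributions under the antenna-capacity rule
  cond_sa <- lapply(n_vals, function(nn) {
    cap <- if (constraints$enforce_sa_le_antennae) nn - core_n else Inf
    ok <- sa_vals <= cap & sa_vals >= constraints$sa_min &
      sa_vals <= constraints$sa_max
    if (!any(ok)) return(NULL)
    sa_w[ok] / sum(sa_w[ok])
  })
  names(cond_sa) <- n_vals
  feasible <- !vapply(cond_sa, is.null, logical(1))
  if (!any(feasible)) {
    stop(paste("infeasible constraints: no HexNAc count in the branching",
               "support can carry any allowed sialic-acid count",
               "(sa_exceeds_antennae)"), call. = FALSE)
  }
  n_w <- spec$antenna_distribution[feasible]
  n_w <- n_w / sum(n_w)
  f_w <- spec$fucose_distribution
  f_vals <- dist_values(f_w)
  ok_f <- f_vals <= constraints$max_fucose
  f_w <- f_w[ok_f] / sum(f_w[ok_f]); f_vals <- f_vals[ok_f]

  # length-1-safe weighted sampling
  draw <- function(v, n, p) v[sample.int(length(v), n, replace = TRUE,
                                         prob = p)]
  draws <- with_seed(spec$seed, {
    n <- spec$n_proteoforms
    variant <- draw(names(shares), n, shares)
    N <- draw(dist_values(n_w), n, n_w)
    S <- vapply(N, function(nn) {
      w <- cond_sa[[as.character(nn)]]
      draw(dist_values(w), 1L, w)
    }, integer(1))
    F <- draw(f_vals, n, f_w)
    data.frame(variant = variant, N = N, S = S, F = F,
               stringsAsFactors = FALSE)
  })
  draws$H <- draws$N + hex_offset(constraints)
  agg <- stats::aggregate(cbind(count = rep(1L, nrow(draws))) ~
                            variant + H + N + F + S, data = draws, FUN = sum)
  # per-variant abundance fractions and empirical variant shares
  v_tot <- tapply(agg$count, agg$variant, sum)
  agg$abundance <- agg$count / as.numeric(v_tot[agg$variant])
  agg$variant_share <- as.numeric(v_tot[agg$variant]) / sum(agg$count)
  agg$composition <- sprintf("H%dN%dF%dS%d", agg$H, agg$N, agg$F, agg$S)
  agg$mods <- vapply(agg$variant, function(v) {
    paste(split_mods(registry$variants[[v]],
                     registry$modifications)$mandatory, collapse = "+")
  }, character(1))
  agg$theoretical_mass_Da <- vapply(seq_len(nrow(agg)), function(i) {
    proteoform_candidate(agg$variant[i],
                         glycan_composition(agg$H[i], agg$N[i], agg$F[i],
                                            agg$S[i]),
                         registry = registry,
                         table = table)$theoretical_mass_Da
  }, numeric(1))
  for (i in seq_len(nrow(agg))) {
    chk <- validate_composition(glycan_composition(agg$H[i], agg$N[i],
                                                   agg$F[i], agg$S[i]),
                                constraints)
    if (!chk$pass) {
      stop(sprintf("sampled composition %s violates: %s", agg$composition[i],
                   paste(chk$reasons, collapse = ", ")), call. = FALSE)
    }
  }
  out <- agg[order(agg$variant, agg$N, agg$F, agg$S),
             c("variant", "H", "N", "F", "S", "composition", "mods",
               "theoretical_mass_Da", "abundance", "variant_share")]
  rownames(out) <- NULL
  out <- cbind(truth_id = seq_len(nrow(out)), out)
  class(out) <- c("TruthProfile", "data.frame")
  out
}

#' Instrument specification for the AEX-MS simulator
#'
#' @param mass_jitter_sd_Da SD of the Gaussian error on each proteoform's
#'   observed neutral mass (Da).
#' @param rt_peak_sigma_min chromatographic Gaussian peak SD (minutes).
#' @param rt_anchor_map data.frame (`sa_count`, `rt_min`) giving the
#'   elution center per sialic-acid count; must be monotone increasing.
#' @param variant_rt_map optional named vector of retention centers per
#'   variant, used for desialylated (S = 0) proteoforms where the
#'   sialic-acid separation has collapsed and an adapted gradient resolves
#'   the variants instead.
#' @param charge_states charge states produced by the source.
#' @param noise_floor additive uniform noise ceiling on raw points.
#' @param mz_sampling_step m/z grid step of profile spectra; peak width
#'   (SD) is `2 * mz_sampling_step`.
#' @param rt_step_min scan spacing in minutes.
#' @param area_noise_sd SD of the multiplicative lognormal abundance noise
#'   (0.01 = 1%); lognormal keeps areas positive.
#' @param intensity_scale total intensity scale of the run.
#' @param mz_range acquisition range.
#' @param seed integer seed.
#' @return An object of class `InstrumentSpec`.
#' @export
instrument_spec <- function(mass_jitter_sd_Da = 0.2,
                            rt_peak_sigma_min = 0.5,
                            rt_anchor_map = default_rt_anchor_map(),
                            variant_rt_map = NULL,
                            charge_states = c(8L, 9L),
                            noise_floor = 0,
                            mz_sampling_step = 0.01,
                            rt_step_min = 0.1,
                            area_noise_sd = 0.01,
                            intensity_scale = 1e6,
                            mz_range = c(796.9, 8000),
                            seed = 1L) {
  a <- rt_anchor_map[order(rt_anchor_map$sa_count), ]
  if (any(diff(a$rt_min) <= 0)) {
    stop("rt_anchor_map must be monotone increasing in sa_count",
         call. = FALSE)
  }
  stopifnot(mass_jitter_sd_Da >= 0, rt_peak_sigma_min > 0,
            length(charge_states) >= 1L, all(charge_states > 0),
            noise_floor >= 0, mz_sampling_step > 0, rt_step_min > 0,
            area_noise_sd >= 0)
  structure(list(mass_jitter_sd_Da = mass_jitter_sd_Da,
                 rt_peak_sigma_min = rt_peak_sigma_min,
                 rt_anchor_map = a, variant_rt_map = variant_rt_map,
                 charge_states = as.integer(charge_states),
                 noise_floor = noise_floor,
                 mz_sampling_step = mz_sampling_step,
                 rt_step_min = rt_step_min,
                 area_noise_sd = area_noise_sd,
                 intensity_scale = intensity_scale,
                 mz_range = as.numeric(mz_range), seed = seed),
            class = "InstrumentSpec")
}

anchor_rt <- function(ispec, sa, variant = NULL) {
  if (!is.null(ispec$variant_rt_map) && !is.null(variant)) {
    use_var <- sa == 0 & variant %in% names(ispec$variant_rt_map)
  } else {
    use_var <- rep(FALSE, length(sa))
  }
  a <- ispec$rt_anchor_map
  rt <- stats::approx(a$sa_count, a$rt_min, xout = sa, rule = 2)$y
  if (any(use_var)) rt[use_var] <- ispec$variant_rt_map[variant[use_var]]
  rt
}

#' Simulate deconvoluted observed features from a ground-truth profile
#'
#' One feature per proteoform: observed mass = theoretical +
#' Normal(0, mass_jitter), retention = the anchor time of its sialic-acid
#' count + Normal(0, rt sigma), area proportional to abundance times
#' variant share with multiplicative lognormal noise. The generating
#' proteoform of each feature is kept in the `truth_map` attribute for
#' round-trip scoring, not in the feature table itself.
#'
#' @param truth a [sample_profile()] result.
#' @param ispec an [instrument_spec()].
#' @param condition optional condition label stamped on every feature.
#' @return data.frame of features (`feature_id`, `rt_min`, `mass_da`,
#'   `area`, `condition`) with attribute `truth_map` (`feature_id`,
#'   `truth_id`, `variant`, `composition`).
#' @export
simulate_features <- function(truth, ispec = instrument_spec(),
                              condition = NA_character_) {
  stopifnot(nrow(truth) >= 1L)
  n <- nrow(truth)
  feats <- with_seed(ispec$seed, {
    mass <- truth$theoretical_mass_Da +
      stats::rnorm(n, 0, ispec$mass_jitter_sd_Da)
    rt <- anchor_rt(ispec, truth$S, truth$variant) +
      stats::rnorm(n, 0, ispec$rt_peak_sigma_min)
    area <- ispec$intensity_scale * truth$abundance * truth$variant_share *
      exp(stats::rnorm(n, 0, ispec$area_noise_sd))
    data.frame(feature_id = seq_len(n), rt_min = rt, mass_da = mass,
               area = area, condition = condition, stringsAsFactors = FALSE)
  })
  attr(feats, "truth_map") <- data.frame(feature_id = feats$feature_id,
                                         truth_id = truth$truth_id,
                                         variant = truth$variant,
                                         composition = truth$composition,
                                         stringsAsFactors = FALSE)
  feats
}

#' Simulate raw profile-mode scans from a ground-truth profile
#'
#' Each proteoform elutes as a Gaussian retention profile centered on the
#' anchor time of its sialic-acid count; in every scan it contributes
#' Gaussian m/z peaks at its charge-ladder positions (width
#' `2 * mz_sampling_step`, sampled on a global m/z grid), with total
#' intensity proportional to abundance times variant share. Optional
#' additive uniform noise up to `noise_floor` is applied per point.
#'
#' @param truth a [sample_profile()] result.
#' @param ispec an [instrument_spec()].
#' @param table a [residue_mass_table()].
#' @return A [scan_table()].
#' @export
simulate_scans <- function(truth, ispec = instrument_spec(),
                           table = residue_mass_table()) {
  stopifnot(nrow(truth) >= 1L)
  step <- ispec$mz_sampling_step
  sigma_mz <- 2 * step
  k <- ceiling(3.5 * sigma_mz / step)
  zs <- ispec$charge_states
  n <- nrow(truth)
  with_seed(ispec$seed, {
    mass <- truth$theoretical_mass_Da +
      stats::rnorm(n, 0, ispec$mass_jitter_sd_Da)
    centers <- anchor_rt(ispec, truth$S, truth$variant)
    amount <- ispec$intensity_scale * truth$abundance * truth$variant_share *
      exp(stats::rnorm(n, 0, ispec$area_noise_sd))
    any_in_range <- FALSE
    rt_lo <- min(centers) - 4 * ispec$rt_peak_sigma_min
    rt_hi <- max(centers) + 4 * ispec$rt_peak_sigma_min
    rt_grid <- seq(floor(rt_lo / ispec$rt_step_min) * ispec$rt_step_min,
                   rt_hi, by = ispec$rt_step_min)
    pieces <- vector("list", n)
    for (i in seq_len(n)) {
      ladder <- charge_ladder(mass[i], zs, table)
      inr <- ladder$mz >= ispec$mz_range[1] & ladder$mz <= ispec$mz_range[2]
      if (!any(inr)) next
      any_in_range <- TRUE
      ladder <- ladder[inr, , drop = FALSE]
      sel <- abs(rt_grid - centers[i]) <= 4 * ispec$rt_peak_sigma_min
      rts <- rt_grid[sel]
      rtw <- stats::dnorm(rts, centers[i], ispec$rt_peak_sigma_min)
      # scaled so the trapezoidal EIC area over rt recovers `amount`
      rtw <- rtw / sum(rtw) / ispec$rt_step_min
      sub <- vector("list", nrow(ladder))
      for (j in seq_len(nrow(ladder))) {
        c0 <- step * round(ladder$mz[j] / step)
        mzs <- c0 + step * (-k:k)
        mzw <- stats::dnorm(mzs, ladder$mz[j], sigma_mz)
        mzw <- mzw / sum(mzw) / length(zs)
        sub[[j]] <- data.frame(
          rt_min = rep(rts, each = length(mzs)),
          mz = rep(mzs, times = length(rts)),
          intensity = amount[i] * rep(rtw, each = length(mzs)) *
            rep(mzw, times = length(rts)))
      }
      pieces[[i]] <- do.call(rbind, sub)
    }
    if (!any_in_range) {
      stop("acquisition range excludes every charge-ladder position",
           call. = FALSE)
    }
    pts <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
    pts <- stats::aggregate(intensity ~ rt_min + mz, data = pts, FUN = sum)
    if (ispec$noise_floor > 0) {
      pts$intensity <- pts$intensity +
        stats::runif(nrow(pts), 0, ispec$noise_floor)
    }
    scan_table(pts, mz_range = ispec$mz_range)
  })
}

#' Write a synthetic fixture (truth + data) to disk
#'
#' Emits `truth.json` plus `features.csv` and/or `scans.csv` under `dir`.
#' All files round-trip losslessly through [read_truth_json()],
#' [read_features()] and [read_scan_csv()].
#'
#' @param truth a [sample_profile()] result.
#' @param dir output directory (created if needed).
#' @param features optional [simulate_features()] result.
#' @param scans optional [simulate_scans()] result.
#' @return named character vector of written paths.
#' @export
write_fixture <- function(truth, dir, features = NULL, scans = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    stop(sprintf("cannot create fixture directory: %s", dir), call. = FALSE)
  }
  paths <- c(truth = file.path(dir, "truth.json"))
  shares <- tapply(truth$variant_share, truth$variant, `[`, 1L)
  jsonlite::write_json(
    list(variant_shares = as.list(shares),
         proteoforms = truth[, c("truth_id", "variant", "composition",
                                 "mods", "theoretical_mass_Da", "abundance",
                                 "variant_share")]),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(features)) {
    paths <- c(paths, features = file.path(dir, "features.csv"))
    write_features(features, paths[["features"]])
  }
  if (!is.null(scans)) {
    paths <- c(paths, scans = file.path(dir, "scans.csv"))
    write_scan_csv(scans, paths[["scans"]])
  }
  paths
}

#' @rdname write_fixture
#' @param path path to a `truth.json`.
#' @return `read_truth_json()`: the truth data.frame with a
#'   `variant_shares` attribute.
#' @export
read_truth_json <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("truth file not found: %s", path), call. = FALSE)
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- as.data.frame(j$proteoforms, stringsAsFactors = FALSE)
  comp <- lapply(truth$composition, parse_composition)
  truth$H <- vapply(comp, `[[`, integer(1), "H")
  truth$N <- vapply(comp, `[[`, integer(1), "N")
  truth$F <- vapply(comp, `[[`, integer(1), "F")
  truth$S <- vapply(comp, `[[`, integer(1), "S")
  attr(truth, "variant_shares") <- unlist(j$variant_shares)
  truth
}

#' Score a round trip against the generating truth
#'
#' `assignment_accuracy()` returns the fraction of total feature area
#' whose unambiguous top assignment is exactly the generating proteoform
#' (ambiguous, unassigned and misassigned features all count as wrong).
#' `profile_recovery()` compares a [relative_quant()] table with the
#' truth at the profile level: per variant it computes the overlap
#' `100 - 0.5 * sum(|recovered% - true%|)` between composition
#' distributions, then averages the overlaps weighted by the true variant
#' shares.
#'
#' @param assignments output of [assign_run()].
#' @param truth_map the `truth_map` attribute of [simulate_features()].
#' @return a number in `[0, 1]` (`assignment_accuracy`) or `[0, 100]`
#'   (`profile_recovery`).
#' @export
assignment_accuracy <- function(assignments, truth_map) {
  m <- merge(assignments, truth_map, by = "feature_id",
             suffixes = c("", ".true"))
  ok <- m$status == "assigned" & m$variant == m$variant.true &
    m$composition == m$composition.true
  sum(m$area[ok]) / sum(m$area)
}

#' @rdname assignment_accuracy
#' @param quant a `QuantTable`.
#' @param truth a [sample_profile()] (or [read_truth_json()]) result.
#' @export
profile_recovery <- function(quant, truth) {
  q <- as.data.frame(quant, stringsAsFactors = FALSE)
  variants <- unique(truth$variant)
  shares <- tapply(truth$variant_share, truth$variant, `[`, 1L)
  ov <- vapply(variants, function(v) {
    tr <- truth[truth$variant == v, ]
    rec <- q[q$variant == v, ]
    comps <- union(tr$composition, rec$composition)
    p_true <- 100 * tr$abundance[match(comps, tr$composition)]
    p_true[is.na(p_true)] <- 0
    p_rec <- rec$relative_abundance_percent[match(comps, rec$composition)]
    p_rec[is.na(p_rec)] <- 0
    100 - 0.5 * sum(abs(p_true - p_rec))
  }, numeric(1))
  sum(ov * shares[variants]) / sum(shares[variants])
}
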