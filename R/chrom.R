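#' Scan tables
#'
#' A `ScanTable` holds raw-level AEX-MS data as sparse profile points:
#' one row per (retention time, m/z, intensity) triple, plus acquisition
#' metadata. Scans are ordered by retention time, then m/z.
#'
#' @param points data.frame with columns `rt_min`, `mz`, `intensity`.
#' @param mz_range acquisition m/z range, length-2 numeric.
#' @param polarity `"positive"` or `"negative"`.
#' @return An object of class `ScanTable`.
#' @export
scan_table <- function(points, mz_range = c(796.9, 8000),
                       polarity = "positive") {
  points <- as.data.frame(points, stringsAsFactors = FALSE)
  need <- c("rt_min", "mz", "intensity")
  if (!all(need %in% names(points))) {
    stop("scan points need columns rt_min, mz, intensity", call. = FALSE)
  }
  if (nrow(points)) {
    if (any(points$mz <= 0)) stop("m/z values must be positive", call. = FALSE)
    if (any(points$intensity < 0)) {
      stop("intensities must be non-negative", call. = FALSE)
    }
    points <- points[order(points$rt_min, points$mz), need, drop = FALSE]
    rownames(points) <- NULL
  } else {
    points <- points[, need, drop = FALSE]
  }
  structure(list(points = points, mz_range = as.numeric(mz_range),
                 polarity = polarity),
            class = "ScanTable")
}

#' @export
print.ScanTable <- function(x, ...) {
  rts <- unique(x$points$rt_min)
  cat(sprintf("<ScanTable> %d scans, %d points, m/z %.1f-%.1f (%s)\n",
              length(rts), nrow(x$points), x$mz_range[1], x$mz_range[2],
              x$polarity))
  invisible(x)
}

#' Read / write the scan-table CSV dialect
#'
#' Plain CSV with columns `rt_min`, `mz`, `intensity`; the acquisition
#' range is stored in a `# mz_range: lo hi` comment on the first line.
#'
#' @param path file path.
#' @param scans a [scan_table()].
#' @export
write_scan_csv <- function(scans, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mz_range: %.6f %.6f", scans$mz_range[1],
                     scans$mz_range[2]), con)
  utils::write.table(scans$points, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_scan_csv
#' @export
read_scan_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("scan file not found: %s", path), call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  mz_range <- c(796.9, 8000)
  if (startsWith(first, "# mz_range:")) {
    mz_range <- as.numeric(strsplit(trimws(sub("# mz_range:", "", first)),
                                    " +")[[1]])
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  scan_table(df, mz_range = mz_range)
}

#' Read a ScanTable from an mzML file
#'
#' Requires the mzR package. Profile or centroid spectra are both read as
#' sparse points; retention times are converted to minutes.
#'
#' @param path mzML file path.
#' @return A [scan_table()].
#' @export
read_scan_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("read_scan_mzml() requires the mzR package", call. = FALSE)
  }
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hdr <- mzR::header(h)
  pk <- mzR::peaks(h)
  if (is.matrix(pk)) pk <- list(pk)
  pts <- do.call(rbind, lapply(seq_along(pk), function(i) {
    m <- pk[[i]]
    if (!nrow(m)) return(NULL)
    data.frame(rt_min = hdr$retentionTime[i] / 60, mz = m[, 1],
               intensity = m[, 2])
  }))
  if (is.null(pts)) {
    pts <- data.frame(rt_min = numeric(0), mz = numeric(0),
                      intensity = numeric(0))
  }
  lo <- if (!is.null(hdr$lowMZ)) min(hdr$lowMZ) else min(pts$mz, 0)
  hi <- if (!is.null(hdr$highMZ)) max(hdr$highMZ) else max(pts$mz, 1)
  scan_table(pts, mz_range = c(lo, hi))
}

#' Theoretical charge ladder of a neutral mass
#'
#' For electrospray positive mode, `m/z = (M + z * m_proton) / z` at each
#' charge `z`. Intact AGP ionizes mainly at 8+ and 9+ under the AEX-MS
#' conditions emulated here, so those are the package-wide defaults.
#'
#' @param mass_Da neutral average mass (Da).
#' @param charges vector of positive integer charge states.
#' @param table a [residue_mass_table()].
#' @return data.frame with columns `z`, `mz`.
#' @examples
#' charge_ladder(33785.61, c(8, 9))  # m/z 4224.21 and 3754.96
#' @export
charge_ladder <- function(mass_Da, charges = c(8L, 9L),
                          table = residue_mass_table()) {
  assert_scalar_number(mass_Da, "mass_Da")
  if (mass_Da < 0) stop("mass_Da must be non-negative", call. = FALSE)
  charges <- as.integer(charges)
  if (!length(charges) || any(charges <= 0L)) {
    stop("charges must be positive integers", call. = FALSE)
  }
  charges <- sort(unique(charges))
  data.frame(z = charges,
             mz = (mass_Da + charges * table$proton_Da) / charges)
}

#' Centroid a profile-mode spectrum
#'
#' Clusters consecutive points closer than `gap` in m/z and splits
#' clusters at valleys (interior local minima below `valley_frac` of the
#' smaller adjacent maximum), then reports the intensity-weighted centroid
#' and summed intensity of each peak.
#'
#' @param mz,intensity numeric vectors of equal length.
#' @param gap maximum m/z spacing within a peak.
#' @param valley_frac relative valley depth required to split two maxima.
#' @param min_intensity drop centroids below this summed intensity.
#' @return data.frame with columns `mz`, `intensity`.
#' @export
centroid_spectrum <- function(mz, intensity, gap = 0.05, valley_frac = 0.5,
                              min_intensity = 0) {
  keep <- intensity > 0
  mz <- mz[keep]; intensity <- intensity[keep]
  if (!length(mz)) return(data.frame(mz = numeric(0), intensity = numeric(0)))
  o <- order(mz); mz <- mz[o]; intensity <- intensity[o]
  cluster <- cumsum(c(1, diff(mz) > gap))
  out <- lapply(split(seq_along(mz), cluster), function(idx) {
    split_at_valleys(mz[idx], intensity[idx], valley_frac)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[out$intensity >= min_intensity, , drop = FALSE]
}

split_at_valleys <- function(mz, y, valley_frac) {
  n <- length(mz)
  centroid <- function(i) data.frame(mz = sum(mz[i] * y[i]) / sum(y[i]),
                                     intensity = sum(y[i]))
  if (n < 3L) return(centroid(seq_len(n)))
  is_max <- vapply(seq_len(n), function(i) {
    l <- if (i > 1L) y[i - 1L] else -Inf
    r <- if (i < n) y[i + 1L] else -Inf
    y[i] >= l && y[i] >= r
  }, logical(1))
  maxima <- which(is_max)
  cuts <- integer(0)
  if (length(maxima) > 1L) {
    for (k in seq_len(length(maxima) - 1L)) {
      seg <- maxima[k]:maxima[k + 1L]
      vi <- seg[which.min(y[seg])]
      if (y[vi] < valley_frac * min(y[maxima[k]], y[maxima[k + 1L]])) {
        cuts <- c(cuts, vi)
      }
    }
  }
  bounds <- c(0L, cuts, n)
  segs <- lapply(seq_len(length(bounds) - 1L), function(k) {
    (bounds[k] + 1L):bounds[k + 1L]
  })
  do.call(rbind, lapply(segs, centroid))
}

#' Adjacent-charge ladder deconvolution
#'
#' A transparent replacement for vendor maximum-entropy deconvolution:
#' every pair of centroided peaks whose m/z values are consistent with
#' adjacent charge states z and z+1 of one neutral mass (the two implied
#' masses agreeing within `pair_tol_Da`) emits that mass with the summed
#' intensity of the pair; the emitted masses are then clustered within
#' `cluster_tol_Da` and their intensities summed.
#'
#' @param peaks data.frame with columns `mz`, `intensity` (centroided).
#' @param z_range vector of charge states to consider (adjacent pairs
#'   within this set are used).
#' @param pair_tol_Da agreement tolerance between the two implied neutral
#'   masses of a pair (Da).
#' @param cluster_tol_Da clustering tolerance for emitted masses (Da).
#' @param table a [residue_mass_table()].
#' @return data.frame with columns `mass_da`, `intensity`, ordered by
#'   mass; empty (not an error) when no consistent pair exists.
#' @export
deconvolute_ladder <- function(peaks, z_range = c(8L, 9L),
                               pair_tol_Da = 0.5, cluster_tol_Da = 1.0,
                               table = residue_mass_table()) {
  empty <- data.frame(mass_da = numeric(0), intensity = numeric(0))
  if (is.null(peaks) || nrow(peaks) < 2L) return(empty)
  z_range <- sort(unique(as.integer(z_range)))
  if (any(z_range <= 0L)) stop("charge states must be positive", call. = FALSE)
  pr <- table$proton_Da
  hits <- list()
  for (z in z_range) {
    if (!((z + 1L) %in% z_range)) next
    # peak i interpreted at charge z+1 (lower m/z), peak j at charge z
    m_hi <- (z + 1L) * (peaks$mz - pr)   # mass if peak carries z+1
    m_lo <- z * (peaks$mz - pr)          # mass if peak carries z
    for (i in seq_len(nrow(peaks))) {
      d <- abs(m_hi[i] - m_lo)
      j <- which(d <= pair_tol_Da)
      j <- j[j != i]
      for (jj in j) {
        hits[[length(hits) + 1L]] <- c(mass = (m_hi[i] + m_lo[jj]) / 2,
                                       intensity = peaks$intensity[i] +
                                         peaks$intensity[jj])
      }
    }
  }
  if (!length(hits)) return(empty)
  h <- do.call(rbind, hits)
  o <- order(h[, "mass"])
  mass <- h[o, "mass"]; inten <- h[o, "intensity"]
  cluster <- cumsum(c(1, diff(mass) > cluster_tol_Da))
  agg <- lapply(split(seq_along(mass), cluster), function(i) {
    data.frame(mass_da = sum(mass[i] * inten[i]) / sum(inten[i]),
               intensity = sum(inten[i]))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Extract an ion chromatogram
#'
#' Per scan, sums the intensities of all points with
#' `|mz - target_mz| <= tol_mz`. The returned trace shares the scan
#' table's retention-time axis; a target outside the acquisition range
#' yields an all-zero trace with a warning.
#'
#' @param scans a [scan_table()].
#' @param target_mz m/z window center.
#' @param tol_mz half-width of the m/z window (> 0).
#' @return data.frame with columns `rt_min`, `intensity`.
#' @export
extract_eic <- function(scans, target_mz, tol_mz) {
  stopifnot(inherits(scans, "ScanTable"))
  assert_scalar_number(tol_mz, "tol_mz", positive = TRUE)
  assert_scalar_number(target_mz, "target_mz")
  rts <- sort(unique(scans$points$rt_min))
  trace <- data.frame(rt_min = rts, intensity = 0)
  if (target_mz < scans$mz_range[1] || target_mz > scans$mz_range[2]) {
    warning(sprintf("target m/z %.4f outside acquisition range [%.1f, %.1f]",
                    target_mz, scans$mz_range[1], scans$mz_range[2]))
    return(trace)
  }
  p <- scans$points
  sel <- abs(p$mz - target_mz) <= tol_mz
  if (any(sel)) {
    s <- stats::aggregate(intensity ~ rt_min, data = p[sel, ], FUN = sum)
    m <- match(s$rt_min, trace$rt_min)
    trace$intensity[m] <- s$intensity
  }
  trace
}

#' Integrate a chromatographic peak
#'
#' Trapezoidal area of a trace over a retention window. With
#' `baseline = TRUE` a linear baseline between the trace values at the
#' window endpoints is subtracted and the baseline-corrected signal is
#' floored at zero before integration.
#'
#' @param trace data.frame with columns `rt_min`, `intensity`.
#' @param rt_window numeric length-2 `[lo, hi]`, within the trace range.
#' @param baseline subtract the endpoint-to-endpoint linear baseline?
#' @return area (intensity x minutes).
#' @export
integrate_peak <- function(trace, rt_window, baseline = TRUE) {
  stopifnot(is.numeric(rt_window), length(rt_window) == 2L)
  if (rt_window[1] > rt_window[2]) {
    stop("rt_window must satisfy lo <= hi", call. = FALSE)
  }
  if (!nrow(trace)) return(0)
  o <- order(trace$rt_min)
  rt <- trace$rt_min[o]; y <- trace$intensity[o]
  lo <- max(rt_window[1], min(rt)); hi <- min(rt_window[2], max(rt))
  if (lo >= hi) return(0)
  y_lo <- stats::approx(rt, y, xout = lo, rule = 2)$y
  y_hi <- stats::approx(rt, y, xout = hi, rule = 2)$y
  inside <- rt > lo & rt < hi
  xs <- c(lo, rt[inside], hi)
  ys <- c(y_lo, y[inside], y_hi)
  if (baseline) {
    bl <- y_lo + (y_hi - y_lo) * (xs - lo) / (hi - lo)
    ys <- pmax(ys - bl, 0)
  }
  sum(diff(xs) * (utils::head(ys, -1L) + utils::tail(ys, -1L)) / 2)
}

#' Derive deconvoluted features from raw scans
#'
#' For each retention window, sums the profile points into one spectrum,
#' centroids it, deconvolutes the charge ladder to neutral masses, and
#' quantifies each mass by integrating its extracted ion chromatograms at
#' the given charge states over the window. This is the raw-level
#' counterpart of importing a deconvoluted feature list.
#'
#' @param scans a [scan_table()].
#' @param windows data.frame with columns `rt_lo`, `rt_hi` (e.g. from
#'   [sa_windows_from_anchors()]).
#' @param z_range charge states used for deconvolution and EICs.
#' @param eic_tol_mz EIC half-window (m/z).
#' @param centroid_gap,valley_frac passed to [centroid_spectrum()].
#' @param pair_tol_Da,cluster_tol_Da passed to [deconvolute_ladder()].
#' @param min_rel_intensity drop deconvoluted masses below this fraction
#'   of the window's strongest mass.
#' @param min_rel_area drop features below this fraction of the run's
#'   strongest feature area (suppresses chromatographic tail spillover
#'   into neighbouring windows).
#' @param table a [residue_mass_table()].
#' @return data.frame of features: `feature_id`, `rt_min` (intensity
#'   weighted apex), `mass_da`, `area`.
#' @export
features_from_scans <- function(scans, windows, z_range = c(8L, 9L),
                                eic_tol_mz = 0.08, centroid_gap = 0.05,
                                valley_frac = 0.5, pair_tol_Da = 0.5,
                                cluster_tol_Da = 1.0,
                                min_rel_intensity = 0.001,
                                min_rel_area = 0.001,
                                table = residue_mass_table()) {
  stopifnot(inherits(scans, "ScanTable"),
            all(c("rt_lo", "rt_hi") %in% names(windows)))
  p <- scans$points
  feats <- list()
  for (w in seq_len(nrow(windows))) {
    lo <- windows$rt_lo[w]; hi <- windows$rt_hi[w]
    sub <- p[p$rt_min >= lo & p$rt_min <= hi, , drop = FALSE]
    if (!nrow(sub)) next
    spec <- stats::aggregate(intensity ~ mz, data = sub, FUN = sum)
    peaks <- centroid_spectrum(spec$mz, spec$intensity, gap = centroid_gap,
                               valley_frac = valley_frac)
    dec <- deconvolute_ladder(peaks, z_range = z_range,
                              pair_tol_Da = pair_tol_Da,
                              cluster_tol_Da = cluster_tol_Da, table = table)
    if (!nrow(dec)) next
    dec <- dec[dec$intensity >= min_rel_intensity * max(dec$intensity), ,
               drop = FALSE]
    wscan <- scan_table(sub, mz_range = scans$mz_range,
                        polarity = scans$polarity)
    for (i in seq_len(nrow(dec))) {
      ladder <- charge_ladder(dec$mass_da[i], z_range, table)
      traces <- lapply(ladder$mz, function(mzc) {
        extract_eic(wscan, mzc, eic_tol_mz)
      })
      comb <- traces[[1L]]
      if (length(traces) > 1L) {
        for (t2 in traces[-1L]) comb$intensity <- comb$intensity + t2$intensity
      }
      area <- integrate_peak(comb, c(lo, hi), baseline = FALSE)
      if (area <= 0) next
      apex <- sum(comb$rt_min * comb$intensity) / sum(comb$intensity)
      feats[[length(feats) + 1L]] <-
        data.frame(rt_min = apex, mass_da = dec$mass_da[i], area = area)
    }
  }
  out <- if (length(feats)) do.call(rbind, feats) else
    data.frame(rt_min = numeric(0), mass_da = numeric(0), area = numeric(0))
  if (nrow(out)) {
    out <- out[out$area >= min_rel_area * max(out$area), , drop = FALSE]
  }
  out <- out[order(out$rt_min, out$mass_da), , drop = FALSE]
  rownames(out) <- NULL
  cbind(feature_id = seq_len(nrow(out)), out)
}

#' Retention windows centered on sialic-acid anchor times
#'
#' Window boundaries are the midpoints between consecutive anchors,
#' extended by half the median anchor spacing at both ends.
#'
#' @param anchors data.frame with columns `rt_min`, `sa_count`.
#' @return data.frame with columns `sa_count`, `rt_lo`, `rt_hi`.
#' @export
sa_windows_from_anchors <- function(anchors) {
  a <- anchors[order(anchors$rt_min), , drop = FALSE]
  if (nrow(a) < 2L) stop("need at least two anchors", call. = FALSE)
  mid <- (a$rt_min[-1L] + a$rt_min[-nrow(a)]) / 2
  half <- stats::median(diff(a$rt_min)) / 2
  data.frame(sa_count = a$sa_count,
             rt_lo = c(a$rt_min[1L] - half, mid),
             rt_hi = c(mid, a$rt_min[nrow(a)] + half))
}
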