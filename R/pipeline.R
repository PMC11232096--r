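#' Run configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown fields are
#' rejected up front so a typo cannot silently change a run.
#'
#' @param input list with `kind` (`"features"` or `"scans"`) and either
#'   `path` (CSV/TSV per [read_features()] / [read_scan_csv()]) or `data`
#'   (an in-memory data.frame / [scan_table()]).
#' @param output_dir directory all outputs are written into (created if
#'   needed); nothing is written outside it.
#' @param workflow `"native"` (sialylated run, retention-to-sialic-acid
#'   calibration applied) or `"desialylated"` (S forced to 0, optional
#'   variant retention clusters).
#' @param registry a [variant_registry()], a registry file path for
#'   [registry_from_json()], or `NULL` for [default_agp_registry()].
#' @param constraints a [composition_constraints()] or a named list of
#'   arguments for it.
#' @param tolerance_Da mass tolerance for matching.
#' @param calibration `"auto"` (anchors from [default_rt_anchor_map()]
#'   over the constraint sialic-acid range intersected with 10..19), a
#'   data.frame of anchors (`rt_min`, `sa_count`), or `NULL` (no
#'   calibration; native workflow then matches without the constraint).
#' @param rt_clusters optional variant retention clusters for the
#'   desialylated workflow (`rt_lo`, `rt_hi`, `variant`).
#' @param condition optional condition label stamped on the features.
#' @param fucose_sa_subset optional sialic-acid counts restricting the
#'   fucosylation summary (e.g. `c(11, 14, 18)` to use only the
#'   best-resolved chromatographic peaks); default uses all calibrated
#'   peaks.
#' @param seed seed for any stochastic step (none in assignment itself;
#'   kept for reproducibility bookkeeping in the summary).
#' @param log_level `"info"` or `"quiet"`.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(input, output_dir, workflow = c("native",
                                                       "desialylated"),
                       registry = NULL, constraints = NULL,
                       tolerance_Da = 1.0, calibration = "auto",
                       rt_clusters = NULL, condition = NA_character_,
                       fucose_sa_subset = NULL, seed = 1L,
                       log_level = c("info", "quiet")) {
  workflow <- match.arg(workflow)
  log_level <- match.arg(log_level)
  if (!is.list(input) || is.null(input$kind) ||
      !input$kind %in% c("features", "scans")) {
    stop("input must be a list with kind 'features' or 'scans'",
         call. = FALSE)
  }
  if (is.null(input$path) && is.null(input$data)) {
    stop("input needs either a path or in-memory data", call. = FALSE)
  }
  extra <- setdiff(names(input), c("kind", "path", "data"))
  if (length(extra)) {
    stop(sprintf("unknown input field(s): %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  assert_scalar_number(tolerance_Da, "tolerance_Da", positive = TRUE)
  if (is.character(registry)) registry <- registry_from_json(registry)
  if (is.null(registry)) registry <- default_agp_registry()
  stopifnot(inherits(registry, "VariantRegistry"))
  if (is.null(constraints)) {
    constraints <- composition_constraints()
  } else if (is.list(constraints) && !inherits(constraints,
                                               "CompositionConstraints")) {
    constraints <- do.call(composition_constraints, constraints)
  }
  stopifnot(inherits(constraints, "CompositionConstraints"))
  structure(list(input = input, output_dir = output_dir,
                 workflow = workflow, registry = registry,
                 constraints = constraints, tolerance_Da = tolerance_Da,
                 calibration = calibration, rt_clusters = rt_clusters,
                 condition = condition, fucose_sa_subset = fucose_sa_subset,
                 seed = seed, log_level = log_level),
            class = "RunConfig")
}

#' Read a run configuration from JSON or YAML
#'
#' Field names mirror the [run_config()] arguments; unknown keys are
#' rejected before anything executes.
#'
#' @param path `.json`, `.yml` or `.yaml` file.
#' @return A `RunConfig`.
#' @export
run_config_from_file <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  allowed <- setdiff(names(formals(run_config)), "")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(raw$calibration) && is.list(raw$calibration)) {
    raw$calibration <- as.data.frame(raw$calibration)
  }
  if (!is.null(raw$rt_clusters)) {
    raw$rt_clusters <- as.data.frame(raw$rt_clusters)
  }
  if (!is.null(raw$fucose_sa_subset)) {
    raw$fucose_sa_subset <- as.integer(unlist(raw$fucose_sa_subset))
  }
  do.call(run_config, raw)
}

resolve_calibration <- function(config) {
  cal <- config$calibration
  if (is.null(cal)) return(NULL)
  if (identical(cal, "auto")) {
    sa <- intersect(config$constraints$sa_min:config$constraints$sa_max,
                    10:19)
    if (length(sa) < 2L) sa <- 10:19
    anchors <- default_rt_anchor_map(sa_range = sa)
    return(calibrate_rt_to_sa(anchors[, c("rt_min", "sa_count")]))
  }
  if (inherits(cal, "RtSaCalibration")) return(cal)
  calibrate_rt_to_sa(as.data.frame(cal))
}

#' Run the full assignment-and-quantification pipeline
#'
#' Loads or accepts the input (a deconvoluted feature table, or raw scans
#' that are first deconvoluted window-by-window), calibrates retention
#' time to sialic-acid count (native workflow), assigns every feature,
#' quantifies per variant, summarizes the glycosylation distributions,
#' and writes the report bundle into the configured output directory:
#' `assignments.tsv`, `quant.tsv`, `ambiguity.tsv`, `summary.json` and
#' `log.txt`. Deterministic for a fixed config and seed; any stage
#' failure aborts with the stage name before partial outputs are written.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `assignments`, `quant`, `summary`
#'   (a [summarize_distributions()] result), `ambiguity`, `counts` and
#'   `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (config$log_level == "info") message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage:%s] %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  calibration <- stage("calibration", resolve_calibration(config))

  features <- stage("input", {
    inp <- config$input
    if (inp$kind == "features") {
      f <- if (!is.null(inp$data)) as.data.frame(inp$data) else
        read_features(inp$path)
      f
    } else {
      scans <- if (!is.null(inp$data)) inp$data else read_scan_csv(inp$path)
      if (is.null(calibration)) {
        stop("scan input needs a calibration to define retention windows")
      }
      windows <- sa_windows_from_anchors(calibration$anchors)
      features_from_scans(scans, windows,
                          z_range = c(8L, 9L))
    }
  })
  if (!is.null(config$condition) && !is.na(config$condition)) {
    features$condition <- config$condition
  }
  say("input: %d features (%s, %s workflow)", nrow(features),
      config$input$kind, config$workflow)

  assignments <- stage("assignment", {
    if (config$workflow == "native") {
      assign_run(features, config$registry, config$constraints,
                 tol_Da = config$tolerance_Da, calibration = calibration,
                 use_sa_constraint = !is.null(calibration), verbose = FALSE)
    } else {
      assign_desialylated(features, config$registry, config$constraints,
                          tol_Da = config$tolerance_Da,
                          rt_clusters = config$rt_clusters, verbose = FALSE)
    }
  })
  counts <- as.list(table(factor(assignments$status,
                                 levels = c("assigned", "ambiguous",
                                            "unassigned", "rejected"))))
  say("assignment: %d assigned, %d ambiguous, %d unassigned, %d rejected",
      counts$assigned, counts$ambiguous, counts$unassigned, counts$rejected)

  quant <- stage("quantification",
                 relative_quant(assignments, verbose = FALSE))
  excl <- attr(quant, "excluded")
  for (i in seq_len(nrow(excl))) {
    say("excluded ambiguous area fraction [%s]: %.2f%%  (unassigned/rejected: %.2f%%)",
        excl$condition[i], 100 * excl$excluded_ambiguous_fraction[i],
        100 * excl$excluded_other_fraction[i])
  }
  summary <- stage("summaries",
                   summarize_distributions(
                     quant, fucose_sa_subset = config$fucose_sa_subset))
  ambiguity <- stage("ambiguity", ambiguity_report(assignments))

  paths <- stage("report", {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    p <- c(assignments = file.path(config$output_dir, "assignments.tsv"),
           quant = file.path(config$output_dir, "quant.tsv"),
           ambiguity = file.path(config$output_dir, "ambiguity.tsv"),
           summary = file.path(config$output_dir, "summary.json"),
           log = file.path(config$output_dir, "log.txt"))
    write_features(assignments, p[["assignments"]])
    write_features(as.data.frame(quant), p[["quant"]])
    write_features(ambiguity, p[["ambiguity"]])
    jsonlite::write_json(
      list(workflow = config$workflow, seed = config$seed,
           tolerance_Da = config$tolerance_Da,
           units = list(mass = "Da (average)", rt = "min",
                        abundance = "percent of variant total"),
           counts = counts,
           excluded_area = excl,
           summary = summary$summary,
           fucose_distribution = summary$fucose,
           hexhexnac_distribution = summary$hexhexnac),
      p[["summary"]], auto_unbox = TRUE, digits = NA, dataframe = "rows",
      pretty = TRUE)
    writeLines(log_lines, p[["log"]])
    p
  })
  invisible(list(assignments = assignments, quant = quant,
                 summary = summary, ambiguity = ambiguity, counts = counts,
                 paths = paths))
}

#' Compare two completed runs
#'
#' Wraps [compare_conditions()] for two [run_pipeline()] results or
#' output directories. The delta table (sign convention: run1 - run2,
#' stated in the output header) is returned and, when `out_dir` is given,
#' written as `comparison.tsv` with a human-readable `comparison.txt`.
#'
#' @param run1,run2 [run_pipeline()] results or their output directories.
#' @param labels length-2 labels for the two runs.
#' @param out_dir optional directory for the written comparison.
#' @param fucose_sa_subset passed to [compare_conditions()].
#' @return the [compare_conditions()] delta table.
#' @export
compare_runs <- function(run1, run2, labels = c("run1", "run2"),
                         out_dir = NULL, fucose_sa_subset = NULL) {
  load_quant <- function(r, lbl) {
    if (is.list(r) && !is.null(r$quant)) return(r$quant)
    if (is.character(r)) {
      path <- file.path(r, "quant.tsv")
      if (!file.exists(path)) {
        stop(sprintf("no quant.tsv under '%s' (%s)", r, lbl), call. = FALSE)
      }
      q <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
      class(q) <- c("QuantTable", "data.frame")
      return(q)
    }
    stop("runs must be run_pipeline() results or output directories",
         call. = FALSE)
  }
  q1 <- load_quant(run1, labels[1L])
  q2 <- load_quant(run2, labels[2L])
  delta <- compare_conditions(q1, q2, labels = labels,
                              fucose_sa_subset = fucose_sa_subset)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tsv <- file.path(out_dir, "comparison.tsv")
    con <- file(tsv, "w")
    writeLines(sprintf("# sign convention: %s", attr(delta,
                                                     "sign_convention")),
               con)
    utils::write.table(delta, con, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    close(con)
    txt <- file.path(out_dir, "comparison.txt")
    lines <- c(sprintf("Condition comparison (%s):",
                       attr(delta, "sign_convention")))
    for (i in seq_len(nrow(delta))) {
      d <- delta[i, ]
      lines <- c(lines, if (!is.na(d$missing_in)) {
        sprintf("  %s: missing in %s", d$variant, d$missing_in)
      } else {
        sprintf(paste0("  %s: mean SA %+0.2f, afucosylated %+0.1f %%pt, ",
                       "HexHexNAc units %+0.2f, variant share %+0.1f %%pt"),
                d$variant, d$d_mean_sa, d$d_pct_afucosylated,
                d$d_mean_hexhexnac_units, d$d_variant_share_percent)
      })
    }
    writeLines(lines, txt)
  }
  delta
}
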