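#' Write and read trace tables
#'
#' Trace tables are plain CSV with the mandatory header
#' `molecule_id, frame, time_s, donor, acceptor` (one file per cohort; a
#' `concentration_nM` column is included when present). An optional truth
#' sidecar (`molecule_id, state, t_start_s, t_end_s`) stores the
#' generating state intervals for oracle tests.
#'
#' @param cohort A cohort tibble (see [generate_cohort()]).
#' @param path Output CSV path.
#' @param truth_path Optional path for the truth sidecar (written only
#'   when the cohort carries a `truth` attribute).
#' @return `write_traces()` returns `path` invisibly; `read_traces()`
#'   returns a cohort tibble sorted by molecule and frame.
#' @export
write_traces <- function(cohort, path, truth_path = NULL) {
  cols <- intersect(c("molecule_id", "concentration_nM", "frame",
                      "time_s", "donor", "acceptor"), names(cohort))
  readr::write_csv(as_tibble(cohort)[cols], path, progress = FALSE)
  truth <- attr(cohort, "truth")
  if (!is.null(truth_path) && !is.null(truth)) {
    readr::write_csv(truth, truth_path, progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_traces
#' @param frame_time Expected uniform frame time; `NULL` infers it from
#'   the data.
#' @export
read_traces <- function(path, frame_time = NULL) {
  if (!file.exists(path)) abort(sprintf("No such trace file: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("molecule_id", "frame", "time_s", "donor", "acceptor")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("Trace file is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  df <- df |> arrange(.data$molecule_id, .data$frame)
  dup <- df |> count(.data$molecule_id, .data$frame) |> filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("Duplicate (molecule, frame) pair: %s frame %d.",
                  dup$molecule_id[1], dup$frame[1]))
  }
  ## frames must be gapless per molecule
  gaps <- df |>
    group_by(.data$molecule_id) |>
    summarise(bad = {
      fr <- .data$frame
      i <- which(diff(fr) != 1L)
      if (length(i) == 0) NA_integer_ else fr[i[1] + 1L]
    }, .groups = "drop") |>
    filter(!is.na(.data$bad))
  if (nrow(gaps) > 0) {
    abort(sprintf("Non-contiguous frame numbering for molecule %s at frame %d.",
                  gaps$molecule_id[1], gaps$bad[1]))
  }
  ## uniform timebase
  dt <- df |>
    group_by(.data$molecule_id) |>
    summarise(dt = if (dplyr::n() > 1) diff(.data$time_s[1:2]) else
      NA_real_, .groups = "drop")
  dts <- unique(round(dt$dt[!is.na(dt$dt)], 9))
  if (length(dts) > 1) {
    abort("Trace file mixes frame times across molecules.")
  }
  ft <- frame_time %||% if (length(dts) == 1) dts else NA_real_
  if (!is.na(ft) && length(dts) == 1 && abs(dts - ft) > 1e-9) {
    abort(sprintf("Frame time %g s does not match expected %g s.", dts, ft))
  }
  structure(df, class = c("cohort", class(df)), frame_time = ft)
}

#' Read and write isotherm tables
#'
#' Isotherm CSV schema: `concentration_nM, signal, sem, n_replicates`.
#'
#' @param iso An isotherm tibble.
#' @param path CSV path.
#' @return `read_isotherm()` returns an `isotherm` tibble.
#' @export
write_isotherm <- function(iso, path) {
  readr::write_csv(as_tibble(iso), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_isotherm
#' @export
read_isotherm <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("concentration_nM", "signal")
  if (!all(need %in% names(df))) {
    abort("Isotherm file needs columns concentration_nM and signal.")
  }
  df <- df |> arrange(.data$concentration_nM)
  if (any(df$concentration_nM < 0)) abort("Concentrations must be >= 0.")
  structure(df, class = c("isotherm", class(df)))
}

#' Assemble and validate a pipeline configuration
#'
#' Bundles the kinetic scheme, photophysics, cohort layout, classifier
#' thresholds and fit options into one validated configuration that
#' [run_pipeline()] consumes. Configurations serialize to YAML via
#' [write_config()] / [read_config()]; `ssb_preset()` returns complete
#' ready-to-run configurations.
#'
#' @param scheme A [kinetic_scheme()].
#' @param phys A [photophysics()].
#' @param concentrations Concentration series (nM).
#' @param n_molecules Molecules per concentration.
#' @param duration Trace duration (s).
#' @param frame_time Camera integration time (s). The camera's readout
#'   clock is exposed separately as `time_resolution` for documentation
#'   of the instrument, but rendering uses `frame_time`.
#' @param seed Master seed for all stochastic stages.
#' @param thresholds A [classifier_thresholds()].
#' @param with_intercept Free intercept in the bimolecular fits.
#' @param fit_method Dwell fit method for dissociation edges (see
#'   [fit_exponential()]); the histogram fit is the default.
#' @param assoc_method Dwell fit method for the association edges out of
#'   the long-lived unbound state (`S1->S2`, `S1->S4`). Defaults to
#'   `"event_rate"`, the censoring-corrected occurrence/exposure
#'   estimator: unbound dwells at sub-nanomolar concentrations routinely
#'   outlive the trace and the donor dye, and only exposure-based
#'   estimation stays unbiased there. Edges out of the short-lived bound
#'   states (`S2->S3` and all dissociations) use `fit_method` instead,
#'   where the dwell-histogram fit with a resolution floor is the
#'   unbiased choice.
#' @param fit_min_dwell_frames Resolution floor for dwell fits, in
#'   frames (default 1): classified dwells at or below this length are
#'   excluded from the exponential fits because frame averaging distorts
#'   them; the exponential tail keeps the rate unbiased. Set 0 to keep
#'   every dwell.
#' @param time_resolution Instrument readout clock (s), metadata only.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(scheme, phys = photophysics(),
                            concentrations = c(0.05, 0.5, 2.5, 10),
                            n_molecules = 300, duration = 60,
                            frame_time = 0.05, seed = 1,
                            thresholds = classifier_thresholds(),
                            with_intercept = TRUE,
                            fit_method = "histogram_ls",
                            assoc_method = "event_rate",
                            fit_min_dwell_frames = 1,
                            time_resolution = 0.033) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(phys, "photophysics"),
            inherits(thresholds, "classifier_thresholds"))
  if (length(concentrations) < 1 || any(concentrations < 0)) {
    abort("`concentrations` must be non-negative.")
  }
  if (n_molecules < 0 || duration <= 0 || frame_time <= 0) {
    abort("Cohort sizes and times must be positive.")
  }
  structure(list(scheme = scheme, phys = phys,
                 concentrations = sort(unique(concentrations)),
                 n_molecules = n_molecules, duration = duration,
                 frame_time = frame_time, seed = as.integer(seed),
                 thresholds = thresholds,
                 with_intercept = with_intercept,
                 fit_method = fit_method,
                 assoc_method = assoc_method,
                 fit_min_dwell_frames = fit_min_dwell_frames,
                 time_resolution = time_resolution),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param name Preset name; `"fig8_12mer"` is the 12-mer multi-state
#'   titration layout (0.05/0.5/2.5/10 nM), `"fig4_20mer"` the 20-mer
#'   two-state layout (0.3/3/30 nM).
#' @export
ssb_preset <- function(name = c("fig8_12mer", "fig4_20mer"), seed = 1,
                       n_molecules = 300, duration = 60) {
  name <- match.arg(name)
  scheme <- scheme_preset(name)
  conc <- switch(name,
                 fig8_12mer = c(0.05, 0.5, 2.5, 10),
                 fig4_20mer = c(0.3, 3, 30))
  pipeline_config(scheme, photophysics(), concentrations = conc,
                  n_molecules = n_molecules, duration = duration,
                  seed = seed)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- list(
    scheme = unclass(config$scheme),
    photophysics = list(
      fret = as.list(setNames(config$phys$emission$fret,
                              config$phys$emission$state)),
      pife = as.list(setNames(config$phys$emission$pife,
                              config$phys$emission$state)),
      acceptor_dark = as.list(setNames(config$phys$emission$acceptor_dark,
                                       config$phys$emission$state)),
      p_near = config$phys$p_near,
      donor_bleach = config$phys$donor_bleach,
      acceptor_bleach = config$phys$acceptor_bleach,
      noise_sigma = config$phys$noise_sigma,
      background = as.list(config$phys$background)),
    cohort = list(concentrations = config$concentrations,
                  n_molecules = config$n_molecules,
                  duration = config$duration,
                  frame_time = config$frame_time,
                  time_resolution = config$time_resolution,
                  seed = config$seed),
    thresholds = unclass(config$thresholds),
    fits = list(with_intercept = config$with_intercept,
                method = config$fit_method,
                assoc_method = config$assoc_method,
                min_dwell_frames = config$fit_min_dwell_frames))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  for (sec in c("scheme", "cohort")) {
    if (is.null(x[[sec]])) abort(sprintf("Config misses section '%s'.", sec))
  }
  sch <- do.call(kinetic_scheme, x$scheme)
  ph <- x$photophysics %||% list()
  phys <- photophysics(
    fret = unlist(ph$fret %||% formals(photophysics)$fret |> eval()),
    pife = unlist(ph$pife %||% formals(photophysics)$pife |> eval()),
    p_near = ph$p_near %||% 0.5,
    donor_bleach = ph$donor_bleach %||% 0.018,
    acceptor_bleach = ph$acceptor_bleach %||% 0.07,
    noise_sigma = ph$noise_sigma %||% 0.1,
    background = unlist(ph$background %||% c(0, 0)))
  thr <- do.call(classifier_thresholds, x$thresholds %||% list())
  pipeline_config(sch, phys,
                  concentrations = unlist(x$cohort$concentrations),
                  n_molecules = x$cohort$n_molecules %||% 300,
                  duration = x$cohort$duration %||% 60,
                  frame_time = x$cohort$frame_time %||% 0.05,
                  seed = x$cohort$seed %||% 1,
                  thresholds = thr,
                  with_intercept = x$fits$with_intercept %||% TRUE,
                  fit_method = x$fits$method %||% "histogram_ls",
                  assoc_method = x$fits$assoc_method %||% "event_rate",
                  fit_min_dwell_frames = x$fits$min_dwell_frames %||% 1,
                  time_resolution = x$cohort$time_resolution %||% 0.033)
}

#' Run the full simulate-classify-fit pipeline
#'
#' End-to-end reproduction of the single-molecule kinetic analysis:
#' simulate (or ingest) a cohort at each concentration, classify frames
#' and segment states, collect dwell tables per scheme edge, fit
#' mono-exponential rates, fit pseudo-first-order rates against
#' concentration for the association edges, and derive dissociation
#' constants. Deterministic given the config's master seed.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-existing cohort tibble (e.g. from
#'   [read_traces()]); when supplied, simulation is skipped.
#' @param verbose Log stage boundaries with [message()].
#' @return An object of class `ssb_report`: list with `rates` (tibble of
#'   per-concentration per-transition estimates), `bimolecular` (named
#'   list of `bimolecular_fit`s for S1->S2, S2->S3, S1->S4), `kd` (tibble
#'   of K_D results for the first monomer, second monomer and direct
#'   coating pathway), `census`, `segments`, `provenance`.
#' @export
run_pipeline <- function(config, cohort = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) inform(sprintf(...))
  t_start <- Sys.time()

  if (is.null(cohort)) {
    say("[simulate] %d molecules x %d concentrations, %.0f s traces",
        config$n_molecules, length(config$concentrations),
        config$duration)
    cohort <- generate_cohort(config$scheme, config$phys,
                              config$concentrations, config$n_molecules,
                              config$duration, config$frame_time,
                              seed = config$seed)
  }
  say("[classify] %d frames", nrow(cohort))
  feats <- compute_features(cohort, baseline = 1,
                            background = config$phys$background)
  labs <- classify_frames(feats, config$thresholds)
  segs <- segment_states(labs, config$frame_time,
                         min_dwell = config$thresholds$min_dwell)

  say("[kinetics] dwell tables and rate fits")
  transitions <- c("S1->S2", "S2->S1", "S2->S3", "S3->S1", "S1->S4",
                   "S4->S1")
  grid <- tidyr::expand_grid(concentration_nM = config$concentrations,
                             transition = transitions)
  rates <- pmap(grid, function(concentration_nM, transition) {
    seg_c <- segs |> filter(.data$concentration_nM == !!concentration_nM)
    dw <- suppressWarnings(collect_dwells(seg_c, transition))
    floor_s <- config$fit_min_dwell_frames * config$frame_time
    meth <- if (transition %in% c("S1->S2", "S1->S4")) {
      config$assoc_method
    } else {
      config$fit_method
    }
    est <- tryCatch(
      fit_exponential(dw, method = meth, min_dwell = floor_s),
      error = function(e) {
        tryCatch(fit_exponential(dw, method = "mle",
                                 min_dwell = floor_s),
                 error = function(e2)
                   rate_estimate(NA_real_, NA_real_, nrow(dw), "none",
                                 transition, concentration_nM, NA_real_))
      })
    est$transition <- transition
    est$concentration_nM <- concentration_nM
    est
  }) |> list_rbind()

  bimolecular <- list()
  for (tr in c("S1->S2", "S2->S3", "S1->S4")) {
    sub_r <- rates |> filter(.data$transition == tr, is.finite(.data$rate))
    bimolecular[[tr]] <- tryCatch(
      rate_vs_concentration(sub_r, with_intercept = config$with_intercept),
      error = function(e) NULL)
  }

  mean_rate <- function(tr) {
    r <- rates |> filter(.data$transition == tr, is.finite(.data$rate))
    if (nrow(r) == 0) return(c(NA_real_, NA_real_))
    w <- if (all(is.finite(r$se)) && all(r$se > 0)) 1 / r$se^2 else
      rep(1, nrow(r))
    c(sum(r$rate * w) / sum(w), sqrt(1 / sum(w)))
  }
  kd <- list()
  add_kd <- function(label, koff_tr, kon_fit) {
    ko <- mean_rate(koff_tr)
    if (!is.null(kon_fit) && is.finite(ko[1]) && kon_fit$slope > 0 &&
        ko[1] > 0) {
      kd[[label]] <<- compute_kd(ko[1], kon_fit$slope, ko[2],
                                 kon_fit$slope_se, label = label)
    }
  }
  add_kd("M1", "S2->S1", bimolecular[["S1->S2"]])
  add_kd("M2", "S3->S1", bimolecular[["S2->S3"]])
  add_kd("S4", "S4->S1", bimolecular[["S1->S4"]])
  kd <- if (length(kd)) list_rbind(kd) else
    tibble(label = character(), kd_nM = numeric(), se_nM = numeric())

  census <- transition_census(segs)
  say("[done] %.1f s elapsed",
      as.numeric(difftime(Sys.time(), t_start, units = "secs")))

  structure(list(rates = rates, bimolecular = bimolecular, kd = kd,
                 census = census, segments = segs,
                 provenance = list(seed = config$seed,
                                   config_hash = rlang::hash(
                                     write_config_string(config)),
                                   n_molecules = config$n_molecules,
                                   concentrations = config$concentrations,
                                   package_version = as.character(
                                     utils::packageVersion("ssbkin")),
                                   timestamp = format(Sys.time(), tz = "UTC"))),
            class = "ssb_report")
}

write_config_string <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  paste(readLines(tmp), collapse = "\n")
}

#' @export
print.ssb_report <- function(x, ...) {
  cat("<ssb_report>\n")
  cat(report_summary_text(x), sep = "\n")
  invisible(x)
}

report_summary_text <- function(report) {
  lines <- c("Kinetic rate ledger (per scheme edge):")
  for (tr in c("S1->S2", "S2->S1", "S2->S3", "S3->S1", "S1->S4",
               "S4->S1")) {
    r <- report$rates |> filter(.data$transition == tr,
                                is.finite(.data$rate))
    bi <- report$bimolecular[[tr]]
    if (!is.null(bi)) {
      lines <- c(lines, sprintf(
        "  %s: bimolecular slope %.4g +/- %.2g nM^-1 s^-1 (intercept %.3g s^-1)",
        tr, bi$slope, bi$slope_se, bi$intercept))
    } else if (nrow(r) > 0) {
      lines <- c(lines, sprintf("  %s: mean rate %.4g s^-1 over %d concentration(s)",
                                tr, mean(r$rate), nrow(r)))
    } else {
      lines <- c(lines, sprintf("  %s: no events observed", tr))
    }
  }
  if (nrow(report$kd) > 0) {
    lines <- c(lines, "Dissociation constants:",
               sprintf("  K_D^%s = %.3g +/- %.2g nM", report$kd$label,
                       report$kd$kd_nM, report$kd$se_nM))
  }
  lines <- c(lines, sprintf(
    "Pathway census: S1->S4 entry fraction %.3g; S3->S2 exit fraction %.3g",
    report$census$s4_entry_fraction, report$census$s3_to_s2_fraction))
  lines <- c(lines, sprintf("Provenance: seed %d, config %s",
                            report$provenance$seed,
                            report$provenance$config_hash))
  lines
}

#' Write a pipeline report to disk
#'
#' Serializes an `ssb_report` as JSON (stable field order, full
#' precision), as a CSV bundle (rates, dissociation constants, segment
#' and transition tables) and/or as a human-readable text summary
#' listing all six scheme edges.
#'
#' @param report An `ssb_report` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @param formats Subset of `c("json", "csv", "text")`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir,
                         formats = c("json", "csv", "text")) {
  stopifnot(inherits(report, "ssb_report"))
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  if ("json" %in% formats) {
    p <- file.path(dir, "report.json")
    bi <- lapply(report$bimolecular, function(b) {
      if (is.null(b)) return(NULL)
      list(slope = b$slope, slope_se = b$slope_se,
           intercept = b$intercept, intercept_se = b$intercept_se,
           r_squared = b$r_squared, n = b$n)
    })
    jsonlite::write_json(
      list(rates = report$rates, bimolecular = bi, kd = report$kd,
           census = list(transitions = report$census$transitions,
                         s4_entry_fraction = report$census$s4_entry_fraction,
                         s3_to_s2_fraction = report$census$s3_to_s2_fraction),
           provenance = report$provenance),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
    paths <- c(paths, p)
  }
  if ("csv" %in% formats) {
    p1 <- file.path(dir, "rates.csv")
    readr::write_csv(report$rates, p1, progress = FALSE)
    p2 <- file.path(dir, "kd.csv")
    readr::write_csv(report$kd, p2, progress = FALSE)
    p3 <- file.path(dir, "segments.csv")
    readr::write_csv(as_tibble(report$segments), p3, progress = FALSE)
    p4 <- file.path(dir, "transitions.csv")
    readr::write_csv(report$census$transitions, p4, progress = FALSE)
    paths <- c(paths, p1, p2, p3, p4)
  }
  if ("text" %in% formats) {
    p <- file.path(dir, "summary.txt")
    writeLines(report_summary_text(report), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_report
#' @param path Path of a `report.json` written by [write_report()].
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
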