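#' Classifier thresholds
#'
#' Operational cutoffs that map per-frame FRET/PIFE/quench features to
#' state labels. The underlying plateaus are E_app ~ 0.1 (unbound,
#' crosstalk), ~0.85 (bound, high FRET), total intensity 1x vs 2x
#' (PIFE); cutoffs default to the midpoints between plateaus.
#'
#' @param e_high Apparent-FRET cutoff above which a frame is FRET-active
#'   (default 0.5, midpoint of the 0.1 and 0.85 plateaus).
#' @param pife_cut Total-intensity cutoff, in units of the unbound donor
#'   baseline, above which PIFE is called (default 1.5, midpoint of 1x
#'   and 2x).
#' @param quench_cut E_app cutoff below which the acceptor is considered
#'   dark (default 0.3).
#' @param donor_tol Half-width of the "donor near baseline" window used
#'   for the unbound call (default 0.25).
#' @param bleach_drop Total-intensity level (x baseline) below which the
#'   molecule is considered photobleached when the drop is permanent
#'   (default 0.3).
#' @param median_window Odd median-filter window in frames applied to the
#'   features before thresholding; 1 disables (default, to avoid biasing
#'   fast dwells).
#' @param min_dwell Minimum segment length in frames; shorter runs are
#'   merged into the longer neighbour (default 1 = keep everything).
#' @param flash_cut Sensitized-acceptor cutoff (x baseline) for
#'   recovering sub-frame FRET transits: when a frame jumps straight from
#'   `UNBOUND` to `PIFE_QUENCH`, a boundary frame whose acceptor signal
#'   (`e_app * total`) exceeds this level betrays a camera-limited pass
#'   through the high-FRET state (a direct coating event has a dark
#'   acceptor and cannot produce the flash) and is relabelled `FRET`.
#'   `Inf` disables (default 0.4, i.e. well above the unbound crosstalk
#'   level plus noise).
#' @param transit_cut Stricter acceptor cutoff (x baseline) applied to
#'   frames *inside* `UNBOUND` runs: an isolated acceptor flash there
#'   marks a binding-and-release cycle faster than one frame, which
#'   would otherwise silently merge two unbound dwells. Higher than
#'   `flash_cut` because every unbound frame is a trial (default 0.45,
#'   ~3.4 noise sd above the crosstalk level; false positives add a
#'   concentration-independent pseudo-rate absorbed by the intercept of
#'   the bimolecular fit). `Inf` disables.
#' @return A list of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(e_high = 0.5, pife_cut = 1.5,
                                  quench_cut = 0.3, donor_tol = 0.25,
                                  bleach_drop = 0.3, median_window = 1,
                                  min_dwell = 1, flash_cut = 0.4,
                                  transit_cut = 0.45) {
  if (e_high <= 0 || e_high >= 1) abort("`e_high` must lie in (0, 1).")
  if (pife_cut <= 1) abort("`pife_cut` must be > 1.")
  if (quench_cut < 0 || quench_cut >= e_high) {
    abort("`quench_cut` must lie in [0, e_high).")
  }
  if (median_window %% 2 != 1) abort("`median_window` must be odd.")
  structure(list(e_high = e_high, pife_cut = pife_cut,
                 quench_cut = quench_cut, donor_tol = donor_tol,
                 bleach_drop = bleach_drop, median_window = median_window,
                 min_dwell = min_dwell, flash_cut = flash_cut,
                 transit_cut = transit_cut),
            class = "classifier_thresholds")
}

#' Per-frame FRET/PIFE features of a trajectory cohort
#'
#' Computes, after background subtraction, the apparent FRET efficiency
#' `E_app = I_A / (I_A + I_D)` (clamped to `[0, 1]`), the donor intensity
#' and the total intensity, both normalized to the unbound donor baseline.
#' Frames with non-positive total intensity get `E_app = NA` and are
#' flagged `undefined`.
#'
#' @param cohort A cohort tibble (columns `molecule_id`, `donor`,
#'   `acceptor`, plus `frame`/`time_s`), e.g. from [generate_cohort()] or
#'   [read_traces()]. A single `trajectory` is accepted too.
#' @param baseline Unbound donor intensity in camera units. `NULL`
#'   estimates it per molecule as the density mode of the donor signal
#'   over unbound-candidate frames.
#' @param background Length-2 numeric background per channel.
#' @return The input tibble with added columns `e_app`, `donor_norm`,
#'   `total_norm`, `undefined`.
#' @export
compute_features <- function(cohort, baseline = NULL,
                             background = c(0, 0)) {
  cohort <- as_cohort(cohort)
  if (!is.null(baseline) && baseline <= 0) {
    abort("`baseline` must be > 0.")
  }
  d <- cohort$donor - background[1]
  a <- cohort$acceptor - background[2]
  tot <- d + a
  e <- ifelse(tot > 0, pmin(pmax(a / tot, 0), 1), NA_real_)
  out <- cohort
  out$e_app <- e
  out$undefined <- !is.finite(e)
  bl <- if (is.null(baseline)) {
    stats_bl <- tibble(molecule_id = cohort$molecule_id, donor = d, e = e) |>
      group_by(.data$molecule_id) |>
      summarise(baseline = estimate_baseline(.data$donor, .data$e),
                .groups = "drop")
    stats_bl$baseline[match(cohort$molecule_id, stats_bl$molecule_id)]
  } else {
    baseline
  }
  out$donor_norm <- d / bl
  out$total_norm <- tot / bl
  out
}

## density mode of the donor signal over unbound-candidate frames
## (low E_app, donor above the bleach floor); falls back to the global
## donor mode when a molecule never visits the unbound state
estimate_baseline <- function(donor, e_app) {
  cand <- donor[!is.na(e_app) & e_app <= 0.3 & donor > 0.3 * median(donor[donor > 0], na.rm = TRUE)]
  if (length(cand) < 10) cand <- donor[donor > 0]
  if (length(cand) < 2) return(max(donor, 1e-6))
  dd <- density(cand, n = 512)
  dd$x[which.max(dd$y)]
}

frame_labels <- c("UNBOUND", "FRET", "FRET_PIFE", "PIFE_QUENCH", "BLEACHED")

#' Classify frames into photophysical state labels
#'
#' Threshold classification of per-frame features into
#' `UNBOUND`, `FRET` (high FRET, no PIFE), `FRET_PIFE` (high FRET with
#' 2-fold total enhancement), `PIFE_QUENCH` (enhanced donor, dark
#' acceptor) and `BLEACHED`:
#'
#' * `FRET`: `e_app >= e_high` and `total < pife_cut`
#' * `FRET_PIFE`: `e_app >= e_high` and `total >= pife_cut`
#' * `PIFE_QUENCH`: `e_app <= quench_cut` and `donor >= pife_cut`
#' * `UNBOUND`: `e_app <= quench_cut`, `|donor - 1| <= donor_tol` and
#'   `total < pife_cut`
#' * `BLEACHED`: from [detect_bleaching()] onwards
#'
#' Ambiguous frames (dead zones between cutoffs, undefined E_app) inherit
#' the previous frame's label, favouring dwell continuity over spurious
#' transitions; a leading ambiguous run is called `UNBOUND`. An optional
#' running-median filter is applied to the features first.
#'
#' @param features Output of [compute_features()].
#' @param thr A [classifier_thresholds()].
#' @return `features` with an added `label` column.
#' @export
classify_frames <- function(features, thr = classifier_thresholds()) {
  stopifnot(inherits(thr, "classifier_thresholds"))
  needed <- c("molecule_id", "e_app", "donor_norm", "total_norm")
  if (!all(needed %in% names(features))) {
    abort("`features` must come from compute_features().")
  }
  features |>
    group_by(.data$molecule_id) |>
    group_modify(function(d, key) {
      d$label <- classify_one(d, thr)
      d
    }) |>
    ungroup()
}

classify_one <- function(d, thr) {
  e <- d$e_app; don <- d$donor_norm; tot <- d$total_norm
  if (thr$median_window > 1 && nrow(d) >= thr$median_window) {
    ok <- !is.na(e)
    if (all(ok)) e <- runmed(e, thr$median_window, endrule = "median")
    don <- runmed(don, thr$median_window, endrule = "median")
    tot <- runmed(tot, thr$median_window, endrule = "median")
  }
  lab <- rep(NA_character_, nrow(d))
  high <- !is.na(e) & e >= thr$e_high
  low <- !is.na(e) & e <= thr$quench_cut
  lab[high & tot < thr$pife_cut] <- "FRET"
  lab[high & tot >= thr$pife_cut] <- "FRET_PIFE"
  lab[low & don >= thr$pife_cut] <- "PIFE_QUENCH"
  lab[low & abs(don - 1) <= thr$donor_tol & tot < thr$pife_cut] <- "UNBOUND"
  ## bleach overrides everything from the detected frame on
  bf <- detect_bleaching_one(tot, thr)
  if (!is.na(bf)) lab[seq(bf, length(lab))] <- "BLEACHED"
  ## ambiguous frames inherit the previous label
  lab <- tidyr::fill(tibble(lab = lab), "lab")$lab
  lab[is.na(lab)] <- "UNBOUND"
  ## sub-frame FRET transit recovery at UNBOUND -> PIFE_QUENCH jumps
  fc <- thr$flash_cut %||% Inf
  acc <- d$e_app * d$total_norm
  acc[is.na(acc)] <- -Inf
  if (is.finite(fc)) {
    jump <- which(lab[-1] == "PIFE_QUENCH" &
                    lab[-length(lab)] == "UNBOUND") + 1L
    for (i in jump) {
      cand <- c(i - 1L, i)
      if (max(acc[cand]) >= fc) lab[cand[which.max(acc[cand])]] <- "FRET"
    }
  }
  ## isolated acceptor flashes inside unbound runs: binding-and-release
  ## cycles faster than one frame
  tc <- thr$transit_cut %||% Inf
  if (is.finite(tc)) {
    n <- length(lab)
    inside <- which(lab == "UNBOUND" & acc >= tc)
    inside <- inside[inside > 1 & inside < n]
    ok <- lab[inside - 1L] == "UNBOUND" & lab[inside + 1L] == "UNBOUND"
    lab[inside[ok]] <- "FRET"
  }
  lab
}

#' Detect permanent photobleaching of a trajectory
#'
#' Finds the first frame after which the (running-median smoothed) total
#' intensity stays below `bleach_drop` times the baseline until the end
#' of the trace. Transient dips that recover do not trigger detection.
#'
#' @param traj A single trajectory's features (needs `total_norm`), or a
#'   cohort feature tibble (then one index per molecule is returned).
#' @param thr A [classifier_thresholds()].
#' @return Integer frame index of the first bleached frame, or `NA` if
#'   the trace never bleaches. For cohorts, a tibble `molecule_id`,
#'   `bleach_frame`.
#' @export
detect_bleaching <- function(traj, thr = classifier_thresholds()) {
  if (!"total_norm" %in% names(traj)) {
    abort("`traj` must carry `total_norm`; run compute_features() first.")
  }
  ids <- unique(traj$molecule_id)
  if (length(ids) > 1) {
    return(traj |>
             group_by(.data$molecule_id) |>
             summarise(bleach_frame = detect_bleaching_one(.data$total_norm,
                                                           thr),
                       .groups = "drop"))
  }
  detect_bleaching_one(traj$total_norm, thr)
}

detect_bleaching_one <- function(total, thr) {
  n <- length(total)
  if (n == 0) return(NA_integer_)
  sm <- if (n >= 5) runmed(total, 5, endrule = "median") else total
  alive <- which(sm >= thr$bleach_drop)
  if (length(alive) == 0) return(1L)
  last_alive <- max(alive)
  if (last_alive >= n) return(NA_integer_)
  as.integer(last_alive + 1L)
}

#' Run-length encode frame labels into state segments
#'
#' Converts per-frame labels into an ordered segment list over the five
#' molecular states, using the transition history to resolve the
#' degenerate PIFE+quench signature: a `PIFE_QUENCH` run is `S3` when the
#' previous bound state was `S2a`/`S2b` (sequential second-monomer
#' binding) and `S4` when entered directly from `S1` (single-step
#' coating). `FRET` maps to `S2a`, `FRET_PIFE` to `S2b`, `UNBOUND` to
#' `S1`. Runs shorter than `min_dwell` frames are merged into the longer
#' neighbour. Trailing `BLEACHED` frames are dropped and the last
#' remaining segment is right-censored; the first segment is flagged
#' left-censored.
#'
#' @param labels Output of [classify_frames()] (columns `molecule_id`,
#'   `label`), or a character vector of labels for a single molecule.
#' @param frame_time Frame integration time in seconds.
#' @param min_dwell Minimum dwell in frames (overrides the value used at
#'   classification time if given).
#' @return A tibble of class `segment_list`: `molecule_id`, `state`,
#'   `start_frame`, `end_frame`, `n_frames`, `dwell_s`, `left_censored`,
#'   `right_censored` (+ `concentration_nM` when present in the input).
#' @export
segment_states <- function(labels, frame_time = 0.05, min_dwell = 1) {
  if (is.character(labels)) {
    labels <- tibble(molecule_id = "mol_1", label = labels)
  }
  if (nrow(labels) == 0) abort("`labels` is empty.")
  out <- labels |>
    group_by(across(any_of(c("molecule_id", "concentration_nM")))) |>
    group_modify(function(d, key) segment_one(d$label, frame_time,
                                              min_dwell)) |>
    ungroup()
  class(out) <- c("segment_list", class(out))
  attr(out, "frame_time") <- frame_time
  out
}

segment_one <- function(lab, frame_time, min_dwell) {
  ## drop trailing bleached block; a fully bleached trace yields no segments
  n <- length(lab)
  keep <- n
  while (keep >= 1 && lab[keep] == "BLEACHED") keep <- keep - 1
  bleach_censored <- keep < n
  if (keep == 0) {
    warn("Trajectory is entirely bleached; returning no segments.")
    return(tibble(state = character(), start_frame = integer(),
                  end_frame = integer(), n_frames = integer(),
                  dwell_s = numeric(), left_censored = logical(),
                  right_censored = logical()))
  }
  lab <- lab[seq_len(keep)]
  ## interior BLEACHED frames (shouldn't occur) inherit the previous label
  if (any(lab == "BLEACHED")) {
    lab[lab == "BLEACHED"] <- NA
    lab <- tidyr::fill(tibble(lab = lab), "lab")$lab
    lab[is.na(lab)] <- "UNBOUND"
  }
  r <- rle(lab)
  ## merge runs shorter than min_dwell into the longer neighbour
  while (length(r$lengths) > 1 && any(r$lengths < min_dwell)) {
    i <- which.min(r$lengths)
    if (r$lengths[i] >= min_dwell) break
    nb <- c(if (i > 1) i - 1L, if (i < length(r$lengths)) i + 1L)
    j <- nb[which.max(r$lengths[nb])]
    r$values[i] <- r$values[j]
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  state <- label_to_state(r$values)
  tibble(state = state,
         start_frame = as.integer(starts),
         end_frame = as.integer(ends),
         n_frames = as.integer(r$lengths),
         dwell_s = r$lengths * frame_time,
         left_censored = seq_along(state) == 1L,
         right_censored = seq_along(state) == length(state))
}

## history rule: PIFE_QUENCH after a FRET state is S3, after UNBOUND (or at
## trace start) it is S4
label_to_state <- function(vals) {
  state <- character(length(vals))
  last_non_quench <- "UNBOUND"
  for (i in seq_along(vals)) {
    v <- vals[i]
    state[i] <- switch(v,
      UNBOUND = "S1",
      FRET = "S2a",
      FRET_PIFE = "S2b",
      PIFE_QUENCH = if (last_non_quench %in% c("FRET", "FRET_PIFE"))
        "S3" else "S4",
      v)
    if (v != "PIFE_QUENCH") last_non_quench <- v
  }
  state
}

#' Pooled population histogram of trajectory openings
#'
#' Pools the first `n_frames` frames of every molecule (fewer if a trace
#' is shorter) and bins the chosen per-frame variable with a fixed bin
#' width, normalizing counts to unit area -- the population histogram
#' used to quantify bound/unbound fractions at each concentration.
#'
#' @param features Output of [compute_features()].
#' @param n_frames Leading frames pooled per molecule (default 15).
#' @param variable `"e_app"` or `"donor_norm"`.
#' @param binwidth Fixed bin width (defaults: 0.05 for `e_app`, 0.1 for
#'   `donor_norm`).
#' @return A tibble of class `population_histogram` with `mid`, `count`,
#'   `density` (integrates to 1).
#' @export
population_histogram <- function(features, n_frames = 15,
                                 variable = c("e_app", "donor_norm"),
                                 binwidth = NULL) {
  variable <- match.arg(variable)
  if (nrow(features) == 0) abort("Empty cohort; nothing to pool.")
  binwidth <- binwidth %||% if (variable == "e_app") 0.05 else 0.1
  x <- features |>
    group_by(.data$molecule_id) |>
    slice_head(n = n_frames) |>
    ungroup() |>
    pull(variable)
  x <- x[is.finite(x)]
  if (length(x) == 0) abort("No finite values to histogram.")
  lo <- floor(min(x) / binwidth) * binwidth
  brks <- seq(lo, max(x) + binwidth, by = binwidth)
  h <- hist(x, breaks = brks, plot = FALSE)
  out <- tibble(mid = h$mids, count = h$counts,
                density = h$counts / (sum(h$counts) * binwidth))
  structure(out, class = c("population_histogram", class(out)),
            variable = variable, binwidth = binwidth, n = length(x))
}

#' @importFrom graphics hist
NULL

## Coerce a single trajectory to the cohort frame layout
as_cohort <- function(x) {
  if (inherits(x, "trajectory")) {
    tibble(molecule_id = attr(x, "molecule_id") %||% "mol_1",
           concentration_nM = attr(x, "concentration") %||% NA_real_,
           frame = x$frame, time_s = x$time_s,
           donor = x$donor, acceptor = x$acceptor)
  } else {
    if (!all(c("molecule_id", "donor", "acceptor") %in% names(x))) {
      abort("Expected a cohort tibble with molecule_id/donor/acceptor columns.")
    }
    x
  }
}
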