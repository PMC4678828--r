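#' Collect dwell times for one transition type
#'
#' Extracts from a classified segment list the dwell times of state `X`
#' that end in the transition `X -> Y`. The photophysical sub-states
#' `S2a`/`S2b` are pooled as the kinetic state `S2` (adjacent runs are
#' merged) before dwells are measured. Right-censored dwells (trace end
#' or photobleaching) are excluded from the default table; left-censored
#' (trace-initial) dwells are kept because exponential dwells are
#' memoryless, so a truncated entry does not bias them.
#'
#' The table also records how many uncensored exits the state made to
#' *other* destinations: dwell-time distributions report the total exit
#' rate of a state, and [fit_exponential()] uses the branching fraction
#' `n_events / n_exits` to convert it into the transition-specific rate.
#'
#' @param segments A `segment_list` from [segment_states()] (or
#'   [true_segments()]).
#' @param transition One of `"S1->S2"`, `"S2->S1"`, `"S2->S3"`,
#'   `"S3->S1"`, `"S3->S2"`, `"S1->S4"`, `"S4->S1"`.
#' @param include_censored Keep right-censored dwells (flagged) instead
#'   of dropping them.
#' @return A tibble of class `dwell_table` with columns `molecule_id`,
#'   `concentration_nM` (if present), `dwell_s`, `right_censored`;
#'   attributes `transition`, `n_events`, `n_exits`, `frame_time`.
#' @export
collect_dwells <- function(segments, transition,
                           include_censored = FALSE) {
  tr <- parse_transition(transition)
  seg <- pool_segments(segments)
  seg <- seg |>
    group_by(across(any_of(c("molecule_id", "concentration_nM")))) |>
    mutate(next_state = dplyr::lead(.data$state)) |>
    ungroup()
  in_state <- seg |> filter(.data$state == tr$from)
  exits <- in_state |> filter(!.data$right_censored,
                              !is.na(.data$next_state))
  sel <- exits |> filter(.data$next_state == tr$to)
  if (include_censored) {
    cens <- in_state |> filter(.data$right_censored)
    sel <- bind_rows(sel, cens)
  }
  if (nrow(sel) == 0) {
    warn(sprintf("No qualifying dwells for transition %s.", transition))
  }
  out <- sel |>
    select(any_of(c("molecule_id", "concentration_nM")),
           dwell_s = "dwell_s", right_censored = "right_censored")
  structure(out, class = c("dwell_table", class(out)),
            transition = transition,
            n_events = sum(!sel$right_censored),
            n_exits = nrow(exits),
            ## full exposure record for the occurrence/exposure estimator:
            ## every dwell of the source state, censored or not, whatever
            ## the destination
            state_dwells = in_state$dwell_s,
            state_censored = in_state$right_censored,
            frame_time = attr(segments, "frame_time"))
}

parse_transition <- function(transition) {
  valid <- c("S1->S2", "S2->S1", "S2->S3", "S3->S1", "S3->S2",
             "S1->S4", "S4->S1")
  if (!transition %in% valid) {
    abort(sprintf("Unknown transition '%s'; valid: %s.", transition,
                  paste(valid, collapse = ", ")))
  }
  parts <- strsplit(transition, "->", fixed = TRUE)[[1]]
  list(from = parts[1], to = parts[2])
}

## pool S2a/S2b into S2 and merge the resulting adjacent runs
pool_segments <- function(segments) {
  segments |>
    mutate(state = pool_state(.data$state)) |>
    group_by(across(any_of(c("molecule_id", "concentration_nM")))) |>
    group_modify(function(d, key) {
      if (nrow(d) == 0) return(d)
      d$grp <- cumsum(c(TRUE, d$state[-1] != d$state[-nrow(d)]))
      d |>
        group_by(.data$grp) |>
        summarise(state = first(.data$state),
                  start_frame = if ("start_frame" %in% names(d))
                    min(.data$start_frame) else NA_integer_,
                  end_frame = if ("end_frame" %in% names(d))
                    max(.data$end_frame) else NA_integer_,
                  dwell_s = sum(.data$dwell_s),
                  left_censored = any(.data$left_censored),
                  right_censored = any(.data$right_censored),
                  .groups = "drop") |>
        select(-"grp")
    }) |>
    ungroup()
}

#' Fit a mono-exponential rate to a dwell-time table
#'
#' Two estimators of the dwell rate:
#'
#' * `"histogram_ls"` (default): dwell times are binned into
#'   `bins` equal-width bins spanning `[0, 5 / k_init]` (with `k_init`
#'   from the sample mean, and the bin width snapped to a whole number of
#'   frames when dwells are frame-quantized) and the counts are fitted to
#'   `A * exp(-k * t)` by least squares. Because truncation preserves the
#'   exponential shape, this estimator is robust to finite trace length.
#' * `"mle"`: `k = 1 / mean(dwells)` with `SE = k / sqrt(n)`
#'   (cross-check; biased under right truncation).
#' * `"event_rate"`: the censoring-corrected occurrence/exposure
#'   estimator `k(X->Y) = N(X->Y events) / T(X)`, where the exposure
#'   `T(X)` sums *every* dwell of the source state -- censored dwells and
#'   dwells ending in other destinations included. For exponential
#'   dwells this is the maximum-likelihood transition rate under right
#'   censoring, so photobleaching and finite trace length do not bias
#'   it; it is the estimator of choice for slow association rates whose
#'   dwells routinely outlive the observation window. Returns the
#'   transition-specific rate directly (no branching step),
#'   `SE = k / sqrt(N events)`.
#'
#' When the dwell table carries competing-exit counts (see
#' [collect_dwells()]), the fitted rate is multiplied by the branching
#' fraction `n_events / n_exits` so that the returned value is the
#' transition-specific rate `k(X->Y)` rather than the total exit rate of
#' `X`; set `branching = FALSE` for the raw dwell-distribution rate.
#'
#' @param dwells A `dwell_table`, or a numeric vector of dwell times (s).
#' @param method `"histogram_ls"` or `"mle"`.
#' @param bins Number of histogram bins (default 20). For frame-quantized
#'   dwells the bin width is snapped to a whole number of frames (at
#'   least one) to avoid lattice aliasing.
#' @param branching Apply the branching-fraction correction when
#'   available (default `TRUE`).
#' @param min_dwell Resolution floor in seconds: dwells of at most this
#'   length are excluded and the histogram starts at the floor (the
#'   exponential tail slope is unchanged by left truncation, so the rate
#'   stays unbiased while frame-averaging artifacts in the shortest
#'   dwells are kept out of the fit). For `"mle"` the memoryless
#'   correction `k = 1 / (mean(x[x > floor]) - floor)` is used. `NULL`
#'   (default) disables the floor.
#' @return A tibble of class `rate_estimate` with one row: `rate` (s^-1),
#'   `se`, `n`, `method`, `transition`, `concentration_nM`,
#'   `branching_fraction`.
#' @examples
#' set.seed(1)
#' fit_exponential(rexp(2000, rate = 2), method = "mle")
#' @export
fit_exponential <- function(dwells,
                            method = c("histogram_ls", "mle",
                                       "event_rate"),
                            bins = 20, branching = TRUE,
                            min_dwell = NULL) {
  method <- match.arg(method)
  if (method == "event_rate") {
    return(fit_event_rate(dwells, min_dwell))
  }
  if (is.numeric(dwells)) {
    x <- dwells
    transition <- NA_character_
    frac <- 1
    conc <- NA_real_
    frame_time <- NA_real_
  } else {
    x <- dwells$dwell_s[!dwells$right_censored]
    transition <- attr(dwells, "transition") %||% NA_character_
    frac <- if (branching && !is.null(attr(dwells, "n_exits")) &&
                attr(dwells, "n_exits") > 0) {
      attr(dwells, "n_events") / attr(dwells, "n_exits")
    } else {
      1
    }
    conc <- if ("concentration_nM" %in% names(dwells) &&
                length(unique(dwells$concentration_nM)) == 1) {
      dwells$concentration_nM[1]
    } else {
      NA_real_
    }
    frame_time <- attr(dwells, "frame_time") %||% NA_real_
  }
  x <- x[is.finite(x) & x > 0]
  floor_s <- min_dwell %||% 0
  if (floor_s > 0) x <- x[x > floor_s + 1e-9]
  n <- length(x)
  if (n < 2 || length(unique(x)) < 2) {
    if (method == "mle" && n >= 1) {
      k <- 1 / (mean(x) - floor_s)
      out <- rate_estimate(frac * k, frac * k / sqrt(n), n, method,
                           transition, conc, frac)
      return(out)
    }
    abort("Need at least 2 distinct dwell values for a rate fit.")
  }
  if (method == "mle") {
    k <- 1 / (mean(x) - floor_s)
    se <- k / sqrt(n)
  } else {
    if (n < 10) {
      abort("Histogram fitting needs >= 10 uncensored dwells; use method = 'mle'.")
    }
    k_init <- 1 / (mean(x) - floor_s)
    bw <- 5 / k_init / bins
    ## snap bin width to the frame lattice to avoid aliasing
    if (is.finite(frame_time) && frame_time > 0) {
      q <- frame_time
      if (all(abs(x / q - round(x / q)) < 1e-6)) {
        bw <- q * max(1, floor(bw / q))
      }
    }
    ## bins stop at the longest observed dwell: bins beyond the
    ## observation window would be structural zeros (trace length and
    ## photobleaching bound what can be seen), not evidence of decay
    brks <- seq(floor_s, max(x) + bw, by = bw)
    h <- hist(x, breaks = brks, plot = FALSE)
    df <- tibble(t = h$mids, cnt = h$counts)
    fit <- tryCatch(
      minpack.lm::nlsLM(cnt ~ A * exp(-k * t), data = df,
                        start = list(A = max(df$cnt), k = k_init),
                        lower = c(A = 0, k = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      warn("Histogram fit failed to converge; falling back to MLE.")
      k <- 1 / (mean(x) - floor_s)
      se <- k / sqrt(n)
    } else {
      co <- summary(fit)$coefficients
      k <- co["k", "Estimate"]
      se <- co["k", "Std. Error"]
    }
  }
  ## delta-method SE including binomial error of the branching fraction
  se_total <- if (frac < 1) {
    n_ex <- attr(dwells, "n_exits")
    se_frac <- sqrt(frac * (1 - frac) / n_ex)
    sqrt((frac * se)^2 + (k * se_frac)^2)
  } else {
    se
  }
  rate_estimate(frac * k, se_total, n, method, transition, conc, frac)
}

fit_event_rate <- function(dwells, min_dwell = NULL) {
  floor_s <- min_dwell %||% 0
  if (is.numeric(dwells)) {
    expo_d <- dwells
    ev <- dwells
    transition <- NA_character_; conc <- NA_real_
  } else {
    expo_d <- attr(dwells, "state_dwells") %||% dwells$dwell_s
    ev <- dwells$dwell_s[!dwells$right_censored]
    transition <- attr(dwells, "transition") %||% NA_character_
    conc <- if ("concentration_nM" %in% names(dwells) &&
                length(unique(dwells$concentration_nM)) == 1) {
      dwells$concentration_nM[1]
    } else {
      NA_real_
    }
  }
  n_ev <- sum(ev > floor_s + 1e-9)
  expo <- sum(pmax(expo_d - floor_s, 0))
  if (n_ev < 1 || expo <= 0) {
    abort("No events (or no exposure) for the event-rate estimator.")
  }
  k <- n_ev / expo
  rate_estimate(k, k / sqrt(n_ev), n_ev, "event_rate", transition, conc,
                NA_real_)
}

rate_estimate <- function(rate, se, n, method, transition, conc, frac) {
  out <- tibble(transition = transition, concentration_nM = conc,
                rate = rate, se = se, n = n, method = method,
                branching_fraction = frac)
  class(out) <- c("rate_estimate", class(out))
  out
}

#' Bimolecular rate constant from a concentration series
#'
#' Weighted linear fit of pseudo-first-order rates against protein
#' concentration; the slope is the second-order association rate constant
#' (nM^-1 s^-1). Weights are `1/SE^2` when standard errors are available.
#' A dissociation-rate series should yield a slope consistent with zero.
#'
#' @param estimates A tibble of rate estimates (rows from
#'   [fit_exponential()], needing `concentration_nM`, `rate` and
#'   optionally `se`).
#' @param with_intercept Fit a free intercept (default `TRUE`; observed
#'   pseudo-first-order rates carry finite-observation floors and, for
#'   uncorrected total-exit rates, the competing dissociation rate).
#' @return An object of class `bimolecular_fit`: list with `slope`,
#'   `slope_se`, `intercept`, `intercept_se`, `r_squared`, `n`, and the
#'   underlying `lm` fit.
#' @export
rate_vs_concentration <- function(estimates, with_intercept = TRUE) {
  need <- c("concentration_nM", "rate")
  if (!all(need %in% names(estimates))) {
    abort("`estimates` needs columns concentration_nM and rate.")
  }
  df <- estimates |> filter(is.finite(.data$rate),
                            is.finite(.data$concentration_nM))
  if (length(unique(df$concentration_nM)) < 2) {
    abort("Need rates at >= 2 distinct concentrations for a linear fit.")
  }
  w <- if ("se" %in% names(df) && all(is.finite(df$se)) && all(df$se > 0)) {
    1 / df$se^2
  } else {
    rep(1, nrow(df))
  }
  fml <- if (with_intercept) rate ~ concentration_nM else
    rate ~ concentration_nM + 0
  fit <- lm(fml, data = df, weights = w)
  co <- summary(fit)$coefficients
  slope <- co["concentration_nM", "Estimate"]
  slope_se <- co["concentration_nM", "Std. Error"]
  intercept <- if (with_intercept) co["(Intercept)", "Estimate"] else 0
  intercept_se <- if (with_intercept) co["(Intercept)", "Std. Error"] else 0
  structure(list(slope = slope, slope_se = slope_se,
                 intercept = intercept, intercept_se = intercept_se,
                 r_squared = summary(fit)$r.squared, n = nrow(df),
                 fit = fit, data = df),
            class = "bimolecular_fit")
}

#' @export
print.bimolecular_fit <- function(x, ...) {
  cat("<bimolecular_fit>\n")
  cat(sprintf("  slope     = %.4g +/- %.2g nM^-1 s^-1\n", x$slope,
              x$slope_se))
  cat(sprintf("  intercept = %.4g +/- %.2g s^-1\n", x$intercept,
              x$intercept_se))
  cat(sprintf("  R^2 = %.4f over %d concentrations\n", x$r_squared, x$n))
  invisible(x)
}

#' Dissociation constant from rate constants
#'
#' `K_D = koff / kon` with first-order error propagation:
#' `SE(K_D) = K_D * sqrt((SE_koff/koff)^2 + (SE_kon/kon)^2)`.
#'
#' @param koff Dissociation rate (s^-1).
#' @param kon Bimolecular association rate constant (nM^-1 s^-1, > 0).
#' @param koff_se,kon_se Standard errors (default 0).
#' @param label Which monomer/pathway the constant describes.
#' @return A tibble of class `kd_result`: `label`, `kd_nM`, `se_nM`.
#' @examples
#' compute_kd(1.72, 0.032)  # ~54 nM
#' @export
compute_kd <- function(koff, kon, koff_se = 0, kon_se = 0, label = "M1") {
  if (kon <= 0) abort("`kon` must be > 0; K_D is undefined otherwise.")
  if (koff <= 0) abort("`koff` must be > 0.")
  kd <- koff / kon
  se <- kd * sqrt((koff_se / koff)^2 + (kon_se / kon)^2)
  out <- tibble(label = label, kd_nM = kd, se_nM = se)
  class(out) <- c("kd_result", class(out))
  out
}

#' Pathway usage census of a classified cohort
#'
#' Counts uncensored transitions between pooled kinetic states and
#' reports the binding-pathway branching: the fraction of binding events
#' entering through the direct-coating pathway (`S1 -> S4` vs
#' `S1 -> S2`), and the fraction of `S3` exits returning to `S2` rather
#' than disassembling to `S1`.
#'
#' @param segments A `segment_list` (classified or truth).
#' @return A list with `transitions` (tibble `from`, `to`, `n`),
#'   `s4_entry_fraction` and `s3_to_s2_fraction` (NA when the
#'   denominator is empty).
#' @export
transition_census <- function(segments) {
  seg <- pool_segments(segments) |>
    group_by(across(any_of(c("molecule_id", "concentration_nM")))) |>
    mutate(next_state = dplyr::lead(.data$state)) |>
    ungroup() |>
    filter(!.data$right_censored, !is.na(.data$next_state))
  trans <- seg |> count(from = .data$state, to = .data$next_state,
                        name = "n")
  n_of <- function(a, b) {
    v <- trans$n[trans$from == a & trans$to == b]
    if (length(v) == 0) 0L else v
  }
  bind_total <- n_of("S1", "S2") + n_of("S1", "S4")
  s3_total <- n_of("S3", "S1") + n_of("S3", "S2")
  list(transitions = trans,
       s4_entry_fraction = if (bind_total > 0)
         n_of("S1", "S4") / bind_total else NA_real_,
       s3_to_s2_fraction = if (s3_total > 0)
         n_of("S3", "S2") / s3_total else NA_real_)
}

#' Photobleaching rate from dye-only trajectories
#'
#' Estimates the fluorophore bleaching rate from trajectories without
#' binding dynamics (e.g. dye-labelled DNA alone): detects the permanent
#' intensity drop per molecule and fits an exponential survival model
#' with right censoring for traces that outlive the recording
#' (`survival::survreg`, exponential distribution). The result can be
#' screened against a dissociation rate with [bleach_control()].
#'
#' @param cohort A cohort tibble of bleach-only traces.
#' @param thr A [classifier_thresholds()] (for the drop level).
#' @param baseline Donor baseline passed to [compute_features()].
#' @return A `rate_estimate` row with `transition = "bleach"`.
#' @export
bleaching_rate <- function(cohort, thr = classifier_thresholds(),
                           baseline = NULL) {
  feats <- compute_features(cohort, baseline = baseline)
  det <- feats |>
    group_by(.data$molecule_id) |>
    summarise(bleach_frame = detect_bleaching_one(.data$total_norm, thr),
              n_frames = dplyr::n(), .groups = "drop")
  ft <- attr(cohort, "frame_time") %||%
    (sort(unique(cohort$time_s))[2] - sort(unique(cohort$time_s))[1])
  det$time <- ifelse(is.na(det$bleach_frame),
                     det$n_frames * ft,
                     (det$bleach_frame - 1) * ft)
  det$event <- as.integer(!is.na(det$bleach_frame))
  if (sum(det$event) == 0) {
    abort("No bleaching events detected; cannot estimate a bleach rate.")
  }
  det$time <- pmax(det$time, ft / 2)  # a first-frame bleach still has exposure
  sr <- survival::survreg(survival::Surv(time, event) ~ 1, data = det,
                          dist = "exponential")
  rate <- exp(-unname(coef(sr)[1]))
  se <- rate * sqrt(vcov(sr)[1, 1])
  rate_estimate(rate, se, nrow(det), "survival_exponential", "bleach",
                NA_real_, 1)
}

#' Screen a dissociation rate against photobleaching
#'
#' Kinetic transitions are trustworthy when dissociation is much faster
#' than dye bleaching; this flags estimates where `koff` is within 10x of
#' the bleach rate.
#'
#' @param koff Dissociation rate (s^-1).
#' @param k_bleach Bleach rate (s^-1).
#' @param min_ratio Required `koff / k_bleach` ratio (default 10).
#' @return A tibble with `ratio` and logical `pass`.
#' @examples
#' bleach_control(4.52, 0.07)  # ratio ~65, passes
#' @export
bleach_control <- function(koff, k_bleach, min_ratio = 10) {
  if (k_bleach <= 0) return(tibble(ratio = Inf, pass = TRUE))
  r <- koff / k_bleach
  tibble(ratio = r, pass = r >= min_ratio)
}
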