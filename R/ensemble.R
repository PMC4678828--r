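#' Fit the Hill binding model to an isotherm
#'
#' Nonlinear least squares of
#' `S(c) = S_free + (S_bound - S_free) * c^n / (K_D^n + c^n)` with
#' multi-start over log-spaced `K_D` initializations (Levenberg-Marquardt
#' via `minpack.lm::nlsLM`). Points are weighted `1/sem^2` when standard
#' errors are present and positive, otherwise unweighted.
#'
#' @param iso An isotherm tibble (`concentration_nM`, `signal`, optional
#'   `sem`), e.g. from [generate_isotherm()] or [read_isotherm()].
#' @param fix_n Fix the Hill coefficient to this value (e.g. 1 for the
#'   Langmuir reduction); `NULL` fits it freely.
#' @param n_starts Number of log-spaced `K_D` starting values (default 8).
#' @return An object of class `hill_fit`: list with `params` (tibble
#'   `term`, `estimate`, `std_error`), `rss`, `fit` (the `nls` object),
#'   `data`.
#' @examples
#' iso <- generate_isotherm(hill_model(9, 1.8, 1, 2),
#'                          10^seq(-0.3, 2.3, length.out = 12),
#'                          noise_sigma = 0.03, replicates = 3, seed = 2)
#' tidy(fit_hill(iso))
#' @export
fit_hill <- function(iso, fix_n = NULL, n_starts = 8) {
  df <- check_isotherm(iso, min_points = 4)
  w <- iso_weights(df)
  span <- range(df$concentration_nM[df$concentration_nM > 0])
  kd_starts <- 10^seq(log10(span[1]), log10(span[2]),
                      length.out = n_starts)
  s_lo <- min(df$signal); s_hi <- max(df$signal)
  fits <- lapply(kd_starts, function(kd0) {
    tryCatch({
      if (is.null(fix_n)) {
        minpack.lm::nlsLM(
          signal ~ s_free + (s_bound - s_free) *
            concentration_nM^n / (kd^n + concentration_nM^n),
          data = df, weights = w,
          start = list(kd = kd0, n = 1, s_free = s_lo, s_bound = s_hi),
          lower = c(kd = 1e-6, n = 1e-3, s_free = -Inf, s_bound = -Inf),
          control = minpack.lm::nls.lm.control(maxiter = 500,
                                               ftol = 1e-12))
      } else {
        n_fix <- fix_n
        minpack.lm::nlsLM(
          signal ~ s_free + (s_bound - s_free) *
            concentration_nM^n_fix / (kd^n_fix + concentration_nM^n_fix),
          data = df, weights = w,
          start = list(kd = kd0, s_free = s_lo, s_bound = s_hi),
          lower = c(kd = 1e-6, s_free = -Inf, s_bound = -Inf),
          control = minpack.lm::nls.lm.control(maxiter = 500,
                                               ftol = 1e-12))
      }
    }, error = function(e) NULL)
  })
  best <- pick_best_fit(fits, "Hill fit did not converge from any start.")
  params <- fit_params(best)
  if (!is.null(fix_n)) {
    params <- bind_rows(params,
                        tibble(term = "n", estimate = fix_n,
                               std_error = 0))
  }
  structure(list(params = params,
                 rss = sum(stats::resid(best)^2 * w) / mean(w),
                 weighted_rss = sum(stats::resid(best)^2 * w),
                 fit = best, data = df, weights = w),
            class = "hill_fit")
}

#' Fit the sequential two-site binding model to an isotherm
#'
#' Nonlinear least squares of
#' `S(c) = a0*f0 + a1*f1 + a2*f2` with species fractions from
#' [two_site_fractions()] (stepwise dissociation constants `K1`, `K2`),
#' multi-start over a log-spaced grid of `(K1, K2)` initializations.
#' Positive cooperativity is reported when `K2 < K1`.
#'
#' @inheritParams fit_hill
#' @param k_starts Number of grid points per constant (default 4, i.e.
#'   16 starts).
#' @return An object of class `two_site_fit` (same layout as
#'   [fit_hill()], plus `cooperative`).
#' @export
fit_two_site <- function(iso, k_starts = 4) {
  df <- check_isotherm(iso, min_points = 6)
  w <- iso_weights(df)
  if (diff(range(df$signal)) <= 10 * .Machine$double.eps +
      1e-12 * max(abs(df$signal))) {
    abort("Signal is flat; two-site amplitudes are not identifiable.")
  }
  span <- range(df$concentration_nM[df$concentration_nM > 0])
  ks <- 10^seq(log10(span[1]), log10(span[2]), length.out = k_starts)
  grid <- expand.grid(k1 = ks, k2 = ks)
  s_lo <- min(df$signal); s_hi <- max(df$signal)
  fits <- lapply(seq_len(nrow(grid)), function(i) {
    tryCatch(
      minpack.lm::nlsLM(
        signal ~ two_site_signal(concentration_nM, k1, k2, a0, a1, a2),
        data = df, weights = w,
        start = list(k1 = grid$k1[i], k2 = grid$k2[i],
                     a0 = s_lo, a1 = (s_lo + s_hi) / 2, a2 = s_hi),
        lower = c(k1 = 1e-6, k2 = 1e-6, a0 = -Inf, a1 = -Inf,
                  a2 = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500,
                                             ftol = 1e-12)),
      error = function(e) NULL)
  })
  best <- pick_best_fit(fits, "Two-site fit did not converge from any start.")
  params <- fit_params(best)
  k1 <- params$estimate[params$term == "k1"]
  k2 <- params$estimate[params$term == "k2"]
  structure(list(params = params,
                 rss = sum(stats::resid(best)^2 * w) / mean(w),
                 weighted_rss = sum(stats::resid(best)^2 * w),
                 cooperative = k2 < k1,
                 fit = best, data = df, weights = w),
            class = "two_site_fit")
}

check_isotherm <- function(iso, min_points) {
  need <- c("concentration_nM", "signal")
  if (!all(need %in% names(iso))) {
    abort("Isotherm needs columns concentration_nM and signal.")
  }
  df <- as_tibble(iso)[c(need, intersect("sem", names(iso)))]
  df <- df[complete.cases(df[need]), ]
  if (nrow(df) < min_points) {
    abort(sprintf("Need >= %d concentrations for this fit.", min_points))
  }
  df
}

iso_weights <- function(df) {
  if ("sem" %in% names(df) && all(is.finite(df$sem)) && all(df$sem > 0)) {
    1 / df$sem^2
  } else {
    rep(1, nrow(df))
  }
}

pick_best_fit <- function(fits, msg) {
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) abort(msg)
  dev <- vapply(fits[ok], stats::deviance, numeric(1))
  fits[ok][[which.min(dev)]]
}

fit_params <- function(fit) {
  co <- summary(fit)$coefficients
  tibble(term = rownames(co), estimate = unname(co[, "Estimate"]),
         std_error = unname(co[, "Std. Error"]))
}

#' FRET efficiency from donor quenching
#'
#' `E(c) = 1 - I_D(c) / I_D(0)`, clamped to `[0, 1]`: the efficiency of
#' energy transfer inferred from the decrease of the donor emission
#' relative to the donor-only reference.
#'
#' @param donor_signal Donor intensities at each titration point.
#' @param reference Donor-only reference intensity `I_D(0)` (> 0).
#' @return Numeric vector of efficiencies.
#' @examples
#' fret_from_donor_quench(c(1, 0.8, 0.65), reference = 1)
#' @export
fret_from_donor_quench <- function(donor_signal, reference) {
  if (!is.numeric(reference) || length(reference) != 1 || reference <= 0) {
    abort("`reference` must be a single positive donor intensity.")
  }
  pmin(pmax(1 - donor_signal / reference, 0), 1)
}

#' Convert between FRET efficiency and inter-dye distance
#'
#' The Foerster relation `E = R0^6 / (R0^6 + R^6)` and its inverse
#' `R = R0 * (1/E - 1)^(1/6)`. `R0` defaults to 60 Angstrom, the
#' Cy3/Cy5-class pair value.
#'
#' @param value Efficiency (for `"EtoR"`, in (0, 1)) or distance in
#'   Angstrom (for `"RtoE"`, > 0); vectorized.
#' @param direction `"EtoR"` or `"RtoE"`.
#' @param r0 Foerster radius in Angstrom (> 0).
#' @return A tibble of class `fret_geometry` with columns `e_fret`,
#'   `r_angstrom`, `r0`.
#' @examples
#' forster_convert(0.08, "EtoR")   # ~90 Angstrom
#' forster_convert(60, "RtoE")     # E = 0.5 at R = R0
#' @export
forster_convert <- function(value, direction = c("EtoR", "RtoE"),
                            r0 = 60) {
  direction <- match.arg(direction)
  if (r0 <= 0) abort("`r0` must be > 0.")
  if (direction == "EtoR") {
    if (any(value <= 0 | value >= 1)) {
      abort("Efficiency must lie strictly in (0, 1): E = 0 or 1 maps to an infinite or zero distance.")
    }
    e <- value
    r <- r0 * (1 / value - 1)^(1 / 6)
  } else {
    if (any(value <= 0)) abort("Distance must be > 0.")
    r <- value
    e <- r0^6 / (r0^6 + value^6)
  }
  out <- tibble(e_fret = e, r_angstrom = r, r0 = r0)
  class(out) <- c("fret_geometry", class(out))
  out
}

#' RatioA FRET efficiency from sensitized acceptor emission
#'
#' Clegg-style ratiometric estimator: the sensitized acceptor emission
#' under donor excitation, corrected for donor leakage, is normalized by
#' the acceptor emission under direct acceptor excitation, then scaled by
#' the extinction-coefficient corrections:
#' \deqn{ratioA = (F_{AD} - leakage \cdot F_{D}) / F_{AA}}
#' \deqn{E = ratioA \cdot \epsilon_{corr} / extinction\_ratio}
#' With all corrections at their identity defaults the estimator returns
#' `ratioA` itself. [ratio_a_forward()] is the matching forward spectral
#' model; the pair round-trips exactly.
#'
#' @param f_ad Acceptor emission under donor excitation.
#' @param f_aa Acceptor emission under direct acceptor excitation (> 0).
#' @param extinction_ratio Ratio of acceptor extinction at its own
#'   excitation wavelength to the donor extinction at the donor
#'   wavelength (default 1; must be non-zero).
#' @param eps_corr Acceptor direct-excitation correction at the donor
#'   wavelength (default 1).
#' @param leakage Donor leakage fraction into the acceptor detection
#'   band (default 0).
#' @param f_donor Donor emission used for the leakage correction
#'   (default 0).
#' @return Numeric FRET efficiency (vectorized).
#' @examples
#' ratio_a(f_ad = 0.08, f_aa = 1)          # E = 0.08
#' ratio_a(ratio_a_forward(0.5), f_aa = 1) # exact round trip
#' @export
ratio_a <- function(f_ad, f_aa, extinction_ratio = 1, eps_corr = 1,
                    leakage = 0, f_donor = 0) {
  if (any(f_aa <= 0)) {
    abort("Direct-excitation acceptor signal must be > 0.")
  }
  if (extinction_ratio == 0) abort("`extinction_ratio` must be non-zero.")
  ratio <- (f_ad - leakage * f_donor) / f_aa
  ratio * eps_corr / extinction_ratio
}

#' @rdname ratio_a
#' @param e True FRET efficiency generating the sensitized emission.
#' @export
ratio_a_forward <- function(e, f_aa = 1, extinction_ratio = 1,
                            eps_corr = 1, leakage = 0, f_donor = 0) {
  e * extinction_ratio / eps_corr * f_aa + leakage * f_donor
}

#' Fit a Gaussian mixture to a population histogram
#'
#' Least-squares fit of one or two Gaussian components to a normalized
#' histogram (e.g. from [population_histogram()]), reporting means,
#' standard deviations, full widths at half maximum
#' (`FWHM = 2 * sqrt(2 * ln 2) * sigma`) and area fractions.
#'
#' @param hist_tbl A tibble with `mid` and `density` columns.
#' @param k Number of components (1 or 2).
#' @return An object of class `gaussian_fit`: list with `components`
#'   (tibble `mean`, `sd`, `fwhm`, `fraction`), `rss`, `fit`.
#' @export
fit_gaussians <- function(hist_tbl, k = 1) {
  if (!all(c("mid", "density") %in% names(hist_tbl))) {
    abort("`hist_tbl` needs columns mid and density.")
  }
  if (!k %in% c(1, 2)) abort("`k` must be 1 or 2.")
  df <- tibble(x = hist_tbl$mid, y = hist_tbl$density)
  mu0 <- sum(df$x * df$y) / sum(df$y)
  sd0 <- sqrt(max(sum((df$x - mu0)^2 * df$y) / sum(df$y), 1e-8))
  if (k == 1) {
    fit <- minpack.lm::nlsLM(
      y ~ a1 / (s1 * sqrt(2 * pi)) * exp(-(x - m1)^2 / (2 * s1^2)),
      data = df, start = list(a1 = 1, m1 = mu0, s1 = sd0),
      lower = c(a1 = 0, m1 = -Inf, s1 = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    co <- fit_params(fit)
    comp <- tibble(mean = co$estimate[co$term == "m1"],
                   sd = co$estimate[co$term == "s1"],
                   area = co$estimate[co$term == "a1"])
  } else {
    ## initialize the two components on either side of the weighted median
    med <- df$x[which.min(abs(cumsum(df$y) / sum(df$y) - 0.5))]
    lo <- df[df$x <= med, ]; hi <- df[df$x > med, ]
    m1_0 <- if (nrow(lo)) sum(lo$x * lo$y) / max(sum(lo$y), 1e-12) else mu0 - sd0
    m2_0 <- if (nrow(hi)) sum(hi$x * hi$y) / max(sum(hi$y), 1e-12) else mu0 + sd0
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a1 / (s1 * sqrt(2 * pi)) * exp(-(x - m1)^2 / (2 * s1^2)) +
          a2 / (s2 * sqrt(2 * pi)) * exp(-(x - m2)^2 / (2 * s2^2)),
        data = df,
        start = list(a1 = 0.5, m1 = m1_0, s1 = sd0 / 2,
                     a2 = 0.5, m2 = m2_0, s2 = sd0 / 2),
        lower = c(a1 = 0, m1 = -Inf, s1 = 1e-9,
                  a2 = 0, m2 = -Inf, s2 = 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) {
      warn("Two-component fit degenerate; refitting with one component.")
      return(fit_gaussians(hist_tbl, k = 1))
    }
    co <- fit_params(fit)
    comp <- tibble(mean = co$estimate[co$term %in% c("m1", "m2")],
                   sd = co$estimate[co$term %in% c("s1", "s2")],
                   area = co$estimate[co$term %in% c("a1", "a2")])
    comp <- comp[order(comp$mean), ]
  }
  comp$fwhm <- 2 * sqrt(2 * log(2)) * comp$sd
  comp$fraction <- comp$area / sum(comp$area)
  structure(list(components = comp[c("mean", "sd", "fwhm", "fraction")],
                 rss = sum(stats::resid(fit)^2),
                 fit = fit, data = df),
            class = "gaussian_fit")
}
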