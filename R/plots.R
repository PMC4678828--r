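#' Plot a single-molecule trajectory
#'
#' Three stacked panels in the style of single-molecule binding figures:
#' donor and acceptor intensities, total intensity (PIFE), and apparent
#' FRET efficiency.
#'
#' @param cohort A cohort or trajectory tibble.
#' @param molecule Molecule id to plot (default: first).
#' @param thr Thresholds used to draw the cutoff guides.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(cohort, molecule = NULL,
                            thr = classifier_thresholds()) {
  feats <- compute_features(cohort, baseline = 1)
  molecule <- molecule %||% feats$molecule_id[1]
  d <- feats |> filter(.data$molecule_id == molecule)
  long <- bind_rows(
    tibble(time_s = d$time_s, value = d$donor, panel = "intensity",
           series = "donor"),
    tibble(time_s = d$time_s, value = d$acceptor, panel = "intensity",
           series = "acceptor"),
    tibble(time_s = d$time_s, value = d$total_norm, panel = "total (PIFE)",
           series = "total"),
    tibble(time_s = d$time_s, value = d$e_app, panel = "E_app",
           series = "E_app"))
  ggplot(long, aes(x = .data$time_s, y = .data$value,
                   colour = .data$series)) +
    geom_step(linewidth = 0.3) +
    facet_grid(rows = vars(.data$panel), scales = "free_y") +
    scale_colour_manual(values = c(donor = "#1b9e77",
                                   acceptor = "#d95f02",
                                   total = "grey30",
                                   E_app = "#7570b3")) +
    labs(x = "time (s)", y = NULL, colour = NULL, title = molecule) +
    theme_minimal()
}

#' Plot a dwell-time histogram with its exponential fit
#'
#' @param dwells A `dwell_table`.
#' @param estimate Optional `rate_estimate` to overlay.
#' @param bins Number of bins.
#' @return A ggplot object.
#' @export
plot_dwell_histogram <- function(dwells, estimate = NULL, bins = 20) {
  x <- dwells$dwell_s[!dwells$right_censored]
  p <- ggplot(tibble(dwell_s = x), aes(x = .data$dwell_s)) +
    geom_histogram(bins = bins, fill = "grey70", colour = "grey30") +
    labs(x = "dwell time (s)", y = "count",
         title = attr(dwells, "transition")) +
    theme_minimal()
  if (!is.null(estimate) && is.finite(estimate$rate[1])) {
    k_tot <- estimate$rate[1] / estimate$branching_fraction[1]
    bw <- diff(range(x)) / bins
    p <- p + stat_function(
      fun = function(t) length(x) * bw * k_tot * exp(-k_tot * t),
      colour = "#d95f02", linewidth = 0.8)
  }
  p
}

#' @export
autoplot.hill_fit <- function(object, ...) {
  df <- object$data
  kd <- object$params$estimate[object$params$term == "kd"]
  grid_c <- 10^seq(log10(max(min(df$concentration_nM[df$concentration_nM > 0]),
                             1e-3)),
                   log10(max(df$concentration_nM)), length.out = 200)
  pred <- tibble(concentration_nM = grid_c,
                 signal = stats::predict(object$fit,
                                         newdata = tibble(concentration_nM = grid_c)))
  p <- ggplot(df, aes(x = .data$concentration_nM, y = .data$signal)) +
    geom_point() +
    geom_line(data = pred, colour = "#d95f02") +
    geom_vline(xintercept = kd, linetype = "dashed", colour = "grey50") +
    scale_x_log10() +
    labs(x = "[protein] (nM)", y = "signal",
         title = sprintf("Hill fit: K_D = %.3g nM", kd)) +
    theme_minimal()
  if ("sem" %in% names(df)) {
    p <- p + geom_errorbar(aes(ymin = .data$signal - .data$sem,
                               ymax = .data$signal + .data$sem),
                           width = 0.02)
  }
  p
}

#' @export
autoplot.two_site_fit <- function(object, ...) {
  df <- object$data
  grid_c <- 10^seq(log10(max(min(df$concentration_nM[df$concentration_nM > 0]),
                             1e-3)),
                   log10(max(df$concentration_nM)), length.out = 200)
  pred <- tibble(concentration_nM = grid_c,
                 signal = stats::predict(object$fit,
                                         newdata = tibble(concentration_nM = grid_c)))
  ggplot(df, aes(x = .data$concentration_nM, y = .data$signal)) +
    geom_point() +
    geom_line(data = pred, colour = "#7570b3") +
    scale_x_log10() +
    labs(x = "[protein] (nM)", y = "signal",
         title = sprintf("Two-site fit: K1 = %.3g, K2 = %.3g nM",
                         object$params$estimate[object$params$term == "k1"],
                         object$params$estimate[object$params$term == "k2"])) +
    theme_minimal()
}

#' @export
autoplot.bimolecular_fit <- function(object, ...) {
  df <- object$data
  ggplot(df, aes(x = .data$concentration_nM, y = .data$rate)) +
    geom_point() +
    geom_abline(slope = object$slope, intercept = object$intercept,
                colour = "#d95f02") +
    labs(x = "[protein] (nM)", y = "pseudo-first-order rate (s^-1)",
         title = sprintf("slope = %.3g nM^-1 s^-1", object$slope)) +
    theme_minimal()
}

#' @export
autoplot.gaussian_fit <- function(object, ...) {
  df <- object$data
  comp <- object$components
  grid_x <- seq(min(df$x), max(df$x), length.out = 400)
  total_area <- sum(comp$fraction)
  curves <- purrr::imap(split(comp, seq_len(nrow(comp))), function(cc, i) {
    tibble(x = grid_x, component = paste0("g", i),
           y = cc$fraction / (cc$sd * sqrt(2 * pi)) *
             exp(-(grid_x - cc$mean)^2 / (2 * cc$sd^2)))
  }) |> list_rbind()
  ggplot(df, aes(x = .data$x, y = .data$y)) +
    geom_col(fill = "grey80", colour = "grey50", width = diff(df$x[1:2])) +
    geom_line(data = curves,
              aes(colour = .data$component), linewidth = 0.8) +
    labs(x = "value", y = "density") +
    theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
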