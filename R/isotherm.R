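#' Hill binding-isotherm model curve
#'
#' Signal as a function of free ligand concentration under the Hill model:
#' \deqn{S(c) = S_{free} + (S_{bound} - S_{free}) \frac{c^n}{K_D^n + c^n}}
#' The midpoint sits at `c = K_D` for every Hill coefficient `n`.
#'
#' @param concentration Concentrations (nM, >= 0), vectorized.
#' @param kd Dissociation constant (nM, > 0).
#' @param n Hill coefficient (> 0).
#' @param s_free,s_bound Signal of the free and saturated species.
#' @return Numeric vector of signals.
#' @export
hill_signal <- function(concentration, kd, n = 1, s_free = 0, s_bound = 1) {
  if (kd <= 0) abort("`kd` must be > 0.")
  if (n <= 0) abort("`n` must be > 0.")
  frac <- concentration^n / (kd^n + concentration^n)
  frac[concentration == 0] <- 0
  s_free + (s_bound - s_free) * frac
}

#' Species fractions of the sequential two-site binding model
#'
#' For stepwise association of two monomers with macroscopic stepwise
#' dissociation constants `K1` (first site) and `K2` (second site), the
#' partition function is \eqn{Z = 1 + c/K_1 + c^2/(K_1 K_2)} and the
#' species fractions are \eqn{f_0 = 1/Z}, \eqn{f_1 = (c/K_1)/Z},
#' \eqn{f_2 = (c^2/(K_1 K_2))/Z}. `K2 < K1` indicates positive
#' cooperativity.
#'
#' @param concentration Concentrations (nM), vectorized.
#' @param k1,k2 Stepwise dissociation constants (nM, > 0).
#' @return A tibble with columns `concentration_nM`, `f0`, `f1`, `f2`
#'   (each row sums to 1).
#' @export
two_site_fractions <- function(concentration, k1, k2) {
  if (k1 <= 0 || k2 <= 0) abort("`k1` and `k2` must be > 0.")
  z <- 1 + concentration / k1 + concentration^2 / (k1 * k2)
  tibble(concentration_nM = concentration,
         f0 = 1 / z,
         f1 = (concentration / k1) / z,
         f2 = (concentration^2 / (k1 * k2)) / z)
}

#' Observed signal of the sequential two-site model
#'
#' @inheritParams two_site_fractions
#' @param a0,a1,a2 Signal amplitudes of the empty, singly and doubly bound
#'   species.
#' @return Numeric vector `a0*f0 + a1*f1 + a2*f2`.
#' @export
two_site_signal <- function(concentration, k1, k2, a0, a1, a2) {
  f <- two_site_fractions(concentration, k1, k2)
  a0 * f$f0 + a1 * f$f1 + a2 * f$f2
}

#' Generate a synthetic ensemble binding isotherm
#'
#' Evaluates a noise-free model curve (Hill or sequential two-site) on a
#' concentration grid, adds Gaussian noise to `replicates` independent
#' replicates per concentration, and summarizes as mean and s.e.m. --
#' the forward model for the ensemble titration assays.
#'
#' @param model Either `hill_model(...)` or `two_site_model(...)`.
#' @param concentrations Concentrations (nM, >= 0).
#' @param noise_sigma Gaussian noise sd in signal units (absolute).
#' @param replicates Number of replicates per concentration (>= 1).
#' @param seed Integer seed (global RNG untouched).
#' @return A tibble of class `isotherm`: `concentration_nM`, `signal`
#'   (mean), `sem`, `n_replicates`; attribute `truth` stores the model.
#' @examples
#' iso <- generate_isotherm(hill_model(kd = 9, n = 1.8, s_free = 1,
#'                                     s_bound = 2),
#'                          concentrations = c(0.5, 2, 9, 30, 200),
#'                          noise_sigma = 0.03, replicates = 3, seed = 1)
#' @export
generate_isotherm <- function(model, concentrations, noise_sigma = 0,
                              replicates = 3, seed = NULL) {
  if (!inherits(model, "binding_model")) {
    abort("`model` must come from hill_model() or two_site_model().")
  }
  if (replicates < 1) abort("`replicates` must be >= 1.")
  if (any(concentrations < 0)) abort("Concentrations must be >= 0.")
  concentrations <- sort(unique(concentrations))
  mu <- model$fn(concentrations)
  if (!is.null(seed)) withr::local_seed(seed)
  reps <- matrix(rnorm(length(mu) * replicates, mean = rep(mu, replicates),
                       sd = noise_sigma),
                 nrow = length(mu))
  out <- tibble(
    concentration_nM = concentrations,
    signal = rowMeans(reps),
    sem = if (replicates > 1) {
      apply(reps, 1, sd) / sqrt(replicates)
    } else {
      rep(0, length(mu))
    },
    n_replicates = replicates
  )
  structure(out, class = c("isotherm", class(out)), truth = model)
}

#' @rdname generate_isotherm
#' @param kd,n,s_free,s_bound Hill model truth parameters.
#' @export
hill_model <- function(kd, n = 1, s_free = 0, s_bound = 1) {
  if (kd <= 0) abort("`kd` must be > 0.")
  structure(list(type = "hill",
                 params = c(kd = kd, n = n, s_free = s_free,
                            s_bound = s_bound),
                 fn = function(c_nM) hill_signal(c_nM, kd, n, s_free,
                                                s_bound)),
            class = "binding_model")
}

#' @rdname generate_isotherm
#' @param k1,k2,a0,a1,a2 Two-site model truth parameters.
#' @export
two_site_model <- function(k1, k2, a0 = 0, a1 = 1, a2 = 0) {
  if (k1 <= 0 || k2 <= 0) abort("`k1` and `k2` must be > 0.")
  structure(list(type = "two_site",
                 params = c(k1 = k1, k2 = k2, a0 = a0, a1 = a1, a2 = a2),
                 fn = function(c_nM) two_site_signal(c_nM, k1, k2, a0, a1,
                                                    a2)),
            class = "binding_model")
}

#' Packaged isotherm truth presets
#'
#' Generator-truth configurations for the ensemble titrations:
#'
#' * `"pife_12mer"`: Hill model of the PIFE titration of Cy3-labelled
#'   12-mer ssDNA (K_D = 9 nM, n = 1.8, signal rising from 1 to the 2-fold
#'   PIFE plateau); 12 log-spaced concentrations 0.5--200 nM, 3
#'   replicates, noise sd 0.03 (3% of the signal span).
#' * `"fret_two_site_12mer"`: sequential two-site model of the
#'   intermolecular FRET titration (K1 = 37 nM, K2 = 2.8 nM; apparent FRET
#'   amplitudes 0 unbound, 0.5 singly bound on ensemble average, and 0.35
#'   at the doubly bound acceptor-quenched plateau); a donor-only blank
#'   plus 19 log-spaced concentrations 0.5--1000 nM, 3 replicates,
#'   noise sd 0.003 E-units (~1% of a typical titration signal; the
#'   measurement precision a three-replicate ensemble titration needs to
#'   reach the reported parameter uncertainties, since the two stepwise
#'   constants share one smooth curve and decouple only at this
#'   precision).
#'
#' @param name Preset name.
#' @param seed Seed forwarded to [generate_isotherm()].
#' @return A list with `model`, `concentrations`, `noise_sigma`,
#'   `replicates`, and `isotherm` (the generated tibble).
#' @export
isotherm_preset <- function(name = c("pife_12mer", "fret_two_site_12mer"),
                            seed = 1) {
  name <- match.arg(name)
  cfg <- switch(name,
    pife_12mer = list(
      model = hill_model(kd = 9, n = 1.8, s_free = 1, s_bound = 2),
      concentrations = 10^seq(log10(0.5), log10(200), length.out = 12),
      noise_sigma = 0.03, replicates = 3),
    fret_two_site_12mer = list(
      model = two_site_model(k1 = 37, k2 = 2.8, a0 = 0, a1 = 0.5,
                             a2 = 0.35),
      concentrations = c(0, 10^seq(log10(0.5), 3, length.out = 19)),
      noise_sigma = 0.003, replicates = 3)
  )
  cfg$isotherm <- generate_isotherm(cfg$model, cfg$concentrations,
                                    cfg$noise_sigma, cfg$replicates,
                                    seed = seed)
  cfg
}
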