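test_that("noise-free Hill curves are recovered exactly", {
  conc <- 10^seq(log10(0.5), log10(200), length.out = 12)
  iso <- generate_isotherm(hill_model(9, 1.8, 1, 2), conc, noise_sigma = 0,
                           replicates = 1)
  fit <- fit_hill(iso)
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_equal(unname(est["kd"]), 9, tolerance = 1e-6)
  expect_equal(unname(est["n"]), 1.8, tolerance = 1e-6)
  expect_equal(unname(est["s_free"]), 1, tolerance = 1e-6)
  expect_equal(unname(est["s_bound"]), 2, tolerance = 1e-6)
})

test_that("the packaged PIFE preset recovers its truth under noise", {
  ps <- isotherm_preset("pife_12mer", seed = 4)
  fit <- fit_hill(ps$isotherm)
  g <- glance(fit)
  expect_equal(g$kd_nM, 9, tolerance = 1.5 / 9)
  expect_equal(g$hill_n, 1.8, tolerance = 0.3 / 1.8)
})

test_that("fixing n to 1 matches an independent Langmuir optimizer", {
  conc <- 10^seq(0, 2, length.out = 10)
  iso <- generate_isotherm(hill_model(20, 1, 0, 1), conc,
                           noise_sigma = 0.02, replicates = 3, seed = 5)
  fit <- fit_hill(iso, fix_n = 1)
  kd_pkg <- fit$params$estimate[fit$params$term == "kd"]
  # independent oracle: brute-force 1-D profile over K_D with the linear
  # amplitude parameters solved exactly by least squares at each K_D
  w <- 1 / iso$sem^2
  prof <- function(kd) {
    f <- iso$concentration_nM / (kd + iso$concentration_nM)
    X <- cbind(1 - f, f)
    b <- solve(t(X) %*% (w * X), t(X) %*% (w * iso$signal))
    sum(w * (iso$signal - X %*% b)^2)
  }
  kd_oracle <- optimize(prof, c(0.1, 1000))$minimum
  expect_equal(kd_pkg, kd_oracle, tolerance = 1e-3)
})

test_that("the Hill fit is never beaten by its n = 1 restriction", {
  for (seed in 1:4) {
    iso <- generate_isotherm(hill_model(15, 1.6, 0, 1),
                             10^seq(-0.3, 2.3, length.out = 10),
                             noise_sigma = 0.03, replicates = 3,
                             seed = seed)
    free <- fit_hill(iso)
    restricted <- fit_hill(iso, fix_n = 1)
    expect_lte(free$weighted_rss, restricted$weighted_rss * (1 + 1e-8))
  }
})

test_that("donor-quench FRET inverts the forward render", {
  expect_equal(fret_from_donor_quench(1, 1), 0)
  expect_equal(fret_from_donor_quench(0.65, 1), 0.35)
  # round trip through the Hill forward model of donor quenching
  e_true <- 0.35
  conc <- c(0, 5, 20, 100, 800)
  donor <- 1 - e_true * hill_signal(conc, kd = 24, n = 1.8)
  e_meas <- fret_from_donor_quench(donor, reference = donor[1])
  expect_equal(e_meas, e_true * hill_signal(conc, 24, 1.8),
               tolerance = 1e-12)
  expect_error(fret_from_donor_quench(1, 0), "positive")
})

test_that("noise-free two-site curves are recovered exactly", {
  conc <- 10^seq(log10(0.5), 3, length.out = 14)
  iso <- generate_isotherm(two_site_model(37, 2.8, 0, 0.6, 0.35), conc,
                           noise_sigma = 0, replicates = 1)
  fit <- fit_two_site(iso)
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_equal(unname(est["k1"]), 37, tolerance = 1e-4)
  expect_equal(unname(est["k2"]), 2.8, tolerance = 1e-4)
  expect_true(fit$cooperative)
})

test_that("the packaged two-site preset recovers both constants under noise", {
  ps <- isotherm_preset("fret_two_site_12mer", seed = 6)
  fit <- fit_two_site(ps$isotherm)
  g <- glance(fit)
  expect_equal(g$k1_nM, 37, tolerance = 0.25)
  expect_equal(g$k2_nM, 2.8, tolerance = 0.25)
})

test_that("two-site fractions stay in [0,1] and sum to one everywhere", {
  conc <- c(0, 10^seq(-2, 4, length.out = 50))
  f <- two_site_fractions(conc, 37, 2.8)
  m <- as.matrix(f[c("f0", "f1", "f2")])
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(unname(rowSums(m)), rep(1, length(conc)))
  expect_error(fit_two_site(tibble::tibble(
    concentration_nM = 1:8, signal = rep(0.5, 8))), "flat")
})

test_that("Foerster conversion matches the published anchors", {
  expect_equal(forster_convert(60, "RtoE")$e_fret, 0.5)
  expect_equal(forster_convert(0.08, "EtoR")$r_angstrom, 90,
               tolerance = 0.01)
  expect_equal(forster_convert(0.02, "EtoR")$r_angstrom, 114.8,
               tolerance = 0.01)
  expect_error(forster_convert(1, "EtoR"), "strictly")
  expect_error(forster_convert(-5, "RtoE"), "> 0")
})

test_that("Foerster conversion round-trips to numerical identity", {
  e <- seq(0.01, 0.99, length.out = 197)
  r <- forster_convert(e, "EtoR")$r_angstrom
  back <- forster_convert(r, "RtoE")$e_fret
  expect_equal(back, e, tolerance = 1e-10)
})

test_that("RatioA inverts its forward spectral model exactly", {
  expect_equal(ratio_a(0, 1), 0)
  expect_equal(ratio_a(ratio_a_forward(0.5), f_aa = 1), 0.5)
  for (e in c(0.02, 0.08, 0.35, 0.9)) {
    fad <- ratio_a_forward(e, f_aa = 2.2, extinction_ratio = 1.7,
                           eps_corr = 0.93, leakage = 0.12,
                           f_donor = 0.8)
    expect_equal(ratio_a(fad, f_aa = 2.2, extinction_ratio = 1.7,
                         eps_corr = 0.93, leakage = 0.12, f_donor = 0.8),
                 e, tolerance = 1e-12)
  }
  expect_error(ratio_a(0.5, 0), "> 0")
  expect_error(ratio_a(0.5, 1, extinction_ratio = 0), "non-zero")
})

test_that("Gaussian population fits report FWHM and fractions", {
  expect_equal(2 * sqrt(2 * log(2)), 2.3548, tolerance = 1e-4)
  # single component with FWHM 0.4
  sigma <- 0.4 / (2 * sqrt(2 * log(2)))
  x <- seq(0, 2, by = 0.02)
  h1 <- tibble::tibble(mid = x, density = dnorm(x, 1, sigma))
  f1 <- fit_gaussians(h1, k = 1)
  expect_equal(f1$components$fwhm, 0.4, tolerance = 1e-6)
  # two components with 14/86 mixing, as in a saturating titration
  h2 <- tibble::tibble(mid = seq(0, 3.5, by = 0.02))
  h2$density <- 0.14 * dnorm(h2$mid, 1, 0.17) + 0.86 * dnorm(h2$mid, 2, 0.47)
  f2 <- fit_gaussians(h2, k = 2)
  expect_equal(f2$components$fraction[2], 0.86, tolerance = 0.02)
  expect_equal(f2$components$mean, c(1, 2), tolerance = 0.02)
  expect_error(fit_gaussians(h2, k = 3), "1 or 2")
})

test_that("fitted parameter uncertainties shrink with replicates", {
  se_at <- vapply(c(2, 8, 32), function(reps) {
    iso <- generate_isotherm(hill_model(9, 1.8, 1, 2),
                             10^seq(-0.3, 2.3, length.out = 12),
                             noise_sigma = 0.05, replicates = reps,
                             seed = 11)
    fit <- fit_hill(iso)
    fit$params$std_error[fit$params$term == "kd"]
  }, numeric(1))
  expect_true(all(diff(se_at) < 0))
})

test_that("tidiers expose estimates in broom shape", {
  iso <- generate_isotherm(hill_model(9, 1.8, 1, 2),
                           10^seq(-0.3, 2.3, length.out = 12),
                           noise_sigma = 0.02, replicates = 3, seed = 12)
  fit <- fit_hill(iso)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error") %in% names(td)))
  expect_equal(nrow(glance(fit)), 1)
  bi <- rate_vs_concentration(tibble::tibble(
    concentration_nM = c(1, 5, 10), rate = c(0.03, 0.16, 0.33)))
  expect_equal(tidy(bi)$term, c("slope", "intercept"))
})
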