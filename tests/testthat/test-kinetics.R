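test_that("dwell collection does the transition bookkeeping", {
  lab <- c(rep("UNBOUND", 40), rep("FRET", 10), rep("UNBOUND", 20),
           rep("FRET_PIFE", 6), rep("PIFE_QUENCH", 30),
           rep("UNBOUND", 10))
  seg <- segment_states(lab, frame_time = 0.05)
  d_on <- collect_dwells(seg, "S1->S2")
  expect_equal(sort(d_on$dwell_s), c(1.0, 2.0))  # first dwell kept (memoryless)
  d_off <- collect_dwells(seg, "S2->S1")
  expect_equal(d_off$dwell_s, 0.5)
  d_on2 <- collect_dwells(seg, "S2->S3")
  expect_equal(d_on2$dwell_s, 0.3)   # S2b dwell pooled into S2
  d_dis <- collect_dwells(seg, "S3->S1")
  expect_equal(d_dis$dwell_s, 1.5)
  expect_equal(attr(d_on, "n_exits"), 2)
  expect_equal(attr(d_on, "n_events"), 2)
})

test_that("right-censored dwells are excluded by default but kept on request", {
  lab <- c(rep("UNBOUND", 10), rep("FRET", 10), rep("PIFE_QUENCH", 20))
  seg <- segment_states(lab, 0.05)
  expect_warning(d <- collect_dwells(seg, "S3->S1"), "No qualifying")
  expect_equal(nrow(d), 0)
  d2 <- collect_dwells(seg, "S3->S1", include_censored = TRUE)
  expect_equal(nrow(d2), 1)
  expect_true(d2$right_censored)
})

test_that("dwell counts match truth-path transition counts on a cohort", {
  coh <- generate_cohort(fig8(), quiet_phys(), 10, 20, 60, 0.05,
                         seed = 50, noise = FALSE, bleaching = FALSE)
  ts <- true_segments(attr(coh, "truth"))
  f <- compute_features(coh, baseline = 1)
  seg <- segment_states(classify_frames(f), 0.05)
  for (tr in c("S2->S1", "S3->S1", "S4->S1")) {
    n_true <- nrow(collect_dwells(ts, tr))
    n_class <- nrow(collect_dwells(seg, tr))
    # noiseless: only sub-frame events can differ
    expect_equal(n_class, n_true, tolerance = 0.12)
  }
})

test_that("both estimators recover a known exponential rate", {
  x <- withr::with_seed(8, stats::rexp(1e4, 2))
  est_h <- fit_exponential(x, method = "histogram_ls")
  est_m <- fit_exponential(x, method = "mle")
  expect_equal(est_h$rate, 2, tolerance = 0.05)
  expect_equal(est_m$rate, 2, tolerance = 0.05)
  # methods agree within their joint uncertainty
  expect_lt(abs(est_h$rate - est_m$rate),
            3 * sqrt(est_h$se^2 + est_m$se^2))
})

test_that("degenerate dwell sets are handled", {
  expect_equal(fit_exponential(rep(0.25, 50), method = "mle")$rate, 4)
  expect_error(fit_exponential(rep(0.25, 50), method = "histogram_ls"),
               "distinct")
  expect_error(fit_exponential(numeric(0), method = "histogram_ls"))
})

test_that("branching correction converts total exit rates to edge rates", {
  # S2 dwells at 10 nM end by dissociation (1.75) or second binding (1.6):
  # the dwell distribution carries the sum, the branching carries the split
  coh <- generate_cohort(fig8(), quiet_phys(), 10, 60, 60, 0.05,
                         seed = 60, noise = FALSE, bleaching = FALSE)
  ts <- true_segments(attr(coh, "truth"))
  dw <- collect_dwells(ts, "S2->S1")
  est <- fit_exponential(dw, method = "mle")
  expect_equal(est$rate, 1.75, tolerance = 0.1)
  est_tot <- fit_exponential(dw, method = "mle", branching = FALSE)
  expect_equal(est_tot$rate, 3.35, tolerance = 0.1)
})

test_that("the event-rate estimator is unbiased under right censoring", {
  # exponential dwells censored at a fixed window: occurrence/exposure
  # still recovers the rate, unlike the censoring-blind mean
  k_true <- 0.02
  win <- 50
  x <- withr::with_seed(21, stats::rexp(4000, k_true))
  obs <- pmin(x, win)
  ev <- x <= win
  dw <- tibble::tibble(molecule_id = "m", dwell_s = obs[ev],
                       right_censored = FALSE)
  attr(dw, "state_dwells") <- obs
  attr(dw, "transition") <- "S1->S2"
  class(dw) <- c("dwell_table", class(dw))
  est <- fit_exponential(dw, method = "event_rate")
  expect_equal(est$rate, k_true, tolerance = 0.05)
  naive <- 1 / mean(obs[ev])
  expect_gt(naive, 1.3 * k_true)  # the censoring-blind estimate is badly off
  # numeric input: n / sum(x)
  expect_equal(fit_exponential(c(1, 2, 3), method = "event_rate")$rate,
               3 / 6)
})

test_that("the resolution floor leaves the exponential rate unbiased", {
  x <- withr::with_seed(9, stats::rexp(2e4, 3))
  est <- fit_exponential(x, method = "mle", min_dwell = 0.1)
  expect_equal(est$rate, 3, tolerance = 0.05)
})

test_that("rate vs concentration recovers exact and noisy lines", {
  df <- tibble::tibble(concentration_nM = c(0.5, 2.5, 10),
                       rate = 0.032 * c(0.5, 2.5, 10),
                       se = rep(0.001, 3))
  fit <- rate_vs_concentration(df)
  expect_equal(fit$slope, 0.032, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_error(rate_vs_concentration(df[c(1, 1), ]), "distinct")
  # a flat (dissociation) series has slope consistent with zero
  df2 <- tibble::tibble(concentration_nM = c(0.5, 2.5, 10),
                        rate = c(1.72, 1.78, 1.80), se = rep(0.05, 3))
  fit2 <- rate_vs_concentration(df2)
  expect_lt(abs(fit2$slope), 2 * fit2$slope_se + 0.01)
})

test_that("dissociation constants follow from the rate ledger", {
  expect_equal(compute_kd(1.72, 0.032)$kd_nM, 53.75, tolerance = 1e-9)
  expect_equal(compute_kd(0.31, 0.16)$kd_nM, 1.9375, tolerance = 1e-9)
  expect_equal(compute_kd(2, 2)$kd_nM, 1)
  kd <- compute_kd(1.72, 0.032, 0.05, 0.002)
  expect_gt(kd$se_nM, 0)
  expect_error(compute_kd(1.72, 0), "> 0")
})

test_that("pathway census matches the branching ratio of the scheme", {
  # truth-path census at 10 nM: kon4 / (kon1 + kon4) = 0.158
  coh <- generate_cohort(fig8(), quiet_phys(), 10, 150, 60, 0.05,
                         seed = 70, noise = FALSE, bleaching = FALSE)
  ts <- true_segments(attr(coh, "truth"))
  cen <- transition_census(ts)
  expect_equal(cen$s4_entry_fraction, 0.006 / 0.038, tolerance = 0.2)
  expect_equal(cen$s3_to_s2_fraction, 0)
  # disabled pathway: no S4 entries at all
  sch0 <- kinetic_scheme(kon1 = 0.032, koff1 = 1.75, kon2 = 0.16,
                         koff_pair = 0.31, kon4 = 0)
  coh0 <- generate_cohort(sch0, quiet_phys(), 10, 30, 60, 0.05,
                          seed = 71, noise = FALSE, bleaching = FALSE)
  cen0 <- transition_census(true_segments(attr(coh0, "truth")))
  expect_equal(cen0$s4_entry_fraction, 0)
})

test_that("bleaching rate is recovered from dye-only traces", {
  sch0 <- kinetic_scheme(kon1 = 0, koff1 = 1)
  phys <- photophysics(noise_sigma = 0.05, donor_bleach = 0.018,
                       acceptor_bleach = 0)
  coh <- generate_cohort(sch0, phys, 0, 300, 200, 0.05, seed = 80)
  est <- bleaching_rate(coh, baseline = 1)
  expect_equal(est$rate, 0.018, tolerance = 0.1)
  # no bleaching configured: estimation must refuse
  phys0 <- photophysics(noise_sigma = 0.05, donor_bleach = 0,
                        acceptor_bleach = 0)
  coh0 <- generate_cohort(sch0, phys0, 0, 20, 30, 0.05, seed = 81)
  expect_error(bleaching_rate(coh0, baseline = 1), "No bleaching")
})

test_that("the bleach control flags rates too close to bleaching", {
  ctrl <- bleach_control(4.52, 0.07)
  expect_equal(ctrl$ratio, 64.6, tolerance = 0.01)
  expect_true(ctrl$pass)
  expect_false(bleach_control(0.3, 0.07)$pass)
})

test_that("rates are invariant under consistent time rescaling", {
  x <- withr::with_seed(12, stats::rexp(5000, 2))
  r1 <- fit_exponential(x, method = "mle")$rate
  r2 <- fit_exponential(x * 60, method = "mle")$rate  # seconds -> minutes
  expect_equal(r1, r2 * 60, tolerance = 1e-9)
})
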