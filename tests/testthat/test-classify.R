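test_that("apparent FRET efficiency follows the intensity ratio", {
  coh <- tibble::tibble(molecule_id = "m1", frame = 1:3,
                        time_s = (0:2) * 0.05,
                        donor = c(0.2, 1, 0.5),
                        acceptor = c(0.8, 0, -0.6))
  f <- compute_features(coh, baseline = 1)
  expect_equal(f$e_app[1], 0.8)
  expect_equal(f$e_app[2], 0)          # donor-only frame
  expect_true(is.na(f$e_app[3]))        # non-positive total is flagged
  expect_true(f$undefined[3])
  expect_error(compute_features(coh, baseline = -1), "> 0")
})

test_that("features are exact on noiseless unbound renders", {
  p <- path_from_dwells("S1", 2)
  tr <- render_trajectory(p, quiet_phys(), 0.05, noise = FALSE,
                          bleaching = FALSE)
  f <- compute_features(tr, baseline = 1)
  expect_equal(f$e_app, rep(0.1, 40))
  expect_equal(f$total_norm, rep(1 + 0.1 / 0.9, 40))
  expect_equal(f$donor_norm, rep(1, 40))
})

test_that("frame labels match the photophysical signatures", {
  thr <- classifier_thresholds()
  feats <- tibble::tibble(
    molecule_id = "m1",
    e_app = c(0.85, 0.85, 0.02, 0.10, 0.45),
    donor_norm = c(0.15, 0.30, 2.00, 1.00, 0.5),
    total_norm = c(1.00, 2.00, 2.00, 1.11, 1.0),
    undefined = FALSE)
  lab <- classify_frames(feats, thr)$label
  expect_equal(lab[1], "FRET")
  expect_equal(lab[2], "FRET_PIFE")
  expect_equal(lab[3], "PIFE_QUENCH")
  expect_equal(lab[4], "UNBOUND")
  expect_equal(lab[5], "UNBOUND")  # dead zone inherits previous label
})

test_that("segments apply the history rule for the quenched state", {
  lab <- c(rep("UNBOUND", 5), rep("FRET", 4), rep("PIFE_QUENCH", 6),
           rep("UNBOUND", 3), rep("PIFE_QUENCH", 4))
  seg <- segment_states(lab, frame_time = 0.1)
  expect_equal(seg$state, c("S1", "S2a", "S3", "S1", "S4"))
  expect_equal(seg$dwell_s, c(0.5, 0.4, 0.6, 0.3, 0.4))
  expect_equal(seg$left_censored, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(seg$right_censored, c(FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("a constant unbound trace is one doubly censored segment", {
  seg <- segment_states(rep("UNBOUND", 200), frame_time = 0.05)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$state, "S1")
  expect_equal(seg$dwell_s, 10)
  expect_true(seg$left_censored && seg$right_censored)
})

test_that("segment dwells always sum to the classified trace duration", {
  coh <- generate_cohort(fig8(), photophysics(donor_bleach = 0), 10, 10,
                         30, 0.05, seed = 31)
  f <- compute_features(coh, baseline = 1)
  seg <- segment_states(classify_frames(f), 0.05)
  tot <- seg |>
    dplyr::group_by(molecule_id) |>
    dplyr::summarise(s = sum(dwell_s))
  expect_equal(tot$s, rep(30, 10))
})

test_that("short runs merge into the longer neighbour", {
  lab <- c(rep("UNBOUND", 10), "FRET", rep("UNBOUND", 5))
  seg <- segment_states(lab, 0.05, min_dwell = 2)
  expect_equal(seg$state, "S1")
  expect_equal(seg$n_frames, 16L)
})

test_that("bleach detection finds permanent drops and ignores transients", {
  thr <- classifier_thresholds()
  tot <- c(rep(1.1, 219), rep(0.02, 181))
  feats <- tibble::tibble(molecule_id = "m1", e_app = 0.1,
                          donor_norm = tot / 1.1, total_norm = tot,
                          undefined = FALSE)
  expect_equal(detect_bleaching(feats, thr), 220L)
  # 3-frame transient dip recovers: no censoring
  tot2 <- rep(1.1, 400); tot2[100:102] <- 0.02
  feats2 <- feats; feats2$total_norm <- tot2
  expect_true(is.na(detect_bleaching(feats2, thr)))
})

test_that("simulated donor bleach is detected within a frame of truth", {
  phys <- photophysics(noise_sigma = 0.05, acceptor_bleach = 0)
  hits <- 0; total <- 0
  for (i in 1:20) {
    path <- simulate_state_path(fig8(), 10, 60, seed = 400 + i)
    tr <- render_trajectory(path, phys, 0.05, seed = 500 + i)
    bl <- attr(tr, "bleach")
    f <- compute_features(tr, baseline = 1)
    det <- detect_bleaching(f)
    if (bl$donor < 59) {
      total <- total + 1
      truth_frame <- floor(bl$donor / 0.05) + 1
      if (!is.na(det) && abs(det - truth_frame) <= 1) hits <- hits + 1
    }
  }
  expect_gt(total, 5)
  expect_gte(hits / total, 0.9)
})

test_that("classifier equals truth on noiseless frame-aligned cohorts", {
  phys <- quiet_phys(p_near = 0.5)
  ok_all <- TRUE
  for (i in 1:15) {
    path <- snap_path(simulate_state_path(slow_scheme(), 10, 120,
                                          seed = 600 + i), 0.05)
    tr <- render_trajectory(path, phys, 0.05, seed = 700 + i,
                            noise = FALSE, bleaching = FALSE)
    f <- compute_features(tr, baseline = 1)
    seg <- segment_states(classify_frames(f), 0.05)
    truth <- attr(tr, "truth")
    tseg <- rle(truth$state)$values
    expect_equal(seg$state, tseg)
    # boundaries exact on the frame grid
    tdur <- tapply(truth$t_end - truth$t_start,
                   cumsum(c(TRUE, truth$state[-1] != truth$state[-nrow(truth)])),
                   sum)
    expect_equal(seg$dwell_s, as.numeric(tdur), tolerance = 1e-9)
  }
})

test_that("classification is invariant under global intensity rescaling", {
  coh <- generate_cohort(fig8(), photophysics(), 10, 5, 20, 0.05,
                         seed = 44)
  f1 <- compute_features(coh, baseline = 1)
  coh2 <- coh
  coh2$donor <- coh$donor * 7.3
  coh2$acceptor <- coh$acceptor * 7.3
  f2 <- compute_features(coh2, baseline = 7.3)
  l1 <- classify_frames(f1)$label
  l2 <- classify_frames(f2)$label
  expect_identical(l1, l2)
})

test_that("misclassification rate is non-decreasing with camera noise", {
  rates <- vapply(c(0.05, 0.15, 0.3), function(sig) {
    phys <- photophysics(noise_sigma = sig, donor_bleach = 0,
                        acceptor_bleach = 0)
    mis <- 0; tot <- 0
    for (i in 1:8) {
      path <- snap_path(simulate_state_path(slow_scheme(), 10, 100,
                                            seed = 800 + i), 0.05)
      tr <- render_trajectory(path, phys, 0.05, seed = 900 + i)
      f <- compute_features(tr, baseline = 1)
      lab <- classify_frames(f)$label
      truth <- attr(tr, "truth")
      idx <- findInterval(tr$time_s + 0.025, c(truth$t_start, Inf))
      tl <- c(S1 = "UNBOUND", S2a = "FRET", S2b = "FRET_PIFE",
              S3 = "PIFE_QUENCH", S4 = "PIFE_QUENCH")[truth$state[idx]]
      mis <- mis + sum(lab != tl)
      tot <- tot + length(lab)
    }
    mis / tot
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("population histograms integrate to one and locate populations", {
  phys <- quiet_phys()
  coh <- generate_cohort(kinetic_scheme(kon1 = 0, koff1 = 1), phys,
                         0, 30, 5, 0.05, seed = 3, noise = FALSE,
                         bleaching = FALSE)
  f <- compute_features(coh, baseline = 1)
  h <- population_histogram(f, variable = "donor_norm")
  expect_equal(sum(h$density * attr(h, "binwidth")), 1)
  expect_equal(h$mid[which.max(h$density)], 1.05, tolerance = 0.1)
  he <- population_histogram(f, variable = "e_app")
  expect_equal(sum(he$density * attr(he, "binwidth")), 1)
  expect_error(population_histogram(f[0, ]), "Empty")
})
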