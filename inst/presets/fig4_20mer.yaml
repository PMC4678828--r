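scheme:
  kon1: 0.068
  koff1: 4.52
  kon2: 0.0
  koff_pair: 0.0
  kon4: 0.0
  koff4: 0.0
  k_s3_s2: 0.0
photophysics:
  fret:
    S1: 0.1
    S2a: 0.85
    S2b: 0.85
    S3: 0.0
    S4: 0.0
  pife:
    S1: 1.0
    S2a: 1.0
    S2b: 2.0
    S3: 2.0
    S4: 2.0
  acceptor_dark:
    S1: no
    S2a: no
    S2b: no
    S3: yes
    S4: yes
  p_near: 0.5
  donor_bleach: 0.018
  acceptor_bleach: 0.07
  noise_sigma: 0.1
  background:
  - 0.0
  - 0.0
cohort:
  concentrations:
  - 0.3
  - 3.0
  - 30.0
  n_molecules: 300.0
  duration: 60.0
  frame_time: 0.05
  time_resolution: 0.033
  seed: 1
thresholds:
  e_high: 0.5
  pife_cut: 1.5
  quench_cut: 0.3
  donor_tol: 0.25
  bleach_drop: 0.3
  median_window: 1.0
  min_dwell: 1.0
  flash_cut: 0.4
  transit_cut: 0.45
fits:
  with_intercept: yes
  method: histogram_ls
  assoc_method: event_rate
  min_dwell_frames: 1.0
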