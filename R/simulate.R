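#' Sample a state path from the binding scheme (exact CTMC simulation)
#'
#' Draws one realization of the continuous-time Markov chain defined by a
#' [kinetic_scheme()] at a fixed protein concentration using the Gillespie
#' algorithm: in each state the waiting time is exponential with the total
#' exit rate, and the destination is chosen proportionally to the
#' individual edge rates. Paths start in `S1` (protein is added at t = 0 to
#' bare surface-tethered ssDNA) and are truncated at `duration`.
#'
#' @param scheme A [kinetic_scheme()].
#' @param concentration Free protein concentration (nM, >= 0).
#' @param duration Path length (s, > 0).
#' @param seed Integer seed; the global RNG state is left untouched.
#' @return A tibble of class `state_path` with columns `state`, `t_start`,
#'   `t_end` (seconds), and attributes `concentration`, `duration`, `seed`.
#' @examples
#' sch <- scheme_preset("fig8_12mer")
#' simulate_state_path(sch, concentration = 10, duration = 30, seed = 1)
#' @export
simulate_state_path <- function(scheme, concentration, duration, seed = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    abort("`duration` must be a single positive number of seconds.")
  }
  Q <- rate_matrix(scheme, concentration)
  if (!is.null(seed)) withr::local_seed(seed)

  ## pre-extract exit structure per state
  exits <- lapply(scheme_states, function(s) {
    r <- Q[s, ]
    r <- r[names(r) != s & r > 0]
    list(total = sum(r), to = names(r), rates = unname(r))
  })
  names(exits) <- scheme_states

  n_alloc <- 64L
  st <- character(n_alloc); t0 <- numeric(n_alloc); t1 <- numeric(n_alloc)
  i <- 0L
  cur <- "S1"; now <- 0
  repeat {
    ex <- exits[[cur]]
    leave <- if (ex$total > 0) now + rexp(1L, ex$total) else Inf
    i <- i + 1L
    if (i > n_alloc) {
      n_alloc <- n_alloc * 2L
      length(st) <- n_alloc; length(t0) <- n_alloc; length(t1) <- n_alloc
    }
    st[i] <- cur; t0[i] <- now
    if (leave >= duration) {
      t1[i] <- duration
      break
    }
    t1[i] <- leave
    cur <- if (length(ex$to) == 1L) ex$to else {
      ex$to[sample.int(length(ex$to), 1L, prob = ex$rates)]
    }
    now <- leave
  }
  out <- tibble(state = st[seq_len(i)], t_start = t0[seq_len(i)],
                t_end = t1[seq_len(i)])
  structure(out, class = c("state_path", class(out)),
            concentration = concentration, duration = duration, seed = seed)
}

#' Sample photobleaching times for one state path
#'
#' Draws the donor bleach time (one exponential clock from trace start) and
#' acceptor bleach times, one clock per binding event: the acceptor clock
#' restarts at every `S1 -> S2` or `S1 -> S4` entry because each newly
#' arriving protein carries a fresh dye. A rate of zero yields an infinite
#' bleach time.
#'
#' @param phys A [photophysics()].
#' @param path A `state_path` from [simulate_state_path()].
#' @param seed Integer seed (global RNG untouched).
#' @return A list with `donor` (scalar time, s) and `acceptor`, a tibble
#'   with one row per binding event: `event_start`, `event_end`,
#'   `bleach_time` (absolute time, `Inf` if the dye survives).
#' @export
sample_bleach_times <- function(phys, path, seed = NULL) {
  stopifnot(inherits(phys, "photophysics"))
  if (!is.null(seed)) withr::local_seed(seed)
  donor <- if (phys$donor_bleach > 0) rexp(1L, phys$donor_bleach) else Inf
  ev <- binding_events(path)
  n <- nrow(ev)
  offs <- if (phys$acceptor_bleach > 0 && n > 0) {
    rexp(n, phys$acceptor_bleach)
  } else {
    rep(Inf, n)
  }
  ev$bleach_time <- ev$event_start + offs
  list(donor = donor, acceptor = ev)
}

## contiguous bound (non-S1) runs of a path, one row per binding event
binding_events <- function(path) {
  bound <- path$state != "S1"
  if (!any(bound)) {
    return(tibble(event_start = numeric(), event_end = numeric(),
                  first_state = character()))
  }
  r <- rle(bound)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(event_start = path$t_start[starts[keep]],
         event_end = path$t_end[ends[keep]],
         first_state = path$state[starts[keep]])
}

#' Render a state path into a noisy two-channel camera trajectory
#'
#' Converts a sampled state path into per-frame donor and acceptor
#' intensities the way an EMCCD camera would record them: each frame
#' integrates the emission over its exposure, so the frame value is the
#' time-weighted average of the per-state emission levels over sub-frame
#' occupancy (frames straddling fast transitions show intermediate
#' levels). Binding events entering through `S2` are assigned the
#' PIFE-proximal sub-state `S2b` with probability `p_near`, once per
#' event. After acceptor bleach the acceptor channel falls to background
#' and the donor recovers its unquenched (PIFE-scaled) level; after donor
#' bleach both channels fall to background. Additive Gaussian camera noise
#' is applied last.
#'
#' @param path A `state_path`.
#' @param phys A [photophysics()].
#' @param frame_time Camera integration time per frame (s, > 0).
#' @param seed Integer seed (global RNG untouched).
#' @param noise Logical, apply camera noise (disable for exact oracles).
#' @param bleaching Logical, apply photobleaching.
#' @param molecule_id Identifier stored on the trajectory.
#' @return A tibble of class `trajectory` with columns `frame`, `time_s`
#'   (frame start), `donor`, `acceptor`; attributes `frame_time`,
#'   `concentration`, `molecule_id` and `truth` (the rendered sub-state
#'   intervals, a tibble with `state`, `t_start`, `t_end`).
#' @export
render_trajectory <- function(path, phys, frame_time = 0.05, seed = NULL,
                              noise = TRUE, bleaching = TRUE,
                              molecule_id = "mol_1") {
  stopifnot(inherits(phys, "photophysics"))
  if (!is.numeric(frame_time) || length(frame_time) != 1 || frame_time <= 0) {
    abort("`frame_time` must be a single positive number of seconds.")
  }
  duration <- max(path$t_end)
  n_frames <- floor(duration / frame_time + 1e-9)
  if (n_frames < 1) {
    abort("Path is shorter than one camera frame; nothing to render.")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  ## 1. sub-state assignment, one draw per binding event entering via S2
  ev <- binding_events(path)
  n_ev <- nrow(ev)
  near <- if (n_ev > 0) runif(n_ev) < phys$p_near else logical(0)
  substate <- path$state
  if (n_ev > 0) {
    for (k in seq_len(n_ev)) {
      in_ev <- path$t_start >= ev$event_start[k] - 1e-12 &
        path$t_end <= ev$event_end[k] + 1e-12
      s2 <- in_ev & substate == "S2"
      substate[s2] <- if (near[k]) "S2b" else "S2a"
    }
  }

  ## 2. bleach times (drawn even when bleaching is off, to keep the RNG
  ##    stream layout stable across the flag)
  bl <- sample_bleach_times(phys, path)
  if (!bleaching) {
    bl$donor <- Inf
    if (nrow(bl$acceptor) > 0) bl$acceptor$bleach_time <- Inf
  }

  ## 3. piecewise-constant emission timeline
  em <- phys$emission
  iv <- tibble(t0 = path$t_start, t1 = path$t_end, state = substate)
  ## overlay acceptor bleach: split affected bound intervals
  acc <- bl$acceptor
  if (nrow(acc) > 0) {
    for (k in seq_len(nrow(acc))) {
      tb <- acc$bleach_time[k]
      if (tb >= acc$event_end[k]) next
      hit <- which(iv$t0 < acc$event_end[k] & iv$t1 > acc$event_start[k])
      if (length(hit) == 0) next
      pieces <- lapply(hit, function(j) {
        if (iv$t1[j] <= tb) return(iv[j, ])
        if (iv$t0[j] >= tb) {
          out <- iv[j, ]; out$state <- paste0(out$state, "*"); return(out)
        }
        a <- iv[j, ]; a$t1 <- tb
        b <- iv[j, ]; b$t0 <- tb; b$state <- paste0(b$state, "*")
        bind_rows(a, b)
      })
      iv <- bind_rows(iv[-hit, ], list_rbind(pieces)) |> arrange(.data$t0)
    }
  }
  ## donor bleach truncation
  if (bl$donor < duration) {
    iv <- iv |> filter(.data$t0 < bl$donor)
    iv$t1 <- pmin(iv$t1, bl$donor)
    iv <- bind_rows(iv, tibble(t0 = bl$donor, t1 = duration,
                               state = "DARK"))
  }

  ## emission lookup: "*" marks acceptor-bleached sub-states (donor
  ## recovers the unquenched PIFE-scaled level, acceptor dark)
  base <- setNames(split(em[, c("donor", "acceptor")], em$state),
                   em$state)
  lev <- function(stt) {
    starred <- endsWith(stt, "*")
    root <- sub("\\*$", "", stt)
    d <- vapply(root, function(s) if (s == "DARK") 0 else base[[s]]$donor,
                numeric(1))
    a <- vapply(root, function(s) if (s == "DARK") 0 else base[[s]]$acceptor,
                numeric(1))
    p <- vapply(root, function(s) {
      if (s == "DARK") 0 else em$pife[em$state == s]
    }, numeric(1))
    d[starred] <- p[starred]
    a[starred] <- 0
    cbind(d, a)
  }
  e <- lev(iv$state)

  ## 4. frame integrals via the cumulative emission integral
  brks <- c(iv$t0, duration)
  cumd <- c(0, cumsum(e[, 1] * (iv$t1 - iv$t0)))
  cuma <- c(0, cumsum(e[, 2] * (iv$t1 - iv$t0)))
  Fint <- function(tt, cm, ee) {
    j <- pmin(pmax(findInterval(tt, brks), 1L), nrow(iv))
    cm[j] + ee[j] * (tt - brks[j])
  }
  f0 <- (seq_len(n_frames) - 1) * frame_time
  f1 <- pmin(f0 + frame_time, duration)
  expo <- f1 - f0
  donor <- (Fint(f1, cumd, e[, 1]) - Fint(f0, cumd, e[, 1])) / expo
  acceptor <- (Fint(f1, cuma, e[, 2]) - Fint(f0, cuma, e[, 2])) / expo

  donor <- donor * phys$brightness + phys$background[1]
  acceptor <- acceptor * phys$brightness + phys$background[2]
  if (noise && phys$noise_sigma > 0) {
    donor <- donor + rnorm(n_frames, 0, phys$noise_sigma)
    acceptor <- acceptor + rnorm(n_frames, 0, phys$noise_sigma)
  }

  out <- tibble(frame = seq_len(n_frames), time_s = f0,
                donor = unname(donor), acceptor = unname(acceptor))
  structure(out, class = c("trajectory", class(out)),
            frame_time = frame_time,
            concentration = attr(path, "concentration"),
            molecule_id = molecule_id,
            bleach = bl,
            truth = iv |> rename(t_start = "t0", t_end = "t1"))
}

#' Simulate a cohort of trajectories across a concentration series
#'
#' Runs [simulate_state_path()] and [render_trajectory()] for
#' `n_molecules` molecules at each concentration, with per-molecule seeds
#' derived deterministically from the master seed so the same call always
#' reproduces the same cohort byte-for-byte.
#'
#' @param scheme A [kinetic_scheme()].
#' @param phys A [photophysics()].
#' @param concentrations Numeric vector of protein concentrations (nM).
#' @param n_molecules Molecules per concentration (0 gives a valid empty
#'   cohort).
#' @param duration Trace length (s).
#' @param frame_time Camera integration time (s).
#' @param seed Master seed.
#' @param noise,bleaching Passed to [render_trajectory()].
#' @return A tibble of class `cohort` with columns `molecule_id`,
#'   `concentration_nM`, `frame`, `time_s`, `donor`, `acceptor`; attributes
#'   `frame_time` and `truth` (tibble `molecule_id`, `concentration_nM`,
#'   `state`, `t_start_s`, `t_end_s` of rendered sub-state intervals).
#' @examples
#' coh <- generate_cohort(scheme_preset("fig8_12mer"), photophysics(),
#'                        concentrations = 10, n_molecules = 2,
#'                        duration = 10, seed = 7)
#' dplyr::count(coh, molecule_id)
#' @export
generate_cohort <- function(scheme, phys, concentrations, n_molecules,
                            duration = 60, frame_time = 0.05, seed = 1,
                            noise = TRUE, bleaching = TRUE) {
  if (n_molecules < 0) abort("`n_molecules` must be >= 0.")
  empty <- tibble(molecule_id = character(), concentration_nM = numeric(),
                  frame = integer(), time_s = numeric(),
                  donor = numeric(), acceptor = numeric())
  empty_truth <- tibble(molecule_id = character(),
                        concentration_nM = numeric(), state = character(),
                        t_start_s = numeric(), t_end_s = numeric())
  if (n_molecules == 0 || length(concentrations) == 0) {
    return(structure(empty, class = c("cohort", class(empty)),
                     frame_time = frame_time, truth = empty_truth))
  }
  grid <- tidyr::expand_grid(concentration_nM = concentrations,
                             idx = seq_len(n_molecules))
  grid$molecule_id <- sprintf("c%g_m%04d", grid$concentration_nM, grid$idx)
  grid$seed_path <- derive_seed(seed, 2L * seq_len(nrow(grid)) - 1L)
  grid$seed_render <- derive_seed(seed, 2L * seq_len(nrow(grid)))

  res <- pmap(grid[c("concentration_nM", "molecule_id",
                     "seed_path", "seed_render")],
              function(concentration_nM, molecule_id, seed_path,
                       seed_render) {
    path <- simulate_state_path(scheme, concentration_nM, duration,
                                seed = seed_path)
    traj <- render_trajectory(path, phys, frame_time, seed = seed_render,
                              noise = noise, bleaching = bleaching,
                              molecule_id = molecule_id)
    truth <- attr(traj, "truth")
    list(frames = tibble(molecule_id = molecule_id,
                         concentration_nM = concentration_nM,
                         frame = traj$frame, time_s = traj$time_s,
                         donor = traj$donor, acceptor = traj$acceptor),
         truth = tibble(molecule_id = molecule_id,
                        concentration_nM = concentration_nM,
                        state = truth$state, t_start_s = truth$t_start,
                        t_end_s = truth$t_end))
  })
  frames <- list_rbind(map(res, "frames"))
  truth <- list_rbind(map(res, "truth"))
  structure(frames, class = c("cohort", class(frames)),
            frame_time = frame_time, truth = truth, seed = seed)
}

## deterministic 31-bit sub-seed stream (Lehmer step plus offset)
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1103 * as.double(k)) %% 2147483647)
}

#' True kinetic segments of a simulated path or cohort truth table
#'
#' Collapses rendered sub-state intervals (`S2a`/`S2b`, acceptor-bleach
#' marks) back to the kinetic states `S1, S2, S3, S4` and merges
#' contiguous runs, giving the ground-truth segment list used by the
#' simulator oracles.
#'
#' @param truth A `state_path`, or the `truth` attribute of a cohort
#'   (columns `molecule_id`, `state`, `t_start_s`, `t_end_s`).
#' @return A tibble with `molecule_id` (if present), `state`, `t_start_s`,
#'   `t_end_s`, `dwell_s`, `left_censored`, `right_censored`.
#' @export
true_segments <- function(truth) {
  if (inherits(truth, "state_path")) {
    truth <- tibble(molecule_id = "mol_1", state = truth$state,
                    t_start_s = truth$t_start, t_end_s = truth$t_end)
  }
  truth |>
    mutate(state = pool_state(sub("\\*$", "", .data$state))) |>
    filter(.data$state != "DARK") |>
    group_by(across(any_of(c("molecule_id", "concentration_nM")))) |>
    group_modify(function(d, key) {
      r <- rle(d$state)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      tibble(state = r$values,
             t_start_s = d$t_start_s[starts],
             t_end_s = d$t_end_s[ends]) |>
        mutate(dwell_s = .data$t_end_s - .data$t_start_s,
               left_censored = dplyr::row_number() == 1L,
               right_censored = dplyr::row_number() == dplyr::n())
    }) |>
    ungroup()
}

## photophysical sub-states -> kinetic states
pool_state <- function(s) {
  out <- s
  out[s %in% c("S2a", "S2b")] <- "S2"
  out
}
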