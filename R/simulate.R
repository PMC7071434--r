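#' Subject simulation parameters
#'
#' Parameters controlling inter-subject variability and measurement noise for
#' the synthetic cohort.  Geometry jitter (heart position/orientation) and the
#' overall amplitude scale are subject properties drawn from `seed`; noise and
#' beat-to-beat amplitude jitter are re-drawn per session from `session_seed`.
#'
#' @param seed RNG seed for subject-level draws.
#' @param session_seed RNG seed for session-level draws (noise, beat jitter).
#' @param sources List of `dipole_source` templates (see
#'   [make_beat_template()]); two or more sources make the pooled
#'   chest-to-12-lead map imperfect, as with real hearts.
#' @param heart_origin_jitter 3-vector SD (cm) of the per-subject heart
#'   position offset.
#' @param orientation_jitter_deg SD (degrees) of per-subject heart rotation.
#' @param beat_amplitude_scale Multiplier applied to all source amplitudes;
#'   per-subject log-normal variation is controlled by `amplitude_jitter_sd`.
#' @param amplitude_jitter_sd SD of log subject amplitude scale.
#' @param beat_jitter_sd SD of per-beat log amplitude modulation (each source
#'   independently), emulating beat-to-beat nonstationarity.
#' @param noise List with `white_sd`, `wander_amp`, `wander_hz`,
#'   `powerline_amp`, `powerline_hz` (amplitudes in microvolts).
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(seed = 1L,
                           session_seed = seed,
                           sources = default_sources(),
                           heart_origin_jitter = c(1, 1, 1),
                           orientation_jitter_deg = 8,
                           beat_amplitude_scale = 1,
                           amplitude_jitter_sd = 0.15,
                           beat_jitter_sd = 0.05,
                           noise = default_noise()) {
  if (inherits(sources, "dipole_source")) sources <- list(sources)
  stopifnot(length(heart_origin_jitter) == 3L)
  if (any(heart_origin_jitter < 0) || orientation_jitter_deg < 0 ||
      amplitude_jitter_sd < 0 || beat_jitter_sd < 0 ||
      any(unlist(noise) < 0))
    stop("jitter SDs and noise amplitudes must be >= 0", call. = FALSE)
  structure(list(seed = seed, session_seed = session_seed, sources = sources,
                 heart_origin_jitter = heart_origin_jitter,
                 orientation_jitter_deg = orientation_jitter_deg,
                 beat_amplitude_scale = beat_amplitude_scale,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 beat_jitter_sd = beat_jitter_sd,
                 noise = noise),
            class = "subject_params")
}

#' @rdname subject_params
#' @export
default_noise <- function() {
  list(white_sd = 10, wander_amp = 100, wander_hz = 0.25,
       powerline_amp = 20, powerline_hz = 60)
}

#' @rdname subject_params
#' @details `default_sources()` returns a two-dipole source: the dominant
#'   ventricular dipole plus a smaller secondary dipole displaced a few cm,
#'   with its own morphology.  With independent beat-to-beat modulation the
#'   mixture is not exactly rank-3, so universal reconstruction is
#'   non-trivially imperfect.  `single_dipole_source()` gives the exactly
#'   linear single-dipole mode used by the physics-oracle tests.
#' @export
default_sources <- function() {
  main <- make_beat_template()
  second <- make_beat_template(
    morphology = list(
      QRS2 = list(amp = c(-0.25, 0.20, 0.30), center = 0.285, width = 0.010),
      T2   = list(amp = c(0.10, -0.08, 0.12), center = 0.57, width = 0.060)),
    origin = main$origin + c(4, -2, 3))
  list(main, second)
}

#' @rdname subject_params
#' @export
single_dipole_source <- function() list(make_beat_template())

zero_noise <- function() {
  list(white_sd = 0, wander_amp = 0, wander_hz = 0.25,
       powerline_amp = 0, powerline_hz = 60)
}

#' Simulate one multichannel recording
#'
#' Generates the 35 chest-grid channels plus limb (LA, RA, LL) and precordial
#' electrode potentials for one subject/session: dipole forward model, then
#' configured additive noise (white, baseline wander, powerline).  Identical
#' `params` give identical output.  With all noise amplitudes 0 and a single
#' dipole, every channel is an exact linear combination of the three
#' dipole-moment components.
#'
#' @param params A [subject_params()].
#' @param torso A [torso_model()].
#' @param duration_s Recording length (s, > 0).
#' @param fs Sampling rate (Hz, > 0); the study design samples at 250 Hz.
#' @param subject_id,session_id Identifiers stored in the recording.
#' @return Object of class `mc_recording`: list with `fs`, `chest` (35 x T,
#'   microvolts), `limb` (LA/RA/LL x T), `precordial` (V1..V6 x T),
#'   `subject_id`, `session_id`.
#' @export
simulate_subject <- function(params, torso = torso_model(),
                             duration_s = 120, fs = 250,
                             subject_id = 1L, session_id = 1L) {
  stopifnot(inherits(params, "subject_params"), inherits(torso, "torso_model"))
  if (duration_s <= 0 || fs <= 0)
    stop("`duration_s` and `fs` must be positive", call. = FALSE)
  t <- seq(0, by = 1 / fs, length.out = round(duration_s * fs))

  # subject-level geometry draws
  subj <- with_seed(params$seed, {
    rot <- random_rotation(params$orientation_jitter_deg)
    shift <- stats::rnorm(3L) * params$heart_origin_jitter
    amp <- params$beat_amplitude_scale *
      exp(stats::rnorm(1L) * params$amplitude_jitter_sd)
    list(rot = rot, shift = shift, amp = amp)
  })
  sources <- lapply(params$sources, function(src) {
    src$origin <- src$origin + subj$shift
    src$orientation <- subj$rot %*% src$orientation
    src$morphology <- lapply(src$morphology, function(comp) {
      comp$amp <- comp$amp * subj$amp; comp
    })
    src
  })

  # session-level draws: per-beat amplitude modulation + noise
  n_ch <- nrow(torso$electrode_positions)
  max_beats <- max(vapply(sources, function(s)
    ceiling(duration_s * s$heart_rate / 60) + 1L, numeric(1)))
  sess <- with_seed(params$session_seed, {
    beat_logs <- lapply(seq_along(sources), function(i)
      stats::rnorm(max_beats) * params$beat_jitter_sd)
    phases <- matrix(stats::runif(n_ch * 2L, 0, 2 * pi), n_ch, 2L)
    white <- if (params$noise$white_sd > 0)
      matrix(stats::rnorm(n_ch * length(t), sd = params$noise$white_sd),
             n_ch, length(t)) else NULL
    list(beat_logs = beat_logs, phases = phases, white = white)
  })
  beat_scales <- if (params$beat_jitter_sd > 0) {
    lapply(sess$beat_logs, function(lg)
      function(k) exp(lg[pmin(k + 1L, length(lg))]))
  } else NULL

  pot <- potential_matrix(sources, torso, t, beat_scales = beat_scales)

  nz <- params$noise
  if (nz$wander_amp > 0)
    pot <- pot + nz$wander_amp *
      sin(outer(sess$phases[, 1L], rep(1, length(t))) +
            outer(rep(2 * pi * nz$wander_hz, n_ch), t))
  if (nz$powerline_amp > 0)
    pot <- pot + nz$powerline_amp *
      sin(outer(sess$phases[, 2L], rep(1, length(t))) +
            outer(rep(2 * pi * nz$powerline_hz, n_ch), t))
  if (!is.null(sess$white)) pot <- pot + sess$white

  n_grid <- torso$grid$n_cols * torso$grid$n_rows
  structure(list(fs = fs,
                 chest = pot[seq_len(n_grid), , drop = FALSE],
                 limb = pot[c("LA", "RA", "LL"), , drop = FALSE],
                 precordial = pot[paste0("V", 1:6), , drop = FALSE],
                 subject_id = subject_id, session_id = session_id),
            class = "mc_recording")
}

#' @export
print.mc_recording <- function(x, ...) {
  cat(sprintf("<mc_recording subject %s session %s: %d+%d+%d channels, %d samples @ %g Hz>\n",
              x$subject_id, x$session_id, nrow(x$chest), nrow(x$limb),
              nrow(x$precordial), ncol(x$chest), x$fs))
  invisible(x)
}

#' Simulate a cohort of recordings
#'
#' Draws per-subject geometry seeds and per-session noise seeds
#' deterministically from `master_seed`, then simulates
#' `n_subjects * n_sessions` recordings.  A subject's heart geometry is
#' identical across their sessions; noise and beat-to-beat modulation differ.
#' The study design is 14 subjects recorded twice.
#'
#' @param n_subjects,n_sessions Cohort dimensions (each >= 1).
#' @param params_template A [subject_params()] whose seeds are overwritten
#'   per subject/session.
#' @param master_seed Integer master seed.
#' @inheritParams simulate_subject
#' @return List of `mc_recording` objects, ordered subject-major.
#' @export
simulate_cohort <- function(n_subjects = 14L, n_sessions = 2L,
                            params_template = subject_params(),
                            master_seed = 1L,
                            torso = torso_model(),
                            duration_s = 120, fs = 250) {
  stopifnot(n_subjects >= 1, n_sessions >= 1)
  seeds <- derive_seeds(master_seed, n_subjects * (n_sessions + 1L))
  subj_seeds <- seeds[seq_len(n_subjects)]
  sess_seeds <- matrix(seeds[-seq_len(n_subjects)], n_subjects, n_sessions)
  out <- vector("list", n_subjects * n_sessions)
  k <- 0L
  for (i in seq_len(n_subjects)) {
    for (j in seq_len(n_sessions)) {
      p <- params_template
      p$seed <- subj_seeds[i]
      p$session_seed <- sess_seeds[i, j]
      k <- k + 1L
      out[[k]] <- simulate_subject(p, torso, duration_s, fs,
                                   subject_id = i, session_id = j)
    }
  }
  out
}
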