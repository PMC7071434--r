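# Shared fixtures: all synthetic, generated in code at test time.

# Exactness regime: one dipole, no noise, no inter-subject variation.
oracle_params <- function(seed = 1L, session_seed = seed) {
  subject_params(seed = seed, session_seed = session_seed,
                 sources = single_dipole_source(),
                 heart_origin_jitter = c(0, 0, 0),
                 orientation_jitter_deg = 0,
                 amplitude_jitter_sd = 0, beat_jitter_sd = 0,
                 noise = list(white_sd = 0, wander_amp = 0, wander_hz = 0.25,
                              powerline_amp = 0, powerline_hz = 60))
}

oracle_config <- function(n_subjects = 3L) {
  study_config(n_subjects = n_subjects, fs = 100, duration_s = 20,
               source_mode = "single", noise_scale = 0, jitter_scale = 0,
               segment_length_s = 6, edge_trim_s = 1,
               families = c("square5", "square10", "triangle"),
               model_types = "mlr")
}

# Desk-scale realistic study: 14 subjects x 2 sessions, two-dipole sources
# with geometry jitter and noise, 100 Hz, 10 s segments, 5-seed ensembles.
scaled_config <- function() {
  study_config(n_subjects = 14L, fs = 100, duration_s = 40,
               segment_length_s = 10,
               families = c("square5", "square10", "triangle"),
               model_types = c("mlr", "ann"),
               ann_max_epochs = 120L, edge_trim_s = 2)
}

# The scaled study takes minutes; compute it once per test run.
.study_cache <- new.env(parent = emptyenv())

get_scaled_study <- function() {
  if (is.null(.study_cache$res))
    .study_cache$res <- run_study(scaled_config())
  .study_cache$res
}

make_flat_recording <- function(limb, precordial = NULL, fs = 100) {
  T <- ncol(limb)
  if (is.null(precordial)) {
    precordial <- matrix(0, 6, T)
    rownames(precordial) <- paste0("V", 1:6)
  }
  structure(list(fs = fs, chest = matrix(0, 35, T,
                                         dimnames = list(as.character(1:35),
                                                         NULL)),
                 limb = limb, precordial = precordial,
                 subject_id = 1L, session_id = 1L),
            class = "mc_recording")
}
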