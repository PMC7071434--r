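#' Study configuration
#'
#' All knobs of the end-to-end study in one serializable object: cohort size
#' and simulation parameters, filtering, segment extraction, the combination
#' families to score, model types, ANN hyperparameters and ensemble seeds,
#' and evaluation options.  Every random draw in a run is controlled by the
#' seeds stored here, so a config determines its results bit-for-bit.
#'
#' The defaults mirror the study design: 14 subjects recorded twice at
#' 250 Hz for 120 s, 0.5-35 Hz second-order Butterworth (zero phase), 20 s
#' segments merged per session, the three patch-shape families (24 + 15 + 60
#' combinations), and a 5-seed ANN ensemble.  The exhaustive all-combination
#' scan (C(35,4) = 52,360) is supported for the MLR via
#' `families = "all"`, but is minutes of compute and off by default.
#'
#' @param n_subjects,n_sessions Cohort dimensions.
#' @param fs Sampling rate (Hz).
#' @param duration_s Recording duration (s).
#' @param master_seed Cohort seed.
#' @param source_mode `"multi"` (realistic, imperfectly reconstructable) or
#'   `"single"` (one dipole, exactly linear; the physics-oracle mode).
#' @param noise_scale Multiplier on the default noise amplitudes (0 disables
#'   noise; `source_mode = "single"` with 0 gives the exactness regime).
#' @param jitter_scale Multiplier on the default inter-subject geometry
#'   jitter SDs.
#' @param filter_low_hz,filter_high_hz,filter_order Bandpass settings.
#' @param segment_length_s Segment length for the merges (s).
#' @param train_segment_seed,test_segment_seed Segment start-point seeds.
#' @param families Character vector from `"square5"`, `"square10"`,
#'   `"triangle"`, `"all"`.
#' @param model_types Character vector from `"mlr"`, `"ann"`.
#' @param ann_hidden,ann_max_epochs,ann_lr_init,ann_tol,ann_patience,ann_output
#'   ANN hyperparameters (see [ann_hyperparams()]).
#' @param ensemble_seeds Five distinct member seeds.
#' @param edge_trim_s Seconds trimmed from segment ends before scoring.
#' @param robustness_include_self Include the unshifted position in the
#'   robustness average.
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_subjects = 14L, n_sessions = 2L, fs = 250,
                         duration_s = 120, master_seed = 1L,
                         source_mode = c("multi", "single"),
                         noise_scale = 1, jitter_scale = 1,
                         filter_low_hz = 0.5, filter_high_hz = 35,
                         filter_order = 2,
                         segment_length_s = 20,
                         train_segment_seed = 101L,
                         test_segment_seed = 202L,
                         families = c("square5", "square10", "triangle"),
                         model_types = c("mlr", "ann"),
                         ann_hidden = 6L, ann_max_epochs = 2000L,
                         ann_lr_init = 0.1, ann_tol = 1e-8,
                         ann_patience = 10L, ann_output = "linear",
                         ensemble_seeds = c(11L, 22L, 33L, 44L, 55L),
                         edge_trim_s = 2,
                         robustness_include_self = FALSE) {
  source_mode <- match.arg(source_mode)
  families <- match.arg(families,
                        c("square5", "square10", "triangle", "all"),
                        several.ok = TRUE)
  model_types <- match.arg(model_types, c("mlr", "ann"), several.ok = TRUE)
  stopifnot(n_subjects >= 1, n_sessions >= 2, fs > 0, duration_s > 0,
            noise_scale >= 0, jitter_scale >= 0,
            segment_length_s > 2 * edge_trim_s)
  structure(as.list(environment()), class = "study_config")
}

config_subject_params <- function(config) {
  nz <- default_noise()
  for (f in c("white_sd", "wander_amp", "powerline_amp"))
    nz[[f]] <- nz[[f]] * config$noise_scale
  subject_params(
    sources = if (config$source_mode == "single") single_dipole_source()
              else default_sources(),
    heart_origin_jitter = c(1, 1, 1) * config$jitter_scale,
    orientation_jitter_deg = 8 * config$jitter_scale,
    amplitude_jitter_sd = 0.15 * config$jitter_scale,
    beat_jitter_sd = if (config$source_mode == "single") 0 else 0.05,
    noise = nz)
}

config_families <- function(config, grid = grid_layout()) {
  fams <- list()
  if ("square5" %in% config$families)
    fams$square5 <- enumerate_squares(5, grid)
  if ("square10" %in% config$families)
    fams$square10 <- enumerate_squares(10, grid)
  if ("triangle" %in% config$families)
    fams$triangle <- enumerate_triangles(grid)
  if ("all" %in% config$families)
    fams$all <- enumerate_all(grid)
  fams
}

#' Run the full reconstruction study
#'
#' Executes simulate -> filter -> segment/merge -> enumerate -> fit -> score
#' -> select -> robustness on a synthetic cohort (or a user-supplied list of
#' recordings).  Session 1 recordings form the training merge, session 2 the
#' test merge, exactly one universal model per (model type, combination).
#'
#' @param config A [study_config()].
#' @param recordings Optional pre-loaded list of `mc_recording`s (bypasses
#'   simulation); must carry `subject_id`/`session_id` in 1..n.
#' @param progress Print per-stage progress lines.
#' @return Object of class `study_results`: the config, the grid, per-family
#'   score tables, fitted selections per (model, family, approach),
#'   robustness maps for the triangle family, shape comparisons, the
#'   position ANOVA at the minCC-best triangle, and Bland-Altman summaries.
#' @export
run_study <- function(config = study_config(), recordings = NULL,
                      progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  grid <- grid_layout()
  torso <- torso_model(grid)
  say <- function(...) if (progress) message(sprintf(...))

  say("simulating cohort: %d subjects x %d sessions",
      config$n_subjects, config$n_sessions)
  if (is.null(recordings))
    recordings <- simulate_cohort(config$n_subjects, config$n_sessions,
                                  config_subject_params(config),
                                  master_seed = config$master_seed,
                                  torso = torso,
                                  duration_s = config$duration_s,
                                  fs = config$fs)

  say("filtering %d recordings", length(recordings))
  recordings <- lapply(recordings, bandpass,
                       low_hz = config$filter_low_hz,
                       high_hz = config$filter_high_hz,
                       order = config$filter_order)

  sess <- vapply(recordings, function(r) r$session_id, numeric(1L))
  train <- extract_and_merge(recordings[sess == 1L],
                             spec_seed = config$train_segment_seed,
                             length_s = config$segment_length_s)
  test <- extract_and_merge(recordings[sess == 2L],
                            spec_seed = config$test_segment_seed,
                            length_s = config$segment_length_s)

  fams <- config_families(config, grid)
  hp <- ann_hyperparams(hidden = config$ann_hidden,
                        max_epochs = config$ann_max_epochs,
                        lr_init = config$ann_lr_init,
                        tol = config$ann_tol,
                        patience = config$ann_patience,
                        output = config$ann_output)

  scored <- list(); selections <- list(); fits <- list()
  for (mt in config$model_types) {
    for (fam in names(fams)) {
      if (fam == "all" && mt == "ann") next  # ANN runs shape families only
      say("fitting %s on %s (%d combinations)", mt, fam, length(fams[[fam]]))
      ft <- lapply(fams[[fam]], function(cb) {
        tryCatch(
          fit_combination(train, cb, method = mt,
                          seeds = config$ensemble_seeds, hyperparams = hp),
          error = function(e) stop("stage fit failed for combination {",
                                   combination_key(cb), "}: ",
                                   conditionMessage(e), call. = FALSE))
      })
      sc <- lapply(ft, score_combination, test = test,
                   edge_trim_s = config$edge_trim_s)
      fits[[mt]][[fam]] <- ft
      scored[[mt]][[fam]] <- sc
      for (ap in c("meanCC", "minCC"))
        selections[[mt]][[fam]][[ap]] <- select_best(sc, ap)
    }
  }

  robustness <- list()
  if ("triangle" %in% names(fams)) {
    for (mt in config$model_types) {
      tri <- scored[[mt]][["triangle"]]
      for (ap in c("meanCC", "minCC"))
        robustness[[mt]][[ap]] <- robustness_map(
          fams$triangle,
          vapply(tri, selection_score, numeric(1L), approach = ap),
          grid = grid, include_self = config$robustness_include_self)
    }
  }

  comparisons <- list()
  fam_shapes <- intersect(names(fams), c("square5", "square10", "triangle"))
  for (mt in config$model_types) {
    if (length(fam_shapes) < 2L) break
    pairs <- utils::combn(fam_shapes, 2L)
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
      a <- selections[[mt]][[pairs[1L, k]]][["meanCC"]]$scores$per_subject
      b <- selections[[mt]][[pairs[2L, k]]][["meanCC"]]$scores$per_subject
      cmp_cc <- compare_shapes(a$cc, b$cc)
      cmp_rmse <- compare_shapes(a$rmse, b$rmse)
      data.frame(model = mt, shape_a = pairs[1L, k], shape_b = pairs[2L, k],
                 p_cc = cmp_cc$p_value, p_rmse = cmp_rmse$p_value)
    })
    comparisons[[mt]] <- do.call(rbind, rows)
  }

  anova_tab <- NULL
  if ("triangle" %in% names(fams)) {
    mt <- config$model_types[1L]
    base <- selections[[mt]][["triangle"]][["minCC"]]$combination
    anova_tab <- tryCatch(
      suppressWarnings(   # aov warns on essentially perfect oracle fits
        position_anova(scored[[mt]][["triangle"]], base, grid = grid)),
      error = function(e) NULL)
  }

  bland <- list()
  ref_test <- derive_12lead(test)$leads
  for (mt in config$model_types) {
    for (fam in fam_shapes) {
      sel <- selections[[mt]][[fam]][["minCC"]]
      keys <- vapply(fams[[fam]], combination_key, character(1L))
      fit <- fits[[mt]][[fam]][[match(combination_key(sel$combination),
                                      keys)]]
      pred <- reconstruct_leads(fit, test)
      bland[[mt]][[fam]] <- bland_altman(as.numeric(ref_test),
                                         as.numeric(pred))
    }
  }

  structure(list(config = config, grid = grid,
                 train = train, test = test,
                 train_segments = train$segments,
                 test_segments = test$segments,
                 families = fams, fits = fits,
                 scored = scored, selections = selections,
                 robustness = robustness, comparisons = comparisons,
                 position_anova = anova_tab, bland_altman = bland),
            class = "study_results")
}

#' Summarize selections as a shape-by-approach table
#'
#' One row per (model, family, approach): the selected combination, its
#' selection score, the subject-mean CC and RMSE over all leads at that
#' combination (the shape table of the study).
#'
#' @param results A `study_results`.
#' @return Data frame.
#' @export
selection_table <- function(results) {
  rows <- list()
  for (mt in names(results$selections)) {
    for (fam in names(results$selections[[mt]])) {
      for (ap in names(results$selections[[mt]][[fam]])) {
        sel <- results$selections[[mt]][[fam]][[ap]]
        ps <- sel$scores$per_subject
        rows[[length(rows) + 1L]] <- data.frame(
          model = mt, family = fam, approach = ap,
          combination = combination_key(sel$combination),
          score = sel$score, mean_cc = mean(ps$cc),
          median_cc = stats::median(ps$cc), mean_rmse = mean(ps$rmse),
          mean_r2 = mean(ps$r2))
      }
    }
  }
  do.call(rbind, rows)
}

#' Write the study report
#'
#' Emits CSV tables (selection table, per-lead scores at each selected
#' combination, robustness maps, shape comparisons, position ANOVA), a JSON
#' summary, and a manifest listing every written file with its MD5 checksum.
#'
#' @param results A `study_results`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  sel_tab <- selection_table(results)
  put(sel_tab, "selection_table.csv")
  for (mt in names(results$selections)) {
    for (fam in names(results$selections[[mt]])) {
      for (ap in names(results$selections[[mt]][[fam]])) {
        sel <- results$selections[[mt]][[fam]][[ap]]
        put(sel$scores$per_lead,
            sprintf("per_lead_%s_%s_%s.csv", mt, fam, ap))
      }
    }
  }
  for (mt in names(results$robustness))
    for (ap in names(results$robustness[[mt]]))
      put(as.data.frame(results$robustness[[mt]][[ap]]),
          sprintf("robustness_%s_%s.csv", mt, ap))
  for (mt in names(results$comparisons))
    put(results$comparisons[[mt]], sprintf("shape_comparison_%s.csv", mt))
  if (!is.null(results$position_anova))
    put(results$position_anova, "position_anova.csv")
  summary <- list(
    selection = sel_tab,
    bland_altman = lapply(results$bland_altman, function(x)
      lapply(x, unclass)))
  jp <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, jp, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  files <- c(files, jp)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
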