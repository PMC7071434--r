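#' Fit a universal reconstruction model for one electrode combination
#'
#' Computes the chest-lead triplet on the training merge, standardizes it
#' (statistics kept for reuse on test data), derives the 12 reference leads,
#' and fits the requested model: MLR targets stay in microvolts; the ANN
#' ensemble standardizes targets internally and inverts its predictions.
#'
#' @param train A `merged_recording` (training sessions).
#' @param combination An `electrode_combination`.
#' @param method `"mlr"` or `"ann"`.
#' @param seeds Ensemble seeds (ANN only).
#' @param hyperparams [ann_hyperparams()] (ANN only).
#' @return Object of class `reconstruction_fit`: `combination`, `method`,
#'   `cl_stats` (training standardization), `model`.
#' @export
fit_combination <- function(train, combination, method = c("mlr", "ann"),
                            seeds = 1:5, hyperparams = ann_hyperparams()) {
  method <- match.arg(method)
  cl <- compute_chest_leads(train, combination)$cl
  std <- standardize(cl)
  leads <- derive_12lead(train)$leads
  model <- switch(method,
    mlr = fit_mlr(std$x, leads),
    ann = fit_ensemble(std$x, leads, seeds = seeds,
                       hyperparams = hyperparams))
  structure(list(combination = combination, method = method,
                 cl_stats = list(center = std$center, scale = std$scale),
                 model = model),
            class = "reconstruction_fit")
}

#' Reconstruct the 12 leads on new data with a fitted model
#'
#' @param fit A `reconstruction_fit`.
#' @param recording A `merged_recording` or `mc_recording` with chest
#'   channels.
#' @return 12 x T matrix of reconstructed leads (microvolts).
#' @export
reconstruct_leads <- function(fit, recording) {
  cl <- compute_chest_leads(recording, fit$combination)$cl
  z <- standardize(cl, stats = fit$cl_stats)$x
  stats::predict(fit$model, z)
}

#' Score a fitted combination on the test merge
#'
#' CC, RMSE and R-squared are computed per subject and per lead on each
#' subject's test segment, with `edge_trim_s` seconds dropped at both ends of
#' every segment (filter/merge transients bias the correlation).  Per-lead
#' aggregates include the subject-mean and median CC, mean RMSE and R-squared,
#' and ICC(2,1) over the pooled (time sample) x (reference, reconstruction)
#' table.
#'
#' @param fit A `reconstruction_fit`.
#' @param test A `merged_recording` with a `segments` table.
#' @param edge_trim_s Seconds excluded at each segment end.
#' @return Object of class `lead_scores`: `per_subject` (subject, lead, cc,
#'   rmse, r2), `per_lead` (lead, mean_cc, median_cc, mean_rmse, mean_r2,
#'   icc), plus `combination` and `method`.
#' @export
score_combination <- function(fit, test, edge_trim_s = 2) {
  if (is.null(test$segments))
    stop("`test` must be a merged recording with a segments table",
         call. = FALSE)
  pred <- reconstruct_leads(fit, test)
  ref <- derive_12lead(test)$leads
  trim <- as.integer(round(edge_trim_s * test$fs))
  leads <- lead_names_12()
  rows <- list()
  keep_idx <- integer(0)
  for (i in seq_len(nrow(test$segments))) {
    s <- test$segments$start_sample[i] + trim
    e <- test$segments$end_sample[i] - trim
    if (e - s + 1L < 8L)
      stop("segment too short after edge trimming", call. = FALSE)
    keep_idx <- c(keep_idx, s:e)
    for (ld in leads) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = test$segments$subject_id[i], lead = ld,
        cc = pearson_cc(ref[ld, s:e], pred[ld, s:e]),
        rmse = rmse(ref[ld, s:e], pred[ld, s:e]),
        r2 = r_square(ref[ld, s:e], pred[ld, s:e]))
    }
  }
  per_subject <- do.call(rbind, rows)
  per_lead <- do.call(rbind, lapply(leads, function(ld) {
    d <- per_subject[per_subject$lead == ld, ]
    data.frame(lead = ld,
               mean_cc = mean(d$cc), median_cc = stats::median(d$cc),
               mean_rmse = mean(d$rmse), mean_r2 = mean(d$r2),
               icc = icc_2_1(cbind(ref[ld, keep_idx], pred[ld, keep_idx])))
  }))
  rownames(per_lead) <- NULL
  structure(list(per_subject = per_subject, per_lead = per_lead,
                 combination = fit$combination, method = fit$method),
            class = "lead_scores")
}

#' Selection score of a combination under an approach
#'
#' `meanCC`: mean of the 12 per-lead subject-mean CCs.  `minCC`: minimum of
#' the same 12 values (subjects averaged first, then the worst lead).  By
#' construction the minCC score never exceeds the meanCC score.
#'
#' @param scores A `lead_scores`.
#' @param approach `"meanCC"` or `"minCC"`.
#' @return Scalar score.
#' @export
selection_score <- function(scores, approach = c("meanCC", "minCC")) {
  approach <- match.arg(approach)
  v <- scores$per_lead$mean_cc
  if (approach == "meanCC") mean(v) else min(v)
}

#' Select the best combination under an approach
#'
#' Returns the combination with the highest selection score; ties are broken
#' deterministically by the lexicographically lowest id quadruple.
#'
#' @param scored Non-empty list of `lead_scores`.
#' @param approach `"meanCC"` or `"minCC"`.
#' @return Object of class `selection_result`: `combination`, `approach`,
#'   `score`, `scores` (the winning `lead_scores`).
#' @export
select_best <- function(scored, approach = c("meanCC", "minCC")) {
  approach <- match.arg(approach)
  if (length(scored) == 0L)
    stop("no scored combinations to select from", call. = FALSE)
  vals <- vapply(scored, selection_score, numeric(1L), approach = approach)
  best <- which(vals == max(vals))
  if (length(best) > 1L) {
    keys <- vapply(scored[best], function(s)
      paste(sprintf("%03d", s$combination$ids), collapse = ""), character(1L))
    best <- best[order(keys)][1L]
  } else best <- best[1L]
  structure(list(combination = scored[[best]]$combination,
                 approach = approach, score = vals[best],
                 scores = scored[[best]]),
            class = "selection_result")
}

#' Positional robustness map
#'
#' For each combination, averages a selection metric over its one-step
#' shifted variants (up, down, left, right); a shifted variant contributes
#' only when it stays on the grid and is itself present in `combinations`
#' (for the triangle family every on-grid shift is).  Combinations touching
#' the grid edge therefore average fewer than four neighbours.  The unshifted
#' position is excluded by default (`include_self`).
#'
#' @param combinations List of `electrode_combination` (typically the 60
#'   triangles).
#' @param scores Numeric vector of the selection metric, aligned with
#'   `combinations`.
#' @param grid A [grid_layout()].
#' @param include_self Also average the combination's own score.
#' @return Data frame of class `robustness_map`: `key`, ids, `shape_tag`,
#'   `orientation`, `score`, `robust_score`, `n_shifts`, `directions`.
#' @export
robustness_map <- function(combinations, scores, grid = grid_layout(),
                           include_self = FALSE) {
  stopifnot(length(combinations) == length(scores))
  keys <- vapply(combinations, combination_key, character(1L))
  lookup <- stats::setNames(scores, keys)
  out <- lapply(seq_along(combinations), function(i) {
    cb <- combinations[[i]]
    vals <- numeric(0); dirs <- character(0)
    for (d in c("up", "down", "left", "right")) {
      sh <- shift_combination(cb, d, grid)
      if (is.null(sh)) next
      k <- combination_key(sh)
      if (!k %in% keys) next
      vals <- c(vals, lookup[[k]]); dirs <- c(dirs, d)
    }
    if (include_self) vals <- c(vals, scores[i])
    data.frame(key = keys[i], id1 = cb$ids[1], id2 = cb$ids[2],
               id3 = cb$ids[3], id4 = cb$ids[4], shape_tag = cb$shape_tag,
               orientation = cb$orientation, score = scores[i],
               robust_score = if (length(vals)) mean(vals) else NA_real_,
               n_shifts = length(dirs),
               directions = paste(dirs, collapse = "+"))
  })
  res <- do.call(rbind, out)
  class(res) <- c("robustness_map", class(res))
  res
}

#' One-way ANOVA of per-subject CCs across a base position and its shifts
#'
#' Builds the position group set (the base combination plus its valid shifts
#' in `directions`), pulls the per-subject CCs per lead from the scored
#' combinations, and runs [compare_orientations()].
#'
#' @param scored List of `lead_scores` covering the base and its shifts.
#' @param base An `electrode_combination`.
#' @param directions Shift directions to include.
#' @param grid A [grid_layout()].
#' @return The [compare_orientations()] table, plus attribute `positions`.
#' @export
position_anova <- function(scored, base,
                           directions = c("up", "left", "right"),
                           grid = grid_layout()) {
  keys <- vapply(scored, function(s) combination_key(s$combination),
                 character(1L))
  positions <- list(base = base)
  for (d in directions) {
    sh <- shift_combination(base, d, grid)
    if (!is.null(sh) && combination_key(sh) %in% keys)
      positions[[d]] <- sh
  }
  if (length(positions) < 2L)
    stop("no valid shifted positions found among the scored combinations",
         call. = FALSE)
  tab <- do.call(rbind, lapply(names(positions), function(nm) {
    k <- combination_key(positions[[nm]])
    d <- scored[[match(k, keys)]]$per_subject
    data.frame(lead = d$lead, position = nm, score = d$cc)
  }))
  res <- compare_orientations(tab)
  attr(res, "positions") <- vapply(positions, combination_key, character(1L))
  res
}
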