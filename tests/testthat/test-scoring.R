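# small physics-oracle study pieces shared within this file
make_oracle_merges <- function(n_subjects = 3) {
  coh <- simulate_cohort(n_subjects, 2, oracle_params(), master_seed = 13,
                         duration_s = 16, fs = 100)
  coh <- lapply(coh, bandpass)
  sess <- vapply(coh, function(r) r$session_id, numeric(1))
  list(train = extract_and_merge(coh[sess == 1], 5, length_s = 6),
       test = extract_and_merge(coh[sess == 2], 6, length_s = 6))
}

fake_scores <- function(ids, per_lead_cc) {
  structure(list(
    per_subject = NULL,
    per_lead = data.frame(lead = lead_names_12(), mean_cc = per_lead_cc),
    combination = structure(list(ids = ids, shape_tag = "free",
                                 orientation = NA_integer_),
                            class = "electrode_combination"),
    method = "mlr"), class = "lead_scores")
}

test_that("scoring a perfect linear reconstruction gives CC of 1", {
  d <- make_oracle_merges()
  cb <- enumerate_squares(10)[[8]]
  fit <- fit_combination(d$train, cb, method = "mlr")
  sc <- score_combination(fit, d$test, edge_trim_s = 1)
  expect_true(all(sc$per_subject$cc > 1 - 1e-6))
  expect_true(all(sc$per_lead$mean_cc > 1 - 1e-6))
  expect_true(all(sc$per_lead$icc > 1 - 1e-4))
  expect_lt(max(sc$per_subject$rmse), 1e-3)
  expect_equal(selection_score(sc, "meanCC"), 1, tolerance = 1e-6)
})

test_that("chest-lead reference choice does not affect reconstruction CC", {
  # fitting on the lead space spanned by any common reference electrode
  # gives identical reconstructions; compare the default (lowest id) against
  # a manual triplet referenced to the highest id
  d <- make_oracle_merges()
  ids <- c(9, 13, 19, 23)
  fit <- fit_combination(d$train, ids, method = "mlr")
  sc <- score_combination(fit, d$test, edge_trim_s = 1)

  alt_cl <- function(rec) {
    rec$chest[c(9, 13, 19), , drop = FALSE] -
      matrix(rec$chest[23, ], 3, ncol(rec$chest), byrow = TRUE)
  }
  std <- standardize(alt_cl(d$train))
  leads <- derive_12lead(d$train)$leads
  alt_fit <- fit_mlr(std$x, leads)
  pred_alt <- predict(alt_fit, standardize(alt_cl(d$test), stats = std)$x)
  ref <- derive_12lead(d$test)$leads
  s <- d$test$segments$start_sample[1] + 100
  e <- d$test$segments$end_sample[1] - 100
  for (ld in c("I", "aVL", "V2"))
    expect_equal(pearson_cc(ref[ld, s:e], pred_alt[ld, s:e]),
                 sc$per_subject$cc[sc$per_subject$subject_id == 1 &
                                     sc$per_subject$lead == ld],
                 tolerance = 1e-6)
})

test_that("controlled corruption of one lead only hurts that lead", {
  d <- make_oracle_merges()
  cb <- enumerate_squares(10)[[3]]
  fit <- fit_combination(d$train, cb, method = "mlr")
  # replace the V5 reference electrode on the test side by pure noise: the
  # V5 score collapses, every other lead is untouched
  set.seed(83)
  d$test$precordial["V5", ] <- rnorm(ncol(d$test$precordial), sd = 300)
  sc <- score_combination(fit, d$test, edge_trim_s = 1)
  pl <- sc$per_lead
  expect_lt(abs(pl$mean_cc[pl$lead == "V5"]), 0.25)
  expect_true(all(pl$mean_cc[pl$lead != "V5"] > 1 - 1e-6))
})

test_that("selection maximizes the approach score with stable tie-breaks", {
  a <- fake_scores(c(1, 2, 6, 7), c(rep(0.95, 11), 0.50))   # high mean, low min
  b <- fake_scores(c(2, 3, 7, 8), c(rep(0.90, 11), 0.80))   # lower mean, higher min
  expect_equal(select_best(list(a, b), "meanCC")$combination$ids, a$combination$ids)
  expect_equal(select_best(list(a, b), "minCC")$combination$ids, b$combination$ids)

  # single combination wins under both approaches
  expect_equal(select_best(list(b), "meanCC")$combination$ids, b$combination$ids)
  expect_equal(select_best(list(b), "minCC")$combination$ids, b$combination$ids)

  # exact tie resolved by lowest id tuple
  tie <- fake_scores(c(5, 6, 10, 11), a$per_lead$mean_cc)
  expect_equal(select_best(list(tie, a), "meanCC")$combination$ids,
               a$combination$ids)

  # argmax agrees with an independent re-scan
  set.seed(79)
  pool <- lapply(1:20, function(i)
    fake_scores(sort(sample(35, 4)), runif(12, 0.3, 0.99)))
  best <- select_best(pool, "meanCC")
  scan <- which.max(vapply(pool, function(s) mean(s$per_lead$mean_cc),
                           numeric(1)))
  expect_equal(best$combination$ids, pool[[scan]]$combination$ids)
  expect_error(select_best(list(), "meanCC"), "no scored")

  # minCC score never exceeds meanCC score
  for (s in pool)
    expect_lte(selection_score(s, "minCC"), selection_score(s, "meanCC"))
})

test_that("robustness maps average exactly the on-grid shifted neighbours", {
  tri <- enumerate_triangles()
  # uniform injected scores -> constant map
  rm_u <- robustness_map(tri, rep(0.8, 60))
  expect_true(all(abs(rm_u$robust_score - 0.8) < 1e-12))

  # interior triangles average 4 shifts, boundary ones fewer
  interior <- vapply(tri, function(cb) {
    pos <- t(vapply(cb$ids, function(i) grid_position(i), integer(2)))
    all(pos[, 1] > 1 & pos[, 1] < 7 & pos[, 2] > 1 & pos[, 2] < 5)
  }, logical(1))
  rm_s <- robustness_map(tri, seq(0, 1, length.out = 60))
  expect_true(all(rm_s$n_shifts[interior] == 4))
  expect_true(all(rm_s$n_shifts[!interior] < 4))
  expect_true(all(rm_s$n_shifts >= 1))

  # spot-check one interior triangle against a manual average
  i <- which(interior)[1]
  cb <- tri[[i]]
  keys <- vapply(tri, leadrecon:::combination_key, character(1))
  manual <- mean(vapply(c("up", "down", "left", "right"), function(d) {
    k <- leadrecon:::combination_key(shift_combination(cb, d))
    seq(0, 1, length.out = 60)[match(k, keys)]
  }, numeric(1)))
  expect_equal(rm_s$robust_score[i], manual, tolerance = 1e-12)

  # include_self folds the combination's own score into the average
  rm_self <- robustness_map(tri, seq(0, 1, length.out = 60),
                            include_self = TRUE)
  expect_equal(rm_self$robust_score[i],
               (manual * 4 + rm_s$score[i]) / 5, tolerance = 1e-12)
})
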