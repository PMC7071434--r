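test_that("beat template is a linear sum of Gaussians with P-QRS-T structure", {
  zero <- lapply(default_morphology(), function(c) { c$amp <- c(0, 0, 0); c })
  src0 <- make_beat_template(zero)
  expect_equal(max(abs(dipole_moment(src0, seq(0, 2, by = 0.01)))), 0)

  src1 <- make_beat_template()
  dbl <- lapply(default_morphology(), function(c) { c$amp <- 2 * c$amp; c })
  src2 <- make_beat_template(dbl)
  t <- seq(0, 1, by = 0.004)
  expect_equal(dipole_moment(src2, t), 2 * dipole_moment(src1, t),
               tolerance = 1e-12)

  # QRS-to-P peak ratio: evaluate the Gaussian sum at the component centers;
  # cross-component tails are below exp(-12) there, so the ratio equals the
  # configured amplitude ratio almost exactly
  morph <- default_morphology(qrs_p_ratio = 10)
  m_qrs <- dipole_moment(make_beat_template(morph), morph$QRS$center)
  m_p <- dipole_moment(make_beat_template(morph), morph$P$center)
  expect_equal(sqrt(sum(m_qrs^2)) / sqrt(sum(m_p^2)), 10, tolerance = 1e-3)

  # periodic over one beat
  expect_equal(dipole_moment(src1, t), dipole_moment(src1, t + 5),
               tolerance = 1e-9)

  expect_error(make_beat_template(heart_rate = 0), "positive")
  bad <- default_morphology(); bad$P$width <- -1
  expect_error(make_beat_template(bad), "width")
})

test_that("surface potential follows the dipole volume-conductor law", {
  torso <- torso_model()
  src <- make_beat_template()
  t <- seq(0, 1, by = 0.01)

  zero <- lapply(default_morphology(), function(c) { c$amp <- c(0, 0, 0); c })
  src0 <- make_beat_template(zero)
  for (el in c("1", "16", "LA", "V2"))
    expect_equal(surface_potential(src0, torso, el, t), rep(0, length(t)))

  # 1/d^2 law along the dipole axis: fixed moment p along +x, electrodes on
  # the +x axis at d and 2d from the origin -> potential ratio 4:1
  const_x <- list(C = list(amp = c(1, 0, 0), center = 0.5, width = 10))
  srcx <- make_beat_template(const_x, origin = c(0, -10, -10))
  g <- grid_layout(n_cols = 1, n_rows = 1)
  mk_torso <- function(d) torso_model(
    grid = g, limb_positions = list(LA = c(d, -10, -10), RA = c(-50, 0, 0),
                                    LL = c(0, 0, -50)))
  phi_d <- surface_potential(srcx, mk_torso(10), "LA", 0.5)
  phi_2d <- surface_potential(srcx, mk_torso(20), "LA", 0.5)
  expect_equal(phi_d / phi_2d, 4, tolerance = 1e-10)

  # electrode in the plane perpendicular to p through the origin -> 0
  phi_perp <- surface_potential(
    srcx, torso_model(grid = g,
                      limb_positions = list(LA = c(0, -10, 5), RA = c(-50, 0, 0),
                                            LL = c(0, 0, -50))), "LA", 0.5)
  expect_equal(phi_perp, 0, tolerance = 1e-15)

  # superposition: two sources sum to the potential of running both
  src_b <- make_beat_template(origin = c(-2, -10, -8))
  both <- surface_potential(list(src, src_b), torso, "V3", t)
  expect_equal(both,
               surface_potential(src, torso, "V3", t) +
                 surface_potential(src_b, torso, "V3", t),
               tolerance = 1e-9)

  # clearance: a dipole on top of an electrode is rejected
  too_close <- make_beat_template(origin = c(-15, -0.2, 0))
  expect_error(surface_potential(too_close, torso, "1", t), "1 cm")
})

test_that("simulate_subject honours the sampling contract and linear physics", {
  p0 <- oracle_params()
  rec <- simulate_subject(p0, duration_s = 120, fs = 250)
  expect_equal(ncol(rec$chest), 30000)   # 2 min at 250 Hz
  expect_equal(nrow(rec$chest), 35)
  expect_equal(rownames(rec$limb), c("LA", "RA", "LL"))

  # noise off, zero dipole -> all channels identically 0
  pz <- oracle_params()
  pz$sources <- list(make_beat_template(
    lapply(default_morphology(), function(c) { c$amp <- c(0, 0, 0); c })))
  recz <- simulate_subject(pz, duration_s = 5, fs = 100)
  expect_equal(max(abs(recz$chest)), 0)
  expect_equal(max(abs(recz$limb)), 0)

  # noiseless single dipole: chest matrix has numerical rank 3
  rec3 <- simulate_subject(p0, duration_s = 20, fs = 100)
  sv <- svd(rec3$chest)$d
  expect_lt(sv[4] / sv[1], 1e-8)

  # determinism
  rec_a <- simulate_subject(subject_params(seed = 42, session_seed = 7),
                            duration_s = 4, fs = 100)
  rec_b <- simulate_subject(subject_params(seed = 42, session_seed = 7),
                            duration_s = 4, fs = 100)
  expect_identical(rec_a, rec_b)

  expect_error(simulate_subject(p0, duration_s = -1), "positive")
  expect_error(subject_params(beat_jitter_sd = -0.1), ">= 0")
})

test_that("simulate_cohort structures and seeds the cohort deterministically", {
  pt <- subject_params()
  coh <- simulate_cohort(14, 2, pt, master_seed = 3, duration_s = 2, fs = 50)
  expect_length(coh, 28)
  expect_equal(vapply(coh, function(r) r$subject_id, numeric(1)),
               rep(1:14, each = 2))
  expect_equal(vapply(coh, function(r) r$session_id, numeric(1)),
               rep(1:2, 14))

  coh2 <- simulate_cohort(14, 2, pt, master_seed = 3, duration_s = 2, fs = 50)
  expect_identical(coh, coh2)

  # with zero jitter and zero noise the subject draws have no effect: two
  # different master seeds give the template's deterministic signal
  po <- oracle_params()
  a <- simulate_cohort(1, 2, po, master_seed = 1, duration_s = 2, fs = 50)
  b <- simulate_cohort(1, 2, po, master_seed = 99, duration_s = 2, fs = 50)
  expect_equal(a[[1]]$chest, b[[1]]$chest, tolerance = 1e-12)

  # a subject's geometry is shared across sessions: with noise off but
  # geometry jitter on, both sessions of a subject coincide
  pg <- subject_params(heart_origin_jitter = c(1, 1, 1),
                       orientation_jitter_deg = 8, beat_jitter_sd = 0,
                       noise = list(white_sd = 0, wander_amp = 0,
                                    wander_hz = 0.25, powerline_amp = 0,
                                    powerline_hz = 60),
                       sources = single_dipole_source())
  cg <- simulate_cohort(2, 2, pg, master_seed = 5, duration_s = 2, fs = 50)
  expect_equal(cg[[1]]$chest, cg[[2]]$chest, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(cg[[1]]$chest, cg[[3]]$chest)))
})
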