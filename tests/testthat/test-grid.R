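test_that("grid numbering is column-major with electrode 16 at top-center", {
  expect_equal(grid_position(1), c(col = 1L, row = 1L))
  expect_equal(grid_position(16), c(col = 4L, row = 1L))
  expect_equal(grid_position(35), c(col = 7L, row = 5L))
  # bijection
  ids <- vapply(1:35, function(i) {
    cr <- grid_position(i); grid_id(cr[["col"]], cr[["row"]])
  }, integer(1))
  expect_equal(ids, 1:35)
  expect_error(grid_position(0), "1..35")
  expect_error(grid_position(36), "1..35")

  # {1,2,6,7} spans a 5 cm x 5 cm square
  pos <- t(vapply(c(1, 2, 6, 7), function(i) grid_position(i), integer(2)))
  expect_equal(diff(range(pos[, 1])) * 5, 5)
  expect_equal(diff(range(pos[, 2])) * 5, 5)
  expect_equal(nrow(unique(pos)), 4)
})

test_that("combination families have the exact enumeration counts", {
  expect_length(enumerate_all(), choose(35, 4))       # 52,360
  expect_length(enumerate_squares(5), 24)             # 6 x 4
  expect_length(enumerate_squares(10), 15)            # 5 x 3
  expect_length(enumerate_triangles(), 60)            # 5 x 3 x 4

  # reduced grids
  expect_length(enumerate_all(grid_layout(2, 2)), 1)
  expect_length(enumerate_all(grid_layout(3, 2)), 15)
  expect_length(enumerate_squares(5, grid_layout(2, 2)), 1)
  expect_error(enumerate_squares(7), "multiple")

  # printed example combinations are present with the documented shapes
  keys10 <- vapply(enumerate_squares(10), function(c)
    paste(c$ids, collapse = "-"), character(1))
  expect_true("1-3-11-13" %in% keys10)
  keys5 <- vapply(enumerate_squares(5), function(c)
    paste(c$ids, collapse = "-"), character(1))
  expect_true("1-2-6-7" %in% keys5)
  keys_tri <- vapply(enumerate_triangles(), function(c)
    paste(c$ids, collapse = "-"), character(1))
  expect_true("1-7-11-13" %in% keys_tri)

  # each 10x10 square placement yields 4 triangle orientations
  tri <- enumerate_triangles()
  expect_equal(as.integer(table(vapply(tri, function(c) c$orientation,
                                       integer(1)))), rep(15L, 4))
})

test_that("shape families agree with a brute-force geometric search", {
  # independent oracle: scan all 4-subsets of a 5 x 4 grid and classify
  # squares by pairwise distances; compare with the closed-form enumerations
  g <- grid_layout(5, 4)
  n <- 20
  subsets <- utils::combn(n, 4)
  pos <- t(vapply(1:n, function(i) {
    cr <- grid_position(i, g); c(cr[["col"]], cr[["row"]]) * g$spacing_cm
  }, numeric(2)))
  is_square <- function(ids, side) {
    p <- pos[ids, , drop = FALSE]
    d <- sort(as.numeric(dist(p)))
    isTRUE(all.equal(d, c(rep(side, 4), rep(side * sqrt(2), 2)))) &&
      # axis-aligned: coordinates take exactly two values per axis
      length(unique(p[, 1])) == 2 && length(unique(p[, 2])) == 2
  }
  for (side in c(5, 10)) {
    brute <- subsets[, vapply(seq_len(ncol(subsets)), function(j)
      is_square(subsets[, j], side), logical(1)), drop = FALSE]
    brute_keys <- sort(apply(brute, 2, paste, collapse = "-"))
    enum_keys <- sort(vapply(enumerate_squares(side, g), function(c)
      paste(c$ids, collapse = "-"), character(1)))
    expect_equal(enum_keys, brute_keys)
  }

  # every triangle is {centre + 3 corners} of an enumerated 10x10 square
  sq_corners <- lapply(enumerate_squares(10), function(c) c$ids)
  all_ids <- vapply(1:35, function(i) i, integer(1))
  for (tr in enumerate_triangles()) {
    hit <- any(vapply(seq_along(sq_corners), function(k) {
      corners <- sq_corners[[k]]
      centre <- setdiff(tr$ids, corners)
      length(centre) == 1 &&
        sum(corners %in% tr$ids) == 3 &&
        all(grid_position(centre) ==
              round(colMeans(t(vapply(corners, function(i)
                grid_position(i), integer(2))))))
    }, logical(1)))
    expect_true(hit)
  }

  # every shape-family combination appears in enumerate_all()
  keys_all <- vapply(enumerate_all(), function(c)
    paste(c$ids, collapse = "-"), character(1))
  fam_keys <- vapply(c(enumerate_squares(5), enumerate_squares(10),
                       enumerate_triangles()),
                     function(c) paste(c$ids, collapse = "-"), character(1))
  expect_true(all(fam_keys %in% keys_all))
})

test_that("chest leads subtract the lowest-id reference electrode", {
  T <- 50
  chest <- matrix(0, 35, T)
  cl0 <- compute_chest_leads(chest, c(4, 9, 14, 19))
  expect_equal(max(abs(cl0$cl)), 0)

  chest[4, ] <- 0; chest[9, ] <- 2; chest[14, ] <- -3; chest[19, ] <- 7
  cl <- compute_chest_leads(chest, c(4, 9, 14, 19))
  expect_equal(cl$reference_id, 4)
  expect_equal(unname(cl$cl[, 1]), c(2, -3, 7))

  expect_error(compute_chest_leads(chest, c(4, 4, 9, 14)), "distinct")

  # noiseless single-dipole simulation: CL triplet has rank 3
  rec <- simulate_subject(oracle_params(), duration_s = 10, fs = 100)
  cl3 <- compute_chest_leads(rec, c(13, 15, 23, 25))
  sv <- svd(cl3$cl)$d
  expect_lt(sv[3] / sv[1], 1)     # non-degenerate
  expect_gt(sv[3] / sv[1], 1e-6)  # genuinely 3-dimensional
})

test_that("combinations shift on the lattice with boundary handling", {
  cb <- structure(list(ids = c(13L, 15L, 19L, 23L), shape_tag = "triangle",
                       orientation = 4L), class = "electrode_combination")
  sh <- shift_combination(cb, "right")
  expect_equal(sh$ids, c(18L, 20L, 24L, 28L))
  expect_equal(sh$shape_tag, "triangle")

  # a combination touching row 1 cannot shift up
  top <- structure(list(ids = c(1L, 2L, 6L, 7L), shape_tag = "square5",
                        orientation = NA_integer_),
                   class = "electrode_combination")
  expect_null(shift_combination(top, "up"))

  # left then right is the identity when both shifts stay on grid
  back <- shift_combination(shift_combination(cb, "left"), "right")
  expect_equal(back$ids, cb$ids)
})
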