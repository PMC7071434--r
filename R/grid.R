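#' Chest electrode grid layout
#'
#' A logical lattice of `n_cols` x `n_rows` electrodes with fixed spacing.
#' Electrodes are numbered column-major: ids 1..n_rows run down the first
#' (subject's right-most) column from the top row, ids n_rows+1..2*n_rows down
#' the second column, and so on.  On the default 7 x 5 grid, electrode 16 is
#' the top of the central (4th) column — the clavicle/sternum junction.  Row 1
#' is the superior (clavicle) edge.
#'
#' @param n_cols,n_rows Lattice dimensions.
#' @param spacing_cm Inter-electrode distance (cm).
#' @return An object of class `grid_layout`.
#' @export
grid_layout <- function(n_cols = 7L, n_rows = 5L, spacing_cm = 5) {
  stopifnot(n_cols >= 1, n_rows >= 1, spacing_cm > 0)
  structure(list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 spacing_cm = spacing_cm),
            class = "grid_layout")
}

#' Electrode id to lattice position and back
#'
#' @param id Electrode id (1-based).
#' @param grid A [grid_layout()].
#' @return `grid_position()`: named vector `c(col =, row =)`;
#'   `grid_id()`: the electrode id.
#' @examples
#' grid_position(16)  # col 4, row 1: top-center of the default grid
#' @export
grid_position <- function(id, grid = grid_layout()) {
  n <- grid$n_cols * grid$n_rows
  if (!is.numeric(id) || length(id) != 1L || id != round(id) ||
      id < 1 || id > n)
    stop("`id` must be an integer in 1..", n, call. = FALSE)
  id <- as.integer(id)
  c(col = (id - 1L) %/% grid$n_rows + 1L,
    row = (id - 1L) %% grid$n_rows + 1L)
}

#' @rdname grid_position
#' @param col,row Lattice coordinates (1-based; row 1 = superior edge).
#' @export
grid_id <- function(col, row, grid = grid_layout()) {
  stopifnot(col >= 1, col <= grid$n_cols, row >= 1, row <= grid$n_rows)
  as.integer((col - 1L) * grid$n_rows + row)
}

new_combination <- function(ids, shape_tag = "free", orientation = NA_integer_) {
  ids <- sort(as.integer(ids))
  if (length(ids) != 4L || anyDuplicated(ids))
    stop("a combination must have exactly 4 distinct electrode ids",
         call. = FALSE)
  structure(list(ids = ids, shape_tag = shape_tag,
                 orientation = orientation),
            class = "electrode_combination")
}

#' @export
format.electrode_combination <- function(x, ...) {
  sprintf("<combination {%s} %s%s>", paste(x$ids, collapse = ","),
          x$shape_tag,
          if (is.na(x$orientation)) "" else paste0(" o", x$orientation))
}

#' @export
print.electrode_combination <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Enumerate electrode-combination families
#'
#' `enumerate_all()` lists every unordered 4-subset of the grid's electrodes
#' (C(35, 4) = 52,360 on the default grid).  `enumerate_squares()` lists
#' axis-aligned squares whose four corners are grid electrodes: 24 placements
#' of the 5 cm x 5 cm square and 15 of the 10 cm x 10 cm square on the default
#' grid.  `enumerate_triangles()` lists right-angled triangles inscribed in a
#' 10 cm x 10 cm square area: for each of the 15 square placements, the four
#' electrodes are the square's centre electrode plus three of its four
#' corners, one corner omitted per orientation (4 orientations, 60 total).
#'
#' @param grid A [grid_layout()].
#' @param side_cm Square side (must be a multiple of the grid spacing).
#' @return List of `electrode_combination` objects.
#' @export
enumerate_all <- function(grid = grid_layout()) {
  n <- grid$n_cols * grid$n_rows
  if (n < 4L) return(list())
  sets <- utils::combn(n, 4L)
  lapply(seq_len(ncol(sets)), function(i) new_combination(sets[, i]))
}

#' @rdname enumerate_all
#' @export
enumerate_squares <- function(side_cm, grid = grid_layout()) {
  s <- side_cm / grid$spacing_cm
  if (abs(s - round(s)) > 1e-9 || s < 1)
    stop("`side_cm` must be a positive multiple of the grid spacing",
         call. = FALSE)
  s <- as.integer(round(s))
  tag <- if (side_cm == 5) "square5" else if (side_cm == 10) "square10"
         else sprintf("square%g", side_cm)
  out <- list()
  for (c0 in seq_len(max(grid$n_cols - s, 0L))) {
    for (r0 in seq_len(max(grid$n_rows - s, 0L))) {
      ids <- c(grid_id(c0, r0, grid), grid_id(c0 + s, r0, grid),
               grid_id(c0, r0 + s, grid), grid_id(c0 + s, r0 + s, grid))
      out[[length(out) + 1L]] <- new_combination(ids, tag)
    }
  }
  out
}

#' @rdname enumerate_all
#' @export
enumerate_triangles <- function(grid = grid_layout()) {
  out <- list()
  for (c0 in seq_len(max(grid$n_cols - 2L, 0L))) {
    for (r0 in seq_len(max(grid$n_rows - 2L, 0L))) {
      centre <- grid_id(c0 + 1L, r0 + 1L, grid)
      corners <- c(grid_id(c0, r0, grid), grid_id(c0 + 2L, r0, grid),
                   grid_id(c0, r0 + 2L, grid), grid_id(c0 + 2L, r0 + 2L, grid))
      for (o in 1:4) {
        ids <- c(centre, corners[-o])
        out[[length(out) + 1L]] <- new_combination(ids, "triangle", o)
      }
    }
  }
  out
}

#' Chest-lead triplet from a four-electrode combination
#'
#' Three bipolar chest leads are formed by subtracting a common reference
#' electrode — the lowest id in the combination — from each of the other
#' three.  Any fixed reference choice spans the same 3-dimensional lead space,
#' so downstream model fits are unaffected by this convention.
#'
#' @param recording A `mc_recording` (see [simulate_subject()]) or any object
#'   with a `chest` channels-x-T matrix, or such a matrix directly.
#' @param combination An `electrode_combination` or a 4-vector of ids.
#' @return List of class `chest_lead_triplet` with `cl` (3 x T matrix,
#'   microvolts), `source_combination`, and `reference_id`.
#' @export
compute_chest_leads <- function(recording, combination) {
  chest <- if (is.matrix(recording)) recording else recording$chest
  if (!inherits(combination, "electrode_combination"))
    combination <- new_combination(combination)
  ids <- combination$ids
  if (any(ids > nrow(chest)))
    stop("combination ids exceed the number of chest channels", call. = FALSE)
  ref <- ids[1L]                      # ids are sorted; lowest id is reference
  others <- ids[-1L]
  cl <- chest[others, , drop = FALSE] -
    matrix(chest[ref, ], 3L, ncol(chest), byrow = TRUE)
  rownames(cl) <- sprintf("CL%d", 1:3)
  structure(list(cl = cl, source_combination = combination,
                 reference_id = ref),
            class = "chest_lead_triplet")
}

#' Shift a combination one lattice step
#'
#' Translates every electrode one step in the given direction.  "up" moves
#' toward the superior edge (row index decreases).  Returns `NULL` when any
#' electrode would leave the grid.
#'
#' @param combination An `electrode_combination`.
#' @param direction One of `"up"`, `"down"`, `"left"`, `"right"`.
#' @param grid A [grid_layout()].
#' @return The shifted `electrode_combination`, or `NULL` if off-grid.
#' @export
shift_combination <- function(combination, direction, grid = grid_layout()) {
  direction <- match.arg(direction, c("up", "down", "left", "right"))
  d <- switch(direction,
              up = c(0L, -1L), down = c(0L, 1L),
              left = c(-1L, 0L), right = c(1L, 0L))
  new_ids <- integer(4L)
  for (i in seq_along(combination$ids)) {
    cr <- grid_position(combination$ids[i], grid)
    col <- cr[["col"]] + d[1L]; row <- cr[["row"]] + d[2L]
    if (col < 1L || col > grid$n_cols || row < 1L || row > grid$n_rows)
      return(NULL)
    new_ids[i] <- grid_id(col, row, grid)
  }
  new_combination(new_ids, combination$shape_tag, combination$orientation)
}

#' Serialize combinations to a data frame / CSV
#'
#' @param combinations List of `electrode_combination` objects.
#' @return Data frame with columns id1..id4, shape_tag, orientation.
#' @export
combinations_to_df <- function(combinations) {
  do.call(rbind, lapply(combinations, function(cb) {
    data.frame(id1 = cb$ids[1], id2 = cb$ids[2], id3 = cb$ids[3],
               id4 = cb$ids[4], shape_tag = cb$shape_tag,
               orientation = cb$orientation)
  }))
}

combination_key <- function(combination)
  paste(combination$ids, collapse = "-")
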