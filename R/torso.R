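#' Torso volume-conductor model
#'
#' An infinite homogeneous volume conductor with a fixed electrode montage:
#' the 35 chest-grid electrodes (ids `"1"`..`"35"`), the limb electrodes
#' (`"LA"`, `"RA"`, `"LL"`) and the six precordial electrode sites
#' (`"V1"`..`"V6"`).  Surface potentials of a current dipole p at r0 are
#' phi(r) = p . (r - r0) / (4 pi sigma |r - r0|^3), which is linear in the
#' instantaneous dipole moment — the structure the reconstruction exploits.
#'
#' Coordinate frame (cm): x toward the subject's left, y anterior, z superior;
#' the chest plane is y = 0 with the grid's top row at z = 0.
#'
#' @param grid A [grid_layout()] describing the chest electrode lattice.
#' @param conductivity Scalar conductivity (S/m).
#' @param limb_positions Named list/matrix of 3-vectors for LA, RA, LL (cm).
#' @param precordial_positions Named list/matrix of 3-vectors for V1..V6 (cm).
#' @param bounding_box 2x3 matrix (rows = min, max) of the torso box used to
#'   validate that dipole origins are interior.
#' @return An object of class `torso_model` with an `electrode_positions`
#'   matrix (one row per electrode, rownames = electrode ids).
#' @export
torso_model <- function(grid = grid_layout(),
                        conductivity = 0.2,
                        limb_positions = default_limb_positions(),
                        precordial_positions = default_precordial_positions(),
                        bounding_box = rbind(min = c(-30, -25, -70),
                                             max = c(30, 5, 10))) {
  if (!is.numeric(conductivity) || conductivity <= 0)
    stop("`conductivity` must be positive", call. = FALSE)
  chest <- t(vapply(seq_len(grid$n_cols * grid$n_rows), function(id) {
    cr <- grid_position(id, grid)
    c((cr[["col"]] - (grid$n_cols + 1) / 2) * grid$spacing_cm,
      0,
      -(cr[["row"]] - 1) * grid$spacing_cm)
  }, numeric(3L)))
  rownames(chest) <- as.character(seq_len(nrow(chest)))
  limb <- do.call(rbind, limb_positions)
  prec <- do.call(rbind, precordial_positions)
  pos <- rbind(chest, limb, prec)
  if (anyDuplicated(pos))
    stop("electrode positions must be distinct", call. = FALSE)
  structure(list(grid = grid,
                 conductivity = conductivity,
                 electrode_positions = pos,
                 bounding_box = bounding_box),
            class = "torso_model")
}

#' @rdname torso_model
#' @details Limb-lead electrodes are placed at their torso-proximal
#'   equivalents (shoulders and left hip), as in wireless limb-lead
#'   placements: in an infinite homogeneous medium the 1/d^2 decay would
#'   otherwise leave electrodes at true limb distances with negligible
#'   potential, which a bounded torso does not exhibit.
#' @export
default_limb_positions <- function() {
  list(LA = c(28, 0, 2), RA = c(-28, 0, 2), LL = c(12, 0, -50))
}

#' @rdname torso_model
#' @export
default_precordial_positions <- function() {
  list(V1 = c(-2.5, 0, -10), V2 = c(2.5, 0, -10), V3 = c(5, 0, -12.5),
       V4 = c(7.5, 0, -15), V5 = c(12.5, 0, -15), V6 = c(17.5, 0, -15))
}

check_source_torso <- function(source, torso) {
  bb <- torso$bounding_box
  o <- source$origin
  if (any(o <= bb[1, ] | o >= bb[2, ]))
    stop("dipole origin must lie strictly inside the torso bounding box",
         call. = FALSE)
  d2 <- rowSums((torso$electrode_positions -
                   matrix(o, nrow(torso$electrode_positions), 3L,
                          byrow = TRUE))^2)
  if (any(d2 < 1))   # >= 1 cm clearance
    stop("every electrode must be at least 1 cm from the dipole origin",
         call. = FALSE)
  invisible(TRUE)
}

#' Dipole lead field for one electrode
#'
#' Transfer vector L such that phi(t) = L . p(t), with p in mA.cm and phi in
#' microvolts.
#'
#' @keywords internal
lead_field_vector <- function(origin, position, conductivity) {
  u <- (position - origin) * 1e-2           # cm -> m
  d <- sqrt(sum(u^2))
  if (d < 1e-9)
    stop("electrode coincides with the dipole origin", call. = FALSE)
  # p [mA.cm] = 1e-5 A.m; potential in V * 1e6 -> microvolts
  u / (4 * pi * conductivity * d^3) * 1e-5 * 1e6
}

#' Surface potential of a dipole source at an electrode
#'
#' @param source A `dipole_source` (or list of them, summed by superposition).
#' @param torso A `torso_model`.
#' @param electrode_id Electrode id: `1..35`, `"LA"`, `"RA"`, `"LL"`, or
#'   `"V1"`..`"V6"`.
#' @param t Numeric vector of times (s).
#' @return Numeric vector of potentials (microvolts).
#' @export
surface_potential <- function(source, torso, electrode_id, t) {
  stopifnot(inherits(torso, "torso_model"))
  sources <- if (inherits(source, "dipole_source")) list(source) else source
  key <- as.character(electrode_id)
  if (!key %in% rownames(torso$electrode_positions))
    stop("unknown electrode id: ", key, call. = FALSE)
  pos <- torso$electrode_positions[key, ]
  phi <- numeric(length(t))
  for (src in sources) {
    check_source_torso(src, torso)
    lf <- lead_field_vector(src$origin, pos, torso$conductivity)
    phi <- phi + as.numeric(crossprod(lf, dipole_moment(src, t)))
  }
  phi
}

#' Potentials at every electrode for a set of sources
#'
#' @param sources List of `dipole_source` objects.
#' @param torso A `torso_model`.
#' @param t Times (s).
#' @param beat_scales Optional list of per-source `beat_scale` functions
#'   (see [dipole_moment()]).
#' @return Electrodes x T matrix (microvolts), rownames = electrode ids.
#' @keywords internal
potential_matrix <- function(sources, torso, t, beat_scales = NULL) {
  pos <- torso$electrode_positions
  out <- matrix(0, nrow = nrow(pos), ncol = length(t),
                dimnames = list(rownames(pos), NULL))
  for (i in seq_along(sources)) {
    src <- sources[[i]]
    check_source_torso(src, torso)
    m <- dipole_moment(src, t,
                       beat_scale = if (is.null(beat_scales)) NULL
                                    else beat_scales[[i]])
    lf <- t(vapply(seq_len(nrow(pos)), function(j)
      lead_field_vector(src$origin, pos[j, ], torso$conductivity),
      numeric(3L)))
    out <- out + lf %*% m
  }
  out
}
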