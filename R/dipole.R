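#' Cardiac dipole source with sum-of-Gaussians beat morphology
#'
#' Builds a periodic equivalent-dipole source whose moment trajectory over one
#' cardiac cycle is a sum of Gaussian deflections (P, QRS, T) per spatial axis.
#' Units: moment in mA.cm, geometry in cm, time in seconds.
#'
#' @param morphology Named list of wave components.  Each component is a list
#'   with `amp` (3-vector, mA.cm, peak moment along x/y/z), `center` (fraction
#'   of the beat in `[0, 1)`), and `width` (Gaussian SD as a fraction of the
#'   beat, > 0).  Defaults give a P-QRS-T morphology with QRS dominant.
#' @param heart_rate Beats per minute (> 0).
#' @param origin 3-vector position of the dipole in the torso frame (cm).
#'   The default sits behind the lower-left chest and deliberately off the
#'   grid's mirror planes: a dipole exactly midway between electrode columns
#'   makes symmetric four-electrode combinations rank-deficient (their three
#'   chest leads collapse to a 2-D space), which no real heart position does.
#' @param orientation 3x3 rotation matrix applied to the moment trajectory.
#' @return An object of class `dipole_source`.
#' @examples
#' src <- make_beat_template()
#' m <- dipole_moment(src, seq(0, 1, by = 0.004))
#' @export
make_beat_template <- function(morphology = default_morphology(),
                               heart_rate = 60,
                               origin = c(2.7, -8, -11.6),
                               orientation = diag(3)) {
  if (!is.numeric(heart_rate) || length(heart_rate) != 1L || heart_rate <= 0)
    stop("`heart_rate` must be a positive scalar", call. = FALSE)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be a finite 3-vector", call. = FALSE)
  if (!is.matrix(orientation) || !all(dim(orientation) == c(3L, 3L)))
    stop("`orientation` must be a 3x3 matrix", call. = FALSE)
  for (comp in morphology) {
    if (length(comp$amp) != 3L || !all(is.finite(comp$amp)))
      stop("each morphology component needs a finite 3-vector `amp`",
           call. = FALSE)
    if (!is.numeric(comp$width) || comp$width <= 0)
      stop("morphology widths must be positive", call. = FALSE)
    if (!is.numeric(comp$center) || comp$center < 0 || comp$center >= 1)
      stop("morphology centers must lie in [0, 1)", call. = FALSE)
  }
  structure(list(morphology = morphology,
                 heart_rate = heart_rate,
                 origin = as.numeric(origin),
                 orientation = orientation),
            class = "dipole_source")
}

#' Default P-QRS-T dipole morphology
#'
#' Peak magnitudes (~0.2, ~2.0 and ~0.7 mA.cm for P, QRS, T) and axis
#' directions follow textbook values for the equivalent cardiac dipole:
#' the QRS axis points toward the subject's left, inferior and slightly
#' anterior.  Axes: x = subject's left, y = anterior, z = superior.
#'
#' @param qrs_p_ratio Ratio of QRS to P peak moment magnitude.
#' @return Named list of wave components for [make_beat_template()].
#' @export
default_morphology <- function(qrs_p_ratio = 10) {
  qrs_dir <- c(0.60, 0.35, -0.72)
  qrs_dir <- qrs_dir / sqrt(sum(qrs_dir^2))
  t_dir <- c(0.50, 0.30, -0.81)
  t_dir <- t_dir / sqrt(sum(t_dir^2))
  p_dir <- c(0.40, 0.10, -0.91)
  p_dir <- p_dir / sqrt(sum(p_dir^2))
  qrs_amp <- 2.0
  list(
    P   = list(amp = p_dir * qrs_amp / qrs_p_ratio, center = 0.15,
               width = 0.020),
    QRS = list(amp = qrs_dir * qrs_amp, center = 0.30, width = 0.012),
    T   = list(amp = t_dir * 0.7, center = 0.55, width = 0.050)
  )
}

#' Evaluate the dipole-moment trajectory
#'
#' The trajectory is strictly periodic over one beat: Gaussian phase
#' differences are wrapped to the nearest period.
#'
#' @param source A `dipole_source`.
#' @param t Numeric vector of times (s).
#' @param beat_scale Optional function `f(beat_index)` returning a scalar
#'   multiplier per beat (beat-to-beat amplitude jitter); beats are indexed
#'   from 0.  `NULL` means no modulation.
#' @return 3 x `length(t)` matrix of moment components (mA.cm).
#' @export
dipole_moment <- function(source, t, beat_scale = NULL) {
  stopifnot(inherits(source, "dipole_source"))
  phase_total <- t * source$heart_rate / 60
  phase <- phase_total %% 1
  m <- matrix(0, nrow = 3L, ncol = length(t))
  for (comp in source$morphology) {
    d <- phase - comp$center
    d <- d - round(d)                       # wrap to [-0.5, 0.5)
    g <- exp(-d^2 / (2 * comp$width^2))
    m <- m + outer(as.numeric(comp$amp), g)
  }
  if (!is.null(beat_scale)) {
    s <- beat_scale(floor(phase_total))
    m <- m * rep(s, each = 3L)
  }
  source$orientation %*% m
}

#' Small random rotation matrix
#'
#' Composes rotations about the x, y and z axes with angles drawn from
#' `N(0, angle_sd_deg)`; used to jitter heart orientation across subjects.
#'
#' @param angle_sd_deg Angle SD in degrees.
#' @return 3x3 rotation matrix (draws from the current RNG stream).
#' @keywords internal
random_rotation <- function(angle_sd_deg) {
  a <- stats::rnorm(3L, sd = angle_sd_deg * pi / 180)
  rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}
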