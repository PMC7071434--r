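#' Zero-phase Butterworth bandpass filter
#'
#' Second-order Butterworth bandpass (0.5–35 Hz by default) applied forward
#' and backward (zero phase), with odd-reflection padding at both ends to
#' suppress edge transients.  Accepts a numeric vector, a channels-x-T
#' matrix, or an `mc_recording` (all channel blocks filtered).
#'
#' @param x Signal(s) to filter.
#' @param fs Sampling rate (Hz); taken from the recording if `x` is one.
#' @param low_hz,high_hz Band edges (Hz), `0 < low < high < fs/2`.
#' @param order Butterworth order of the single-pass prototype.
#' @return Same shape/class as the input.
#' @export
bandpass <- function(x, fs = NULL, low_hz = 0.5, high_hz = 35, order = 2) {
  if (inherits(x, "mc_recording")) {
    fs <- x$fs
    for (fld in c("chest", "limb", "precordial"))
      x[[fld]] <- bandpass(x[[fld]], fs, low_hz, high_hz, order)
    return(x)
  }
  if (is.null(fs)) stop("`fs` is required for raw signals", call. = FALSE)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop("require 0 < low_hz < high_hz < fs/2", call. = FALSE)
  flt <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  filt1 <- function(v) {
    n <- length(v)
    np <- min(n - 1L, as.integer(round(3 * fs / low_hz)))
    pre <- 2 * v[1L] - v[seq(np + 1L, 2L)]
    post <- 2 * v[n] - v[seq(n - 1L, n - np)]
    out <- signal::filtfilt(flt, c(pre, v, post))
    out[np + seq_len(n)]
  }
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, filt1))
    dimnames(out) <- dimnames(x)
    out
  } else filt1(x)
}

#' Wilson's central terminal
#'
#' The reference potential for the precordial leads: the mean of the left-arm,
#' right-arm and left-leg electrode potentials, WCT = (LA + RA + LL) / 3.
#'
#' @param limb_electrodes 3 x T matrix with rownames LA, RA, LL (or a list
#'   with those names), or an `mc_recording`.
#' @return Numeric vector of WCT samples (microvolts).
#' @export
compute_wct <- function(limb_electrodes) {
  if (inherits(limb_electrodes, "mc_recording"))
    limb_electrodes <- limb_electrodes$limb
  if (is.list(limb_electrodes) && !is.data.frame(limb_electrodes))
    limb_electrodes <- do.call(rbind, limb_electrodes[c("LA", "RA", "LL")])
  need <- c("LA", "RA", "LL")
  if (is.null(rownames(limb_electrodes)) ||
      !all(need %in% rownames(limb_electrodes)))
    stop("limb electrodes LA, RA, LL are required", call. = FALSE)
  as.numeric(colMeans(limb_electrodes[need, , drop = FALSE]))
}

lead_names_12 <- function()
  c("I", "II", "III", "aVR", "aVL", "aVF", paste0("V", 1:6))

#' Derive the standard 12-lead ECG from electrode potentials
#'
#' Limb leads from the limb electrodes (I = LA - RA, II = LL - RA,
#' III = LL - LA), the augmented leads from the limb leads
#' (aVR = -(I + II)/2, aVL = (I - III)/2, aVF = (II + III)/2), and the
#' precordial leads V1..V6 as the precordial electrode potentials referenced
#' to Wilson's central terminal.  The constructions guarantee the Einthoven
#' closure I - II + III = 0 and the Goldberger closure aVR + aVL + aVF = 0.
#'
#' @param recording An `mc_recording` (limb + precordial channels present).
#' @return Object of class `lead_set_12`: list with `leads` (12 x T matrix,
#'   rows I, II, III, aVR, aVL, aVF, V1..V6; microvolts) and `fs`.
#' @export
derive_12lead <- function(recording) {
  if (is.null(recording$limb) || is.null(recording$precordial))
    stop("recording must carry limb and precordial channels", call. = FALSE)
  LA <- recording$limb["LA", ]; RA <- recording$limb["RA", ]
  LL <- recording$limb["LL", ]
  I <- LA - RA; II <- LL - RA; III <- LL - LA
  aVR <- -(I + II) / 2
  aVL <- (I - III) / 2
  aVF <- (II + III) / 2
  wct <- compute_wct(recording)
  prec <- recording$precordial -
    matrix(wct, nrow(recording$precordial), length(wct), byrow = TRUE)
  leads <- rbind(I, II, III, aVR, aVL, aVF, prec)
  rownames(leads) <- lead_names_12()
  structure(list(leads = leads, fs = recording$fs,
                 subject_id = recording$subject_id,
                 session_id = recording$session_id),
            class = "lead_set_12")
}

#' Extract one random segment per recording and merge
#'
#' From each recording a contiguous segment of `length_s` seconds is taken at
#' a uniformly random start (deterministic for a fixed seed) and the segments
#' are concatenated in input order.  With 14 recordings of 20 s segments this
#' yields the 280 s pooled signal on which universal coefficients are fitted.
#'
#' @param recordings List of `mc_recording` objects with equal `fs`.
#' @param spec_seed Integer seed for the segment start points.
#' @param length_s Segment length in seconds (default 20).
#' @return Object of class `merged_recording`: `chest`/`limb`/`precordial`
#'   concatenated matrices, `fs`, and `segments` — a data frame with one row
#'   per input recording (`subject_id`, `session_id`, `start_sample`,
#'   `end_sample`, both 1-based, in merged coordinates).
#' @export
extract_and_merge <- function(recordings, spec_seed = 1L, length_s = 20) {
  stopifnot(length(recordings) >= 1L)
  fs <- recordings[[1L]]$fs
  n_seg <- as.integer(round(length_s * fs))
  starts <- with_seed(spec_seed, vapply(recordings, function(rec) {
    if (rec$fs != fs) stop("all recordings must share fs", call. = FALSE)
    n <- ncol(rec$chest)
    if (n < n_seg)
      stop("recording shorter than the segment length", call. = FALSE)
    sample.int(n - n_seg + 1L, 1L)
  }, integer(1L)))
  pick <- function(mat, s) mat[, s:(s + n_seg - 1L), drop = FALSE]
  chest <- do.call(cbind, Map(function(r, s) pick(r$chest, s),
                              recordings, starts))
  limb <- do.call(cbind, Map(function(r, s) pick(r$limb, s),
                             recordings, starts))
  prec <- do.call(cbind, Map(function(r, s) pick(r$precordial, s),
                             recordings, starts))
  seg <- data.frame(
    subject_id = vapply(recordings, function(r) r$subject_id, numeric(1L)),
    session_id = vapply(recordings, function(r) r$session_id, numeric(1L)),
    source_start = starts,
    start_sample = (seq_along(recordings) - 1L) * n_seg + 1L,
    end_sample = seq_along(recordings) * n_seg)
  structure(list(fs = fs, chest = chest, limb = limb, precordial = prec,
                 segments = seg),
            class = c("merged_recording", "mc_recording"))
}

#' Standardize channels to zero mean and unit SD
#'
#' @param channels Channels-x-T matrix (or numeric vector, treated as one
#'   channel).
#' @param stats Optional list with `center` and `scale` (e.g. from a training
#'   merge) to apply instead of estimating from `channels`.
#' @return List of class `standardized`: `x` (standardized matrix), `center`,
#'   `scale`.  Invert with [unstandardize()].
#' @export
standardize <- function(channels, stats = NULL) {
  x <- if (is.matrix(channels)) channels else matrix(channels, nrow = 1L)
  if (is.null(stats)) {
    center <- rowMeans(x)
    scale <- apply(x, 1L, stats::sd)
    if (any(scale < 1e-12))
      stop("cannot standardize a constant channel", call. = FALSE)
  } else {
    center <- stats$center; scale <- stats$scale
  }
  z <- (x - center) / scale
  structure(list(x = z, center = center, scale = scale),
            class = "standardized")
}

#' @rdname standardize
#' @param z Standardized matrix (channels x T).
#' @export
unstandardize <- function(z, stats) {
  if (inherits(z, "standardized")) { stats <- z; z <- z$x }
  z * stats$scale + stats$center
}
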