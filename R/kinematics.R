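# Joint derivation, root-centred local coordinates and velocity
# estimation.
#
# Axis convention (frozen for the whole package): axis 1 = mediolateral,
# axis 2 = anteroposterior, axis 3 = vertical. The local frame translates
# the root joint to the origin every frame and rotates about the vertical
# axis so the left-hip -> right-hip vector lies along the mediolateral
# axis.

#' Construct a joint recording
#'
#' @param values numeric array frames x joints x 3 (mm for positions,
#'   mm/s for velocities).
#' @param joint_labels character vector of joint names, order fixed by the
#'   [marker_joint_map()].
#' @param sampling_rate Hz.
#' @param frame_kind `"position"` or `"velocity"`.
#' @param coordinate_frame `"global"` or `"local"`.
#' @param participant_id,stimulus_id identifiers carried along.
#' @return An object of class `joint_recording`.
#' @export
joint_recording <- function(values, joint_labels, sampling_rate,
                            frame_kind = c("position", "velocity"),
                            coordinate_frame = c("global", "local"),
                            participant_id = "p1", stimulus_id = "s1") {
  frame_kind <- match.arg(frame_kind)
  coordinate_frame <- match.arg(coordinate_frame)
  if (length(dim(values)) != 3L || dim(values)[3] != 3L)
    stop("`values` must be frames x joints x 3", call. = FALSE)
  if (dim(values)[2] != length(joint_labels))
    stop("joint label count must match values", call. = FALSE)
  if (!all(is.finite(values)))
    stop("joint values must be finite", call. = FALSE)
  structure(list(joint_labels = as.character(joint_labels), values = values,
                 sampling_rate = sampling_rate, frame_kind = frame_kind,
                 coordinate_frame = coordinate_frame,
                 participant_id = as.character(participant_id),
                 stimulus_id = as.character(stimulus_id)),
            class = "joint_recording")
}

#' @export
print.joint_recording <- function(x, ...) {
  cat(sprintf("<joint_recording> %s / %s: %d frames x %d joints @ %g Hz [%s, %s]\n",
              x$participant_id, x$stimulus_id, dim(x$values)[1],
              length(x$joint_labels), x$sampling_rate, x$frame_kind,
              x$coordinate_frame))
  invisible(x)
}

#' Derive joints from markers
#'
#' Each joint is the per-frame arithmetic mean of the markers mapped to it
#' (e.g. the root as midpoint of the two back-hip markers, the head as the
#' mean of three head markers). Joint order follows the map.
#'
#' @param rec a gap-free [marker_recording()].
#' @param map a [marker_joint_map()].
#' @return A global-frame position [joint_recording()].
#' @export
derive_joints <- function(rec, map = default_joint_map()) {
  stopifnot(inherits(rec, "marker_recording"), inherits(map, "marker_joint_map"))
  if (any(rec$missing_mask))
    stop("recording still has missing samples; run fill_gaps() first",
         call. = FALSE)
  needed <- unique(unlist(map$joint_definitions))
  absent <- setdiff(needed, rec$marker_labels)
  if (length(absent))
    stop(sprintf("markers not present in recording: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  nf <- dim(rec$positions)[1]
  nj <- length(map$joint_definitions)
  vals <- array(0, c(nf, nj, 3L))
  for (j in seq_len(nj)) {
    idx <- match(map$joint_definitions[[j]], rec$marker_labels)
    for (a in 1:3)
      vals[, j, a] <- rowMeans(rec$positions[, idx, a, drop = FALSE])
  }
  joint_recording(vals, names(map$joint_definitions), rec$sampling_rate,
                  "position", "global", rec$participant_id, rec$stimulus_id)
}

#' Transform a joint recording to root-centred local coordinates
#'
#' Per frame the root joint is translated to the origin, then the frame is
#' rotated about the vertical axis so the left-hip -> right-hip vector lies
#' along the positive mediolateral (first) axis with zero anteroposterior
#' component. This removes the dancer's position and heading in capture
#' space, so downstream features see only movement relative to the body.
#' Already-local input is returned unchanged (the transform is idempotent).
#'
#' @param jrec a global-frame position [joint_recording()].
#' @param map a [marker_joint_map()] naming root and hip joints.
#' @param rotation_mode `"per-frame"` (default) realigns the heading every
#'   frame; `"first-frame"` applies the first frame's rotation throughout,
#'   preserving within-trial turning.
#' @return A local-frame position [joint_recording()].
#' @export
to_local_coordinates <- function(jrec, map = default_joint_map(),
                                 rotation_mode = c("per-frame", "first-frame")) {
  stopifnot(inherits(jrec, "joint_recording"))
  rotation_mode <- match.arg(rotation_mode)
  if (jrec$frame_kind != "position")
    stop("local-coordinate transform expects position data", call. = FALSE)
  if (jrec$coordinate_frame == "local") return(jrec)
  ir <- match(map$root_joint, jrec$joint_labels)
  il <- match(map$left_hip_joint, jrec$joint_labels)
  ihr <- match(map$right_hip_joint, jrec$joint_labels)
  if (anyNA(c(ir, il, ihr)))
    stop("root/hip joints of the map are absent from the recording",
         call. = FALSE)
  v <- jrec$values
  nf <- dim(v)[1]
  for (a in 1:3) v[, , a] <- v[, , a] - v[, ir, a]
  hx <- v[, ihr, 1] - v[, il, 1]
  hy <- v[, ihr, 2] - v[, il, 2]
  if (any(hx * hx + hy * hy < 1e-12))
    stop("left and right hip coincide in the horizontal plane; rotation undefined",
         call. = FALSE)
  th <- atan2(hy, hx)
  if (rotation_mode == "first-frame") th <- rep(th[1], nf)
  ct <- cos(th); st <- sin(th)
  x <- v[, , 1]; y <- v[, , 2]
  v[, , 1] <- ct * x + st * y
  v[, , 2] <- -st * x + ct * y
  joint_recording(v, jrec$joint_labels, jrec$sampling_rate, "position",
                  "local", jrec$participant_id, jrec$stimulus_id)
}

# --- velocity estimation ----------------------------------------------------

# Central-difference time derivative, one-sided at the ends, in units/s.
diff_central <- function(x, rate) {
  n <- length(x)
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate / 2
  v[1] <- (x[2] - x[1]) * rate
  v[n] <- (x[n] - x[n - 1]) * rate
  v
}

# Digital low-pass Butterworth design via the bilinear transform of the
# analog prototype (all-pole; zeros at z = -1). wn = cutoff / nyquist.
butter_lowpass <- function(order, wn) {
  stopifnot(order >= 1, wn > 0, wn < 1)
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # analog prototype poles
  fs <- 2
  warped <- 2 * fs * tan(pi * wn / fs)
  p <- warped * p
  gain <- warped^order
  fs2 <- 2 * fs
  zd <- (fs2 + p) / (fs2 - p)
  gain_z <- gain * Re(prod(1 / (fs2 - p)))
  a <- Re(poly_from_roots(zd))
  b <- gain_z * Re(poly_from_roots(rep(-1 + 0i, order)))
  list(b = b, a = a)
}

# Monic polynomial coefficients from roots, highest degree first.
poly_from_roots <- function(r) {
  cf <- 1 + 0i
  for (rt in r) cf <- c(cf, 0) - c(0, cf * rt)
  cf
}

# Direct-form II transposed IIR filter with initial state zi (length
# length(a) - 1), returning the filtered signal.
iir_filter <- function(b, a, x, zi = NULL) {
  n <- length(a)
  b <- b / a[1]; a <- a / a[1]
  z <- if (is.null(zi)) numeric(n - 1) else zi
  y <- numeric(length(x))
  for (m in seq_along(x)) {
    xm <- x[m]
    ym <- b[1] * xm + z[1]
    if (n > 2)
      for (i in 1:(n - 2)) z[i] <- b[i + 1] * xm + z[i + 1] - a[i + 1] * ym
    z[n - 1] <- b[n] * xm - a[n] * ym
    y[m] <- ym
  }
  y
}

# Steady-state initial filter state for a unit step input.
filter_zi <- function(b, a) {
  n <- length(a)
  b <- b / a[1]; a <- a / a[1]
  A <- diag(n - 1)
  A[, 1] <- A[, 1] + a[-1]
  if (n > 2) for (i in 1:(n - 2)) A[i, i + 1] <- A[i, i + 1] - 1
  B <- b[-1] - a[-1] * b[1]
  solve(A, B)
}

# Zero-phase filtering: odd-reflection padding, forward pass, backward
# pass, each initialised at steady state scaled by the first sample.
filtfilt_zero_phase <- function(b, a, x) {
  ntaps <- max(length(a), length(b))
  padlen <- 3L * ntaps
  if (length(x) <= padlen)
    stop(sprintf("signal of %d samples is shorter than the filter warm-up (%d)",
                 length(x), padlen + 1L), call. = FALSE)
  pre <- 2 * x[1] - x[(padlen + 1L):2L]
  post <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - padlen)]
  ext <- c(pre, x, post)
  zi <- filter_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + length(x))]
}

#' Velocity by differentiation plus zero-phase Butterworth smoothing
#'
#' Per axis and joint: central-difference time differentiation (one-sided
#' at the ends, scaled by the sampling rate) followed by a zero-phase
#' (forward-backward) low-pass Butterworth filter. Defaults: 2nd order,
#' 24 Hz cutoff.
#'
#' @param jrec a local-frame position [joint_recording()].
#' @param cutoff low-pass cutoff in Hz; must be below the Nyquist rate.
#' @param order filter order.
#' @return A velocity [joint_recording()] of the same length.
#' @export
velocity_butterworth <- function(jrec, cutoff = 24, order = 2) {
  stopifnot(inherits(jrec, "joint_recording"))
  if (jrec$frame_kind != "position" || jrec$coordinate_frame != "local")
    stop("expects local-frame position data", call. = FALSE)
  if (cutoff >= jrec$sampling_rate / 2)
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  co <- butter_lowpass(order, cutoff / (jrec$sampling_rate / 2))
  v <- jrec$values
  for (j in seq_along(jrec$joint_labels)) for (a in 1:3)
    v[, j, a] <- filtfilt_zero_phase(co$b, co$a,
                                     diff_central(jrec$values[, j, a],
                                                  jrec$sampling_rate))
  joint_recording(v, jrec$joint_labels, jrec$sampling_rate, "velocity",
                  "local", jrec$participant_id, jrec$stimulus_id)
}

# Savitzky-Golay first-derivative estimate with polynomial-fit boundary
# handling: interior samples use the central convolution stencil; the
# first/last half-windows evaluate the derivative of the polynomial fit to
# the first/last full window.
savgol_deriv <- function(x, window, polyorder, rate) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  A <- outer(seq(-h, h), 0:polyorder, `^`)
  # row of the pseudoinverse giving the fitted first-derivative at offset 0
  P <- solve(crossprod(A), t(A))
  w <- P[2L, ]
  v <- numeric(n)
  for (i in (h + 1L):(n - h)) v[i] <- sum(w * x[(i - h):(i + h)])
  # boundary: polynomial fitted to the first/last window, derivative
  # evaluated at each in-window offset
  cf <- P %*% x[1:window]
  dcf <- cf[-1] * seq_len(polyorder)
  for (i in 1:h) {
    tt <- i - 1L - h
    v[i] <- sum(dcf * tt^(0:(polyorder - 1L)))
  }
  cf <- P %*% x[(n - window + 1L):n]
  dcf <- cf[-1] * seq_len(polyorder)
  for (i in (n - h + 1L):n) {
    tt <- i - (n - h)
    v[i] <- sum(dcf * tt^(0:(polyorder - 1L)))
  }
  v * rate
}

#' Velocity by Savitzky-Golay derivative filtering
#'
#' First-derivative Savitzky-Golay estimate per axis (local least-squares
#' polynomial fit in a sliding window), scaled by the sampling rate.
#' Boundary samples evaluate the derivative of the polynomial fitted to
#' the first/last full window, so polynomials up to `polyorder` are
#' differentiated exactly everywhere. Defaults: window of 7 samples,
#' polynomial order 2.
#'
#' @param jrec a local-frame position [joint_recording()].
#' @param window odd window length in frames.
#' @param polyorder polynomial order, `< window`.
#' @return A velocity [joint_recording()] of the same length.
#' @export
velocity_savgol <- function(jrec, window = 7, polyorder = 2) {
  stopifnot(inherits(jrec, "joint_recording"))
  if (jrec$frame_kind != "position" || jrec$coordinate_frame != "local")
    stop("expects local-frame position data", call. = FALSE)
  if (window %% 2 == 0 || window < polyorder + 1)
    stop("window must be odd and at least polyorder + 1", call. = FALSE)
  if (dim(jrec$values)[1] < window)
    stop("fewer frames than the filter window", call. = FALSE)
  v <- jrec$values
  for (j in seq_along(jrec$joint_labels)) for (a in 1:3)
    v[, j, a] <- savgol_deriv(jrec$values[, j, a], as.integer(window),
                              as.integer(polyorder), jrec$sampling_rate)
  joint_recording(v, jrec$joint_labels, jrec$sampling_rate, "velocity",
                  "local", jrec$participant_id, jrec$stimulus_id)
}
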