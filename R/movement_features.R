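# Correntropy kernel covariance features.
#
# Each recording yields a D x D similarity matrix over the D = 3J
# univariate coordinate time series (joint-major dimension order, axis
# order mediolateral / anteroposterior / vertical), and the strictly lower
# triangle of that matrix, enumerated row-major, is the decoding feature
# vector (length D(D-1)/2; 1770 for the default 20-joint skeleton).

#' Correntropy between two time series
#'
#' A Gaussian-kernel similarity used as a nonlinear stand-in for
#' covariance:
#' \deqn{K(x, y) = \exp(-\|x - y\|_2^2 / (2 \sigma^2 T^2))}
#' where \eqn{T} is the series length. Normalising the squared distance by
#' \eqn{T^2} makes series of different stimulus durations comparable. The
#' value lies in (0, 1] and equals 1 exactly when `x == y`.
#'
#' The kernel bandwidth is interpreted on the input unit scale; with
#' trajectories in millimetres the conventional default is `sigma = 12`.
#'
#' @param x,y numeric vectors of equal length.
#' @param sigma kernel bandwidth (> 0).
#' @return A scalar in (0, 1].
#' @export
correntropy <- function(x, y, sigma = 12) {
  if (length(x) != length(y))
    stop("series lengths differ", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite input", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  T <- length(x)
  exp(-sum((x - y)^2) / (2 * sigma^2 * T^2))
}

#' Correntropy matrix of a joint recording
#'
#' Computes the D x D correntropy matrix over all `D = 3 * joints`
#' univariate coordinate series of a local-frame recording (position or
#' velocity). Dimensions are joint-major with axis order mediolateral,
#' anteroposterior, vertical.
#'
#' @param jrec a local-frame [joint_recording()].
#' @param sigma kernel bandwidth; default 12.0 on the millimetre scale.
#' @param unit_scale optional rescale factor applied to the values before
#'   the kernel (use e.g. `1e-3` for data in metres recorded against a
#'   millimetre-scale `sigma`).
#' @return An object of class `correntropy_matrix` with fields `K`,
#'   `sigma`, `T`, `dim_labels` (data frame of joint/axis per dimension)
#'   and `source_kind`.
#' @export
correntropy_matrix <- function(jrec, sigma = 12, unit_scale = 1) {
  stopifnot(inherits(jrec, "joint_recording"))
  if (jrec$coordinate_frame != "local")
    stop("features are defined on local-frame data", call. = FALSE)
  nj <- length(jrec$joint_labels)
  if (nj < 2L) stop("need at least 2 joints", call. = FALSE)
  T <- dim(jrec$values)[1]
  if (T < 1L) stop("empty recording", call. = FALSE)
  D <- 3L * nj
  # M: T x D, joint-major columns (joint 1 M/A/V, joint 2 M/A/V, ...)
  M <- matrix(aperm(jrec$values, c(1, 3, 2)), nrow = T) * unit_scale
  sq <- colSums(M * M)
  G <- crossprod(M)
  d2 <- outer(sq, sq, `+`) - 2 * G
  d2[d2 < 0] <- 0
  K <- exp(-d2 / (2 * sigma^2 * T^2))
  K <- (K + t(K)) / 2
  diag(K) <- 1
  dim_labels <- data.frame(
    joint = rep(jrec$joint_labels, each = 3L),
    axis = rep(c("mediolateral", "anteroposterior", "vertical"), nj),
    stringsAsFactors = FALSE)
  structure(list(K = K, sigma = sigma, T = T, dim_labels = dim_labels,
                 source_kind = jrec$frame_kind,
                 participant_id = jrec$participant_id,
                 stimulus_id = jrec$stimulus_id),
            class = "correntropy_matrix")
}

#' @export
print.correntropy_matrix <- function(x, ...) {
  cat(sprintf("<correntropy_matrix> %d x %d (sigma = %g, T = %d, %s)\n",
              nrow(x$K), ncol(x$K), x$sigma, x$T, x$source_kind))
  invisible(x)
}

# Row-major strictly-lower-triangle enumeration: element e runs over
# i = 2..D, j = 1..i-1 (1-based).
lower_tri_index <- function(D) {
  i <- rep(2:D, times = 1:(D - 1))
  j <- sequence(1:(D - 1))
  cbind(dim_i = i, dim_j = j)
}

#' Vectorise the strictly lower triangle of a correntropy matrix
#'
#' Elements are enumerated row-major over rows `i = 2..D`, columns
#' `j = 1..i-1`, giving `D(D-1)/2` values (1770 for D = 60). The index map
#' from element to dimension pair is returned alongside so model weights
#' can be attributed back to joints.
#'
#' @param K a [correntropy_matrix()].
#' @param tol maximum tolerated asymmetry.
#' @return An object of class `feature_vector` with fields `values`,
#'   `index_map` (data frame element/dim_i/dim_j), and identifiers.
#' @export
vectorize_lower <- function(K, tol = 1e-8) {
  stopifnot(inherits(K, "correntropy_matrix"))
  if (max(abs(K$K - t(K$K))) > tol)
    stop("matrix is asymmetric beyond tolerance", call. = FALSE)
  D <- nrow(K$K)
  idx <- lower_tri_index(D)
  structure(list(values = K$K[idx],
                 index_map = data.frame(element = seq_len(nrow(idx)),
                                        dim_i = idx[, 1], dim_j = idx[, 2]),
                 participant_id = K$participant_id,
                 stimulus_id = K$stimulus_id,
                 source_kind = K$source_kind,
                 D = D),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s / %s: length %d (D = %d, %s)\n",
              x$participant_id, x$stimulus_id, length(x$values), x$D,
              x$source_kind))
  invisible(x)
}

#' Feature element to dimension/joint lookup table
#'
#' Enumerates the strictly-lower-triangle elements of a D x D matrix
#' (row-major, `dim_i > dim_j`) and attributes each dimension to its joint
#' under joint-major ordering (`joint = ceiling(dim / 3)`).
#'
#' @param D dimension count; must be a multiple of 3.
#' @param joint_labels optional joint names of length `D / 3`.
#' @return A data frame with columns `element`, `dim_i`, `dim_j`,
#'   `joint_i`, `joint_j` (joint indices), and, when labels are given,
#'   `joint_i_label`, `joint_j_label`.
#' @export
feature_pair_index <- function(D, joint_labels = NULL) {
  if (D %% 3L != 0L) stop("D must be a multiple of 3", call. = FALSE)
  idx <- lower_tri_index(D)
  tab <- data.frame(element = seq_len(nrow(idx)),
                    dim_i = idx[, 1], dim_j = idx[, 2],
                    joint_i = (idx[, 1] - 1L) %/% 3L + 1L,
                    joint_j = (idx[, 2] - 1L) %/% 3L + 1L)
  if (!is.null(joint_labels)) {
    stopifnot(length(joint_labels) == D / 3L)
    tab$joint_i_label <- joint_labels[tab$joint_i]
    tab$joint_j_label <- joint_labels[tab$joint_j]
  }
  tab
}

#' Compute a feature vector straight from a marker recording
#'
#' Convenience wrapper running joint derivation, the local-coordinate
#' transform, optional velocity estimation, and correntropy
#' vectorisation.
#'
#' @param rec a [marker_recording()].
#' @param map a [marker_joint_map()].
#' @param source_kind `"position"` or `"velocity"`.
#' @param velocity_filter `"butterworth"` or `"savgol"` when
#'   `source_kind = "velocity"`.
#' @param sigma kernel bandwidth.
#' @param ... passed to the velocity estimator.
#' @return A `feature_vector`.
#' @export
extract_features <- function(rec, map = default_joint_map(),
                             source_kind = c("position", "velocity"),
                             velocity_filter = c("butterworth", "savgol"),
                             sigma = 12, ...) {
  source_kind <- match.arg(source_kind)
  velocity_filter <- match.arg(velocity_filter)
  jrec <- to_local_coordinates(derive_joints(rec, map), map)
  if (source_kind == "velocity")
    jrec <- switch(velocity_filter,
                   butterworth = velocity_butterworth(jrec, ...),
                   savgol = velocity_savgol(jrec, ...))
  vectorize_lower(correntropy_matrix(jrec, sigma = sigma))
}
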