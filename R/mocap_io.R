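# Reading, validating, gap-filling, trimming and writing optical
# motion-capture marker trajectories, plus the marker-to-joint mapping
# configuration.
#
# File dialect: wide tab-separated table, header "frame", "time", then one
# <marker>_X, <marker>_Y, <marker>_Z triplet per marker. Units are
# millimetres; the coordinate system is right-handed with the vertical as
# the third axis. Missing samples are empty cells.

#' Construct a marker recording
#'
#' A `marker_recording` holds raw per-frame 3-D marker positions together
#' with identifiers, the sampling rate and a missingness mask.
#'
#' @param positions numeric array of dimension frames x markers x 3
#'   (millimetres; right-handed, vertical = third axis).
#' @param marker_labels character vector of unique marker names, one per
#'   column of `positions`.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param participant_id,stimulus_id identifiers carried through the
#'   pipeline.
#' @param missing_mask logical frames x markers matrix; `TRUE` marks a
#'   missing sample. Defaults to all observed.
#' @return An object of class `marker_recording`.
#' @export
marker_recording <- function(positions, marker_labels, sampling_rate,
                             participant_id = "p1", stimulus_id = "s1",
                             missing_mask = NULL) {
  if (length(dim(positions)) != 3L || dim(positions)[3] != 3L)
    stop("`positions` must be a frames x markers x 3 array", call. = FALSE)
  nf <- dim(positions)[1]
  nm <- dim(positions)[2]
  if (nf < 2L) stop("a recording needs at least 2 frames", call. = FALSE)
  if (length(marker_labels) != nm)
    stop("positions second dimension must equal the number of marker labels",
         call. = FALSE)
  if (anyDuplicated(marker_labels))
    stop("marker labels must be unique", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("`sampling_rate` must be a positive number (Hz)", call. = FALSE)
  if (is.null(missing_mask))
    missing_mask <- matrix(FALSE, nf, nm)
  storage.mode(missing_mask) <- "logical"
  if (!identical(dim(missing_mask), c(nf, nm)))
    stop("`missing_mask` must be frames x markers", call. = FALSE)
  obs <- !missing_mask
  if (!all(is.finite(positions[rep(obs, 3L)])))
    stop("positions must be finite wherever not masked missing", call. = FALSE)
  structure(list(participant_id = as.character(participant_id),
                 stimulus_id = as.character(stimulus_id),
                 marker_labels = as.character(marker_labels),
                 positions = positions,
                 sampling_rate = sampling_rate,
                 missing_mask = missing_mask),
            class = "marker_recording")
}

#' @export
print.marker_recording <- function(x, ...) {
  cat(sprintf("<marker_recording> %s / %s: %d frames x %d markers @ %g Hz (%.1f s, %d missing samples)\n",
              x$participant_id, x$stimulus_id, nrow(x$missing_mask),
              length(x$marker_labels), x$sampling_rate,
              nrow(x$missing_mask) / x$sampling_rate, sum(x$missing_mask)))
  invisible(x)
}

n_frames <- function(rec) dim(rec$positions)[1]

#' Read a marker trajectory file
#'
#' Parses the wide TSV dialect written by [write_marker_recording()]:
#' columns `frame`, `time`, then `<marker>_X/_Y/_Z` triplets. Blank cells
#' become missing samples. The sampling rate is inferred from the median
#' frame interval of the time column unless `expected_rate` is supplied.
#'
#' @param path path to a tab-separated trajectory file.
#' @param expected_rate optional sampling rate in Hz overriding inference.
#' @param participant_id,stimulus_id identifiers for the returned recording;
#'   default to the file name.
#' @return A [marker_recording()].
#' @export
read_marker_recording <- function(path, expected_rate = NULL,
                                  participant_id = NULL, stimulus_id = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "numeric", na.strings = c("", "NA"))
  cn <- names(tab)
  if (length(cn) < 3L || cn[1] != "frame" || cn[2] != "time")
    stop("malformed header: expected columns frame, time, <marker>_X/_Y/_Z ...",
         call. = FALSE)
  mcols <- cn[-(1:2)]
  if (length(mcols) %% 3L != 0L)
    stop("marker column count is not a multiple of 3", call. = FALSE)
  labs <- sub("_X$", "", mcols[seq(1, length(mcols), by = 3)])
  expect <- as.vector(rbind(paste0(labs, "_X"), paste0(labs, "_Y"),
                            paste0(labs, "_Z")))
  if (!identical(mcols, expect))
    stop("malformed header: marker columns must be <name>_X, <name>_Y, <name>_Z triplets",
         call. = FALSE)
  nf <- nrow(tab)
  if (nf < 2L) stop("fewer than 2 frames", call. = FALSE)
  tm <- tab$time
  if (any(!is.finite(tm)) || any(diff(tm) <= 0))
    stop("time column must be finite and strictly increasing", call. = FALSE)
  rate <- if (is.null(expected_rate)) 1 / stats::median(diff(tm)) else expected_rate
  nm <- length(labs)
  pos <- array(NA_real_, c(nf, nm, 3L))
  for (a in 1:3) pos[, , a] <- as.matrix(tab[, 2L + seq(a, 3L * nm, by = 3L)])
  mask <- apply(is.na(pos), c(1, 2), any)
  pos[is.na(pos)] <- 0
  base <- tools::file_path_sans_ext(basename(path))
  marker_recording(pos, labs, rate,
                   participant_id = participant_id %||% base,
                   stimulus_id = stimulus_id %||% base,
                   missing_mask = mask)
}

#' Write a marker trajectory file
#'
#' Emits the same tab-separated dialect that [read_marker_recording()]
#' accepts; masked samples are written as empty cells. Columns follow the
#' recording's marker order.
#'
#' @param rec a [marker_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_recording <- function(rec, path) {
  stopifnot(inherits(rec, "marker_recording"))
  nf <- n_frames(rec)
  nm <- length(rec$marker_labels)
  out <- matrix(NA_real_, nf, 3L * nm)
  for (a in 1:3) out[, seq(a, 3L * nm, by = 3L)] <- rec$positions[, , a]
  out[rec$missing_mask[, rep(seq_len(nm), each = 3L), drop = FALSE]] <- NA_real_
  colnames(out) <- as.vector(rbind(paste0(rec$marker_labels, "_X"),
                                   paste0(rec$marker_labels, "_Y"),
                                   paste0(rec$marker_labels, "_Z")))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  df <- data.frame(frame = seq_len(nf) - 1L,
                   time = fmt((seq_len(nf) - 1L) / rec$sampling_rate))
  body <- as.data.frame(apply(out, 2, fmt), check.names = FALSE)
  df <- cbind(df, body)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Fill short occlusion gaps by linear interpolation
#'
#' Runs of missing samples no longer than `max_gap` frames are replaced by
#' per-axis linear interpolation between the flanking observed frames, and
#' the missingness mask is cleared. Gaps touching the first or last frame,
#' or longer than `max_gap`, are an error: there is nothing defensible to
#' extrapolate from.
#'
#' @param rec a [marker_recording()].
#' @param max_gap maximum gap length in frames that may be interpolated.
#' @return A gap-free [marker_recording()].
#' @export
fill_gaps <- function(rec, max_gap = 10L) {
  stopifnot(inherits(rec, "marker_recording"))
  if (!any(rec$missing_mask)) return(rec)
  pos <- rec$positions
  for (m in seq_along(rec$marker_labels)) {
    miss <- rec$missing_mask[, m]
    if (!any(miss)) next
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      if (starts[k] == 1L || ends[k] == n_frames(rec))
        stop(sprintf("marker '%s': gap at sequence boundary cannot be filled",
                     rec$marker_labels[m]), call. = FALSE)
      if (r$lengths[k] > max_gap)
        stop(sprintf("marker '%s': gap of %d frames exceeds max_gap = %d",
                     rec$marker_labels[m], r$lengths[k], max_gap), call. = FALSE)
      i0 <- starts[k] - 1L
      i1 <- ends[k] + 1L
      w <- (starts[k]:ends[k] - i0) / (i1 - i0)
      for (a in 1:3)
        pos[starts[k]:ends[k], m, a] <-
          (1 - w) * pos[i0, m, a] + w * pos[i1, m, a]
    }
  }
  marker_recording(pos, rec$marker_labels, rec$sampling_rate,
                   rec$participant_id, rec$stimulus_id)
}

#' Trim a recording to a time window
#'
#' Retains frames in `[start, end)` seconds (start inclusive, end
#' exclusive); the boundary frame indices are `round(t * rate)`.
#'
#' @param rec a [marker_recording()].
#' @param start,end window boundaries in seconds, `0 <= start < end <=`
#'   recording duration.
#' @return The trimmed [marker_recording()].
#' @export
trim_to_window <- function(rec, start, end) {
  stopifnot(inherits(rec, "marker_recording"))
  nf <- n_frames(rec)
  dur <- nf / rec$sampling_rate
  if (!(start >= 0 && start < end))
    stop("need 0 <= start < end", call. = FALSE)
  if (end > dur + 1e-9)
    stop(sprintf("window end %.3f s exceeds recording duration %.3f s",
                 end, dur), call. = FALSE)
  i0 <- round(start * rec$sampling_rate)
  i1 <- round(end * rec$sampling_rate)
  if (i1 - i0 < 2L) stop("trimmed window holds fewer than 2 frames", call. = FALSE)
  idx <- (i0 + 1L):i1
  marker_recording(rec$positions[idx, , , drop = FALSE], rec$marker_labels,
                   rec$sampling_rate, rec$participant_id, rec$stimulus_id,
                   rec$missing_mask[idx, , drop = FALSE])
}

#' Construct a marker-to-joint mapping
#'
#' Defines how raw markers are reduced to the 20 joints used throughout the
#' pipeline: each joint is the per-frame mean of one or more markers. The
#' map also designates the root (pelvis-centre) joint and the two hip
#' joints that anchor the local coordinate system, and the pair groups used
#' for the 12-joint reduction of importance profiles (left/right pairs are
#' averaged; axial joints are singletons).
#'
#' @param joint_definitions named list: joint name -> character vector of
#'   marker names (non-empty). Order fixes the joint order everywhere.
#' @param root_joint,left_hip_joint,right_hip_joint joint names anchoring
#'   the local frame.
#' @param pair_groups named list: group name -> 1 or 2 joint names; must
#'   partition the joint set.
#' @return An object of class `marker_joint_map`.
#' @export
marker_joint_map <- function(joint_definitions, root_joint, left_hip_joint,
                             right_hip_joint, pair_groups) {
  jn <- names(joint_definitions)
  if (is.null(jn) || anyDuplicated(jn) || any(jn == ""))
    stop("joint_definitions must be a uniquely named list", call. = FALSE)
  if (any(lengths(joint_definitions) == 0L))
    stop("every joint needs at least one marker", call. = FALSE)
  for (anchor in c(root_joint, left_hip_joint, right_hip_joint))
    if (!anchor %in% jn)
      stop(sprintf("designated joint '%s' is not among the joint definitions",
                   anchor), call. = FALSE)
  members <- unlist(pair_groups, use.names = FALSE)
  if (anyDuplicated(members))
    stop("a joint appears in more than one pair group", call. = FALSE)
  if (!setequal(members, jn))
    stop("pair groups must cover every joint exactly once", call. = FALSE)
  if (any(!lengths(pair_groups) %in% 1:2))
    stop("pair groups must hold 1 or 2 joints", call. = FALSE)
  structure(list(joint_definitions = joint_definitions,
                 root_joint = root_joint,
                 left_hip_joint = left_hip_joint,
                 right_hip_joint = right_hip_joint,
                 pair_groups = pair_groups),
            class = "marker_joint_map")
}

#' @export
print.marker_joint_map <- function(x, ...) {
  cat(sprintf("<marker_joint_map> %d joints from %d markers, %d pair groups (root = '%s')\n",
              length(x$joint_definitions),
              length(unique(unlist(x$joint_definitions))),
              length(x$pair_groups), x$root_joint))
  invisible(x)
}

#' Default 20-joint, 12-group mapping
#'
#' The default skeleton: `root`, `torso`, `neck`, `head` as axial
#' singletons and `hip`, `knee`, `ankle`, `toe`, `shoulder`, `elbow`,
#' `wrist`, `finger` as left/right pairs (20 joints, 12 pair groups). The
#' root is the mean of two back-hip markers and the head the mean of three
#' head markers; all other joints pass a single marker through.
#'
#' @return A [marker_joint_map()].
#' @export
default_joint_map <- function() {
  singles <- c("torso", "neck",
               "hip_l", "hip_r", "knee_l", "knee_r", "ankle_l", "ankle_r",
               "toe_l", "toe_r", "shoulder_l", "shoulder_r", "elbow_l",
               "elbow_r", "wrist_l", "wrist_r", "finger_l", "finger_r")
  defs <- c(list(root = c("root_back_l", "root_back_r")),
            stats::setNames(as.list(singles), singles),
            list(head = c("head_front", "head_left", "head_right")))
  ord <- c("root", "torso", "neck", "head",
           "hip_l", "hip_r", "knee_l", "knee_r", "ankle_l", "ankle_r",
           "toe_l", "toe_r", "shoulder_l", "shoulder_r", "elbow_l", "elbow_r",
           "wrist_l", "wrist_r", "finger_l", "finger_r")
  defs <- defs[ord]
  groups <- list(root = "root", torso = "torso", neck = "neck", head = "head",
                 hip = c("hip_l", "hip_r"), knee = c("knee_l", "knee_r"),
                 ankle = c("ankle_l", "ankle_r"), toe = c("toe_l", "toe_r"),
                 shoulder = c("shoulder_l", "shoulder_r"),
                 elbow = c("elbow_l", "elbow_r"),
                 wrist = c("wrist_l", "wrist_r"),
                 finger = c("finger_l", "finger_r"))
  marker_joint_map(defs, "root", "hip_l", "hip_r", groups)
}

#' Read a marker-joint mapping configuration
#'
#' Plain-text key/value format, one statement per line; `#` starts a
#' comment. Statements:
#' \preformatted{
#' joint <name> = <marker> [<marker> ...]
#' group <name> = <joint> [<joint>]
#' root = <joint>
#' left_hip = <joint>
#' right_hip = <joint>
#' }
#'
#' @param path path to the configuration file.
#' @return A validated [marker_joint_map()].
#' @seealso [write_marker_joint_map()] for the emitter,
#'   [default_joint_map()] for the shipped default.
#' @export
read_marker_joint_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defs <- list(); groups <- list()
  root <- NULL; lhip <- NULL; rhip <- NULL
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop(sprintf("cannot parse joint-map line: '%s'", ln), call. = FALSE)
    key <- strsplit(trimws(kv[1]), "[[:space:]]+")[[1]]
    val <- strsplit(trimws(kv[2]), "[[:space:]]+")[[1]]
    if (identical(key[1], "joint") && length(key) == 2L) {
      defs[[key[2]]] <- val
    } else if (identical(key[1], "group") && length(key) == 2L) {
      groups[[key[2]]] <- val
    } else if (identical(key, "root")) {
      root <- val
    } else if (identical(key, "left_hip")) {
      lhip <- val
    } else if (identical(key, "right_hip")) {
      rhip <- val
    } else {
      stop(sprintf("unknown joint-map statement: '%s'", ln), call. = FALSE)
    }
  }
  if (is.null(root)) stop("joint map does not designate a root joint", call. = FALSE)
  if (is.null(lhip) || is.null(rhip))
    stop("joint map must designate left_hip and right_hip joints", call. = FALSE)
  marker_joint_map(defs, root, lhip, rhip, groups)
}

#' Write a marker-joint mapping configuration
#'
#' @param map a [marker_joint_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_joint_map <- function(map, path) {
  stopifnot(inherits(map, "marker_joint_map"))
  out <- c(
    vapply(names(map$joint_definitions), function(j)
      paste("joint", j, "=", paste(map$joint_definitions[[j]], collapse = " ")),
      character(1)),
    paste("root =", map$root_joint),
    paste("left_hip =", map$left_hip_joint),
    paste("right_hip =", map$right_hip_joint),
    vapply(names(map$pair_groups), function(g)
      paste("group", g, "=", paste(map$pair_groups[[g]], collapse = " ")),
      character(1)))
  writeLines(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
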