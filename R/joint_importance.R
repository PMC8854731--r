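# Joint Importance: attributing cross-validated linear-model weights back
# to the joints whose coordinate pairs generated each feature element.
#
# Every feature element is the correntropy of one dimension pair; its
# absolute weight is credited to each joint the pair touches (once per
# joint, even when both dimensions belong to the same joint), summed over
# the k fold models, and min-max normalised into a length-20 profile.
# Left/right pairs are then averaged into 12 pair groups.

#' Accumulate absolute model weights onto joints
#'
#' For each feature element with endpoint joints `(a, b)`, `|w|` is added
#' to joint `a`'s sum and, if `b != a`, to joint `b`'s sum; accumulated
#' over all supplied fold models.
#'
#' @param models list of `trained_linear_model`s sharing one feature space.
#' @param pair_index table from [feature_pair_index()] matching that
#'   feature space.
#' @param n_joints number of joints (defaults to the maximum joint index
#'   in the table).
#' @return Numeric vector of raw non-negative per-joint sums.
#' @export
accumulate_importance <- function(models, pair_index,
                                  n_joints = max(pair_index$joint_i)) {
  stopifnot(length(models) >= 1)
  sums <- numeric(n_joints)
  for (m in models) {
    if (length(m$weights) != nrow(pair_index))
      stop("model weight length does not match the pair index", call. = FALSE)
    aw <- abs(m$weights)
    si <- rowsum(aw, pair_index$joint_i)
    sums[as.integer(rownames(si))] <- sums[as.integer(rownames(si))] + si
    off <- pair_index$joint_j != pair_index$joint_i
    if (any(off)) {
      sj <- rowsum(aw[off], pair_index$joint_j[off])
      sums[as.integer(rownames(sj))] <- sums[as.integer(rownames(sj))] + sj
    }
  }
  sums
}

#' Min-max normalisation to \[0, 1\]
#'
#' `(x - min) / (max - min)`; a constant vector maps to all zeros rather
#' than dividing by zero.
#'
#' @param raw numeric vector.
#' @return Values in \[0, 1\].
#' @export
minmax_normalize <- function(raw) {
  if (!length(raw)) stop("empty input", call. = FALSE)
  if (!all(is.finite(raw))) stop("non-finite input", call. = FALSE)
  rng <- range(raw)
  if (rng[1] == rng[2]) return(rep(0, length(raw)))
  (raw - rng[1]) / (rng[2] - rng[1])
}

#' Construct a joint-importance profile
#'
#' Wraps raw per-joint sums into a normalised profile object.
#'
#' @param raw_sums raw per-joint accumulated weights.
#' @param joint_labels names matching `raw_sums`.
#' @param target_name decoded target the weights came from.
#' @param granularity `"full20"` or `"paired12"`.
#' @param dataset_tag identifier for the source dataset/cohort.
#' @return An object of class `joint_importance_profile`.
#' @export
joint_importance_profile <- function(raw_sums, joint_labels, target_name,
                                     granularity = c("full20", "paired12"),
                                     dataset_tag = "d1") {
  granularity <- match.arg(granularity)
  stopifnot(length(raw_sums) == length(joint_labels))
  structure(list(joint_labels = joint_labels,
                 values = minmax_normalize(raw_sums),
                 raw_sums = as.numeric(raw_sums),
                 granularity = granularity, target_name = target_name,
                 dataset_tag = dataset_tag),
            class = "joint_importance_profile")
}

#' @export
print.joint_importance_profile <- function(x, ...) {
  cat(sprintf("<joint_importance_profile> %s [%s, %s]\n", x$target_name,
              x$granularity, x$dataset_tag))
  print(stats::setNames(round(x$values, 3), x$joint_labels))
  invisible(x)
}

#' Reduce a 20-joint profile to 12 pair-averaged groups
#'
#' Group values are means of the member joints' raw (pre-normalisation)
#' sums; the reduced vector is then min-max normalised. Averaging before
#' normalising keeps the normalisation anchors from distorting pair
#' means; set `normalize_first = TRUE` for the alternative order.
#'
#' @param raw20 raw per-joint sums over the full joint set.
#' @param joint_labels names matching `raw20`.
#' @param pair_groups named list from the [marker_joint_map()].
#' @param target_name,dataset_tag metadata for the resulting profile.
#' @param normalize_first normalise the full profile before averaging.
#' @return A `joint_importance_profile` with `granularity = "paired12"`.
#' @export
reduce_pairs <- function(raw20, joint_labels, pair_groups,
                         target_name = "target", dataset_tag = "d1",
                         normalize_first = FALSE) {
  stopifnot(length(raw20) == length(joint_labels))
  unknown <- setdiff(unlist(pair_groups), joint_labels)
  if (length(unknown))
    stop(sprintf("pair group references unknown joints: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  src <- if (normalize_first) minmax_normalize(raw20) else as.numeric(raw20)
  vals <- vapply(pair_groups, function(members)
    mean(src[match(members, joint_labels)]), numeric(1))
  joint_importance_profile(vals, names(pair_groups), target_name,
                           granularity = "paired12", dataset_tag = dataset_tag)
}

#' Joint importance from cross-validated fold models
#'
#' End-to-end attribution: sums absolute weights across fold models onto
#' joints, and returns both the full 20-joint profile and the 12-group
#' pair-averaged profile.
#'
#' @param models list of fold `trained_linear_model`s (e.g. from
#'   [crossval_experiment()]).
#' @param map the [marker_joint_map()] fixing joint order and pair groups.
#' @param target_name,dataset_tag metadata.
#' @return A list with elements `full20` and `paired12`, both
#'   `joint_importance_profile`s.
#' @export
joint_importance <- function(models, map = default_joint_map(),
                             target_name = "target", dataset_tag = "d1") {
  labels <- names(map$joint_definitions)
  D <- 3L * length(labels)
  pidx <- feature_pair_index(D, labels)
  raw <- accumulate_importance(models, pidx, n_joints = length(labels))
  list(full20 = joint_importance_profile(raw, labels, target_name,
                                         "full20", dataset_tag),
       paired12 = reduce_pairs(raw, labels, map$pair_groups, target_name,
                               dataset_tag))
}

#' Write importance profiles as CSV
#'
#' One row per joint: `dataset_tag, target_name, granularity, joint,
#' raw_sum, value`.
#'
#' @param profiles a single profile or list of `joint_importance_profile`s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_importance_profiles <- function(profiles, path) {
  if (inherits(profiles, "joint_importance_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p)
    data.frame(dataset_tag = p$dataset_tag, target_name = p$target_name,
               granularity = p$granularity, joint = p$joint_labels,
               raw_sum = p$raw_sums, value = p$values,
               stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read importance profiles from CSV
#'
#' @param path CSV written by [write_importance_profiles()].
#' @return A list of `joint_importance_profile`s.
#' @export
read_importance_profiles <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- interaction(tab$dataset_tag, tab$target_name, tab$granularity,
                     drop = TRUE)
  lapply(split(tab, key), function(d)
    joint_importance_profile(d$raw_sum, d$joint, d$target_name[1],
                             granularity = d$granularity[1],
                             dataset_tag = d$dataset_tag[1]))
}
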