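#' Lower-limb joint vocabulary
#'
#' The eight joints tracked for drop-vertical-jump analysis: hip, knee,
#' ankle and foot on each side. All skeletal input must provide exactly
#' these joints in every frame (after gap filling).
#'
#' @return Character vector of the eight joint names.
#' @export
dvj_joint_names <- function() {
  as.vector(outer(c("hip", "knee", "ankle", "foot"),
                  c("left", "right"), paste, sep = "_"))
}

#' Construct a skeleton sequence
#'
#' A `skeleton_sequence` holds per-frame 3-D positions (metres, subject
#' frame) of the eight lower-limb joints captured by one device. The
#' subject frame has +Y vertical up, +Z pointing from the subject toward
#' the sensor (anterior) and +X the subject's anatomical left; the subject
#' faces the sensor.
#'
#' @param joints Long-format data frame with columns `frame`, `joint`,
#'   `x`, `y`, `z` (a `time` column, if present, is checked against
#'   `frame / fps`). One row per joint per frame; every frame must contain
#'   all eight joints from [dvj_joint_names()].
#' @param device_id Label for the capturing device (e.g. `"azure"`, `"v2"`).
#' @param fps Capture rate in frames per second (default 30).
#' @return An object of class `skeleton_sequence`: a list with elements
#'   `device_id`, `fps`, `frame` (integer frame indices), `time` (seconds)
#'   and `joints` (named list of n-by-3 position matrices).
#' @export
skeleton_sequence <- function(joints, device_id = "unknown", fps = 30) {
  if (!is.data.frame(joints)) abort_validation("`joints` must be a data frame")
  need <- c("frame", "joint", "x", "y", "z")
  miss <- setdiff(need, names(joints))
  if (length(miss)) abort_format("missing required column(s): %s",
                                 paste(miss, collapse = ", "))
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0)
    abort_parameter("fps must be a single positive number")

  frames <- sort(unique(as.integer(joints$frame)))
  if (length(frames) < 2) abort_validation("a skeleton sequence needs at least 2 frames")
  if (any(frames < 0)) abort_validation("frame indices must be non-negative")
  step <- unique(diff(frames))
  if (length(step) != 1)
    abort_validation("frame indices must be strictly increasing with uniform spacing")

  jn <- dvj_joint_names()
  unknown <- setdiff(unique(joints$joint), jn)
  if (length(unknown))
    abort_validation("unknown joint name(s): %s", paste(unknown, collapse = ", "))

  n <- length(frames)
  pos <- vector("list", length(jn)); names(pos) <- jn
  idx <- match(as.integer(joints$frame), frames)
  for (j in jn) {
    sel <- joints$joint == j
    if (sum(sel) != n) {
      have <- frames[unique(idx[sel])]
      lack <- setdiff(frames, have)
      if (length(lack))
        abort_validation("frame %d is missing joint %s", lack[1], j)
      abort_validation("joint %s appears more than once in a frame", j)
    }
    m <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
    m[idx[sel], ] <- as.matrix(joints[sel, c("x", "y", "z")])
    if (!all(is.finite(m)))
      abort_validation("non-finite position for joint %s", j)
    pos[[j]] <- m
  }

  tm <- frames / fps
  if ("time" %in% names(joints)) {
    tgiven <- joints$time[match(frames, as.integer(joints$frame))]
    if (any(abs(tgiven - tm) > 1e-6))
      abort_validation("time column inconsistent with frame/fps (max dev %.3g s)",
                       max(abs(tgiven - tm)))
  }

  structure(
    list(device_id = as.character(device_id), fps = fps,
         frame = frames, time = tm, joints = pos),
    class = "skeleton_sequence"
  )
}

# fast internal constructor for trusted inputs (e.g. forward kinematics):
# pos is a complete named list of n-by-3 matrices, frames a uniform grid
.new_skeleton_sequence <- function(pos, frames, device_id, fps) {
  structure(
    list(device_id = as.character(device_id), fps = fps,
         frame = frames, time = frames / fps, joints = pos),
    class = "skeleton_sequence"
  )
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat(sprintf("<skeleton_sequence> device=%s fps=%g frames=%d (%.2f s)\n",
              x$device_id, x$fps, length(x$frame),
              length(x$frame) / x$fps))
  invisible(x)
}

#' Number of frames in a skeleton sequence
#' @param seq A [skeleton_sequence()].
#' @return Integer frame count.
#' @export
n_frames <- function(seq) length(seq$frame)

#' Extract one joint's trajectory
#' @param seq A [skeleton_sequence()].
#' @param joint One of [dvj_joint_names()].
#' @return n-by-3 matrix of positions (metres).
#' @export
joint_position <- function(seq, joint) {
  if (!joint %in% dvj_joint_names()) abort_parameter("unknown joint '%s'", joint)
  seq$joints[[joint]]
}

#' @export
as.data.frame.skeleton_sequence <- function(x, ...) {
  n <- length(x$frame)
  jn <- dvj_joint_names()
  do.call(rbind, lapply(jn, function(j) {
    m <- x$joints[[j]]
    data.frame(frame = x$frame, time = x$time, joint = j,
               x = m[, 1], y = m[, 2], z = m[, 3])
  }))
}

#' Interpolate short runs of missing joint samples
#'
#' Depth sensors intermittently drop individual joints. Runs of at most
#' `max_gap` consecutive missing samples for a joint are filled by linear
#' interpolation between the flanking observed samples; longer runs, or
#' missing samples at the first/last frame (no flank), are validation
#' errors. `max_gap = 0` disables filling.
#'
#' @param joints Long-format data frame as for [skeleton_sequence()],
#'   possibly with joint samples absent in some frames. The frame grid is
#'   the range of observed frame indices.
#' @param max_gap Maximum fillable run length in frames (default 2,
#'   about 67 ms at 30 fps; longer occlusions invalidate event triggers).
#' @inheritParams skeleton_sequence
#' @return A complete, validated [skeleton_sequence()].
#' @export
fill_short_gaps <- function(joints, max_gap = 2, device_id = "unknown", fps = 30) {
  if (!is.numeric(max_gap) || max_gap < 0) abort_parameter("max_gap must be >= 0")
  need <- c("frame", "joint", "x", "y", "z")
  miss <- setdiff(need, names(joints))
  if (length(miss)) abort_format("missing required column(s): %s",
                                 paste(miss, collapse = ", "))
  fr <- as.integer(joints$frame)
  grid <- seq(min(fr), max(fr))
  jn <- dvj_joint_names()
  out <- vector("list", length(jn))
  for (i in seq_along(jn)) {
    j <- jn[i]
    sel <- joints$joint == j
    have <- fr[sel]
    if (anyDuplicated(have))
      abort_validation("joint %s appears more than once in a frame", j)
    m <- matrix(NA_real_, length(grid), 3)
    m[match(have, grid), ] <- as.matrix(joints[sel, c("x", "y", "z")])
    hole <- which(is.na(m[, 1]))
    if (length(hole)) {
      runs <- split(hole, cumsum(c(1, diff(hole) != 1)))
      for (r in runs) {
        lo <- min(r) - 1; hi <- max(r) + 1
        if (lo < 1 || hi > length(grid))
          abort_validation("joint %s missing at sequence boundary (frames %d-%d)",
                           j, grid[min(r)], grid[max(r)])
        if (length(r) > max_gap)
          abort_validation("joint %s gap of %d frames (frames %d-%d) exceeds max_gap = %d",
                           j, length(r), grid[min(r)], grid[max(r)], max_gap)
        w <- (r - lo) / (hi - lo)
        m[r, ] <- (1 - w) %o% m[lo, ] + w %o% m[hi, ]
      }
    }
    out[[i]] <- data.frame(frame = grid, joint = j,
                           x = m[, 1], y = m[, 2], z = m[, 3])
  }
  skeleton_sequence(do.call(rbind, out), device_id = device_id, fps = fps)
}
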