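# Kinematic event triggers for a single drop vertical jump:
#  - initial contact (IC): the foot joint stops travelling downward;
#  - peak coronal (PC): most-valgus (most negative) coronal angle after IC;
#  - peak sagittal (PS): largest flexion angle over the whole recording.

.moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x); h <- (w - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1); hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

.central_diff <- function(s, fps) {
  n <- length(s)
  v <- numeric(n)
  v[1] <- (s[2] - s[1]) * fps
  v[n] <- (s[n] - s[n - 1]) * fps
  if (n > 2) v[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) * fps / 2
  v
}

#' Vertical velocity of a joint
#'
#' Central-difference velocity of the joint's Y (vertical) coordinate,
#' optionally after a centred moving-average filter on position. Endpoints
#' use one-sided differences.
#'
#' @param seq A [skeleton_sequence()].
#' @param joint_name One of [dvj_joint_names()].
#' @param smoothing_window Odd window length (frames) for the position
#'   filter; 1 disables smoothing. Default 3: at 30 fps the minimal window
#'   that suppresses single-frame sensor jitter without shifting event
#'   timing by more than one frame.
#' @return Numeric vector of velocities (m/s), one per frame.
#' @export
vertical_velocity <- function(seq, joint_name, smoothing_window = 3) {
  if (smoothing_window < 1 || smoothing_window %% 2 != 1)
    abort_parameter("smoothing_window must be odd and >= 1")
  if (smoothing_window >= n_frames(seq))
    abort_parameter("smoothing_window (%d) must be smaller than the sequence (%d frames)",
                    smoothing_window, n_frames(seq))
  h <- joint_position(seq, joint_name)[, 2]
  .central_diff(.moving_average(h, smoothing_window), seq$fps)
}

# one side's landing: index of the first frame at which the foot has
# stopped travelling downward. The moving-average filter and the central
# difference both delay the velocity zero crossing by up to one frame
# each, so after locating the crossing the event is refined on raw
# positions: the earliest frame already at (within settle_tol of) the
# height where the velocity first turned non-negative.
.detect_landing_side <- function(seq, joint, smoothing_window, min_drop, settle_tol) {
  h <- joint_position(seq, joint)[, 2]
  s <- .moving_average(h, smoothing_window)
  v <- .central_diff(s, seq$fps)
  d <- which(s <= s[1] - min_drop)[1]
  if (is.na(d))
    abort_detection("no drop phase found (foot '%s' never descends %.2f m)",
                    joint, min_drop)
  k <- which(v >= 0 & seq_along(v) >= d)[1]
  if (is.na(k))
    abort_detection("no landing found (foot '%s' velocity never returns to >= 0)",
                    joint)
  m <- which(h[seq_len(k)] <= h[k] + settle_tol)[1]
  if (is.na(m)) k else m
}

#' Detect the initial-contact frame
#'
#' The trigger is the moment the foot joint stops travelling in the
#' downward direction: after a descent of at least `min_drop` from the
#' starting height, the first frame at which the foot's vertical velocity
#' transitions from negative to non-negative. Both feet are tested and
#' the earlier event is returned (the feet contact the floor as a pair);
#' ties resolve to the left side.
#'
#' @inheritParams vertical_velocity
#' @param joint `"foot"` (default) or `"ankle"` as the tracked landing
#'   joint.
#' @param min_drop Minimum descent (m) that qualifies as a drop phase
#'   (default 0.10; rejects standing sway, well below a 0.31 m box drop).
#' @param settle_tol Height tolerance (m) used to refine the event to the
#'   first frame already at landing height, cancelling the one-to-two
#'   frame lag of the smoothed central-difference velocity (default 1e-3).
#' @return List with `frame` (the common IC frame index), `side` (which
#'   foot triggered it) and `side_frames` (named per-side IC frames).
#' @export
detect_initial_contact <- function(seq, joint = c("foot", "ankle"),
                                   smoothing_window = 3, min_drop = 0.10,
                                   settle_tol = 1e-3) {
  joint <- match.arg(joint)
  if (smoothing_window < 1 || smoothing_window %% 2 != 1)
    abort_parameter("smoothing_window must be odd and >= 1")
  idx <- vapply(c("left", "right"), function(sd)
    .detect_landing_side(seq, paste0(joint, "_", sd),
                         smoothing_window, min_drop, settle_tol),
    numeric(1))
  side <- if (idx[["left"]] <= idx[["right"]]) "left" else "right"
  list(frame = seq$frame[min(idx)], side = side,
       side_frames = c(left = seq$frame[idx[["left"]]],
                       right = seq$frame[idx[["right"]]]))
}

#' Detect the peak-coronal (most valgus) frame
#'
#' Searches the signed coronal angle from the initial-contact frame to the
#' end of the recording (or `end_frame`) for its minimum, i.e. the most
#' valgus configuration. Ties resolve to the earliest frame.
#'
#' @param angles A [knee_angle_series()] data frame.
#' @param side `"left"` or `"right"`.
#' @param ic_frame Initial-contact frame index (start of the search
#'   window).
#' @param end_frame Optional last frame of the search window (defaults to
#'   the end of the recording, i.e. the entire DVJ).
#' @return List with `frame` and `angle_deg`.
#' @export
detect_peak_coronal <- function(angles, side, ic_frame, end_frame = NULL) {
  a <- angles[angles$side == side, ]
  if (is.null(end_frame)) end_frame <- max(a$frame)
  w <- a[a$frame >= ic_frame & a$frame <= end_frame, ]
  if (nrow(w) == 0)
    abort_detection("empty peak-coronal search window (frames %s-%s)",
                    ic_frame, end_frame)
  i <- which.min(w$coronal_deg)  # which.min returns the earliest tie
  list(frame = w$frame[i], angle_deg = w$coronal_deg[i])
}

#' Detect the peak-sagittal (maximum flexion) frame
#'
#' Searches the flexion angle over the whole recording for its maximum.
#' Ties resolve to the earliest frame.
#'
#' @inheritParams detect_peak_coronal
#' @return List with `frame` and `angle_deg`.
#' @export
detect_peak_sagittal <- function(angles, side) {
  a <- angles[angles$side == side, ]
  if (nrow(a) == 0) abort_detection("empty angle series")
  i <- which.max(a$sagittal_deg)
  list(frame = a$frame[i], angle_deg = a$sagittal_deg[i])
}

#' Extract IC, PC and PS parameters from one jump
#'
#' Composes the kinematic triggers: a single initial-contact frame common
#' to both knees (the earlier foot landing), the per-side coronal angle
#' read at that frame (IC), the most-valgus coronal angle at or after IC
#' (PC), and the maximum flexion angle over the entire recording (PS).
#'
#' @inheritParams detect_initial_contact
#' @param jump_id Identifier carried into the result (default `NA`).
#' @param pc_end_frame Optional end of the peak-coronal search window
#'   (default: end of recording).
#' @return Data frame of class `dvj_parameters`, one row per side, with
#'   columns `jump_id`, `device_id`, `side`, `ic_deg`, `pc_deg`, `ps_deg`,
#'   `ic_frame`, `pc_frame`, `ps_frame`.
#' @export
extract_dvj_parameters <- function(seq, jump_id = NA, joint = c("foot", "ankle"),
                                   smoothing_window = 3, min_drop = 0.10,
                                   settle_tol = 1e-3, pc_end_frame = NULL) {
  ic <- detect_initial_contact(seq, joint = joint,
                               smoothing_window = smoothing_window,
                               min_drop = min_drop, settle_tol = settle_tol)
  angles <- knee_angle_series(seq)
  rows <- lapply(c("left", "right"), function(sd) {
    a <- angles[angles$side == sd, ]
    ic_deg <- a$coronal_deg[a$frame == ic$frame]
    pc <- detect_peak_coronal(angles, sd, ic$frame, pc_end_frame)
    ps <- detect_peak_sagittal(angles, sd)
    data.frame(jump_id = jump_id, device_id = seq$device_id, side = sd,
               ic_deg = ic_deg, pc_deg = pc$angle_deg, ps_deg = ps$angle_deg,
               ic_frame = ic$frame, pc_frame = pc$frame, ps_frame = ps$frame)
  })
  structure(do.call(rbind, rows), class = c("dvj_parameters", "data.frame"))
}
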