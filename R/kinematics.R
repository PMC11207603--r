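# Knee angles from segment surrogate vectors: knee->hip stands in for the
# femur and knee->ankle for the tibia. Coronal (abduction) angles are
# measured between the frontal-plane (X-Y) projections of the two vectors,
# sagittal (flexion) angles between their sagittal-plane (Y-Z) projections;
# both are reported as deviation from a straight leg (180 deg included
# angle), so a fully extended leg scores 0 in both planes. Valgus (knee
# collapsing medially, ankle deviated laterally) is negative coronal.

.deg <- function(rad) rad * 180 / pi

.as_mat3 <- function(v) {
  if (is.matrix(v)) v else matrix(v, nrow = 1)
}

#' Femur and tibia surrogate vectors for one side
#'
#' @param seq A [skeleton_sequence()].
#' @param side `"left"` or `"right"`.
#' @return List with n-by-3 matrices `femur` (hip minus knee) and `tibia`
#'   (ankle minus knee).
#' @export
limb_vectors <- function(seq, side = c("left", "right")) {
  side <- match.arg(side)
  hip   <- joint_position(seq, paste0("hip_", side))
  knee  <- joint_position(seq, paste0("knee_", side))
  ankle <- joint_position(seq, paste0("ankle_", side))
  femur <- hip - knee
  tibia <- ankle - knee
  nf <- sqrt(rowSums(femur^2)); nt <- sqrt(rowSums(tibia^2))
  bad <- which(nf < 1e-12 | nt < 1e-12)
  if (length(bad))
    abort_degenerate("coincident joints (%s) at frame %d",
                     side, seq$frame[bad[1]])
  list(femur = femur, tibia = tibia)
}

#' Signed coronal (abduction/valgus) knee angle
#'
#' Angle between the frontal-plane (X-Y) projections of the femur and
#' tibia vectors, expressed as deviation from a straight leg: 0 for a
#' fully extended leg, negative for valgus (ankle deviated toward the
#' lateral side of the limb), positive for varus. Under the subject-frame
#' convention (+X = anatomical left), lateral is +X for the left limb and
#' -X for the right limb.
#'
#' @param femur,tibia 3-vectors or n-by-3 matrices (femur = hip - knee,
#'   tibia = ankle - knee).
#' @param side `"left"` or `"right"` (fixes the medial/lateral sign).
#' @return Signed angle(s) in degrees.
#' @export
coronal_angle <- function(femur, tibia, side = c("left", "right")) {
  side <- match.arg(side)
  f <- .as_mat3(femur); t <- .as_mat3(tibia)
  fx <- f[, 1]; fy <- f[, 2]; tx <- t[, 1]; ty <- t[, 2]
  nf <- sqrt(fx^2 + fy^2); nt <- sqrt(tx^2 + ty^2)
  bad <- which(nf < 1e-12 | nt < 1e-12)
  if (length(bad))
    abort_degenerate("frontal-plane projection degenerate (limb parallel to Z) at row %d",
                     bad[1])
  # deviation of the tibia from the extended femur line, in the X-Y plane
  ux <- -fx; uy <- -fy
  raw <- atan2(ux * ty - uy * tx, ux * tx + uy * ty)
  sgn <- if (side == "left") -1 else 1
  .deg(sgn * raw)
}

#' Sagittal (flexion) knee angle
#'
#' Angle between the sagittal-plane (Y-Z) projections of the femur and
#' tibia vectors, expressed as deviation from a straight leg: 0 for a
#' fully extended leg, increasing with flexion, unsigned.
#'
#' @inheritParams coronal_angle
#' @return Flexion angle(s) in degrees, in `[0, 180)`.
#' @export
sagittal_angle <- function(femur, tibia) {
  f <- .as_mat3(femur); t <- .as_mat3(tibia)
  fy <- f[, 2]; fz <- f[, 3]; ty <- t[, 2]; tz <- t[, 3]
  nf <- sqrt(fy^2 + fz^2); nt <- sqrt(ty^2 + tz^2)
  bad <- which(nf < 1e-12 | nt < 1e-12)
  if (length(bad))
    abort_degenerate("sagittal-plane projection degenerate (limb parallel to X) at row %d",
                     bad[1])
  included <- atan2(abs(fy * tz - fz * ty), fy * ty + fz * tz)
  180 - .deg(included)
}

#' Per-frame knee angle series for both sides
#'
#' Computes the signed coronal and unsigned sagittal knee angle at every
#' frame for both limbs. No smoothing is applied: angles reflect the raw
#' (gap-filled) joint positions.
#'
#' @param seq A [skeleton_sequence()].
#' @return Data frame of class `knee_angle_series` with columns `frame`,
#'   `time`, `side`, `coronal_deg`, `sagittal_deg` (long over sides,
#'   frame-aligned with `seq`).
#' @export
knee_angle_series <- function(seq) {
  out <- lapply(c("left", "right"), function(side) {
    lv <- limb_vectors(seq, side)
    cor <- tryCatch(coronal_angle(lv$femur, lv$tibia, side),
                    dvj_degenerate_error = function(e) {
                      row <- as.integer(sub(".*row ", "", conditionMessage(e)))
                      abort_degenerate("frontal-plane projection degenerate (%s) at frame %d",
                                       side, seq$frame[row])
                    })
    sag <- tryCatch(sagittal_angle(lv$femur, lv$tibia),
                    dvj_degenerate_error = function(e) {
                      row <- as.integer(sub(".*row ", "", conditionMessage(e)))
                      abort_degenerate("sagittal-plane projection degenerate (%s) at frame %d",
                                       side, seq$frame[row])
                    })
    if (any(cor <= -90 | cor >= 90))
      warning(sprintf("coronal angle outside (-90, 90) deg (%s side): non-physiological input?",
                      side), call. = FALSE)
    data.frame(frame = seq$frame, time = seq$time, side = side,
               coronal_deg = cor, sagittal_deg = sag)
  })
  structure(do.call(rbind, out), class = c("knee_angle_series", "data.frame"))
}

#' Write a per-frame angle CSV
#'
#' Columns `frame,side,coronal_deg,sagittal_deg`; the data behind
#' frame-by-frame angle plots.
#'
#' @param angles A [knee_angle_series()] data frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_angle_csv <- function(angles, path) {
  utils::write.csv(angles[, c("frame", "side", "coronal_deg", "sagittal_deg")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
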