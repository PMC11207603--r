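# Synthetic paired-device DVJ generator. One jump is a piecewise angle /
# foot-height profile on the frame grid (stand on the box, ballistic drop,
# landing absorption with the coronal excursion to PC and the flexion rise
# to PS, extension, flight, second landing, settle), pushed through forward
# kinematics that the angle-extraction code inverts exactly. Two devices
# observe the same underlying jump through their own bias and noise.

.G <- 9.81  # m/s^2

#' Simulation configuration for synthetic drop vertical jumps
#'
#' Defaults emulate the study conditions the package targets: a 31 cm box,
#' 30 fps capture, and per-side true IC/PC/PS angles in the range reported
#' for recreational athletes (slightly valgus at contact, a few degrees
#' more valgus at PC, around 100 degrees of peak flexion). Between-jump
#' variability draws each jump's true angles from independent normals
#' around these means (with the physical constraint PC <= IC enforced by
#' clamping).
#'
#' @param fps Frames per second (>= 10; default 30).
#' @param box_height Drop height in metres (default 0.31).
#' @param femur_length,tibia_length,hip_width,ankle_height Anthropometry
#'   in metres.
#' @param stand_s,absorb_s,extend_s,flight_s,settle_s Phase durations in
#'   seconds (each at least 2 frames). The drop duration follows from the
#'   box height.
#' @param dt_pc_s,dt_ps_s Time from initial contact to peak coronal / peak
#'   sagittal, in seconds (within the absorption phase).
#' @param ic_deg,pc_deg,ps_deg Named length-2 vectors (`left`, `right`) of
#'   mean true angles in degrees. Coronal angles are signed (valgus
#'   negative); `pc_deg <= ic_deg` per side; `ps_deg` in (0, 160).
#' @param ic_sd,pc_sd,ps_sd Between-jump SDs (degrees) of the true angles.
#' @param baseline_flexion_deg Standing knee flexion (degrees).
#' @param n_jumps Number of jumps per simulated session.
#' @param seed Integer seed driving all randomness.
#' @return Validated list of class `dvj_sim_config`.
#' @export
dvj_sim_config <- function(fps = 30, box_height = 0.31,
                           femur_length = 0.42, tibia_length = 0.40,
                           hip_width = 0.22, ankle_height = 0.08,
                           stand_s = 0.30, absorb_s = 0.50, extend_s = 0.30,
                           flight_s = 0.40, settle_s = 0.35,
                           dt_pc_s = 0.20, dt_ps_s = 1 / 3,
                           ic_deg = c(left = -2, right = -2.5),
                           pc_deg = c(left = -5, right = -5.5),
                           ps_deg = c(left = 100, right = 98),
                           ic_sd = 3, pc_sd = 3, ps_sd = 15,
                           baseline_flexion_deg = 10,
                           n_jumps = 10, seed = 1) {
  cfg <- list(fps = fps, box_height = box_height,
              femur_length = femur_length, tibia_length = tibia_length,
              hip_width = hip_width, ankle_height = ankle_height,
              stand_s = stand_s, absorb_s = absorb_s, extend_s = extend_s,
              flight_s = flight_s, settle_s = settle_s,
              dt_pc_s = dt_pc_s, dt_ps_s = dt_ps_s,
              ic_deg = ic_deg, pc_deg = pc_deg, ps_deg = ps_deg,
              ic_sd = ic_sd, pc_sd = pc_sd, ps_sd = ps_sd,
              baseline_flexion_deg = baseline_flexion_deg,
              n_jumps = n_jumps, seed = seed)
  if (fps < 10) abort_parameter("fps must be >= 10")
  lens <- c(box_height, femur_length, tibia_length, hip_width, ankle_height)
  if (any(lens <= 0)) abort_parameter("all lengths must be > 0")
  phases <- c(stand_s, absorb_s, extend_s, flight_s, settle_s)
  if (any(phases <= 0)) abort_parameter("all phase durations must be > 0")
  if (any(round(phases * fps) < 2))
    abort_parameter("every phase must span at least 2 frames")
  for (nm in c("ic_deg", "pc_deg", "ps_deg"))
    if (!all(c("left", "right") %in% names(cfg[[nm]])))
      abort_parameter("%s must be a named vector with 'left' and 'right'", nm)
  if (any(pc_deg > ic_deg))
    abort_parameter("pc_deg must be <= ic_deg (PC is the most valgus angle)")
  if (any(ps_deg <= 0 | ps_deg >= 160))
    abort_parameter("ps_deg must lie in (0, 160)")
  if (any(c(ic_sd, pc_sd, ps_sd) < 0)) abort_parameter("angle SDs must be >= 0")
  if (dt_pc_s < 1 / fps || dt_ps_s < 1 / fps ||
      dt_pc_s >= absorb_s || dt_ps_s >= absorb_s)
    abort_parameter("dt_pc_s and dt_ps_s must lie within the absorption phase")
  if (n_jumps < 1) abort_parameter("n_jumps must be >= 1")
  structure(cfg, class = "dvj_sim_config")
}

#' Device observation model for the simulator
#'
#' @param device_id Label (e.g. `"azure"`, `"v2"`).
#' @param position_sd Isotropic per-joint, per-axis position noise SD in
#'   metres. Defaults reflect that the newer sensor tracks joints with
#'   visibly less jitter than its predecessor: 0.003 is a plausible value
#'   for the quieter device, 0.006 for the noisier one.
#' @param bias_coronal_deg,bias_sagittal_deg Systematic additive bias on
#'   the true coronal / sagittal angle profiles before forward kinematics.
#' @param angle_noise_sd_deg Per-frame white noise SD (degrees) added to
#'   both angle profiles before forward kinematics; useful for studying
#'   angle-level measurement error with a closed-form ICC expectation.
#' @param dropout Per-joint, per-frame probability of a dropped sample
#'   (repaired downstream by [fill_short_gaps()]).
#' @return List of class `device_noise_model`.
#' @export
device_noise_model <- function(device_id, position_sd = 0.003,
                               bias_coronal_deg = 0, bias_sagittal_deg = 0,
                               angle_noise_sd_deg = 0, dropout = 0) {
  if (position_sd < 0 || angle_noise_sd_deg < 0)
    abort_parameter("noise SDs must be >= 0")
  if (dropout < 0 || dropout >= 1) abort_parameter("dropout must be in [0, 1)")
  structure(list(device_id = device_id, position_sd = position_sd,
                 bias_coronal_deg = bias_coronal_deg,
                 bias_sagittal_deg = bias_sagittal_deg,
                 angle_noise_sd_deg = angle_noise_sd_deg,
                 dropout = dropout),
            class = "device_noise_model")
}

# piecewise-linear profile through knots, evaluated on integer frames
.interp_knots <- function(frames, kf, kv) {
  o <- order(kf)
  stats::approx(kf[o], kv[o], xout = frames, rule = 2)$y
}

#' True angle and foot-height profiles for one jump
#'
#' Builds the per-frame coronal and sagittal angle profiles and the foot
#' height profile for a single DVJ, with the IC/PC/PS extrema placed
#' exactly on frame-grid points, and records the ground-truth frames and
#' angles. The drop is ballistic (`h = box_height - g t^2 / 2`); initial
#' contact snaps to the first frame at floor height.
#'
#' @param cfg A [dvj_sim_config()].
#' @param draw Optional list with per-side true angles for this jump
#'   (`ic`, `pc`, `ps`, each a named length-2 vector); defaults to the
#'   config means.
#' @return List with `frame` (0-based indices), `coronal` and `sagittal`
#'   (n-by-2 matrices, columns `left`/`right`, degrees), `foot_h` (metres)
#'   and `truth` (data frame: side, ic/pc/ps degrees and frames).
#' @export
angle_profiles <- function(cfg, draw = NULL) {
  stopifnot(inherits(cfg, "dvj_sim_config"))
  if (is.null(draw))
    draw <- list(ic = cfg$ic_deg, pc = cfg$pc_deg, ps = cfg$ps_deg)
  fps <- cfg$fps
  d0 <- as.integer(round(cfg$stand_s * fps))          # drop starts
  t_fall <- sqrt(2 * cfg$box_height / .G)
  ic_f <- d0 + as.integer(ceiling(t_fall * fps + 1e-12))  # first frame at floor
  land_end <- ic_f + as.integer(round(cfg$absorb_s * fps))
  takeoff <- land_end + as.integer(round(cfg$extend_s * fps))
  land2 <- takeoff + as.integer(round(cfg$flight_s * fps))
  end_f <- land2 + as.integer(round(cfg$settle_s * fps))
  pc_f <- ic_f + as.integer(round(cfg$dt_pc_s * fps))
  ps_f <- ic_f + as.integer(round(cfg$dt_ps_s * fps))

  frames <- 0:end_f
  # foot height: box -> ballistic fall -> floor -> flight arc -> floor
  h <- numeric(length(frames))
  h[frames < d0] <- cfg$box_height
  fall <- frames >= d0 & frames < ic_f
  h[fall] <- cfg$box_height - 0.5 * .G * ((frames[fall] - d0) / fps)^2
  v0 <- .G * cfg$flight_s / 2
  air <- frames > takeoff & frames < land2
  tf <- (frames[air] - takeoff) / fps
  h[air] <- pmax(0, v0 * tf - 0.5 * .G * tf^2)

  mk_side <- function(sd) {
    ic <- draw$ic[[sd]]; pc <- draw$pc[[sd]]; ps <- draw$ps[[sd]]
    rec <- 0.5 * ic
    dip2 <- (pc + rec) / 2                    # second-landing dip, > pc
    cor <- .interp_knots(frames,
      c(0, d0, ic_f, pc_f, land_end, takeoff, land2, land2 + 2, end_f),
      c(0, 0, ic, pc, rec, 0.3 * ic, 0.3 * ic, dip2, 0.2 * ic))
    s0 <- min(cfg$baseline_flexion_deg, 0.1 * ps)
    s_toff <- min(15, 0.15 * ps)
    bump_f <- min(land2 + max(2, round(0.1 * fps)), end_f - 1)
    sag <- .interp_knots(frames,
      c(0, ic_f, ps_f, land_end, takeoff, land2, bump_f, end_f),
      c(s0, s0, ps, 0.5 * ps, s_toff, s_toff, 0.6 * ps, min(20, 0.2 * ps)))
    list(cor = cor, sag = sag, ic = ic, pc = pc, ps = ps)
  }
  L <- mk_side("left"); R <- mk_side("right")
  truth <- data.frame(
    side = c("left", "right"),
    ic_deg = c(L$ic, R$ic), pc_deg = c(L$pc, R$pc), ps_deg = c(L$ps, R$ps),
    ic_frame = ic_f, pc_frame = pc_f, ps_frame = ps_f)
  list(frame = frames,
       coronal = cbind(left = L$cor, right = R$cor),
       sagittal = cbind(left = L$sag, right = R$sag),
       foot_h = h, truth = truth)
}

#' Forward kinematics: skeleton sequence from angle profiles
#'
#' Places the eight lower-limb joints so that [knee_angle_series()]
#' recovers the supplied coronal and sagittal profiles exactly and the
#' foot joint follows the supplied height profile. The flexion angle is
#' split equally between thigh pitch and shank pitch (a symmetric squat),
#' which keeps the frontal-plane projection of the femur well conditioned
#' at deep flexion.
#'
#' @param profiles Output of [angle_profiles()] (possibly with bias/noise
#'   added to the angle matrices).
#' @param cfg A [dvj_sim_config()] (anthropometry, fps).
#' @param device_id Label for the produced sequence.
#' @return A [skeleton_sequence()].
#' @export
forward_kinematics <- function(profiles, cfg, device_id = "sim") {
  stopifnot(inherits(cfg, "dvj_sim_config"))
  n <- length(profiles$frame)
  joints <- vector("list", 8); names(joints) <- dvj_joint_names()
  for (sd in c("left", "right")) {
    xs <- if (sd == "left") cfg$hip_width / 2 else -cfg$hip_width / 2
    cor <- profiles$coronal[, sd]
    sag <- profiles$sagittal[, sd]
    alpha <- sag * pi / 360                       # half the flexion angle
    raw <- (if (sd == "left") -cor else cor) * pi / 180
    ca <- cos(alpha); sa <- sin(alpha)
    ut <- cbind(ca * tan(raw), -ca, -sa)          # tibia direction (unnormalized y,z scale)
    ut <- ut / sqrt(rowSums(ut^2))
    foot  <- cbind(xs, profiles$foot_h, 0.12)
    ankle <- cbind(xs, profiles$foot_h + cfg$ankle_height, 0)
    knee  <- ankle - cfg$tibia_length * ut
    hip   <- knee + cfg$femur_length * cbind(0, ca, -sa)
    joints[[paste0("hip_", sd)]]   <- hip
    joints[[paste0("knee_", sd)]]  <- knee
    joints[[paste0("ankle_", sd)]] <- ankle
    joints[[paste0("foot_", sd)]]  <- foot
  }
  joints <- lapply(joints, function(m) {
    m <- unname(m)
    if (nrow(m) == 1) m <- m[rep(1, n), , drop = FALSE]
    colnames(m) <- c("x", "y", "z")
    m
  })
  .new_skeleton_sequence(joints, profiles$frame, device_id, cfg$fps)
}

# apply a device's observation model to one jump's true profiles;
# draws from the current RNG state
.observe_device <- function(profiles, cfg, noise) {
  p <- profiles
  n <- length(p$frame)
  if (noise$angle_noise_sd_deg > 0) {
    p$coronal <- p$coronal + matrix(stats::rnorm(2 * n, 0, noise$angle_noise_sd_deg), n, 2)
    p$sagittal <- p$sagittal + matrix(stats::rnorm(2 * n, 0, noise$angle_noise_sd_deg), n, 2)
  }
  p$coronal <- p$coronal + noise$bias_coronal_deg
  p$sagittal <- pmin(pmax(p$sagittal + noise$bias_sagittal_deg, 0), 179)
  seq <- forward_kinematics(p, cfg, device_id = noise$device_id)
  if (noise$position_sd > 0) {
    for (j in dvj_joint_names())
      seq$joints[[j]] <- seq$joints[[j]] +
        matrix(stats::rnorm(3 * n, 0, noise$position_sd), n, 3)
  }
  if (noise$dropout > 0) {
    df <- as.data.frame(seq)
    interior <- df$frame > min(df$frame) + 1 & df$frame < max(df$frame) - 1
    drop <- interior & stats::runif(nrow(df)) < noise$dropout
    # never drop more than one consecutive frame per joint, so repair is safe
    for (j in dvj_joint_names()) {
      sel <- which(df$joint == j & drop)
      if (length(sel) > 1) drop[sel[c(FALSE, diff(sel) == 1)]] <- FALSE
    }
    seq <- fill_short_gaps(df[!drop, ], max_gap = 1,
                           device_id = seq$device_id, fps = seq$fps)
  }
  seq
}

#' Simulate one session of paired-device DVJ recordings
#'
#' Draws `cfg$n_jumps` jumps with between-jump variability; both devices
#' observe the same underlying jump through their own bias and noise
#' models. All randomness flows from `cfg$seed`.
#'
#' @param cfg A [dvj_sim_config()].
#' @param noise_a,noise_b [device_noise_model()]s for the two devices.
#' @return List with `jumps` (per jump: `a` and `b` skeleton sequences)
#'   and `truth` (data frame of true parameters, one row per jump and
#'   side).
#' @export
simulate_paired_devices <- function(cfg, noise_a = device_noise_model("azure", 0.003),
                                    noise_b = device_noise_model("v2", 0.006)) {
  stopifnot(inherits(cfg, "dvj_sim_config"))
  set.seed(cfg$seed)
  jumps <- vector("list", cfg$n_jumps)
  truth <- vector("list", cfg$n_jumps)
  for (i in seq_len(cfg$n_jumps)) {
    p <- angle_profiles(cfg, .draw_truth(cfg))
    a <- .observe_device(p, cfg, noise_a)
    b <- .observe_device(p, cfg, noise_b)
    tr <- p$truth; tr$jump_id <- i
    jumps[[i]] <- list(a = a, b = b)
    truth[[i]] <- tr
  }
  list(jumps = jumps, truth = do.call(rbind, truth))
}

# per-jump draw of true angles around the config means
.draw_truth <- function(cfg) {
  ic <- cfg$ic_deg + stats::rnorm(2, 0, cfg$ic_sd)
  pc <- cfg$pc_deg + stats::rnorm(2, 0, cfg$pc_sd)
  ps <- cfg$ps_deg + stats::rnorm(2, 0, cfg$ps_sd)
  pc <- pmin(pc, ic)                     # PC is the most valgus angle
  ps <- pmin(pmax(ps, 5), 155)
  list(ic = ic, pc = pc, ps = ps)
}

#' Simulate and extract: full-pipeline study
#'
#' Runs the complete pipeline jump by jump — generate the true jump,
#' observe it with both devices, extract IC/PC/PS with the kinematic
#' triggers — without keeping the skeleton sequences, so large
#' Monte-Carlo studies stay in constant memory.
#'
#' @inheritParams simulate_paired_devices
#' @param ... Extraction options forwarded to [extract_dvj_parameters()].
#' @return List with `params` (extracted parameters: jump_id, device,
#'   side, ic/pc/ps degrees and frames) and `truth`.
#' @export
simulate_dvj_study <- function(cfg, noise_a = device_noise_model("azure", 0.003),
                               noise_b = device_noise_model("v2", 0.006), ...) {
  stopifnot(inherits(cfg, "dvj_sim_config"))
  set.seed(cfg$seed)
  params <- vector("list", 2L * cfg$n_jumps)
  truth <- vector("list", cfg$n_jumps)
  for (i in seq_len(cfg$n_jumps)) {
    p <- angle_profiles(cfg, .draw_truth(cfg))
    a <- .observe_device(p, cfg, noise_a)
    b <- .observe_device(p, cfg, noise_b)
    params[[2L * i - 1L]] <- extract_dvj_parameters(a, jump_id = i, ...)
    params[[2L * i]] <- extract_dvj_parameters(b, jump_id = i, ...)
    tr <- p$truth; tr$jump_id <- i
    truth[[i]] <- tr
  }
  list(params = do.call(rbind, params), truth = do.call(rbind, truth))
}

#' Expected absolute-agreement ICC under the simulator's error model
#'
#' For the measurement model `x_dev = truth + bias_dev + noise_dev` with
#' between-jump truth variance `var_between`, device noise variances
#' `var_a` and `var_b`, and a systematic between-device bias `delta`, the
#' population single-measure absolute-agreement ICC (large-n limit of the
#' ICC(A,1) estimator, where the bias enters through the column variance
#' component) is
#' \deqn{\rho = \frac{\sigma_b^2}{\sigma_b^2 + (\sigma_A^2+\sigma_B^2)/2 + \Delta^2/2}.}
#' This is an asymptotic oracle: Monte-Carlo estimates at finite n scatter
#' around it.
#'
#' @param var_between Between-jump variance of the true parameter.
#' @param var_a,var_b Measurement-noise variances of the two devices.
#' @param delta Systematic bias of device A relative to device B.
#' @param n Nominal study size (>= 3; the formula itself is the large-n
#'   limit).
#' @return Expected ICC(A,1).
#' @export
expected_icc_a1 <- function(var_between, var_a, var_b, delta = 0, n = Inf) {
  if (any(c(var_between, var_a, var_b) < 0))
    abort_parameter("variances must be >= 0")
  if (!is.infinite(n) && n < 3) abort_parameter("n must be >= 3")
  if (var_between == 0 && var_a == 0 && var_b == 0 && delta == 0)
    abort_degenerate("all variance components are zero: ICC undefined")
  var_between / (var_between + (var_a + var_b) / 2 + delta^2 / 2)
}
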