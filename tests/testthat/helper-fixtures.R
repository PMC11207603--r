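# Fixtures are built in code: a standing straight-leg skeleton and small
# joint tables for the I/O edge cases.

# one frame of a straight vertical leg, both sides, as a long data frame
straight_leg_frame <- function(frame) {
  rows <- list()
  for (sd in c("left", "right")) {
    xs <- if (sd == "left") 0.11 else -0.11
    rows[[sd]] <- data.frame(
      frame = frame,
      joint = paste0(c("hip", "knee", "ankle", "foot"), "_", sd),
      x = xs,
      y = c(0.95, 0.53, 0.13, 0.05),
      z = c(0, 0, 0, 0.12))
  }
  do.call(rbind, rows)
}

standing_seq <- function(n = 5, fps = 30, device_id = "test") {
  df <- do.call(rbind, lapply(seq_len(n) - 1, straight_leg_frame))
  skeleton_sequence(df, device_id = device_id, fps = fps)
}

# a noise-free simulated jump and its truth, for reuse across tests
noise_free_jump <- function(seed = 1, ...) {
  cfg <- dvj_sim_config(seed = seed, n_jumps = 1,
                        ic_sd = 0, pc_sd = 0, ps_sd = 0, ...)
  p <- angle_profiles(cfg)
  list(cfg = cfg, profiles = p,
       seq = forward_kinematics(p, cfg, device_id = "sim"),
       truth = p$truth)
}

expect_dvj_error <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
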