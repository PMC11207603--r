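test_that("profiles attain the configured extrema exactly at the truth frames", {
  cfg <- dvj_sim_config(ic_deg = c(left = -2, right = -2),
                        pc_deg = c(left = -6, right = -6),
                        ps_deg = c(left = 100, right = 100))
  p <- angle_profiles(cfg)
  tr <- p$truth[p$truth$side == "left", ]
  i <- match(tr$ic_frame, p$frame)
  expect_equal(unname(p$coronal[i, "left"]), -2)
  expect_equal(unname(p$coronal[match(tr$pc_frame, p$frame), "left"]), -6)
  expect_equal(unname(p$sagittal[match(tr$ps_frame, p$frame), "left"]), 100)
  # PC is the unique post-IC minimum; PS the unique global maximum
  post <- p$coronal[p$frame >= tr$ic_frame, "left"]
  expect_equal(p$frame[p$frame >= tr$ic_frame][which.min(post)], tr$pc_frame)
  expect_equal(p$frame[which.max(p$sagittal[, "left"])], tr$ps_frame)
})

test_that("the ballistic drop snaps initial contact to the next frame boundary", {
  cfg <- dvj_sim_config(stand_s = 0.3)
  p <- angle_profiles(cfg)
  d0 <- round(0.3 * 30)
  expected_ic <- d0 + ceiling(sqrt(2 * 0.31 / 9.81) * 30)   # 7.54 frames -> 8
  expect_equal(p$truth$ic_frame[1], expected_ic)
  expect_equal(expected_ic - d0, 8)
  # foot is on the box before the drop, at the floor from IC through takeoff
  expect_equal(p$foot_h[p$frame < d0], rep(0.31, d0))
  expect_equal(p$foot_h[match(expected_ic, p$frame)], 0)
  expect_gt(p$foot_h[match(expected_ic - 1, p$frame)], 0)
})

test_that("generation is deterministic given a seed and varies between jumps", {
  cfg <- dvj_sim_config(n_jumps = 3, seed = 99)
  s1 <- simulate_paired_devices(cfg)
  s2 <- simulate_paired_devices(cfg)
  expect_equal(s1$truth, s2$truth)
  expect_equal(s1$jumps[[2]]$b$joints, s2$jumps[[2]]$b$joints)
  expect_false(isTRUE(all.equal(s1$truth$ic_deg[1:2], s1$truth$ic_deg[3:4])))
  # zero between-jump SD: every jump has identical truth
  cfg0 <- dvj_sim_config(n_jumps = 2, seed = 99, ic_sd = 0, pc_sd = 0, ps_sd = 0)
  t0 <- simulate_paired_devices(cfg0)$truth
  expect_equal(t0[t0$jump_id == 1, 1:7], t0[t0$jump_id == 2, 1:7],
               ignore_attr = TRUE)
})

test_that("forward kinematics inverts the angle computation", {
  for (seed in 1:4) {
    set.seed(seed)
    cfg <- dvj_sim_config(
      ic_deg = c(left = runif(1, -6, 2), right = runif(1, -6, 2)),
      pc_deg = c(left = runif(1, -12, -7), right = runif(1, -12, -7)),
      ps_deg = c(left = runif(1, 70, 130), right = runif(1, 70, 130)))
    p <- angle_profiles(cfg)
    ang <- knee_angle_series(forward_kinematics(p, cfg))
    for (sd in c("left", "right")) {
      a <- ang[ang$side == sd, ]
      expect_lt(max(abs(a$coronal_deg - p$coronal[, sd])), 1e-6)
      expect_lt(max(abs(a$sagittal_deg - p$sagittal[, sd])), 1e-6)
    }
  }
})

test_that("a straight-leg profile yields collinear hip, knee and ankle", {
  cfg <- dvj_sim_config()
  p <- angle_profiles(cfg)
  n <- length(p$frame)
  p$coronal[] <- 0; p$sagittal[] <- 0
  seq <- forward_kinematics(p, cfg)
  femur <- seq$joints$hip_left - seq$joints$knee_left
  tibia <- seq$joints$ankle_left - seq$joints$knee_left
  cross <- femur[, c(2, 3, 1)] * tibia[, c(3, 1, 2)] -
    femur[, c(3, 1, 2)] * tibia[, c(2, 3, 1)]
  expect_lt(max(abs(cross)), 1e-12)
})

test_that("swapping the side truths mirrors the skeleton in X", {
  cfgA <- dvj_sim_config(ic_deg = c(left = -2, right = -4),
                         pc_deg = c(left = -6, right = -8),
                         ps_deg = c(left = 95, right = 105))
  cfgB <- dvj_sim_config(ic_deg = c(left = -4, right = -2),
                         pc_deg = c(left = -8, right = -6),
                         ps_deg = c(left = 105, right = 95))
  sA <- forward_kinematics(angle_profiles(cfgA), cfgA)
  sB <- forward_kinematics(angle_profiles(cfgB), cfgB)
  for (base in c("hip", "knee", "ankle", "foot")) {
    l <- sA$joints[[paste0(base, "_left")]]
    r <- sB$joints[[paste0(base, "_right")]]
    expect_equal(l[, 1], -r[, 1], tolerance = 1e-9)
    expect_equal(l[, 2:3], r[, 2:3], tolerance = 1e-9)
  }
})

test_that("the closed-form expected ICC behaves as a population oracle", {
  expect_equal(expected_icc_a1(1, 0, 0, 0), 1)
  expect_equal(expected_icc_a1(1, 0.5, 0.5, 0), 1 / 1.5)
  deltas <- c(0, 0.5, 1, 2)
  vals <- sapply(deltas, function(d) expected_icc_a1(1, 0.25, 0.25, d))
  expect_true(all(diff(vals) < 0))
  expect_dvj_error(expected_icc_a1(0, 0, 0, 0), "dvj_degenerate_error")
  expect_dvj_error(expected_icc_a1(-1, 0, 0), "dvj_parameter_error")
})

test_that("noise-free identical devices give ICC 1 on every parameter", {
  cfg <- dvj_sim_config(n_jumps = 8, seed = 13)
  z <- device_noise_model("azure", position_sd = 0)
  z2 <- device_noise_model("v2", position_sd = 0)
  st <- simulate_dvj_study(cfg, z, z2)
  for (sd in c("left", "right")) for (par in c("ic_deg", "pc_deg", "ps_deg")) {
    p <- st$params[st$params$side == sd, ]
    a <- p[[par]][p$device_id == "azure"]; b <- p[[par]][p$device_id == "v2"]
    expect_equal(a, b, tolerance = 1e-9)
    expect_equal(icc_a1(cbind(a, b))$icc, 1, tolerance = 1e-6)
  }
})

test_that("a coronal bias shifts the IC difference and lowers absolute agreement", {
  cfg <- dvj_sim_config(n_jumps = 30, seed = 14)
  a <- device_noise_model("azure", position_sd = 0)
  b <- device_noise_model("v2", position_sd = 0, bias_coronal_deg = 1)
  st <- simulate_dvj_study(cfg, a, b)
  ic <- st$params[st$params$side == "left", ]
  va <- ic$ic_deg[ic$device_id == "azure"]; vb <- ic$ic_deg[ic$device_id == "v2"]
  expect_equal(mean(va - vb), -1, tolerance = 1e-6)
  b0 <- device_noise_model("v2", position_sd = 0)
  st0 <- simulate_dvj_study(cfg, a, b0)
  ic0 <- st0$params[st0$params$side == "left", ]
  v0a <- ic0$ic_deg[ic0$device_id == "azure"]; v0b <- ic0$ic_deg[ic0$device_id == "v2"]
  expect_lt(icc_a1(cbind(va, vb))$icc, icc_a1(cbind(v0a, v0b))$icc)
})

test_that("dropout produces repairable sequences that still extract", {
  cfg <- dvj_sim_config(n_jumps = 2, seed = 15)
  noisy <- device_noise_model("v2", position_sd = 0.002, dropout = 0.05)
  sim <- simulate_paired_devices(cfg, device_noise_model("azure"), noisy)
  par <- extract_dvj_parameters(sim$jumps[[1]]$b)
  expect_equal(nrow(par), 2)
  expect_true(all(par$pc_deg <= par$ic_deg))
})
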