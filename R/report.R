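# End-to-end analysis and simulation runners behind the command-line
# wrapper (inst/cli/dvj.R). CSV is the canonical output format; plots are
# optional, non-canonical artifacts.

.jump_id_from_path <- function(path) {
  base <- sub("\\.csv$", "", basename(path))
  sub("^jump_", "", base)
}

# read every jump CSV of one device: a directory of *.csv or a character
# vector of files; names are jump ids
.read_device_inputs <- function(input, device_id = NULL, max_gap = 2) {
  files <- if (length(input) == 1 && dir.exists(input))
    list.files(input, pattern = "\\.csv$", full.names = TRUE)
  else input
  if (length(files) == 0) abort_io("no CSV inputs found in '%s'", input)
  seqs <- lapply(sort(files), read_joint_csv, device_id = device_id,
                 max_gap = max_gap)
  names(seqs) <- vapply(sort(files), .jump_id_from_path, character(1))
  seqs
}

#' Analyze one or two devices' DVJ recordings
#'
#' Reads per-jump joint CSVs, extracts IC/PC/PS parameters for every jump,
#' and — when two devices are given — pairs the jumps by id and computes
#' the full agreement battery (normality-gated location tests and
#' ICC(A,1) per parameter). Writes the per-jump parameter table and, for
#' two devices, the two agreement report tables to `out_dir`.
#'
#' @param input_a Directory of per-jump CSVs (or vector of CSV paths) for
#'   device A. Jump ids are taken from file names (`jump_<id>.csv`).
#' @param input_b Same for device B, or `NULL` for single-device mode
#'   (parameter extraction only; the agreement section is skipped with a
#'   warning).
#' @param out_dir Output directory (created if needed).
#' @param alpha Significance level for the normality gate.
#' @param max_gap Gap-fill limit forwarded to [read_joint_csv()].
#' @param write_angles Also write per-frame angle CSVs per jump and
#'   device.
#' @param write_plots Also write per-jump frame-by-frame angle plots
#'   (PNG; non-canonical).
#' @param ... Extraction options forwarded to [extract_dvj_parameters()].
#' @return Invisibly, a list with `params` (per-jump parameter data
#'   frame), `agreement` (a [build_agreement_table()] result or `NULL`)
#'   and `files` (paths written).
#' @export
run_dvj_analysis <- function(input_a, input_b = NULL, out_dir = ".",
                             alpha = 0.05, max_gap = 2,
                             write_angles = FALSE, write_plots = FALSE, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seqs_a <- .read_device_inputs(input_a, max_gap = max_gap)
  seqs_b <- if (!is.null(input_b)) .read_device_inputs(input_b, max_gap = max_gap)

  if (!is.null(seqs_b)) {
    if (!setequal(names(seqs_a), names(seqs_b)))
      abort_validation("jump ids differ between devices: only in A: %s; only in B: %s",
                       paste(setdiff(names(seqs_a), names(seqs_b)), collapse = ","),
                       paste(setdiff(names(seqs_b), names(seqs_a)), collapse = ","))
    seqs_b <- seqs_b[names(seqs_a)]
  }

  extract_all <- function(seqs) do.call(rbind, lapply(names(seqs), function(id)
    extract_dvj_parameters(seqs[[id]], jump_id = id, ...)))
  params <- rbind(extract_all(seqs_a),
                  if (!is.null(seqs_b)) extract_all(seqs_b))
  files <- file.path(out_dir, "dvj_parameters.csv")
  utils::write.csv(params, files[1], row.names = FALSE)

  agreement <- NULL
  if (!is.null(seqs_b)) {
    pms <- list()
    for (sd in c("left", "right")) for (par in c("ic", "pc", "ps")) {
      col <- paste0(par, "_deg")
      va <- params[params$device_id == seqs_a[[1]]$device_id & params$side == sd, ]
      vb <- params[params$device_id == seqs_b[[1]]$device_id & params$side == sd, ]
      va <- va[order(va$jump_id), ]; vb <- vb[order(vb$jump_id), ]
      pms[[length(pms) + 1]] <- paired_measurements(
        sprintf("%s knee %s", sd, toupper(par)),
        va[[col]], vb[[col]], jump_id = va$jump_id)
    }
    agreement <- build_agreement_table(pms, alpha = alpha)
    files <- c(files, write_agreement_tables(agreement, out_dir))
  } else {
    warning("single-device input: agreement analysis skipped", call. = FALSE)
  }

  if (write_angles || write_plots) {
    ang_dir <- file.path(out_dir, "angles")
    dir.create(ang_dir, showWarnings = FALSE)
    all_seqs <- c(list(a = seqs_a), if (!is.null(seqs_b)) list(b = seqs_b))
    for (seqs in all_seqs) for (id in names(seqs)) {
      ang <- knee_angle_series(seqs[[id]])
      dev <- seqs[[id]]$device_id
      if (write_angles) {
        f <- file.path(ang_dir, sprintf("angles_%s_jump_%s.csv", dev, id))
        write_angle_csv(ang, f); files <- c(files, f)
      }
      if (write_plots) {
        f <- file.path(ang_dir, sprintf("angles_%s_jump_%s.png", dev, id))
        grDevices::png(f, width = 800, height = 500)
        plot_angle_series(ang, main = sprintf("%s jump %s", dev, id))
        grDevices::dev.off()
        files <- c(files, f)
      }
    }
  }
  invisible(list(params = params, agreement = agreement, files = files))
}

#' Plot a frame-by-frame knee angle series
#'
#' Coronal (signed, valgus negative) and sagittal (flexion) angles per
#' frame for both sides, on two stacked panels.
#'
#' @param angles A [knee_angle_series()] data frame.
#' @param main Title.
#' @export
plot_angle_series <- function(angles, main = "") {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (what in c("coronal_deg", "sagittal_deg")) {
    lab <- if (what == "coronal_deg") "coronal (deg, valgus < 0)" else "sagittal flexion (deg)"
    l <- angles[angles$side == "left", ]; r <- angles[angles$side == "right", ]
    graphics::plot(l$frame, l[[what]], type = "l", col = "firebrick",
                   xlab = "frame", ylab = lab,
                   ylim = range(angles[[what]]),
                   main = if (what == "coronal_deg") main else "")
    graphics::lines(r$frame, r[[what]], col = "navy")
    graphics::legend("topright", c("left", "right"), lty = 1,
                     col = c("firebrick", "navy"), bty = "n")
  }
  invisible(NULL)
}

#' Simulate a paired-device session and write it to disk
#'
#' Writes one joint CSV per jump per device (layout consumed by
#' [run_dvj_analysis()]) plus the ground-truth record.
#'
#' @inheritParams simulate_paired_devices
#' @param out_dir Output directory; per-device subdirectories are created.
#' @return Invisibly, a list with the per-device directories, the truth
#'   CSV path and the truth data frame.
#' @export
run_dvj_simulation <- function(cfg, noise_a = device_noise_model("azure", 0.003),
                               noise_b = device_noise_model("v2", 0.006),
                               out_dir = ".") {
  sim <- simulate_paired_devices(cfg, noise_a, noise_b)
  dir_a <- file.path(out_dir, noise_a$device_id)
  dir_b <- file.path(out_dir, noise_b$device_id)
  dir.create(dir_a, showWarnings = FALSE, recursive = TRUE)
  dir.create(dir_b, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(sim$jumps)) {
    write_joint_csv(sim$jumps[[i]]$a, file.path(dir_a, sprintf("jump_%03d.csv", i)))
    write_joint_csv(sim$jumps[[i]]$b, file.path(dir_b, sprintf("jump_%03d.csv", i)))
  }
  truth_path <- file.path(out_dir, "truth.csv")
  utils::write.csv(sim$truth, truth_path, row.names = FALSE)
  invisible(list(device_dirs = c(dir_a, dir_b), truth_path = truth_path,
                 truth = sim$truth))
}
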