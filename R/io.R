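#' Read a long-format joint CSV
#'
#' Expected dialect: comma-separated, UTF-8, header
#' `frame,time,joint,x,y,z`, one row per joint per frame, positions in
#' metres in the subject frame. An optional leading comment line of the
#' form `# device_id=<id> fps=<fps>` (as written by [write_joint_csv()])
#' supplies metadata; explicit arguments override it.
#'
#' Rows with joint names outside [dvj_joint_names()] (e.g. upper-body
#' joints from a full-skeleton export) are dropped with a warning. Short
#' runs of missing joint samples are interpolated via [fill_short_gaps()].
#'
#' @param path Path to the CSV file.
#' @param device_id Device label; default taken from the header comment,
#'   else `"unknown"`.
#' @param fps Frames per second; default from the header comment, else 30.
#' @param max_gap Maximum fillable gap in frames (see [fill_short_gaps()]).
#' @return A validated [skeleton_sequence()].
#' @export
read_joint_csv <- function(path, device_id = NULL, fps = NULL, max_gap = 2) {
  if (!file.exists(path)) abort_io("file not found: %s", path)
  first <- readLines(path, n = 1L)
  meta <- list(device_id = "unknown", fps = 30)
  if (startsWith(first, "#")) {
    kv <- regmatches(first, gregexpr("[A-Za-z_]+=[^ ]+", first))[[1]]
    for (p in kv) {
      k <- sub("=.*", "", p); v <- sub("^[^=]*=", "", p)
      if (k == "device_id") meta$device_id <- v
      if (k == "fps") meta$fps <- as.numeric(v)
    }
  }
  if (is.null(device_id)) device_id <- meta$device_id
  if (is.null(fps)) fps <- meta$fps

  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("frame", "time", "joint", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_format("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", "))

  unknown <- setdiff(unique(df$joint), dvj_joint_names())
  if (length(unknown)) {
    warning(sprintf("%s: ignoring %d row(s) with unknown joint(s): %s",
                    path, sum(df$joint %in% unknown),
                    paste(unknown, collapse = ", ")), call. = FALSE)
    df <- df[!df$joint %in% unknown, , drop = FALSE]
  }

  seq <- fill_short_gaps(df, max_gap = max_gap, device_id = device_id, fps = fps)
  # re-check the caller-supplied time column against frame/fps
  tgiven <- df$time[!duplicated(df$frame)]
  tref <- as.integer(df$frame[!duplicated(df$frame)]) / fps
  if (any(abs(tgiven - tref) > 1e-6))
    abort_validation("%s: time column inconsistent with frame/fps", path)
  seq
}

#' Write a skeleton sequence to CSV
#'
#' Writes the long-format dialect read by [read_joint_csv()], preceded by
#' a `# device_id=<id> fps=<fps>` metadata comment. Positions are written
#' with 10 decimal digits so a write/read round trip reproduces them to
#' better than 1e-9 m.
#'
#' @param seq A [skeleton_sequence()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_joint_csv <- function(seq, path) {
  if (!inherits(seq, "skeleton_sequence"))
    abort_validation("`seq` must be a skeleton_sequence")
  con <- tryCatch(file(path, "w"), error = function(e)
    abort_io("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  on.exit(close(con))
  writeLines(sprintf("# device_id=%s fps=%.10g", seq$device_id, seq$fps), con)
  df <- as.data.frame(seq)
  df <- df[order(df$frame, match(df$joint, dvj_joint_names())), ]
  writeLines("frame,time,joint,x,y,z", con)
  writeLines(sprintf("%d,%.9f,%s,%.10f,%.10f,%.10f",
                     df$frame, df$time, df$joint, df$x, df$y, df$z), con)
  invisible(path)
}
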