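#' Read a force CSV
#'
#' Reads a comma-separated force record (header required, UTF-8). The
#' column mapping accommodates other acquisition layouts; a unit scale
#' converts e.g. millinewtons to newtons.
#'
#' @param path File path.
#' @param meta A [trial_meta()]; the time grid must match
#'   `1/meta$force_rate` within 1e-9 s.
#' @param col_map Named list mapping the internal names `time`, `fx`, `fy`,
#'   `fz` (and optionally `tx`, `ty`, `tz`) to the file's column names.
#' @param scale Multiplicative factor applied to the force (and torque)
#'   columns to obtain newtons (e.g. `0.001` for a file in mN).
#' @return A [strike_force_trace()].
#' @export
read_force_csv <- function(path, meta,
                           col_map = list(time = "time_s", fx = "fx_N",
                                          fy = "fy_N", fz = "fz_N"),
                           scale = 1) {
  stopifnot(inherits(meta, "trial_meta"))
  df <- utils::read.csv(path, check.names = FALSE)
  for (nm in c("time", "fx", "fy", "fz"))
    if (is.null(col_map[[nm]]) || !col_map[[nm]] %in% names(df))
      stop(sprintf("force file %s: missing column '%s' (mapped to %s)",
                   path, col_map[[nm]] %||% nm, nm), call. = FALSE)
  time <- df[[col_map$time]]
  for (i in seq_along(time))
    if (!is.finite(time[i]))
      stop(sprintf("force file %s: non-finite time at row %d", path, i),
           call. = FALSE)
  dt <- .check_uniform_time(time, sprintf("force file %s", path))
  if (abs(dt - 1 / meta$force_rate) > 1e-9)
    stop(sprintf("force file %s: time step %.6g s does not match 1/force_rate = %.6g s",
                 path, dt, 1 / meta$force_rate), call. = FALSE)
  tq <- NULL
  tq_names <- intersect(c("tx", "ty", "tz"), names(col_map))
  if (length(tq_names) && all(unlist(col_map[tq_names]) %in% names(df)))
    tq <- data.frame(lapply(col_map[tq_names], function(cn) df[[cn]] * scale))
  strike_force_trace(time, df[[col_map$fx]] * scale, df[[col_map$fy]] * scale,
                     df[[col_map$fz]] * scale, torques = tq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fill NA runs of length <= max_gap by linear interpolation; longer runs
# are an error. Returns the filled vector plus the filled indices.
.fill_gaps <- function(x, max_gap, what) {
  na <- is.na(x)
  if (!any(na)) return(list(x = x, filled = integer()))
  r <- rle(na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    if (r$lengths[k] > max_gap)
      stop(sprintf("%s: digitisation gap of %d frames (rows %d-%d) exceeds the %d-frame limit",
                   what, r$lengths[k], starts[k], ends[k], max_gap), call. = FALSE)
    if (starts[k] == 1L || ends[k] == length(x))
      stop(sprintf("%s: gap at the record boundary (rows %d-%d) cannot be interpolated",
                   what, starts[k], ends[k]), call. = FALSE)
  }
  idx <- which(!na)
  filled <- which(na)
  x[filled] <- stats::approx(idx, x[idx], xout = filled)$y
  list(x = x, filled = filled)
}

#' Read a DLTdv-style kinematics CSV
#'
#' Reads digitised head (`pt1`) and tail (`pt2`) planar coordinates, one
#' row per video frame, in pixels, and converts to metres. Missing frames
#' (empty/NaN cells) are linearly interpolated when the gap is at most
#' `max_gap` frames and flagged; longer gaps are an error. Frame 1 is
#' assigned time 0 (the camera trigger).
#'
#' @param path File path.
#' @param meta A [trial_meta()].
#' @param scale_m_per_px Metres per pixel; defaults to `meta$scale_m_per_px`.
#' @param col_map Named list mapping `head_x`, `head_y`, `tail_x`, `tail_y`
#'   to the file's column names (default DLTdv layout
#'   `pt1_cam1_X`, `pt1_cam1_Y`, `pt2_cam1_X`, `pt2_cam1_Y`).
#' @param max_gap Longest interpolatable gap, frames (default 3).
#' @return A [strike_kinematic_trace()]; interpolated frame indices are in
#'   `attr(, "interpolated_frames")`.
#' @export
read_kinematics_csv <- function(path, meta, scale_m_per_px = NULL,
                                col_map = list(head_x = "pt1_cam1_X",
                                               head_y = "pt1_cam1_Y",
                                               tail_x = "pt2_cam1_X",
                                               tail_y = "pt2_cam1_Y"),
                                max_gap = 3L) {
  stopifnot(inherits(meta, "trial_meta"))
  scale_m_per_px <- scale_m_per_px %||% meta$scale_m_per_px
  if (!is.finite(scale_m_per_px) || scale_m_per_px <= 0)
    stop("`scale_m_per_px` must be positive", call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  for (nm in c("head_x", "head_y", "tail_x", "tail_y"))
    if (!col_map[[nm]] %in% names(df))
      stop(sprintf("kinematics file %s: missing column '%s'", path, col_map[[nm]]),
           call. = FALSE)
  n <- nrow(df)
  time <- (seq_len(n) - 1L) / meta$video_rate
  filled_all <- integer()
  vals <- lapply(c("head_x", "head_y", "tail_x", "tail_y"), function(nm) {
    g <- .fill_gaps(as.numeric(df[[col_map[[nm]]]]), max_gap,
                    sprintf("kinematics file %s, column %s", path, col_map[[nm]]))
    filled_all <<- union(filled_all, g$filled)
    g$x * scale_m_per_px
  })
  strike_kinematic_trace(time, vals[[1]], vals[[2]], vals[[3]], vals[[4]],
                         interpolated_frames = sort(filled_all))
}

#' Read trial metadata from YAML
#'
#' @param path YAML file with the [trial_meta()] fields. Unknown keys are
#'   rejected.
#' @return A [trial_meta()].
#' @export
read_trial_meta <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(trial_meta))
  extra <- setdiff(names(y), known)
  if (length(extra))
    stop(sprintf("metadata file %s: unknown keys: %s", path,
                 paste(extra, collapse = ", ")), call. = FALSE)
  do.call(trial_meta, y)
}

#' Write a synthetic trial to disk
#'
#' Writes one force CSV, one DLTdv-style kinematics CSV (pixels), one
#' metadata YAML, and one ground-truth JSON into `dir`. The written files
#' round-trip through [read_force_csv()] / [read_kinematics_csv()] /
#' [read_trial_meta()] losslessly to within 1e-9.
#'
#' @param trial A `strike_trial` (from the generators).
#' @param dir Output directory (created if needed).
#' @param stem File stem (default the trial id).
#' @return Invisibly, the named vector of file paths.
#' @export
write_strike_trial <- function(trial, dir, stem = NULL) {
  stopifnot(inherits(trial, "strike_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- stem %||% trial$meta$trial_id
  fp <- file.path(dir, paste0(stem, "_force.csv"))
  kp <- file.path(dir, paste0(stem, "_kinematics.csv"))
  mp <- file.path(dir, paste0(stem, "_meta.yaml"))
  tp <- file.path(dir, paste0(stem, "_truth.json"))

  fdf <- data.frame(time_s = trial$force$time, fx_N = trial$force$fx,
                    fy_N = trial$force$fy, fz_N = trial$force$fz)
  utils::write.csv(format(fdf, digits = 15, trim = TRUE, scientific = FALSE),
                   fp, row.names = FALSE, quote = FALSE)

  s <- trial$meta$scale_m_per_px
  kdf <- data.frame(pt1_cam1_X = trial$kin$head_x / s,
                    pt1_cam1_Y = trial$kin$head_y / s,
                    pt2_cam1_X = trial$kin$tail_x / s,
                    pt2_cam1_Y = trial$kin$tail_y / s)
  utils::write.csv(format(kdf, digits = 15, trim = TRUE, scientific = FALSE),
                   kp, row.names = FALSE, quote = FALSE)

  m <- unclass(trial$meta)
  m$svl <- if (is.na(m$svl)) NULL else m$svl
  yaml::write_yaml(m, mp)
  jsonlite::write_json(trial$truth, tp, auto_unbox = TRUE, digits = NA)
  invisible(c(force = fp, kinematics = kp, meta = mp, truth = tp))
}

#' Read a trial directory written by [write_strike_trial()]
#'
#' @param dir Directory containing the four files.
#' @param stem File stem.
#' @return A `strike_trial` list (`truth` present when the JSON exists).
#' @export
read_strike_trial <- function(dir, stem) {
  meta <- read_trial_meta(file.path(dir, paste0(stem, "_meta.yaml")))
  force <- read_force_csv(file.path(dir, paste0(stem, "_force.csv")), meta)
  kin <- read_kinematics_csv(file.path(dir, paste0(stem, "_kinematics.csv")), meta)
  tp <- file.path(dir, paste0(stem, "_truth.json"))
  truth <- if (file.exists(tp)) jsonlite::read_json(tp, simplifyVector = TRUE) else NULL
  structure(list(force = force, kin = kin, meta = meta, truth = truth),
            class = "strike_trial")
}

#' Synchronize force and video clocks
#'
#' Expresses both records on a shared time axis with t = 0 at the camera
#' trigger: the force time base is shifted so that sample
#' `meta$trigger_force_sample` sits at t = 0 (video frame 1 is already at
#' t = 0 by construction of [read_kinematics_csv()]). Only timestamps are
#' changed, never signal values.
#'
#' @param force A [strike_force_trace()].
#' @param kin A [strike_kinematic_trace()].
#' @param meta A [trial_meta()].
#' @return A list `force`, `kin`, `overlap` (length-2 common time window).
#' @export
synchronize_trial <- function(force, kin, meta) {
  stopifnot(inherits(force, "strike_force_trace"),
            inherits(kin, "strike_kinematic_trace"),
            inherits(meta, "trial_meta"))
  if (meta$trigger_force_sample > nrow(force))
    stop("trigger_force_sample is beyond the force record", call. = FALSE)
  shift <- force$time[meta$trigger_force_sample]
  force$time <- force$time - shift
  overlap <- c(max(min(force$time), min(kin$time)),
               min(max(force$time), max(kin$time)))
  if (overlap[1] >= overlap[2])
    stop("force and kinematic records do not overlap after trigger alignment",
         call. = FALSE)
  list(force = force, kin = kin, overlap = overlap)
}
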