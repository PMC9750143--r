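## File interchange: 16-bit two-page TIFF frames with YAML ground-truth
## sidecars, CSV calibration/measurement tables, and CSV or extended-XYZ
## coordinate frames for buckled membranes.

#' Write / read a tube frame as TIFF + YAML sidecar
#'
#' The two channels are stored as a two-page 16-bit TIFF (membrane first),
#' counts scaled by 1/65535; pixel size, timestamp, ROI hints and (for
#' synthetic frames) scalar ground-truth fields go to a YAML sidecar next
#' to the image.
#'
#' @param frame a `tube_frame`.
#' @param path output TIFF path; the sidecar is `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_tube_frame <- function(frame, path) {
  stopifnot(inherits(frame, "tube_frame"))
  tiff::writeTIFF(
    list(pmin(pmax(frame$membrane, 0), 65535) / 65535,
         pmin(pmax(frame$protein, 0), 65535) / 65535),
    path, bits.per.sample = 16L
  )
  truth <- frame$truth
  truth_scalar <- if (is.null(truth)) NULL else {
    truth[vapply(truth, function(v) is.atomic(v) && length(v) <= 3 &&
                   !is.matrix(v), TRUE)]
  }
  yaml::write_yaml(
    list(pixel_size = frame$pixel_size, timestamp = frame$timestamp,
         hints = lapply(frame$hints, as.integer), truth = truth_scalar),
    paste0(path, ".yaml")
  )
  invisible(path)
}

#' @rdname write_tube_frame
#' @return For `read_tube_frame`, a `tube_frame` (counts quantised to the
#'   16-bit grid).
#' @export
read_tube_frame <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) stop("expected a two-page TIFF (membrane, protein)")
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  structure(
    list(membrane = pages[[1]] * 65535, protein = pages[[2]] * 65535,
         pixel_size = meta$pixel_size, timestamp = meta$timestamp,
         hints = lapply(meta$hints, as.numeric), truth = meta$truth),
    class = "tube_frame"
  )
}

#' Write / read a frame series
#'
#' @param frames list of `tube_frame` objects.
#' @param dir directory; frames are written as `frame_0001.tif`, ... with
#'   YAML sidecars.
#' @return File paths (write) or the list of frames (read), invisibly for
#'   write.
#' @export
write_tube_frames <- function(frames, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(seq_along(frames), function(i) {
    p <- file.path(dir, sprintf("frame_%04d.tif", i))
    write_tube_frame(frames[[i]], p)
    p
  }, "")
  invisible(paths)
}

#' @rdname write_tube_frames
#' @export
read_tube_frames <- function(dir) {
  paths <- sort(list.files(dir, pattern = "^frame_\\d+\\.tif$",
                           full.names = TRUE))
  if (!length(paths)) stop(sprintf("no frames found in %s", dir))
  lapply(paths, read_tube_frame)
}

#' Write / read a calibration pull table
#'
#' CSV with header `dP_Pa, r_pip_um, r_guv_um, F_pN, ratio`.
#'
#' @param cal a `calibration_set` data frame.
#' @param path CSV path.
#' @export
write_calibration_csv <- function(cal, path) {
  stopifnot(is.data.frame(cal))
  write.csv(as.data.frame(cal)[, c("dP_Pa", "r_pip_um", "r_guv_um",
                                   "F_pN", "ratio")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  df <- read.csv(path)
  need <- c("dP_Pa", "r_pip_um", "r_guv_um", "F_pN", "ratio")
  if (!all(need %in% names(df))) {
    stop("calibration CSV must have columns ", paste(need, collapse = ", "))
  }
  structure(df, class = c("calibration_set", "data.frame"))
}

.traj_to_table <- function(traj) {
  do.call(rbind, lapply(seq_along(traj$frames), function(i) {
    f <- traj$frames[[i]]
    rbind(
      data.frame(frame = i, time_ns = f$time, kind = "lipid",
                 leaflet = f$lipids$leaflet,
                 x = f$lipids$x, y = f$lipids$y, z = f$lipids$z),
      data.frame(frame = i, time_ns = f$time, kind = "probe", leaflet = NA,
                 x = f$probe[["x"]], y = f$probe[["y"]], z = f$probe[["z"]])
    )
  }))
}

#' Write / read a buckled-membrane trajectory as CSV + YAML sidecar
#'
#' Long-format CSV with columns `frame, time_ns, kind, leaflet, x, y, z`
#' (`kind` is `lipid` or `probe`); the box, equilibration cut and scalar
#' ground-truth fields go to `<path>.yaml`.
#'
#' @param traj a `buckle_trajectory`.
#' @param path CSV path.
#' @export
write_buckle_csv <- function(traj, path) {
  stopifnot(inherits(traj, "buckle_trajectory"))
  write.csv(.traj_to_table(traj), path, row.names = FALSE)
  gt <- traj$gt
  yaml::write_yaml(
    list(box = as.numeric(traj$box),
         equilibration_time = gt$equilibration_fraction * gt$n_frames *
           gt$frame_interval,
         gt = unclass(gt)),
    paste0(path, ".yaml")
  )
  invisible(path)
}

#' @rdname write_buckle_csv
#' @export
read_buckle_csv <- function(path) {
  df <- read.csv(path)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  box <- as.numeric(meta$box)
  eq_cut <- meta$equilibration_time
  frames <- lapply(split(df, df$frame), function(d) {
    p <- d[d$kind == "probe", , drop = FALSE]
    if (nrow(p) != 1) stop("each frame must contain exactly one probe row")
    l <- d[d$kind == "lipid", , drop = FALSE]
    list(
      time = d$time_ns[1],
      equilibrated = d$time_ns[1] > eq_cut,
      lipids = data.frame(x = l$x, y = l$y, z = l$z, leaflet = l$leaflet),
      probe = c(x = p$x, y = p$y, z = p$z)
    )
  })
  names(frames) <- NULL
  gt <- meta$gt
  if (!is.null(gt)) {
    gt$box <- as.numeric(gt$box)
    class(gt) <- "buckle_ground_truth"
  }
  structure(list(gt = gt, box = box, frames = frames),
            class = "buckle_trajectory")
}

#' Write a trajectory in extended-XYZ format
#'
#' One concatenated XYZ block per frame: atom count, a comment line with
#' `time=<ns> box=<Lx> <Ly> <Lz>`, then `P`/`PRB` records for lipid
#' phosphates and the probe.
#'
#' @param traj a `buckle_trajectory`.
#' @param path output path.
#' @export
write_buckle_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "buckle_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in traj$frames) {
    n <- nrow(f$lipids) + 1L
    writeLines(as.character(n), con)
    writeLines(sprintf("time=%g box=%g %g %g", f$time,
                       traj$box[1], traj$box[2], traj$box[3]), con)
    writeLines(sprintf("P %.4f %.4f %.4f", f$lipids$x, f$lipids$y,
                       f$lipids$z), con)
    writeLines(sprintf("PRB %.4f %.4f %.4f", f$probe[["x"]],
                       f$probe[["y"]], f$probe[["z"]]), con)
  }
  invisible(path)
}

#' Write measurement results
#'
#' @param results data frame of per-frame results.
#' @param path CSV path.
#' @export
write_results_csv <- function(results, path) {
  write.csv(results, path, row.names = FALSE)
  invisible(path)
}
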