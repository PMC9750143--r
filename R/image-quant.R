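## Segmentation and background-subtracted intensity measurement of
## GUV + tube frames. The tube and the GUV rim are processed in separate
## rectangular sub-regions (mirroring manually drawn ROIs), each thresholded
## on the membrane-dye channel by Otsu's method; pixels of a region outside
## its foreground mask serve as that region's background.

.check_rect <- function(r, nx, ny, what) {
  if (!(length(r) == 4 && r[1] >= 1 && r[2] <= nx && r[3] >= 1 && r[4] <= ny &&
          r[1] < r[2] && r[3] < r[4])) {
    stop(sprintf("invalid %s hint rectangle", what))
  }
  as.integer(round(r))
}

## Otsu threshold of one rectangular region of the membrane channel.
## Normalising the region to [0, 1] makes segmentation invariant under
## positive rescaling and offsets of the intensities.
.segment_region <- function(mem, rect, what) {
  sub <- mem[rect[3]:rect[4], rect[1]:rect[2]]
  rng <- range(sub)
  if (diff(rng) == 0) {
    stop(sprintf("degenerate Otsu threshold: %s region is single-valued", what))
  }
  norm <- (sub - rng[1]) / diff(rng)
  thr <- EBImage::otsu(norm, range = c(0, 1), levels = 256)
  mask <- matrix(FALSE, nrow(mem), ncol(mem))
  mask[rect[3]:rect[4], rect[1]:rect[2]] <- norm > thr
  mask
}

#' Segment tube and GUV regions of a frame
#'
#' Thresholds the membrane-dye channel within two rectangular hint regions
#' (tube and GUV) by Otsu's method. Foreground pixels form the tube and GUV
#' masks; the remaining pixels of each region form its background mask.
#' Tube-mask pixels closer than `trim_psf_mult` PSF standard deviations to
#' the GUV mask are discarded, so that light bleeding across the tube-GUV
#' junction does not bias the tube measurement.
#'
#' @param frame a `tube_frame` (see [generate_tube_frame()] or
#'   [read_tube_frame()]).
#' @param tube_hint,guv_hint rectangles `c(x0, x1, y0, y1)` in pixel
#'   coordinates, or `"auto"` to use the hints stored in the frame
#'   (available for synthetic frames).
#' @param psf_sigma PSF standard deviation (nm) used for junction trimming.
#' @param trim_psf_mult trim margin in units of the PSF sigma.
#' @return An object of class `roi_set` with logical full-frame masks
#'   `tube_mask`, `guv_mask`, `background_tube_mask`, `background_guv_mask`
#'   and their union `background_mask`.
#' @export
segment_rois <- function(frame, tube_hint = "auto", guv_hint = "auto",
                         psf_sigma = 120, trim_psf_mult = 5) {
  stopifnot(inherits(frame, "tube_frame"))
  mem <- frame$membrane
  nx <- ncol(mem); ny <- nrow(mem)
  if (identical(tube_hint, "auto")) tube_hint <- frame$hints$tube
  if (identical(guv_hint, "auto")) guv_hint <- frame$hints$guv
  if (is.null(tube_hint) || is.null(guv_hint)) {
    stop("no ROI hints available: pass tube_hint and guv_hint explicitly")
  }
  tube_hint <- .check_rect(tube_hint, nx, ny, "tube")
  guv_hint <- .check_rect(guv_hint, nx, ny, "GUV")

  guv_mask <- .segment_region(mem, guv_hint, "GUV")
  tube_mask <- .segment_region(mem, tube_hint, "tube")

  ## junction trim: drop tube pixels within the PSF bleed distance of the GUV
  trim_px <- trim_psf_mult * psf_sigma / frame$pixel_size
  if (any(tube_mask) && any(guv_mask) && trim_px > 0) {
    ti <- which(tube_mask, arr.ind = TRUE)
    gi <- which(guv_mask, arr.ind = TRUE)
    d2min <- vapply(seq_len(nrow(ti)), function(i) {
      min((ti[i, 1] - gi[, 1])^2 + (ti[i, 2] - gi[, 2])^2)
    }, 0)
    tube_mask[ti[d2min < trim_px^2, , drop = FALSE]] <- FALSE
  }
  if (!any(tube_mask)) stop("no tube detected in the tube hint region")
  if (!any(guv_mask)) stop("no GUV rim detected in the GUV hint region")

  in_tube_rect <- matrix(FALSE, ny, nx)
  in_tube_rect[tube_hint[3]:tube_hint[4], tube_hint[1]:tube_hint[2]] <- TRUE
  in_guv_rect <- matrix(FALSE, ny, nx)
  in_guv_rect[guv_hint[3]:guv_hint[4], guv_hint[1]:guv_hint[2]] <- TRUE
  bg_tube <- in_tube_rect & !tube_mask & !guv_mask
  bg_guv <- in_guv_rect & !guv_mask & !tube_mask
  ## keep the masks pairwise disjoint even for overlapping hints
  tube_mask <- tube_mask & !guv_mask

  structure(
    list(tube_mask = tube_mask, guv_mask = guv_mask,
         background_tube_mask = bg_tube, background_guv_mask = bg_guv,
         background_mask = bg_tube | bg_guv,
         tube_hint = tube_hint, guv_hint = guv_hint),
    class = "roi_set"
  )
}

#' Measure background-subtracted mean intensities
#'
#' For each channel, the mean intensity over the tube and GUV masks minus
#' the mean over the corresponding region's background pixels. Adding a
#' constant offset to both channels therefore leaves the measurement
#' unchanged.
#'
#' @param frame a `tube_frame`.
#' @param rois an `roi_set` from [segment_rois()].
#' @return An object of class `intensity_measurement`: list with
#'   `I_prot_tube`, `I_mem_tube`, `I_prot_guv`, `I_mem_guv`
#'   (background-subtracted means), `background_prot` and `background_mem`
#'   (named vectors, per region), `n_pixels`, `timestamp` and a `low_signal`
#'   flag set when any subtracted mean is non-positive.
#' @export
measure_intensities <- function(frame, rois) {
  stopifnot(inherits(frame, "tube_frame"), inherits(rois, "roi_set"))
  for (m in c("tube_mask", "guv_mask", "background_tube_mask",
              "background_guv_mask")) {
    if (!any(rois[[m]])) stop(sprintf("empty mask: %s", m))
  }
  bg_mem <- c(tube = mean(frame$membrane[rois$background_tube_mask]),
              guv = mean(frame$membrane[rois$background_guv_mask]))
  bg_prot <- c(tube = mean(frame$protein[rois$background_tube_mask]),
               guv = mean(frame$protein[rois$background_guv_mask]))
  out <- list(
    I_prot_tube = mean(frame$protein[rois$tube_mask]) - bg_prot[["tube"]],
    I_mem_tube = mean(frame$membrane[rois$tube_mask]) - bg_mem[["tube"]],
    I_prot_guv = mean(frame$protein[rois$guv_mask]) - bg_prot[["guv"]],
    I_mem_guv = mean(frame$membrane[rois$guv_mask]) - bg_mem[["guv"]],
    background_prot = bg_prot,
    background_mem = bg_mem,
    n_pixels = c(tube = sum(rois$tube_mask), guv = sum(rois$guv_mask),
                 background_tube = sum(rois$background_tube_mask),
                 background_guv = sum(rois$background_guv_mask)),
    timestamp = frame$timestamp
  )
  out$low_signal <- any(unlist(out[c("I_prot_tube", "I_mem_tube",
                                     "I_prot_guv", "I_mem_guv")]) <= 0)
  structure(out, class = "intensity_measurement")
}

#' @export
print.intensity_measurement <- function(x, ...) {
  cat("<intensity_measurement> (background-subtracted means)\n")
  cat(sprintf("  tube: I_prot = %.2f, I_mem = %.2f  (%d px)\n",
              x$I_prot_tube, x$I_mem_tube, x$n_pixels[["tube"]]))
  cat(sprintf("  GUV:  I_prot = %.2f, I_mem = %.2f  (%d px)\n",
              x$I_prot_guv, x$I_mem_guv, x$n_pixels[["guv"]]))
  if (isTRUE(x$low_signal)) cat("  flag: low signal\n")
  invisible(x)
}
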