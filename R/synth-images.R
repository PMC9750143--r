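#' Ground truth for a synthetic GUV + tube frame
#'
#' Bundles the physical and optical parameters from which
#' [generate_tube_frame()] renders a two-channel confocal frame of a giant
#' unilamellar vesicle (GUV) with a pulled membrane nanotube. The GUV is
#' rendered as its equatorial optical section (a bright ring); the tube as a
#' quasi-1D line whose membrane-channel brightness is proportional to its
#' radius in the thin-tube limit, so that the tube/GUV membrane intensity
#' ratio equals `tube_radius_true / k_tub` by construction.
#'
#' Channel brightness follows a simple photometric model: the membrane dye
#' contributes `counts_per_label` detector counts per dye lipid per um^2
#' (both leaflets fluoresce in an equatorial section), and the protein label
#' `counts_per_protein` counts per fluorophore per um^2. On the tube the
#' protein signal is additionally scaled by `sorting_true`.
#'
#' @param tube_radius_true tube radius (nm).
#' @param guv_radius_true GUV radius (um).
#' @param sorting_true dimensionless sorting ratio S >= 0 imposed on the tube.
#' @param density_guv_true protein surface density on the GUV
#'   (fluorophore copies um^-2).
#' @param label_fraction mole fraction of the dye-conjugated lipid.
#' @param pixel_size image calibration (nm per pixel).
#' @param psf_sigma standard deviation of the isotropic Gaussian point-spread
#'   function (nm); `0` renders unblurred single-pixel structures.
#' @param noise_model list with elements `type` (one of `"poisson"`,
#'   `"gaussian"`, `"none"`) and `scale` (camera gain for Poisson, additive
#'   standard deviation in counts for Gaussian).
#' @param seed integer seed; all randomness of the frame flows from it.
#' @param k_tub radius calibration constant implied by the rendering (nm).
#' @param image_dim image width and height in pixels.
#' @param counts_per_label detector counts per dye lipid per um^2.
#' @param counts_per_protein detector counts per protein fluorophore per um^2.
#' @param background constant background offset (counts), added to both
#'   channels.
#' @param lipid_area area per lipid (nm^2) used to convert `label_fraction`
#'   to a dye surface density.
#' @param timestamp acquisition time (s), carried through to measurements.
#'
#' @return An object of class `imaging_ground_truth`.
#' @seealso [generate_tube_frame()], [generate_timecourse()]
#' @export
imaging_ground_truth <- function(tube_radius_true = 50,
                                 guv_radius_true = 8,
                                 sorting_true = 10,
                                 density_guv_true = 500,
                                 label_fraction = 0.003,
                                 pixel_size = 100,
                                 psf_sigma = 120,
                                 noise_model = list(type = "poisson", scale = 1),
                                 seed = 1L,
                                 k_tub = 200,
                                 image_dim = c(320L, 200L),
                                 counts_per_label = 0.35,
                                 counts_per_protein = 0.6,
                                 background = 100,
                                 lipid_area = 0.7,
                                 timestamp = 0) {
  stopifnot(
    is.numeric(tube_radius_true), tube_radius_true > 0,
    is.numeric(guv_radius_true), guv_radius_true > 0,
    sorting_true >= 0, density_guv_true >= 0,
    label_fraction > 0, pixel_size > 0, psf_sigma >= 0,
    k_tub > 0, lipid_area > 0, background >= 0,
    length(image_dim) == 2, all(image_dim > 0)
  )
  ## the tube must be far thinner than the vesicle for the thin-tube
  ## rendering (and the physics) to hold
  if (tube_radius_true >= 0.05 * guv_radius_true * 1000) {
    stop("tube_radius_true must be much smaller than the GUV radius")
  }
  noise_model$type <- match.arg(noise_model$type, c("poisson", "gaussian", "none"))
  if (is.null(noise_model$scale)) {
    noise_model$scale <- if (noise_model$type == "gaussian") 30 else 1
  }
  structure(
    list(
      tube_radius_true = tube_radius_true,
      guv_radius_true = guv_radius_true,
      sorting_true = sorting_true,
      density_guv_true = density_guv_true,
      label_fraction = label_fraction,
      pixel_size = pixel_size,
      psf_sigma = psf_sigma,
      noise_model = noise_model,
      seed = seed,
      k_tub = k_tub,
      image_dim = as.integer(image_dim),
      counts_per_label = counts_per_label,
      counts_per_protein = counts_per_protein,
      background = background,
      lipid_area = lipid_area,
      timestamp = timestamp
    ),
    class = "imaging_ground_truth"
  )
}

## Frame geometry in pixel units shared by the renderer and the auto hints.
## The GUV centre sits off the pixel grid and the tube runs at a slight
## tilt, as in real acquisitions; a grid-aligned tube would be sampled at a
## single special sub-pixel phase of the PSF profile and bias its measured
## mean relative to the rim arc, which averages over all phases.
.frame_geometry <- function(gt) {
  nx <- gt$image_dim[1]
  ny <- gt$image_dim[2]
  r_px <- gt$guv_radius_true * 1000 / gt$pixel_size
  cx <- r_px + 12
  cy <- ny / 2 + 0.37
  tilt <- 0.02
  x_junction <- cx + r_px
  x_end <- nx - 10
  if (x_end <= x_junction + 20) {
    stop("tube longer than image extent: enlarge image_dim or shrink the GUV")
  }
  sigma_px <- gt$psf_sigma / gt$pixel_size
  trim_px <- max(6, ceiling(5 * sigma_px))
  list(
    nx = nx, ny = ny, cx = cx, cy = cy, r_px = r_px, tilt = tilt,
    x_junction = x_junction, x_end = x_end,
    sigma_px = sigma_px, trim_px = trim_px
  )
}

## Distance fields to the GUV rim circle and to the (tilted) tube segment;
## computed once per frame and reused for both channels and the
## ground-truth masks.
.distance_fields <- function(g) {
  X <- matrix(seq_len(g$nx), g$ny, g$nx, byrow = TRUE)
  Y <- matrix(seq_len(g$ny), g$ny, g$nx)
  d_rim <- abs(sqrt((X - g$cx)^2 + (Y - g$cy)^2) - g$r_px)
  a <- atan(g$tilt)
  ux <- cos(a); uy <- sin(a)
  len <- (g$x_end - g$x_junction) / ux
  t <- pmin(pmax((X - g$x_junction) * ux + (Y - g$cy) * uy, 0), len)
  d_tube <- sqrt((X - g$x_junction - t * ux)^2 + (Y - g$cy - t * uy)^2)
  list(rim = d_rim, tube = d_tube)
}

## A PSF-convolved ideal line has a Gaussian transverse profile, so ridges
## are rendered analytically rather than by discrete convolution. With
## sigma = 0 structures rasterise to single-pixel-wide uniform lines.
.render_ridges <- function(dist, sigma_px, amp_rim, amp_tube) {
  if (sigma_px > 0) {
    amp_rim * exp(-dist$rim^2 / (2 * sigma_px^2)) +
      amp_tube * exp(-dist$tube^2 / (2 * sigma_px^2))
  } else {
    amp_rim * (dist$rim < 0.5) + amp_tube * (dist$tube < 0.5)
  }
}

.apply_noise <- function(img, model) {
  out <- switch(model$type,
    none = img,
    poisson = matrix(rpois(length(img), lambda = pmax(img, 0) * model$scale) /
                       model$scale, nrow(img), ncol(img)),
    gaussian = img + rnorm(length(img), 0, model$scale)
  )
  pmin(pmax(out, 0), 65535)
}

#' Render a synthetic two-channel GUV + tube frame
#'
#' Renders the equatorial section of a GUV (bright ring) with a membrane
#' nanotube extending from its rim, in a membrane-dye channel and a
#' protein-label channel. Membrane-channel tube brightness is proportional
#' to `tube_radius_true` (projected membrane area per pixel in the thin-tube
#' limit); the protein channel equals the membrane channel scaled by the
#' label stoichiometry and, on the tube, additionally by `sorting_true`.
#' Both channels are blurred by the Gaussian PSF and noised per
#' `gt$noise_model`. The full ground truth (including half-maximum masks of
#' the noise-free structures and rectangular ROI hints that avoid the
#' tube-GUV junction) is retained alongside the pixel data.
#'
#' @param gt an [imaging_ground_truth()].
#' @return An object of class `tube_frame`: list with `membrane` and
#'   `protein` count matrices (rows = y), `pixel_size`, `timestamp`, `hints`
#'   (rectangles `c(x0, x1, y0, y1)` for tube and GUV) and `truth`.
#' @examples
#' fr <- generate_tube_frame(imaging_ground_truth(sorting_true = 4, seed = 7))
#' dim(fr$membrane)
#' @export
generate_tube_frame <- function(gt) {
  stopifnot(inherits(gt, "imaging_ground_truth"))
  if (!is.null(gt$seed)) set.seed(gt$seed)
  g <- .frame_geometry(gt)
  dist <- .distance_fields(g)

  label_density <- reference_label_density(gt$label_fraction,
                                           lipid_area = gt$lipid_area)
  amp_rim_mem <- gt$counts_per_label * label_density
  amp_tube_mem <- amp_rim_mem * gt$tube_radius_true / gt$k_tub
  rho <- gt$counts_per_protein * gt$density_guv_true / amp_rim_mem

  mem0 <- .render_ridges(dist, g$sigma_px, amp_rim_mem, amp_tube_mem)
  prot0 <- .render_ridges(dist, g$sigma_px,
                          amp_rim_mem * rho,
                          amp_tube_mem * rho * gt$sorting_true)

  membrane <- .apply_noise(mem0 + gt$background, gt$noise_model)
  protein <- .apply_noise(prot0 + gt$background, gt$noise_model)

  ## half-maximum ground-truth masks of the unblurred/blurred structures
  half_w <- if (g$sigma_px > 0) g$sigma_px * sqrt(2 * log(2)) else 0.5
  hints <- list(
    tube = c(ceiling(g$x_junction + g$trim_px), g$x_end,
             floor(g$cy - 10),
             ceiling(g$cy + 10 + g$tilt * (g$x_end - g$x_junction))),
    guv = c(max(1, floor(g$cx - g$r_px - 10)), ceiling(g$cx - g$r_px + 10),
            floor(g$cy - 40), ceiling(g$cy + 40))
  )
  truth <- c(unclass(gt), list(
    geometry = g,
    amp_rim_mem = amp_rim_mem,
    amp_tube_mem = amp_tube_mem,
    label_density = label_density,
    density_tube_true = gt$density_guv_true * gt$sorting_true,
    tube_mask_true = dist$tube <= half_w,
    guv_mask_true = dist$rim <= half_w,
    saturated = any(mem0 + gt$background > 65535) ||
      any(prot0 + gt$background > 65535)
  ))

  structure(
    list(membrane = membrane, protein = protein,
         pixel_size = gt$pixel_size, timestamp = gt$timestamp,
         hints = hints, truth = truth),
    class = "tube_frame"
  )
}

#' @export
print.tube_frame <- function(x, ...) {
  cat(sprintf(
    "<tube_frame> %d x %d px (%.0f nm/px), t = %.1f s\n",
    ncol(x$membrane), nrow(x$membrane), x$pixel_size, x$timestamp
  ))
  if (!is.null(x$truth)) {
    cat(sprintf("  truth: R = %.1f nm, S = %.3g, phi_GUV = %.3g um^-2\n",
                x$truth$tube_radius_true, x$truth$sorting_true,
                x$truth$density_guv_true))
  }
  invisible(x)
}

#' Render a time course of synthetic frames
#'
#' Renders one frame per ground truth in `gt_series`, mimicking the
#' experiment in which protein diffuses from the GUV onto a freshly pulled
#' tube until it reaches its equilibrium sorting value, optionally
#' constricting the tube as it accumulates. The tube protein density implied
#' by the series (`sorting_true * density_guv_true`) must be monotone
#' non-decreasing.
#'
#' @param gt_series list of [imaging_ground_truth()] objects, in time order.
#' @return List of `tube_frame` objects, each retaining its own ground truth.
#' @seealso [induction_schedule()] to build coupled density/radius ramps.
#' @export
generate_timecourse <- function(gt_series) {
  if (length(gt_series) == 0) stop("empty ground-truth series")
  stopifnot(all(vapply(gt_series, inherits, TRUE, "imaging_ground_truth")))
  dens <- vapply(gt_series, function(g) g$sorting_true * g$density_guv_true, 0)
  if (any(diff(dens) < -1e-9)) {
    stop("tube protein density must be monotone non-decreasing over the series")
  }
  lapply(gt_series, generate_tube_frame)
}

#' Ground-truth schedule for a curvature-induction time course
#'
#' Builds the series of ground truths for a tube on which protein
#' accumulates while the tube constricts: tube protein density ramps
#' linearly from `phi_tube[1]` to `phi_tube[2]` (complexes um^-2) while the
#' radius ramps from `radius[1]` to `radius[2]` nm over `duration` seconds.
#' The GUV density is held constant, so the ramp is realised through the
#' per-frame sorting ratio.
#'
#' @param phi_tube initial and final tube protein density (complexes um^-2).
#' @param radius initial and final tube radius (nm).
#' @param duration total duration (s).
#' @param dt frame interval (s).
#' @param phi_guv_copies GUV density in fluorophore copies um^-2 (constant).
#' @param copies_per_complex fluorophore copies per counted complex (2 for a
#'   dimer carrying one label per protomer).
#' @param seed base seed; frame i uses `seed + i`.
#' @param ... further arguments passed to [imaging_ground_truth()].
#' @return List of ground truths suitable for [generate_timecourse()].
#' @export
induction_schedule <- function(phi_tube = c(600, 1700), radius = c(50, 25),
                               duration = 80, dt = 6,
                               phi_guv_copies = 200, copies_per_complex = 2,
                               seed = 1L, ...) {
  stopifnot(duration > 0, dt > 0, phi_guv_copies > 0)
  times <- seq(0, duration, by = dt)
  f <- times / duration
  phi_t <- phi_tube[1] + f * (phi_tube[2] - phi_tube[1])
  r_t <- radius[1] + f * (radius[2] - radius[1])
  lapply(seq_along(times), function(i) {
    imaging_ground_truth(
      tube_radius_true = r_t[i],
      sorting_true = phi_t[i] * copies_per_complex / phi_guv_copies,
      density_guv_true = phi_guv_copies,
      seed = seed + i,
      timestamp = times[i],
      ...
    )
  })
}
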