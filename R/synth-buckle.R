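#' Ground truth for a synthetic buckled-membrane trajectory
#'
#' Parameters of a sinusoidally buckled bilayer patch,
#' `z = A sin(2 pi x / Lx)`, with periodic box `(Lx, Ly, Lz)`, plus a
#' membrane-bound probe (e.g. an amphipathic helix) whose in-plane position
#' is sampled with weight `exp(probe_bias * H(x))`, where `H` is the true
#' local mean curvature. `probe_bias = 0` gives an unbiased probe;
#' positive values bias it toward regions bulging toward the binding
#' leaflet. The sign convention throughout the package is that `H > 0`
#' where the membrane is convex toward +z (the probe-binding side), so a
#' buckle crest carries positive `H`.
#'
#' @param amplitude buckle amplitude A (nm); must satisfy `A < Lz / 2`.
#' @param box periodic box `c(Lx, Ly, Lz)` (nm).
#' @param lipid_count total number of lipids (both leaflets).
#' @param monolayer_thickness distance from the bilayer midplane to the
#'   phosphate level of each leaflet (nm).
#' @param probe_bias curvature-preference parameter (nm); exponent scale of
#'   the positional tilt.
#' @param probe_z_offset height of the probe's geometric center relative to
#'   the local phosphate level of the binding (upper) leaflet (nm);
#'   negative = inserted below the phosphates.
#' @param frame_interval sampling interval (ns).
#' @param n_frames number of frames.
#' @param equilibration_fraction fraction of initial frames flagged
#'   pre-equilibration; the probe is unbiased during these frames (it has
#'   not yet reached its preferred membrane regions).
#' @param jitter_sd thermal height jitter of headgroup positions (nm).
#' @param seed integer seed.
#' @return An object of class `buckle_ground_truth`.
#' @seealso [generate_buckled_membrane()]
#' @export
buckle_ground_truth <- function(amplitude = 6,
                                box = c(63, 28, 38),
                                lipid_count = 5040,
                                monolayer_thickness = 2,
                                probe_bias = 100,
                                probe_z_offset = 0,
                                frame_interval = 10,
                                n_frames = 200,
                                equilibration_fraction = 0.1,
                                jitter_sd = 0.3,
                                seed = 1L) {
  stopifnot(
    length(box) == 3, all(box > 0),
    amplitude >= 0, lipid_count > 0,
    monolayer_thickness > 0, frame_interval > 0, n_frames >= 1,
    equilibration_fraction >= 0, equilibration_fraction < 1,
    jitter_sd >= 0
  )
  if (amplitude >= box[3] / 2) {
    stop("incompatible box/amplitude: need A < Lz / 2")
  }
  structure(
    list(
      amplitude = amplitude, box = box, lipid_count = as.integer(lipid_count),
      monolayer_thickness = monolayer_thickness,
      probe_bias = probe_bias, probe_z_offset = probe_z_offset,
      frame_interval = frame_interval, n_frames = as.integer(n_frames),
      equilibration_fraction = equilibration_fraction,
      jitter_sd = jitter_sd, seed = seed
    ),
    class = "buckle_ground_truth"
  )
}

## True height and mean curvature of the generating sinusoid. H uses the
## full Monge-gauge expression for a 1D profile, signed so that crests
## (convex toward +z, the binding side) are positive.
.buckle_height <- function(x, A, Lx) A * sin(2 * pi * x / Lx)

.buckle_H_true <- function(x, A, Lx) {
  k <- 2 * pi / Lx
  hp <- A * k * cos(k * x)
  hpp <- -A * k^2 * sin(k * x)
  -hpp / (2 * (1 + hp^2)^1.5)
}

## Rejection sampler for the exponentially tilted probe x-marginal.
.sample_tilted_x <- function(n, A, Lx, bias) {
  if (bias == 0 || A == 0) return(runif(n, 0, Lx))
  grid <- seq(0, Lx, length.out = 4096)
  w_max <- max(exp(bias * .buckle_H_true(grid, A, Lx))) * 1.0001
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 100L)
    x <- runif(m, 0, Lx)
    keep <- runif(m) < exp(bias * .buckle_H_true(x, A, Lx)) / w_max
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}

#' Generate a buckled-membrane trajectory with a curvature-seeking probe
#'
#' Scatters phosphate headgroups of both leaflets on the sinusoidal surface
#' `z = A sin(2 pi x / Lx)` (leaflets offset by the monolayer thickness,
#' with thermal height jitter and uniform in-plane density in the periodic
#' box), and places one probe per frame. After the equilibration period the
#' probe's x position is drawn with weight `exp(probe_bias * H(x))`; before
#' it, uniformly. The probe's height is the local binding-leaflet phosphate
#' level plus `probe_z_offset` (plus jitter), supporting insertion-depth
#' analysis.
#'
#' @param gt a [buckle_ground_truth()].
#' @return An object of class `buckle_trajectory`: list with `gt`, `box`,
#'   and `frames`, each frame a list with `time` (ns), `equilibrated`
#'   (logical), `lipids` (data frame `x`, `y`, `z`, `leaflet`) and `probe`
#'   (named vector `x`, `y`, `z`).
#' @examples
#' traj <- generate_buckled_membrane(
#'   buckle_ground_truth(n_frames = 5, lipid_count = 400, seed = 2))
#' length(traj$frames)
#' @export
generate_buckled_membrane <- function(gt) {
  stopifnot(inherits(gt, "buckle_ground_truth"))
  if (!is.null(gt$seed)) set.seed(gt$seed)
  Lx <- gt$box[1]; Ly <- gt$box[2]
  n_leaf <- gt$lipid_count %/% 2L
  times <- seq_len(gt$n_frames) * gt$frame_interval
  eq_cut <- gt$equilibration_fraction * gt$n_frames * gt$frame_interval

  frames <- lapply(seq_len(gt$n_frames), function(i) {
    x <- runif(2L * n_leaf, 0, Lx)
    y <- runif(2L * n_leaf, 0, Ly)
    leaflet <- rep(c("upper", "lower"), each = n_leaf)
    offs <- ifelse(leaflet == "upper", gt$monolayer_thickness,
                   -gt$monolayer_thickness)
    z <- .buckle_height(x, gt$amplitude, Lx) + offs +
      rnorm(2L * n_leaf, 0, gt$jitter_sd)
    equilibrated <- times[i] > eq_cut
    px <- .sample_tilted_x(1L, gt$amplitude, Lx,
                           if (equilibrated) gt$probe_bias else 0)
    py <- runif(1L, 0, Ly)
    pz <- .buckle_height(px, gt$amplitude, Lx) + gt$monolayer_thickness +
      gt$probe_z_offset + rnorm(1L, 0, gt$jitter_sd)
    list(
      time = times[i], equilibrated = equilibrated,
      lipids = data.frame(x = x, y = y, z = z, leaflet = leaflet),
      probe = c(x = px, y = py, z = pz)
    )
  })
  structure(list(gt = gt, box = gt$box, frames = frames),
            class = "buckle_trajectory")
}

#' @export
print.buckle_trajectory <- function(x, ...) {
  gt <- x$gt
  cat(sprintf(
    "<buckle_trajectory> %d frames x %d lipids, box %.0f x %.0f x %.0f nm, A = %.1f nm\n",
    gt$n_frames, gt$lipid_count, gt$box[1], gt$box[2], gt$box[3], gt$amplitude
  ))
  cat(sprintf("  probe bias %.0f nm, z offset %.2f nm, dt = %.0f ns\n",
              gt$probe_bias, gt$probe_z_offset, gt$frame_interval))
  invisible(x)
}
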