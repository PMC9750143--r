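## Periodic 2D Fourier height-field fit to headgroup positions and local
## mean curvature from the shape operator of the fitted profile.
##
## Basis per dimension (length L, order N): {1, cos(2*pi*m*u/L),
## sin(2*pi*m*u/L)} for m = 1..N; the surface basis is the tensor product,
## (2*Nx+1)*(2*Ny+1) functions in total. Derivatives are analytic.

.fourier_dim_basis <- function(u, L, N, deriv = 0) {
  n <- length(u)
  B <- matrix(0, n, 2L * N + 1L)
  B[, 1] <- if (deriv == 0) 1 else 0
  if (N > 0) {
    for (m in seq_len(N)) {
      k <- 2 * pi * m / L
      a <- k * u
      cc <- switch(as.character(deriv),
                   "0" = cos(a), "1" = -k * sin(a), "2" = -k^2 * cos(a))
      ss <- switch(as.character(deriv),
                   "0" = sin(a), "1" = k * cos(a), "2" = -k^2 * sin(a))
      B[, 2L * m] <- cc
      B[, 2L * m + 1L] <- ss
    }
  }
  B
}

.surface_design <- function(x, y, box, orders, dx = 0, dy = 0) {
  Bx <- .fourier_dim_basis(x, box[1], orders[1], dx)
  By <- .fourier_dim_basis(y, box[2], orders[2], dy)
  px <- ncol(Bx); py <- ncol(By)
  D <- matrix(0, length(x), px * py)
  for (j in seq_len(py)) {
    D[, ((j - 1L) * px + 1L):(j * px)] <- Bx * By[, j]
  }
  D
}

#' Fit a periodic Fourier height field to headgroup positions
#'
#' Least-squares fit of the membrane profile `z(x, y)` as a truncated
#' two-dimensional Fourier expansion, periodic on the simulation box. When
#' positions from both leaflets are supplied the fit recovers the bilayer
#' midsurface; a single leaflet gives that leaflet's surface.
#'
#' @param positions data frame or matrix with columns `x`, `y`, `z` (nm).
#' @param box in-plane box lengths `c(Lx, Ly)` (nm).
#' @param orders Fourier truncation orders `c(Nx, Ny)`.
#' @param frame_id optional identifier carried through to the result.
#' @return An object of class `membrane_surface`: list with `coef` (matrix
#'   `(2Nx+1) x (2Ny+1)`), `orders`, `box`, `rms` (residual RMS, nm) and
#'   `n_points`.
#' @export
fit_membrane_profile <- function(positions, box, orders = c(6, 2),
                                 frame_id = NULL) {
  positions <- as.data.frame(positions)
  stopifnot(all(c("x", "y", "z") %in% names(positions)),
            length(box) >= 2, length(orders) == 2, all(orders >= 0))
  if (any(box[1:2] <= 0)) stop("degenerate box")
  n_basis <- (2 * orders[1] + 1) * (2 * orders[2] + 1)
  if (nrow(positions) < n_basis) {
    stop(sprintf("underdetermined fit: %d points for %d basis functions",
                 nrow(positions), n_basis))
  }
  D <- .surface_design(positions$x, positions$y, box, orders)
  fit <- lm.fit(D, positions$z)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  structure(
    list(
      coef = matrix(cf, 2 * orders[1] + 1, 2 * orders[2] + 1),
      orders = as.integer(orders), box = box[1:2],
      rms = sqrt(mean(fit$residuals^2)),
      n_points = nrow(positions), frame_id = frame_id
    ),
    class = "membrane_surface"
  )
}

#' @export
print.membrane_surface <- function(x, ...) {
  cat(sprintf(
    "<membrane_surface> orders (%d, %d) on %.1f x %.1f nm box; %d points, residual RMS %.3f nm\n",
    x$orders[1], x$orders[2], x$box[1], x$box[2], x$n_points, x$rms
  ))
  invisible(x)
}

.surf_partial <- function(surface, x, y, dx = 0, dy = 0) {
  Bx <- .fourier_dim_basis(x, surface$box[1], surface$orders[1], dx)
  By <- .fourier_dim_basis(y, surface$box[2], surface$orders[2], dy)
  rowSums((Bx %*% surface$coef) * By)
}

#' Evaluate a fitted membrane height field
#'
#' @param surface a `membrane_surface` from [fit_membrane_profile()].
#' @param x,y positions (nm); vectorised.
#' @return Heights z (nm).
#' @export
membrane_height <- function(surface, x, y) {
  stopifnot(inherits(surface, "membrane_surface"))
  .surf_partial(surface, x, y, 0, 0)
}

#' Local mean curvature from the shape operator
#'
#' Mean curvature `H` of the fitted height field, evaluated as half the
#' trace of the shape operator in the Monge gauge from the analytic first
#' and second derivatives of the Fourier expansion:
#' \deqn{H = -\frac{(1 + h_y^2) h_{xx} - 2 h_x h_y h_{xy} + (1 + h_x^2) h_{yy}}
#'   {2 (1 + h_x^2 + h_y^2)^{3/2}}}
#' The sign is fixed so that `H > 0` where the surface is convex toward +z,
#' the side on which the probe binds; the crest of a buckle therefore has
#' positive `H` of magnitude `2 pi^2 A / Lx^2` (for a pure sinusoid of
#' amplitude A at its crest).
#'
#' @param surface a `membrane_surface`.
#' @param x,y positions (nm); vectorised.
#' @return Mean curvature H (nm^-1).
#' @export
mean_curvature <- function(surface, x, y) {
  stopifnot(inherits(surface, "membrane_surface"))
  hx <- .surf_partial(surface, x, y, 1, 0)
  hy <- .surf_partial(surface, x, y, 0, 1)
  hxx <- .surf_partial(surface, x, y, 2, 0)
  hyy <- .surf_partial(surface, x, y, 0, 2)
  hxy <- .surf_partial(surface, x, y, 1, 1)
  -((1 + hy^2) * hxx - 2 * hx * hy * hxy + (1 + hx^2) * hyy) /
    (2 * (1 + hx^2 + hy^2)^1.5)
}

## Binding-leaflet assignment: the leaflet whose *local* phosphate level
## (mean height within an in-plane neighbourhood of the probe, periodic
## distances) is nearer the probe's height. A global leaflet mean would
## misassign on strongly buckled membranes, where the surface height
## varies by more than the bilayer thickness.
.binding_leaflet <- function(lipids, probe, box, radius = 2.5) {
  dx <- .min_image(lipids$x - probe[["x"]], box[1])
  dy <- .min_image(lipids$y - probe[["y"]], box[2])
  near <- dx^2 + dy^2 <= radius^2
  while (!all(vapply(split(near, lipids$leaflet), any, TRUE))) {
    radius <- radius * 1.5
    near <- dx^2 + dy^2 <= radius^2
  }
  mu <- tapply(lipids$z[near], lipids$leaflet[near], mean)
  names(mu)[which.min(abs(mu - probe[["z"]]))]
}

#' Sample curvature at the probe versus random lipid positions
#'
#' For every equilibrated frame of a buckled-membrane trajectory, fits the
#' binding-leaflet height field, evaluates the local mean curvature at the
#' probe's in-plane position, and at `n_random` randomly chosen phosphate
#' positions of the same leaflet and frame. Histograms over shared bins
#' summarise the probe's curvature preference against the random-lipid
#' null.
#'
#' @param traj a `buckle_trajectory` (see [generate_buckled_membrane()] and
#'   [read_buckle_csv()]).
#' @param orders Fourier truncation orders passed to
#'   [fit_membrane_profile()].
#' @param equilibration_cut drop frames with `time < equilibration_cut`
#'   (ns); by default the trajectory's own pre-equilibration flags are used.
#' @param n_random random lipid positions sampled per frame.
#' @param sampling_interval only use frames whose time is a multiple of
#'   this interval (ns); `NULL` uses every retained frame.
#' @param bins number of histogram bins.
#' @return An object of class `curvature_samples`: list with `probe_H`,
#'   `random_H` (nm^-1), `histogram` (data frame `mid`, `probe`, `random`;
#'   each column sums to 1), `mean_probe`, `mean_random`, `n_frames`,
#'   `equilibration_cut` and per-frame fit RMS.
#' @export
sample_probe_curvature <- function(traj, orders = c(6, 2),
                                   equilibration_cut = NULL,
                                   n_random = 10, sampling_interval = NULL,
                                   bins = 25) {
  stopifnot(inherits(traj, "buckle_trajectory"), n_random >= 1)
  keep <- vapply(traj$frames, function(f) {
    ok <- isTRUE(f$equilibrated)
    if (!is.null(equilibration_cut)) ok <- ok && f$time >= equilibration_cut
    if (!is.null(sampling_interval)) {
      ok <- ok && abs(f$time %% sampling_interval) < 1e-9
    }
    ok
  }, TRUE)
  if (!any(keep)) stop("empty sample: all frames are pre-equilibration")
  frames <- traj$frames[keep]

  probe_H <- numeric(length(frames))
  random_H <- vector("list", length(frames))
  rms <- numeric(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    leaf <- .binding_leaflet(f$lipids, f$probe, traj$box)
    lip <- f$lipids[f$lipids$leaflet == leaf, , drop = FALSE]
    surf <- fit_membrane_profile(lip, traj$box, orders, frame_id = f$time)
    probe_H[i] <- mean_curvature(surf, f$probe[["x"]], f$probe[["y"]])
    idx <- sample.int(nrow(lip), n_random, replace = n_random > nrow(lip))
    random_H[[i]] <- mean_curvature(surf, lip$x[idx], lip$y[idx])
    rms[i] <- surf$rms
  }
  random_H <- unlist(random_H)

  breaks <- seq(min(probe_H, random_H), max(probe_H, random_H),
                length.out = bins + 1)
  breaks[1] <- breaks[1] - 1e-12
  breaks[bins + 1] <- breaks[bins + 1] + 1e-12
  hp <- hist(probe_H, breaks = breaks, plot = FALSE)
  hr <- hist(random_H, breaks = breaks, plot = FALSE)
  histogram <- data.frame(
    mid = hp$mids,
    probe = hp$counts / sum(hp$counts),
    random = hr$counts / sum(hr$counts)
  )
  structure(
    list(probe_H = probe_H, random_H = random_H, histogram = histogram,
         mean_probe = mean(probe_H), mean_random = mean(random_H),
         n_frames = length(frames),
         equilibration_cut = equilibration_cut,
         fit_rms = rms),
    class = "curvature_samples"
  )
}

#' @export
print.curvature_samples <- function(x, ...) {
  cat(sprintf(
    "<curvature_samples> %d frames; mean H: probe %.4f, random %.4f nm^-1\n",
    x$n_frames, x$mean_probe, x$mean_random
  ))
  invisible(x)
}

#' Insertion depth relative to the local phosphate level
#'
#' For each equilibrated frame, the local phosphate level is the mean
#' height of binding-leaflet phosphates within `radius` (nm, periodic
#' in-plane distance) of the probe; the insertion offset is the probe
#' height minus that level, and the depth fraction expresses it as a
#' percentage of the monolayer thickness (negative = inserted below the
#' phosphate level).
#'
#' @param traj a `buckle_trajectory`.
#' @param radius neighbourhood radius (nm) for the local phosphate level.
#' @param monolayer_thickness monolayer thickness (nm); defaults to the
#'   trajectory's ground truth when available.
#' @return An object of class `insertion_depth_profile`: list with
#'   `per_frame` (data frame `time`, `z_offset`, `n_neighbors`),
#'   `mean_offset` (nm), `depth_fraction_pct` and `monolayer_thickness`.
#' @export
insertion_depth <- function(traj, radius = 1.5, monolayer_thickness = NULL) {
  stopifnot(inherits(traj, "buckle_trajectory"), radius > 0)
  if (is.null(monolayer_thickness)) {
    monolayer_thickness <- traj$gt$monolayer_thickness
  }
  if (is.null(monolayer_thickness) || monolayer_thickness <= 0) {
    stop("monolayer_thickness must be positive")
  }
  frames <- Filter(function(f) isTRUE(f$equilibrated), traj$frames)
  if (!length(frames)) stop("empty sample: all frames are pre-equilibration")
  rows <- lapply(frames, function(f) {
    leaf <- .binding_leaflet(f$lipids, f$probe, traj$box)
    lip <- f$lipids[f$lipids$leaflet == leaf, , drop = FALSE]
    dx <- .min_image(lip$x - f$probe[["x"]], traj$box[1])
    dy <- .min_image(lip$y - f$probe[["y"]], traj$box[2])
    sel <- dx^2 + dy^2 <= radius^2
    if (!any(sel)) {
      stop(sprintf("no phosphates within %.2f nm of the probe at t = %g ns",
                   radius, f$time))
    }
    data.frame(time = f$time,
               z_offset = f$probe[["z"]] - mean(lip$z[sel]),
               n_neighbors = sum(sel))
  })
  per_frame <- do.call(rbind, rows)
  mean_offset <- mean(per_frame$z_offset)
  structure(
    list(per_frame = per_frame, mean_offset = mean_offset,
         depth_fraction_pct = mean_offset / monolayer_thickness * 100,
         monolayer_thickness = monolayer_thickness, radius = radius),
    class = "insertion_depth_profile"
  )
}

#' @export
print.insertion_depth_profile <- function(x, ...) {
  cat(sprintf(
    "<insertion_depth_profile> mean offset %.3f nm = %.1f%% of the %.1f nm monolayer (%d frames)\n",
    x$mean_offset, x$depth_fraction_pct, x$monolayer_thickness,
    nrow(x$per_frame)
  ))
  invisible(x)
}
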