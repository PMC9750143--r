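#' Sorting ratio S
#'
#' The sorting ratio quantifies protein enrichment on the tube relative to
#' the GUV surface, normalised for membrane area via the membrane-dye
#' channel:
#' \deqn{S = \frac{I_{prot,tube} / I_{mem,tube}}{I_{prot,GUV} / I_{mem,GUV}}}
#' Gain changes of either channel cancel, so S is invariant under
#' independent rescaling of the protein and membrane channels.
#'
#' @param m an `intensity_measurement`, or a numeric vector/list with
#'   elements `I_prot_tube`, `I_mem_tube`, `I_prot_guv`, `I_mem_guv`.
#' @return S (dimensionless). `NA` with a warning if a denominator
#'   intensity is non-positive; `0` if only the tube protein signal is zero.
#' @export
sorting_ratio <- function(m) {
  v <- unlist(m[c("I_prot_tube", "I_mem_tube", "I_prot_guv", "I_mem_guv")])
  if (any(is.na(v))) return(NA_real_)
  if (v[["I_mem_tube"]] <= 0 || v[["I_mem_guv"]] <= 0 ||
        v[["I_prot_guv"]] <= 0) {
    warning("non-positive denominator intensity: sorting ratio undefined")
    return(NA_real_)
  }
  if (v[["I_prot_tube"]] < 0) {
    warning("negative tube protein signal: sorting ratio flagged low-signal")
    return(NA_real_)
  }
  (v[["I_prot_tube"]] / v[["I_mem_tube"]]) /
    (v[["I_prot_guv"]] / v[["I_mem_guv"]])
}

#' Tube radius from membrane fluorescence
#'
#' `R = k_tub * I_mem_tube / I_mem_guv`: the tube/GUV membrane-dye intensity
#' ratio times the experimentally calibrated constant `k_tub` (see
#' [fit_ktub()]).
#'
#' @param m an `intensity_measurement`, or directly the tube/GUV membrane
#'   intensity ratio as a numeric.
#' @param k_tub calibration constant (nm).
#' @return Tube radius (nm).
#' @export
tube_radius_from_fluorescence <- function(m, k_tub) {
  stopifnot(k_tub > 0)
  ratio <- if (is.numeric(m)) m else {
    if (m$I_mem_guv <= 0) stop("non-positive GUV membrane intensity")
    m$I_mem_tube / m$I_mem_guv
  }
  if (any(ratio <= 0)) stop("non-positive membrane intensity ratio")
  k_tub * ratio
}

#' Membrane tension from micropipette aspiration
#'
#' \deqn{\sigma = \frac{\Delta P \, r_{pip}}{2 (1 - r_{pip}/r_{GUV})}}
#' with the aspiration pressure step in Pa and radii in um; returns N/m.
#'
#' @param dP aspiration pressure difference from baseline (Pa).
#' @param r_pip aspiration pipette radius (um).
#' @param r_guv GUV radius (um).
#' @return Membrane tension sigma (N/m). Vectorised.
#' @export
membrane_tension <- function(dP, r_pip, r_guv) {
  if (any(dP < 0)) stop("aspiration pressure step must be non-negative")
  if (any(r_pip <= 0) || any(r_pip >= r_guv)) {
    stop("undefined geometry: need 0 < r_pip < r_guv")
  }
  dP * (r_pip * 1e-6) / (2 * (1 - r_pip / r_guv))
}

#' Tube radius from trap force and membrane tension
#'
#' `R = F / (4 pi sigma)`, the equilibrium radius of a membrane tether held
#' at force F under tension sigma. Force in pN, tension in N/m, radius in nm.
#'
#' @param F trap force (pN).
#' @param sigma membrane tension (N/m).
#' @return Tube radius (nm). Vectorised.
#' @export
radius_from_force <- function(F, sigma) {
  if (any(sigma <= 0)) stop("membrane tension must be positive")
  if (any(F < 0)) stop("force must be non-negative")
  F / (4 * pi * sigma) * 1e-3  # pN / (N/m) = 1e-12 m = 1e-3 nm
}

#' Calibrate k_tub from tube-pulling records
#'
#' For each pull, the reference tube radius is computed from aspiration
#' tension ([membrane_tension()]) and trap force ([radius_from_force()]),
#' then regressed against the tube/GUV membrane fluorescence ratio by
#' ordinary least squares. The slope is `k_tub`; the intercept is reported
#' as a quality control (it should be compatible with zero) but not used.
#'
#' @param cal a `calibration_set` (see [generate_calibration_pulls()] and
#'   [read_calibration_csv()]): data frame with columns `dP_Pa`, `r_pip_um`,
#'   `r_guv_um`, `F_pN`, `ratio`.
#' @param intercept fit with an intercept (default) or force the regression
#'   through the origin.
#' @param conf_level confidence level of the slope interval.
#' @return An object of class `ktub_fit`: list with `k_tub` (nm), `ci`,
#'   `intercept`, `r_squared`, `radii` (the per-record reference radii, nm)
#'   and the underlying `lm` fit.
#' @export
fit_ktub <- function(cal, intercept = TRUE, conf_level = 0.95) {
  stopifnot(is.data.frame(cal),
            all(c("dP_Pa", "r_pip_um", "r_guv_um", "F_pN", "ratio") %in%
                  names(cal)))
  if (nrow(cal) < 2 || length(unique(cal$ratio)) < 2) {
    stop("need at least 2 records with distinct intensity ratios")
  }
  if (any(cal$ratio <= 0)) stop("intensity ratios must be positive")
  sigma <- membrane_tension(cal$dP_Pa, cal$r_pip_um, cal$r_guv_um)
  R <- radius_from_force(cal$F_pN, sigma)
  df <- data.frame(R = R, ratio = cal$ratio)
  fit <- if (intercept) lm(R ~ ratio, df) else lm(R ~ ratio + 0, df)
  slope <- coef(fit)[["ratio"]]
  ci <- tryCatch(suppressWarnings(confint(fit, "ratio", level = conf_level)[1, ]),
                 error = function(e) c(NA_real_, NA_real_))
  r2 <- if (nrow(df) > 2) suppressWarnings(summary(fit)$r.squared) else 1
  structure(
    list(k_tub = slope, ci = ci,
         intercept = if (intercept) coef(fit)[["(Intercept)"]] else 0,
         r_squared = r2, radii = R, fit = fit, n = nrow(df)),
    class = "ktub_fit"
  )
}

#' @export
print.ktub_fit <- function(x, ...) {
  cat(sprintf("<ktub_fit> k_tub = %.2f nm (%d pulls, r^2 = %.3f)\n",
              x$k_tub, x$n, x$r_squared))
  cat(sprintf("  95%% CI [%.2f, %.2f] nm; intercept %.2f nm (QC)\n",
              x$ci[1], x$ci[2], x$intercept))
  invisible(x)
}

#' Surface-density calibration constants
#'
#' Holds the standard-curve slopes linking fluorescence to surface density:
#' bulk slopes of the protein and lipid fluorophores (whose ratio corrects
#' for their different optical properties) and the GUV membrane intensity
#' per dye-lipid surface density.
#'
#' @param slope_protein_fluor bulk intensity per concentration of the
#'   protein fluorophore.
#' @param slope_lipid_fluor bulk intensity per concentration of the lipid
#'   dye.
#' @param guv_intensity_vs_density GUV membrane intensity (counts) per
#'   dye-lipid surface density (um^-2).
#' @param lipid_area area per lipid (nm^2), default 0.7.
#' @param leaflet_factor leaflets contributing fluorescence in an equatorial
#'   section (default 2).
#' @return An object of class `density_calibration`.
#' @export
density_calibration <- function(slope_protein_fluor, slope_lipid_fluor,
                                guv_intensity_vs_density,
                                lipid_area = 0.7, leaflet_factor = 2) {
  stopifnot(slope_protein_fluor > 0, slope_lipid_fluor > 0,
            guv_intensity_vs_density > 0, lipid_area > 0,
            leaflet_factor %in% c(1, 2))
  structure(
    list(slope_protein_fluor = slope_protein_fluor,
         slope_lipid_fluor = slope_lipid_fluor,
         guv_intensity_vs_density = guv_intensity_vs_density,
         lipid_area = lipid_area, leaflet_factor = leaflet_factor),
    class = "density_calibration"
  )
}

#' Reference dye-lipid surface density
#'
#' Surface density implied by a dye-lipid mole fraction at a given area per
#' lipid: `leaflet_factor * fraction / lipid_area`, returned in um^-2.
#' E.g. 0.3 mol% dye at 0.7 nm^2 per lipid over both leaflets gives
#' 2 x 0.003 / 0.7 nm^-2 = 8571 um^-2.
#'
#' @inheritParams density_calibration
#' @param label_fraction dye-lipid mole fraction.
#' @return Surface density (um^-2).
#' @export
reference_label_density <- function(label_fraction, lipid_area = 0.7,
                                    leaflet_factor = 2) {
  stopifnot(label_fraction >= 0, lipid_area > 0)
  leaflet_factor * label_fraction / lipid_area * 1e6
}

#' Protein surface density from GUV intensity
#'
#' Converts a background-subtracted GUV protein intensity to a surface
#' density using the GUV intensity-vs-density slope, corrected by the bulk
#' slope ratio of the two fluorophores:
#' `phi = I / guv_intensity_vs_density * slope_lipid / slope_protein`.
#' For complexes carrying more than one fluorophore (e.g. a dimer with one
#' label per protomer), set `copies_per_complex` accordingly.
#'
#' @param I_prot_guv background-subtracted GUV protein intensity (counts).
#' @param cal a [density_calibration()].
#' @param copies_per_complex fluorophore copies per counted complex.
#' @return Surface density (complexes um^-2). Vectorised in `I_prot_guv`.
#' @export
surface_density <- function(I_prot_guv, cal, copies_per_complex = 1) {
  if (!inherits(cal, "density_calibration")) {
    stop("missing or invalid density calibration")
  }
  stopifnot(copies_per_complex >= 1)
  I_prot_guv / cal$guv_intensity_vs_density *
    cal$slope_lipid_fluor / cal$slope_protein_fluor / copies_per_complex
}

#' Quantify one frame: S, R and surface densities
#'
#' Runs segmentation and intensity measurement on a frame and derives the
#' sorting ratio, the fluorescence tube radius and (when a density
#' calibration is supplied) the protein surface densities on the GUV and on
#' the tube (`phi_tube = S * phi_guv`).
#'
#' @param frame a `tube_frame`.
#' @param k_tub radius calibration constant (nm).
#' @param density_cal optional [density_calibration()].
#' @param copies_per_complex fluorophore copies per counted complex.
#' @param ... passed to [segment_rois()].
#' @return One-row data frame (class `sorting_result`) with columns `t`,
#'   `S`, `R_nm`, `phi_guv`, `phi_tube` and `flags`.
#' @export
quantify_frame <- function(frame, k_tub, density_cal = NULL,
                           copies_per_complex = 1, ...) {
  m <- measure_intensities(frame, segment_rois(frame, ...))
  flags <- character(0)
  if (isTRUE(m$low_signal)) flags <- c(flags, "low_signal")
  if (!is.null(frame$truth$saturated) && frame$truth$saturated) {
    flags <- c(flags, "saturation")
  }
  S <- if (m$low_signal) NA_real_ else sorting_ratio(m)
  R <- if (m$I_mem_tube > 0 && m$I_mem_guv > 0) {
    tube_radius_from_fluorescence(m, k_tub)
  } else NA_real_
  phi_guv <- if (!is.null(density_cal)) {
    surface_density(m$I_prot_guv, density_cal, copies_per_complex)
  } else NA_real_
  res <- data.frame(
    t = if (is.null(m$timestamp)) NA_real_ else m$timestamp,
    S = S, R_nm = R, phi_guv = phi_guv, phi_tube = S * phi_guv,
    flags = paste(flags, collapse = ";")
  )
  class(res) <- c("sorting_result", "data.frame")
  res
}

#' Quantify a series of frames
#'
#' @param frames list of `tube_frame` objects.
#' @inheritParams quantify_frame
#' @return Data frame with one [quantify_frame()] row per frame plus a
#'   `frame` index column.
#' @export
quantify_frames <- function(frames, k_tub, density_cal = NULL,
                            copies_per_complex = 1, ...) {
  if (length(frames) == 0) stop("no frames to quantify")
  rows <- lapply(frames, quantify_frame, k_tub = k_tub,
                 density_cal = density_cal,
                 copies_per_complex = copies_per_complex, ...)
  out <- do.call(rbind, rows)
  out <- cbind(frame = seq_along(frames), out)
  class(out) <- "data.frame"
  out
}

#' Curvature-induction time-course analysis
#'
#' Summarises a time course of tube measurements into initial and final
#' protein density and radius (means over head/tail windows) and the slope
#' of protein density change over radius change, the signature of
#' protein-driven tube constriction (negative slope: the tube narrows as
#' protein accumulates).
#'
#' @param results data frame with columns `t`, `phi_tube` and `R_nm` (e.g.
#'   from [quantify_frames()]); rows with missing values are dropped.
#' @param window number of frames averaged for the initial and final values.
#' @return An object of class `induction_record`: list with `phi_initial`,
#'   `phi_final`, `R_initial`, `R_final` , `slope` (um^-2 per nm), `flags`
#'   and the retained `series`.
#' @export
timecourse_analysis <- function(results, window = 3) {
  stopifnot(is.data.frame(results),
            all(c("t", "phi_tube", "R_nm") %in% names(results)))
  ok <- stats::complete.cases(results[, c("t", "phi_tube", "R_nm")])
  series <- results[ok, , drop = FALSE]
  series <- series[order(series$t), , drop = FALSE]
  n <- nrow(series)
  if (n < 2) stop("need at least 2 valid time points")
  w <- max(1L, min(as.integer(window), n %/% 2L))
  phi_i <- mean(head(series$phi_tube, w)); phi_f <- mean(tail(series$phi_tube, w))
  R_i <- mean(head(series$R_nm, w)); R_f <- mean(tail(series$R_nm, w))
  dR <- R_f - R_i; dphi <- phi_f - phi_i
  flags <- character(0)
  tol_R <- 1e-6 * max(abs(series$R_nm))
  tol_phi <- 1e-6 * max(abs(series$phi_tube), 1)
  slope <- if (abs(dR) < tol_R) {
    flags <- c(flags, if (abs(dphi) < tol_phi) "flat" else "infinite_slope")
    NA_real_
  } else {
    dphi / dR
  }
  structure(
    list(phi_initial = phi_i, phi_final = phi_f,
         R_initial = R_i, R_final = R_f,
         slope = slope, flags = flags, window = w, series = series),
    class = "induction_record"
  )
}

#' @export
print.induction_record <- function(x, ...) {
  cat(sprintf(
    "<induction_record> phi_tube %.0f -> %.0f um^-2, R %.1f -> %.1f nm (%d frames)\n",
    x$phi_initial, x$phi_final, x$R_initial, x$R_final, nrow(x$series)
  ))
  if (length(x$flags)) {
    cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  } else {
    cat(sprintf("  slope d(phi)/dR = %.2f um^-2 nm^-1\n", x$slope))
  }
  invisible(x)
}
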