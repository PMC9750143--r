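#' Pipeline configuration
#'
#' A single configuration object ties the analysis stages into reproducible
#' pipelines: input/output paths, the physical constants, the seed and the
#' surface-density threshold splitting tubes into high- and low-density
#' groups. Configurations round-trip losslessly through YAML
#' ([write_pipeline_config()] / [read_pipeline_config()]), and every output
#' table carries a hash of the configuration that produced it.
#'
#' @param frames_dir directory of TIFF frames (see [write_tube_frames()]).
#' @param trajectory_file CSV path of a buckled-membrane trajectory.
#' @param output_dir where result tables and plots are written; `NULL`
#'   keeps results in memory only.
#' @param k_tub radius calibration constant (nm).
#' @param lipid_area area per lipid (nm^2).
#' @param leaflet_factor fluorescing leaflets in an equatorial section.
#' @param copies_per_complex fluorophore copies per counted complex.
#' @param density_split GUV surface density (um^-2) separating the
#'   "high" from the "low" density group.
#' @param head_tail_window frames averaged for time-course endpoints.
#' @param fourier_orders Fourier truncation `c(Nx, Ny)`.
#' @param equilibration_cut optional extra equilibration gate (ns).
#' @param n_random random lipid positions per frame.
#' @param insertion_radius neighbourhood radius (nm) for the local
#'   phosphate level in the insertion-depth analysis.
#' @param psf_sigma PSF sigma (nm) used for junction trimming.
#' @param density_cal optional list with `slope_protein_fluor`,
#'   `slope_lipid_fluor`, `guv_intensity_vs_density`.
#' @param seed integer seed for every stochastic step of a pipeline run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(frames_dir = NULL, trajectory_file = NULL,
                            output_dir = NULL,
                            k_tub = 200, lipid_area = 0.7,
                            leaflet_factor = 2, copies_per_complex = 1,
                            density_split = 250, head_tail_window = 3,
                            fourier_orders = c(6, 2),
                            equilibration_cut = NULL, n_random = 10,
                            insertion_radius = 1.5,
                            psf_sigma = 120, density_cal = NULL,
                            seed = 1L) {
  stopifnot(k_tub > 0, lipid_area > 0, leaflet_factor %in% c(1, 2),
            copies_per_complex >= 1, density_split > 0,
            head_tail_window >= 1, length(fourier_orders) == 2,
            all(fourier_orders >= 0), n_random >= 1, insertion_radius > 0,
            psf_sigma >= 0)
  structure(
    list(frames_dir = frames_dir, trajectory_file = trajectory_file,
         output_dir = output_dir, k_tub = k_tub, lipid_area = lipid_area,
         leaflet_factor = leaflet_factor,
         copies_per_complex = copies_per_complex,
         density_split = density_split,
         head_tail_window = head_tail_window,
         fourier_orders = as.integer(fourier_orders),
         equilibration_cut = equilibration_cut,
         n_random = as.integer(n_random),
         insertion_radius = insertion_radius, psf_sigma = psf_sigma,
         density_cal = density_cal, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path, precision = 17L)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

## Short content hash of the analysis parameters (paths excluded, so the
## same analysis written to a different location keeps the same hash),
## stamped onto every output row.
.config_hash <- function(config) {
  pars <- unclass(config)
  pars[c("frames_dir", "trajectory_file", "output_dir")] <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(pars, precision = 17L), tmp)
  substr(unname(tools::md5sum(tmp)), 1, 8)
}

.density_cal_from_config <- function(config) {
  dc <- config$density_cal
  if (is.null(dc)) return(NULL)
  density_calibration(
    slope_protein_fluor = dc$slope_protein_fluor,
    slope_lipid_fluor = dc$slope_lipid_fluor,
    guv_intensity_vs_density = dc$guv_intensity_vs_density,
    lipid_area = config$lipid_area,
    leaflet_factor = config$leaflet_factor
  )
}

#' Run the sorting-versus-curvature pipeline
#'
#' Quantifies every frame (sorting ratio S, tube radius R, surface
#' densities), splits tubes into high- and low-density groups at
#' `config$density_split`, and fits S against tube curvature 1/R by
#' ordinary least squares per group. Results, fits and a scatter plot are
#' written to `config$output_dir` when set.
#'
#' @param config a [pipeline_config()].
#' @param frames optional in-memory list of `tube_frame` objects,
#'   overriding `config$frames_dir`.
#' @return List with `results` (per-tube rows, including `curvature` = 1/R
#'   and the density group), `fits` (per-group slope, intercept, r^2, n),
#'   `plot` (a ggplot), and `config_hash`.
#' @export
run_sorting_pipeline <- function(config, frames = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  if (is.null(frames)) {
    if (is.null(config$frames_dir)) stop("no input frames: set frames_dir")
    frames <- read_tube_frames(config$frames_dir)
  }
  if (!length(frames)) stop("no valid tubes: empty input")
  hash <- .config_hash(config)
  dcal <- .density_cal_from_config(config)

  results <- quantify_frames(frames, k_tub = config$k_tub,
                             density_cal = dcal,
                             copies_per_complex = config$copies_per_complex,
                             psf_sigma = config$psf_sigma)
  results$curvature <- 1 / results$R_nm
  results$group <- if (all(is.na(results$phi_guv))) "all" else {
    ifelse(results$phi_guv > config$density_split, "high", "low")
  }
  results$config_hash <- hash

  valid <- results[!is.na(results$S) & !is.na(results$curvature), ,
                   drop = FALSE]
  if (!nrow(valid)) stop("no valid tubes after quantification")
  fits <- do.call(rbind, lapply(split(valid, valid$group), function(d) {
    if (nrow(d) >= 2 && length(unique(d$curvature)) >= 2) {
      f <- lm(S ~ curvature, d)
      data.frame(group = d$group[1], slope = coef(f)[["curvature"]],
                 intercept = coef(f)[["(Intercept)"]],
                 r_squared = if (nrow(d) > 2)
                   suppressWarnings(summary(f)$r.squared) else 1,
                 n = nrow(d))
    } else {
      data.frame(group = d$group[1], slope = NA_real_, intercept = NA_real_,
                 r_squared = NA_real_, n = nrow(d))
    }
  }))
  rownames(fits) <- NULL
  fits$config_hash <- hash

  plt <- ggplot2::ggplot(valid,
                         ggplot2::aes(x = .data$curvature, y = .data$S,
                                      colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = expression(1 / R ~ (nm^-1)), y = "sorting ratio S",
                  colour = expression(phi[v] ~ group)) +
    ggplot2::theme_classic()

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_csv(results, file.path(config$output_dir, "sorting_results.csv"))
    write_results_csv(fits, file.path(config$output_dir, "sorting_fits.csv"))
    ggplot2::ggsave(file.path(config$output_dir, "sorting_vs_curvature.png"),
                    plt, width = 5, height = 4, dpi = 150)
  }
  list(results = results, fits = fits, plot = plt, config_hash = hash)
}

#' Run the buckled-membrane curvature pipeline
#'
#' Fits per-frame height fields, samples probe and random-lipid curvature
#' distributions after equilibration gating, measures insertion depth, and
#' writes histogram/summary tables plus a histogram plot when
#' `config$output_dir` is set.
#'
#' @param config a [pipeline_config()].
#' @param trajectory optional in-memory `buckle_trajectory`, overriding
#'   `config$trajectory_file`.
#' @return List with `samples` (a `curvature_samples`), `depth` (an
#'   `insertion_depth_profile`), `summary` (one-row data frame), `plot` and
#'   `config_hash`.
#' @export
run_curvature_pipeline <- function(config, trajectory = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  if (is.null(trajectory)) {
    if (is.null(config$trajectory_file)) {
      stop("no input trajectory: set trajectory_file")
    }
    if (!file.exists(config$trajectory_file)) {
      stop(sprintf("trajectory file not found: %s", config$trajectory_file))
    }
    trajectory <- read_buckle_csv(config$trajectory_file)
  }
  hash <- .config_hash(config)

  samples <- sample_probe_curvature(
    trajectory, orders = config$fourier_orders,
    equilibration_cut = config$equilibration_cut,
    n_random = config$n_random
  )
  depth <- insertion_depth(trajectory, radius = config$insertion_radius)
  summary_df <- data.frame(
    mean_H_probe = samples$mean_probe,
    mean_H_random = samples$mean_random,
    n_frames = samples$n_frames,
    insertion_offset_nm = depth$mean_offset,
    depth_fraction_pct = depth$depth_fraction_pct,
    config_hash = hash
  )

  hd <- samples$histogram
  long <- data.frame(
    mid = rep(hd$mid, 2),
    p = c(hd$probe, hd$random),
    which = rep(c("probe", "random lipid"), each = nrow(hd))
  )
  plt <- ggplot2::ggplot(long, ggplot2::aes(x = .data$mid, y = .data$p,
                                            colour = .data$which)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = expression(H ~ (nm^-1)), y = "probability",
                  colour = NULL) +
    ggplot2::theme_classic()

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_csv(cbind(hd, config_hash = hash),
                      file.path(config$output_dir, "curvature_histogram.csv"))
    write_results_csv(summary_df,
                      file.path(config$output_dir, "curvature_summary.csv"))
    ggplot2::ggsave(file.path(config$output_dir, "curvature_histogram.png"),
                    plt, width = 5, height = 4, dpi = 150)
  }
  list(samples = samples, depth = depth, summary = summary_df, plot = plt,
       config_hash = hash)
}
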