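#' Generate a synthetic tube-pulling calibration set
#'
#' Emulates the k_tub calibration experiment: tubes pulled from aspirated
#' GUVs at varied aspiration pressure. For each pull, pipette and GUV radii,
#' pressure step and target tube radius are drawn from plausible
#' experimental ranges; membrane tension follows from the aspiration
#' formula, the trap force is back-computed as `F = 4 pi sigma R`, and the
#' tube/GUV membrane fluorescence ratio is set to `R / k_tub_true` with
#' optional multiplicative noise.
#'
#' @param n number of pulls (>= 2).
#' @param k_tub_true calibration constant to encode (nm).
#' @param noise relative standard deviation of the intensity ratio (0 =
#'   noiseless).
#' @param seed integer seed.
#' @param r_pip_range,r_guv_range,radius_range,dP_range sampling ranges for
#'   pipette radius (um), GUV radius (um), tube radius (nm) and pressure
#'   step (Pa).
#' @return A `calibration_set`: data frame with columns `dP_Pa`, `r_pip_um`,
#'   `r_guv_um`, `F_pN`, `ratio`, carrying `k_tub_true` as an attribute.
#' @seealso [fit_ktub()]
#' @export
generate_calibration_pulls <- function(n, k_tub_true = 200, noise = 0,
                                       seed = 1L,
                                       r_pip_range = c(1.5, 2.5),
                                       r_guv_range = c(6, 15),
                                       radius_range = c(10, 150),
                                       dP_range = c(20, 300)) {
  if (n < 2) stop("need at least 2 calibration pulls")
  stopifnot(k_tub_true > 0, noise >= 0)
  if (!is.null(seed)) set.seed(seed)
  r_pip <- runif(n, r_pip_range[1], r_pip_range[2])
  r_guv <- runif(n, r_guv_range[1], r_guv_range[2])
  dP <- runif(n, dP_range[1], dP_range[2])
  R <- if (n == 2) radius_range else runif(n, radius_range[1], radius_range[2])
  sigma <- membrane_tension(dP, r_pip, r_guv)
  F_pN <- 4 * pi * sigma * R * 1e3          # N/m * nm -> pN
  ratio <- R / k_tub_true * (1 + noise * rnorm(n))
  structure(
    data.frame(dP_Pa = dP, r_pip_um = r_pip, r_guv_um = r_guv,
               F_pN = F_pN, ratio = ratio),
    k_tub_true = k_tub_true,
    class = c("calibration_set", "data.frame")
  )
}

#' Generate synthetic fluorophore standard curves and a density calibration
#'
#' Emulates the surface-density calibration: (i) bulk serial dilutions of
#' the protein fluorophore and of the dye-conjugated lipid, whose linear
#' slopes correct for the fluorophores' different optical properties, and
#' (ii) GUVs containing known dye-lipid mole fractions, rendered and
#' measured through the package's own segmentation pipeline so that the
#' GUV intensity-per-density slope carries the same optical geometry as
#' later sorting measurements.
#'
#' @param base_gt template [imaging_ground_truth()] providing the optics and
#'   photometry; its `label_fraction` is overridden per standard.
#' @param dye_fractions dye-lipid mole fractions of the GUV standards.
#' @param bulk_concentrations bulk concentrations (arbitrary units) of the
#'   serial dilution.
#' @param bulk_gain instrument gain of the bulk measurement (counts per
#'   concentration unit per brightness unit).
#' @param noise relative noise on the bulk intensities.
#' @param seed integer seed.
#' @return List with `calibration` (a [density_calibration()]), the bulk
#'   standard table `bulk`, the GUV standard table `guv`, and `truth`
#'   (the per-molecule brightness constants used).
#' @export
generate_density_standards <- function(base_gt = imaging_ground_truth(),
                                       dye_fractions = c(3e-4, 1e-3, 3e-3, 6e-3, 1e-2),
                                       bulk_concentrations = seq(10, 100, by = 10),
                                       bulk_gain = 2,
                                       noise = 0,
                                       seed = 1L) {
  stopifnot(inherits(base_gt, "imaging_ground_truth"), bulk_gain > 0)
  if (!is.null(seed)) set.seed(seed)

  ## bulk serial dilutions: slope ratio encodes relative brightness
  n <- length(bulk_concentrations)
  bulk <- data.frame(
    concentration = bulk_concentrations,
    I_protein = bulk_gain * base_gt$counts_per_protein * bulk_concentrations *
      (1 + noise * rnorm(n)),
    I_lipid = bulk_gain * base_gt$counts_per_label * bulk_concentrations *
      (1 + noise * rnorm(n))
  )
  slope_protein <- coef(lm(I_protein ~ concentration, bulk))[["concentration"]]
  slope_lipid <- coef(lm(I_lipid ~ concentration, bulk))[["concentration"]]

  ## GUV standards: render + measure with the same pipeline as real frames
  guv <- do.call(rbind, lapply(seq_along(dye_fractions), function(i) {
    gt <- base_gt
    gt$label_fraction <- dye_fractions[i]
    gt$seed <- if (is.null(base_gt$seed)) NULL else base_gt$seed + i
    fr <- generate_tube_frame(gt)
    m <- measure_intensities(fr, segment_rois(fr))
    data.frame(
      dye_fraction = dye_fractions[i],
      density_um2 = reference_label_density(dye_fractions[i],
                                            lipid_area = gt$lipid_area),
      I_mem_guv = m$I_mem_guv
    )
  }))
  slope_guv <- coef(lm(I_mem_guv ~ density_um2, guv))[["density_um2"]]

  cal <- density_calibration(
    slope_protein_fluor = slope_protein,
    slope_lipid_fluor = slope_lipid,
    guv_intensity_vs_density = slope_guv,
    lipid_area = base_gt$lipid_area
  )
  list(
    calibration = cal, bulk = bulk, guv = guv,
    truth = list(counts_per_protein = base_gt$counts_per_protein,
                 counts_per_label = base_gt$counts_per_label,
                 bulk_gain = bulk_gain)
  )
}
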