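#' Simulation parameters for synthetic confocal fields
#'
#' Bundles the generative model for a two/three-channel field of dendritic
#' spines: compact Gaussian puncta on the red (phalloidin/F-actin) channel
#' with heavy-tailed amplitudes, a green (EGFP-CapZ) channel whose per-spine
#' amplitude is the red amplitude times a spine-specific CapZ factor drawn
#' from a dim/bright mixture, distractor structures (dendritic shafts,
#' somata) that segmentation must reject, a flat background pedestal
#' defining the image mode, and a confocal-style noise model.
#'
#' @param image_shape integer (rows, cols) of the simulated field, pixels.
#' @param pixel_size microns per pixel. The default 0.103 makes the
#'   5-pixel-diameter measurement ROI 0.515 um across, i.e. roughly one
#'   spine head.
#' @param n_spines number of spine puncta planted per field.
#' @param spot_sigma isotropic Gaussian sigma of a punctum, pixels; the
#'   profile is truncated at 4 sigma.
#' @param red_amp_median,red_amp_sigma median and log-sd of the log-normal
#'   red peak-amplitude distribution (arbitrary DN). The log-normal gives
#'   the heavy upper tail typical of phalloidin brightness.
#' @param capz_p_bright probability that a spine belongs to the bright
#'   CapZ component (default 0.25: CapZ is detectable in roughly a quarter
#'   of spines).
#' @param capz_dim_mean,capz_bright_mean log-normal medians of the dim and
#'   bright CapZ-factor components (green/red amplitude ratio, unitless).
#' @param capz_spread log-sd shared by both mixture components.
#' @param n_shafts,shaft_width,shaft_amp number, width (px) and added
#'   amplitude (DN) of elongated dendritic-shaft structures.
#' @param n_somata,soma_radius,soma_amp number, radius (px) and added
#'   amplitude (DN) of large disc-shaped somata.
#' @param background_level flat pedestal (DN) added to every pixel; the
#'   most frequent pixel value of a noiseless field, and the quantity the
#'   mode-based background estimator must recover.
#' @param read_noise_sd additive Gaussian read noise sd (DN).
#' @param shot_noise logical; Poisson noise on the photon signal when
#'   TRUE (the pedestal is an electronic offset and carries only read
#'   noise).
#' @param actinin_coupling NULL for a two-channel field, otherwise a value
#'   in [0, 1]: a third (alpha-actinin immunolabel) channel is rendered
#'   with per-spine amplitude
#'   `actinin_baseline * red_amp * (1 + coupling * z)` where z is the
#'   spine's CapZ factor scaled to the field maximum — actinin scales
#'   with the spine's actin content, with optional preferential
#'   accumulation in high-CapZ spines.
#' @param actinin_baseline baseline actinin amplitude as a fraction of
#'   the spine's red amplitude (unitless).
#' @param quantize NA for automatic (quantize to integer DN in the 16-bit
#'   range whenever any noise is on), or TRUE/FALSE to force.
#' @param seed integer seed; identical parameters and seed give
#'   bit-identical output.
#'
#' @return an object of class `sim_params` (a validated list).
#' @export
sim_params <- function(image_shape = c(256L, 256L),
                       pixel_size = 0.103,
                       n_spines = 250L,
                       spot_sigma = 1.0,
                       red_amp_median = 1000,
                       red_amp_sigma = 0.6,
                       capz_p_bright = 0.25,
                       capz_dim_mean = 0.2,
                       capz_bright_mean = 1.0,
                       capz_spread = 0.3,
                       n_shafts = 2L,
                       shaft_width = 3,
                       shaft_amp = 800,
                       n_somata = 1L,
                       soma_radius = 15,
                       soma_amp = 1600,
                       background_level = 100,
                       read_noise_sd = 3,
                       shot_noise = TRUE,
                       actinin_coupling = NULL,
                       actinin_baseline = 0.5,
                       quantize = NA,
                       seed = 1L) {
  p <- list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
            n_spines = as.integer(n_spines), spot_sigma = spot_sigma,
            red_amp_median = red_amp_median, red_amp_sigma = red_amp_sigma,
            capz_p_bright = capz_p_bright, capz_dim_mean = capz_dim_mean,
            capz_bright_mean = capz_bright_mean, capz_spread = capz_spread,
            n_shafts = as.integer(n_shafts), shaft_width = shaft_width,
            shaft_amp = shaft_amp, n_somata = as.integer(n_somata),
            soma_radius = soma_radius, soma_amp = soma_amp,
            background_level = background_level,
            read_noise_sd = read_noise_sd, shot_noise = isTRUE(shot_noise),
            actinin_coupling = actinin_coupling,
            actinin_baseline = actinin_baseline,
            quantize = quantize, seed = as.integer(seed))
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  if (length(p$image_shape) != 2L || any(p$image_shape < 8L))
    stopf("image_shape must be two dimensions of at least 8 pixels")
  if (!is_scalar_num(p$pixel_size) || p$pixel_size <= 0)
    stopf("pixel_size must be a positive scalar")
  if (!is_count(p$n_spines)) stopf("n_spines must be a nonnegative count")
  for (f in c("spot_sigma", "red_amp_median", "red_amp_sigma", "capz_dim_mean",
              "capz_bright_mean", "capz_spread", "background_level"))
    if (!is_scalar_num(p[[f]]) || p[[f]] <= 0)
      stopf("%s must be positive", f)
  if (!is_scalar_num(p$capz_p_bright) || p$capz_p_bright < 0 || p$capz_p_bright > 1)
    stopf("capz_p_bright must lie in [0, 1]")
  if (p$read_noise_sd < 0) stopf("read_noise_sd must be nonnegative")
  for (f in c("shaft_width", "soma_radius", "shaft_amp", "soma_amp",
              "actinin_baseline"))
    if (!is_scalar_num(p[[f]]) || p[[f]] <= 0) stopf("%s must be positive", f)
  if (!is.null(p$actinin_coupling) &&
      (!is_scalar_num(p$actinin_coupling) ||
       p$actinin_coupling < 0 || p$actinin_coupling > 1))
    stopf("actinin_coupling must be NULL or in [0, 1]")
  # density guard: fraction of the field covered by punctum footprints
  foot <- pi * (2 * p$spot_sigma)^2
  dens <- p$n_spines * foot / prod(p$image_shape)
  if (dens > 0.7)
    stopf("punctum density %.2f exceeds the hard cap 0.7; enlarge the field or reduce n_spines", dens)
  if (dens > 0.3)
    warnf("punctum density %.2f is high; expect heavy overlap", dens)
  invisible(p)
}

#' Lateralized-effect specification
#'
#' Describes the planted hemispheric asymmetry of a simulated animal: on the
#' effect side, `n_extra_bright` spines per image have their CapZ factor
#' multiplied by `bright_gain`. The default mode converts existing spines
#' rather than adding new ones, so the phalloidin-defined spine count stays
#' balanced between hemispheres (as observed in vivo).
#'
#' @param n_extra_bright number of spines per effect-side image made bright.
#' @param bright_gain multiplicative factor (>= 1) applied to their CapZ
#'   factor.
#' @param side hemisphere receiving the effect, `"contra"` by default (the
#'   cortex contralateral to a unilateral stimulus).
#' @param mode `"convert"` (default) re-draws no positions and multiplies
#'   existing spines' CapZ factors; `"add"` plants that many additional
#'   bright spines instead.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(n_extra_bright = 50L, bright_gain = 3,
                        side = c("contra", "ipsi"),
                        mode = c("convert", "add")) {
  side <- match.arg(side)
  mode <- match.arg(mode)
  if (!is_count(n_extra_bright)) stopf("n_extra_bright must be a nonnegative count")
  if (!is_scalar_num(bright_gain) || bright_gain < 1)
    stopf("bright_gain must be >= 1")
  structure(list(n_extra_bright = as.integer(n_extra_bright),
                 bright_gain = bright_gain, side = side, mode = mode),
            class = "effect_spec")
}

#' ROI-detection parameters
#'
#' Controls the watershed spot caller. Seeds are local maxima of the 3x3
#' Gaussian-smoothed red channel above the `seed_percentile` of that image;
#' watershed segments whose area falls outside
#' `[min_segment_area, max_segment_area]` are discarded, which is what
#' rejects somata and main dendritic shafts (too large) and single-pixel
#' noise specks (too small).
#'
#' @param seed_percentile percentile (0-100, exclusive) of the smoothed red
#'   image used as the seeding/flooding threshold.
#' @param min_segment_area,max_segment_area retained segment area band,
#'   pixels.
#' @param border_margin ROIs whose 13-pixel mask would cross the image
#'   border are dropped; 2 px for the 5-pixel-diameter mask.
#' @param merge_tolerance watershed merge tolerance as a fraction of the
#'   seeding threshold: adjacent basins whose maxima rise less than
#'   `merge_tolerance * threshold` above the separating ridge are merged,
#'   which keeps detector noise from splitting a punctum or a shaft.
#'   Relative to the threshold so that segmentation is invariant under a
#'   uniform intensity rescaling.
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(seed_percentile = 90,
                             min_segment_area = 3L,
                             max_segment_area = 200L,
                             border_margin = 2L,
                             merge_tolerance = 0.4) {
  if (!is_scalar_num(seed_percentile) || seed_percentile <= 0 || seed_percentile >= 100)
    stopf("seed_percentile must lie strictly between 0 and 100")
  if (!is_count(min_segment_area) || !is_count(max_segment_area) ||
      min_segment_area <= 0 || min_segment_area >= max_segment_area)
    stopf("need 0 < min_segment_area < max_segment_area")
  if (!is_count(border_margin)) stopf("border_margin must be a count")
  if (!is_scalar_num(merge_tolerance) || merge_tolerance < 0)
    stopf("merge_tolerance must be nonnegative")
  structure(list(seed_percentile = seed_percentile,
                 min_segment_area = as.integer(min_segment_area),
                 max_segment_area = as.integer(max_segment_area),
                 border_margin = as.integer(border_margin),
                 merge_tolerance = merge_tolerance),
            class = "detection_params")
}
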