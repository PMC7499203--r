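# Synthetic confocal field generator.
#
# A field is rendered in three layers: (1) a flat background pedestal, the
# image mode; (2) "signal" — Gaussian spine puncta plus distractor
# structures (shafts, somata), which is the part attenuated by depth in a
# focal series; (3) noise — optional Poisson shot noise on the full
# expectation plus Gaussian read noise, quantized to integer DN.

# Relative brightness of shaft/soma structures in the non-red channels.
GREEN_STRUCT_FACTOR <- 0.6
ACTININ_STRUCT_FACTOR <- 0.5
# Hard-core spine placement: minimum center separation and clearance
# from structure masks, pixels (~0.4-0.5 um at the default pixel size).
SPINE_MIN_SEPARATION <- 4
SPINE_STRUCT_CLEARANCE <- 4L

# Draw the per-field ground truth (spine positions, amplitudes, CapZ
# factors, structure masks). Spines are planted in the neuropil, i.e.
# off the shaft/soma masks (rejection sampling): the structures model
# the bright somata and main dendritic branches that segmentation must
# exclude, not spine carriers. Consumes RNG; callers wrap in
# with_seed().
draw_truth <- function(params) {
  nr <- params$image_shape[1]; nc <- params$image_shape[2]
  n <- params$n_spines
  m <- max(2L, as.integer(ceiling(4 * params$spot_sigma)))
  if (n > 0L && (nr - 2 * m < 1L || nc - 2 * m < 1L))
    stopf("image_shape too small for spots of sigma %.2f", params$spot_sigma)

  shaft <- matrix(FALSE, nr, nc)
  if (params$n_shafts > 0) {
    rr <- matrix(rep(seq_len(nr), nc), nr, nc)
    cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    for (i in seq_len(params$n_shafts)) {
      r0 <- stats::runif(1, 1, nr); c0 <- stats::runif(1, 1, nc)
      th <- stats::runif(1, 0, pi)
      d <- abs(sin(th) * (rr - r0) - cos(th) * (cc - c0))
      shaft <- shaft | (d <= params$shaft_width / 2)
    }
  }
  soma <- matrix(FALSE, nr, nc)
  if (params$n_somata > 0) {
    rad <- params$soma_radius
    rr <- matrix(rep(seq_len(nr), nc), nr, nc)
    cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    for (i in seq_len(params$n_somata)) {
      r0 <- stats::runif(1, rad + 1, nr - rad)
      c0 <- stats::runif(1, rad + 1, nc - rad)
      soma <- soma | ((rr - r0)^2 + (cc - c0)^2 <= rad^2)
    }
  }
  # Spine heads are ~0.5 um objects: place them as a hard-core process
  # (minimum center separation) clear of the structure masks plus a
  # margin, rather than pure Poisson darts.
  occupied <- shaft | soma
  if (any(occupied)) {
    brush <- EBImage::makeBrush(2L * SPINE_STRUCT_CLEARANCE + 1L, "disc")
    occupied <- EBImage::dilate(occupied, brush) > 0
  }
  rows <- cols <- integer(0)
  if (n > 0) {
    min_sep2 <- SPINE_MIN_SEPARATION^2
    rows <- integer(n); cols <- integer(n)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 200L * n
    while (placed < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      r <- sample(seq.int(m + 1L, nr - m), 1L)
      c <- sample(seq.int(m + 1L, nc - m), 1L)
      if (occupied[r, c]) next
      if (placed > 0L) {
        d2 <- (rows[seq_len(placed)] - r)^2 + (cols[seq_len(placed)] - c)^2
        if (min(d2) < min_sep2) next
      }
      placed <- placed + 1L
      rows[placed] <- r; cols[placed] <- c
    }
    if (placed < n)
      stopf("could only place %d of %d spines; field too crowded", placed, n)
  }
  amps <- if (n > 0) stats::rlnorm(n, log(params$red_amp_median),
                                   params$red_amp_sigma) else numeric(0)
  bright <- if (n > 0) stats::runif(n) < params$capz_p_bright else logical(0)
  med <- ifelse(bright, params$capz_bright_mean, params$capz_dim_mean)
  capz <- if (n > 0) stats::rlnorm(n, log(med), params$capz_spread) else numeric(0)
  structure(list(spine_centers = cbind(row = rows, col = cols),
                 red_amplitudes = amps, capz_factors = capz,
                 is_bright = bright, planted_extra_bright = 0L,
                 shaft_mask = shaft, soma_mask = soma),
            class = "ground_truth")
}

# Truncated-Gaussian punctum stamp: (2w+1)^2 profile, zero beyond 4 sigma.
spot_profile <- function(sigma) {
  w <- max(2L, as.integer(ceiling(4 * sigma)))
  d <- outer((-w:w)^2, (-w:w)^2, "+")
  p <- exp(-d / (2 * sigma^2))
  p[d > (4 * sigma)^2] <- 0
  list(w = w, p = p)
}

add_spots <- function(img, centers, amps, sigma) {
  if (nrow(centers) == 0L) return(img)
  sp <- spot_profile(sigma)
  w <- sp$w
  for (i in seq_len(nrow(centers))) {
    r <- centers[i, 1]; c <- centers[i, 2]
    img[(r - w):(r + w), (c - w):(c + w)] <-
      img[(r - w):(r + w), (c - w):(c + w)] + amps[i] * sp$p
  }
  img
}

# Detector model: the background pedestal is an electronic offset (no
# shot noise); Poisson shot noise applies to the photon signal only;
# Gaussian read noise applies to every pixel; quantization to integer DN
# in the 16-bit range whenever any noise is on.
apply_noise <- function(signal, params) {
  if (params$shot_noise) {
    lam <- pmax(signal, 0)
    signal <- matrix(stats::rpois(length(lam), lam), nrow(signal), ncol(signal))
  }
  img <- params$background_level + signal
  if (params$read_noise_sd > 0)
    img <- img + stats::rnorm(length(img), 0, params$read_noise_sd)
  q <- params$quantize
  if (is.na(q)) q <- params$shot_noise || params$read_noise_sd > 0
  if (isTRUE(q)) img <- pmin(pmax(round(img), 0), 65535)
  img
}

# Render one field from truth; `attenuation` scales signal (not pedestal).
render_field <- function(truth, params, attenuation = 1) {
  nr <- params$image_shape[1]; nc <- params$image_shape[2]
  zero <- matrix(0, nr, nc)
  struct_red <- params$shaft_amp * truth$shaft_mask +
    params$soma_amp * truth$soma_mask
  red_sig <- add_spots(zero + struct_red, truth$spine_centers,
                       truth$red_amplitudes, params$spot_sigma)
  green_sig <- add_spots(zero + GREEN_STRUCT_FACTOR * struct_red,
                         truth$spine_centers,
                         truth$red_amplitudes * truth$capz_factors,
                         params$spot_sigma)
  chans <- list(
    red = apply_noise(attenuation * red_sig, params),
    green = apply_noise(attenuation * green_sig, params))
  if (!is.null(params$actinin_coupling)) {
    # actinin scales with the spine's actin content (red amplitude);
    # the coupling term adds preferential accumulation in high-CapZ spines
    zmax <- if (length(truth$capz_factors)) max(truth$capz_factors) else 1
    z <- if (zmax > 0) truth$capz_factors / zmax else truth$capz_factors
    act_amp <- params$actinin_baseline * truth$red_amplitudes *
      (1 + params$actinin_coupling * z)
    act_sig <- add_spots(zero + ACTININ_STRUCT_FACTOR * struct_red,
                         truth$spine_centers, act_amp, params$spot_sigma)
    chans$actinin <- apply_noise(attenuation * act_sig, params)
  }
  chans
}

#' Generate one synthetic multi-channel field with ground truth
#'
#' Renders `n_spines` Gaussian puncta on the red channel (log-normal peak
#' amplitudes), a green channel whose per-punctum amplitude is the red
#' amplitude times a spine-specific CapZ factor drawn from a dim/bright
#' log-normal mixture, distractor shafts and somata present in both
#' channels, a flat background pedestal, and optional Poisson + read
#' noise. If `params$actinin_coupling` is non-NULL a third channel is
#' rendered whose per-spine amplitude increases with the CapZ factor.
#' Deterministic given `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @param hemisphere,animal_id,image_id labels stored on the image.
#' @return list with elements `image` (a [field_image]) and `truth`
#'   (spine centers, amplitudes, CapZ factors, bright flags, structure
#'   masks).
#' @export
generate_field <- function(params, hemisphere = NA_character_,
                           animal_id = NA_character_,
                           image_id = "field") {
  validate_sim_params(params)
  res <- with_seed(params$seed, {
    truth <- draw_truth(params)
    chans <- render_field(truth, params)
    list(truth = truth, chans = chans)
  })
  img <- field_image(res$chans, params$pixel_size, hemisphere = hemisphere,
                     animal_id = animal_id, image_id = image_id)
  list(image = img, truth = res$truth)
}

# Apply a lateralized effect to a drawn truth: promote n dim spines to
# bright (CapZ factor x gain), or plant that many additional bright spines.
apply_effect <- function(truth, params, effect) {
  n <- effect$n_extra_bright
  if (n == 0L) return(truth)
  if (effect$mode == "convert") {
    dim_idx <- which(!truth$is_bright)
    if (length(dim_idx) < n)
      stopf("cannot convert %d spines: only %d dim spines available", n,
            length(dim_idx))
    idx <- if (length(dim_idx) == 1L) dim_idx else sample(dim_idx, n)
    truth$capz_factors[idx] <- truth$capz_factors[idx] * effect$bright_gain
    truth$is_bright[idx] <- TRUE
  } else {
    nr <- params$image_shape[1]; nc <- params$image_shape[2]
    m <- max(2L, as.integer(ceiling(4 * params$spot_sigma)))
    rows <- sample(seq.int(m + 1L, nr - m), n, replace = TRUE)
    cols <- sample(seq.int(m + 1L, nc - m), n, replace = TRUE)
    amps <- stats::rlnorm(n, log(params$red_amp_median), params$red_amp_sigma)
    capz <- stats::rlnorm(n, log(params$capz_bright_mean),
                          params$capz_spread) * effect$bright_gain
    truth$spine_centers <- rbind(truth$spine_centers, cbind(row = rows, col = cols))
    truth$red_amplitudes <- c(truth$red_amplitudes, amps)
    truth$capz_factors <- c(truth$capz_factors, capz)
    truth$is_bright <- c(truth$is_bright, rep(TRUE, n))
  }
  truth$planted_extra_bright <- n
  truth
}

#' Generate the four images of one simulated animal
#'
#' Two independent fields per hemisphere from the same parameters, the
#' design used for the in-vivo comparisons (two images of layer IV per
#' side per animal). The hemisphere named by `effect$side` receives
#' `effect$n_extra_bright` extra high-CapZ spines per image; with
#' `n_extra_bright = 0` the two sides are draws from identical
#' distributions.
#'
#' @param params a [sim_params()]; `params$seed` seeds the whole animal.
#' @param effect an [effect_spec()].
#' @param animal_id,group labels propagated to the images.
#' @return list with `images` (list of four [field_image], image ids
#'   `<hemisphere>_1/2`), `truths` (matching ground truths), `animal_id`,
#'   `group`.
#' @export
generate_animal <- function(params, effect = effect_spec(0L),
                            animal_id = "A1", group = NA_character_) {
  validate_sim_params(params)
  stopifnot(inherits(effect, "effect_spec"))
  hemis <- c("contra", "contra", "ipsi", "ipsi")
  idx_in_hemi <- c(1L, 2L, 1L, 2L)
  images <- vector("list", 4L)
  truths <- vector("list", 4L)
  for (k in 1:4) {
    sk <- derive_seed(params$seed, k)
    res <- with_seed(sk, {
      truth <- draw_truth(params)
      if (hemis[k] == effect$side) truth <- apply_effect(truth, params, effect)
      chans <- render_field(truth, params)
      list(truth = truth, chans = chans)
    })
    iid <- sprintf("%s_%s_%d", animal_id, hemis[k], idx_in_hemi[k])
    images[[k]] <- field_image(res$chans, params$pixel_size,
                               hemisphere = hemis[k], animal_id = animal_id,
                               image_id = iid)
    truths[[k]] <- res$truth
  }
  structure(list(animal_id = animal_id, group = group,
                 images = images, truths = truths),
            class = "sim_animal")
}

#' Generate a focal-plane series of one field
#'
#' The same underlying field rendered `n_steps` times; at step k (0-based)
#' both signal channels are multiplied by `attenuation_per_step^k` (the
#' background pedestal, a detector offset, is not attenuated) and fresh
#' noise is drawn. Spine positions are identical across steps, so the
#' green/red ratio of a matched punctum is depth-invariant by
#' construction.
#'
#' @param params a [sim_params()].
#' @param n_steps number of focal steps (>= 2).
#' @param attenuation_per_step per-step signal attenuation in (0, 1].
#' @return list with `images` (one [field_image] per step, ids `step_k`)
#'   and `truth`.
#' @export
generate_focal_series <- function(params, n_steps = 6L,
                                  attenuation_per_step = 0.9) {
  validate_sim_params(params)
  if (!is_count(n_steps) || n_steps < 2) stopf("n_steps must be >= 2")
  if (!is_scalar_num(attenuation_per_step) ||
      attenuation_per_step <= 0 || attenuation_per_step > 1)
    stopf("attenuation_per_step must lie in (0, 1]")
  truth <- with_seed(params$seed, draw_truth(params))
  images <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    att <- attenuation_per_step^(k - 1)
    chans <- with_seed(derive_seed(params$seed, 100L + k),
                       render_field(truth, params, attenuation = att))
    images[[k]] <- field_image(chans, params$pixel_size,
                               image_id = sprintf("step_%d", k - 1L))
  }
  list(images = images, truth = truth)
}

#' Generate a slice-overview image with a high-gain sub-region
#'
#' Emulates the low-magnification slice regime used for the region-ratio
#' metric: three side-by-side square regions (high, neighbor, background).
#' The high and neighbor regions carry identical punctum layouts and
#' amplitude draws (the neighbor layout is the high layout translated),
#' except that green punctum amplitudes in the high region are multiplied
#' by `high_region_gain`; the background region is punctum-free, so its
#' mean is the pedestal. Four square measurement ROIs of side
#' `roi_side_um` are laid out inside the high region and, translated,
#' inside the neighbor region.
#'
#' @param params a [sim_params()]; `params$pixel_size` should be coarse
#'   enough that a `roi_side_um` square fits four times into
#'   `region_size` (e.g. 1 um/px for the defaults).
#' @param high_region_gain multiplicative green gain (>= 1) in the high
#'   region.
#' @param n_puncta puncta per region.
#' @param region_size side of each square region, pixels.
#' @param roi_side_um side of each measurement ROI, microns.
#' @param gap spacing between ROIs and region edges, pixels.
#' @return list with `image`, `high_rois` (list of four logical masks),
#'   `neighbor_mask`, `background_mask`, `truth`.
#' @export
generate_slice_image <- function(params, high_region_gain = 2,
                                 n_puncta = 150L, region_size = 100L,
                                 roi_side_um = 40, gap = 5L) {
  validate_sim_params(params)
  if (!is_scalar_num(high_region_gain) || high_region_gain < 1)
    stopf("high_region_gain must be >= 1")
  roi_px <- as.integer(round(roi_side_um / params$pixel_size))
  if (2L * roi_px + 3L * gap > region_size)
    stopf("four %d-px ROIs do not fit in a %d-px region: region outside image",
          roi_px, region_size)
  nr <- as.integer(region_size); nc <- 3L * nr
  m <- max(2L, as.integer(ceiling(4 * params$spot_sigma)))
  res <- with_seed(params$seed, {
    rows <- sample(seq.int(m + 1L, nr - m), n_puncta, replace = TRUE)
    cols <- sample(seq.int(m + 1L, nr - m), n_puncta, replace = TRUE)
    amps <- stats::rlnorm(n_puncta, log(params$red_amp_median),
                          params$red_amp_sigma)
    bright <- stats::runif(n_puncta) < params$capz_p_bright
    med <- ifelse(bright, params$capz_bright_mean, params$capz_dim_mean)
    capz <- stats::rlnorm(n_puncta, log(med), params$capz_spread)
    red <- matrix(0, nr, nc); green <- matrix(0, nr, nc)
    high_centers <- cbind(rows, cols)
    nb_centers <- cbind(rows, cols + nr)
    red <- add_spots(red, high_centers, amps, params$spot_sigma)
    red <- add_spots(red, nb_centers, amps, params$spot_sigma)
    green <- add_spots(green, high_centers, amps * capz * high_region_gain,
                       params$spot_sigma)
    green <- add_spots(green, nb_centers, amps * capz, params$spot_sigma)
    list(red = apply_noise(red, params),
         green = apply_noise(green, params),
         truth = list(rows = rows, cols = cols, red_amp = amps,
                      capz_factor = capz, gain = high_region_gain))
  })
  img <- field_image(list(red = res$red, green = res$green),
                     params$pixel_size, image_id = "slice")
  square <- function(r0, c0) {
    msk <- matrix(FALSE, nr, nc)
    msk[r0:(r0 + roi_px - 1L), c0:(c0 + roi_px - 1L)] <- TRUE
    msk
  }
  corners <- list(c(gap + 1L, gap + 1L),
                  c(gap + 1L, 2L * gap + roi_px + 1L),
                  c(2L * gap + roi_px + 1L, gap + 1L),
                  c(2L * gap + roi_px + 1L, 2L * gap + roi_px + 1L))
  high_rois <- lapply(corners, function(p) square(p[1], p[2]))
  nb_mask <- Reduce(`|`, lapply(corners, function(p) square(p[1], p[2] + nr)))
  bg_mask <- matrix(FALSE, nr, nc)
  bg_mask[(gap + 1L):(nr - gap), (2L * nr + gap + 1L):(nc - gap)] <- TRUE
  list(image = img, high_rois = high_rois, neighbor_mask = nb_mask,
       background_mask = bg_mask, truth = res$truth)
}
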