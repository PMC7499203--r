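# Table-level cohort simulation for Monte-Carlo calibration.
#
# These functions draw ROI measurements directly from the generative
# model the image renderer uses — the same log-normal red amplitudes,
# dim/bright CapZ mixture and noise model, with the 13-pixel ROI mean of
# a centered Gaussian punctum computed analytically — but skip pixel
# rendering and watershed detection. That makes thousand-cohort power
# and type-I-error calibrations of the downstream statistics tractable;
# detection fidelity is validated separately on rendered fields.

#' Analytic 13-pixel ROI gain of a centered Gaussian punctum
#'
#' Mean of `exp(-d^2 / (2 sigma^2))` over the 13 offsets of
#' [roi_mask_offsets()]: the factor relating a punctum's peak amplitude
#' to its measured ROI mean when the ROI is centered on it.
#'
#' @param sigma punctum Gaussian sigma, pixels.
#' @return scalar in (0, 1].
#' @export
psf_mask_gain <- function(sigma) {
  offs <- roi_mask_offsets()
  d2 <- offs[, 1]^2 + offs[, 2]^2
  mean(exp(-d2 / (2 * sigma^2)))
}

#' Simulate one ROI table from the measurement model
#'
#' Draws `n` spines (amplitudes, CapZ mixture, optional actinin
#' coupling) and returns their measured ROI means directly: signal =
#' peak amplitude x the analytic mask gain, plus ROI-mean noise with
#' variance `(background + signal + read_sd^2) / 13` when shot noise is
#' on (Poisson variance of the 13-pixel mean, to first order), or
#' `read_sd^2 / 13` otherwise. Backgrounds are attached exactly.
#' Consumes RNG; seed with [with_seed()]-style wrappers or
#' `params$seed` via the higher-level functions.
#'
#' @param n number of ROIs.
#' @param params a [sim_params()].
#' @param convert_n,convert_gain promote this many dim spines to bright
#'   by multiplying their CapZ factor by `convert_gain` (the planted
#'   lateralized effect).
#' @param image_id,hemisphere labels stored on the table.
#' @return a `roi_table` with backgrounds set; ground truth
#'   (`capz_factors`, `is_bright`) attached as attribute `truth`.
#' @export
simulate_roi_table <- function(n, params, convert_n = 0L, convert_gain = 1,
                               image_id = "sim", hemisphere = NA_character_) {
  g <- psf_mask_gain(params$spot_sigma)
  amps <- stats::rlnorm(n, log(params$red_amp_median), params$red_amp_sigma)
  bright <- stats::runif(n) < params$capz_p_bright
  med <- ifelse(bright, params$capz_bright_mean, params$capz_dim_mean)
  capz <- stats::rlnorm(n, log(med), params$capz_spread)
  if (convert_n > 0L) {
    dim_idx <- which(!bright)
    if (length(dim_idx) < convert_n)
      stopf("cannot convert %d spines: only %d dim", convert_n, length(dim_idx))
    idx <- if (length(dim_idx) == 1L) dim_idx else sample(dim_idx, convert_n)
    capz[idx] <- capz[idx] * convert_gain
    bright[idx] <- TRUE
  }
  bg <- params$background_level
  npx <- nrow(roi_mask_offsets())
  measure <- function(sig) {
    # ROI-mean noise: Poisson shot noise on the signal photons plus read
    # noise, both averaged over the 13 mask pixels (pedestal is an
    # offset and carries no shot noise)
    if (params$shot_noise)
      sd <- sqrt((sig + params$read_noise_sd^2) / npx)
    else sd <- rep(params$read_noise_sd / sqrt(npx), length(sig))
    noise <- if (any(sd > 0)) stats::rnorm(length(sig), 0, sd) else 0
    bg + sig + noise
  }
  tab <- data.frame(image_id = image_id, roi_id = seq_len(n),
                    row = NA_integer_, col = NA_integer_,
                    segment_id = seq_len(n),
                    mean_red = measure(amps * g),
                    mean_green = measure(amps * capz * g))
  bgv <- c(red = bg, green = bg)
  if (!is.null(params$actinin_coupling)) {
    z <- capz / max(capz)
    act <- params$actinin_baseline * amps * (1 + params$actinin_coupling * z)
    tab$mean_actinin <- measure(act * g)
    bgv <- c(bgv, actinin = bg)
  }
  tab$hemisphere <- hemisphere
  attr(tab, "hemisphere") <- hemisphere
  class(tab) <- c("roi_table", "data.frame")
  tab <- set_background(tab, bgv)
  attr(tab, "truth") <- list(capz_factors = capz, is_bright = bright,
                             red_amplitudes = amps)
  tab
}

#' Simulate one animal's records at the measurement-model level
#'
#' Four ROI tables (two per hemisphere) drawn with
#' [simulate_roi_table()]; the `effect$side` tables receive the planted
#' bright-spine conversion. Records are c-intensity-computed and
#' cn-normalized exactly as in the image pipeline.
#'
#' @param params a [sim_params()]; `params$seed` seeds the animal.
#' @param effect an [effect_spec()].
#' @param animal_id,group labels.
#' @return a cn-normalized [animal_record()].
#' @export
simulate_animal_records <- function(params, effect = effect_spec(0L),
                                    animal_id = "A1",
                                    group = NA_character_) {
  hemis <- c("contra", "contra", "ipsi", "ipsi")
  idx <- c(1L, 2L, 1L, 2L)
  recs <- vector("list", 4L)
  for (k in 1:4) {
    eff_here <- hemis[k] == effect$side
    tab <- with_seed(derive_seed(params$seed, k),
                     simulate_roi_table(
                       params$n_spines, params,
                       convert_n = if (eff_here) effect$n_extra_bright else 0L,
                       convert_gain = effect$bright_gain,
                       image_id = sprintf("%s_%s_%d", animal_id, hemis[k], idx[k]),
                       hemisphere = hemis[k]))
    r <- c_intensity(tab)
    if ("mean_actinin" %in% names(r)) r <- actinin_c_intensity(r)
    recs[[k]] <- r
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  cn_normalize(animal_record(records, animal_id, group))
}

#' Simulate a cohort of animals
#'
#' @param params a [sim_params()]; per-animal seeds are derived from
#'   `seed`.
#' @param effect an [effect_spec()] applied to every animal.
#' @param n_animals cohort size (default 8, the in-vivo group size).
#' @param seed cohort seed (defaults to `params$seed`).
#' @param group label.
#' @return list of [animal_record()]s (class `cohort`).
#' @export
simulate_cohort <- function(params, effect = effect_spec(0L),
                            n_animals = 8L, seed = params$seed,
                            group = NA_character_) {
  animals <- lapply(seq_len(n_animals), function(a) {
    p <- params
    p$seed <- derive_seed(seed, a)
    simulate_animal_records(p, effect, animal_id = sprintf("A%d", a),
                            group = group)
  })
  class(animals) <- c("cohort", "list")
  animals
}

#' Paired lateralization test on a cohort
#'
#' Per animal, the integrated top-`n` cn-intensity of each hemisphere
#' ([top_n_sum()]); contra vs ipsi compared with a two-sided paired
#' t-test, plus per-animal contra/ipsi ratios.
#'
#' @param cohort list of cn-normalized [animal_record()]s.
#' @param n top-N size (default 100).
#' @param value column to integrate (`"cn"` or `"gn"`).
#' @return list: `p_value`, `statistic`, `mean_ratio`, `summaries`
#'   (per-animal data.frame with contra, ipsi, ratio).
#' @export
cohort_test <- function(cohort, n = 100L, value = "cn") {
  rows <- lapply(cohort, function(a) {
    s <- top_n_sum(a, n = n, value = value)
    data.frame(animal_id = a$animal_id,
               contra = s$integrated_cn[s$hemisphere == "contra"],
               ipsi = s$integrated_cn[s$hemisphere == "ipsi"])
  })
  df <- do.call(rbind, rows)
  df$ratio <- df$contra / df$ipsi
  tt <- stats::t.test(df$contra, df$ipsi, paired = TRUE)
  list(p_value = unname(tt$p.value), statistic = unname(tt$statistic),
       mean_ratio = mean(df$ratio), summaries = df)
}

#' Compare contra/ipsi ratios between two cohorts
#'
#' Unpaired two-sided Student's t-test on the per-animal top-N
#' contra/ipsi ratios of two groups (e.g. stimulated vs control).
#'
#' @param cohort_a,cohort_b cohorts from [simulate_cohort()] or built
#'   from [process_animal()] records.
#' @param n top-N size.
#' @return `htest` object.
#' @export
compare_cohort_ratios <- function(cohort_a, cohort_b, n = 100L) {
  ra <- cohort_test(cohort_a, n = n)$summaries$ratio
  rb <- cohort_test(cohort_b, n = n)$summaries$ratio
  stats::t.test(ra, rb, var.equal = TRUE)
}
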