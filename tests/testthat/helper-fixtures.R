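# Shared fixtures for the test suite. Everything is generated in code.

# A minimal two-channel field from explicit matrices.
make_field <- function(red, green = red, actinin = NULL, pixel_size = 0.103,
                       hemisphere = NA_character_, image_id = "fix") {
  ch <- list(red = red, green = green)
  if (!is.null(actinin)) ch$actinin <- actinin
  field_image(ch, pixel_size, hemisphere = hemisphere, image_id = image_id)
}

# Noiseless simulation parameters (continuous DN, no quantization).
noiseless_params <- function(...) {
  sim_params(shot_noise = FALSE, read_noise_sd = 0, ...)
}

# An animal_record built directly from given c values.
record_from_c <- function(c_values, hemisphere = "contra",
                          image_id = "im1", animal_id = "A1") {
  recs <- data.frame(image_id = image_id,
                     roi_id = seq_along(c_values),
                     hemisphere = hemisphere, c = c_values)
  animal_record(recs, animal_id)
}

# Match ground-truth centers to ROI centers; returns recovery metrics.
match_metrics <- function(truth, tab, radius = 2) {
  d2 <- outer(truth$spine_centers[, 1], tab$row, "-")^2 +
    outer(truth$spine_centers[, 2], tab$col, "-")^2
  in_struct <- truth$shaft_mask[cbind(tab$row, tab$col)] |
    truth$soma_mask[cbind(tab$row, tab$col)]
  list(recovery = mean(apply(d2, 1, min) <= radius^2),
       false_rate = mean(apply(d2, 2, min) > radius^2),
       in_structure = mean(in_struct),
       n_roi = nrow(tab))
}

# Brute-force 8-neighbour local-maximum detector (independent oracle for
# the watershed + ROI placement path on well-separated spots).
brute_local_maxima <- function(img, threshold) {
  nr <- nrow(img); nc <- ncol(img)
  out <- NULL
  for (r in 2:(nr - 1)) for (c in 2:(nc - 1)) {
    v <- img[r, c]
    if (v <= threshold) next
    nb <- img[(r - 1):(r + 1), (c - 1):(c + 1)]
    if (v > max(nb[-5])) out <- rbind(out, c(r, c))
  }
  out
}
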