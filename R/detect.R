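# ROI detection on the phalloidin channel: 3x3 Gaussian smoothing,
# marker-controlled watershed segmentation, fixed 5-pixel round ROIs at
# per-segment maxima, and mode-based background estimation. Intensities
# are always measured on the RAW channels; smoothing is used only to
# define geometry.

#' 3x3 Gaussian smoothing
#'
#' Convolution with the separable 3x3 binomial Gaussian kernel
#' `[1 2 1; 2 4 2; 1 2 1]/16` (weights sum to 1) with reflective border
#' handling, the pre-filter applied to the phalloidin channel before
#' watershed segmentation.
#'
#' @param image numeric matrix.
#' @return matrix of the same shape.
#' @export
smooth_gauss3 <- function(image) {
  if (!is.matrix(image) || length(image) == 0L) stopf("image must be a non-empty matrix")
  nr <- nrow(image); nc <- ncol(image)
  # reflective padding by one pixel
  ri <- c(1L, seq_len(nr), nr)
  ci <- c(1L, seq_len(nc), nc)
  p <- image[ri, ci, drop = FALSE]
  k <- c(1, 2, 1) / 4
  # horizontal then vertical pass on the padded matrix
  h <- k[1] * p[, 1:nc, drop = FALSE] + k[2] * p[, 2:(nc + 1), drop = FALSE] +
    k[3] * p[, 3:(nc + 2), drop = FALSE]
  k[1] * h[1:nr, , drop = FALSE] + k[2] * h[2:(nr + 1), , drop = FALSE] +
    k[3] * h[3:(nr + 2), , drop = FALSE]
}

#' Pixel offsets of the 5-pixel-diameter round ROI
#'
#' All integer offsets `(dr, dc)` with `dr^2 + dc^2 <= 4`, i.e. within
#' Euclidean distance 2 of the center: exactly 13 pixels, the fixed
#' spine-sized ROI (0.515 um across at 0.103 um/px).
#'
#' @return integer matrix with columns `dr`, `dc` (13 rows), ordered
#'   row-major.
#' @export
roi_mask_offsets <- function() {
  g <- expand.grid(dc = -2:2, dr = -2:2)
  g <- g[g$dr^2 + g$dc^2 <= 4, ]
  cbind(dr = as.integer(g$dr), dc = as.integer(g$dc))
}

#' Modal pixel value of an image channel
#'
#' The most frequent integer DN value; real-valued input is binned at
#' width 1 DN (rounded to nearest integer). Ties resolve to the smallest
#' modal value.
#'
#' @param image numeric matrix.
#' @return scalar mode (integer-valued).
#' @export
image_mode <- function(image) {
  v <- round(as.numeric(image))
  lo <- min(v)
  counts <- tabulate(v - lo + 1L)
  lo + which.max(counts) - 1L   # which.max takes the first (smallest) tie
}

#' Watershed segmentation of the smoothed phalloidin channel
#'
#' Marker-controlled watershed on the smoothed red channel: pixels below
#' the `seed_percentile` of the image are background; each remaining
#' local maximum floods its own catchment basin (basins shallower than
#' `merge_tolerance` times the threshold are merged into their
#' neighbor). Segments whose
#' area falls outside `[min_segment_area, max_segment_area]` are
#' relabeled 0 — this is what rejects somata and main dendritic shafts
#' (too large) and noise specks (too small).
#'
#' @param smoothed_red output of [smooth_gauss3()] on the red channel.
#' @param params a [detection_params()].
#' @return integer label matrix, 0 = unsegmented; retained labels are
#'   renumbered 1..K.
#' @export
segment_watershed <- function(smoothed_red, params = detection_params()) {
  stopifnot(is.matrix(smoothed_red))
  thr <- stats::quantile(smoothed_red, params$seed_percentile / 100,
                         names = FALSE, type = 7)
  rel <- smoothed_red - thr
  rel[rel < 0] <- 0
  if (all(rel == 0)) {
    warnf("no maxima above the %.6g seeding threshold; empty label map", thr)
    return(matrix(0L, nrow(smoothed_red), ncol(smoothed_red)))
  }
  lab <- EBImage::watershed(rel, tolerance = params$merge_tolerance * max(thr, 0),
                            ext = 1)
  lab <- matrix(as.integer(lab), nrow(smoothed_red), ncol(smoothed_red))
  if (max(lab) == 0L) return(lab)
  area <- tabulate(lab)
  keep <- which(area >= params$min_segment_area &
                  area <= params$max_segment_area)
  remap <- integer(length(area))
  remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

#' Place fixed 5-pixel round ROIs at segment maxima and measure raw means
#'
#' For each retained watershed segment the ROI center is the pixel of
#' maximum smoothed red intensity inside the segment (ties: smallest row,
#' then smallest column); the ROI is the 13-pixel disc of
#' [roi_mask_offsets()] around it. ROIs whose mask would cross the image
#' border are dropped. Per-channel means are taken over the RAW pixel
#' values — no filtering enters the measurement.
#'
#' @param labels label matrix from [segment_watershed()].
#' @param smoothed_red the smoothed red channel the labels came from.
#' @param image the [field_image] holding the raw channels.
#' @param params a [detection_params()] (border margin).
#' @return a `roi_table`: data.frame with columns `image_id`, `roi_id`,
#'   `row`, `col`, `segment_id`, and `mean_<channel>` per channel
#'   (1-based pixel coordinates); detection parameters attached as
#'   attribute `detection_params`.
#' @export
place_rois <- function(labels, smoothed_red, image,
                       params = detection_params()) {
  stopifnot(inherits(image, "field_image"))
  if (!identical(dim(labels), dim(image$channels$red)))
    stopf("label map and image shapes differ")
  nr <- nrow(labels); nc <- ncol(labels)
  idx <- which(labels > 0L)
  if (length(idx) == 0L) return(empty_roi_table(image, params))
  lab <- labels[idx]
  val <- smoothed_red[idx]
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  o <- order(lab, -val, rows, cols)
  first <- !duplicated(lab[o])
  sel <- o[first]
  cen_r <- rows[sel]; cen_c <- cols[sel]; seg <- lab[sel]
  # drop ROIs whose 13-px mask would cross the border
  bm <- max(2L, params$border_margin)
  ok <- cen_r > bm & cen_r <= nr - bm & cen_c > bm & cen_c <= nc - bm
  cen_r <- cen_r[ok]; cen_c <- cen_c[ok]; seg <- seg[ok]
  if (length(cen_r) == 0L) return(empty_roi_table(image, params))
  offs <- roi_mask_offsets()
  tab <- data.frame(image_id = image$image_id,
                    roi_id = seq_along(cen_r),
                    row = cen_r, col = cen_c, segment_id = seg)
  for (ch in names(image$channels)) {
    raw <- image$channels[[ch]]
    acc <- numeric(length(cen_r))
    for (j in seq_len(nrow(offs)))
      acc <- acc + raw[cbind(cen_r + offs[j, 1], cen_c + offs[j, 2])]
    tab[[paste0("mean_", ch)]] <- acc / nrow(offs)
  }
  attr(tab, "detection_params") <- params
  attr(tab, "hemisphere") <- image$hemisphere
  attr(tab, "animal_id") <- image$animal_id
  class(tab) <- c("roi_table", "data.frame")
  tab
}

empty_roi_table <- function(image, params) {
  tab <- data.frame(image_id = character(0), roi_id = integer(0),
                    row = integer(0), col = integer(0),
                    segment_id = integer(0))
  for (ch in names(image$channels)) tab[[paste0("mean_", ch)]] <- numeric(0)
  attr(tab, "detection_params") <- params
  attr(tab, "hemisphere") <- image$hemisphere
  attr(tab, "animal_id") <- image$animal_id
  class(tab) <- c("roi_table", "data.frame")
  tab
}

#' Detect ROIs on one field image
#'
#' Convenience wrapper: smooth the red channel, watershed-segment it, and
#' place measured ROIs. Background is not set here — see
#' [estimate_background()] and [set_background()], which need the paired
#' hemisphere image.
#'
#' @param image a [field_image].
#' @param params a [detection_params()].
#' @return a `roi_table` (see [place_rois()]).
#' @export
detect_rois <- function(image, params = detection_params()) {
  sm <- smooth_gauss3(image$channels$red)
  lab <- segment_watershed(sm, params)
  place_rois(lab, sm, image, params)
}

#' Measure the fixed 13-pixel ROIs at given centers
#'
#' Re-measures raw per-channel ROI means at externally supplied centers
#' (no detection). Used for focal-series stability, where the ROIs found
#' on the reference plane are re-measured at every depth: re-detecting
#' per plane would add a max-selection bias that varies with depth.
#' Centers whose mask would cross the border are dropped.
#'
#' @param image a [field_image].
#' @param centers two-column matrix (row, col) of ROI centers.
#' @param params a [detection_params()] (border margin).
#' @return a `roi_table`; `roi_id` indexes rows of `centers` so tables
#'   measured at the same centers align.
#' @export
measure_rois_at <- function(image, centers, params = detection_params()) {
  stopifnot(inherits(image, "field_image"))
  centers <- matrix(as.integer(centers), ncol = 2)
  nr <- nrow(image$channels$red); nc <- ncol(image$channels$red)
  bm <- max(2L, params$border_margin)
  ok <- centers[, 1] > bm & centers[, 1] <= nr - bm &
    centers[, 2] > bm & centers[, 2] <= nc - bm
  cen_r <- centers[ok, 1]; cen_c <- centers[ok, 2]
  offs <- roi_mask_offsets()
  tab <- data.frame(image_id = image$image_id,
                    roi_id = which(ok),
                    row = cen_r, col = cen_c,
                    segment_id = NA_integer_)
  for (ch in names(image$channels)) {
    raw <- image$channels[[ch]]
    acc <- numeric(length(cen_r))
    for (j in seq_len(nrow(offs)))
      acc <- acc + raw[cbind(cen_r + offs[j, 1], cen_c + offs[j, 2])]
    tab[[paste0("mean_", ch)]] <- acc / nrow(offs)
  }
  attr(tab, "detection_params") <- params
  attr(tab, "hemisphere") <- image$hemisphere
  attr(tab, "animal_id") <- image$animal_id
  class(tab) <- c("roi_table", "data.frame")
  tab
}

#' Mode-based background from a hemisphere pair
#'
#' The background value of a channel is the lesser of the two modal pixel
#' values of the paired left/right (or contra/ipsi) hemisphere images —
#' the pedestal common to the pair, robust to the minority of signal
#' pixels.
#'
#' @param left_image,right_image the two paired [field_image]s.
#' @param role channel name (`"red"`, `"green"`, `"actinin"`).
#' @return scalar background DN.
#' @export
estimate_background <- function(left_image, right_image, role) {
  for (im in list(left_image, right_image))
    if (is.null(im$channels[[role]]))
      stopf("channel '%s' missing from image %s", role, im$image_id)
  min(image_mode(left_image$channels[[role]]),
      image_mode(right_image$channels[[role]]))
}

#' Attach per-channel background values to an ROI table
#'
#' @param table a `roi_table`.
#' @param background named numeric vector, one nonnegative value per
#'   measured channel (e.g. `c(red = 100, green = 100)`).
#' @return the table with attribute `background` set and `bg_<channel>`
#'   columns added.
#' @export
set_background <- function(table, background) {
  chans <- sub("^mean_", "", grep("^mean_", names(table), value = TRUE))
  missing <- setdiff(chans, names(background))
  if (length(missing))
    stopf("background missing for channel(s): %s", paste(missing, collapse = ", "))
  if (any(background < 0)) stopf("background values must be >= 0")
  for (ch in chans) table[[paste0("bg_", ch)]] <- unname(background[[ch]])
  attr(table, "background") <- background[chans]
  table
}

#' Write an ROI table to CSV
#'
#' @param table a `roi_table` (background columns included if set).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roi_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
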