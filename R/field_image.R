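#' Multi-channel field image
#'
#' Container for one acquired or simulated 2D confocal plane: a named list
#' of channel matrices (`red` = phalloidin spine marker, `green` =
#' EGFP-CapZ, optional `actinin` immunolabel), plus pixel size and
#' hemisphere/animal/image labels. All channels must share one shape.
#' Matrices are indexed `[row, col]`, 1-based.
#'
#' @param channels named list of numeric matrices; `red` and `green`
#'   required, `actinin` optional.
#' @param pixel_size microns per pixel (> 0).
#' @param hemisphere `"contra"`, `"ipsi"`, `"left"`, `"right"` or NA.
#' @param animal_id,image_id identifiers (character or NA).
#' @return an object of class `field_image`.
#' @export
field_image <- function(channels, pixel_size,
                        hemisphere = NA_character_,
                        animal_id = NA_character_,
                        image_id = NA_character_) {
  if (!is.list(channels) || is.null(names(channels)))
    stopf("channels must be a named list of matrices")
  if (!all(c("red", "green") %in% names(channels)))
    stopf("channels must include 'red' and 'green'")
  shapes <- lapply(channels, dim)
  if (any(!vapply(channels, is.matrix, logical(1))))
    stopf("every channel must be a matrix")
  if (length(unique(lapply(shapes, identity))) != 1L)
    stopf("all channels must share the same shape")
  if (!is_scalar_num(pixel_size) || pixel_size <= 0)
    stopf("pixel_size must be positive")
  if (!is.na(hemisphere) &&
      !hemisphere %in% c("contra", "ipsi", "left", "right"))
    stopf("hemisphere must be contra/ipsi/left/right or NA")
  structure(list(channels = channels, pixel_size = pixel_size,
                 hemisphere = hemisphere,
                 animal_id = as.character(animal_id),
                 image_id = as.character(image_id)),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels$red)
  cat(sprintf("<field_image> %d x %d px (%.3f um/px), channels: %s\n",
              d[1], d[2], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  animal=%s image=%s hemisphere=%s\n",
              x$animal_id, x$image_id, x$hemisphere))
  invisible(x)
}

#' Write a field image as a multi-page TIFF with a YAML sidecar
#'
#' One 16-bit page per channel in the order red, green, `[actinin]`; the
#' sidecar (`<path>.yaml`) records the channel order, pixel size and
#' labels so the image can be read back without guessing.
#'
#' @param image a [field_image].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(image, path) {
  stopifnot(inherits(image, "field_image"))
  pages <- lapply(image$channels, function(ch) {
    m <- pmin(pmax(ch, 0), 65535) / 65535
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(channels = names(image$channels),
               pixel_size = image$pixel_size,
               hemisphere = image$hemisphere,
               animal_id = image$animal_id,
               image_id = image$image_id,
               scale = 65535)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a field image written by [write_field_tiff()]
#'
#' @param path TIFF path; `<path>.yaml` must exist alongside it unless
#'   `channels` and `pixel_size` are supplied.
#' @param channels optional character vector naming the pages in order.
#' @param pixel_size optional microns per pixel.
#' @return a [field_image].
#' @export
read_field_tiff <- function(path, channels = NULL, pixel_size = NULL) {
  sidecar <- paste0(path, ".yaml")
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()
  channels <- channels %||% meta$channels
  pixel_size <- pixel_size %||% meta$pixel_size
  if (is.null(channels) || is.null(pixel_size))
    stopf("no sidecar metadata found for %s; supply channels and pixel_size", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(channels))
    stopf("%s has %d pages but %d channel names", path,
          length(pages), length(channels))
  scale <- meta$scale %||% 65535
  chans <- lapply(pages, function(p) round(p * scale))
  names(chans) <- channels
  field_image(chans, pixel_size,
              hemisphere = meta$hemisphere %||% NA_character_,
              animal_id = meta$animal_id %||% NA_character_,
              image_id = meta$image_id %||% NA_character_)
}

#' Write a ground-truth table as CSV
#'
#' Columns: spine id, row, col, red amplitude, CapZ factor, bright flag.
#'
#' @param truth a ground-truth object from [generate_field()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(truth, path) {
  df <- data.frame(spine_id = seq_along(truth$red_amplitudes),
                   row = truth$spine_centers[, 1],
                   col = truth$spine_centers[, 2],
                   red_amp = truth$red_amplitudes,
                   capz_factor = truth$capz_factors,
                   is_bright = truth$is_bright)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
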