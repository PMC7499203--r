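# Ratiometric quantification: c-intensity (background-subtracted
# green/red per ROI), per-animal cn-normalization, histograms,
# difference-ratio curves, top-N integrals, contra/ipsi ratios,
# focal-plane stability, and the slice region ratio.

#' Corrected (c-)intensity per ROI
#'
#' The per-ROI ratio `(mean_green - bg_green) / (mean_red - bg_red)`.
#' Dividing EGFP-CapZ by phalloidin corrects for spine size and focal
#' depth: a uniform attenuation of both channels cancels. ROIs whose
#' background-subtracted red denominator is not positive are excluded;
#' their number is recorded in attribute `n_excluded`. The uncorrected
#' background-subtracted green value is kept alongside (`green_corr`) to
#' support the no-phalloidin-correction variant.
#'
#' @param table a `roi_table` with backgrounds set
#'   (see [set_background()]).
#' @return the table rows that survive exclusion, with columns `c` and
#'   `green_corr` appended and a `hemisphere` column taken from the
#'   table's provenance.
#' @export
c_intensity <- function(table) {
  need <- c("mean_red", "mean_green", "bg_red", "bg_green")
  if (!all(need %in% names(table)))
    stopf("table needs measured means and backgrounds (call set_background first)")
  den <- table$mean_red - table$bg_red
  keep <- den > 0
  if (!any(keep))
    stopf("all %d ROIs excluded in image %s: no positive red denominator",
          nrow(table), table$image_id[1] %||% "?")
  out <- table[keep, , drop = FALSE]
  out$c <- (out$mean_green - out$bg_green) / (out$mean_red - out$bg_red)
  out$green_corr <- out$mean_green - out$bg_green
  if (is.null(out$hemisphere))
    out$hemisphere <- attr(table, "hemisphere") %||% NA_character_
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Assemble an animal record from per-image c-intensity records
#'
#' @param records data.frame with at least `image_id`, `roi_id`,
#'   `hemisphere`, `c` (rbind of [c_intensity()] outputs over the
#'   animal's images).
#' @param animal_id,group labels.
#' @return an object of class `animal_record`.
#' @export
animal_record <- function(records, animal_id, group = NA_character_) {
  need <- c("image_id", "roi_id", "hemisphere", "c")
  if (!all(need %in% names(records)))
    stopf("records must have columns %s", paste(need, collapse = ", "))
  structure(list(animal_id = animal_id, group = group,
                 records = as.data.frame(records),
                 normalization_max = NA_real_),
            class = "animal_record")
}

#' @export
print.animal_record <- function(x, ...) {
  cat(sprintf("<animal_record> %s (group %s): %d ROIs over %d images; max c = %s\n",
              x$animal_id, x$group, nrow(x$records),
              length(unique(x$records$image_id)),
              format(x$normalization_max)))
  invisible(x)
}

#' Per-animal cn-normalization
#'
#' Each c-intensity is expressed as a percentage of the single maximum
#' c-intensity across all of the animal's images (both hemispheres), so
#' the maximum-bearing ROI gets exactly 100 and values are comparable
#' across animals. Also normalizes `green_corr` the same way
#' (`gn` column) when present.
#'
#' @param animal an [animal_record()].
#' @return the record with `cn` added and `normalization_max` set.
#' @export
cn_normalize <- function(animal) {
  stopifnot(inherits(animal, "animal_record"))
  if (nrow(animal$records) == 0L) stopf("animal %s has no ROIs", animal$animal_id)
  mx <- max(animal$records$c)
  if (!is.finite(mx) || mx <= 0)
    stopf("normalization maximum must be positive (animal %s)", animal$animal_id)
  animal$records$cn <- 100 * animal$records$c / mx
  if (!is.null(animal$records$green_corr)) {
    gmx <- max(animal$records$green_corr)
    if (gmx > 0) animal$records$gn <- 100 * animal$records$green_corr / gmx
  }
  animal$normalization_max <- mx
  animal
}

#' Run the full per-animal pipeline on four field images
#'
#' Detects ROIs on each image, estimates per-channel backgrounds from
#' hemisphere pairs (images are paired across hemispheres by acquisition
#' index; the lesser of the two modes is used for both images of a
#' pair), computes c-intensities (and actinin c-intensities when a third
#' channel is present), and cn-normalizes within the animal.
#'
#' @param images list of [field_image]s with `hemisphere` labels, two
#'   per hemisphere.
#' @param params a [detection_params()].
#' @param animal_id,group labels; `animal_id` defaults to the images'.
#' @return a cn-normalized [animal_record()]; the per-image `roi_table`s
#'   are attached as attribute `tables`.
#' @export
process_animal <- function(images, params = detection_params(),
                           animal_id = NULL, group = NA_character_) {
  hemi <- vapply(images, function(im) im$hemisphere, character(1))
  sides <- unique(hemi)
  if (length(sides) != 2L)
    stopf("need images from exactly two hemispheres, got: %s",
          paste(sides, collapse = ", "))
  animal_id <- animal_id %||% images[[1]]$animal_id
  tables <- lapply(images, detect_rois, params = params)
  chans <- names(images[[1]]$channels)
  a <- which(hemi == sides[1]); b <- which(hemi == sides[2])
  if (length(a) != length(b))
    stopf("hemispheres have unequal image counts (%d vs %d)", length(a), length(b))
  for (j in seq_along(a)) {
    bg <- vapply(chans, function(ch)
      estimate_background(images[[a[j]]], images[[b[j]]], ch), numeric(1))
    names(bg) <- chans
    tables[[a[j]]] <- set_background(tables[[a[j]]], bg)
    tables[[b[j]]] <- set_background(tables[[b[j]]], bg)
  }
  recs <- lapply(tables, function(tb) {
    r <- c_intensity(tb)
    if ("mean_actinin" %in% names(r)) r <- actinin_c_intensity(r)
    r
  })
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  out <- cn_normalize(animal_record(records, animal_id, group))
  attr(out, "tables") <- tables
  out
}

#' cn-intensity histogram over a cohort
#'
#' Bins of width `bin_width` percent covering (0, 100], left-open and
#' right-closed. Counts are formed per image, averaged over each
#' animal's images within hemisphere, then averaged across animals, so
#' the y-axis is the mean count per animal.
#'
#' @param animals list of cn-normalized [animal_record()]s.
#' @param bin_width bin width in percent; must divide 100.
#' @return data.frame `bin_lo`, `bin_hi`, `hemisphere`, `mean_count`;
#'   per-animal means attached as attribute `per_animal` (array
#'   animal x hemisphere x bin).
#' @export
histogram_cn <- function(animals, bin_width = 1) {
  nb <- 100 / bin_width
  if (!is_scalar_num(bin_width) || bin_width <= 0 || abs(nb - round(nb)) > 1e-9)
    stopf("bin_width must be a positive divisor of 100")
  nb <- as.integer(round(nb))
  recs <- lapply(animals, function(a) {
    stopifnot(inherits(a, "animal_record"))
    if (is.null(a$records$cn)) stopf("animal %s is not cn-normalized", a$animal_id)
    a$records
  })
  sides <- sort(unique(unlist(lapply(recs, function(r) unique(r$hemisphere)))))
  per_animal <- array(0, dim = c(length(animals), length(sides), nb),
                      dimnames = list(NULL, sides, NULL))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    for (s in sides) {
      rs <- r[r$hemisphere == s, , drop = FALSE]
      imgs <- unique(rs$image_id)
      if (length(imgs) == 0L) next
      cmat <- sapply(imgs, function(im) {
        cn <- rs$cn[rs$image_id == im]
        cn <- cn[cn > 0 & cn <= 100]
        tabulate(pmin(nb, as.integer(ceiling(cn / bin_width))), nbins = nb)
      })
      per_animal[i, s, ] <- rowMeans(matrix(cmat, nrow = nb))
    }
  }
  out <- do.call(rbind, lapply(sides, function(s) {
    data.frame(bin_lo = (seq_len(nb) - 1) * bin_width,
               bin_hi = seq_len(nb) * bin_width,
               hemisphere = s,
               mean_count = apply(per_animal[, s, , drop = FALSE], 3, mean))
  }))
  rownames(out) <- NULL
  attr(out, "per_animal") <- per_animal
  attr(out, "bin_width") <- bin_width
  class(out) <- c("cn_histogram", "data.frame")
  out
}

#' Per-bin contra-ipsi difference ratio
#'
#' For each cn bin, the increase in mean spine count on the contralateral
#' side relative to the ipsilateral side:
#' `(mean contra - mean ipsi) / mean ipsi`. Bins with zero mean ipsi
#' count are reported as NA (undefined), not infinity. The summed
#' absolute per-bin difference is attached as attribute
#' `mean_abs_difference`.
#'
#' @param hist a [histogram_cn()] result containing both `contra` and
#'   `ipsi` hemispheres.
#' @return data.frame `bin_lo`, `bin_hi`, `ratio`.
#' @export
difference_ratio <- function(hist) {
  stopifnot(inherits(hist, "cn_histogram"))
  sides <- unique(hist$hemisphere)
  if (!all(c("contra", "ipsi") %in% sides))
    stopf("histogram must contain both contra and ipsi hemispheres")
  co <- hist[hist$hemisphere == "contra", ]
  ip <- hist[hist$hemisphere == "ipsi", ]
  stopifnot(all(co$bin_lo == ip$bin_lo))
  ratio <- ifelse(ip$mean_count == 0, NA_real_,
                  (co$mean_count - ip$mean_count) / ip$mean_count)
  out <- data.frame(bin_lo = co$bin_lo, bin_hi = co$bin_hi, ratio = ratio)
  attr(out, "mean_abs_difference") <- sum(abs(co$mean_count - ip$mean_count))
  out
}

#' Integrated top-N cn-intensity per hemisphere
#'
#' For each image, the sum of that image's `n` largest cn-intensities
#' (ties at the cutoff broken deterministically by roi id); the
#' per-hemisphere value is the mean over that hemisphere's images — one
#' number per animal per side, the paired lateralization statistic.
#'
#' @param animal a cn-normalized [animal_record()].
#' @param n how many top spines to integrate (default 100; 200/300 are
#'   the reported variants).
#' @param value column to rank and sum, `"cn"` (default) or `"gn"` for
#'   the no-phalloidin-correction variant.
#' @return data.frame `animal_id`, `hemisphere`, `n`, `integrated_cn`.
#' @export
top_n_sum <- function(animal, n = 100L, value = "cn") {
  stopifnot(inherits(animal, "animal_record"))
  r <- animal$records
  if (is.null(r[[value]])) stopf("animal %s lacks a '%s' column; normalize first",
                                 animal$animal_id, value)
  imgs <- unique(r$image_id)
  per_image <- vapply(imgs, function(im) {
    v <- r[r$image_id == im, , drop = FALSE]
    if (nrow(v) < n)
      stopf("image %s has %d ROIs, fewer than n = %d", im, nrow(v), n)
    o <- order(-v[[value]], v$roi_id)
    sum(v[[value]][o[seq_len(n)]])
  }, numeric(1))
  hemi_of <- vapply(imgs, function(im) r$hemisphere[r$image_id == im][1],
                    character(1))
  sides <- unique(hemi_of)
  data.frame(animal_id = animal$animal_id,
             hemisphere = sides,
             n = as.integer(n),
             integrated_cn = vapply(sides, function(s)
               mean(per_image[hemi_of == s]), numeric(1)),
             row.names = NULL)
}

#' Contralateral / ipsilateral ratio of integrated top-N values
#'
#' @param summary a [top_n_sum()] result with both hemispheres.
#' @return scalar ratio contra / ipsi.
#' @export
contra_ipsi_ratio <- function(summary) {
  if (!all(c("contra", "ipsi") %in% summary$hemisphere))
    stopf("summary must contain both contra and ipsi hemispheres")
  if (length(unique(summary$n)) != 1L)
    stopf("hemispheres summarized with different n")
  co <- summary$integrated_cn[summary$hemisphere == "contra"]
  ip <- summary$integrated_cn[summary$hemisphere == "ipsi"]
  if (ip == 0) stopf("ipsilateral integrated value is zero")
  co / ip
}

#' Build matched ROI tables for a focal series
#'
#' Detects ROIs on the reference (first) plane, then re-measures the
#' same fixed 13-pixel ROIs on every plane ([measure_rois_at()]). The
#' per-channel background is the modal pixel value of the reference
#' plane, used for every step: the pedestal is a detector offset and
#' does not change with focal depth, and a per-plane re-estimate would
#' inject coherent step-to-step jitter into the ratio.
#'
#' @param images list of [field_image]s, one per focal step in order.
#' @param params a [detection_params()].
#' @return list of `roi_table`s ready for [focal_stability()].
#' @export
focal_series_tables <- function(images, params = detection_params()) {
  ref <- detect_rois(images[[1]], params)
  centers <- cbind(ref$row, ref$col)
  bg <- vapply(names(images[[1]]$channels),
               function(ch) image_mode(images[[1]]$channels[[ch]]),
               numeric(1))
  lapply(images, function(im)
    set_background(measure_rois_at(im, centers, params), bg))
}

#' Focal-plane stability of the c-intensity
#'
#' Matches ROIs across the steps of a focal series (nearest center
#' within `match_radius` pixels of the step-0 center, complete cases
#' only), expresses each matched ROI's c-intensity relative to its
#' step-0 value, and tests for a step effect with a one-way
#' repeated-measures ANOVA (ROI as subject). Step 0 is the reference
#' (relative value identically 1) and is therefore excluded from the
#' ANOVA, which runs over steps 1..K-1.
#'
#' @param tables list of `roi_table`s, one per focal step in order, each
#'   with backgrounds set.
#' @param match_radius matching tolerance in pixels.
#' @return list: `relative` (data.frame step, mean_relative, n),
#'   `p_value` (RM-ANOVA step effect), `n_matched`.
#' @export
focal_stability <- function(tables, match_radius = 2) {
  if (length(tables) < 2L) stopf("need at least two focal steps")
  recs <- lapply(tables, c_intensity)
  base <- recs[[1]]
  if (nrow(base) == 0L) stopf("no ROIs in the reference step")
  match_idx <- matrix(NA_integer_, nrow(base), length(recs))
  match_idx[, 1] <- seq_len(nrow(base))
  for (k in 2:length(recs)) {
    rk <- recs[[k]]
    if (nrow(rk) == 0L) next
    d2 <- outer(base$row, rk$row, "-")^2 + outer(base$col, rk$col, "-")^2
    j <- apply(d2, 1, which.min)
    ok <- d2[cbind(seq_len(nrow(base)), j)] <= match_radius^2
    match_idx[ok, k] <- j[ok]
  }
  complete <- stats::complete.cases(match_idx) & base$c > 0
  if (!any(complete)) stopf("no ROIs matched across all steps")
  midx <- match_idx[complete, , drop = FALSE]
  cmat <- sapply(seq_along(recs), function(k) recs[[k]]$c[midx[, k]])
  cmat <- matrix(cmat, nrow = sum(complete))
  rel <- cmat / cmat[, 1]
  nstep <- ncol(rel)
  df <- data.frame(
    roi = factor(rep(seq_len(nrow(rel)), nstep - 1L)),
    step = factor(rep(seq_len(nstep - 1L), each = nrow(rel))),
    rel = as.vector(rel[, -1, drop = FALSE]))
  p <- tryCatch({
    fit <- stats::aov(rel ~ step + Error(roi), data = df)
    s <- summary(fit)
    s[["Error: Within"]][[1]]["step", "Pr(>F)"]
  }, error = function(e) NA_real_)
  list(relative = data.frame(step = seq_len(nstep) - 1L,
                             mean_relative = colMeans(rel),
                             n = nrow(rel)),
       p_value = p, n_matched = nrow(rel))
}

#' Slice region ratio
#'
#' The mean of four square measurement ROIs in the highest-intensity
#' region, background-subtracted, divided by the background-subtracted
#' mean of a neighboring region:
#' `(mean(high ROIs) - mean(bg region)) / (mean(neighbor) - mean(bg region))`.
#'
#' @param image a [field_image].
#' @param high_rois list of four logical masks (the 40 x 40 um squares).
#' @param neighbor_region,background_region logical masks; all masks
#'   must be pairwise disjoint and non-empty.
#' @param channel channel measured (default `"green"`).
#' @return scalar ratio.
#' @export
region_ratio <- function(image, high_rois, neighbor_region,
                         background_region, channel = "green") {
  stopifnot(inherits(image, "field_image"))
  ch <- image$channels[[channel]]
  if (is.null(ch)) stopf("channel '%s' missing", channel)
  if (!is.list(high_rois) || length(high_rois) == 0L)
    stopf("high_rois must be a non-empty list of masks")
  masks <- c(high_rois, list(neighbor_region, background_region))
  for (m in masks) {
    if (!identical(dim(m), dim(ch))) stopf("mask shape differs from image")
    if (!any(m)) stopf("empty region mask")
  }
  high_union <- Reduce(`|`, high_rois)
  if (any(high_union & neighbor_region) || any(high_union & background_region) ||
      any(neighbor_region & background_region))
    stopf("region masks overlap")
  bg <- mean(ch[background_region])
  high <- mean(vapply(high_rois, function(m) mean(ch[m]), numeric(1)))
  den <- mean(ch[neighbor_region]) - bg
  if (den <= 0) stopf("non-positive background-subtracted neighbor intensity")
  (high - bg) / den
}
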