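# Third-channel (alpha-actinin) colocalization over CapZ-ranked spines.
# The statistic is rank-based and within-image by design: immunolabel
# intensities are hard to compare across sections, but the ratio of the
# mean actinin c-intensity in the top-100 CapZ spines to that in the
# top-1000 within one image is self-normalizing.

#' Alpha-actinin c-intensity per ROI
#'
#' `(mean_actinin - bg_actinin) / (mean_red - bg_red)`, the third-channel
#' analogue of [c_intensity()], with the same exclusion of non-positive
#' red denominators.
#'
#' @param table a `roi_table` (or [c_intensity()] output) with actinin
#'   means and backgrounds present.
#' @return the surviving rows with column `c_actinin` appended.
#' @export
actinin_c_intensity <- function(table) {
  if (!all(c("mean_actinin", "bg_actinin") %in% names(table)))
    stopf("actinin channel (mean_actinin/bg_actinin) missing from table")
  den <- table$mean_red - table$bg_red
  keep <- den > 0
  out <- table[keep, , drop = FALSE]
  out$c_actinin <- (out$mean_actinin - out$bg_actinin) /
    (out$mean_red - out$bg_red)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Rank-based colocalization ratio
#'
#' Ranks the ROIs of each image by EGFP-CapZ c-intensity (descending,
#' ties by roi id) and reports
#' `100 * mean(actinin c over top n_top) / mean(actinin c over top n_ref)`.
#' With `nested = TRUE` (default) the top `n_top` set is a subset of the
#' reference set; `nested = FALSE` uses ranks `n_top+1 .. n_ref` as the
#' reference instead. Values above 100 indicate preferential actinin
#' localization in the brightest-CapZ spines; under independence the
#' expectation is 100.
#'
#' @param records data.frame with `image_id`, `roi_id`, `c` and
#'   `c_actinin` columns (see [c_intensity()], [actinin_c_intensity()]).
#' @param n_top,n_ref rank strata sizes; `n_top < n_ref` and every image
#'   must have at least `n_ref` ROIs.
#' @param nested whether the reference stratum includes the top stratum.
#' @return data.frame `image_id`, `n_top`, `n_ref`, `ratio_percent`.
#' @export
coloc_ratio <- function(records, n_top = 100L, n_ref = 1000L, nested = TRUE) {
  if (!all(c("c", "c_actinin") %in% names(records)))
    stopf("records need both 'c' and 'c_actinin' columns")
  if (!(n_top < n_ref)) stopf("need n_top < n_ref")
  imgs <- unique(records$image_id)
  rows <- lapply(imgs, function(im) {
    r <- records[records$image_id == im, , drop = FALSE]
    if (nrow(r) < n_ref)
      stopf("image %s has %d ROIs, fewer than n_ref = %d", im, nrow(r), n_ref)
    o <- order(-r$c, r$roi_id)
    top <- r$c_actinin[o[seq_len(n_top)]]
    ref <- if (nested) r$c_actinin[o[seq_len(n_ref)]]
           else r$c_actinin[o[seq.int(n_top + 1L, n_ref)]]
    data.frame(image_id = im, n_top = as.integer(n_top),
               n_ref = as.integer(n_ref),
               ratio_percent = 100 * mean(top) / mean(ref))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare colocalization ratios between two groups
#'
#' Per-image ratios are averaged within animal and the per-animal means
#' compared with an unpaired two-sided Student's t-test.
#'
#' @param ratios_a,ratios_b data.frames from [coloc_ratio()] with an
#'   `animal_id` column added.
#' @return `htest` object from [stats::t.test()].
#' @export
compare_coloc_groups <- function(ratios_a, ratios_b) {
  per_animal <- function(x) {
    if (is.null(x$animal_id)) stopf("ratios need an animal_id column")
    tapply(x$ratio_percent, x$animal_id, mean)
  }
  stats::t.test(per_animal(ratios_a), per_animal(ratios_b),
                var.equal = TRUE)
}
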