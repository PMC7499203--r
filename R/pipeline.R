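# Pipeline orchestration: config validation and an end-to-end
# simulate -> detect -> quantify -> coloc run with provenance, producing
# the panel-style tables (histograms, difference ratios, paired top-N
# comparisons, contra/ipsi ratios, coloc ratios) as CSV/JSON.

#' Validate a cohort image manifest
#'
#' Checks a manifest (a list, or a path to a YAML file) describing
#' acquired images: the channel map must include `red` and `green`,
#' `pixel_size` must be present and positive, every animal must have
#' images from both hemispheres, and every referenced file must exist.
#' Reports issues; never throws for content problems.
#'
#' @param manifest list or YAML path with fields `pixel_size`,
#'   `channels` (character vector of page roles), `animals` (each with
#'   `id`, optional `group`, and `images`: list of `hemisphere` + `path`).
#' @return data.frame `animal_id`, `issue` (zero rows when valid).
#' @export
validate_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- yaml::read_yaml(manifest)
  issues <- list()
  note <- function(animal, msg)
    issues[[length(issues) + 1L]] <<- data.frame(animal_id = animal, issue = msg)
  if (is.null(manifest$pixel_size) || !is_scalar_num(manifest$pixel_size) ||
      manifest$pixel_size <= 0)
    note(NA_character_, "missing or non-positive pixel_size")
  chans <- unlist(manifest$channels)
  for (req in c("red", "green"))
    if (!req %in% chans)
      note(NA_character_, sprintf("missing required channel '%s'", req))
  if (is.null(manifest$animals) || length(manifest$animals) == 0L) {
    note(NA_character_, "no animals listed")
  } else {
    for (an in manifest$animals) {
      id <- an$id %||% NA_character_
      sides <- vapply(an$images %||% list(),
                      function(im) im$hemisphere %||% NA_character_,
                      character(1))
      for (s in c("contra", "ipsi"))
        if (!s %in% sides) note(id, sprintf("unpaired animal: no %s images", s))
      for (im in an$images %||% list())
        if (!is.null(im$path) && !file.exists(im$path))
          note(id, sprintf("missing file: %s", im$path))
    }
  }
  if (length(issues) == 0L)
    return(data.frame(animal_id = character(0), issue = character(0)))
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}

#' Run the full simulation-and-analysis pipeline
#'
#' Simulates the configured groups of animals, quantifies them, and
#' writes versioned outputs to `out_dir`: `records.csv` (per-ROI c/cn
#' values), `summary.csv` (per-animal top-N integrals and contra/ipsi
#' ratios), `histogram.csv`, `difference_ratio.csv`, optionally
#' `coloc.csv`, and `report.json` (seed, parameters, paired within-group
#' tests, between-group ratio test, coloc group test). Deterministic
#' under a fixed config seed; partial outputs are retained if a later
#' stage fails.
#'
#' @param config list with elements `seed`; `sim` (arguments to
#'   [sim_params()]); `groups` (list of `name`, `n_animals`, `effect` =
#'   arguments to [effect_spec()]); optional `stats`
#'   (`top_n`, `bin_width`, `alpha`); optional `mode` (`"table"`,
#'   default, for the measurement-model path, or `"image"` for full
#'   rendering + watershed detection); optional `detection` (arguments
#'   to [detection_params()], image mode only); optional `coloc`
#'   (`n_top`, `n_ref`) when the simulated fields carry an actinin
#'   channel.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the per-group cohorts, test results,
#'   and output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  seed <- config$seed %||% 1L
  if (is.null(config$groups) || length(config$groups) == 0L)
    stopf("validation error: config has no groups")
  stats_cfg <- config$stats %||% list()
  top_n <- stats_cfg$top_n %||% 100L
  bin_width <- stats_cfg$bin_width %||% 1
  alpha <- stats_cfg$alpha %||% 0.05
  mode <- config$mode %||% "table"
  base_sim <- do.call(sim_params, config$sim %||% list())

  cohorts <- list()
  for (gi in seq_along(config$groups)) {
    g <- config$groups[[gi]]
    gname <- g$name %||% sprintf("group%d", gi)
    eff <- do.call(effect_spec, g$effect %||% list(n_extra_bright = 0L))
    n_animals <- g$n_animals %||% 8L
    gseed <- derive_seed(seed, gi * 1000L)
    if (mode == "table") {
      cohorts[[gname]] <- simulate_cohort(base_sim, eff, n_animals = n_animals,
                                          seed = gseed, group = gname)
    } else {
      dpar <- do.call(detection_params, config$detection %||% list())
      cohorts[[gname]] <- lapply(seq_len(n_animals), function(a) {
        p <- base_sim
        p$seed <- derive_seed(gseed, a)
        sim <- generate_animal(p, eff, animal_id = sprintf("%s_A%d", gname, a),
                               group = gname)
        process_animal(sim$images, dpar, animal_id = sim$animal_id,
                       group = gname)
      })
      class(cohorts[[gname]]) <- c("cohort", "list")
    }
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  all_records <- do.call(rbind, lapply(unlist(cohorts, recursive = FALSE),
    function(a) cbind(animal_id = a$animal_id, group = a$group,
                      a$records[, intersect(c("image_id", "roi_id", "hemisphere",
                                              "c", "cn", "green_corr", "gn",
                                              "c_actinin"),
                                            names(a$records))])))
  rownames(all_records) <- NULL
  paths$records <- file.path(out_dir, "records.csv")
  utils::write.csv(all_records, paths$records, row.names = FALSE)

  tests <- list()
  summaries <- list()
  hists <- list()
  for (gname in names(cohorts)) {
    co <- cohorts[[gname]]
    ct <- cohort_test(co, n = top_n)
    tests[[gname]] <- list(paired_p = ct$p_value, t = ct$statistic,
                           mean_ratio = ct$mean_ratio,
                           significant = ct$p_value < alpha,
                           direction = if (mean(ct$summaries$contra -
                                                  ct$summaries$ipsi) > 0)
                             "contra>ipsi" else "contra<=ipsi")
    summaries[[gname]] <- cbind(group = gname, n = top_n, ct$summaries)
    h <- histogram_cn(co, bin_width = bin_width)
    hists[[gname]] <- cbind(group = gname, as.data.frame(h))
    dr <- difference_ratio(h)
    hists[[paste0(gname, "_diff")]] <- cbind(group = gname, hemisphere = "diff",
      data.frame(bin_lo = dr$bin_lo, bin_hi = dr$bin_hi, mean_count = dr$ratio))
  }
  paths$summary <- file.path(out_dir, "summary.csv")
  utils::write.csv(do.call(rbind, summaries), paths$summary, row.names = FALSE)
  paths$histogram <- file.path(out_dir, "histogram.csv")
  utils::write.csv(do.call(rbind, hists), paths$histogram, row.names = FALSE)

  if (length(cohorts) == 2L) {
    bt <- compare_cohort_ratios(cohorts[[1]], cohorts[[2]], n = top_n)
    tests$between_groups <- list(p = unname(bt$p.value), t = unname(bt$statistic))
  }

  if (!is.null(base_sim$actinin_coupling)) {
    ccfg <- config$coloc %||% list()
    n_ref <- ccfg$n_ref %||% min(base_sim$n_spines, 1000L)
    n_top <- min(ccfg$n_top %||% 100L, n_ref - 1L)
    coloc_rows <- list()
    for (gname in names(cohorts)) for (a in cohorts[[gname]]) {
      cr <- coloc_ratio(a$records, n_top = n_top, n_ref = n_ref)
      coloc_rows[[length(coloc_rows) + 1L]] <-
        cbind(group = gname, animal_id = a$animal_id, cr)
    }
    coloc_df <- do.call(rbind, coloc_rows)
    paths$coloc <- file.path(out_dir, "coloc.csv")
    utils::write.csv(coloc_df, paths$coloc, row.names = FALSE)
    if (length(cohorts) == 2L) {
      gs <- names(cohorts)
      ctst <- compare_coloc_groups(coloc_df[coloc_df$group == gs[1], ],
                                   coloc_df[coloc_df$group == gs[2], ])
      tests$coloc_between_groups <- list(p = unname(ctst$p.value))
    }
  }

  report <- list(seed = seed, mode = mode, top_n = top_n,
                 bin_width = bin_width, alpha = alpha,
                 sim = config$sim %||% list(), tests = tests)
  paths$report <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(cohorts = cohorts, tests = tests, paths = paths))
}
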