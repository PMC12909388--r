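RUN_CONFIG_KEYS <- c("output_dir", "seed", "spacing", "alpha", "kappa",
                     "grubbs_sidedness", "annotations", "cohort_table",
                     "uae_interval", "simulate")

#' Load and validate a pipeline run configuration
#'
#' @param config a YAML file path or a named list. Recognised keys:
#'   `output_dir`, `seed`, `spacing` (px), `alpha`, `kappa`,
#'   `grubbs_sidedness`, `annotations` (vector of annotation JSON paths),
#'   `cohort_table` (CSV path), `uae_interval` (length-2 numeric, normalised),
#'   `simulate` (sub-list of [image_sim_params()] / [cohort_sim_params()]
#'   overrides under `image` and `cohort`).
#' @return validated config list with defaults filled in.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop(sprintf("no such config file: %s", config),
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  defaults <- list(output_dir = ".", seed = 1L, spacing = 1, alpha = 0.05,
                   kappa = 1, grubbs_sidedness = "two_sided")
  config <- utils::modifyList(defaults, config)
  stopifnot(config$spacing > 0, config$alpha > 0, config$alpha < 1,
            config$kappa >= 1)
  config
}

pipeline_log <- function(out_dir, lines) {
  path <- file.path(out_dir, "run.log")
  con <- file(path, open = "a", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), lines),
             con)
  invisible(path)
}

#' Run one stage of the analysis pipeline
#'
#' Configuration-driven orchestration of the measurement stages:
#' \describe{
#'   \item{measure}{reads each annotation file, measures the physis
#'     ([measure_physis()]), writes `rates.csv` (one row per image: regional
#'     rates and percent growth modulation) and per-image rate profiles
#'     `profile_<image_id>.csv`.}
#'   \item{morpho}{reads each annotation file and writes `morphometry.csv`
#'     (zone thicknesses, ossification percent, NP position where the
#'     annotations are present).}
#'   \item{stats}{reads `cohort_table`, writes `summary_by_level.csv`,
#'     `pairwise_t.csv`, `grubbs.csv` and a text report.}
#'   \item{simulate}{writes a synthetic fixture set: two-channel TIFF +
#'     annotation JSON + ground-truth JSON + cohort CSV.}
#' }
#' Per-item failures are logged to `run.log` and the run continues; all
#' randomness flows from `config$seed`.
#'
#' @param config a [run_config()] list or YAML path.
#' @param subcommand one of `"measure"`, `"morpho"`, `"stats"`, `"simulate"`.
#' @return invisibly, a named list of output file paths.
#' @export
run_pipeline <- function(config,
                         subcommand = c("measure", "morpho", "stats", "simulate")) {
  subcommand <- match.arg(subcommand)
  config <- run_config(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  pipeline_log(out, sprintf("physgrowth %s | subcommand=%s seed=%s spacing=%g alpha=%g kappa=%g",
                            as.character(utils::packageVersion("physgrowth")),
                            subcommand, config$seed, config$spacing,
                            config$alpha, config$kappa))
  switch(subcommand,
         measure = pipeline_measure(config, out),
         morpho = pipeline_morpho(config, out),
         stats = pipeline_stats(config, out),
         simulate = pipeline_simulate(config, out))
}

pipeline_measure <- function(config, out) {
  if (is.null(config$annotations)) {
    stop("measure requires 'annotations' in the config", call. = FALSE)
  }
  uae <- if (is.null(config$uae_interval)) NULL else
    interval(config$uae_interval[1], config$uae_interval[2])
  rows <- list(); profiles <- character()
  for (path in config$annotations) {
    res <- tryCatch({
      ann <- read_annotation_set(path)
      m <- measure_physis(ann, spacing = config$spacing, uae_interval = uae)
      pp <- file.path(out, sprintf("profile_%s.csv", ann$image_id))
      utils::write.csv(data.frame(s = m$rate_profile$s,
                                  rate_um_day = m$rate_profile$rates),
                       pp, row.names = FALSE)
      profiles <- c(profiles, pp)
      data.frame(image_id = ann$image_id,
                 rate_anterior_q = m$regional$anterior_q,
                 rate_middle_h = m$regional$middle_h,
                 rate_posterior_q = m$regional$posterior_q,
                 rate_overall = m$regional$overall,
                 rate_uae = if (is.null(m$regional$uae)) NA_real_ else m$regional$uae,
                 pct_growth_modulation = m$pct_growth_modulation)
    }, error = function(e) {
      pipeline_log(out, sprintf("measure FAILED for %s: %s", path,
                                conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  if (!length(rows)) stop("no annotation could be measured", call. = FALSE)
  rates_path <- file.path(out, "rates.csv")
  utils::write.csv(do.call(rbind, rows), rates_path, row.names = FALSE)
  invisible(list(rates = rates_path, profiles = profiles))
}

pipeline_morpho <- function(config, out) {
  if (is.null(config$annotations)) {
    stop("morpho requires 'annotations' in the config", call. = FALSE)
  }
  rows <- list()
  for (path in config$annotations) {
    res <- tryCatch({
      ann <- read_annotation_set(path)
      fr <- resolve_frame(ann)
      row <- data.frame(image_id = ann$image_id,
                        thickness_hypertrophic_um = NA_real_,
                        thickness_proliferative_reserve_um = NA_real_,
                        thickness_total_um = NA_real_,
                        ossification_pct = NA_real_,
                        np_pct_epiphysis = NA_real_, np_pct_vertebra = NA_real_,
                        cobb_deg = NA_real_)
      if (!is.null(ann$zone_polygons)) {
        zones <- lapply(ann$zone_polygons, function(z) {
          zone_annotation(z$zone, z$polygon, z$region_tag)
        })
        cls <- vapply(zones, function(z) z$zone, character(1))
        for (zc in unique(cls)) {
          col <- paste0("thickness_", zc, "_um")
          zs <- zones[cls == zc]
          row[[col]] <- mean(vapply(zs, mean_thickness, numeric(1),
                                    frame = fr, cal = ann$calibration))
        }
        if (all(c("hypertrophic", "proliferative_reserve") %in% cls)) {
          row$thickness_total_um <-
            total_physeal_thickness(zones, fr, ann$calibration)
        }
      }
      if (!is.null(ann$epiphysis_intervals)) {
        pcts <- vapply(ann$epiphysis_intervals, function(e) {
          ossification_percent(e$ossified, e$total)
        }, numeric(1))
        row$ossification_pct <- mean(pcts)
      }
      if (!is.null(ann$np_polygon) && !is.null(ann$epiphysis_intervals) &&
          !is.null(ann$vertebra_interval)) {
        epi <- ann$epiphysis_intervals[[1]]
        np <- np_location_percent(ann$np_polygon, epi$ossified,
                                  ann$vertebra_interval, fr)
        row$np_pct_epiphysis <- np$pct_epiphysis
        row$np_pct_vertebra <- np$pct_vertebra
      }
      if (!is.null(ann$endplate_lines) && length(ann$endplate_lines) == 2) {
        roles <- vapply(ann$endplate_lines, function(l) l$role, character(1))
        cr <- ann$endplate_lines[[match("cranial", roles)]]
        cd <- ann$endplate_lines[[match("caudal", roles)]]
        row$cobb_deg <- cobb_angle(endplate_line(cr$p1, cr$p2, "cranial"),
                                   endplate_line(cd$p1, cd$p2, "caudal"),
                                   fr$ap_unit)
      }
      row
    }, error = function(e) {
      pipeline_log(out, sprintf("morpho FAILED for %s: %s", path,
                                conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  if (!length(rows)) stop("no annotation could be processed", call. = FALSE)
  path <- file.path(out, "morphometry.csv")
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(list(morphometry = path))
}

pipeline_stats <- function(config, out) {
  if (is.null(config$cohort_table)) {
    stop("stats requires 'cohort_table' in the config", call. = FALSE)
  }
  records <- read_cohort_table(config$cohort_table)
  summ <- aggregate_levels(records, group_by = "level",
                           value = "pct_growth_modulation")
  summary_path <- file.path(out, "summary_by_level.csv")
  utils::write.csv(summ, summary_path, row.names = FALSE)

  groups <- split(records$pct_growth_modulation, records$level)
  pw <- pairwise_one_tailed_t(groups, alpha = config$alpha,
                              kappa = config$kappa)
  pw_path <- file.path(out, "pairwise_t.csv")
  utils::write.csv(pw, pw_path, row.names = FALSE)

  grows <- lapply(names(groups), function(lv) {
    v <- groups[[lv]][!is.na(groups[[lv]])]
    g <- tryCatch(grubbs_test(v, alpha = config$alpha,
                              sidedness = config$grubbs_sidedness),
                  error = function(e) NULL)
    if (is.null(g)) return(NULL)
    data.frame(level = lv, G = g$G, G_crit = g$G_crit, n = g$n,
               is_outlier = g$is_outlier, suspect = g$suspect)
  })
  gr <- do.call(rbind, grows)
  grubbs_path <- file.path(out, "grubbs.csv")
  utils::write.csv(gr, grubbs_path, row.names = FALSE)

  report_path <- file.path(out, "stats_report.txt")
  con <- file(report_path, open = "w", encoding = "UTF-8")
  writeLines(c(
    "Percent growth modulation by level (mean, sample SD, n):",
    utils::capture.output(print(summ, row.names = FALSE)),
    "",
    sprintf("Pairwise one-tailed Welch t tests, Bonferroni kappa = %g (adjusted alpha = %.4g):",
            config$kappa, attr(pw, "adjusted_alpha")),
    utils::capture.output(print(pw, row.names = FALSE)),
    "",
    sprintf("Grubbs' outlier test per level (%s, alpha = %g):",
            config$grubbs_sidedness, config$alpha),
    utils::capture.output(print(gr, row.names = FALSE))), con)
  close(con)
  invisible(list(summary = summary_path, pairwise = pw_path,
                 grubbs = grubbs_path, report = report_path))
}

pipeline_simulate <- function(config, out) {
  sim_cfg <- if (is.null(config$simulate)) list() else config$simulate
  img_args <- utils::modifyList(list(seed = config$seed),
                                if (is.null(sim_cfg$image)) list() else sim_cfg$image)
  coh_args <- utils::modifyList(list(seed = config$seed),
                                if (is.null(sim_cfg$cohort)) list() else sim_cfg$cohort)
  sim <- simulate_physis_image(do.call(image_sim_params, img_args))
  tiff_path <- file.path(out, sprintf("physis_seed%d.tif", sim$params$seed))
  write_physis_tiff(sim, tiff_path)
  ann_path <- file.path(out, sprintf("physis_seed%d_annotation.json",
                                     sim$params$seed))
  write_annotation_set(sim$annotation, ann_path)
  gt_path <- file.path(out, sprintf("physis_seed%d_truth.json", sim$params$seed))
  gt <- sim$ground_truth
  jsonlite::write_json(
    list(pct_growth_modulation = gt$pct_growth_modulation,
         regional = unclass(gt$regional), x = gt$x,
         y_alizarin = gt$y_alizarin, y_oxytet = gt$y_oxytet,
         seed = sim$params$seed),
    gt_path, auto_unbox = TRUE, digits = NA, null = "null")
  cohort <- simulate_cohort(do.call(cohort_sim_params, coh_args))
  cohort_path <- file.path(out, sprintf("cohort_seed%d.csv", coh_args$seed))
  write_cohort_table(cohort, cohort_path)
  invisible(list(tiff = tiff_path, annotation = ann_path, truth = gt_path,
                 cohort = cohort_path))
}
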