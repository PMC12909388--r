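# Synthetic stand-ins for the study's undeposited micrographs and cohort
# tables: a two-channel label-band image over a curved front with an exactly
# known growth field, and a multi-animal cohort with a prescribed level-wise
# modulation structure.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Parameters of the synthetic physis image
#'
#' Defaults emulate a coronal physis slab imaged at low magnification: a
#' gently curved mineralisation front, an alizarin band laid down
#' `delta_days` before harvest, and an oxytetracycline band at the
#' chondro-osseous junction at harvest. The true separation field is linear
#' in the normalised A-P station, so the percent growth modulation of the
#' ground truth equals `modulation_pct` analytically; the shared sinusoidal
#' baseline contributes curvature but cancels from the separation.
#'
#' @param width_px,height_px image size (px).
#' @param um_per_px physical scale (um/px).
#' @param delta_days days between label administrations (default 13, the
#'   midpoint of the 12-14 day protocol window; real analyses must pass each
#'   animal's actual interval).
#' @param base_separation_um mean front separation (um). The default, 2132
#'   um, corresponds to an overall rate of 164 um/day over 13 days.
#' @param modulation_pct target percent growth modulation of the true field,
#'   in (-200, 200).
#' @param front_curvature amplitude (px) of the sinusoidal baseline.
#' @param band_width_px Gaussian sigma of the rendered label bands (px).
#' @param noise_sd additive Gaussian intensity noise, fraction of peak.
#' @param n_trace_points simulated operator points per front.
#' @param trace_jitter_px SD of the simulated operator's click error (px),
#'   applied along the growth axis.
#' @param seed RNG seed; the generator is a pure function of params + seed.
#' @return validated parameter list of class `image_sim_params`.
#' @export
image_sim_params <- function(width_px = 800, height_px = 1024, um_per_px = 4,
                             delta_days = 13, base_separation_um = 2132,
                             modulation_pct = 20, front_curvature = 20,
                             band_width_px = 4, noise_sd = 0.05,
                             n_trace_points = 40, trace_jitter_px = 0.5,
                             seed = 1) {
  p <- list(width_px = width_px, height_px = height_px, um_per_px = um_per_px,
            delta_days = delta_days, base_separation_um = base_separation_um,
            modulation_pct = modulation_pct, front_curvature = front_curvature,
            band_width_px = band_width_px, noise_sd = noise_sd,
            n_trace_points = n_trace_points, trace_jitter_px = trace_jitter_px,
            seed = seed)
  stopifnot(width_px >= 16, height_px >= 16, um_per_px > 0, delta_days > 0,
            base_separation_um > 0, front_curvature >= 0, band_width_px > 0,
            noise_sd >= 0, n_trace_points >= 4, trace_jitter_px >= 0)
  if (modulation_pct <= -200 || modulation_pct >= 200) {
    stop("modulation_pct must lie in (-200, 200)", call. = FALSE)
  }
  structure(p, class = "image_sim_params")
}

#' Simulate a two-channel fluorochrome-labelled physis image
#'
#' Renders both label fronts as Gaussian-profile intensity bands in separate
#' channels over a shared curved baseline, with additive noise, and returns
#' the exact ground truth alongside: the dense front polylines, the true
#' per-station rate field, its analytic regional means, and the true percent
#' growth modulation. A simulated operator trace (jittered control points
#' sampled from the true fronts) and the matching [annotation_set()] are
#' included so the measurement pipeline can be exercised exactly as on real
#' annotations.
#'
#' @param p an [image_sim_params()] list.
#' @return list with elements `image` (height x width x 2 array, channel 1 =
#'   alizarin, channel 2 = oxytetracycline), `ground_truth` (list: `x`,
#'   `y_alizarin`, `y_oxytet`, `rate_um_day`, `regional`, `pct_growth_modulation`),
#'   `annotation` (an [annotation_set()] carrying the traced points), and
#'   `params`.
#' @export
simulate_physis_image <- function(p = image_sim_params()) {
  stopifnot(inherits(p, "image_sim_params"))
  w <- p$width_px; h <- p$height_px
  sep_px <- p$base_separation_um / p$um_per_px
  # linear separation field d(s) = A + B s over normalised station s in [0,1]
  # gives %GM = 100 * 0.75 B / (A + B/2): choose B for the target modulation
  B <- p$modulation_pct * sep_px / 75
  A <- sep_px - B / 2
  x <- seq(0, w - 1)
  s <- x / (w - 1)
  y_base <- 0.05 * h + p$front_curvature
  y_old <- y_base + p$front_curvature * sin(pi * s)
  d_px <- A + B * s
  y_new <- y_old + d_px
  if (max(y_new) + 3 * p$band_width_px > h || min(d_px) < 0) {
    stop("front separation exceeds the image height; enlarge height_px or reduce base_separation_um",
         call. = FALSE)
  }
  region_mean <- function(lo, hi) {  # analytic mean of A + B s over (lo, hi]
    (A + B * (lo + hi) / 2) * p$um_per_px / p$delta_days
  }
  truth <- list(
    x = x, y_alizarin = y_old, y_oxytet = y_new,
    rate_um_day = d_px * p$um_per_px / p$delta_days,
    regional = as_regional_rates(
      anterior_q = region_mean(0.75, 1), middle_h = region_mean(0.25, 0.75),
      posterior_q = region_mean(0, 0.25), overall = region_mean(0, 1)),
    pct_growth_modulation = p$modulation_pct)
  with_seed(p$seed, {
    render <- function(front_y) {
      dev <- outer(seq(0, h - 1), front_y, "-")
      img <- exp(-dev^2 / (2 * p$band_width_px^2))
      if (p$noise_sd > 0) img <- img + matrix(stats::rnorm(h * w, 0, p$noise_sd), h, w)
      img
    }
    image <- array(c(render(y_old), render(y_new)), dim = c(h, w, 2))
    trace <- function(front_y, label) {
      xs <- round(seq(0, w - 1, length.out = p$n_trace_points))
      ys <- front_y[xs + 1] + stats::rnorm(length(xs), 0, p$trace_jitter_px)
      cbind(xs, ys)
    }
    pts_old <- trace(y_old); pts_new <- trace(y_new)
  })
  ann <- annotation_set(
    image_id = sprintf("synthetic-physis-seed%d", p$seed),
    calibration = calibration(p$um_per_px, p$delta_days),
    fronts = list(alizarin = pts_old, oxytetracycline = pts_new),
    frame_spec = list(chord_start = c(0, 0), chord_end = c(w - 1, 0),
                      growth_sign = 1),
    channel_map = c(alizarin = 1L, oxytetracycline = 2L))
  list(image = image, ground_truth = truth, annotation = ann, params = p)
}

#' Write a simulated image as a two-channel TIFF
#'
#' Intensities are clamped to `[0, 1]`.
#'
#' @param sim a [simulate_physis_image()] result.
#' @param path output TIFF path.
#' @export
write_physis_tiff <- function(sim, path) {
  img <- pmin(pmax(sim$image, 0), 1)
  tiff::writeTIFF(img, path, bits.per.sample = 16)
  invisible(path)
}

#' Parameters of the synthetic cohort
#'
#' Defaults encode the effect structure of a six-animal posterior-tether
#' cohort: the most proximal instrumented disk (D5) carries the largest mean
#' percent growth modulation (55), the remaining instrumented disks D1-D4
#' rise gradually from 7 to 21, and the adjacent uninstrumented levels (Dd,
#' P1, P2) reverse sign (-20, an arbitrary but representative magnitude for
#' junctional reversal). Overall rates default to 164 um/day at instrumented
#' and 154 um/day at adjacent levels.
#'
#' @param n_animals number of animals (>= 2; default 6, split evenly into
#'   high- and low-tension groups).
#' @param level_effects named vector: true mean percent growth modulation per
#'   disk level.
#' @param level_overall_rates named vector: true mean overall growth rate per
#'   level (um/day).
#' @param between_animal_sd SD of the shared per-animal modulation offset
#'   (percentage points).
#' @param within_level_sd SD of the independent per-measurement modulation
#'   noise (percentage points).
#' @param rate_sd SD of the per-measurement overall-rate noise (um/day).
#' @param failure_injection optional list of `list(animal =, level =,
#'   attenuation =)`: multiplies the affected measurement's modulation effect
#'   by `attenuation` and flags the row as an implant failure.
#' @param seed RNG seed.
#' @return validated parameter list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(
    n_animals = 6,
    level_effects = c(Dd = -20, D1 = 7, D2 = 11, D3 = 16, D4 = 21, D5 = 55,
                      P1 = -20, P2 = -20),
    level_overall_rates = c(Dd = 154, D1 = 164, D2 = 164, D3 = 164, D4 = 164,
                            D5 = 164, P1 = 154, P2 = 154),
    between_animal_sd = 8, within_level_sd = 15, rate_sd = 20,
    failure_injection = NULL, seed = 1) {
  stopifnot(n_animals >= 2, between_animal_sd >= 0, within_level_sd >= 0,
            rate_sd >= 0)
  bad <- setdiff(names(level_effects), DISK_LEVELS)
  if (length(bad)) {
    stop(sprintf("unknown level key(s) in level_effects: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (!setequal(names(level_effects), names(level_overall_rates))) {
    stop("level_effects and level_overall_rates must cover the same levels",
         call. = FALSE)
  }
  if (!is.null(failure_injection)) {
    if (!is.null(failure_injection$level)) failure_injection <- list(failure_injection)
    for (f in failure_injection) {
      if (!f$level %in% names(level_effects)) {
        stop(sprintf("failure_injection names unknown level '%s'", f$level),
             call. = FALSE)
      }
      stopifnot(f$animal >= 1, f$animal <= n_animals)
    }
  }
  structure(list(n_animals = n_animals, level_effects = level_effects,
                 level_overall_rates = level_overall_rates,
                 between_animal_sd = between_animal_sd,
                 within_level_sd = within_level_sd, rate_sd = rate_sd,
                 failure_injection = failure_injection, seed = seed),
            class = "cohort_sim_params")
}

#' Simulate a multi-animal cohort table
#'
#' For each animal and disk level, the true modulation is
#' `level_effects[level] + animal offset + measurement noise` and the overall
#' rate is `level_overall_rates[level] + rate noise`. Regional rates are then
#' constructed so that the row's percent growth modulation and overall rate
#' equal those draws exactly (anterior/posterior = overall +/- delta with
#' `delta = gm * overall / 200`, middle = overall). Deterministic given the
#' seed.
#'
#' @param p a [cohort_sim_params()] list.
#' @return cohort `data.frame` (one `"combined"` row per animal x level; see
#'   [cohort_record()]).
#' @export
simulate_cohort <- function(p = cohort_sim_params()) {
  stopifnot(inherits(p, "cohort_sim_params"))
  levels <- names(p$level_effects)
  with_seed(p$seed, {
    rows <- list()
    u <- stats::rnorm(p$n_animals, 0, p$between_animal_sd)
    for (a in seq_len(p$n_animals)) {
      tension <- if (a <= ceiling(p$n_animals / 2)) "high" else "low"
      for (lv in levels) {
        gm <- p$level_effects[[lv]] + u[a] +
          stats::rnorm(1, 0, p$within_level_sd)
        fail <- FALSE
        if (!is.null(p$failure_injection)) {
          for (f in p$failure_injection) {
            if (f$animal == a && f$level == lv) {
              gm <- gm * f$attenuation
              fail <- TRUE
            }
          }
        }
        overall <- p$level_overall_rates[[lv]] + stats::rnorm(1, 0, p$rate_sd)
        delta <- gm * overall / 200
        rows[[length(rows) + 1]] <- cohort_record(
          animal_id = sprintf("A%02d", a), tension_group = tension,
          level = lv, side = "combined",
          rates = as_regional_rates(overall + delta, overall,
                                    overall - delta, overall),
          implant_failure = fail)
      }
    }
  })
  do.call(rbind, rows)
}
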