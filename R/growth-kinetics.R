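#' Pixel-wise growth-distance profile between two label fronts
#'
#' Samples both fronts at matched A-P stations over the intersection of their
#' traced extents and measures the signed separation along the frame's growth
#' axis: `distance(x) = height_new(x) - height_old(x)`. Positive distances
#' mean mineralisation advanced along the growth unit vector between the two
#' label administrations. Stations outside either traced front are excluded,
#' never extrapolated, and distances are kept signed so that pathological
#' front crossings remain visible.
#'
#' @param old_front the earlier label front (alizarin), a [build_front()]
#'   front.
#' @param new_front the harvest-day front (oxytetracycline), in the same
#'   frame.
#' @param spacing station sampling step, px (default 1: pixel-by-pixel).
#' @return An object of class `growth_profile` with uniformly spaced
#'   `stations` (px) and signed `distances` (px).
#' @export
distance_profile <- function(old_front, new_front, spacing = 1) {
  stopifnot(inherits(old_front, "front"), inherits(new_front, "front"),
            is.numeric(spacing), spacing > 0)
  lo <- max(min(old_front$stations), min(new_front$stations))
  hi <- min(max(old_front$stations), max(new_front$stations))
  if (hi - lo < 4 * spacing) {
    stop("insufficient front overlap: need at least 4 spacing units", call. = FALSE)
  }
  stations <- seq(lo, hi, by = spacing)
  distances <- height_at(new_front, stations) - height_at(old_front, stations)
  structure(list(stations = stations, distances = distances, spacing = spacing),
            class = "growth_profile")
}

#' @export
print.growth_profile <- function(x, ...) {
  cat(sprintf("<growth_profile> %d stations, spacing %g px, mean distance %.2f px\n",
              length(x$stations), x$spacing, mean(x$distances)))
  invisible(x)
}

#' Convert a distance profile to growth rates
#'
#' Divides each per-station label separation by the time elapsed between the
#' two fluorochrome administrations: `rate = distance * um_per_px /
#' delta_days` (um/day). Stations are normalised to `s` in `[0, 1]` with
#' `s = 1` at the anterior edge and `s = 0` at the posterior edge.
#'
#' @param profile a [distance_profile()] result.
#' @param cal the image [calibration()]. `delta_days` must be the animal's
#'   actual label interval; it is never pooled or defaulted.
#' @return An object of class `rate_profile` with fields `s` and `rates`
#'   (um/day).
#' @export
rates_from_profile <- function(profile, cal) {
  stopifnot(inherits(profile, "growth_profile"), inherits(cal, "calibration"))
  if (mean(profile$distances) < 0) {
    warning("mean front separation is negative: fronts may be swapped")
  }
  rng <- range(profile$stations)
  structure(list(
    s = (profile$stations - rng[1]) / (rng[2] - rng[1]),
    rates = profile$distances * cal$um_per_px / cal$delta_days),
    class = "rate_profile")
}

#' @export
print.rate_profile <- function(x, ...) {
  cat(sprintf("<rate_profile> %d stations, mean rate %.2f um/day\n",
              length(x$s), mean(x$rates)))
  invisible(x)
}

new_regional_rates <- function(anterior_q, middle_h, posterior_q, overall,
                               uae = NULL) {
  structure(list(anterior_q = anterior_q, middle_h = middle_h,
                 posterior_q = posterior_q, overall = overall, uae = uae),
            class = "regional_rates")
}

#' Construct regional rates from explicit region means
#'
#' Low-level constructor used by the cohort simulator and by disk-level
#' combination; [regional_rates()] is the measurement path.
#'
#' @param anterior_q,middle_h,posterior_q,overall region mean rates (um/day).
#' @param uae optional unossified-anterior-epiphysis mean rate (um/day).
#' @return a `regional_rates` object.
#' @export
as_regional_rates <- function(anterior_q, middle_h, posterior_q, overall,
                              uae = NULL) {
  vals <- c(anterior_q, middle_h, posterior_q, overall, uae)
  stopifnot(is.numeric(vals), all(is.finite(vals)))
  new_regional_rates(anterior_q, middle_h, posterior_q, overall, uae)
}

#' Regional growth-rate summaries of a rate profile
#'
#' Averages the per-station rates over the anatomically motivated regions of
#' the vertebral endplate: posterior quarter `s` in `[0, 0.25]`, middle half
#' `(0.25, 0.75]`, anterior quarter `(0.75, 1]`, plus the overall mean and,
#' optionally, the mean under the unossified anterior epiphysis (UAE) over a
#' caller-supplied normalised interval. Regions partition the normalised A-P
#' chord extent, not arc length.
#'
#' @param rp a [rates_from_profile()] rate profile with >= 8 stations.
#' @param uae_interval optional [interval()] of normalised positions for the
#'   UAE region.
#' @return An object of class `regional_rates` with fields `anterior_q`,
#'   `middle_h`, `posterior_q`, `overall`, `uae` (um/day).
#' @export
regional_rates <- function(rp, uae_interval = NULL) {
  stopifnot(inherits(rp, "rate_profile"))
  if (length(rp$s) < 8) stop("need at least 8 stations for regional rates",
                             call. = FALSE)
  post <- rp$s <= 0.25
  mid <- rp$s > 0.25 & rp$s <= 0.75
  ant <- rp$s > 0.75
  if (!any(post) || !any(mid) || !any(ant)) {
    stop("a region is empty after binning", call. = FALSE)
  }
  uae <- NULL
  if (!is.null(uae_interval)) {
    stopifnot(inherits(uae_interval, "interval"))
    sel <- rp$s >= uae_interval$lo & rp$s <= uae_interval$hi
    if (!any(sel)) stop("UAE interval contains no stations", call. = FALSE)
    uae <- mean(rp$rates[sel])
  }
  new_regional_rates(mean(rp$rates[ant]), mean(rp$rates[mid]),
                     mean(rp$rates[post]), mean(rp$rates), uae)
}

#' @export
print.regional_rates <- function(x, ...) {
  cat(sprintf(
    "<regional_rates> ant 1/4 %.2f | mid 1/2 %.2f | post 1/4 %.2f | overall %.2f um/day%s\n",
    x$anterior_q, x$middle_h, x$posterior_q, x$overall,
    if (is.null(x$uae)) "" else sprintf(" | UAE %.2f", x$uae)))
  invisible(x)
}

#' Percent growth modulation
#'
#' The primary outcome statistic: the anterior-posterior growth-rate
#' difference normalised by the overall mean physeal rate,
#'
#' \deqn{\%GM = 100 \cdot \frac{r_{ant\,1/4} - r_{post\,1/4}}{r_{overall}}}
#'
#' Normalising by the overall rate makes the statistic comparable across
#' animals growing at different speeds. In a kyphotic spine, positive values
#' indicate therapeutic (kyphosis-correcting) modulation — the anterior
#' column outgrowing the posterior — and negative values indicate worsening
#' kyphosis.
#'
#' @param rr a [regional_rates()] object with nonzero overall rate.
#' @return percent growth modulation (signed).
#' @examples
#' percent_growth_modulation(as_regional_rates(2, 1.5, 1, 1.5))  # 66.67
#' @export
percent_growth_modulation <- function(rr) {
  stopifnot(inherits(rr, "regional_rates"))
  if (!is.finite(rr$overall) || rr$overall == 0) {
    stop("percent growth modulation is undefined at zero overall rate",
         call. = FALSE)
  }
  100 * (rr$anterior_q - rr$posterior_q) / rr$overall
}

#' Combine the two physes of a disk space
#'
#' Each tethered disk space pairs the distal physis of its proximal vertebra
#' with the proximal physis of its distal vertebra. The disk-level growth is
#' their region-wise sum; disk-level percent growth modulation is then
#' computed from the summed regional rates.
#'
#' @param proximal_vertebra_distal regional rates of the proximal vertebra's
#'   distal physis (um/day).
#' @param distal_vertebra_proximal regional rates of the distal vertebra's
#'   proximal physis (um/day).
#' @return summed `regional_rates`; `uae` is kept only when both inputs carry
#'   it (otherwise dropped with a warning).
#' @export
combine_disk <- function(proximal_vertebra_distal, distal_vertebra_proximal) {
  a <- proximal_vertebra_distal; b <- distal_vertebra_proximal
  stopifnot(inherits(a, "regional_rates"), inherits(b, "regional_rates"))
  uae <- NULL
  if (!is.null(a$uae) && !is.null(b$uae)) {
    uae <- a$uae + b$uae
  } else if (xor(is.null(a$uae), is.null(b$uae))) {
    warning("UAE rate present in only one physis; omitted from the disk sum")
  }
  new_regional_rates(a$anterior_q + b$anterior_q, a$middle_h + b$middle_h,
                     a$posterior_q + b$posterior_q, a$overall + b$overall, uae)
}

#' Measure one annotated physis end to end
#'
#' Convenience wrapper: resolves the frame, builds both fronts, computes the
#' distance profile, converts to rates, and summarises regionally.
#'
#' @param ann an [annotation_set()].
#' @param spacing station sampling step, px.
#' @param uae_interval optional normalised [interval()] for the UAE region.
#' @return list with `frame`, `profile`, `rate_profile`, `regional`,
#'   `pct_growth_modulation`.
#' @export
measure_physis <- function(ann, spacing = 1, uae_interval = NULL) {
  stopifnot(inherits(ann, "annotation_set"))
  fr <- resolve_frame(ann)
  old <- build_front(ann$fronts$alizarin, fr, "alizarin")
  new <- build_front(ann$fronts$oxytetracycline, fr, "oxytetracycline")
  prof <- distance_profile(old, new, spacing = spacing)
  rp <- rates_from_profile(prof, ann$calibration)
  rr <- regional_rates(rp, uae_interval)
  list(frame = fr, profile = prof, rate_profile = rp, regional = rr,
       pct_growth_modulation = percent_growth_modulation(rr))
}
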