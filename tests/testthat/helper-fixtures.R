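# Fixtures are built in code at test time; no binary files.

# A fully populated, internally consistent annotation set: flat alizarin
# front at height 100, oxytetracycline at 130, frame along the x axis.
make_test_annotation <- function(with_optionals = TRUE) {
  base <- list(
    image_id = "fixture-01",
    calibration = calibration(um_per_px = 0.5, delta_days = 13),
    fronts = list(
      alizarin = cbind(seq(0, 200, by = 20), 100 + 0 * seq(0, 200, by = 20)),
      oxytetracycline = cbind(seq(0, 200, by = 25), rep(130, 9))),
    frame_spec = list(chord_start = c(0, 0), chord_end = c(200, 0),
                      growth_sign = 1))
  if (!with_optionals) {
    return(do.call(annotation_set, base))
  }
  base$channel_map <- c(alizarin = 1L, oxytetracycline = 2L)
  base$zone_polygons <- list(
    list(zone = "hypertrophic",
         polygon = rbind(c(0, 100), c(200, 100), c(200, 150), c(0, 150)),
         region_tag = NULL),
    list(zone = "proliferative_reserve",
         polygon = rbind(c(0, 150), c(200, 150), c(200, 230), c(0, 230)),
         region_tag = NULL))
  base$epiphysis_intervals <- list(
    list(physis_end = "proximal", ossified = interval(20, 180),
         total = interval(0, 200)))
  base$vertebra_interval <- interval(0, 200)
  base$np_polygon <- rbind(c(80, 40), c(120, 40), c(120, 60), c(80, 60))
  base$endplate_lines <- list(
    list(role = "cranial", p1 = c(0, 0), p2 = c(200, 10)),
    list(role = "caudal", p1 = c(0, 300), p2 = c(200, 290)))
  do.call(annotation_set, base)
}

# Independent piecewise-linear interpolation oracle (no package code).
oracle_interp <- function(xs, ys, x) {
  sapply(x, function(xx) {
    i <- max(which(xs <= xx + 1e-12))
    if (i == length(xs)) return(ys[i])
    ys[i] + (ys[i + 1] - ys[i]) * (xx - xs[i]) / (xs[i + 1] - xs[i])
  })
}

# Shoelace polygon area oracle.
oracle_area <- function(m) {
  n <- nrow(m)
  j <- c(2:n, 1)
  abs(sum(m[, 1] * m[j, 2] - m[j, 1] * m[, 2])) / 2
}

# Build a rate profile directly (bypassing image geometry) for statistic
# tests: n uniform stations, given rate vector.
make_rate_profile <- function(rates) {
  structure(list(s = seq(0, 1, length.out = length(rates)), rates = rates),
            class = "rate_profile")
}

# Linear-field fixture: old front flat at 0 over [0, 100], new at 30 + 0.2 x.
make_linear_field <- function() {
  fr <- make_frame(c(0, 0), c(100, 0), 1)
  list(frame = fr,
       old = build_front(rbind(c(0, 0), c(100, 0)), fr, "alizarin"),
       new = build_front(rbind(c(0, 30), c(100, 50)), fr, "oxytetracycline"))
}
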