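test_that("flat and identical fronts give constant and zero distance fields", {
  fr <- make_frame(c(0, 0), c(200, 0), 1)
  old <- build_front(rbind(c(0, 100), c(200, 100)), fr, "alizarin")
  new <- build_front(rbind(c(0, 130), c(200, 130)), fr, "oxytetracycline")
  prof <- distance_profile(old, new)
  expect_true(all(prof$distances == 30))

  same <- build_front(rbind(c(0, 100), c(200, 100)), fr, "oxytetracycline")
  expect_true(all(distance_profile(old, same)$distances == 0))
})

test_that("the linear separation field reproduces its closed-form regional means", {
  lf <- make_linear_field()
  # closed form: d(x) = 30 + 0.2 x over [0, 100]; continuous region means
  # are 47.5 (anterior quarter), 40 (middle half), 32.5 (posterior quarter),
  # 40 overall; fine sampling converges to them at O(spacing)
  prof <- distance_profile(lf$old, lf$new, spacing = 0.01)
  rp <- rates_from_profile(prof, calibration(1, 10))
  rr <- regional_rates(rp)
  expect_equal(rr$anterior_q, 4.75, tolerance = 1e-3)
  expect_equal(rr$middle_h, 4.00, tolerance = 1e-3)
  expect_equal(rr$posterior_q, 3.25, tolerance = 1e-3)
  expect_equal(rr$overall, 4.00, tolerance = 1e-3)
  expect_equal(percent_growth_modulation(rr), 37.5, tolerance = 1e-2)
})

test_that("distances are measured only over the front overlap", {
  fr <- make_frame(c(0, 0), c(300, 0), 1)
  old <- build_front(rbind(c(0, 0), c(200, 0)), fr, "alizarin")
  new <- build_front(rbind(c(100, 30), c(300, 30)), fr, "oxytetracycline")
  prof <- distance_profile(old, new)
  expect_equal(range(prof$stations), c(100, 200))

  short <- build_front(rbind(c(198, 30), c(300, 30)), fr, "oxytetracycline")
  expect_error(distance_profile(old, short), "insufficient front overlap")
})

test_that("distance_profile at spacing 1 matches brute-force per-pixel interpolation", {
  set.seed(21)
  fr <- make_frame(c(0, 0), c(400, 0), 1)
  for (rep in 1:5) {
    xs_o <- sort(sample(0:400, 15)); xs_n <- sort(sample(0:400, 12))
    old <- build_front(cbind(xs_o, runif(15, 80, 120)), fr, "alizarin")
    new <- build_front(cbind(xs_n, runif(12, 180, 260)), fr, "oxytetracycline")
    prof <- distance_profile(old, new, spacing = 1)
    lo <- max(min(old$stations), min(new$stations))
    hi <- min(max(old$stations), max(new$stations))
    xs <- seq(lo, hi, by = 1)
    brute <- oracle_interp(new$stations, new$heights, xs) -
      oracle_interp(old$stations, old$heights, xs)
    expect_equal(prof$stations, xs)
    expect_equal(prof$distances, brute, tolerance = 1e-12)
  }
})

test_that("rates scale by calibration and warn on swapped fronts", {
  fr <- make_frame(c(0, 0), c(200, 0), 1)
  old <- build_front(rbind(c(0, 100), c(200, 100)), fr, "alizarin")
  new <- build_front(rbind(c(0, 130), c(200, 130)), fr, "oxytetracycline")
  prof <- distance_profile(old, new)
  rp <- rates_from_profile(prof, calibration(0.5, 12))
  expect_true(all(rp$rates == 30 * 0.5 / 12))  # 1.25 um/day
  rp2 <- rates_from_profile(prof, calibration(1.0, 12))
  expect_equal(rp2$rates, 2 * rp$rates)

  expect_warning(rates_from_profile(distance_profile(new, old),
                                    calibration(0.5, 12)),
                 "swapped")
})

test_that("regional means obey the 1/4-1/2-1/4 weight identity on uniform stations", {
  set.seed(31)
  for (k in c(2, 10, 25)) {
    rp <- make_rate_profile(runif(4 * k, 0, 5))
    rr <- regional_rates(rp)
    lhs <- 0.25 * rr$anterior_q + 0.5 * rr$middle_h + 0.25 * rr$posterior_q
    expect_equal(lhs, rr$overall, tolerance = 1e-9)
  }
  # constant profile: every region equals the constant
  rc <- regional_rates(make_rate_profile(rep(2, 16)))
  expect_equal(c(rc$anterior_q, rc$middle_h, rc$posterior_q, rc$overall),
               rep(2, 4))
})

test_that("reversing the profile swaps anterior and posterior quarters exactly", {
  set.seed(41)
  rates <- runif(40, 1, 6)
  a <- regional_rates(make_rate_profile(rates))
  b <- regional_rates(make_rate_profile(rev(rates)))
  expect_identical(a$anterior_q, b$posterior_q)
  expect_identical(a$posterior_q, b$anterior_q)
  expect_identical(a$middle_h, b$middle_h)
  expect_equal(percent_growth_modulation(a), -percent_growth_modulation(b))
})

test_that("the UAE mean is computed only when an interval is supplied", {
  rp <- make_rate_profile(seq(0, 3.9, by = 0.1))
  expect_null(regional_rates(rp)$uae)
  rr <- regional_rates(rp, uae_interval = interval(0.75, 1))
  expect_equal(rr$uae, mean(rp$rates[rp$s >= 0.75]))
})

test_that("percent growth modulation follows its printed definition and sign", {
  expect_equal(percent_growth_modulation(as_regional_rates(2, 1.5, 1, 1.5)),
               100 * (2 - 1) / 1.5)
  expect_equal(percent_growth_modulation(as_regional_rates(1.7, 2, 1.7, 1.8)), 0)
  # kyphogenic: posterior outgrows anterior
  expect_equal(percent_growth_modulation(as_regional_rates(1, 1.5, 2, 1.5)),
               -100 / 1.5)
  expect_error(percent_growth_modulation(as_regional_rates(1, 0, -1, 0)),
               "zero overall")
})

test_that("percent growth modulation is invariant to calibration", {
  lf <- make_linear_field()
  prof <- distance_profile(lf$old, lf$new, spacing = 0.5)
  set.seed(51)
  gms <- replicate(20, {
    cal <- calibration(runif(1, 0.1, 10), runif(1, 1, 60))
    percent_growth_modulation(regional_rates(rates_from_profile(prof, cal)))
  })
  expect_equal(max(gms) - min(gms), 0)
})

test_that("disk combination sums region-wise and keeps the sum rule", {
  a <- as_regional_rates(100, 95, 80, 90)
  b <- as_regional_rates(80, 75, 60, 70)
  d <- combine_disk(a, b)
  expect_equal(d$anterior_q, 180)
  expect_equal(d$overall, 160)
  expect_identical(d$overall, a$overall + b$overall)

  zero <- as_regional_rates(0, 0, 0, 0)
  dz <- combine_disk(a, zero)
  expect_equal(unclass(dz)[1:4], unclass(a)[1:4])

  # mirror-modulated physes cancel at the disk level
  p1 <- as_regional_rates(110, 100, 90, 100)   # +20%
  p2 <- as_regional_rates(90, 100, 110, 100)   # -20%
  expect_equal(percent_growth_modulation(combine_disk(p1, p2)), 0)

  # UAE present on one side only is dropped with a warning
  au <- as_regional_rates(100, 95, 80, 90, uae = 105)
  expect_warning(du <- combine_disk(au, b), "UAE")
  expect_null(du$uae)
  expect_equal(combine_disk(au, as_regional_rates(80, 75, 60, 70, uae = 85))$uae,
               190)
})
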