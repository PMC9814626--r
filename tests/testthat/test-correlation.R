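test_that("FFT autocorrelation equals the sliding-shift oracle", {
  set.seed(2)
  img <- matrix(runif(64), 8, 8)
  a <- autocorrelation_2d(img)
  o <- acf2d_direct(img)
  expect_equal(a$counts, o$counts)
  expect_lt(max(abs(a$corr - o$corr), na.rm = TRUE), 1e-10)

  # with a non-trivial mask
  mask <- shgmap:::disk_mask(c(8, 8), c(3.5, 3.5), 3.6)
  am <- autocorrelation_2d(img, mask)
  om <- acf2d_direct(img, mask)
  expect_equal(am$counts, om$counts)
  expect_lt(max(abs(am$corr - om$corr), na.rm = TRUE), 1e-10)
})

test_that("FFT/oracle agreement holds across small random stacks", {
  set.seed(31)
  for (rep in 1:5) {
    nr <- sample(5:16, 1); nc <- sample(5:16, 1)
    img <- matrix(rnorm(nr * nc), nr, nc)
    mask <- matrix(runif(nr * nc) > 0.2, nr, nc)
    if (sum(mask) < 4) next
    a <- autocorrelation_2d(img, mask)
    o <- acf2d_direct(img, mask)
    expect_lt(max(abs(a$corr - o$corr), na.rm = TRUE), 1e-10)
  }
})

test_that("SACF is 1 at zero lag and bounded by 1 over returned lags", {
  sim <- small_sim(seed = 8, n_frames = 3)
  corr <- subtract_background(sim$stack, matrix(50, 64, 64))
  for (f in corr$frames) {
    s <- sacf(f, sim$truth$mask)
    expect_equal(s$values[1], 1)
    expect_true(all(s$values <= 1 + 1e-8))
  }
})

test_that("SACF of a Gaussian spot is Gaussian with width scaled by sqrt(2)", {
  # field much larger than the spot: the mean-subtraction drift in the ACF
  # tail scales with the spot's area fraction and would bias the width up
  spot_sacf_width <- function(n, s0) {
    x <- matrix(rep(0:(n - 1), each = n), n, n)
    y <- matrix(rep(0:(n - 1), times = n), n, n)
    img <- exp(-((x - (n - 1) / 2)^2 + (y - (n - 1) / 2)^2) / (2 * s0^2))
    fit_gaussian(sacf(img, pixel_size = 1000))$width  # 1 um/px: lags = px
  }
  w <- spot_sacf_width(192, 3)
  expect_lt(abs(w - 3 * sqrt(2)) / (3 * sqrt(2)), 0.02)
  # the finite-field bias shrinks as the field grows
  w_small <- spot_sacf_width(96, 3)
  expect_lt(abs(w - 3 * sqrt(2)), abs(w_small - 3 * sqrt(2)))
})

test_that("SACF of white noise is a delta at zero lag", {
  set.seed(12)
  img <- matrix(rnorm(96 * 96), 96, 96)
  s <- sacf(img, pixel_size = 1000)
  expect_equal(s$values[1], 1)
  expect_lt(max(abs(s$values[-1])), 5 / sqrt(96 * 96))
})

test_that("constant fields are rejected as degenerate", {
  expect_error(sacf(matrix(4, 32, 32)), "degenerate")
})

test_that("Gaussian fit recovers exact parameters and the analytic FWHM factor", {
  lags <- seq(0, 6, by = 0.25)
  vals <- exp(-lags^2 / 2)
  fit <- fit_gaussian(correlogram(lags, vals, "spatial"))
  expect_equal(fit$width, 1, tolerance = 1e-6)
  expect_equal(fit$fwhm, 2 * sqrt(2 * log(2)) * fit$width)
  expect_equal(fit$fwhm, 2.3548, tolerance = 1e-4)
  # offset recovery, noiseless
  fit2 <- fit_gaussian(correlogram(lags, 0.9 * exp(-lags^2 / 2) + 0.1,
                                   "spatial"))
  expect_lt(abs(fit2$offset - 0.1), 1e-6)
  expect_error(fit_gaussian(correlogram(0:3, exp(-(0:3)), "spatial")),
               "at least 5")
})

test_that("Gaussian fit width is robust to 1 percent noise", {
  set.seed(44)
  lags <- seq(0, 5, length.out = 50)
  errs <- replicate(100, {
    vals <- exp(-lags^2 / 2) + rnorm(50, 0, 0.01)
    fit_gaussian(correlogram(lags, vals, "spatial"))$width - 1
  })
  expect_lt(max(abs(errs)), 0.05)
})

test_that("domain radius round-trips through the SACF at 1.5 um", {
  sim <- small_sim(seed = 5, n_frames = 20, mean_count = 12)
  corr <- subtract_background(sim$stack, matrix(50, 64, 64))
  est <- estimate_radius(corr, sim$truth$mask)
  expect_lt(abs(est$radius - 1.5) / 1.5, 0.10)
})

test_that("radius estimate is independent of domain amplitude", {
  a <- small_sim(seed = 6, n_frames = 5, potential = -0.05,
                 shot_noise = FALSE, hrs = 0)
  b <- small_sim(seed = 6, n_frames = 5, potential = -0.5,
                 shot_noise = FALSE, hrs = 0)
  ra <- estimate_radius(a$stack, a$truth$mask)
  rb <- estimate_radius(b$stack, b$truth$mask)
  expect_lt(abs(ra$radius - rb$radius) / ra$radius, 0.01)
})

test_that("radius in um scales with the pixel-size metadata", {
  sim <- small_sim(seed = 7, n_frames = 3)
  corr <- subtract_background(sim$stack, matrix(50, 64, 64))
  r1 <- estimate_radius(corr, sim$truth$mask)
  wide <- corr; wide$pixel_size <- 860
  r2 <- estimate_radius(wide, sim$truth$mask)
  expect_equal(r2$radius / r1$radius, 2, tolerance = 1e-9)
})

test_that("TACF of a static stack is 1 at all lags", {
  f <- matrix(runif(64 * 64), 64, 64)
  s <- sh_stack(rep(list(f), 6))
  g <- tacf(s)
  expect_true(all(g$values == 1))
  expect_true(g$meta$static)
  expect_error(tacf(sh_stack(list(f, f))), "at least 3")
})

test_that("short-lived domains show no frame-to-frame correlation", {
  sim <- small_sim(seed = 10, n_frames = 20, lifetime = 0.1)
  corr <- subtract_background(sim$stack, matrix(50, 64, 64))
  g <- tacf(corr, sim$truth$mask)
  expect_lt(g$values[g$lags == 1], 0.1)
})

test_that("long-lived domains show strong lag-1 correlation", {
  cfg <- domain_field_config(mean_domain_count = 8, lifetime_frames = 20,
                             registry_coupling = 0, aperture_diameter = 18,
                             seed = 13)
  sim <- simulate_stack(cfg, n_frames = 400, dim = c(48, 48))
  corr <- subtract_background(sim$stack, matrix(50, 48, 48))
  g <- tacf(corr, sim$truth$mask, max_lag = 10)
  expect_gt(g$values[g$lags == 1], 0.8)
})

test_that("lifetime logic: unresolved bound, static flag, and 1/e recovery", {
  fast <- small_sim(seed = 14, n_frames = 20, lifetime = 0.1)
  cf <- subtract_background(fast$stack, matrix(50, 64, 64))
  lt <- estimate_lifetime(cf, fast$truth$mask)
  expect_false(lt$resolved)
  expect_equal(lt$upper_bound_ms, 560)

  st <- estimate_lifetime(sh_stack(rep(list(matrix(runif(36), 6, 6)), 5)))
  expect_true(st$resolved)
  expect_identical(st$note, "static")

  taus <- vapply(1:5, function(s) {
    cfg <- domain_field_config(mean_domain_count = 5, lifetime_frames = 5,
                               registry_coupling = 0, aperture_diameter = 22,
                               seed = s)
    sim <- simulate_stack(cfg, n_frames = 60, dim = c(56, 56))
    cc <- subtract_background(sim$stack, matrix(50, 56, 56))
    estimate_lifetime(cc, sim$truth$mask)$lifetime_frames
  }, numeric(1))
  expect_lt(abs(median(taus) - 5) / 5, 0.3)
})
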