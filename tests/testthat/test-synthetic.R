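test_that("symmetric leaflets radiate no coherent signal", {
  d <- c(16, 16)
  opt <- optical_model(chi2_top = 0.3, chi2_bottom = 0.3)
  phi <- matrix(runif(prod(d), -0.3, 0.3), d[1], d[2])
  tr <- ground_truth(phi, phi, hrs_level = 42)
  img <- render_intensity(opt, tr)
  expect_equal(img, matrix(42, d[1], d[2]))
})

test_that("coherent intensity follows the quadratic law in the potential difference", {
  tr <- uniform_truth(0.1)
  img <- render_intensity(optical_model(gain = 1), tr)
  expect_equal(img[1, 1], 0.01)
  tr2 <- uniform_truth(0.2)
  img2 <- render_intensity(optical_model(gain = 1), tr2)
  expect_equal(img2[1, 1] / img[1, 1], 4)
  # machine-precision proportionality over random amplitudes
  for (phi in c(0.03, -0.17, 0.45)) {
    r <- render_intensity(optical_model(gain = 7, pump_intensity = 2),
                          uniform_truth(phi))[1, 1]
    expect_equal(r, 7 * 4 * phi^2, tolerance = 1e-14)
  }
})

test_that("swapping leaflet labels leaves the intensity unchanged", {
  d <- c(12, 12)
  set.seed(7)
  pt <- matrix(rnorm(prod(d), 0, 0.2), d[1], d[2])
  pb <- matrix(rnorm(prod(d), 0, 0.2), d[1], d[2])
  a <- render_intensity(optical_model(chi2_top = 0.2, chi2_bottom = 0.5),
                        ground_truth(pt, pb, hrs_level = 10))
  b <- render_intensity(optical_model(chi2_top = 0.5, chi2_bottom = 0.2),
                        ground_truth(pb, pt, hrs_level = 10))
  expect_equal(a, b, tolerance = 1e-14)
})

test_that("mismatched grids are rejected", {
  tr <- ground_truth(matrix(0, 8, 8), matrix(0, 8, 9))
  expect_error(render_intensity(optical_model(), tr), "grids do not match")
})

test_that("identical config and seed give bit-identical stacks", {
  a <- small_sim(seed = 11)
  b <- small_sim(seed = 11)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth$domain_catalog, b$truth$domain_catalog)
  c <- small_sim(seed = 12)
  expect_false(identical(a$stack$frames, c$stack$frames))
})

test_that("an empty domain field renders background only", {
  sim <- small_sim(mean_count = 0, shot_noise = TRUE, hrs = 40,
                   n_frames = 30)
  noiseless <- render_intensity(optical_model(), sim$truth)
  expect_true(all(vapply(noiseless, function(f) all(f == 40), logical(1))))
  m <- mean(vapply(sim$stack$frames, mean, numeric(1)))
  # Poisson mean 40 over 30*64*64 draws
  expect_lt(abs(m - 40), 3 * sqrt(40 / (30 * 64 * 64)))
})

test_that("perfect leaflet registry cancels the coherent signal", {
  cfg <- domain_field_config(mean_domain_count = 15, registry_coupling = 1,
                             aperture_diameter = 24, seed = 3)
  sim <- simulate_stack(cfg, n_frames = 3, dim = c(64, 64), shot_noise = FALSE,
                        hrs_level = 25)
  for (f in sim$stack$frames) expect_equal(f, matrix(25, 64, 64))
})

test_that("shot-noise sample mean converges to the noiseless render", {
  tr <- uniform_truth(0.3, d = c(24, 24), hrs = 20)
  img <- render_intensity(optical_model(gain = 2000), tr)  # 200 counts
  n <- 10000
  acc <- with(list(), {
    set.seed(5)
    s <- matrix(0, 24, 24)
    for (i in seq_len(n)) s <- s + rpois(length(img), img)
    s / n
  })
  expect_lt(max(abs(acc - img) / img), 0.01)
})

test_that("sub-pixel domain radius is clamped with a warning", {
  cfg <- domain_field_config(mean_domain_count = 5, domain_radius = 0.2,
                             aperture_diameter = 24, seed = 1)
  expect_warning(simulate_stack(cfg, n_frames = 1, dim = c(64, 64)),
                 "clamped")
})

test_that("domain catalog entries lie inside the aperture", {
  sim <- small_sim(seed = 21, n_frames = 8, mean_count = 20)
  cat <- sim$truth$domain_catalog
  ctr <- (c(64, 64) - 1) / 2
  ap_px <- 24 * 1000 / 430 / 2
  r <- sqrt((cat$y - ctr[1])^2 + (cat$x - ctr[2])^2)
  expect_true(all(r <= ap_px + 1e-9))
})

test_that("bias sweep intensity is a parabola with vertex at the cancelling bias", {
  tr <- uniform_truth(-0.217, d = c(16, 16))
  biases <- seq(-0.1, 0.5, by = 0.1)
  sw <- simulate_bias_series(bias_series_config(biases), optical_model(), tr)
  series <- as_calibration_series(sw)
  means <- vapply(series$images, mean, numeric(1))
  # vertex at U = +0.217; symmetric sweep values match
  expect_equal(means[abs(series$biases - 0.117) < 1e-9],
               means[abs(series$biases - 0.317) < 1e-9], tolerance = 1e-12)
  expect_equal(min(5000 * (biases - 0.217)^2), min(means), tolerance = 1e-9)
  expect_error(bias_series_config(c(0, 0.1)), "3 distinct")
})
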