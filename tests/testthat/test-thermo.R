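test_that("capacitor conversion reproduces the tabulated charge densities", {
  expect_equal(round(potential_to_charge(-0.154), 2), -0.72)
  expect_equal(round(potential_to_charge(-0.070), 2), -0.33)
  expect_equal(round(potential_to_charge(-0.368), 1), -1.7)
  expect_equal(potential_to_charge(0), 0)
})

test_that("area capacitance is recomputed from the stated constants", {
  cap <- capacitor_model(epsilon = 2.1, thickness = 4e-9)
  expect_equal(cap$capacitance_per_area, 4.648e-3, tolerance = 1e-3)
  # recomputed, not stored: changing epsilon moves it proportionally
  expect_equal(capacitor_model(epsilon = 4.2)$capacitance_per_area,
               2 * cap$capacitance_per_area)
})

test_that("free-energy conversion reproduces the tabulated values", {
  expect_equal(round(as.numeric(potential_to_free_energy(-0.217)), 0), 17)
  expect_equal(round(as.numeric(potential_to_free_energy(-0.154)), 0), 12)
  expect_equal(round(as.numeric(potential_to_free_energy(-0.070)), 1), 5.4)
  expect_equal(round(as.numeric(potential_to_free_energy(-0.368)), 1), 28.6)
  expect_equal(as.numeric(potential_to_free_energy(0)), 0)
  # magnitude reported; sign kept in the attribute
  dg <- potential_to_free_energy(-0.2)
  expect_gt(as.numeric(dg), 0)
  expect_lt(attr(dg, "signed"), 0)
})

test_that("dissociation constant follows exp(-dG) and is strictly monotone", {
  expect_equal(free_energy_to_kd(0), 1)
  expect_equal(free_energy_to_kd(28.6), exp(-28.6))
  expect_equal(free_energy_to_kd(28.6), 3.8e-13, tolerance = 0.02)
  dg <- seq(0, 30, by = 0.5)
  expect_true(all(diff(free_energy_to_kd(dg)) < 0))
})

test_that("charge and free-energy conversions are homogeneous in the potential", {
  phi <- matrix(c(-0.3, -0.1, 0, 0.2), 2, 2)
  expect_equal(potential_to_charge(2 * phi), 2 * potential_to_charge(phi))
  a <- potential_to_free_energy(phi); attr(a, "signed") <- NULL
  b <- potential_to_free_energy(3 * phi); attr(b, "signed") <- NULL
  expect_equal(b, 3 * a)
})

test_that("domain segmentation recovers planted domains without false positives", {
  set.seed(20)
  hits <- 0; false_comp <- 0; planted <- 0
  for (s in 1:10) {
    sim <- small_sim(seed = 100 + s, n_frames = 1, mean_count = 10,
                     lifetime = 0.1, potential = -0.3)
    frame <- pmax(sim$stack$frames[[1]] - 50, 0)
    seg <- segment_domains(frame, sim$truth$mask,
                           background_stats = list(mean = 0, sd = sqrt(50)))
    cat0 <- sim$truth$domain_catalog
    cat0 <- cat0[cat0$frame == 1, ]
    planted <- planted + nrow(cat0)
    for (k in seq_len(nrow(cat0))) {
      iy <- round(cat0$y[k]) + 1; ix <- round(cat0$x[k]) + 1
      if (seg[iy, ix]) hits <- hits + 1
    }
    # any labelled pixel further than 2 radii from every planted center is false
    lab <- which(seg, arr.ind = TRUE)
    if (nrow(lab) > 0) {
      dmin <- sapply(seq_len(nrow(lab)), function(i)
        min(sqrt((lab[i, 1] - 1 - cat0$y)^2 + (lab[i, 2] - 1 - cat0$x)^2)))
      false_comp <- false_comp + sum(dmin > 2 * 1.5 * 1000 / 430)
    }
  }
  expect_gte(hits / planted, 0.9)
  expect_equal(false_comp, 0)
})

test_that("segmentation threshold is monotone and degenerate inputs behave", {
  u <- matrix(1, 16, 16)
  expect_equal(sum(segment_domains(u)), 0)  # uniform map: nothing above bg
  expect_error(segment_domains(u, matrix(FALSE, 16, 16)), "empty mask")
  sim <- small_sim(seed = 30, n_frames = 1, mean_count = 10)
  frame <- pmax(sim$stack$frames[[1]] - 50, 0)
  bs <- list(mean = 0, sd = sqrt(50))
  m2 <- segment_domains(frame, sim$truth$mask, bs, k = 2)
  m4 <- segment_domains(frame, sim$truth$mask, bs, k = 4)
  expect_true(all(!m4 | m2))  # raising the multiplier never grows the mask
})

test_that("summary table reports averages and domain ranges", {
  v <- matrix(2, 8, 8)
  all_mask <- matrix(TRUE, 8, 8)
  s <- summarize_maps(list(q = v), domain_mask = all_mask, mask = all_mask)
  expect_equal(s$average, 2)
  expect_equal(s$domain_sd, 0)
  expect_equal(c(s$domain_lo, s$domain_hi), c(2, 2))
  # planted two-level field
  m <- matrix(0, 10, 10); dm <- matrix(FALSE, 10, 10)
  dm[1:2, 1:5] <- TRUE; m[dm] <- 7
  s2 <- summarize_maps(list(q = m), dm)
  expect_equal(s2$average, 7 * sum(dm) / 100)
  # empty domain mask -> NA domain rows
  s3 <- summarize_maps(list(q = m), matrix(FALSE, 10, 10))
  expect_true(is.na(s3$domain_mean))
  expect_error(summarize_maps(list(q = m), dm, mask = matrix(FALSE, 10, 10)),
               "outside")
})

test_that("domain statistics round-trip the planted amplitude distribution", {
  # amplitudes drawn from N(287, 42) mV: the pooled per-domain peaks must
  # recover the distribution within the pipeline's 15% recovery margin
  sim <- small_sim(seed = 40, n_frames = 15, mean_count = 8, lifetime = 0.1,
                   potential = -0.287, amplitude_sd = 0.042)
  corr <- subtract_background(sim$stack, matrix(50, 64, 64))
  fit <- structure(list(scale = 5000, baseline = 0, vertex = 0,
                        per_pixel = FALSE), class = "calibration_fit")
  dp <- domain_potentials(corr, fit, sim$truth$mask, sign = -1)
  expect_gt(nrow(dp), 30)
  v <- abs(dp$value_V) * 1e3
  expect_lt(abs(mean(v) - 287) / 287, 0.15)
  expect_lt(abs((mean(v) - sd(v)) - 245) / 245, 0.2)
  expect_lt(abs((mean(v) + sd(v)) - 329) / 329, 0.2)
})
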