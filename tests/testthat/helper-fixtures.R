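# Shared fixtures and independent oracles for the test suite.

# Direct O(N^2) sliding-shift masked autocorrelation: the brute-force oracle
# for the FFT route. Enumerates every signed lag; pairs count only when both
# pixels are inside the mask.
acf2d_direct <- function(image, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  w <- mask * 1
  mu <- sum(image * w) / sum(w)
  f <- (image - mu) * w
  nr <- nrow(image); nc <- ncol(image)
  dys <- -(nr - 1):(nr - 1); dxs <- -(nc - 1):(nc - 1)
  g <- matrix(NA_real_, length(dys), length(dxs))
  cnt <- matrix(0, length(dys), length(dxs))
  for (a in seq_along(dys)) for (b in seq_along(dxs)) {
    dy <- dys[a]; dx <- dxs[b]
    s <- 0; n <- 0
    for (i in 1:nr) for (j in 1:nc) {
      i2 <- i + dy; j2 <- j + dx
      if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc &&
          mask[i, j] && mask[i2, j2]) {
        s <- s + f[i, j] * f[i2, j2]
        n <- n + 1
      }
    }
    cnt[a, b] <- n
    if (n >= 1) g[a, b] <- s / n
  }
  list(corr = g / g[nr, nc], counts = cnt)
}

# Uniform static scene: every pixel carries the same potential difference.
uniform_truth <- function(phi, d = c(32, 32), hrs = 0) {
  ground_truth(matrix(phi, d[1], d[2]), matrix(0, d[1], d[2]),
               hrs_level = hrs)
}

# Small simulated acquisition used by several tests.
small_sim <- function(seed = 1, n_frames = 10, lifetime = 0.3,
                      mean_count = 12, radius = 1.5, dim = c(64, 64),
                      aperture = 24, potential = -0.25, amplitude_sd = 0,
                      coupling = 0, shot_noise = TRUE, hrs = 50) {
  cfg <- domain_field_config(
    mean_domain_count = mean_count, domain_radius = radius,
    domain_potential = potential, amplitude_sd = amplitude_sd,
    lifetime_frames = lifetime, registry_coupling = coupling,
    aperture_diameter = aperture, seed = seed)
  simulate_stack(cfg, optical_model(), n_frames = n_frames, dim = dim,
                 hrs_level = hrs)
}
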