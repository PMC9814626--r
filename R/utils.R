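# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Logical disk mask on an nrow x ncol pixel grid. Center and radius in pixel
# units, 0-based pixel-centered coordinates (position = index * pixel size).
disk_mask <- function(dim, center, radius) {
  x <- matrix(rep(seq_len(dim[2]) - 1, each = dim[1]), dim[1], dim[2])
  y <- matrix(rep(seq_len(dim[1]) - 1, times = dim[2]), dim[1], dim[2])
  (x - center[2])^2 + (y - center[1])^2 <= radius^2
}

# 3x3 median filter with edge replication; used before domain thresholding.
median3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  pad[1, ] <- pad[2, ]; pad[nr + 2, ] <- pad[nr + 1, ]
  pad[, 1] <- pad[, 2]; pad[, nc + 2] <- pad[, nc + 1]
  stack <- vapply(1:9, function(k) {
    di <- (k - 1) %% 3; dj <- (k - 1) %/% 3
    as.vector(pad[(1 + di):(nr + di), (1 + dj):(nc + dj)])
  }, numeric(nr * nc))
  matrix(apply(stack, 1, stats::median), nr, nc)
}

fwhm_factor <- function() 2 * sqrt(2 * log(2))
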