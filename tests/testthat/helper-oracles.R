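# Independent brute-force reference implementations used to cross-check the
# package. Deliberately naive: explicit stacks and full-grid scans, no code
# shared with the implementations under test.

# Depth-first flood fill with an explicit stack and nested neighbour loops.
naive_cc <- function(bin, seed, connectivity = 26) {
  d <- dim(bin)
  out <- array(FALSE, d)
  if (!bin[seed[1], seed[2], seed[3]]) return(out)
  stack <- list(as.integer(seed))
  out[seed[1], seed[2], seed[3]] <- TRUE
  while (length(stack) > 0L) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      if (connectivity == 6 && abs(dx) + abs(dy) + abs(dz) != 1) next
      i <- v[1] + dx; j <- v[2] + dy; k <- v[3] + dz
      if (i < 1 || i > d[1] || j < 1 || j > d[2] || k < 1 || k > d[3]) next
      if (bin[i, j, k] && !out[i, j, k]) {
        out[i, j, k] <- TRUE
        stack[[length(stack) + 1L]] <- c(i, j, k)
      }
    }
  }
  out
}

# Full-grid threshold segmentation: scan every voxel, then naive flood fill.
naive_segment <- function(vol, search_mask, seed, threshold) {
  d <- dim(vol$values)
  supra <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    supra[i, j, k] <- search_mask[i, j, k] && vol$values[i, j, k] >= threshold
  naive_cc(supra, seed)
}

# Metric extraction by explicit accumulation.
naive_metrics <- function(vol, mask) {
  d <- dim(vol$values)
  n <- 0L; s <- 0; mx <- -Inf
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (mask[i, j, k]) {
      n <- n + 1L
      s <- s + vol$values[i, j, k]
      if (vol$values[i, j, k] > mx) mx <- vol$values[i, j, k]
    }
  if (n == 0L) return(list(suvmax = 0, suvmean = 0, mtv_ml = 0, tlg = 0))
  mtv <- n * prod(vol$spacing) / 1000
  list(suvmax = mx, suvmean = s / n, mtv_ml = mtv, tlg = mtv * s / n)
}

# SUVpeak by exhaustive search: hottest masked voxel (assumes no ties),
# then mean over voxels whose centres fall in the 1 mL sphere.
naive_suvpeak <- function(vol, mask) {
  d <- dim(vol$values)
  best <- NULL; mx <- -Inf
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (mask[i, j, k] && vol$values[i, j, k] > mx) {
      mx <- vol$values[i, j, k]; best <- c(i, j, k)
    }
  r <- (3 / (4 * pi) * 1000)^(1 / 3)
  ctr <- vol$origin + (best - 1) * vol$spacing
  s <- 0; n <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- vol$origin + (c(i, j, k) - 1) * vol$spacing
    if (sum((p - ctr)^2) <= r^2) { s <- s + vol$values[i, j, k]; n <- n + 1L }
  }
  s / n
}

# Centre value of a uniform sphere (radius R, amplitude A over background B)
# convolved with an isotropic Gaussian of SD sigma: closed form.
blurred_sphere_center <- function(A, B, R, sigma) {
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  B + (A - B) * (erf(R / (sqrt(2) * sigma)) -
                 sqrt(2 / pi) * (R / sigma) * exp(-R^2 / (2 * sigma^2)))
}
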