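# Shared fixtures and independent brute-force oracles used across tests.
# Oracles are deliberately written as direct enumerations, separate from the
# package's vectorized implementations.

# random non-empty blob mask: union of a few random spheres on a small grid
randomBlobMask <- function(shape, nBlobs = 2L, rmax = 4) {
  m <- array(0, shape)
  idx <- which(m == 0, arr.ind = TRUE)
  for (b in seq_len(nBlobs)) {
    ctr <- vapply(shape, function(n) runif(1, 2, n - 1), numeric(1))
    r <- runif(1, 1.2, rmax)
    d2 <- rowSums(sweep(idx, 2L, ctr)^2)
    m[idx[d2 <= r^2, , drop = FALSE]] <- 1
  }
  if (sum(m) == 0) m[ceiling(shape / 2)[1], ceiling(shape / 2)[2]] <- 1
  m
}

# counting oracle for the Dice coefficient
bruteDice <- function(x, y) {
  inter <- 0; nx <- 0; ny <- 0
  for (i in seq_along(x)) {
    if (x[i] == 1) nx <- nx + 1
    if (y[i] == 1) ny <- ny + 1
    if (x[i] == 1 && y[i] == 1) inter <- inter + 1
  }
  if (nx + ny == 0) return(1)
  2 * inter / (nx + ny)
}

# boundary voxels by explicit neighbour loops (outside grid = background)
bruteBoundary <- function(m) {
  d <- dim(m)
  r <- length(d)
  out <- NULL
  idx <- which(m == 1, arr.ind = TRUE)
  if (is.vector(idx)) idx <- matrix(idx, ncol = r)
  for (k in seq_len(nrow(idx))) {
    v <- idx[k, ]
    isB <- FALSE
    for (ax in seq_len(r)) for (off in c(-1L, 1L)) {
      nb <- v
      nb[ax] <- nb[ax] + off
      if (nb[ax] < 1 || nb[ax] > d[ax]) { isB <- TRUE; break }
      val <- if (r == 2) m[nb[1], nb[2]] else m[nb[1], nb[2], nb[3]]
      if (val == 0) { isB <- TRUE; break }
    }
    if (isB) out <- rbind(out, v)
  }
  out
}

# all-pairs brute-force HD95 (pooled directed nearest distances, linear
# interpolation percentile) and the exact Hausdorff distance
bruteHD <- function(x, y, spacing, percentile = 95) {
  A <- sweep(bruteBoundary(x) - 1, 2L, spacing, "*")
  B <- sweep(bruteBoundary(y) - 1, 2L, spacing, "*")
  dxy <- numeric(nrow(A))
  for (i in seq_len(nrow(A)))
    dxy[i] <- min(sqrt(rowSums(sweep(B, 2L, A[i, ])^2)))
  dyx <- numeric(nrow(B))
  for (i in seq_len(nrow(B)))
    dyx[i] <- min(sqrt(rowSums(sweep(A, 2L, B[i, ])^2)))
  pooled <- sort(c(dxy, dyx))
  # linear interpolation between order statistics (type-7 convention)
  h <- (length(pooled) - 1) * percentile / 100
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  p95 <- pooled[lo] + (h - floor(h)) * (pooled[hi] - pooled[lo])
  list(hd95 = p95, hausdorff = max(c(dxy, dyx)))
}

# closed-form parameter count of the fusion architecture, derived from the
# layer structure (independent of the model's own accounting)
expectedFusionParams <- function(cfg) {
  d <- cfg@dims
  kv <- function(k) k^2 * (if (d == 3L) k else 1L)
  conv <- function(k, cin, cout) kv(k) * cin * cout + cout
  norm <- function(C) 2L * C + 1L
  se <- function(C, r) {
    bw <- max(1L, C %/% r)
    C * bw + bw + bw * C + C
  }
  F <- cfg@encoderFilters
  n <- length(F)
  F0 <- cfg@zeroLayerFilters
  total <- 0L
  for (m in 1:2) {
    total <- total + conv(cfg@zeroLayerKernel, 1L, F0)
    if (cfg@useZeroLayer) total <- total + norm(F0)
    cin <- F0
    for (i in seq_len(n)) {
      total <- total + conv(3L, cin, F[i]) + se(F[i], cfg@seReduction) +
        norm(F[i])
      cin <- F[i]
    }
  }
  for (i in seq_len(n)) {
    total <- total + 2L * conv(1L, F[i], F[i])           # pf convs
    if (cfg@fusionConv) total <- total + conv(1L, F[i], F[i])
    total <- total + conv(1L, F[i], F[i]) + norm(F[i])   # decoder head
  }
  for (i in seq_len(n - 1L))
    total <- total + conv(1L, F[i + 1L], F[i]) + conv(3L, F[i], F[i])
  total <- total + conv(1L, F[1L], F0) + conv(3L, F0, 1L)
  total
}

# tiny 2D fusion config used across network tests (8x8-compatible)
tinyConfig <- function(...) {
  modelConfig(dims = 2L, encoderFilters = c(4L, 3L), zeroLayerFilters = 2L,
              ...)
}

# small 2D phantom pair for end-to-end tests (geometry scaled to the grid)
tinySample <- function(seed = 11L, shape = c(32L, 32L)) {
  r <- if (min(shape) <= 16L) c(2, 2.5) else c(3, 5)
  generatePhantom(phantomSpec(shape = shape, nTumors = 1L,
                              tumorRadiusRange = r,
                              nConfounders = if (min(shape) <= 16L) 0L
                              else 1L, seed = seed))
}
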