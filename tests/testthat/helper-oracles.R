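# Small geometry builders and naive reference implementations, kept
# deliberately independent of the package's code paths.

sphereArray <- function(shape, centerVox, radiusVox) {
  idx <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                     z = seq_len(shape[3]))
  inside <- (idx$x - centerVox[1])^2 + (idx$y - centerVox[2])^2 +
    (idx$z - centerVox[3])^2 <= radiusVox^2
  array(as.double(inside), shape)
}

randomBlobMask <- function(shape, spacing = c(1, 1, 1), nSeeds = 2) {
  arr <- array(0, shape)
  for (s in seq_len(nSeeds)) {
    ctr <- sapply(shape, function(n) sample(2:(n - 1), 1))
    r <- runif(1, 1, max(2, min(shape) / 3))
    arr <- pmax(arr, sphereArray(shape, ctr, r))
  }
  binaryMask(arr, spacing = spacing)
}

# --- naive oracles -----------------------------------------------------

bruteDice <- function(a, b) {
  av <- gridValues(a); bv <- gridValues(b)
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(av)) {
    if (av[i] == 1) na <- na + 1
    if (bv[i] == 1) nb <- nb + 1
    if (av[i] == 1 && bv[i] == 1) inter <- inter + 1
  }
  2 * inter / (na + nb)
}

# surface voxels by explicit 6-neighbour check (border voxels count)
bruteSurface <- function(arr) {
  d <- dim(arr)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (arr[i, j, k] == 0) next
    nb <- c(
      if (i > 1) arr[i - 1, j, k] else 0,
      if (i < d[1]) arr[i + 1, j, k] else 0,
      if (j > 1) arr[i, j - 1, k] else 0,
      if (j < d[2]) arr[i, j + 1, k] else 0,
      if (k > 1) arr[i, j, k - 1] else 0,
      if (k < d[3]) arr[i, j, k + 1] else 0)
    if (length(nb) < 6 || any(nb == 0)) out[i, j, k] <- TRUE
  }
  out
}

bruteHausdorffCm <- function(a, b) {
  coords <- function(m) {
    idx <- which(bruteSurface(gridValues(m)), arr.ind = TRUE)
    sweep(sweep(idx - 1, 2, gridSpacing(m), "*"), 2, gridOrigin(m), "+")
  }
  pa <- coords(a); pb <- coords(b)
  dmat <- sqrt(outer(pa[, 1], pb[, 1], "-")^2 +
               outer(pa[, 2], pb[, 2], "-")^2 +
               outer(pa[, 3], pb[, 3], "-")^2)
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min))) / 10
}

bruteDvh <- function(doseVals, edges) {
  vapply(edges, function(d) sum(doseVals >= d) / length(doseVals), numeric(1))
}

# linear-interpolation quantile of the sorted values (type-7 definition,
# written out directly)
bruteQuantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

# naive scatter-based Gaussian smoothing: each input voxel distributes
# its value over a truncated Gaussian box, renormalised inside the grid
bruteSmooth <- function(arr, spacing, fwhmMm) {
  if (fwhmMm == 0) return(arr)
  sigma <- fwhmMm / (2 * sqrt(2 * log(2))) / spacing   # voxels, per axis
  r <- pmax(1, ceiling(4 * sigma))
  d <- dim(arr)
  out <- array(0, d)
  w1 <- lapply(1:3, function(ax) exp(-((-r[ax]:r[ax])^2) / (2 * sigma[ax]^2)))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    v <- arr[i, j, k]
    if (v == 0) next
    ii <- max(1, i - r[1]):min(d[1], i + r[1])
    jj <- max(1, j - r[2]):min(d[2], j + r[2])
    kk <- max(1, k - r[3]):min(d[3], k + r[3])
    wx <- w1[[1]][ii - i + r[1] + 1]
    wy <- w1[[2]][jj - j + r[2] + 1]
    wz <- w1[[3]][kk - k + r[3] + 1]
    kern <- outer(outer(wx, wy), wz)
    out[ii, jj, kk] <- out[ii, jj, kk] + v * kern / sum(kern)
  }
  out
}

# naive threshold segmentation: smooth (scatter loops), take the max,
# threshold the ORIGINAL image, no component cleanup
bruteAutoMask <- function(counts, spacing, fwhmMm, fraction) {
  sm <- bruteSmooth(counts, rep(spacing, 3), fwhmMm)
  array(as.double(counts >= fraction * max(sm)), dim(counts))
}
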