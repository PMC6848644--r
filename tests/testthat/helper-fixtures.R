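## Small in-code fixtures shared across test files.

## a tiny 3-slice image/mask pair with known label geometry
tinyPair <- function(H = 8L, W = 8L) {
  img <- array(50, c(H, W, 3L))
  lab <- array(0L, c(H, W, 3L))
  for (s in 2:3) {
    img[3:6, 3:6, s] <- 100
    lab[3:6, 3:6, s] <- 1L
    img[4:5, 4:5, s] <- 140
    lab[4:5, 4:5, s] <- 2L
  }
  list(image = imageStack(img), mask = labelMask(lab))
}

## noiseless phantom defaults used by several oracle tests
noiselessParams <- function(...) phantomParams(sigmaNoise = 0, ...)

## brute-force suprathreshold count: explicit loop over the SNpc and
## background pixels of the slice pair, with hand-rolled mean/SD
bruteForceCount <- function(image, mask, k, slices) {
  a <- imageData(image); m <- imageData(mask)
  tot <- 0; n <- 0L
  for (s in slices) {
    as <- a[, , s]; ms <- m[, , s]
    for (i in which(ms == 1L)) { tot <- tot + as[i]; n <- n + 1L }
  }
  msi <- tot / n
  ss <- 0
  for (s in slices) {
    as <- a[, , s]; ms <- m[, , s]
    for (i in which(ms == 1L)) ss <- ss + (as[i] - msi)^2
  }
  thr <- msi + k * sqrt(ss / (n - 1))
  cnt <- 0L
  for (s in slices) {
    as <- a[, , s]; ms <- m[, , s]
    for (i in which(ms == 2L)) if (as[i] > thr) cnt <- cnt + 1L
  }
  cnt
}

## Mann-Whitney pair-counting AUC oracle (positive = PD, oriented so
## that lower scores indicate PD)
pairCountAUC <- function(scores, labels, lowIsPositive = TRUE) {
  s <- if (lowIsPositive) -scores else scores
  pos <- s[labels == "PD"]; neg <- s[labels == "HC"]
  tot <- 0
  for (x in pos) for (y in neg)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(pos) * length(neg))
}

## fast desk-scale training configuration for structural tests
tinyTrainConfig <- function(...) {
  trainConfig(cropSize = 32L, batchSize = 2L, epochs = 1L,
              augment = "none", alpha = 1e-3, seed = 42L, ...)
}

tinyNetConfigs <- function() {
  list(mid = netConfig(depth = 2L, baseChannels = 4L, inChannels = 1L),
       snpc = netConfig(depth = 2L, baseChannels = 4L, inChannels = 2L))
}

## small in-memory phantom cohort at reduced canvas for cheap training
tinyPhantomParams <- function(...) {
  phantomParams(imageSize = c(64L, 64L), ...)
}
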