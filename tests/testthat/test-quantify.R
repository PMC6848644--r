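test_that("slice selection maximises midbrain content with a deterministic tie-break", {
  mk <- function(counts) {
    lab <- array(0L, c(10, 10, length(counts)))
    for (s in seq_along(counts))
      if (counts[s] > 0) lab[seq_len(counts[s]), 1, s] <- 1L
    labelMask(lab)
  }
  expect_identical(selectSlices(mk(c(5, 5, 0, 0))), c(1L, 2L))
  ## argmax of pair sums
  lab <- array(0L, c(40, 40, 5))
  for (s in 1:5) {
    n <- c(0, 10, 30, 30, 0)[s]
    if (n > 0) lab[seq_len(n), 1, s] <- 1L
  }
  expect_identical(selectSlices(labelMask(lab)), c(3L, 4L))
  ## tie between (2,3) and (3,4) -> smaller index
  lab2 <- array(0L, c(40, 40, 5))
  for (s in 2:4) lab2[1:20, 1, s] <- 1L
  expect_identical(selectSlices(labelMask(lab2)), c(2L, 3L))
  expect_error(selectSlices(labelMask(array(0L, c(4, 4, 3)))),
               "no consecutive slice pair")
})

test_that("background statistics pool both slices with sample SD", {
  img <- array(0, c(2, 2, 2)); lab <- array(0L, c(2, 2, 2))
  img[1, 1:2, 1] <- c(1, 2); lab[1, 1:2, 1] <- 1L
  img[1, 1, 2] <- 3; lab[1, 1, 2] <- 1L
  bg <- backgroundStats(imageStack(img), labelMask(lab), c(1L, 2L))
  expect_equal(bg@msi, 2); expect_equal(bg@sd, 1)
  expect_identical(bg@nPixels, 3L)

  img2 <- array(5, c(2, 2, 2)); lab2 <- array(1L, c(2, 2, 2))
  bg2 <- backgroundStats(imageStack(img2), labelMask(lab2), c(1L, 2L))
  expect_equal(bg2@msi, 5); expect_equal(bg2@sd, 0)

  ## pooled (not per-slice averaged): {1,2} and {3,4}
  img3 <- array(0, c(2, 2, 2)); lab3 <- array(0L, c(2, 2, 2))
  img3[1, 1:2, 1] <- c(1, 2); lab3[1, 1:2, 1] <- 1L
  img3[1, 1:2, 2] <- c(3, 4); lab3[1, 1:2, 2] <- 1L
  bg3 <- backgroundStats(imageStack(img3), labelMask(lab3), c(1L, 2L))
  expect_equal(bg3@msi, 2.5)
  expect_equal(bg3@sd, sd(c(1, 2, 3, 4)))

  lab4 <- array(0L, c(2, 2, 2)); lab4[1, 1, 1] <- 1L
  expect_error(backgroundStats(imageStack(img3), labelMask(lab4), c(1L, 2L)),
               "fewer than 2 background")
})

test_that("hyperintense area counts strictly suprathreshold SNpc pixels", {
  ## background mean 100 sd 10; SNpc pixels {120, 110, 116, 115}
  img <- array(0, c(4, 4, 2)); lab <- array(0L, c(4, 4, 2))
  bgvals <- c(90, 110, 90, 110, 100, 100)  # mean 100, sd 8.944
  ## craft background with mean 100 sd exactly 10: use {90,110} x3 pairs
  bgvals <- c(90, 110, 90, 110, 90, 110)
  img[1, 1:3, 1] <- bgvals[1:3]; lab[1, 1:3, 1] <- 1L
  img[1, 1:3, 2] <- bgvals[4:6]; lab[1, 1:3, 2] <- 1L
  sdv <- sd(bgvals)                         # 10.954
  img[2, 1:2, 1] <- c(120, 110); lab[2, 1:2, 1] <- 2L
  img[2, 1:2, 2] <- c(116, 115); lab[2, 1:2, 2] <- 2L
  st <- imageStack(img); mk <- labelMask(lab)
  ## use an explicit BackgroundStats so the threshold is exactly 115
  bg <- new("BackgroundStats", msi = 100, sd = 10, nPixels = 6L,
            sliceIndices = c(1L, 2L))
  h <- hyperintenseArea(st, mk, 1.5, slices = c(1L, 2L), stats = bg)
  expect_equal(h@threshold, 115)
  expect_identical(h@count, 2L)             # 115 excluded: strict >
  expect_equal(h@areaMM2, 2 * 0.43 * 0.43, tolerance = 1e-12)
  expect_identical(sum(h@perSlice$count), h@count)

  ## sd 0, all SNpc equal to msi -> count 0
  bg0 <- new("BackgroundStats", msi = 110, sd = 0, nPixels = 6L,
             sliceIndices = c(1L, 2L))
  img0 <- img; img0[2, 1:2, 1] <- 110; img0[2, 1:2, 2] <- 110
  h0 <- hyperintenseArea(imageStack(img0), mk, 1.5, c(1L, 2L), bg0)
  expect_identical(h0@count, 0L)

  ## k = 0, all SNpc above msi -> count = |SNpc|
  hk <- hyperintenseArea(st, mk, 0, c(1L, 2L), bg)
  expect_identical(hk@count, 4L)
})

test_that("area identity: area / pixel-area is the integer count", {
  p <- phantomParams()
  for (seed in c(3, 5)) {
    s <- generateSubject(p, "PD", seed)
    h <- hyperintenseArea(s@image, s@truth, 1)
    expect_equal(h@areaMM2 / prod(pixelSpacing(s@image)), h@count)
  }
})

test_that("suprathreshold counts are non-increasing in k", {
  p <- phantomParams()
  subs <- generateCohortInMemory(p, 3, 3)
  res <- quantifyCohort(subs, ks = c(1, 1.5, 2))
  for (id in unique(res$subject_id)) {
    cnt <- res$count[res$subject_id == id][order(res$k[res$subject_id == id])]
    expect_true(all(diff(cnt) <= 0))
  }
})

test_that("threshold sweep picks the highest-AUC multiplier, ties to smallest", {
  ## construct areas where k = 1.5 separates perfectly and others do not
  areas <- rbind(data.frame(subject_id = sprintf("HC%d", 1:4), group = "HC",
                            k = rep(c(1, 1.5, 2), each = 4),
                            area_mm2 = c(5, 6, 1, 2, 10, 11, 12, 13,
                                         1, 2, 5, 6)),
                 data.frame(subject_id = sprintf("PD%d", 1:4), group = "PD",
                            k = rep(c(1, 1.5, 2), each = 4),
                            area_mm2 = c(3, 4, 7, 8, 1, 2, 3, 4,
                                         3, 4, 7, 8)))
  sw <- thresholdSweep(areas)
  expect_equal(sw$k, 1.5)
  expect_equal(unname(sw$auc[["1.5"]]), 1.0)

  ## all k give AUC 1 -> smallest k wins
  m <- cbind(`1` = c(1, 2, 9, 10), `1.5` = c(1, 2, 9, 10),
             `2` = c(1, 2, 9, 10))
  sw2 <- thresholdSweep(m, labels = c("PD", "PD", "HC", "HC"))
  expect_equal(sw2$k, 1)
})

test_that("relative variation is msi/sd and fails for sd 0", {
  b <- function(msi, sdv) new("BackgroundStats", msi = msi, sd = sdv,
                              nPixels = 10L, sliceIndices = c(1L, 2L))
  expect_equal(relativeVariation(b(2, 1)), 2)
  expect_equal(relativeVariation(b(100, 10)), 10)
  expect_error(relativeVariation(b(5, 0)), "undefined")
})

test_that("affine intensity maps leave the suprathreshold set invariant", {
  p <- phantomParams()
  s <- generateSubject(p, "HC", 77)
  sl <- selectSlices(s@truth)
  base <- vapply(c(0, 1, 1.5, 2), function(k)
    hyperintenseArea(s@image, s@truth, k, sl)@count, integer(1))
  set.seed(1)
  for (i in 1:8) {
    a <- runif(1, 0.1, 5); b <- runif(1, -300, 300)
    tr <- s@image; tr@data <- a * tr@data + b
    got <- vapply(c(0, 1, 1.5, 2), function(k)
      hyperintenseArea(tr, s@truth, k, sl)@count, integer(1))
    expect_identical(got, base)
  }
})
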