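test_that("subject generation is deterministic for a fixed seed", {
  p <- phantomParams()
  a <- generateSubject(p, "HC", 123)
  b <- generateSubject(p, "HC", 123)
  expect_identical(imageData(a@image), imageData(b@image))
  expect_identical(imageData(a@truth), imageData(b@truth))
  c <- generateSubject(p, "HC", 124)
  expect_false(identical(imageData(a@image), imageData(c@image)))
})

test_that("noise-free limit plants exact intensities", {
  p <- noiselessParams(snpcExtent = c(HC = 1.0, PD = 0.55), extentSD = 0)
  s <- generateSubject(p, "HC", 5)
  a <- imageData(s@image); m <- imageData(s@truth)
  expect_true(all(a[m == 2L] == 100 + 40))
  expect_true(all(a[m == 1L] == 100))
  expect_true(all(a[m == 0L] == 50))
  expect_equal(s@trueHyperFraction, 1.0)
})

test_that("PD/HC suprathreshold ratio tracks the extent ratio (noiseless)", {
  p <- noiselessParams(snpcExtent = c(HC = 1.0, PD = 0.5), extentSD = 0)
  nhc <- 0L; npd <- 0L
  for (i in 1:5) {
    hc <- generateSubject(p, "HC", 100 + i)
    pd <- generateSubject(p, "PD", 200 + i)
    ## direct pixel count on the noiseless rasters
    nhc <- nhc + sum(imageData(hc@image) > 100 & imageData(hc@truth) == 2L)
    npd <- npd + sum(imageData(pd@image) > 100 & imageData(pd@truth) == 2L)
  }
  expect_equal(npd / nhc, 0.5, tolerance = 0.05)
})

test_that("truth masks satisfy the partition and containment invariants", {
  p <- phantomParams()
  for (seed in c(11, 17, 23)) {
    s <- generateSubject(p, sample(c("HC", "PD"), 1), seed)
    lab <- imageData(s@truth)
    expect_true(all(lab %in% labelCodes()))
    expect_true(validObject(s@truth))
    ## midbrain only on the configured consecutive slices
    mbPerSlice <- apply(lab != 0L, 3, any)
    expect_identical(which(mbPerSlice), p$midbrainSlices)
    ## crescents non-empty on both midbrain slices
    for (sl in p$midbrainSlices)
      expect_gt(sum(lab[, , sl] == 2L), 0)
  }
})

test_that("increasing extent strictly increases the planted hyperintense count", {
  counts <- vapply(c(0.3, 0.6, 0.9), function(ext) {
    p <- noiselessParams(snpcExtent = c(HC = ext, PD = 0.5), extentSD = 0)
    generateSubject(p, "HC", 42)@trueHyperCount
  }, integer(1))
  expect_true(all(diff(counts) > 0))
})

test_that("cohort generation writes a reproducible, valid dataset", {
  dir1 <- file.path(withr::local_tempdir(), "c1")
  dir2 <- file.path(withr::local_tempdir(), "c2")
  p <- phantomParams(seed = 303)
  man1 <- generateCohort(p, 4, 4, dir1)
  expect_identical(nrow(records(man1)), 8L)
  expect_identical(as.integer(table(records(man1)$group)[c("HC", "PD")]),
                   c(4L, 4L))
  expect_identical(anyDuplicated(records(man1)$subject_id), 0L)
  expect_error(generateCohort(p, 4, 4, dir1), "exists")

  man2 <- generateCohort(p, 4, 4, dir2)
  for (i in seq_len(8)) {
    f1 <- file.path(dir1, records(man1)$image[i])
    f2 <- file.path(dir2, records(man2)$image[i])
    expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  }
  ## reload through the manifest machinery
  man <- suppressMessages(loadManifest(file.path(dir1, "manifest.csv")))
  expect_identical(records(man)$subject_id, records(man1)$subject_id)
})

test_that("group-mean true hyperintense area is lower in PD than HC", {
  p <- noiselessParams()
  subs <- generateCohortInMemory(p, 10, 10)
  counts <- vapply(subs, function(s) s@trueHyperCount, integer(1))
  groups <- vapply(subs, function(s) s@record$group, character(1))
  expect_lt(mean(counts[groups == "PD"]), mean(counts[groups == "HC"]))
})

test_that("in-memory and on-disk cohorts share per-subject seeds", {
  dir <- file.path(withr::local_tempdir(), "c")
  p <- phantomParams(seed = 99)
  man <- generateCohort(p, 2, 2, dir)
  mem <- generateCohortInMemory(p, 2, 2)
  img <- readImageStack(file.path(dir, records(man)$image[1]))
  expect_equal(imageData(img), imageData(mem[[1]]@image), tolerance = 1e-6)
})

test_that("rician noise mode and delta PD mode are available", {
  pr <- phantomParams(noiseModel = "rician", seed = 7)
  s <- generateSubject(pr, "HC", 3)
  expect_true(all(imageData(s@image) >= 0))
  pdm <- noiselessParams(pdMode = "delta", snpcExtent = c(HC = 1, PD = 0.5),
                         extentSD = 0)
  s2 <- generateSubject(pdm, "PD", 3)
  a <- imageData(s2@image); m <- imageData(s2@truth)
  ## delta mode: full extent, attenuated contrast
  expect_equal(s2@trueHyperFraction, 1.0)
  expect_true(all(a[m == 2L] == 100 + 40 * 0.5))
})
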