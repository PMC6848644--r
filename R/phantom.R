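#' Parameters of the synthetic midbrain phantom
#'
#' Defines a cohort of NM-MRI-like phantoms: a "butterfly" midbrain on
#' two consecutive axial slices, containing two hyperintense SNpc
#' crescents. Intensities follow the contrast structure of
#' neuromelanin-sensitive imaging: a dim extra-midbrain region, a
#' brighter midbrain background (the thresholding reference tissue), and
#' a hyperintense sub-region of the SNpc sitting `deltaSNpc` above the
#' background mean. The Parkinson's-disease effect is, by default, a
#' reduction of the *extent* of the hyperintense sub-region within the
#' anatomical SNpc (matching the measured quantity, a suprathreshold
#' area); an alternative `pdMode = "delta"` attenuates the contrast
#' instead.
#'
#' @param imageSize `(rows, cols)` in pixels.
#' @param pixelSpacing in-plane spacing in mm (0.43 x 0.43 as in
#'   NM-MRI protocols).
#' @param nSlices number of axial slices; the midbrain occupies
#'   `midbrainSlices` (two consecutive slices by default, so slice
#'   selection is exercised downstream).
#' @param midbrainSlices indices (1-based) of consecutive slices
#'   carrying the midbrain.
#' @param muOutside,muBackground mean intensity outside / inside the
#'   midbrain (arbitrary units).
#' @param deltaSNpc hyperintense contrast above the background mean.
#' @param sigmaNoise noise SD (same units); 0 gives the exact noiseless
#'   limit used by the analytic oracles.
#' @param snpcExtent named vector `c(HC = , PD = )`: group-mean fraction
#'   of anatomical SNpc pixels planted hyperintense.
#' @param extentSD per-subject SD of the extent around its group mean
#'   (truncated to `[0.05, 1]`).
#' @param jitterShift,jitterRotate,jitterScale per-subject geometry
#'   jitter: max |shift| in px, max |rotation| in degrees, max
#'   relative scale deviation.
#' @param noiseModel `"gaussian"` (default) or `"rician"`.
#' @param pdMode `"extent"` (default) or `"delta"`.
#' @param seed cohort-level seed; per-subject seeds derive from it.
#' @return A validated list of class `PhantomParams`.
#' @export
#' @examples
#' p <- phantomParams(sigmaNoise = 0)
#' s <- generateSubject(p, "HC", subjectSeed = 7)
#' s
phantomParams <- function(imageSize = c(128L, 128L),
                          pixelSpacing = c(0.43, 0.43),
                          nSlices = 4L, midbrainSlices = c(2L, 3L),
                          muOutside = 50, muBackground = 100,
                          deltaSNpc = 40, sigmaNoise = 8,
                          snpcExtent = c(HC = 0.95, PD = 0.55),
                          extentSD = 0.06,
                          jitterShift = 3, jitterRotate = 5,
                          jitterScale = 0.05,
                          noiseModel = c("gaussian", "rician"),
                          pdMode = c("extent", "delta"),
                          seed = 20260101L) {
  noiseModel <- match.arg(noiseModel)
  pdMode <- match.arg(pdMode)
  stopifnot(length(imageSize) == 2L, all(imageSize >= 32L),
            all(pixelSpacing > 0), nSlices >= 2L,
            length(midbrainSlices) == 2L,
            diff(midbrainSlices) == 1L,
            max(midbrainSlices) <= nSlices,
            sigmaNoise >= 0,
            all(c("HC", "PD") %in% names(snpcExtent)),
            all(snpcExtent >= 0 & snpcExtent <= 1),
            extentSD >= 0)
  structure(list(imageSize = as.integer(imageSize),
                 pixelSpacing = as.numeric(pixelSpacing),
                 nSlices = as.integer(nSlices),
                 midbrainSlices = as.integer(midbrainSlices),
                 muOutside = muOutside, muBackground = muBackground,
                 deltaSNpc = deltaSNpc, sigmaNoise = sigmaNoise,
                 snpcExtent = snpcExtent, extentSD = extentSD,
                 jitterShift = jitterShift, jitterRotate = jitterRotate,
                 jitterScale = jitterScale, noiseModel = noiseModel,
                 pdMode = pdMode, seed = as.integer(seed)),
            class = "PhantomParams")
}

## Rasterise midbrain + SNpc shapes for one slice, under a per-subject
## rigid jitter (shift t, rotation phi, scale s about the image centre)
## and a per-slice shrink factor. Shapes are analytic: the midbrain is
## the union of two overlapping ellipses; each SNpc crescent is an
## angular sector of an annulus around a lateral anchor point,
## intersected with the midbrain. Evaluating the inverse-transformed
## pixel coordinates keeps the rasterisation exact (no resampling).
.phantomSliceGeometry <- function(H, W, shift, phi, scale, sliceScale) {
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  g <- expand.grid(r = seq_len(H), c = seq_len(W))
  ## inverse transform into the canonical shape frame
  y <- (g$r - cy - shift[1]) / (scale * sliceScale)
  x <- (g$c - cx - shift[2]) / (scale * sliceScale)
  a <- -phi * pi / 180
  yr <- cos(a) * y - sin(a) * x
  xr <- sin(a) * y + cos(a) * x
  inEllipse <- function(y0, x0, ry, rx)
    ((yr - y0) / ry)^2 + ((xr - x0) / rx)^2 <= 1
  midbrain <- inEllipse(0, -9, 22, 17) | inEllipse(0, 9, 22, 17)
  crescent <- function(side) {    # side = -1 left, +1 right
    dy <- yr - 5; dx <- xr - side * 11
    d <- sqrt(dy^2 + dx^2)
    theta <- atan2(dy, dx * side)  # 0 points laterally outward
    ang <- abs(theta)
    list(inside = d >= 6 & d <= 10.5 & ang <= (160 / 2) * pi / 180,
         ang = ang)
  }
  left <- crescent(-1); right <- crescent(1)
  list(midbrain = midbrain,
       snpcL = left$inside & midbrain, snpcR = right$inside & midbrain,
       angL = left$ang, angR = right$ang)
}

## deterministic per-crescent hyperintense subset: the `extent` fraction
## of crescent pixels closest in angle to the crescent midline, so the
## PD effect erodes the crescent from both tips
.hyperSubset <- function(inside, ang, extent) {
  idx <- which(inside)
  n <- length(idx)
  k <- round(extent * n)
  if (k <= 0L) return(integer(0))
  idx[order(ang[idx])][seq_len(min(k, n))]
}

#' Generate one synthetic phantom subject
#'
#' Deterministic for fixed `(params, group, subjectSeed)`. The midbrain
#' is rendered on the two configured consecutive slices (the second
#' slightly smaller, as on real caudal slices); a fraction
#' `snpcExtent[group]` (jittered per subject) of anatomical SNpc pixels
#' receives mean `muBackground + deltaSNpc`, the rest `muBackground`;
#' noise is added everywhere. If the geometry jitter empties a
#' crescent, the subject is regenerated with a derived sub-seed (at
#' most 10 attempts).
#'
#' @param params a [phantomParams()] list.
#' @param group `"HC"` or `"PD"`.
#' @param subjectSeed integer seed for this subject.
#' @param subjectID identifier; default derived from group and seed.
#' @return A [PhantomSubject-class].
#' @export
generateSubject <- function(params, group = c("HC", "PD"), subjectSeed,
                            subjectID = NULL) {
  group <- match.arg(group)
  stopifnot(inherits(params, "PhantomParams"))
  for (attempt in 0:9) {
    res <- .generateSubjectOnce(params, group,
                                (subjectSeed + attempt * 7919L) %% .Machine$integer.max,
                                subjectID)
    if (!is.null(res)) return(res)
  }
  stop("phantom geometry degenerate (empty SNpc) after 10 attempts; ",
       "reduce the jitter ranges")
}

.generateSubjectOnce <- function(params, group, subjectSeed, subjectID) {
  p <- params
  H <- p$imageSize[1]; W <- p$imageSize[2]
  set.seed(subjectSeed)
  shift <- stats::runif(2, -p$jitterShift, p$jitterShift)
  phi <- stats::runif(1, -p$jitterRotate, p$jitterRotate)
  scale <- 1 + stats::runif(1, -p$jitterScale, p$jitterScale)
  extent <- p$snpcExtent[[group]]
  if (p$extentSD > 0)
    extent <- min(1, max(0.05, extent + stats::rnorm(1, 0, p$extentSD)))

  lab <- array(.LBL[["OUTSIDE"]], c(H, W, p$nSlices))
  base <- array(p$muOutside, c(H, W, p$nSlices))
  hyperTotal <- 0L; snpcTotal <- 0L
  sliceScales <- c(1, 0.92)
  for (j in seq_along(p$midbrainSlices)) {
    s <- p$midbrainSlices[j]
    geo <- .phantomSliceGeometry(H, W, shift, phi, scale, sliceScales[j])
    if (!any(geo$snpcL) || !any(geo$snpcR)) return(NULL)
    eff <- if (p$pdMode == "extent") extent else 1
    hypL <- .hyperSubset(geo$snpcL, geo$angL, eff)
    hypR <- .hyperSubset(geo$snpcR, geo$angR, eff)
    sl <- matrix(p$muOutside, H, W)
    sl[geo$midbrain] <- p$muBackground
    delta <- if (p$pdMode == "delta") p$deltaSNpc * extent else p$deltaSNpc
    sl[hypL] <- p$muBackground + delta
    sl[hypR] <- p$muBackground + delta
    lm <- matrix(.LBL[["OUTSIDE"]], H, W)
    lm[geo$midbrain] <- .LBL[["BACKGROUND"]]
    lm[geo$snpcL | geo$snpcR] <- .LBL[["SNPC"]]
    base[, , s] <- sl
    lab[, , s] <- lm
    hyperTotal <- hyperTotal + length(hypL) + length(hypR)
    snpcTotal <- snpcTotal + sum(geo$snpcL | geo$snpcR)
  }
  vox <- switch(p$noiseModel,
    gaussian = base + stats::rnorm(length(base), 0, p$sigmaNoise),
    rician = sqrt((base + stats::rnorm(length(base), 0, p$sigmaNoise))^2 +
                  stats::rnorm(length(base), 0, p$sigmaNoise)^2))

  if (is.null(subjectID)) subjectID <- sprintf("%s_%08d", group, subjectSeed)
  record <- .phantomRecord(subjectID, group, extent)
  new("PhantomSubject",
      image = imageStack(vox, pixelSpacing = p$pixelSpacing,
                         subjectID = subjectID),
      truth = labelMask(lab, source = "PHANTOM_TRUTH"),
      record = record,
      trueHyperFraction = if (snpcTotal > 0) hyperTotal / snpcTotal else 0,
      trueHyperCount = as.integer(hyperTotal))
}

## clinical covariates loosely matching a PD-vs-HC cohort: PD slightly
## older; UPDRS-III increases as the hyperintense extent shrinks, so a
## negative area-severity correlation is built in
.phantomRecord <- function(subjectID, group, extent) {
  age <- round(stats::rnorm(1, if (group == "PD") 68 else 66, 8))
  sex <- sample(c("M", "F"), 1)
  if (group == "PD") {
    duration <- round(stats::rexp(1, 1 / 5), 1)
    updrs <- max(5, round(15 + 80 * (0.95 - extent) + stats::rnorm(1, 0, 5)))
  } else {
    duration <- NA_real_; updrs <- NA_integer_
  }
  data.frame(subject_id = subjectID, group = group, age = age, sex = sex,
             disease_duration = duration, updrs3 = updrs,
             stringsAsFactors = FALSE)
}

#' Derive a per-subject seed from the cohort seed
#'
#' Reproducible independently of generation order:
#' `hash(cohortSeed, index, group)` folded below 2^31.
#' @noRd
.subjectSeed <- function(cohortSeed, index, group) {
  g <- if (group == "PD") 1L else 0L
  as.integer((as.double(cohortSeed) * 48271 + index * 10007 + g * 65537) %%
             2147483563)
}

#' Generate a synthetic cohort on disk
#'
#' Writes NIfTI images, ground-truth masks and a CSV manifest for
#' `nHC + nPD` phantom subjects. Per-subject seeds derive from
#' `params$seed`, so regeneration with the same parameters is
#' file-identical.
#'
#' @param params a [phantomParams()] list.
#' @param nHC,nPD subjects per group (>= 1).
#' @param dir output directory (created; must not exist unless
#'   `overwrite = TRUE`).
#' @param overwrite allow writing into an existing directory.
#' @param datasetTag manifest tag (`"synthetic"` by default).
#' @return The [CohortManifest-class] (also written to
#'   `dir/manifest.csv`).
#' @export
generateCohort <- function(params, nHC, nPD, dir, overwrite = FALSE,
                           datasetTag = "synthetic") {
  stopifnot(inherits(params, "PhantomParams"), nHC >= 1L, nPD >= 1L)
  if (dir.exists(dir) && !overwrite)
    stop("output directory exists (use overwrite = TRUE): ", dir)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  groups <- c(rep("HC", nHC), rep("PD", nPD))
  idx <- c(seq_len(nHC), seq_len(nPD))
  recs <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    sid <- sprintf("%s%03d", g, idx[i])
    subj <- generateSubject(params, g, .subjectSeed(params$seed, idx[i], g),
                            subjectID = sid)
    ipath <- file.path("images", paste0(sid, ".nii.gz"))
    mpath <- file.path("masks", paste0(sid, "_truth.nii.gz"))
    writeImageStack(subj@image, file.path(dir, ipath))
    writeLabelMask(subj@truth, file.path(dir, mpath),
                   reference = subj@image)
    r <- subj@record
    r$image <- ipath; r$mask_truth <- mpath; r$mask_pred <- ""
    recs[[i]] <- r
  }
  man <- new("CohortManifest", records = do.call(rbind, recs),
             datasetTag = datasetTag, rootDir = dir)
  writeManifest(man, file.path(dir, "manifest.csv"))
  man
}

#' Generate a cohort in memory (no files)
#'
#' Convenience for testing and training: returns a list of
#' [PhantomSubject-class] objects with the same per-subject seeds as
#' [generateCohort()].
#'
#' @inheritParams generateCohort
#' @return List of `PhantomSubject`s, named by subject id.
#' @export
generateCohortInMemory <- function(params, nHC, nPD) {
  stopifnot(inherits(params, "PhantomParams"), nHC >= 1L, nPD >= 1L)
  groups <- c(rep("HC", nHC), rep("PD", nPD))
  idx <- c(seq_len(nHC), seq_len(nPD))
  out <- vector("list", length(groups))
  nm <- character(length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    sid <- sprintf("%s%03d", g, idx[i])
    out[[i]] <- generateSubject(params, g,
                                .subjectSeed(params$seed, idx[i], g),
                                subjectID = sid)
    nm[i] <- sid
  }
  names(out) <- nm
  out
}
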