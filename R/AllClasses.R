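#' @import methods
NULL

#' Integer label codes used in mask rasters
#'
#' Every [LabelMask-class] pixel carries exactly one of three labels:
#' `OUTSIDE` (not midbrain), `BACKGROUND` (midbrain minus SNpc, the
#' reference tissue for the intensity threshold) and `SNPC` (substantia
#' nigra pars compacta). The midbrain is by definition
#' `BACKGROUND | SNPC`.
#'
#' @return Named integer vector `c(OUTSIDE = 0L, BACKGROUND = 1L, SNPC = 2L)`.
#' @export
#' @examples
#' labelCodes()
labelCodes <- function() c(OUTSIDE = 0L, BACKGROUND = 1L, SNPC = 2L)

.LBL <- labelCodes()

.validSources <- c("MANUAL_READER1", "MANUAL_READER2", "NETWORK",
                   "PHANTOM_TRUTH")

#' ImageStack: an ordered stack of axial 2D grayscale slices
#'
#' The in-memory representation of a neuromelanin-sensitive MR volume:
#' a 3D numeric array `(rows, cols, slices)` with in-plane pixel spacing
#' in mm, slice thickness and inter-slice gap. Slice index increases
#' superior to inferior.
#'
#' @slot data numeric 3D array, `dim = c(rows, cols, slices)`; finite.
#' @slot pixelSpacing numeric length 2, `(row, col)` spacing in mm, > 0.
#' @slot sliceThickness numeric, slice thickness in mm.
#' @slot sliceGap numeric, inter-slice gap in mm.
#' @slot subjectID character scalar.
#'
#' @aliases ImageStack
#' @exportClass ImageStack
setClass("ImageStack",
  representation(data = "array", pixelSpacing = "numeric",
                 sliceThickness = "numeric", sliceGap = "numeric",
                 subjectID = "character"),
  prototype(pixelSpacing = c(0.43, 0.43), sliceThickness = 2.5,
            sliceGap = 0.5, subjectID = ""))

setValidity("ImageStack", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("data must be a 3D array (rows, cols, slices)")
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0) ||
      any(!is.finite(object@pixelSpacing)))
    return("pixelSpacing must be two positive finite values (mm)")
  nbad <- sum(!is.finite(object@data))
  if (nbad > 0L)
    return(sprintf("image contains %d non-finite voxel(s)", nbad))
  TRUE
})

#' LabelMask: per-pixel structure labels aligned to an ImageStack
#'
#' Integer raster with values from [labelCodes()]: outside, midbrain
#' background, SNpc. Holds manual (MS), network (US) or phantom
#' ground-truth segmentations.
#'
#' @slot data integer 3D array with values in `labelCodes()`.
#' @slot source one of `"MANUAL_READER1"`, `"MANUAL_READER2"`,
#'   `"NETWORK"`, `"PHANTOM_TRUTH"`.
#'
#' @aliases LabelMask
#' @exportClass LabelMask
setClass("LabelMask",
  representation(data = "array", source = "character"),
  prototype(source = "PHANTOM_TRUTH"))

setValidity("LabelMask", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("data must be a 3D array (rows, cols, slices)")
  v <- unique(as.vector(object@data))
  if (anyNA(v) || !all(v %in% .LBL))
    return(sprintf("labels outside the {OUTSIDE, BACKGROUND, SNPC} alphabet: %s",
                   paste(setdiff(v, .LBL), collapse = ", ")))
  if (length(object@source) != 1L || !(object@source %in% .validSources))
    return(sprintf("source must be one of %s",
                   paste(.validSources, collapse = ", ")))
  TRUE
})

#' CohortManifest: a validated table of subjects with image/mask paths
#'
#' @slot records data.frame with one row per subject: `subject_id`,
#'   `group` (HC/PD), optional clinical covariates, and file paths
#'   (`image`, `mask_truth`, optional `mask_pred`).
#' @slot datasetTag one of `"principal"`, `"external"`, `"synthetic"`.
#' @slot rootDir directory against which relative paths resolve.
#'
#' @aliases CohortManifest
#' @exportClass CohortManifest
setClass("CohortManifest",
  representation(records = "data.frame", datasetTag = "character",
                 rootDir = "character"),
  prototype(datasetTag = "synthetic", rootDir = "."))

setValidity("CohortManifest", function(object) {
  rec <- object@records
  req <- c("subject_id", "group", "image", "mask_truth")
  miss <- setdiff(req, names(rec))
  if (length(miss))
    return(sprintf("manifest lacks required column(s): %s",
                   paste(miss, collapse = ", ")))
  if (anyDuplicated(rec$subject_id))
    return(sprintf("duplicate subject_id: %s",
                   paste(unique(rec$subject_id[duplicated(rec$subject_id)]),
                         collapse = ", ")))
  bad <- which(!(rec$group %in% c("HC", "PD")))
  if (length(bad))
    return(sprintf("unknown group token '%s' in row %d (expected HC or PD)",
                   rec$group[bad[1]], bad[1]))
  if (!(object@datasetTag %in% c("principal", "external", "synthetic")))
    return("datasetTag must be principal, external or synthetic")
  TRUE
})

#' BackgroundStats: midbrain-background reference statistics
#'
#' Mean signal intensity (MSI) and standard deviation of the background
#' region (midbrain minus SNpc), pooled over the two consecutive slices
#' used for quantification. Defines the threshold `MSI + k * SD`.
#'
#' @slot msi mean background signal intensity.
#' @slot sd sample standard deviation (denominator n - 1) of the
#'   background intensities.
#' @slot nPixels number of background pixels pooled.
#' @slot sliceIndices the two consecutive slice indices used (1-based).
#'
#' @aliases BackgroundStats
#' @exportClass BackgroundStats
setClass("BackgroundStats",
  representation(msi = "numeric", sd = "numeric", nPixels = "integer",
                 sliceIndices = "integer"))

setValidity("BackgroundStats", function(object) {
  if (object@nPixels < 2L) return("nPixels must be >= 2")
  if (object@sd < 0) return("sd must be >= 0")
  TRUE
})

#' HyperintenseResult: suprathreshold SNpc pixel count and area
#'
#' Result of thresholding the SNpc at `MSI + k * SD`: the number of SNpc
#' pixels with intensity strictly above the threshold and the
#' corresponding area in mm^2 (count times in-plane pixel area).
#'
#' @slot k threshold multiplier (SD units above the background mean).
#' @slot threshold intensity threshold `msi + k * sd`.
#' @slot count suprathreshold SNpc pixel count over the slice pair.
#' @slot areaMM2 `count * rowSpacing * colSpacing`, in mm^2.
#' @slot perSlice data.frame with per-slice counts.
#' @slot background the [BackgroundStats-class] used.
#'
#' @aliases HyperintenseResult
#' @exportClass HyperintenseResult
setClass("HyperintenseResult",
  representation(k = "numeric", threshold = "numeric", count = "integer",
                 areaMM2 = "numeric", perSlice = "data.frame",
                 background = "BackgroundStats"))

setValidity("HyperintenseResult", function(object) {
  if (object@count < 0L) return("count must be >= 0")
  if (object@areaMM2 < 0) return("area must be >= 0")
  TRUE
})

#' PhantomSubject: one synthetic subject (image + ground truth + record)
#'
#' @slot image [ImageStack-class] with simulated NM-MRI intensities.
#' @slot truth [LabelMask-class] with source `PHANTOM_TRUTH`.
#' @slot record one-row data.frame (subject_id, group, covariates).
#' @slot trueHyperFraction fraction of anatomical SNpc pixels planted
#'   hyperintense.
#' @slot trueHyperCount number of planted hyperintense pixels.
#'
#' @aliases PhantomSubject
#' @exportClass PhantomSubject
setClass("PhantomSubject",
  representation(image = "ImageStack", truth = "LabelMask",
                 record = "data.frame", trueHyperFraction = "numeric",
                 trueHyperCount = "integer"))

setValidity("PhantomSubject", function(object) {
  if (!identical(dim(object@image@data), dim(object@truth@data)))
    return("image and truth mask geometries differ")
  if (object@trueHyperFraction < 0 || object@trueHyperFraction > 1)
    return("trueHyperFraction must lie in [0, 1]")
  TRUE
})

#' CascadeModel: the two-stage segmentation model
#'
#' Holds the midbrain network (image -> midbrain vs outside) and the
#' SNpc network (image + midbrain probability -> SNpc vs background),
#' their configurations, and training provenance. The two networks'
#' losses are disconnected: an optimisation step for one never changes
#' the other's weights.
#'
#' @slot netMidbrain list: weights and optimiser state of network 1.
#' @slot netSNpc list: weights and optimiser state of network 2.
#' @slot trainConfig list: the [trainConfig()] used (empty if untrained).
#' @slot provenance list: seed, fold id, loss trace, package version.
#'
#' @aliases CascadeModel
#' @exportClass CascadeModel
setClass("CascadeModel",
  representation(netMidbrain = "list", netSNpc = "list",
                 trainConfig = "list", provenance = "list"))

## ---- constructors ----

#' Construct an ImageStack
#'
#' @param data 2D matrix (promoted to one slice) or 3D array of
#'   intensities `(rows, cols, slices)`.
#' @param pixelSpacing in-plane `(row, col)` spacing in mm.
#' @param sliceThickness slice thickness in mm.
#' @param sliceGap inter-slice gap in mm.
#' @param subjectID subject identifier.
#' @return An [ImageStack-class].
#' @export
#' @examples
#' s <- imageStack(array(0, c(8, 8, 2)))
#' nSlices(s)
imageStack <- function(data, pixelSpacing = c(0.43, 0.43),
                       sliceThickness = 2.5, sliceGap = 0.5,
                       subjectID = "") {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  storage.mode(data) <- "double"
  new("ImageStack", data = data, pixelSpacing = as.numeric(pixelSpacing),
      sliceThickness = sliceThickness, sliceGap = sliceGap,
      subjectID = subjectID)
}

#' Construct a LabelMask
#'
#' @param data 2D or 3D integer array with values in [labelCodes()].
#' @param source provenance of the segmentation (see [LabelMask-class]).
#' @return A [LabelMask-class].
#' @export
labelMask <- function(data, source = "PHANTOM_TRUTH") {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  storage.mode(data) <- "integer"
  new("LabelMask", data = data, source = source)
}

## ---- accessors ----

#' @rdname imageData
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' Raw raster access
#'
#' `imageData()` returns the 3D intensity array of an [ImageStack-class]
#' or the 3D integer label array of a [LabelMask-class];
#' `pixelSpacing()` the in-plane spacing (mm); `nSlices()` the number of
#' slices; `subjectID()` the subject identifier.
#'
#' @param x an `ImageStack` or `LabelMask`.
#' @return `imageData`: a 3D array; `pixelSpacing`: numeric length 2;
#'   `nSlices`: integer; `subjectID`: character.
#' @name imageData
#' @export
setMethod("imageData", "ImageStack", function(x) x@data)

#' @rdname imageData
#' @export
setMethod("imageData", "LabelMask", function(x) x@data)

#' @rdname imageData
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname imageData
#' @export
setMethod("pixelSpacing", "ImageStack", function(x) x@pixelSpacing)

#' @rdname imageData
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname imageData
#' @export
setMethod("nSlices", "ImageStack", function(x) dim(x@data)[3L])

#' @rdname imageData
#' @export
setMethod("nSlices", "LabelMask", function(x) dim(x@data)[3L])

#' @rdname imageData
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @rdname imageData
#' @export
setMethod("subjectID", "ImageStack", function(x) x@subjectID)

#' @rdname imageData
#' @export
setGeneric("maskSource", function(x) standardGeneric("maskSource"))

#' @rdname imageData
#' @export
setMethod("maskSource", "LabelMask", function(x) x@source)

#' Manifest records
#'
#' @param x a [CohortManifest-class].
#' @return `records()`: the data.frame of subjects; `datasetTag()`: the
#'   dataset tag.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname records
#' @export
setMethod("records", "CohortManifest", function(x) x@records)

#' @rdname records
#' @export
setGeneric("datasetTag", function(x) standardGeneric("datasetTag"))

#' @rdname records
#' @export
setMethod("datasetTag", "CohortManifest", function(x) x@datasetTag)

## ---- show methods ----

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageStack '%s': %d x %d pixels, %d slice(s)\n",
              object@subjectID, d[1], d[2], d[3]))
  cat(sprintf("  pixel spacing %.3g x %.3g mm, thickness %.3g mm, gap %.3g mm\n",
              object@pixelSpacing[1], object@pixelSpacing[2],
              object@sliceThickness, object@sliceGap))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@data)
  n <- tabulate(as.vector(object@data) + 1L, nbins = 3L)
  cat(sprintf("LabelMask (%s): %d x %d x %d\n", object@source,
              d[1], d[2], d[3]))
  cat(sprintf("  OUTSIDE %d | BACKGROUND %d | SNPC %d\n", n[1], n[2], n[3]))
})

setMethod("show", "CohortManifest", function(object) {
  tab <- table(object@records$group)
  cat(sprintf("CohortManifest (%s): %d subject(s) [%s]\n", object@datasetTag,
              nrow(object@records),
              paste(sprintf("%s:%d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "BackgroundStats", function(object) {
  cat(sprintf("BackgroundStats: MSI %.4g, SD %.4g (n = %d px, slices %s)\n",
              object@msi, object@sd, object@nPixels,
              paste(object@sliceIndices, collapse = "-")))
})

setMethod("show", "HyperintenseResult", function(object) {
  cat(sprintf("HyperintenseResult: k = %.3g, threshold %.4g -> %d px, %.4g mm^2\n",
              object@k, object@threshold, object@count, object@areaMM2))
})

setMethod("show", "CascadeModel", function(object) {
  trained <- length(object@trainConfig) > 0L
  cat(sprintf("CascadeModel (%s)\n",
              if (trained) "trained" else "initialised"))
  cat(sprintf("  net 1 (midbrain): depth %d, base channels %d\n",
              object@netMidbrain$cfg$depth, object@netMidbrain$cfg$baseChannels))
  cat(sprintf("  net 2 (SNpc):     depth %d, base channels %d\n",
              object@netSNpc$cfg$depth, object@netSNpc$cfg$baseChannels))
  if (trained && !is.null(object@provenance$foldID))
    cat(sprintf("  fold %s, seed %s\n", object@provenance$foldID,
                object@provenance$seed))
})
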