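#' Read an NM-MRI image stack from a NIfTI file
#'
#' Reads a 2D or 3D NIfTI file into an [ImageStack-class]. A 2D file is
#' promoted to a one-slice stack. In-plane pixel spacing is taken from
#' the header (`pixdim`); the third pixdim component, when present, is
#' interpreted as spacing between slices (thickness + gap).
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param subjectID subject identifier; default: file name without
#'   extension.
#' @return An [ImageStack-class].
#' @export
readImageStack <- function(path, subjectID = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim(img))   # strip the niftiImage class
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  if (length(dim(a)) != 3L)
    stop("expected a 2D or 3D image, got ", length(dim(a)), " dimensions: ",
         path)
  nbad <- sum(!is.finite(a))
  if (nbad > 0L)
    stop(sprintf("image %s contains %d non-finite voxel(s)", path, nbad))
  pd <- RNifti::pixdim(img)
  ## pixdim is float32 on disk; round off single-precision noise
  spacing <- if (length(pd) >= 2L) signif(abs(pd[1:2]), 6) else c(1, 1)
  if (any(spacing <= 0)) spacing <- c(1, 1)
  between <- if (length(pd) >= 3L && is.finite(pd[3]) && pd[3] > 0) pd[3] else 3.0
  if (is.null(subjectID))
    subjectID <- sub("\\.nii(\\.gz)?$", "", basename(path))
  ## thickness/gap split is not recoverable from pixdim alone; store the
  ## between-slice spacing as thickness with zero gap
  imageStack(a, pixelSpacing = spacing, sliceThickness = between,
             sliceGap = 0, subjectID = subjectID)
}

#' Write an ImageStack to NIfTI
#'
#' @param stack an [ImageStack-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeImageStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  img <- RNifti::asNifti(stack@data)
  RNifti::pixdim(img) <- c(stack@pixelSpacing,
                           stack@sliceThickness + stack@sliceGap)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label mask from NIfTI
#'
#' Reads an integer-valued NIfTI file and maps the on-disk integers to
#' the canonical label alphabet. Every integer present in the file must
#' be covered by `labelMap`, otherwise an error lists the offending
#' values.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param labelMap named integer vector mapping label names
#'   (`OUTSIDE`, `BACKGROUND`, `SNPC`) to the integers used on disk.
#'   Default: the canonical 0/1/2 encoding.
#' @param source provenance tag (see [LabelMask-class]).
#' @return A [LabelMask-class].
#' @export
readLabelMask <- function(path, labelMap = labelCodes(),
                          source = "PHANTOM_TRUTH") {
  if (!file.exists(path)) stop("mask file not found: ", path)
  stopifnot(all(names(labelMap) %in% names(labelCodes())))
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim(img))
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  d <- dim(a)
  if (any(!is.finite(a)) || any(a != round(a)))
    stop("mask file is not integer-valued: ", path)
  a <- as.integer(round(a))
  present <- unique(a)
  unknown <- setdiff(present, labelMap)
  if (length(unknown))
    stop("mask ", path, " contains unmapped value(s): ",
         paste(sort(unknown), collapse = ", "))
  out <- integer(length(a))
  canon <- labelCodes()
  for (nm in names(labelMap)) out[a == labelMap[[nm]]] <- canon[[nm]]
  dim(out) <- d
  labelMask(out, source = source)
}

#' Write a LabelMask to NIfTI
#'
#' Labels are written as unsigned 8-bit integers using `labelMap`
#' (default 0/1/2 for OUTSIDE/BACKGROUND/SNPC), so that
#' `readLabelMask(writeLabelMask(m, p), labelMap)` round-trips exactly.
#'
#' @param mask a [LabelMask-class].
#' @param path output path.
#' @param labelMap named integer vector mapping label names to on-disk
#'   integers.
#' @param reference optional [ImageStack-class]; if supplied the mask
#'   geometry must match it.
#' @param pixelSpacing in-plane spacing written to the header (mm).
#' @return `path`, invisibly.
#' @export
writeLabelMask <- function(mask, path, labelMap = labelCodes(),
                           reference = NULL, pixelSpacing = c(0.43, 0.43)) {
  stopifnot(is(mask, "LabelMask"))
  if (!is.null(reference)) {
    stopifnot(is(reference, "ImageStack"))
    if (!identical(dim(mask@data), dim(reference@data)))
      stop("mask geometry ", paste(dim(mask@data), collapse = "x"),
           " does not match reference image ",
           paste(dim(reference@data), collapse = "x"))
    pixelSpacing <- reference@pixelSpacing
  }
  canon <- labelCodes()
  a <- mask@data
  out <- array(0L, dim(a))
  for (nm in names(canon)) out[a == canon[[nm]]] <- as.integer(labelMap[[nm]])
  if (any(out < 0L | out > 255L))
    stop("labelMap values must fit unsigned 8-bit")
  img <- RNifti::asNifti(out)
  RNifti::pixdim(img) <- c(pixelSpacing, 3.0)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Load and validate a cohort manifest
#'
#' Reads a CSV manifest with columns `subject_id`, `group` (HC/PD),
#' optional `age`, `sex`, `disease_duration`, `updrs3`, and file paths
#' `image`, `mask_truth`, optional `mask_pred`. Relative paths resolve
#' against `rootDir`. Duplicate ids, unknown group tokens (reported
#' with their row number) and dangling paths are errors.
#'
#' @param path path to the manifest CSV.
#' @param rootDir base directory for relative paths; default: the
#'   manifest's directory.
#' @param checkPaths verify that referenced files exist (default TRUE).
#' @param datasetTag dataset tag recorded on the manifest.
#' @return A [CohortManifest-class].
#' @export
loadManifest <- function(path, rootDir = dirname(path), checkPaths = TRUE,
                         datasetTag = "synthetic") {
  if (!file.exists(path)) stop("manifest not found: ", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "image", "mask_truth")
  miss <- setdiff(req, names(rec))
  if (length(miss))
    stop("manifest lacks required column(s): ", paste(miss, collapse = ", "))
  bad <- which(!(rec$group %in% c("HC", "PD")))
  if (length(bad))
    stop(sprintf("unknown group token '%s' in manifest row %d",
                 rec$group[bad[1]], bad[1]))
  if (anyDuplicated(rec$subject_id))
    stop("duplicate subject_id in manifest: ",
         paste(unique(rec$subject_id[duplicated(rec$subject_id)]),
               collapse = ", "))
  if (checkPaths) {
    for (col in intersect(c("image", "mask_truth", "mask_pred"), names(rec))) {
      p <- rec[[col]]
      keep <- !is.na(p) & nzchar(p)
      if (!any(keep)) next
      full <- ifelse(.isAbsPath(p[keep]), p[keep], file.path(rootDir, p[keep]))
      gone <- !file.exists(full)
      if (any(gone))
        stop("manifest column '", col, "' references missing file(s): ",
             paste(utils::head(full[gone], 3L), collapse = ", "))
    }
  }
  m <- new("CohortManifest", records = rec, datasetTag = datasetTag,
           rootDir = rootDir)
  tab <- table(rec$group)
  message(sprintf("manifest: %d subjects (%s)", nrow(rec),
                  paste(sprintf("%s = %d", names(tab), tab), collapse = ", ")))
  m
}

#' Write a cohort manifest to CSV
#'
#' @param manifest a [CohortManifest-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  stopifnot(is(manifest, "CohortManifest"))
  utils::write.csv(manifest@records, path, row.names = FALSE)
  invisible(path)
}

.isAbsPath <- function(p) grepl("^(/|[A-Za-z]:)", p)

#' Resolve a manifest path column entry to an absolute path
#' @noRd
.manifestPath <- function(manifest, i, col) {
  p <- manifest@records[[col]][i]
  if (is.na(p) || !nzchar(p)) return(NA_character_)
  if (.isAbsPath(p)) p else file.path(manifest@rootDir, p)
}

#' Load image and masks for one manifest row
#' @noRd
.loadSubject <- function(manifest, i, masks = "truth") {
  col <- switch(masks, truth = "mask_truth", predicted = "mask_pred")
  img <- readImageStack(.manifestPath(manifest, i, "image"),
                        subjectID = manifest@records$subject_id[i])
  mp <- .manifestPath(manifest, i, col)
  if (is.na(mp)) stop("subject ", subjectID(img), " has no ", masks, " mask")
  src <- if (masks == "truth") "PHANTOM_TRUTH" else "NETWORK"
  msk <- readLabelMask(mp, source = src)
  list(image = img, truth = msk)
}
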