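#' Select the two consecutive slices carrying the midbrain
#'
#' Returns the consecutive slice pair maximising the total midbrain
#' (BACKGROUND + SNPC) pixel count; ties break to the smaller index.
#'
#' @param mask a [LabelMask-class].
#' @return Integer vector `c(i, i + 1)` of 1-based slice indices.
#' @export
#' @examples
#' m <- array(0L, c(4, 4, 4)); m[2, 2, 2:3] <- 1L
#' selectSlices(labelMask(m))  # 2 3
selectSlices <- function(mask) {
  stopifnot(is(mask, "LabelMask"))
  lab <- mask@data
  counts <- apply(lab != .LBL[["OUTSIDE"]], 3L, sum)
  if (length(counts) < 2L)
    stop("mask has fewer than 2 slices")
  pairSums <- counts[-length(counts)] + counts[-1L]
  if (max(pairSums) == 0L)
    stop("no consecutive slice pair contains midbrain pixels")
  i <- which.max(pairSums)   # which.max takes the first maximum: smaller index
  c(i, i + 1L)
}

#' Background (midbrain minus SNpc) intensity statistics
#'
#' The background is the midbrain with the SNpc subtracted. Mean signal
#' intensity (MSI) and sample SD (denominator n - 1) are pooled over the
#' BACKGROUND pixels of both slices of the pair — one MSI/SD per
#' subject.
#'
#' @param image an [ImageStack-class].
#' @param mask the aligned [LabelMask-class].
#' @param slices the consecutive slice pair; default [selectSlices()].
#' @return A [BackgroundStats-class].
#' @export
backgroundStats <- function(image, mask, slices = NULL) {
  stopifnot(is(image, "ImageStack"), is(mask, "LabelMask"))
  if (!identical(dim(image@data), dim(mask@data)))
    stop("image and mask geometries differ")
  if (is.null(slices)) slices <- selectSlices(mask)
  stopifnot(length(slices) == 2L, diff(slices) == 1L)
  vals <- image@data[, , slices][mask@data[, , slices] == .LBL[["BACKGROUND"]]]
  if (length(vals) < 2L)
    stop("fewer than 2 background pixels on slices ",
         paste(slices, collapse = "-"))
  new("BackgroundStats", msi = mean(vals), sd = stats::sd(vals),
      nPixels = length(vals), sliceIndices = as.integer(slices))
}

#' Hyperintense SNpc area above MSI + k * SD
#'
#' Counts SNpc-labelled pixels on the selected slice pair whose
#' intensity is strictly greater than `msi + k * sd` of the background,
#' and converts the count to an area by multiplying with the in-plane
#' pixel area (mm^2).
#'
#' @param image an [ImageStack-class].
#' @param mask the aligned [LabelMask-class].
#' @param k threshold multiplier in background-SD units (the sweep uses
#'   1, 1.5, 2; 1.5 is the reference threshold).
#' @param slices slice pair; default [selectSlices()].
#' @param stats optional precomputed [BackgroundStats-class].
#' @return A [HyperintenseResult-class].
#' @export
hyperintenseArea <- function(image, mask, k = 1.5, slices = NULL,
                             stats = NULL) {
  stopifnot(is(image, "ImageStack"), is(mask, "LabelMask"), is.finite(k))
  if (is.null(slices)) slices <- selectSlices(mask)
  if (is.null(stats)) stats <- backgroundStats(image, mask, slices)
  thr <- stats@msi + k * stats@sd
  perSlice <- data.frame(slice = as.integer(slices), count = 0L)
  for (j in seq_along(slices)) {
    s <- slices[j]
    snpc <- mask@data[, , s] == .LBL[["SNPC"]]
    perSlice$count[j] <- sum(image@data[, , s][snpc] > thr)
  }
  count <- sum(perSlice$count)
  new("HyperintenseResult", k = k, threshold = thr,
      count = as.integer(count),
      areaMM2 = count * prod(image@pixelSpacing),
      perSlice = perSlice, background = stats)
}

#' Relative variation of the background signal
#'
#' MSI divided by its SD; an image-quality index.
#'
#' @param stats a [BackgroundStats-class] with `sd > 0`.
#' @return `msi / sd`.
#' @export
relativeVariation <- function(stats) {
  stopifnot(is(stats, "BackgroundStats"))
  if (stats@sd == 0)
    stop("relative variation undefined: background SD is 0")
  stats@msi / stats@sd
}

#' Quantify hyperintense areas for a whole cohort
#'
#' Runs [hyperintenseArea()] for every subject and every threshold
#' multiplier. Subjects whose masks carry no midbrain slices are
#' reported in a `failures` attribute and skipped.
#'
#' @param subjects named list of `list(image = , truth = )` pairs (as
#'   from [generateCohortInMemory()]), or a [CohortManifest-class].
#' @param ks threshold multipliers (default `c(1, 1.5, 2)`).
#' @param masks for a manifest: `"truth"` or `"predicted"`.
#' @param groups optional character vector of group labels (taken from
#'   the manifest/records when available).
#' @return data.frame with one row per subject x k: `subject_id`,
#'   `group`, `k`, `msi`, `sd`, `threshold`, `count`, `area_mm2`,
#'   `slices_used`; failures (if any) in `attr(, "failures")`.
#' @export
quantifyCohort <- function(subjects, ks = c(1, 1.5, 2), masks = "truth",
                           groups = NULL) {
  if (is(subjects, "CohortManifest")) {
    man <- subjects
    n <- nrow(man@records)
    loader <- function(i) .loadSubject(man, i, masks)
    ids <- man@records$subject_id
    groups <- man@records$group
  } else {
    n <- length(subjects)
    loader <- function(i) {
      s <- subjects[[i]]
      if (is(s, "PhantomSubject")) list(image = s@image, truth = s@truth)
      else s
    }
    ids <- if (!is.null(names(subjects))) names(subjects)
           else sprintf("S%03d", seq_len(n))
    if (is.null(groups))
      groups <- vapply(seq_len(n), function(i) {
        s <- subjects[[i]]
        if (is(s, "PhantomSubject")) s@record$group else NA_character_
      }, character(1))
  }
  rows <- list(); failures <- character(0)
  for (i in seq_len(n)) {
    sub <- loader(i)
    res <- tryCatch({
      slices <- selectSlices(sub$truth)
      bg <- backgroundStats(sub$image, sub$truth, slices)
      do.call(rbind, lapply(ks, function(k) {
        h <- hyperintenseArea(sub$image, sub$truth, k, slices, bg)
        data.frame(subject_id = ids[i], group = groups[i], k = k,
                   msi = bg@msi, sd = bg@sd, threshold = h@threshold,
                   count = h@count, area_mm2 = h@areaMM2,
                   slices_used = paste(slices, collapse = "-"),
                   stringsAsFactors = FALSE)
      }))
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", ids[i], conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "failures") <- failures
  out
}

#' Sweep threshold multipliers and pick the most discriminative
#'
#' Computes the ROC AUC of the per-subject hyperintense area for each
#' multiplier `k` (orientation: a LOW area indicates PD) and returns
#' the `k` with the highest AUC; ties break to the smallest `k`.
#'
#' @param areas data.frame from [quantifyCohort()] (columns `k`,
#'   `area_mm2`, `group`), or a matrix `subjects x ks` with `ks` as
#'   column names and `labels` supplied.
#' @param labels group labels (HC/PD) when `areas` is a matrix.
#' @return list with `k` (optimal multiplier), `auc` (named vector of
#'   AUCs per k).
#' @export
thresholdSweep <- function(areas, labels = NULL) {
  if (is.matrix(areas)) {
    ks <- as.numeric(colnames(areas))
    aucs <- vapply(seq_along(ks), function(j)
      rocAUC(areas[, j], labels, orientation = "low_is_positive")$auc,
      numeric(1))
  } else {
    stopifnot(all(c("k", "area_mm2", "group") %in% names(areas)))
    ks <- sort(unique(areas$k))
    aucs <- vapply(ks, function(kk) {
      sub <- areas[areas$k == kk, ]
      rocAUC(sub$area_mm2, sub$group, orientation = "low_is_positive")$auc
    }, numeric(1))
  }
  names(aucs) <- ks
  list(k = ks[which.max(aucs)], auc = aucs)   # which.max: first max = smallest k
}
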