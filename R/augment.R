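#' Training-time augmentation specification
#'
#' Intensity deviation `A * (orig + B)`, in-plane rotation, and
#' rescaling, applied consistently to image and mask. Defaults are
#' gains 0.7/1.0/1.3, offsets -100/0/100, angles -30/0/+30 degrees and
#' scales 90/100/110%. `combine = "cartesian"` crosses all four axes
#' (81 variants at defaults); `"per_category"` takes the union of
#' single-axis deviations with the identity counted once (13 at
#' defaults).
#'
#' @param A gains (must include 1.0 for the identity by default).
#' @param B offsets.
#' @param angles rotation angles in degrees.
#' @param scales rescale factors (> 0).
#' @param combine `"cartesian"` or `"per_category"`.
#' @return A list of class `AugmentSpec`.
#' @export
augmentSpec <- function(A = c(0.7, 1.0, 1.3), B = c(-100, 0, 100),
                        angles = c(-30, 0, 30), scales = c(0.9, 1.0, 1.1),
                        combine = c("cartesian", "per_category")) {
  combine <- match.arg(combine)
  stopifnot(length(A) >= 1, length(B) >= 1, length(angles) >= 1,
            length(scales) >= 1, all(is.finite(c(A, B, angles, scales))),
            all(scales > 0))
  structure(list(A = A, B = B, angles = angles, scales = scales,
                 combine = combine), class = "AugmentSpec")
}

#' Affine intensity deviation A * (orig + B)
#'
#' Applies the gain/offset transform pixelwise. Masks are never touched
#' by intensity augmentation. For `A > 0` the transform is monotone in
#' the pixel intensities, so background-referenced suprathreshold sets
#' are invariant under it.
#'
#' @param image an [ImageStack-class].
#' @param A finite gain.
#' @param B finite offset.
#' @return A transformed [ImageStack-class].
#' @export
#' @examples
#' s <- imageStack(matrix(100, 4, 4))
#' range(imageData(intensityTransform(s, 0.7, 100)))  # 140
intensityTransform <- function(image, A, B) {
  stopifnot(is(image, "ImageStack"), is.finite(A), is.finite(B))
  out <- image
  out@data <- A * (image@data + B)
  out
}

## Inverse-mapped affine resampling of one slice about its centre.
## method "bilinear" for intensities, "nearest" for labels; coordinates
## falling outside the canvas take `fill`.
.resampleSlice <- function(mat, angle = 0, scale = 1,
                           method = c("bilinear", "nearest"), fill = 0) {
  method <- match.arg(method)
  H <- nrow(mat); W <- ncol(mat)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  g <- expand.grid(r = seq_len(H), c = seq_len(W))
  a <- -angle * pi / 180            # inverse rotation
  y <- (g$r - cy) / scale; x <- (g$c - cx) / scale
  ys <- cos(a) * y - sin(a) * x + cy
  xs <- sin(a) * y + cos(a) * x + cx
  if (method == "nearest") {
    ri <- round(ys); ci <- round(xs)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out <- rep(fill, H * W)
    out[ok] <- mat[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(ys); c0 <- floor(xs)
    fr <- ys - r0; fc <- xs - c0
    out <- rep(as.numeric(fill), H * W)
    ok <- r0 >= 1 & r0 + 1 <= H & c0 >= 1 & c0 + 1 <= W
    if (any(ok)) {
      r0k <- r0[ok]; c0k <- c0[ok]; frk <- fr[ok]; fck <- fc[ok]
      v00 <- mat[cbind(r0k, c0k)];     v01 <- mat[cbind(r0k, c0k + 1)]
      v10 <- mat[cbind(r0k + 1, c0k)]; v11 <- mat[cbind(r0k + 1, c0k + 1)]
      out[ok] <- (1 - frk) * ((1 - fck) * v00 + fck * v01) +
                 frk * ((1 - fck) * v10 + fck * v11)
    }
    ## border pixels exactly on the last row/col: nearest fallback
    edge <- !ok & ys >= 0.5 & ys <= H + 0.49 & xs >= 0.5 & xs <= W + 0.49
    if (any(edge)) {
      ri <- pmin(pmax(round(ys[edge]), 1), H)
      ci <- pmin(pmax(round(xs[edge]), 1), W)
      out[edge] <- mat[cbind(ri, ci)]
    }
  }
  matrix(out, H, W)
}

.transformPair <- function(image, mask, angle, scale) {
  stopifnot(is(image, "ImageStack"), is(mask, "LabelMask"))
  if (!identical(dim(image@data), dim(mask@data)))
    stop("image and mask geometries differ")
  imgOut <- image; mskOut <- mask
  for (s in seq_len(nSlices(image))) {
    sl <- image@data[, , s]
    imgOut@data[, , s] <- .resampleSlice(sl, angle, scale, "bilinear",
                                         fill = min(sl))
    mskOut@data[, , s] <- .resampleSlice(mask@data[, , s], angle, scale,
                                         "nearest",
                                         fill = .LBL[["OUTSIDE"]])
  }
  storage.mode(mskOut@data) <- "integer"
  list(image = imgOut, mask = mskOut)
}

#' Rotate an image/mask pair about the slice centre
#'
#' Bilinear interpolation for the image, nearest-neighbour for the mask
#' (labels stay in the three-letter alphabet). Pixels rotated in from
#' outside the canvas take the slice minimum (image) or OUTSIDE (mask).
#'
#' @param image an [ImageStack-class].
#' @param mask the aligned [LabelMask-class].
#' @param angle rotation in degrees (counter-clockwise in row/col
#'   space).
#' @return `list(image = , mask = )`.
#' @export
rotatePair <- function(image, mask, angle) {
  stopifnot(is.finite(angle))
  if (angle == 0) return(list(image = image, mask = mask))
  .transformPair(image, mask, angle = angle, scale = 1)
}

#' Rescale an image/mask pair about the slice centre
#'
#' The canvas size is preserved: scaling up crops, scaling down pads
#' with the fill values. A factor small enough to shrink the midbrain
#' away produces a warning, not an error.
#'
#' @inheritParams rotatePair
#' @param factor scale factor (> 0); 0.9 shrinks to 90%.
#' @return `list(image = , mask = )`.
#' @export
rescalePair <- function(image, mask, factor) {
  stopifnot(is.finite(factor), factor > 0)
  if (factor == 1) return(list(image = image, mask = mask))
  out <- .transformPair(image, mask, angle = 0, scale = factor)
  if (any(mask@data != .LBL[["OUTSIDE"]]) &&
      !any(out$mask@data != .LBL[["OUTSIDE"]]))
    warning("rescaling removed all non-OUTSIDE pixels (factor = ", factor, ")")
  out
}

#' Enumerate the augmented variants of one subject
#'
#' `cartesian` crosses gains x offsets x angles x scales;
#' `per_category` applies each single-axis deviation to the original
#' (identity included once). The identity variant is always first.
#'
#' @param image an [ImageStack-class].
#' @param mask the aligned [LabelMask-class].
#' @param spec an [augmentSpec()].
#' @return List of `list(image, mask, params)` variants.
#' @export
enumerateAugmentations <- function(image, mask, spec = augmentSpec()) {
  stopifnot(inherits(spec, "AugmentSpec"))
  if (spec$combine == "cartesian") {
    grid <- expand.grid(A = spec$A, B = spec$B, angle = spec$angles,
                        scale = spec$scales, KEEP.OUT.ATTRS = FALSE)
  } else {
    grid <- rbind(
      expand.grid(A = spec$A, B = spec$B, angle = 0, scale = 1,
                  KEEP.OUT.ATTRS = FALSE),
      data.frame(A = 1, B = 0, angle = spec$angles, scale = 1),
      data.frame(A = 1, B = 0, angle = 0, scale = spec$scales))
    grid <- grid[!duplicated(grid), , drop = FALSE]
  }
  ## identity first when present
  idt <- which(grid$A == 1 & grid$B == 0 & grid$angle == 0 & grid$scale == 1)
  if (length(idt) == 1L)
    grid <- rbind(grid[idt, , drop = FALSE], grid[-idt, , drop = FALSE])
  lapply(seq_len(nrow(grid)), function(i) {
    p <- grid[i, ]
    geo <- if (p$angle == 0 && p$scale == 1) list(image = image, mask = mask)
           else .transformPair(image, mask, p$angle, p$scale)
    img <- if (p$A == 1 && p$B == 0) geo$image
           else intensityTransform(geo$image, p$A, p$B)
    list(image = img, mask = geo$mask,
         params = c(A = p$A, B = p$B, angle = p$angle, scale = p$scale))
  })
}
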