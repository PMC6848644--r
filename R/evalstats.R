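#' Dice similarity coefficient between two segmentations
#'
#' `Dice(A, B) = 2 |A n B| / (|A| + |B|)` over the pixels of the chosen
#' structure: `"midbrain"` selects BACKGROUND + SNPC, `"snpc"` selects
#' SNPC only. When both regions are empty the coefficient is defined as
#' 1 (perfect agreement on absence).
#'
#' @param a,b [LabelMask-class] objects of identical geometry, or
#'   logical arrays of identical dimension.
#' @param structure `"midbrain"` or `"snpc"` (ignored for logical
#'   input).
#' @param slices optional slice indices over which to evaluate
#'   (default: all slices).
#' @return The Dice coefficient in `[0, 1]`.
#' @export
#' @examples
#' a <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
#' b <- array(c(TRUE, FALSE, TRUE, FALSE), c(2, 2, 1))
#' dice(a, b)  # 0.5
dice <- function(a, b, structure = c("midbrain", "snpc"), slices = NULL) {
  structure <- match.arg(structure)
  toRegion <- function(x) {
    if (is(x, "LabelMask")) {
      lab <- x@data
      if (structure == "midbrain") lab != .LBL[["OUTSIDE"]]
      else lab == .LBL[["SNPC"]]
    } else if (is.logical(x)) x
    else stop("inputs must be LabelMask or logical arrays")
  }
  ra <- toRegion(a); rb <- toRegion(b)
  if (!identical(dim(ra), dim(rb)))
    stop("geometry mismatch: ", paste(dim(ra), collapse = "x"), " vs ",
         paste(dim(rb), collapse = "x"))
  if (!is.null(slices)) {
    ra <- ra[, , slices, drop = FALSE]
    rb <- rb[, , slices, drop = FALSE]
  }
  na <- sum(ra); nb <- sum(rb)
  if (na + nb == 0L) return(1)
  2 * sum(ra & rb) / (na + nb)
}

#' Rate a Dice coefficient on the three-level scale
#'
#' `0.0-0.39` low, `0.40-0.79` moderate, `0.80-1.0` high; band edges
#' exactly as printed (0.79 is moderate, 0.80 is high).
#'
#' @param dsc Dice coefficient(s) in `[0, 1]`.
#' @return Character vector: `"low"`, `"moderate"` or `"high"`.
#' @export
rateDSC <- function(dsc) {
  if (any(!is.finite(dsc)) || any(dsc < 0 | dsc > 1))
    stop("DSC values must lie in [0, 1]")
  ifelse(dsc < 0.40, "low", ifelse(dsc < 0.80, "moderate", "high"))
}

#' Strength bands for a Spearman correlation coefficient
#'
#' `|r|`: 0.00-0.19 very weak, 0.20-0.39 weak, 0.40-0.59 moderate,
#' 0.60-0.79 strong, 0.80-1.0 very strong.
#' @noRd
.spearmanBand <- function(r) {
  a <- abs(r)
  if (a < 0.20) "very weak" else if (a < 0.40) "weak"
  else if (a < 0.60) "moderate" else if (a < 0.80) "strong"
  else "very strong"
}

#' ROC analysis of a per-subject statistic
#'
#' AUC by the rank (Mann-Whitney) method with ties contributing 1/2;
#' the optimal cut-off maximises Youden's J (sensitivity +
#' specificity - 1), ties breaking to the higher specificity. For the
#' hyperintense SNpc area use `orientation = "low_is_positive"`: PD
#' (the positive class) has *smaller* areas.
#'
#' @param scores numeric per-subject statistic.
#' @param labels group labels; `"PD"` is the positive class, `"HC"` the
#'   negative (a factor/character with exactly these two levels, or a
#'   logical with TRUE = positive).
#' @param orientation `"low_is_positive"` or `"high_is_positive"`.
#' @return list of class `rocReport`: `auc`, `cutoff` (in score units),
#'   `sensitivity`, `specificity` at the cut-off, `orientation`, and a
#'   `curve` data.frame of (cutoff, sensitivity, specificity).
#' @export
#' @examples
#' rocAUC(c(1, 2, 3, 4), c("PD", "PD", "HC", "HC"))$auc  # 1
rocAUC <- function(scores, labels,
                   orientation = c("low_is_positive", "high_is_positive")) {
  orientation <- match.arg(orientation)
  pos <- .positiveLabels(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  stopifnot(length(scores) == length(pos), all(is.finite(scores)))
  ## direction: s has higher values for the positive class
  s <- if (orientation == "low_is_positive") -scores else scores
  n1 <- sum(pos); n2 <- sum(!pos)
  r <- rank(s)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  ## candidate cut-offs in oriented score space: positive iff s > c
  cand <- sort(unique(c(s, min(s) - 1)))
  sens <- vapply(cand, function(cc) sum(pos & s > cc) / n1, numeric(1))
  spec <- vapply(cand, function(cc) sum(!pos & s <= cc) / n2, numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]
  cutoff <- if (orientation == "low_is_positive") -cand[best] else cand[best]
  structure(list(auc = auc, cutoff = cutoff,
                 sensitivity = sens[best], specificity = spec[best],
                 orientation = orientation,
                 curve = data.frame(
                   cutoff = if (orientation == "low_is_positive") -cand
                            else cand,
                   sensitivity = sens, specificity = spec)),
            class = "rocReport")
}

#' @export
print.rocReport <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f | cutoff %.4g (%s): sens %.3f, spec %.3f\n",
              x$auc, x$cutoff, x$orientation, x$sensitivity, x$specificity))
  invisible(x)
}

.positiveLabels <- function(labels) {
  if (is.logical(labels)) return(labels)
  u <- unique(as.character(labels))
  if (!all(u %in% c("HC", "PD")))
    stop("labels must be HC/PD (or logical); got: ",
         paste(u, collapse = ", "))
  as.character(labels) == "PD"
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two scores measured on the same subjects using
#' the placement-value (structural components) covariance estimate;
#' `z = (auc_a - auc_b) / sqrt(var)`, two-sided normal p value.
#' Identical curves give `z = 0, p = 1`; a zero-variance difference
#' with unequal AUCs is an error.
#'
#' @param scoresA,scoresB paired per-subject statistics.
#' @param labels group labels (see [rocAUC()]).
#' @param orientation score orientation, shared by both methods.
#' @return list of class `delongResult`: `aucA`, `aucB`, `z`, `p`.
#' @export
delongTest <- function(scoresA, scoresB, labels,
                       orientation = c("low_is_positive",
                                       "high_is_positive")) {
  orientation <- match.arg(orientation)
  pos <- .positiveLabels(labels)
  stopifnot(length(scoresA) == length(pos),
            length(scoresB) == length(pos))
  if (!any(pos) || all(pos)) stop("both classes must be present")
  flip <- if (orientation == "low_is_positive") -1 else 1
  placements <- function(s) {
    x <- flip * s[pos]; y <- flip * s[!pos]
    m <- length(x); n <- length(y)
    ## psi(x_i, y_j) = 1 if x > y, 1/2 if tie
    cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
    list(auc = mean(cmp), v10 = rowMeans(cmp), v01 = colMeans(cmp))
  }
  pa <- placements(scoresA); pb <- placements(scoresB)
  m <- sum(pos); n <- sum(!pos)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  varDiff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- pa$auc - pb$auc
  if (varDiff <= .Machine$double.eps^0.5) {
    if (abs(d) < 1e-12) {
      z <- 0; p <- 1
    } else {
      stop("zero variance of the AUC difference with unequal AUCs")
    }
  } else {
    z <- d / sqrt(varDiff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(aucA = pa$auc, aucB = pb$auc, z = z, p = p),
            class = "delongResult")
}

#' @export
print.delongResult <- function(x, ...) {
  cat(sprintf("DeLong: AUC %.3f vs %.3f | z = %.3f, p = %.4g\n",
              x$aucA, x$aucB, x$z, x$p))
  invisible(x)
}

#' Spearman rank correlation with strength rating
#'
#' Average ranks for ties; p value from [stats::cor.test()]. The
#' strength category follows the five-band scale on `|r|`
#' (0.00-0.19 very weak ... 0.80-1.0 very strong).
#'
#' @param x,y paired finite numeric vectors, `n >= 3`.
#' @return list: `r`, `p`, `category`.
#' @export
spearmanStrength <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input vector: rank correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  r <- unname(ct$estimate)
  list(r = r, p = ct$p.value, category = .spearmanBand(r))
}

#' Two-group comparison tests
#'
#' Wrappers with the conventions used throughout the package:
#' `"t"` is the classic equal-variance Student's t test (two-sided),
#' `"mann_whitney"` the Wilcoxon rank-sum test, `"chi2"` the chi-squared
#' test *without* continuity correction on a 2x2 count table (passed as
#' `a`, with `b` ignored).
#'
#' @param a,b numeric samples, or (`chi2`) `a` a 2x2 matrix.
#' @param test `"t"`, `"mann_whitney"` or `"chi2"`.
#' @return list: `statistic`, `p`, `test`.
#' @export
groupCompare <- function(a, b = NULL, test = c("t", "mann_whitney", "chi2")) {
  test <- match.arg(test)
  res <- switch(test,
    t = {
      if (!length(a) || !length(b)) stop("empty group")
      h <- stats::t.test(a, b, var.equal = TRUE)
      list(statistic = unname(h$statistic), p = h$p.value)
    },
    mann_whitney = {
      if (!length(a) || !length(b)) stop("empty group")
      h <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                               correct = FALSE))
      list(statistic = unname(h$statistic), p = h$p.value)
    },
    chi2 = {
      stopifnot(is.matrix(a), all(dim(a) == 2L))
      if (any(rowSums(a) == 0) || any(colSums(a) == 0))
        stop("chi-squared test undefined: zero margin")
      h <- suppressWarnings(stats::chisq.test(a, correct = FALSE))
      list(statistic = unname(h$statistic), p = h$p.value)
    })
  c(res, list(test = test))
}

#' Dice table for a cohort (structure x group)
#'
#' Mean and SD of the per-subject Dice coefficients between two mask
#' sets, split by structure and group, in the layout of a segmentation
#' accuracy table.
#'
#' @param masksA,masksB named lists of [LabelMask-class] (same names).
#' @param groups named character vector of group labels per subject.
#' @param slices optional named list of slice pairs per subject.
#' @return data.frame: structure, group (All/HC/PD), n, meanDSC, sdDSC,
#'   rating.
#' @export
diceTable <- function(masksA, masksB, groups, slices = NULL) {
  stopifnot(identical(sort(names(masksA)), sort(names(masksB))))
  ids <- names(masksA)
  per <- do.call(rbind, lapply(ids, function(id) {
    sl <- if (!is.null(slices)) slices[[id]] else NULL
    data.frame(subject_id = id, group = unname(groups[id]),
               midbrain = dice(masksA[[id]], masksB[[id]], "midbrain", sl),
               snpc = dice(masksA[[id]], masksB[[id]], "snpc", sl),
               stringsAsFactors = FALSE)
  }))
  rows <- list()
  for (st in c("midbrain", "snpc")) {
    for (gr in c("All", "HC", "PD")) {
      sel <- if (gr == "All") rep(TRUE, nrow(per)) else per$group == gr
      if (!any(sel)) next
      v <- per[[st]][sel]
      rows[[length(rows) + 1L]] <- data.frame(
        structure = st, group = gr, n = sum(sel),
        meanDSC = mean(v), sdDSC = if (sum(sel) > 1) stats::sd(v) else NA_real_,
        rating = rateDSC(mean(v)), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "perSubject") <- per
  out
}
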