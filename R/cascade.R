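#' Network configuration for one stage of the cascade
#'
#' The architecture follows the U-net encoder-decoder with skip
#' connections, except that max pooling is replaced by 3x3 convolution
#' with a stride of 2, and upsampling uses 2x2 transposed convolution.
#' Two presets are provided: `"desk"` (depth 3, 8 base channels) trains
#' on a CPU in minutes; `"paper_like"` (depth 4, 64 base channels)
#' follows the original U-net channel schedule.
#'
#' @param depth number of resolution levels (>= 2).
#' @param baseChannels channels at the finest level; doubled per level.
#' @param inChannels input channels (1 for the midbrain net, 2 for the
#'   SNpc net, which also receives the midbrain probability).
#' @param preset `"desk"` or `"paper_like"`; overrides depth/channels.
#' @return A list of class `NetConfig`.
#' @export
netConfig <- function(depth = 3L, baseChannels = 8L, inChannels = 1L,
                      preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("desk", "paper_like"))
    if (preset == "desk") { depth <- 3L; baseChannels <- 8L }
    else { depth <- 4L; baseChannels <- 64L }
  }
  stopifnot(depth >= 2L, baseChannels >= 1L, inChannels >= 1L)
  structure(list(depth = as.integer(depth),
                 baseChannels = as.integer(baseChannels),
                 inChannels = as.integer(inChannels), classes = 2L),
            class = "NetConfig")
}

#' Training configuration for the cascade
#'
#' Defaults mirror the original training recipe at desk scale: random
#' crops, batch size 2, mean cross entropy per network, Adam with
#' `alpha = 1e-4`, `beta1 = 0.5`, `beta2 = 0.999`, 10 epochs, 4-fold
#' cross-validation, no early stopping. One epoch is a shuffled pass
#' over every (subject x augmentation variant) sample.
#'
#' @param cropSize square crop side in pixels (256 at full scale; 96
#'   for the 128 px phantoms). Must be divisible by
#'   `2^(depth - 1)`.
#' @param batchSize samples per optimisation step.
#' @param epochs training epochs (>= 1).
#' @param alpha,beta1,beta2 Adam hyper-parameters.
#' @param folds cross-validation folds (>= 2).
#' @param seed RNG seed for initialisation, shuffling and crops.
#' @param normalize `"zscore"` (per-slice standardisation of network
#'   input; the background-referenced quantification downstream is
#'   unaffected) or `"none"` (raw intensities).
#' @param augment `"per_category"`, `"cartesian"` or `"none"`.
#' @param secondInput `"soft"` (concatenate the midbrain probability
#'   map) or `"hard"` (concatenate the binarised midbrain mask).
#' @param freeze character subset of `c("midbrain", "snpc")`: networks
#'   whose weights are left untouched during training.
#' @param emptySliceFrac fraction of training samples drawn from slices
#'   without midbrain.
#' @return A list of class `TrainConfig`.
#' @export
trainConfig <- function(cropSize = 96L, batchSize = 2L, epochs = 10L,
                        alpha = 1e-4, beta1 = 0.5, beta2 = 0.999,
                        folds = 4L, seed = 1L,
                        normalize = c("zscore", "none"),
                        augment = c("per_category", "cartesian", "none"),
                        secondInput = c("soft", "hard"),
                        freeze = character(0),
                        emptySliceFrac = 0.2) {
  normalize <- match.arg(normalize)
  augment <- match.arg(augment)
  secondInput <- match.arg(secondInput)
  if (epochs < 1L) stop("epochs must be >= 1")
  stopifnot(cropSize >= 8L, batchSize >= 1L, folds >= 2L,
            all(freeze %in% c("midbrain", "snpc")),
            emptySliceFrac >= 0, emptySliceFrac < 1)
  structure(list(cropSize = as.integer(cropSize),
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), alpha = alpha,
                 beta1 = beta1, beta2 = beta2, folds = as.integer(folds),
                 seed = as.integer(seed), normalize = normalize,
                 augment = augment, secondInput = secondInput,
                 freeze = freeze, emptySliceFrac = emptySliceFrac),
            class = "TrainConfig")
}

#' Build an untrained cascade
#'
#' Network 1 segments midbrain vs outside from the image; network 2
#' segments SNpc vs background from the image plus network 1's midbrain
#' probability map. The two networks are independent parameter sets:
#' their losses are disconnected by construction.
#'
#' @param cfgMidbrain [netConfig()] for network 1 (`inChannels = 1`).
#' @param cfgSNpc [netConfig()] for network 2 (`inChannels = 2`).
#' @param seed initialisation seed (same seed, same initial weights).
#' @return A [CascadeModel-class].
#' @export
buildCascade <- function(cfgMidbrain = netConfig(inChannels = 1L),
                         cfgSNpc = netConfig(inChannels = 2L),
                         seed = 1L) {
  stopifnot(inherits(cfgMidbrain, "NetConfig"), inherits(cfgSNpc, "NetConfig"))
  new("CascadeModel",
      netMidbrain = .initUNet(cfgMidbrain, seed),
      netSNpc = .initUNet(cfgSNpc, seed + 1L),
      trainConfig = list(),
      provenance = list(seed = seed,
                        version = as.character(utils::packageVersion("nmseg"))))
}

#' Compose the second network's input
#'
#' Deterministic channel concatenation of the (normalised) image slice
#' and network 1's midbrain probability map: the second network sees
#' where the first believes the midbrain is, without hard masking.
#'
#' @param imageSlice numeric matrix (H x W), or an (H*W x 1) matrix.
#' @param midbrainProb numeric matrix of identical geometry with values
#'   in `[0, 1]`.
#' @return An (H*W x 2) matrix: image channel, probability channel.
#' @export
composeSecondInput <- function(imageSlice, midbrainProb) {
  if (length(imageSlice) != length(midbrainProb))
    stop("geometry mismatch between image and midbrain probability map")
  cbind(as.vector(imageSlice), as.vector(midbrainProb))
}

.normalizeSlice <- function(x, mode) {
  if (mode == "none") return(x)
  s <- stats::sd(x)
  if (s == 0) x - mean(x) else (x - mean(x)) / s
}

## subjects argument: CohortManifest, list of PhantomSubject, or list
## of list(image=, truth=)
.asSubjectList <- function(subjects, masks = "truth") {
  if (is(subjects, "CohortManifest")) {
    n <- nrow(subjects@records)
    out <- lapply(seq_len(n), function(i) .loadSubject(subjects, i, masks))
    names(out) <- subjects@records$subject_id
    attr(out, "groups") <- stats::setNames(subjects@records$group,
                                           subjects@records$subject_id)
    return(out)
  }
  out <- lapply(subjects, function(s) {
    if (is(s, "PhantomSubject")) list(image = s@image, truth = s@truth)
    else s
  })
  if (is.null(names(out)))
    names(out) <- sprintf("S%03d", seq_along(out))
  grp <- vapply(subjects, function(s)
    if (is(s, "PhantomSubject")) s@record$group else NA_character_,
    character(1))
  attr(out, "groups") <- stats::setNames(grp, names(out))
  out
}

## Precompute the augmented sample pool: one entry per
## (subject x variant), each holding the full image/mask arrays
.samplePool <- function(subs, cfg) {
  spec <- switch(cfg$augment,
                 none = augmentSpec(A = 1, B = 0, angles = 0, scales = 1),
                 per_category = augmentSpec(combine = "per_category"),
                 cartesian = augmentSpec(combine = "cartesian"))
  pool <- list()
  for (nm in names(subs)) {
    vars <- enumerateAugmentations(subs[[nm]]$image, subs[[nm]]$truth, spec)
    for (v in vars)
      pool[[length(pool) + 1L]] <- list(img = v$image@data,
                                        lab = v$mask@data)
  }
  pool
}

.randomCrop <- function(H, W, crop) {
  r0 <- if (H > crop) sample.int(H - crop + 1L, 1L) else 1L
  c0 <- if (W > crop) sample.int(W - crop + 1L, 1L) else 1L
  c(r0, c0)
}

#' Train the cascade
#'
#' Per iteration: a random slice and crop per batch element, forward
#' through both networks (the second fed by [composeSecondInput()] on
#' the first's current output), two mean cross-entropy losses —
#' network 1 over all crop pixels (midbrain vs outside), network 2
#' restricted to pixels inside the ground-truth midbrain (SNpc vs
#' background) — and two disconnected Adam updates. Fully reproducible
#' for a fixed `cfg$seed`.
#'
#' @param subjects training set: a [CohortManifest-class], a list of
#'   [PhantomSubject-class], or a list of `list(image =, truth =)`.
#' @param cfg a [trainConfig()].
#' @param model optional starting [CascadeModel-class]; default built
#'   from desk-preset configs with `cfg$seed`.
#' @return The trained [CascadeModel-class]; the per-iteration loss
#'   trace is in `provenance$lossTrace` (data.frame with columns
#'   `iter`, `lossMidbrain`, `lossSNpc`).
#' @export
trainCascade <- function(subjects, cfg = trainConfig(), model = NULL) {
  stopifnot(inherits(cfg, "TrainConfig"))
  subs <- .asSubjectList(subjects)
  if (length(subs) == 0L) stop("empty training set")
  dims <- dim(subs[[1L]]$image@data)
  if (cfg$cropSize > min(dims[1:2]))
    stop("crop size ", cfg$cropSize, " larger than image ",
         paste(dims[1:2], collapse = "x"))
  if (is.null(model))
    model <- buildCascade(netConfig(inChannels = 1L),
                          netConfig(inChannels = 2L), seed = cfg$seed)
  net1 <- model@netMidbrain; net2 <- model@netSNpc
  .checkDivisible(cfg$cropSize, cfg$cropSize, net1$cfg$depth)
  .checkDivisible(cfg$cropSize, cfg$cropSize, net2$cfg$depth)

  set.seed(cfg$seed)
  pool <- .samplePool(subs, cfg)
  ## per-sample slice inventory
  midSlices <- lapply(pool, function(p)
    which(apply(p$lab != .LBL[["OUTSIDE"]], 3L, any)))
  allSlices <- seq_len(dim(pool[[1L]]$img)[3L])
  crop <- cfg$cropSize
  trace <- list()
  iter <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(length(pool))
    bstarts <- seq(1L, length(ord), by = cfg$batchSize)
    for (bs in bstarts) {
      batch <- ord[bs:min(bs + cfg$batchSize - 1L, length(ord))]
      g1 <- NULL; g2 <- NULL; l1 <- c(); l2 <- c()
      for (pi in batch) {
        p <- pool[[pi]]
        ms <- midSlices[[pi]]
        useEmpty <- length(setdiff(allSlices, ms)) > 0L &&
          stats::runif(1) < cfg$emptySliceFrac
        s <- if (useEmpty) sample(setdiff(allSlices, ms), 1L)
             else if (length(ms)) ms[sample.int(length(ms), 1L)]
             else sample(allSlices, 1L)
        off <- .randomCrop(dims[1L], dims[2L], crop)
        rows <- off[1L]:(off[1L] + crop - 1L)
        cols <- off[2L]:(off[2L] + crop - 1L)
        img <- .normalizeSlice(p$img[rows, cols, s], cfg$normalize)
        lab <- p$lab[rows, cols, s]
        x1 <- matrix(as.vector(img), ncol = 1L)
        y1 <- as.integer(as.vector(lab) != .LBL[["OUTSIDE"]]) + 1L
        fw1 <- .unetForward(net1, x1, crop, crop)
        ce1 <- .softmaxCE(fw1$prob, y1)
        b1 <- .unetBackward(net1, fw1$cache, ce1$dLogits)
        g1 <- .accumGrads(g1, b1)
        l1 <- c(l1, ce1$loss)
        pm <- fw1$prob[, 2L]
        if (cfg$secondInput == "hard") pm <- as.numeric(pm > 0.5)
        x2 <- composeSecondInput(img, matrix(pm, crop, crop))
        inMB <- as.vector(lab) != .LBL[["OUTSIDE"]]
        y2 <- as.integer(as.vector(lab) == .LBL[["SNPC"]]) + 1L
        fw2 <- .unetForward(net2, x2, crop, crop)
        ce2 <- .softmaxCE(fw2$prob, y2, include = inMB)
        if (!is.null(ce2$dLogits)) {
          b2 <- .unetBackward(net2, fw2$cache, ce2$dLogits)
          g2 <- .accumGrads(g2, b2)
          l2 <- c(l2, ce2$loss)
        }
      }
      nb <- length(batch)
      if (!("midbrain" %in% cfg$freeze) && !is.null(g1))
        net1 <- .adamStep(net1, .scaleGrads(g1, 1 / nb),
                          cfg$alpha, cfg$beta1, cfg$beta2)
      if (!("snpc" %in% cfg$freeze) && !is.null(g2))
        net2 <- .adamStep(net2, .scaleGrads(g2, 1 / length(l2)),
                          cfg$alpha, cfg$beta1, cfg$beta2)
      iter <- iter + 1L
      trace[[iter]] <- data.frame(iter = iter,
                                  lossMidbrain = mean(l1),
                                  lossSNpc = if (length(l2)) mean(l2)
                                             else NA_real_)
    }
  }
  model@netMidbrain <- net1
  model@netSNpc <- net2
  model@trainConfig <- unclass(cfg)
  model@provenance <- c(model@provenance[setdiff(names(model@provenance),
                                                 c("lossTrace", "seed"))],
                        list(seed = cfg$seed,
                             lossTrace = do.call(rbind, trace)))
  model
}

.accumGrads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) {
    acc[[nm]]$dW <- acc[[nm]]$dW + g[[nm]]$dW
    acc[[nm]]$db <- acc[[nm]]$db + g[[nm]]$db
  }
  acc
}

.scaleGrads <- function(g, f) {
  for (nm in names(g)) {
    g[[nm]]$dW <- g[[nm]]$dW * f
    g[[nm]]$db <- g[[nm]]$db * f
  }
  g
}

.reflectPad <- function(mat, padR, padC) {
  H <- nrow(mat); W <- ncol(mat)
  ri <- c(seq_len(H), H - seq_len(padR))      # reflect, edge not repeated
  ci <- c(seq_len(W), W - seq_len(padC))
  mat[ri, ci, drop = FALSE]
}

#' Segment an image with a cascade model
#'
#' Full-image inference (no cropping): each slice is reflect-padded to
#' the nearest multiple of `2^(depth-1)`, passed through network 1
#' (midbrain vs outside, argmax per pixel), composed with the image and
#' passed through network 2; within the predicted midbrain, network 2's
#' argmax decides SNpc vs background. Outside-midbrain pixels are
#' OUTSIDE, so predicted SNpc is contained in the predicted midbrain by
#' construction. At exactly tied probabilities the lower class index
#' wins (OUTSIDE over midbrain, BACKGROUND over SNpc), making inference
#' deterministic.
#'
#' @param model a [CascadeModel-class].
#' @param image an [ImageStack-class].
#' @return A [LabelMask-class] with source `"NETWORK"`.
#' @export
predictMask <- function(model, image) {
  stopifnot(is(model, "CascadeModel"), is(image, "ImageStack"))
  cfg <- model@trainConfig
  normalize <- if (length(cfg)) cfg$normalize else "zscore"
  secondInput <- if (length(cfg)) cfg$secondInput else "soft"
  d <- dim(image@data)
  f <- 2L^(max(model@netMidbrain$cfg$depth, model@netSNpc$cfg$depth) - 1L)
  padR <- (f - d[1L] %% f) %% f
  padC <- (f - d[2L] %% f) %% f
  H <- d[1L] + padR; W <- d[2L] + padC
  out <- array(.LBL[["OUTSIDE"]], d)
  for (s in seq_len(d[3L])) {
    sl <- .reflectPad(image@data[, , s], padR, padC)
    img <- .normalizeSlice(sl, normalize)
    fw1 <- .unetForward(model@netMidbrain,
                        matrix(as.vector(img), ncol = 1L), H, W,
                        keepCache = FALSE)
    isMB <- fw1$prob[, 2L] > fw1$prob[, 1L]
    pm <- fw1$prob[, 2L]
    if (secondInput == "hard") pm <- as.numeric(isMB)
    fw2 <- .unetForward(model@netSNpc, composeSecondInput(img, pm), H, W,
                        keepCache = FALSE)
    isSN <- fw2$prob[, 2L] > fw2$prob[, 1L]
    lab <- matrix(.LBL[["OUTSIDE"]], H, W)
    lab[isMB & !isSN] <- .LBL[["BACKGROUND"]]
    lab[isMB & isSN] <- .LBL[["SNPC"]]
    out[, , s] <- lab[seq_len(d[1L]), seq_len(d[2L])]
  }
  labelMask(out, source = "NETWORK")
}

#' Stratified k-fold cross-validation of the cascade
#'
#' Folds are stratified to a 1:1 HC:PD ratio (as close as the counts
#' allow): within each group, subjects are shuffled under `cfg$seed`
#' and dealt round-robin to folds. Each fold's model is trained on the
#' remaining folds and validated on the fold itself; per-structure mean
#' Dice is reported for both sets. The model trained with fold 1 held
#' out is designated the deployment model.
#'
#' @param subjects as in [trainCascade()]; group labels are required.
#' @param cfg a [trainConfig()].
#' @return list: `report` (data.frame fold x structure with mean
#'   train/validation Dice), `model` (deployment model, fold 1),
#'   `folds` (named fold assignment), `models` (all fold models).
#' @export
crossValidate <- function(subjects, cfg = trainConfig()) {
  subs <- .asSubjectList(subjects)
  groups <- attr(subs, "groups")
  if (anyNA(groups)) stop("group labels are required for stratification")
  k <- cfg$folds
  set.seed(cfg$seed)
  fold <- stats::setNames(integer(length(subs)), names(subs))
  for (g in unique(groups)) {
    ids <- names(groups)[groups == g]
    if (length(ids) < k)
      stop("group ", g, " has fewer subjects (", length(ids),
           ") than folds (", k, ")")
    fold[sample(ids)] <- rep_len(seq_len(k), length(ids))
  }
  report <- list(); models <- vector("list", k)
  for (f in seq_len(k)) {
    trainIDs <- names(fold)[fold != f]
    valIDs <- names(fold)[fold == f]
    cfgF <- cfg; cfgF$seed <- cfg$seed + f
    model <- trainCascade(subs[trainIDs], structure(cfgF,
                                                    class = "TrainConfig"))
    model@provenance$foldID <- f
    models[[f]] <- model
    evalSet <- function(ids) {
      dmb <- c(); dsn <- c()
      for (id in ids) {
        pred <- predictMask(model, subs[[id]]$image)
        sl <- selectSlices(subs[[id]]$truth)
        dmb <- c(dmb, dice(subs[[id]]$truth, pred, "midbrain", sl))
        dsn <- c(dsn, dice(subs[[id]]$truth, pred, "snpc", sl))
      }
      c(midbrain = mean(dmb), snpc = mean(dsn))
    }
    tr <- evalSet(trainIDs); va <- evalSet(valIDs)
    report[[f]] <- data.frame(fold = f,
                              structure = c("midbrain", "snpc"),
                              diceTrain = tr, diceValidation = va,
                              row.names = NULL)
  }
  list(report = do.call(rbind, report), model = models[[1L]],
       folds = fold, models = models)
}
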