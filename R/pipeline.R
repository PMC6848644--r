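#' Default run configuration
#'
#' A single structured configuration drives the full pipeline:
#' simulate -> train/cross-validate -> predict -> quantify -> evaluate.
#' Sections mirror [phantomParams()], [trainConfig()] and the
#' quantification options; unknown keys are rejected at load time.
#'
#' @param outputDir pipeline output directory.
#' @param seed global seed; stage seeds derive from it.
#' @return Nested list of class `RunConfig`.
#' @export
defaultRunConfig <- function(outputDir = "nmseg-run", seed = 20260101L) {
  structure(list(
    seed = as.integer(seed),
    output_dir = outputDir,
    phantom = list(n_hc = 8L, n_pd = 8L, sigma_noise = 8,
                   extent_hc = 0.95, extent_pd = 0.55),
    train = list(crop_size = 96L, batch_size = 2L, epochs = 10L,
                 alpha = 1e-4, beta1 = 0.5, beta2 = 0.999, folds = 4L,
                 normalize = "zscore", augment = "per_category",
                 second_input = "soft"),
    net = list(preset = "desk"),
    quantify = list(ks = c(1, 1.5, 2), frozen_k = NULL,
                    frozen_from = NULL),
    evaluate = list(roc_orientation = "low_is_positive")),
    class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with (a subset of) the sections of
#'   [defaultRunConfig()]; missing keys take defaults, unknown keys are
#'   an error.
#' @return A `RunConfig`.
#' @export
readRunConfig <- function(path) {
  usr <- yaml::read_yaml(path)
  def <- defaultRunConfig()
  merge <- function(d, u, prefix = "") {
    unknown <- setdiff(names(u), names(d))
    if (length(unknown))
      stop("unknown configuration key(s): ",
           paste0(prefix, unknown, collapse = ", "))
    for (nm in names(u)) {
      d[[nm]] <- if (is.list(d[[nm]]) && is.list(u[[nm]]))
        merge(d[[nm]], u[[nm]], paste0(prefix, nm, "."))
      else u[[nm]]
    }
    d
  }
  structure(merge(unclass(def), usr), class = "RunConfig")
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

.writeProvenance <- function(config, dir, stage, extra = list()) {
  prov <- c(list(stage = stage, config_hash = .configHash(config),
                 seed = config$seed,
                 version = as.character(utils::packageVersion("nmseg")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            extra)
  jsonlite::write_json(prov, file.path(dir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(prov)
}

.phantomFromConfig <- function(config) {
  ph <- config$phantom
  phantomParams(sigmaNoise = ph$sigma_noise,
                snpcExtent = c(HC = ph$extent_hc, PD = ph$extent_pd),
                seed = config$seed)
}

.trainFromConfig <- function(config) {
  tr <- config$train
  trainConfig(cropSize = tr$crop_size, batchSize = tr$batch_size,
              epochs = tr$epochs, alpha = tr$alpha, beta1 = tr$beta1,
              beta2 = tr$beta2, folds = tr$folds,
              seed = config$seed + 1L, normalize = tr$normalize,
              augment = tr$augment, secondInput = tr$second_input)
}

#' Simulate a phantom cohort (pipeline stage)
#'
#' Delegates to [generateCohort()] and writes a provenance record
#' (config hash, seed, package version) next to the data.
#'
#' @param config a `RunConfig`.
#' @param overwrite allow writing into an existing cohort directory.
#' @return The [CohortManifest-class].
#' @export
cmdSimulate <- function(config = defaultRunConfig(), overwrite = FALSE) {
  dir <- file.path(config$output_dir, "cohort")
  parent <- dirname(config$output_dir)
  if (!dir.exists(parent))
    stop("parent of output_dir does not exist: ", parent)
  dir.create(config$output_dir, showWarnings = FALSE)
  man <- generateCohort(.phantomFromConfig(config), config$phantom$n_hc,
                        config$phantom$n_pd, dir, overwrite = overwrite)
  .writeProvenance(config, config$output_dir, "simulate",
                   list(n_subjects = nrow(records(man))))
  man
}

#' Train the cascade by cross-validation (pipeline stage)
#'
#' Runs [crossValidate()] on the simulated cohort, writes the per-fold
#' Dice report, the per-iteration loss traces and the deployment model
#' (fold 1) checkpoint with a JSON sidecar.
#'
#' @param config a `RunConfig`.
#' @param overwrite allow replacing existing training outputs.
#' @return The [crossValidate()] result, invisibly.
#' @export
cmdTrain <- function(config = defaultRunConfig(), overwrite = FALSE) {
  modelDir <- file.path(config$output_dir, "model")
  if (dir.exists(modelDir) && !overwrite)
    stop("training outputs exist (use overwrite = TRUE): ", modelDir)
  dir.create(modelDir, recursive = TRUE, showWarnings = FALSE)
  man <- loadManifest(file.path(config$output_dir, "cohort", "manifest.csv"))
  cv <- crossValidate(man, .trainFromConfig(config))
  utils::write.csv(cv$report, file.path(modelDir, "fold_report.csv"),
                   row.names = FALSE)
  for (f in seq_along(cv$models))
    utils::write.csv(cv$models[[f]]@provenance$lossTrace,
                     file.path(modelDir, sprintf("loss_fold%d.csv", f)),
                     row.names = FALSE)
  saveRDS(cv$model, file.path(modelDir, "cascade_fold1.rds"))
  jsonlite::write_json(
    list(netMidbrain = unclass(cv$model@netMidbrain$cfg),
         netSNpc = unclass(cv$model@netSNpc$cfg),
         trainConfig = unclass(cv$model@trainConfig),
         foldID = cv$model@provenance$foldID,
         seed = cv$model@provenance$seed),
    file.path(modelDir, "cascade_fold1.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null")
  .writeProvenance(config, config$output_dir, "train")
  invisible(cv)
}

#' Predict masks for every cohort subject (pipeline stage)
#'
#' @param config a `RunConfig`.
#' @return The updated [CohortManifest-class] (with `mask_pred` paths).
#' @export
cmdPredict <- function(config = defaultRunConfig()) {
  dir <- file.path(config$output_dir, "cohort")
  man <- loadManifest(file.path(dir, "manifest.csv"))
  model <- readRDS(file.path(config$output_dir, "model",
                             "cascade_fold1.rds"))
  rec <- records(man)
  for (i in seq_len(nrow(rec))) {
    img <- readImageStack(.manifestPath(man, i, "image"),
                          subjectID = rec$subject_id[i])
    pred <- predictMask(model, img)
    rel <- file.path("masks", paste0(rec$subject_id[i], "_pred.nii.gz"))
    writeLabelMask(pred, file.path(dir, rel), reference = img)
    rec$mask_pred[i] <- rel
  }
  man@records <- rec
  writeManifest(man, file.path(dir, "manifest.csv"))
  .writeProvenance(config, config$output_dir, "predict")
  man
}

#' Quantify hyperintense SNpc areas (pipeline stage)
#'
#' Sweeps the threshold multipliers and records the most discriminative
#' one — unless `config$quantify$frozen_k` is set (external-validation
#' mode), in which case no sweep is performed, only the frozen
#' multiplier is applied, and the provenance records its source run.
#'
#' @param config a `RunConfig`.
#' @param masks `"truth"` or `"predicted"`.
#' @return data.frame of per-subject results (written to
#'   `quantify_<masks>.csv`); the chosen/frozen `k` and the per-k AUCs
#'   in attributes `k` and `auc`.
#' @export
cmdQuantify <- function(config = defaultRunConfig(), masks = "truth") {
  man <- loadManifest(file.path(config$output_dir, "cohort",
                                "manifest.csv"))
  frozen <- config$quantify$frozen_k
  ks <- if (is.null(frozen)) config$quantify$ks else frozen
  res <- quantifyCohort(man, ks = ks, masks = masks)
  if (length(attr(res, "failures")))
    message("quantification failures:\n  ",
            paste(attr(res, "failures"), collapse = "\n  "))
  if (is.null(frozen)) {
    sweep <- thresholdSweep(res)
    attr(res, "k") <- sweep$k
    attr(res, "auc") <- sweep$auc
    extra <- list(mode = "sweep", k = sweep$k,
                  auc = as.list(sweep$auc))
  } else {
    attr(res, "k") <- frozen
    extra <- list(mode = "frozen", k = frozen,
                  frozen_from = config$quantify$frozen_from)
  }
  out <- file.path(config$output_dir, sprintf("quantify_%s.csv", masks))
  utils::write.csv(res, out, row.names = FALSE)
  .writeProvenance(config, config$output_dir,
                   paste0("quantify_", masks),
                   c(extra, list(failures = attr(res, "failures"))))
  res
}

#' Evaluate segmentation and diagnostic performance (pipeline stage)
#'
#' Produces the Dice table (structure x group, network vs truth), the
#' per-method ROC of the hyperintense area (truth-mask and
#' predicted-mask statistics), their DeLong comparison, the PD-vs-HC
#' group test on areas, and the area-vs-UPDRS-III Spearman correlation
#' in the PD group.
#'
#' @param config a `RunConfig`.
#' @return list: `diceTable`, `roc` (per method), `delong`,
#'   `groupTest`, `spearmanUPDRS`; also written as CSV/JSON under the
#'   output directory.
#' @export
cmdEvaluate <- function(config = defaultRunConfig()) {
  dir <- config$output_dir
  man <- loadManifest(file.path(dir, "cohort", "manifest.csv"))
  rec <- records(man)
  groups <- stats::setNames(rec$group, rec$subject_id)
  truths <- list(); preds <- list(); slices <- list()
  for (i in seq_len(nrow(rec))) {
    id <- rec$subject_id[i]
    truths[[id]] <- readLabelMask(.manifestPath(man, i, "mask_truth"))
    preds[[id]] <- readLabelMask(.manifestPath(man, i, "mask_pred"),
                                 source = "NETWORK")
    slices[[id]] <- selectSlices(truths[[id]])
  }
  dt <- diceTable(truths, preds, groups, slices)
  kRef <- if (!is.null(config$quantify$frozen_k)) config$quantify$frozen_k
          else 1.5
  qt <- utils::read.csv(file.path(dir, "quantify_truth.csv"))
  qp <- utils::read.csv(file.path(dir, "quantify_predicted.csv"))
  at <- qt[qt$k == kRef, ]; ap <- qp[qp$k == kRef, ]
  stopifnot(identical(at$subject_id, ap$subject_id))
  orient <- config$evaluate$roc_orientation
  rocT <- rocAUC(at$area_mm2, at$group, orient)
  rocP <- rocAUC(ap$area_mm2, ap$group, orient)
  dl <- delongTest(at$area_mm2, ap$area_mm2, at$group, orient)
  gt <- groupCompare(at$area_mm2[at$group == "PD"],
                     at$area_mm2[at$group == "HC"], test = "t")
  pd <- merge(at[at$group == "PD", c("subject_id", "area_mm2")],
              rec[, c("subject_id", "updrs3")], by = "subject_id")
  sp <- if (sum(stats::complete.cases(pd[, c("area_mm2", "updrs3")])) >= 3)
    spearmanStrength(pd$area_mm2, pd$updrs3) else NULL
  out <- list(diceTable = dt,
              roc = list(truth = rocT, predicted = rocP),
              delong = dl, groupTest = gt, spearmanUPDRS = sp)
  utils::write.csv(dt, file.path(dir, "dice_table.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(k = kRef,
         auc_truth = rocT$auc, cutoff_truth = rocT$cutoff,
         auc_predicted = rocP$auc, cutoff_predicted = rocP$cutoff,
         delong_z = dl$z, delong_p = dl$p,
         area_t_p = gt$p,
         spearman_updrs = if (is.null(sp)) NULL
                          else sp[c("r", "p", "category")]),
    file.path(dir, "evaluation.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  .writeProvenance(config, dir, "evaluate")
  out
}

#' Run the full pipeline
#'
#' simulate -> train -> predict -> quantify (truth and predicted
#' masks) -> evaluate, from one configuration and one global seed.
#'
#' @param config a `RunConfig`.
#' @param overwrite allow replacing existing outputs.
#' @return The [cmdEvaluate()] result, invisibly.
#' @export
runPipeline <- function(config = defaultRunConfig(), overwrite = FALSE) {
  cmdSimulate(config, overwrite = overwrite)
  cmdTrain(config, overwrite = overwrite)
  cmdPredict(config)
  cmdQuantify(config, masks = "truth")
  cmdQuantify(config, masks = "predicted")
  invisible(cmdEvaluate(config))
}
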