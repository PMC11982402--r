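# Training (Adam, batch size 1, plateau learning-rate schedule), prediction,
# split evaluation and the ablation harness.

#' Construct a training configuration
#'
#' Defaults follow the optimization schedule of the method: Adam at initial
#' learning rate 0.005, batch size 1, learning rate multiplied by 0.1
#' whenever the monitored loss fails to improve for 10 consecutive epochs
#' (floor 1e-6). The default loss is BCE + soft Dice: with batch size 1 and
#' small foregrounds, pure soft Dice can drive the sigmoid output into
#' saturation ("predict empty") where its gradient vanishes; the BCE term
#' keeps gradients alive (see the methods vignette).
#'
#' @param lr initial learning rate.
#' @param plateauPatience,plateauFactor,minLr plateau schedule settings.
#' @param maxEpochs training epochs.
#' @param loss `"dice"` or `"bce_dice"`.
#' @param seed seed for weight init, shuffling and augmentation.
#' @param threshold prediction binarization threshold.
#' @param valFraction fraction of training data held out for monitoring when
#'   no validation set is given (0 disables).
#' @param augment augmentation ops applied online each epoch (character(0)
#'   disables).
#' @return A [TrainConfig-class].
#' @export
trainConfig <- function(lr = 0.005, plateauPatience = 10L,
                        plateauFactor = 0.1, minLr = 1e-6, maxEpochs = 30L,
                        loss = "bce_dice", seed = 1L, threshold = 0.5,
                        valFraction = 0.1,
                        augment = c("hflip", "vflip", "rotate")) {
  new("TrainConfig", lr = lr, plateauPatience = as.integer(plateauPatience),
      plateauFactor = plateauFactor, minLr = minLr,
      maxEpochs = as.integer(maxEpochs), loss = loss,
      seed = as.integer(seed), threshold = threshold,
      valFraction = valFraction, augment = as.character(augment))
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p * t) + s) / (sum(p) + sum(t) + s)` with smoothing
#' `s = 1`; the differentiable surrogate aligned with the Dice evaluation
#' metric.
#'
#' @param pred probability array in (0, 1).
#' @param target binary mask of the same shape.
#' @param smooth smoothing constant.
#' @return Scalar loss in `[0, 1]`.
#' @export
softDiceLoss <- function(pred, target, smooth = 1) {
  if (!identical(dim(as.array(pred)), dim(as.array(target))))
    stop("prediction and target shapes differ")
  p <- as.numeric(pred)
  t <- as.numeric(target)
  1 - (2 * sum(p * t) + smooth) / (sum(p) + sum(t) + smooth)
}

#' Normalize a sample for the network
#'
#' Applies the modality preprocessing (CT clip to `[-1024, 1024]` and linear
#' map to `[-1, 1]`; PET z-score) to a pair, leaving the mask untouched.
#'
#' @param sample a [SamplePair-class].
#' @return The normalized [SamplePair-class].
#' @export
preprocessSample <- function(sample) {
  new("SamplePair", pet = zscorePET(sample@pet),
      ct = clipScaleCT(sample@ct), mask = sample@mask,
      center = sample@center, patient = sample@patient)
}

# model inputs for a sample honouring single-modality baseline variants
.modelInputs <- function(model, sample) {
  mod <- model@meta$modality %||% "petct"
  if (model@arch == "fusion" || mod == "petct")
    list(pet = sample@pet@data, ct = sample@ct@data)
  else if (mod == "ct") list(pet = NULL, ct = sample@ct@data)
  else list(pet = sample@pet@data, ct = NULL)
}

.lossNode <- function(out, mask, loss) {
  t <- array(mask, dim(out$value))
  dn <- agSoftDiceLoss(out, t)
  if (loss == "bce_dice") {
    bce <- if (!is.null(out$logits)) agBCEWithLogits(out$logits, t)
    else agBCELoss(out, t)
    agScalarAdd(dn, bce)
  } else dn
}

.meanValLoss <- function(model, valSamples, loss) {
  vl <- vapply(valSamples, function(s) {
    agTapeStart()
    on.exit(agTapeStop())
    inp <- .modelInputs(model, s)
    out <- .forwardGraph(model, inp$pet, inp$ct)
    .lossNode(out, s@mask@data, loss)$value
  }, numeric(1))
  mean(vl)
}

#' Train a segmentation model
#'
#' Runs seeded, shuffled, batch-size-1 Adam steps over the training samples,
#' minimizing the configured loss on whole volumes. The learning rate is
#' multiplied by `plateauFactor` whenever the monitored loss (validation
#' loss when a validation set exists, else the epoch training loss) fails to
#' improve for `plateauPatience` consecutive epochs. Fully reproducible
#' given the seed; the model's parameters are updated in place.
#'
#' @param model a [SegmentationModel-class].
#' @param samples training [SamplePair-class] list (with masks).
#' @param config a [TrainConfig-class].
#' @param valSamples optional validation list; when `NULL` and
#'   `valFraction > 0` with at least 5 training samples, a seeded fraction
#'   of the training set is held out.
#' @param normalize apply [preprocessSample()] to every sample (disable to
#'   train on raw intensities, as in the preprocessing ablation).
#' @param stopAtTrainLoss optional early-stop threshold on the epoch
#'   training loss.
#' @param stopAtTrainDice optional early-stop threshold on the epoch mean
#'   training DSC (computed at no extra cost from each step's forward
#'   output, i.e. just before that step's update; noisy under
#'   augmentation).
#' @return List with `model` and `history` (data.frame: epoch, loss,
#'   valLoss, trainDice, lr).
#' @export
trainModel <- function(model, samples, config = trainConfig(),
                       valSamples = NULL, normalize = TRUE,
                       stopAtTrainLoss = NULL, stopAtTrainDice = NULL) {
  stopifnot(is(model, "SegmentationModel"), length(samples) >= 1L)
  validObject(config)
  if (normalize) samples <- lapply(samples, preprocessSample)
  if (!is.null(valSamples) && normalize)
    valSamples <- lapply(valSamples, preprocessSample)
  .withSeed(config@seed + 211L, {
    if (is.null(valSamples) && config@valFraction > 0 &&
        length(samples) >= 5L) {
      nv <- max(1L, ceiling(config@valFraction * length(samples)))
      vi <- sample(seq_along(samples), nv)
      valSamples <- samples[vi]
      samples <- samples[-vi]
    }
    params <- model@params$tensors
    opt <- makeAdam(params, lr = config@lr)
    best <- Inf
    badEpochs <- 0L
    hist <- vector("list", config@maxEpochs)
    for (epoch in seq_len(config@maxEpochs)) {
      order <- sample(length(samples))
      losses <- numeric(length(order))
      dices <- numeric(length(order))
      for (j in seq_along(order)) {
        s <- samples[[order[j]]]
        if (length(config@augment) > 0)
          s <- augmentSample(s, seed = sample.int(2^30, 1L),
                             ops = config@augment)
        agTapeStart()
        inp <- .modelInputs(model, s)
        out <- .forwardGraph(model, inp$pet, inp$ct)
        ln <- .lossNode(out, s@mask@data, config@loss)
        if (!is.finite(ln$value))
          stop("non-finite loss at epoch ", epoch, ", step ", j,
               " (lr = ", opt$lr, "); aborting")
        agBackward(ln)
        agTapeStop()
        opt$step()
        agZeroGrad(params)
        losses[j] <- ln$value
        pred <- (out$value > config@threshold) * 1
        dices[j] <- as.numeric(dice(pred, array(s@mask@data, dim(pred))))
      }
      monitored <- if (!is.null(valSamples))
        .meanValLoss(model, valSamples, config@loss) else mean(losses)
      if (monitored < best - 1e-8) {
        best <- monitored
        badEpochs <- 0L
      } else {
        badEpochs <- badEpochs + 1L
        if (badEpochs >= config@plateauPatience) {
          opt$lr <- max(opt$lr * config@plateauFactor, config@minLr)
          badEpochs <- 0L
        }
      }
      hist[[epoch]] <- data.frame(
        epoch = epoch, loss = mean(losses),
        valLoss = if (!is.null(valSamples)) monitored else NA_real_,
        trainDice = mean(dices), lr = opt$lr)
      if (!is.null(stopAtTrainLoss) && mean(losses) <= stopAtTrainLoss)
        break
      if (!is.null(stopAtTrainDice) && mean(dices) >= stopAtTrainDice)
        break
    }
    list(model = model, history = do.call(rbind, hist))
  })
}

#' Predict a binary tumor mask
#'
#' Thresholded sigmoid output of the model on one sample; the returned mask
#' carries the input spacing. Deterministic.
#'
#' @param model a trained [SegmentationModel-class].
#' @param sample a [SamplePair-class].
#' @param threshold probability threshold.
#' @param normalize apply [preprocessSample()] first.
#' @return A `MASK` [ImageVolume-class].
#' @export
predictMask <- function(model, sample, threshold = 0.5, normalize = TRUE) {
  if (normalize) sample <- preprocessSample(sample)
  inp <- .modelInputs(model, sample)
  prob <- forwardModel(model, inp$pet, inp$ct)
  imageVolume((prob > threshold) * 1, spacing = sample@pet@spacing,
              modality = "MASK", id = paste0(sample@patient, "_pred"))
}

#' Pad a sample to a stage-divisible shape
#'
#' Symmetrically zero-pads (CT with -1000 HU air, PET and mask with 0) each
#' spatial axis up to the next multiple of `2^nStages`.
#'
#' @param sample a [SamplePair-class].
#' @param nStages number of pooling stages.
#' @return A padded [SamplePair-class].
#' @export
padToStages <- function(sample, nStages) {
  d <- dim(sample@pet@data)
  target <- as.integer(ceiling(d / 2^nStages) * 2^nStages)
  if (all(target == d)) return(sample)
  lo <- (target - d) %/% 2L
  padVol <- function(vol, fill) {
    out <- array(fill, target)
    idx <- lapply(seq_along(d), function(i) lo[i] + seq_len(d[i]))
    out <- do.call(`[<-`, c(list(out), idx, list(value = vol@data)))
    imageVolume(out, spacing = vol@spacing, modality = vol@modality,
                id = vol@id)
  }
  new("SamplePair", pet = padVol(sample@pet, 0),
      ct = padVol(sample@ct, -1000),
      mask = if (is.null(sample@mask)) NULL else padVol(sample@mask, 0),
      center = sample@center, patient = sample@patient)
}

# ---- ablation harness ------------------------------------------------------

.ablationVariants <- c("CT_ONLY", "PET_ONLY", "EARLY_FUSION",
                       "ATTENTIVE_FUSION", "PLUS_ZERO_LAYER", "PLUS_SE",
                       "CT_GUIDED", "PET_GUIDED")

# map a variant to a concrete model; netCfg fixes dims/filters for the
# fusion arch; the baseline UNet uses a comparable doubling schedule
.buildVariant <- function(variant, netCfg, seed, baseFilters = 16L) {
  switch(variant,
    CT_ONLY = buildBaselineUNet(netCfg, inChannels = 1L,
                                baseFilters = baseFilters, seed = seed,
                                modality = "ct"),
    PET_ONLY = buildBaselineUNet(netCfg, inChannels = 1L,
                                 baseFilters = baseFilters, seed = seed,
                                 modality = "pet"),
    EARLY_FUSION = buildBaselineUNet(netCfg, inChannels = 2L,
                                     baseFilters = baseFilters, seed = seed),
    ATTENTIVE_FUSION = buildModel(.cfgWith(netCfg, useZeroLayer = FALSE,
                                           useSE = FALSE), seed = seed),
    PLUS_ZERO_LAYER = buildModel(.cfgWith(netCfg, useZeroLayer = TRUE,
                                          useSE = FALSE), seed = seed),
    PLUS_SE = buildModel(.cfgWith(netCfg, useZeroLayer = TRUE,
                                  useSE = TRUE), seed = seed),
    CT_GUIDED = buildModel(.cfgWith(netCfg, guidance = "ct"), seed = seed),
    PET_GUIDED = buildModel(.cfgWith(netCfg, guidance = "pet"), seed = seed),
    stop("unknown ablation variant: ", variant))
}

.cfgWith <- function(cfg, ...) {
  mods <- list(...)
  for (nm in names(mods)) slot(cfg, nm) <- mods[[nm]]
  cfg
}

# mean test metrics of one trained model
.evalOnSamples <- function(model, testSamples, threshold = 0.5) {
  rows <- do.call(rbind, lapply(testSamples, function(s) {
    pred <- predictMask(model, s, threshold = threshold)
    caseMetrics(s@mask, pred, spacing = s@pet@spacing, id = s@patient,
                center = s@center)
  }))
  c(dsc = mean(rows$dsc), hd95 = mean(rows$hd95, na.rm = TRUE))
}

#' Run the ablation harness
#'
#' Trains each requested architecture variant with an identical protocol
#' (same seeds, same split, same schedule) and reports held-out mean DSC and
#' HD95 per variant and seed. Variants: `CT_ONLY`, `PET_ONLY` (single-
#' channel baseline UNet), `EARLY_FUSION` (channel-stacked baseline UNet),
#' `ATTENTIVE_FUSION` (fusion decoder, no zero layer, no SE),
#' `PLUS_ZERO_LAYER` (adds zero layers), `PLUS_SE` / `CT_GUIDED` (the full
#' model), `PET_GUIDED` (guidance from PET features). The function reports
#' and asserts nothing itself.
#'
#' @param samples dataset as a list of [SamplePair-class].
#' @param plan a [SplitPlan-class]; its first fold defines train/test.
#' @param variants character vector of variant names.
#' @param netCfg base [ModelConfig-class] for the fusion variants.
#' @param trainCfg a [TrainConfig-class]; `seed` is offset per run seed.
#' @param seeds integer seeds; each variant is trained once per seed.
#' @param baseFilters first-stage filters of the baseline UNet arms.
#' @return `data.frame` with columns `variant`, `seed`, `dsc`, `hd95`.
#' @export
runAblation <- function(samples, plan, variants = .ablationVariants,
                        netCfg = modelConfig(dims = 2L,
                                             encoderFilters = c(32L, 16L),
                                             zeroLayerFilters = 8L),
                        trainCfg = trainConfig(maxEpochs = 8L,
                                               valFraction = 0),
                        seeds = 1L, baseFilters = 16L) {
  stopifnot(all(variants %in% .ablationVariants))
  ids <- vapply(samples, function(s) s@patient, character(1))
  fold <- plan@folds[[1L]]
  train <- samples[match(fold$train, ids)]
  test <- samples[match(fold$test, ids)]
  rows <- list()
  for (sd in seeds) {
    for (v in variants) {
      model <- .buildVariant(v, netCfg, seed = sd, baseFilters = baseFilters)
      cfg <- trainCfg
      cfg@seed <- as.integer(sd)
      fit <- trainModel(model, train, cfg)
      m <- .evalOnSamples(fit$model, test, threshold = trainCfg@threshold)
      rows[[length(rows) + 1L]] <-
        data.frame(variant = v, seed = sd, dsc = m["dsc"], hd95 = m["hd95"],
                   row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Train and evaluate across a split plan
#'
#' For every fold of the plan: builds a fresh seeded model, trains on the
#' fold's training samples and evaluates on its test samples; then
#' aggregates per-fold mean metrics with [summarizeFolds()]. Per-case rows
#' can be written to CSV.
#'
#' @param samples dataset as a list of [SamplePair-class].
#' @param plan a [SplitPlan-class] covering the sample ids.
#' @param netCfg [ModelConfig-class] for the trained model (fusion
#'   architecture; use [runAblation()] for baseline arms).
#' @param trainCfg a [TrainConfig-class].
#' @param casesCSV optional path for the per-case CSV report
#'   (`case, center, dsc, hd95, precision, recall`).
#' @return List with `summary` (a [FoldSummary-class]) and `cases`
#'   (per-case `data.frame`).
#' @export
evaluateSplit <- function(samples, plan, netCfg, trainCfg = trainConfig(),
                          casesCSV = NULL) {
  ids <- vapply(samples, function(s) s@patient, character(1))
  allCases <- list()
  foldRows <- list()
  for (fi in seq_along(plan@folds)) {
    fold <- plan@folds[[fi]]
    if (length(fold$test) == 0L)
      stop("fold ", fi, " has no test samples")
    train <- samples[match(fold$train, ids)]
    test <- samples[match(fold$test, ids)]
    cfg <- trainCfg
    cfg@seed <- trainCfg@seed + fi
    model <- buildModel(netCfg, seed = cfg@seed)
    fit <- trainModel(model, train, cfg)
    cases <- do.call(rbind, lapply(test, function(s) {
      pred <- predictMask(fit$model, s, threshold = trainCfg@threshold)
      cm <- caseMetrics(s@mask, pred, spacing = s@pet@spacing,
                        id = s@patient, center = s@center)
      cm$fold <- fi
      cm
    }))
    allCases[[fi]] <- cases
    foldRows[[fi]] <- data.frame(
      fold = fi, n = nrow(cases), dsc = mean(cases$dsc),
      hd95 = mean(cases$hd95, na.rm = TRUE),
      precision = mean(cases$precision), recall = mean(cases$recall))
  }
  cases <- do.call(rbind, allCases)
  if (!is.null(casesCSV))
    write.csv(cases, casesCSV, row.names = FALSE)
  folds <- do.call(rbind, foldRows)
  list(summary = summarizeFolds(folds[c("dsc", "hd95", "precision",
                                        "recall")]),
       folds = folds, cases = cases)
}
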