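# The segmentation architecture: per-modality zero layers (convolution +
# ReLU + learnable normalization), squeeze-and-excite encoders, and an
# anatomy-guided intermediate fusion decoder, plus a baseline encoder-decoder
# UNet comparator. Feature maps are (X, Y, Z, C) arrays (Z = 1 in 2D).

#' Construct a model configuration
#'
#' @param dims spatial dimensionality, 2 or 3.
#' @param encoderFilters per-stage encoder filter counts; the default
#'   `c(128, 64, 32, 16)` decreases with depth.
#' @param zeroLayerFilters,zeroLayerKernel zero-layer stem filters F and
#'   (odd) kernel size k.
#' @param seReduction squeeze-and-excite reduction ratio r (bottleneck width
#'   `max(1, C %/% r)`).
#' @param fusionActivation activation after additive fusion, `"relu"`
#'   (default, per the fusion design) or `"sigmoid"`.
#' @param fusionConv keep the 1x1 convolution after fusion.
#' @param normEpsInit initial learnable-normalization stabilizer.
#' @param reverseFilters apply the filter schedule deep-to-shallow reversed.
#' @param useZeroLayer,useSE ablation toggles for the zero layers and the
#'   squeeze-and-excite attention.
#' @param guidance which modality's excited features gate the fused map:
#'   `"ct"` (anatomy guidance, default) or `"pet"`.
#' @return A [ModelConfig-class].
#' @export
modelConfig <- function(dims = 3L, encoderFilters = c(128L, 64L, 32L, 16L),
                        zeroLayerFilters = 16L, zeroLayerKernel = 3L,
                        seReduction = 4L, fusionActivation = "relu",
                        fusionConv = TRUE, normEpsInit = 1e-5,
                        reverseFilters = FALSE, useZeroLayer = TRUE,
                        useSE = TRUE, guidance = "ct") {
  filters <- as.integer(encoderFilters)
  if (reverseFilters) filters <- rev(filters)
  new("ModelConfig", dims = as.integer(dims), encoderFilters = filters,
      zeroLayerFilters = as.integer(zeroLayerFilters),
      zeroLayerKernel = as.integer(zeroLayerKernel),
      seReduction = as.integer(seReduction),
      fusionActivation = fusionActivation, fusionConv = fusionConv,
      normEpsInit = normEpsInit, reverseFilters = reverseFilters,
      useZeroLayer = useZeroLayer, useSE = useSE, guidance = guidance)
}

# ---- parameter construction ------------------------------------------------

.kvec <- function(k, dims) if (dims == 2L) c(k, k, 1L) else c(k, k, k)

.heUniform <- function(dims, fanIn) {
  limit <- sqrt(6 / fanIn)
  array(runif(prod(dims), -limit, limit), dims)
}

.addConv <- function(store, name, k, cin, cout) {
  kd <- c(k, cin, cout)
  store$tensors[[paste0(name, ".w")]] <-
    agLeaf(.heUniform(kd, prod(k) * cin))
  store$tensors[[paste0(name, ".b")]] <- agLeaf(numeric(cout))
  store
}

.addNorm <- function(store, name, C, epsInit) {
  store$tensors[[paste0(name, ".gamma")]] <- agLeaf(rep(1, C))
  store$tensors[[paste0(name, ".beta")]] <- agLeaf(numeric(C))
  # inverse softplus so that softplus(epsRaw) == epsInit at initialization
  store$tensors[[paste0(name, ".epsRaw")]] <- agLeaf(log(expm1(epsInit)))
  store
}

.addDense <- function(store, name, nin, nout) {
  store$tensors[[paste0(name, ".W")]] <-
    agLeaf(.heUniform(c(nin, nout), nin))
  store$tensors[[paste0(name, ".b")]] <- agLeaf(numeric(nout))
  store
}

.seWidth <- function(C, r) max(1L, C %/% r)

#' Build the anatomy-guided fusion segmentation model
#'
#' Assembles two zero layers (one per modality), parallel squeeze-and-excite
#' encoder stacks over `encoderFilters`, a per-stage fusion block
#' (average + max pooling, 1x1 convolutions, additive fusion, modality
#' guidance, sigmoid head with learnable normalization) and an upsampling
#' decoder that combines the per-stage fusion outputs back to full
#' resolution, ending in a 1-channel sigmoid head. Weight initialization is
#' seeded He-uniform; normalization starts at gamma = 1, beta = 0,
#' eps = `normEpsInit`.
#'
#' @param config a [ModelConfig-class].
#' @param seed integer seed for weight initialization.
#' @param inputShape optional spatial shape, checked to be divisible by
#'   `2^n_stages` (the forward pass enforces this too).
#' @return A [SegmentationModel-class].
#' @export
buildModel <- function(config = modelConfig(), seed = 1L,
                       inputShape = NULL) {
  validObject(config)
  .checkStageDivisibility(config, inputShape)
  F <- config@encoderFilters
  n <- length(F)
  k3 <- .kvec(3L, config@dims)
  k1 <- .kvec(1L, config@dims)
  kz <- .kvec(config@zeroLayerKernel, config@dims)
  store <- new.env(parent = emptyenv())
  store$tensors <- list()
  .withSeed(seed, {
    for (m in c("pet", "ct")) {
      .addConv(store, paste0(m, ".zero.conv"), kz, 1L,
               config@zeroLayerFilters)
      if (config@useZeroLayer)
        .addNorm(store, paste0(m, ".zero.norm"), config@zeroLayerFilters,
                 config@normEpsInit)
      cin <- config@zeroLayerFilters
      for (i in seq_len(n)) {
        pre <- sprintf("%s.enc%d", m, i)
        .addConv(store, paste0(pre, ".conv"), k3, cin, F[i])
        .addDense(store, paste0(pre, ".se.fc1"), F[i],
                  .seWidth(F[i], config@seReduction))
        .addDense(store, paste0(pre, ".se.fc2"),
                  .seWidth(F[i], config@seReduction), F[i])
        .addNorm(store, paste0(pre, ".norm"), F[i], config@normEpsInit)
        cin <- F[i]
      }
    }
    for (i in seq_len(n)) {
      .addConv(store, sprintf("fuse%d.pet.conv", i), k1, F[i], F[i])
      .addConv(store, sprintf("fuse%d.ct.conv", i), k1, F[i], F[i])
      if (config@fusionConv)
        .addConv(store, sprintf("fuse%d.post.conv", i), k1, F[i], F[i])
      .addConv(store, sprintf("dec%d.head.conv", i), k1, F[i], F[i])
      .addNorm(store, sprintf("dec%d.head.norm", i), F[i],
               config@normEpsInit)
    }
    for (i in rev(seq_len(max(n - 1L, 0L)))) {
      .addConv(store, sprintf("up%d.proj.conv", i), k1, F[i + 1L], F[i])
      .addConv(store, sprintf("up%d.conv", i), k3, F[i], F[i])
    }
    # full-resolution refinement at reduced width keeps the head light
    .addConv(store, "final.conv", k1, F[1L], config@zeroLayerFilters)
    .addConv(store, "out.conv", k3, config@zeroLayerFilters, 1L)
  })
  new("SegmentationModel", arch = "fusion", config = config, params = store,
      inChannels = 1L, meta = list(seed = as.integer(seed)))
}

#' Build the baseline encoder-decoder UNet comparator
#'
#' A standard UNet-style encoder-decoder with a doubling filter schedule
#' (`baseFilters * 2^(stage-1)`) and channel-stacked input: 2 channels for
#' early PET-CT fusion, or 1 channel for the CT-only / PET-only variants.
#' Used for parameter-count comparison and as the early-fusion /
#' single-modality arm of the ablation harness.
#'
#' @param config a [ModelConfig-class]; its `dims` and number of encoder
#'   stages are used.
#' @param inChannels 1 (single modality) or 2 (stacked PET+CT).
#' @param baseFilters filters of the first stage (doubled each stage).
#' @param seed integer seed for weight initialization.
#' @param modality which modality feeds a single-channel variant
#'   (`"petct"` for the stacked input).
#' @return A [SegmentationModel-class] with `arch == "unet"`.
#' @export
buildBaselineUNet <- function(config = modelConfig(), inChannels = 2L,
                              baseFilters = 32L, seed = 1L,
                              modality = c("petct", "ct", "pet")) {
  modality <- match.arg(modality)
  if (inChannels == 2L && modality != "petct")
    stop("2-channel baseline requires modality = 'petct'")
  validObject(config)
  n <- length(config@encoderFilters)
  F <- as.integer(baseFilters * 2^(seq_len(n) - 1L))
  k3 <- .kvec(3L, config@dims)
  k1 <- .kvec(1L, config@dims)
  store <- new.env(parent = emptyenv())
  store$tensors <- list()
  .withSeed(seed, {
    cin <- as.integer(inChannels)
    for (i in seq_len(n)) {
      .addConv(store, sprintf("enc%d.conv", i), k3, cin, F[i])
      cin <- F[i]
    }
    .addConv(store, "bottleneck.conv", k3, F[n], F[n])
    for (i in rev(seq_len(n))) {
      cinDec <- if (i == n) F[n] else F[i + 1L]
      .addConv(store, sprintf("up%d.proj.conv", i), k1, cinDec, F[i])
      .addConv(store, sprintf("up%d.conv", i), k3, F[i], F[i])
    }
    .addConv(store, "out.conv", k1, F[1L], 1L)
  })
  new("SegmentationModel", arch = "unet", config = config, params = store,
      inChannels = as.integer(inChannels),
      meta = list(seed = as.integer(seed), baseFilters = as.integer(F),
                  modality = modality))
}

.checkStageDivisibility <- function(config, spatial) {
  if (is.null(spatial)) return(invisible(NULL))
  n <- length(config@encoderFilters)
  sp <- spatial[seq_len(config@dims)]
  if (any(sp %% 2^n != 0))
    stop("input spatial size (", paste(sp, collapse = "x"),
         ") must be divisible by 2^", n, " = ", 2^n,
         " for ", n, " pooling stages; pad or crop the volume")
  invisible(NULL)
}

# ---- forward building blocks (operate on autograd tensors) -----------------

.P <- function(model, name) {
  t <- model@params$tensors[[name]]
  if (is.null(t)) stop("model has no parameter block '", name, "'")
  t
}

.fwdConv <- function(model, x, name)
  agConv(x, .P(model, paste0(name, ".w")), .P(model, paste0(name, ".b")))

.fwdNorm <- function(model, x, name)
  agInstanceNorm(x, .P(model, paste0(name, ".gamma")),
                 .P(model, paste0(name, ".beta")),
                 .P(model, paste0(name, ".epsRaw")))

.fwdSE <- function(model, x, name) {
  g <- agGAP(x)
  h <- agRelu(agDense(g, .P(model, paste0(name, ".fc1.W")),
                      .P(model, paste0(name, ".fc1.b"))))
  agSigmoid(agDense(h, .P(model, paste0(name, ".fc2.W")),
                    .P(model, paste0(name, ".fc2.b"))))
}

# promote a (X,Y[,Z]) input array to a (X,Y,Z,1) constant tensor
.asInputTensor <- function(a, dims) {
  a <- as.array(a)
  d <- dim(a)
  if (dims == 2L && length(d) == 2L) dim(a) <- c(d, 1L, 1L)
  else if (dims == 3L && length(d) == 3L) dim(a) <- c(d, 1L)
  else if (length(d) == 4L) { } # already channelled
  else stop("input rank ", length(d), " does not match a ", dims, "D model")
  agLeaf(a, requiresGrad = FALSE)
}

.zeroForward <- function(model, x, modality) {
  cfg <- model@config
  h <- agRelu(.fwdConv(model, x, paste0(modality, ".zero.conv")))
  if (cfg@useZeroLayer) .fwdNorm(model, h, paste0(modality, ".zero.norm"))
  else h
}

.stageForward <- function(model, x, modality, stage, forceExcitation = NULL) {
  cfg <- model@config
  pre <- sprintf("%s.enc%d", modality, stage)
  enc <- agRelu(.fwdConv(model, x, paste0(pre, ".conv")))
  C <- cfg@encoderFilters[stage]
  exc <- if (!is.null(forceExcitation)) {
    agLeaf(rep(forceExcitation, length.out = C), requiresGrad = FALSE)
  } else if (cfg@useSE) {
    .fwdSE(model, enc, paste0(pre, ".se"))
  } else {
    agLeaf(rep(1, C), requiresGrad = FALSE)
  }
  excited <- agScaleChannels(enc, exc)
  pool <- if (cfg@dims == 2L) c(2L, 2L, 1L) else c(2L, 2L, 2L)
  out <- .fwdNorm(model, agMaxPool(excited, pool), paste0(pre, ".norm"))
  list(enc = enc, excitation = exc, excited = excited, out = out)
}

.fuseForward <- function(model, petExc, ctExc, stage, forceFused = NULL) {
  cfg <- model@config
  pooled <- if (cfg@dims == 2L) c(1L, 1L, 0L) else c(1L, 1L, 1L)
  pf <- function(x, name) {
    a <- agPoolK2S1(x, pooled, "avg")
    m <- agPoolK2S1(a, pooled, "max")
    .fwdConv(model, m, name)
  }
  f <- agAdd(pf(petExc, sprintf("fuse%d.pet.conv", stage)),
             pf(ctExc, sprintf("fuse%d.ct.conv", stage)))
  f <- if (cfg@fusionActivation == "sigmoid") agSigmoid(f) else agRelu(f)
  if (cfg@fusionConv) f <- .fwdConv(model, f, sprintf("fuse%d.post.conv", stage))
  if (!is.null(forceFused))
    f <- agLeaf(array(forceFused, dim(f$value)), requiresGrad = FALSE)
  f
}

.decHeadForward <- function(model, guidance, stage) {
  h <- agSigmoid(.fwdConv(model, guidance,
                          sprintf("dec%d.head.conv", stage)))
  .fwdNorm(model, h, sprintf("dec%d.head.norm", stage))
}

# Full forward graph; `force` supports the identity ablations
# (force$excitation: scalar clamped excitation; force$fused: scalar clamp of
# the fused map). Returns the output probability tensor.
.forwardFusion <- function(model, pet, ct, force = list()) {
  cfg <- model@config
  n <- length(cfg@encoderFilters)
  up <- if (cfg@dims == 2L) c(2L, 2L, 1L) else c(2L, 2L, 2L)
  xP <- .asInputTensor(pet, cfg@dims)
  xC <- .asInputTensor(ct, cfg@dims)
  .checkStageDivisibility(cfg, dim(xP$value))
  hP <- .zeroForward(model, xP, "pet")
  hC <- .zeroForward(model, xC, "ct")
  decs <- vector("list", n)
  for (i in seq_len(n)) {
    sP <- .stageForward(model, hP, "pet", i, force$excitation)
    sC <- .stageForward(model, hC, "ct", i, force$excitation)
    hP <- sP$out
    hC <- sC$out
    fused <- .fuseForward(model, hP, hC, i, force$fused)
    guideSrc <- if (cfg@guidance == "ct") hC else hP
    guid <- agMulElem(guideSrc, fused)
    decs[[i]] <- .decHeadForward(model, guid, i)
  }
  d <- decs[[n]]
  for (i in rev(seq_len(n - 1L))) {
    d <- agUpsample(d, up)
    d <- .fwdConv(model, d, sprintf("up%d.proj.conv", i))
    d <- agRelu(.fwdConv(model, agAdd(d, decs[[i]]),
                         sprintf("up%d.conv", i)))
  }
  d <- agUpsample(d, up)
  d <- agRelu(.fwdConv(model, d, "final.conv"))  # 1x1 width reduction
  z <- .fwdConv(model, d, "out.conv")
  out <- agSigmoid(z)
  out$logits <- z  # kept for the logit-space cross-entropy loss
  out
}

.forwardUNet <- function(model, pet, ct) {
  cfg <- model@config
  n <- length(cfg@encoderFilters)
  up <- if (cfg@dims == 2L) c(2L, 2L, 1L) else c(2L, 2L, 2L)
  pool <- if (cfg@dims == 2L) c(2L, 2L, 1L) else c(2L, 2L, 2L)
  chans <- list()
  if (model@inChannels == 2L) {
    a <- .asInputTensor(pet, cfg@dims)$value
    b <- .asInputTensor(ct, cfg@dims)$value
    x <- agLeaf(array(c(a, b), c(dim(a)[1:3], 2L)), requiresGrad = FALSE)
  } else {
    x <- .asInputTensor(if (is.null(ct)) pet else ct, cfg@dims)
  }
  .checkStageDivisibility(cfg, dim(x$value))
  skips <- vector("list", n)
  for (i in seq_len(n)) {
    skips[[i]] <- agRelu(.fwdConv(model, x, sprintf("enc%d.conv", i)))
    x <- agMaxPool(skips[[i]], pool)
  }
  d <- agRelu(.fwdConv(model, x, "bottleneck.conv"))
  for (i in rev(seq_len(n))) {
    d <- agUpsample(d, up)
    d <- .fwdConv(model, d, sprintf("up%d.proj.conv", i))
    d <- agRelu(.fwdConv(model, agAdd(d, skips[[i]]),
                         sprintf("up%d.conv", i)))
  }
  z <- .fwdConv(model, d, "out.conv")
  out <- agSigmoid(z)
  out$logits <- z
  out
}

.forwardGraph <- function(model, pet, ct, force = list()) {
  if (model@arch == "fusion") .forwardFusion(model, pet, ct, force)
  else .forwardUNet(model, pet, ct)
}

#' Run the model forward on a PET/CT pair
#'
#' @param model a [SegmentationModel-class].
#' @param pet,ct input arrays on the model's grid (already normalized). For
#'   single-channel baseline variants pass the used modality and `NULL`.
#' @param force optional list of identity clamps: `force$excitation` clamps
#'   every squeeze-and-excite output, `force$fused` clamps the fused map
#'   (used by the architecture's identity checks).
#' @return Array of per-voxel probabilities in (0, 1), input spatial shape.
#' @export
forwardModel <- function(model, pet, ct, force = list()) {
  agTapeStart()
  on.exit(agTapeStop())
  out <- .forwardGraph(model, pet, ct, force)
  drop(out$value)
}

# ---- exported architecture blocks (array in / array out) -------------------

#' Architecture blocks on plain arrays
#'
#' Single-block forward passes used to inspect and verify the architecture:
#' the zero layer (`Norm(ReLU(Conv_k(v)))`), the squeeze-and-excite
#' excitation (`sigmoid(FC2(ReLU(FC1(GAP(x)))))`, one weight per channel,
#' each in (0, 1)), one full encoder stage (`Norm(MaxPool(Enc * Exc))`), the
#' fusion block (`act(Conv1x1(MP(AP(pet))) + Conv1x1(MP(AP(ct))))`), the
#' guidance product (`excited * fused`), and the per-stage decoder head
#' (`Norm(sigmoid(Conv1x1(guidance)))`).
#'
#' @param model a `"fusion"` [SegmentationModel-class].
#' @param input input array: a raw 2D/3D volume for `zeroLayerForward`, a
#'   `(X, Y, Z, C)` feature map otherwise.
#' @param modality `"pet"` or `"ct"`.
#' @param stage encoder stage index.
#' @param forceExcitation optional scalar clamped excitation.
#' @return `zeroLayerForward`, `fuseFeatures`, `anatomyGuide`,
#'   `decoderHead`: a feature-map array. `squeezeExcite`: a numeric vector of
#'   per-channel weights. `encoderStageForward`: list with `enc`,
#'   `excitation`, `excited`, and the stage output `out`.
#' @export
zeroLayerForward <- function(model, input, modality = c("pet", "ct")) {
  modality <- match.arg(modality)
  agTapeStart()
  on.exit(agTapeStop())
  x <- .asInputTensor(input, model@config@dims)
  .zeroForward(model, x, modality)$value
}

#' @rdname zeroLayerForward
#' @export
squeezeExcite <- function(model, input, modality = c("pet", "ct"),
                          stage = 1L) {
  modality <- match.arg(modality)
  agTapeStart()
  on.exit(agTapeStop())
  x <- agLeaf(input, requiresGrad = FALSE)
  .fwdSE(model, x, sprintf("%s.enc%d.se", modality, stage))$value
}

#' @rdname zeroLayerForward
#' @export
encoderStageForward <- function(model, input, modality = c("pet", "ct"),
                                stage = 1L, forceExcitation = NULL) {
  modality <- match.arg(modality)
  agTapeStart()
  on.exit(agTapeStop())
  x <- agLeaf(input, requiresGrad = FALSE)
  s <- .stageForward(model, x, modality, stage, forceExcitation)
  list(enc = s$enc$value, excitation = s$excitation$value,
       excited = s$excited$value, out = s$out$value)
}

#' @rdname zeroLayerForward
#' @param petFeat,ctFeat excited feature maps of the stage (same shape).
#' @export
fuseFeatures <- function(model, petFeat, ctFeat, stage = 1L) {
  if (!identical(dim(petFeat), dim(ctFeat)))
    stop("fusion error: feature shapes differ")
  agTapeStart()
  on.exit(agTapeStop())
  .fuseForward(model, agLeaf(petFeat, requiresGrad = FALSE),
               agLeaf(ctFeat, requiresGrad = FALSE), stage)$value
}

#' @rdname zeroLayerForward
#' @param excited,fused guidance inputs (broadcast-equal shapes).
#' @export
anatomyGuide <- function(excited, fused) {
  if (!identical(dim(excited), dim(fused)))
    stop("fusion error: incompatible shapes for guidance product")
  excited * fused
}

#' @rdname zeroLayerForward
#' @param guidance guided feature map entering the decoder head.
#' @export
decoderHead <- function(model, guidance, stage = 1L) {
  agTapeStart()
  on.exit(agTapeStop())
  .decHeadForward(model, agLeaf(guidance, requiresGrad = FALSE),
                  stage)$value
}

# ---- parameter accounting and checkpoints ----------------------------------

#' Count trainable parameters
#'
#' Exact count of trainable scalars with a per-block breakdown (blocks are
#' the named parameter groups of the architecture).
#'
#' @param model a [SegmentationModel-class].
#' @return List with `total` (integer) and `breakdown` (named integer vector
#'   per block).
#' @export
countParameters <- function(model) {
  tensors <- model@params$tensors
  sizes <- vapply(tensors, function(p) length(p$value), numeric(1))
  block <- vapply(strsplit(names(sizes), ".", fixed = TRUE),
                  function(p) paste(head(p, 2), collapse = "."),
                  character(1))
  breakdown <- vapply(split(sizes, block), sum, numeric(1))
  list(total = as.integer(sum(sizes)),
       breakdown = as.integer(breakdown) |>
         stats::setNames(names(breakdown)))
}

#' Save / load a model checkpoint
#'
#' Checkpoints hold the architecture tag, the full configuration, every
#' parameter tensor and a config digest; loading rebuilds the model and
#' verifies the digest.
#'
#' @param model a [SegmentationModel-class].
#' @param path checkpoint file.
#' @return `saveCheckpoint`: `path` invisibly; `loadCheckpoint`: the model.
#' @export
saveCheckpoint <- function(model, path) {
  cfg <- model@config
  cfgList <- sapply(slotNames(cfg), function(s) slot(cfg, s),
                    simplify = FALSE)
  saveRDS(list(arch = model@arch, config = cfgList,
               inChannels = model@inChannels, meta = model@meta,
               values = lapply(model@params$tensors, function(p) p$value),
               digest = .configDigest(cfgList)),
          path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$digest, .configDigest(ck$config)))
    stop("checkpoint config digest mismatch")
  cfg <- do.call(new, c(list("ModelConfig"), ck$config))
  model <- if (ck$arch == "fusion") buildModel(cfg, seed = ck$meta$seed)
  else buildBaselineUNet(cfg, inChannels = ck$inChannels,
                         baseFilters = ck$meta$baseFilters[1] %||% 32L,
                         seed = ck$meta$seed,
                         modality = ck$meta$modality %||% "petct")
  stopifnot(identical(names(model@params$tensors), names(ck$values)))
  for (nm in names(ck$values))
    model@params$tensors[[nm]]$value <- ck$values[[nm]]
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.configDigest <- function(cfgList)
  paste(vapply(cfgList, function(v) paste(format(v, digits = 15),
                                          collapse = ","), character(1)),
        collapse = "|")
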