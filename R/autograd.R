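# Minimal reverse-mode autodiff tape.
#
# Tensors are environments holding $value (a dim-ed array or plain vector),
# $grad, and for non-leaves a $backward closure plus $parents. Operations
# record themselves on a per-forward-pass tape; agBackward() replays it in
# reverse. Leaf tensors (model parameters) persist across passes and
# accumulate gradients until agZeroGrad().
#
# Feature maps are dim (X, Y, Z, C) with Z == 1 for 2D models.

.agState <- new.env(parent = emptyenv())
.agState$tape <- NULL

agTapeStart <- function() {
  .agState$tape <- vector("list", 256L)
  .agState$n <- 0L
  invisible(NULL)
}

agTapeStop <- function() {
  .agState$tape <- NULL
  invisible(NULL)
}

.agRecord <- function(node) {
  n <- .agState$n + 1L
  if (n > length(.agState$tape))
    .agState$tape <- c(.agState$tape, vector("list", length(.agState$tape)))
  .agState$tape[[n]] <- node
  .agState$n <- n
  node
}

.agNode <- function(value, parents, backward) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$leaf <- FALSE
  node$parents <- parents
  node$backward <- backward
  if (is.null(.agState$tape))
    stop("no active tape: wrap the forward pass in agTapeStart()/agTapeStop()")
  .agRecord(node)
}

agLeaf <- function(value, requiresGrad = TRUE) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$leaf <- TRUE
  node$requiresGrad <- requiresGrad
  node
}

.agAccum <- function(node, g) {
  if (node$leaf && !node$requiresGrad) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

agBackward <- function(out) {
  if (is.null(.agState$tape)) stop("no active tape")
  out$grad <- if (length(out$value) == 1L) 1 else array(1, dim(out$value))
  for (i in seq(.agState$n, 1L)) {
    node <- .agState$tape[[i]]
    if (!is.null(node$grad) && !is.null(node$backward)) node$backward(node$grad)
  }
  invisible(NULL)
}

agZeroGrad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- operations ------------------------------------------------------------

agConv <- function(x, w, b) {
  r <- .convForward(x$value, w$value, b$value, FALSE)
  kdim <- dim(w$value)[1:3]
  .agNode(r$out, list(x, w, b), function(g) {
    .agAccum(x, .convBackwardInput(g, w$value))
    gw <- .convBackwardWeight(x$value, g, as.integer(kdim), r$cols)
    .agAccum(w, gw$dw)
    .agAccum(b, gw$db)
  })
}

agRelu <- function(x) {
  mask <- x$value > 0
  .agNode(x$value * mask, list(x), function(g) .agAccum(x, g * mask))
}

agSigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  .agNode(s, list(x), function(g) .agAccum(x, g * s * (1 - s)))
}

agAdd <- function(a, b) {
  .agNode(a$value + b$value, list(a, b), function(g) {
    .agAccum(a, g)
    .agAccum(b, g)
  })
}

agMulElem <- function(a, b) {
  .agNode(a$value * b$value, list(a, b), function(g) {
    .agAccum(a, g * b$value)
    .agAccum(b, g * a$value)
  })
}

# Per-channel scaling of a (X,Y,Z,C) map by a length-C vector (SE excitation).
agScaleChannels <- function(x, s) {
  d <- dim(x$value)
  nvox <- prod(d[1:3])
  sv <- rep(s$value, each = nvox)
  .agNode(x$value * sv, list(x, s), function(g) {
    .agAccum(x, g * sv)
    gs <- colSums(matrix(g * x$value, nrow = nvox, ncol = d[4]))
    .agAccum(s, gs)
  })
}

# Learnable instance normalization: per channel over spatial positions,
# y = gamma * (x - mu) / sqrt(var + eps) + beta with eps = softplus(epsRaw)
# so the stabilizer stays strictly positive under gradient descent.
agInstanceNorm <- function(x, gamma, beta, epsRaw) {
  d <- dim(x$value)
  nvox <- prod(d[1:3])
  C <- d[4]
  xm <- matrix(x$value, nvox, C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  v <- colMeans(xc * xc)                 # population variance
  eps <- log1p(exp(epsRaw$value))
  s <- sqrt(v + eps)
  xhat <- sweep(xc, 2L, s, "/")
  val <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
  dim(val) <- d
  .agNode(val, list(x, gamma, beta, epsRaw), function(g) {
    gm <- matrix(g, nvox, C)
    .agAccum(beta, colSums(gm))
    .agAccum(gamma, colSums(gm * xhat))
    dxhat <- sweep(gm, 2L, gamma$value, "*")
    # d/d(var + eps): shared by the variance and the learnable eps
    dvpe <- colSums(dxhat * xc) * (-0.5) / (s^3)
    dmu <- colSums(dxhat) * (-1 / s)     # centered xc makes the dvar*mu term 0
    dx <- sweep(dxhat, 2L, s, "/") +
      sweep(xc, 2L, dvpe * 2 / nvox, "*") +
      matrix(rep(dmu / nvox, each = nvox), nvox, C)
    dim(dx) <- d
    .agAccum(x, dx)
    .agAccum(epsRaw, sum(dvpe) / (1 + exp(-epsRaw$value)))
  })
}

agMaxPool <- function(x, pool) {
  d <- dim(x$value)
  r <- .maxPoolForward(x$value, as.integer(pool))
  .agNode(r$out, list(x), function(g)
    .agAccum(x, .maxPoolBackward(g, r$argmax, as.integer(d))))
}

# Size-preserving window-2 stride-1 pooling (fusion branch), type "avg"|"max".
agPoolK2S1 <- function(x, pooledAxes, type = c("avg", "max")) {
  type <- match.arg(type)
  tcode <- if (type == "max") 1L else 0L
  d <- dim(x$value)
  r <- .poolK2S1Forward(x$value, as.integer(pooledAxes), tcode)
  .agNode(r$out, list(x), function(g)
    .agAccum(x, .poolK2S1Backward(g, r$argmax, as.integer(d),
                                  as.integer(pooledAxes), tcode)))
}

# Nearest-neighbour upsampling by integer factors per spatial axis.
agUpsample <- function(x, factor) {
  d <- dim(x$value)
  ix <- rep(seq_len(d[1]), each = factor[1])
  iy <- rep(seq_len(d[2]), each = factor[2])
  iz <- rep(seq_len(d[3]), each = factor[3])
  val <- x$value[ix, iy, iz, , drop = FALSE]
  .agNode(val, list(x), function(g) {
    # fold each upsampled axis back by summing within blocks
    m <- array(g, c(factor[1], d[1], factor[2], d[2], factor[3], d[3], d[4]))
    dx <- colSums(aperm(m, c(1, 3, 5, 2, 4, 6, 7)), dims = 3L)
    .agAccum(x, array(dx, d))
  })
}

# Global average pooling to a length-C vector.
agGAP <- function(x) {
  d <- dim(x$value)
  nvox <- prod(d[1:3])
  val <- colMeans(matrix(x$value, nvox, d[4]))
  .agNode(val, list(x), function(g) {
    dx <- array(rep(g / nvox, each = nvox), d)
    .agAccum(x, dx)
  })
}

# Fully connected layer on a plain vector: out = v %*% W + b.
agDense <- function(v, W, b) {
  val <- drop(v$value %*% W$value) + b$value
  .agNode(val, list(v, W, b), function(g) {
    .agAccum(v, drop(W$value %*% g))
    .agAccum(W, outer(v$value, g))
    .agAccum(b, g)
  })
}

# Soft Dice loss, smoothing s: 1 - (2*sum(p*t) + s) / (sum(p) + sum(t) + s).
agSoftDiceLoss <- function(pred, target, smooth = 1) {
  t <- as.numeric(target)
  p <- pred$value
  A <- 2 * sum(p * t) + smooth
  B <- sum(p) + sum(t) + smooth
  .agNode(1 - A / B, list(pred), function(g) {
    dp <- -g * (2 * t * B - A) / (B * B)
    dim(dp) <- dim(p)
    .agAccum(pred, dp)
  })
}

# Binary cross-entropy computed from logits (mean over voxels):
# bce = mean(t * softplus(-z) + (1 - t) * softplus(z)); the gradient is
# (sigmoid(z) - t) / n, which stays informative even when the sigmoid
# output saturates to 0 or 1 in double precision.
agBCEWithLogits <- function(z, target) {
  t <- as.numeric(target)
  zv <- as.numeric(z$value)
  sp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))  # stable softplus
  n <- length(zv)
  .agNode(sum(t * sp(-zv) + (1 - t) * sp(zv)) / n, list(z), function(g) {
    dz <- g * (1 / (1 + exp(-zv)) - t) / n
    dim(dz) <- dim(z$value)
    .agAccum(z, dz)
  })
}

# Binary cross-entropy (mean over voxels), numerically clamped.
agBCELoss <- function(pred, target, clamp = 1e-7) {
  t <- as.numeric(target)
  p <- pmin(pmax(pred$value, clamp), 1 - clamp)
  n <- length(p)
  .agNode(-mean(t * log(p) + (1 - t) * log(1 - p)), list(pred), function(g) {
    dp <- g * (p - t) / (p * (1 - p)) / n
    dp[pred$value <= clamp | pred$value >= 1 - clamp] <- 0
    dim(dp) <- dim(pred$value)
    .agAccum(pred, dp)
  })
}

agScalarAdd <- function(a, b) {
  .agNode(a$value + b$value, list(a, b), function(g) {
    .agAccum(a, g)
    .agAccum(b, g)
  })
}

# ---- Adam ------------------------------------------------------------------

# Classic Adam with bias correction; state kept per parameter tensor.
makeAdam <- function(params, lr = 0.005, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$lr <- lr
  opt$t <- 0L
  opt$m <- lapply(params, function(p) p$value * 0)
  opt$v <- lapply(params, function(p) p$value * 0)
  opt$params <- params
  opt$step <- function() {
    opt$t <- opt$t + 1L
    b1t <- 1 - beta1^opt$t
    b2t <- 1 - beta2^opt$t
    for (i in seq_along(opt$params)) {
      p <- opt$params[[i]]
      if (is.null(p$grad)) next
      opt$m[[i]] <- beta1 * opt$m[[i]] + (1 - beta1) * p$grad
      opt$v[[i]] <- beta2 * opt$v[[i]] + (1 - beta2) * p$grad^2
      p$value <- p$value - opt$lr * (opt$m[[i]] / b1t) /
        (sqrt(opt$v[[i]] / b2t) + eps)
    }
    invisible(NULL)
  }
  opt
}
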