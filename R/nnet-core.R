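# Compact fully convolutional encoder-decoder used for both the cellular
# localization network (5 sigmoid heads + a half-resolution deep-supervision
# head) and the tumor-region segmenter (3-class softmax head).
#
# Architecture, for depth D and base width Wb (stage width Wd = Wb * 2^(d-1)):
#   encoder stage d:  3x3 conv -> ReLU
#   transition d:     1x1 conv (Wd -> W_{d+1}) -> 2x2 average pool
#   bottleneck:       3x3 conv -> ReLU
#   decoder stage d:  nearest 2x upsample -> 3x3 conv, plus a 1x1-projected
#                     additive skip from encoder stage d -> ReLU
#   head:             1x1 conv -> sigmoid (cnet) or softmax (rnet)
# All convolutions are zero-padded "same"; backprop is derived by hand and
# verified against finite differences in the test suite.

heInit <- function(k, cin, cout) {
  matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
         k * k * cin, cout)
}

# FNV-1a hash of a serialized object; used as the checkpoint config hash.
configHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

newNet <- function(kind, nClasses, baseWidth, depth, seed) {
  stopifnot(depth >= 2)
  withSeed(seed, {
    wd <- baseWidth * 2^(0:depth)       # widths of stages 1..depth+1
    weights <- list()
    cin <- 3L
    for (d in seq_len(depth)) {
      weights[[paste0("enc", d, "_w")]] <- heInit(3L, cin, wd[d])
      weights[[paste0("enc", d, "_b")]] <- numeric(wd[d])
      weights[[paste0("trans", d, "_w")]] <- heInit(1L, wd[d], wd[d + 1])
      weights[[paste0("trans", d, "_b")]] <- numeric(wd[d + 1])
      weights[[paste0("skip", d, "_w")]] <- heInit(1L, wd[d], wd[d])
      weights[[paste0("skip", d, "_b")]] <- numeric(wd[d])
      cin <- wd[d + 1]
    }
    weights[["bott_w"]] <- heInit(3L, wd[depth + 1], wd[depth + 1])
    weights[["bott_b"]] <- numeric(wd[depth + 1])
    for (d in rev(seq_len(depth))) {
      weights[[paste0("dec", d, "_w")]] <- heInit(3L, wd[d + 1], wd[d])
      weights[[paste0("dec", d, "_b")]] <- numeric(wd[d])
    }
    weights[["head_w"]] <- heInit(1L, wd[1], nClasses)
    weights[["head_b"]] <- numeric(nClasses)
    if (kind == "cnet") {
      # deep-supervision head on the half-resolution decoder stage
      weights[["aux_w"]] <- heInit(1L, wd[2], nClasses)
      weights[["aux_b"]] <- numeric(nClasses)
    }
    cfg <- list(nClasses = nClasses, baseWidth = baseWidth, depth = depth,
                norm = list(mean = rep(0.5, 3), sd = rep(0.25, 3)))
    cfg$hash <- configHash(cfg[c("nClasses", "baseWidth", "depth")])
    new("IHCNet", kind = kind, weights = weights, config = cfg,
        trained = FALSE,
        history = data.frame(epoch = integer(0), train = numeric(0),
                             validation = numeric(0)))
  })
}

#' Build the cellular localization network
#'
#' Fully convolutional; the output maps have the same spatial size as the
#' input and five per-class channels through 1x1 convolutions with sigmoid
#' activation (channels do not compete). During training an auxiliary
#' half-resolution head is supervised with weight 0.4 (deep supervision).
#' Inputs whose sides are not divisible by `2^depth` are reflect-padded
#' internally and the outputs cropped back.
#'
#' @param nClasses number of output channels (default 5 cell classes).
#' @param baseWidth channel width of the first stage (doubles per stage).
#' @param depth number of encoder stages, `>= 2`.
#' @param seed seed for weight initialization.
#' @return an [IHCNet-class] handle.
#' @export
buildCnet <- function(nClasses = 5L, baseWidth = 8L, depth = 2L, seed = 42L) {
  newNet("cnet", nClasses, baseWidth, depth, seed)
}

#' Build the tumor-region segmentation network
#'
#' Same encoder-decoder family as [buildCnet()] with a 3-class softmax head
#' (TC(+) region, TC(-) region, normal region); output probabilities sum to
#' one at every pixel. Operates at region scale (1/4 of cell-scale linear
#' resolution).
#'
#' @inheritParams buildCnet
#' @return an [IHCNet-class] handle.
#' @export
buildRnet <- function(nClasses = 3L, baseWidth = 8L, depth = 2L, seed = 42L) {
  newNet("rnet", nClasses, baseWidth, depth, seed)
}

convFwd <- function(x, w, b, k) {
  d <- dim(x)
  col <- cpp_im2col(x, k)
  y <- col %*% w
  y <- sweep(y, 2L, b, "+")
  list(y = array(y, c(d[1], d[2], length(b))), col = col)
}

convBwd <- function(dy, col, w, k, H, W, cin) {
  dyMat <- matrix(dy, ncol = dim(w)[2])
  list(dx = cpp_col2im(dyMat %*% t(w), H, W, cin, k),
       dw = crossprod(col, dyMat),
       db = colSums(dyMat))
}

sigmoidA <- function(z) 1 / (1 + exp(-z))

softmaxA <- function(z) {
  m <- apply(z, c(1, 2), max)
  e <- exp(sweep(z, c(1, 2), m))
  sweep(e, c(1, 2), apply(e, c(1, 2), sum), "/")
}

# Forward pass on one normalized image cube (H, W, 3). Returns the main
# head probabilities, the aux head (cnet, train = TRUE only) and a cache
# for the backward pass.
nnForward <- function(model, x, train = FALSE) {
  wts <- model@weights
  depth <- model@config$depth
  d0 <- dim(x)
  mult <- 2^depth
  padY <- (mult - d0[1] %% mult) %% mult
  padX <- (mult - d0[2] %% mult) %% mult
  if (padY > 0 || padX > 0) x <- reflectPad(x, padY, padX)
  cache <- list(pad = c(padY, padX), shape0 = d0, x = x)
  enc <- list()
  for (d in seq_len(depth)) {
    cv <- convFwd(x, wts[[paste0("enc", d, "_w")]],
                  wts[[paste0("enc", d, "_b")]], 3L)
    a <- pmax(cv$y, 0)
    enc[[d]] <- list(col = cv$col, pre = cv$y, a = a, dimIn = dim(x))
    tr <- convFwd(a, wts[[paste0("trans", d, "_w")]],
                  wts[[paste0("trans", d, "_b")]], 1L)
    enc[[d]]$trCol <- tr$col
    x <- cpp_avgpool2(tr$y)
  }
  bt <- convFwd(x, wts[["bott_w"]], wts[["bott_b"]], 3L)
  a <- pmax(bt$y, 0)
  cache$enc <- enc
  cache$bott <- list(col = bt$col, pre = bt$y, dimIn = dim(x))
  dec <- list()
  for (d in rev(seq_len(depth))) {
    up <- cpp_upsample2(a)
    cv <- convFwd(up, wts[[paste0("dec", d, "_w")]],
                  wts[[paste0("dec", d, "_b")]], 3L)
    sk <- convFwd(enc[[d]]$a, wts[[paste0("skip", d, "_w")]],
                  wts[[paste0("skip", d, "_b")]], 1L)
    pre <- cv$y + sk$y
    a <- pmax(pre, 0)
    dec[[d]] <- list(col = cv$col, skCol = sk$col, pre = pre, a = a,
                     dimUp = dim(up))
    if (d == 2L && model@kind == "cnet" && train) {
      az <- convFwd(a, wts[["aux_w"]], wts[["aux_b"]], 1L)
      cache$aux <- list(col = az$col, p = sigmoidA(az$y))
    }
  }
  cache$dec <- dec
  hd <- convFwd(a, wts[["head_w"]], wts[["head_b"]], 1L)
  cache$head <- list(col = hd$col, z = hd$y)
  out <- if (model@kind == "cnet") sigmoidA(hd$y) else softmaxA(hd$y)
  cache$out <- out
  crop <- function(m) m[seq_len(d0[1]), seq_len(d0[2]), , drop = FALSE]
  list(out = crop(out), aux = if (!is.null(cache$aux))
    cache$aux$p[seq_len(ceiling(d0[1] / 2)), seq_len(ceiling(d0[2] / 2)), ,
                drop = FALSE] else NULL,
    cache = cache)
}

# Backward pass. dOut / dAux are gradients w.r.t. the PRE-SIGMOID logits
# for cnet, or w.r.t. logits for rnet (softmax+CE combined), at the padded
# resolution. Returns a named list of weight gradients.
nnBackward <- function(model, cache, dOutZ, dAuxZ = NULL) {
  wts <- model@weights
  depth <- model@config$depth
  g <- list()
  hd <- cache$head
  dimA <- dim(cache$dec[[1]]$a)
  bw <- convBwd(dOutZ, hd$col, wts[["head_w"]], 1L,
                dimA[1], dimA[2], dimA[3])
  g[["head_w"]] <- bw$dw; g[["head_b"]] <- bw$db
  da <- bw$dx
  for (d in seq_len(depth)) {
    dc <- cache$dec[[d]]
    if (d == 2L && !is.null(dAuxZ) && !is.null(cache$aux)) {
      abw <- convBwd(dAuxZ, cache$aux$col, wts[["aux_w"]], 1L,
                     dim(dc$a)[1], dim(dc$a)[2], dim(dc$a)[3])
      g[["aux_w"]] <- abw$dw; g[["aux_b"]] <- abw$db
      da <- da + abw$dx
    }
    dpre <- da * (dc$pre > 0)
    sbw <- convBwd(dpre, dc$skCol, wts[[paste0("skip", d, "_w")]], 1L,
                   dim(cache$enc[[d]]$a)[1], dim(cache$enc[[d]]$a)[2],
                   dim(cache$enc[[d]]$a)[3])
    g[[paste0("skip", d, "_w")]] <- sbw$dw
    g[[paste0("skip", d, "_b")]] <- sbw$db
    cache$enc[[d]]$dSkip <- sbw$dx   # gradient into encoder activation
    cbw <- convBwd(dpre, dc$col, wts[[paste0("dec", d, "_w")]], 3L,
                   dc$dimUp[1], dc$dimUp[2], dc$dimUp[3])
    g[[paste0("dec", d, "_w")]] <- cbw$dw
    g[[paste0("dec", d, "_b")]] <- cbw$db
    da <- cpp_upsample2_bwd(cbw$dx)
  }
  dpre <- da * (cache$bott$pre > 0)
  bbw <- convBwd(dpre, cache$bott$col, wts[["bott_w"]], 3L,
                 cache$bott$dimIn[1], cache$bott$dimIn[2],
                 cache$bott$dimIn[3])
  g[["bott_w"]] <- bbw$dw; g[["bott_b"]] <- bbw$db
  dx <- bbw$dx
  for (d in rev(seq_len(depth))) {
    ec <- cache$enc[[d]]
    dtr <- cpp_avgpool2_bwd(dx)
    tbw <- convBwd(dtr, ec$trCol, wts[[paste0("trans", d, "_w")]], 1L,
                   dim(ec$a)[1], dim(ec$a)[2], dim(ec$a)[3])
    g[[paste0("trans", d, "_w")]] <- tbw$dw
    g[[paste0("trans", d, "_b")]] <- tbw$db
    daEnc <- tbw$dx + ec$dSkip
    dpre <- daEnc * (ec$pre > 0)
    ebw <- convBwd(dpre, ec$col, wts[[paste0("enc", d, "_w")]], 3L,
                   ec$dimIn[1], ec$dimIn[2], ec$dimIn[3])
    g[[paste0("enc", d, "_w")]] <- ebw$dw
    g[[paste0("enc", d, "_b")]] <- ebw$db
    dx <- ebw$dx
  }
  g
}

# Stain-space input representation: per-pixel Ruifrok-Johnston
# concentrations (hematoxylin, DAB, residual). Standard IHC preprocessing;
# it presents the discriminating chromogen structure to the network
# directly instead of leaving color unmixing to be learned.
toStainSpace <- function(image) {
  cc <- stainConcentrations(image)
  out <- array(0, dim(image))
  out[, , 1] <- cc$hematoxylin
  out[, , 2] <- cc$dab
  out[, , 3] <- cc$residual
  out
}

normalizeInput <- function(model, image) {
  x <- toStainSpace(image)
  nm <- model@config$norm
  for (ch in 1:3) x[, , ch] <- (x[, , ch] - nm$mean[ch]) / nm$sd[ch]
  x
}

#' Run a network on an image tile
#'
#' Normalizes the input with the channel statistics stored in the model
#' (training-set whitening) and returns the per-class probability maps at
#' the input resolution: values in `[0, 1]`; for the region network the
#' three channels sum to one at every pixel.
#'
#' @param model an [IHCNet-class].
#' @param image numeric array `(H, W, 3)` in `[0, 1]`.
#' @return numeric array `(H, W, nClasses)` of probabilities, with channel
#'   names (cell classes for cnet, region classes for rnet).
#' @export
predictProbabilityMaps <- function(model, image) {
  out <- nnForward(model, normalizeInput(model, image), train = FALSE)$out
  nms <- if (model@kind == "cnet") CELL_CLASSES[seq_len(dim(out)[3])]
         else REGION_CLASSES[seq_len(dim(out)[3])]
  dimnames(out) <- list(NULL, NULL, nms)
  out
}

sgdStep <- function(weights, grads, velocity, lr, momentum) {
  for (nm in names(grads)) {
    velocity[[nm]] <- momentum * velocity[[nm]] - lr * grads[[nm]]
    weights[[nm]] <- weights[[nm]] + velocity[[nm]]
  }
  list(weights = weights, velocity = velocity)
}
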