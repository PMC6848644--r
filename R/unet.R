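## Minimal U-net engine on BLAS matrix products.
##
## Activations are (H*W x C) matrices in R's column-major pixel order.
## 3x3 convolutions use im2col: the column matrix is (oH*oW x 9*Cin)
## with column order (kernel offset fastest, then input channel), and a
## weight matrix (9*Cin x Cout). Downsampling is a 3x3 convolution with
## stride 2 (no pooling); upsampling a 2x2 transposed convolution with
## stride 2. All index maps are memoised per geometry.

.unetCache <- new.env(parent = emptyenv())

.convOutDim <- function(n, stride) as.integer(floor((n - 1) / stride) + 1L)

## im2col gather indices into the zero-padded (H+2)x(W+2) canvas,
## plus the interior indices used to (un)pad
.geomIdx <- function(H, W, stride) {
  key <- sprintf("g_%d_%d_%d", H, W, stride)
  hit <- .unetCache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- W + 2L
  oH <- .convOutDim(H, stride); oW <- .convOutDim(W, stride)
  r0 <- (seq_len(oH) - 1L) * stride   # top-left of each window, 0-based
  c0 <- (seq_len(oW) - 1L) * stride
  idx <- matrix(0L, oH * oW, 9L)
  j <- 0L
  for (dc in 0:2) for (dr in 0:2) {   # offset order: dr fastest
    j <- j + 1L
    rr <- r0 + dr + 1L                # 1-based row in padded canvas
    cc <- c0 + dc + 1L
    idx[, j] <- as.vector(outer(rr, (cc - 1L) * Hp, "+"))
  }
  interior <- as.vector(outer(2:(Hp - 1L), (2:(Wp - 1L) - 1L) * Hp, "+"))
  out <- list(idx = idx, interior = interior, Hp = Hp, Wp = Wp,
              oH = oH, oW = oW)
  .unetCache[[key]] <- out
  out
}

## scatter indices of the 2x2/stride-2 transposed convolution:
## input pixel (r, c), offset (a, b) -> output (2r-1+a, 2c-1+b)
.tconvIdx <- function(H, W) {
  key <- sprintf("t_%d_%d", H, W)
  hit <- .unetCache[[key]]
  if (!is.null(hit)) return(hit)
  r <- rep(seq_len(H), times = W); c <- rep(seq_len(W), each = H)
  oH <- 2L * H
  idx <- matrix(0L, H * W, 4L)
  j <- 0L
  for (b in 0:1) for (a in 0:1) {     # offset order: a fastest
    j <- j + 1L
    idx[, j] <- (2L * r - 1L + a) + (2L * c - 2L + b) * oH
  }
  .unetCache[[key]] <- idx
  idx
}

.addBias <- function(y, b) y + matrix(b, nrow(y), length(b), byrow = TRUE)

.im2col <- function(x, H, W, stride) {
  g <- .geomIdx(H, W, stride)
  C <- ncol(x)
  P <- matrix(0, g$Hp * g$Wp, C)
  P[g$interior, ] <- x
  cols <- P[as.vector(g$idx), , drop = FALSE]
  dim(cols) <- c(g$oH * g$oW, 9L * C)
  cols
}

.convF <- function(x, Wm, b, H, W, stride = 1L) {
  cols <- .im2col(x, H, W, stride)
  g <- .geomIdx(H, W, stride)
  list(y = .addBias(cols %*% Wm, b), cols = cols, oH = g$oH, oW = g$oW)
}

.convB <- function(dY, cols, Wm, H, W, stride, Cin) {
  dW <- crossprod(cols, dY)
  db <- colSums(dY)
  Cout <- ncol(dY)
  if (stride == 1L) {
    ## input gradient as a correlation: convolve dY with the kernel
    ## rotated 180 degrees and the channel axes swapped (pure BLAS)
    Wa <- Wm
    dim(Wa) <- c(9L, Cin, Cout)
    Wt <- aperm(Wa[9:1, , , drop = FALSE], c(1L, 3L, 2L))
    dim(Wt) <- c(9L * Cout, Cin)
    dX <- .im2col(dY, H, W, 1L) %*% Wt
  } else {
    g <- .geomIdx(H, W, stride)
    dCols <- dY %*% t(Wm)
    dim(dCols) <- c(nrow(dY), 9L, Cin)
    dP <- matrix(0, g$Hp * g$Wp, Cin)
    for (j in 1:9) {
      ij <- g$idx[, j]
      dP[ij, ] <- dP[ij, ] + dCols[, j, ]
    }
    dX <- dP[g$interior, , drop = FALSE]
  }
  list(dW = dW, db = db, dX = dX)
}

.tconvF <- function(x, Wt, b, H, W) {
  idx <- .tconvIdx(H, W)
  Cout <- length(b)
  y2 <- x %*% Wt                       # (HW x 4*Cout)
  Y <- matrix(0, 4L * H * W, Cout)
  Y[as.vector(idx), ] <- matrix(y2, nrow(x) * 4L, Cout)
  .addBias(Y, b)
}

.tconvB <- function(dY, x, Wt, H, W) {
  idx <- .tconvIdx(H, W)
  Cout <- ncol(dY)
  dy2 <- dY[as.vector(idx), , drop = FALSE]  # (HW*4 x Cout)
  dim(dy2) <- c(nrow(x), 4L * Cout)
  list(dW = crossprod(x, dy2), db = colSums(dY), dX = dy2 %*% t(Wt))
}

## ---- parameter construction ----

.unetChannels <- function(cfg) cfg$baseChannels * 2L^(seq_len(cfg$depth) - 1L)

.heW <- function(nin, nout, fan) matrix(stats::rnorm(nin * nout,
                                                     sd = sqrt(2 / fan)),
                                        nin, nout)

#' Initialise U-net parameters (internal)
#' @noRd
.initUNet <- function(cfg, seed) {
  set.seed(seed)
  d <- cfg$depth
  ch <- .unetChannels(cfg)
  P <- list()
  cin <- cfg$inChannels
  for (i in seq_len(d)) {
    if (i > 1L) {
      P[[sprintf("down%d", i)]] <-
        list(W = .heW(9L * ch[i - 1L], ch[i], 9L * ch[i - 1L]),
             b = numeric(ch[i]))
      cin <- ch[i]
    }
    P[[sprintf("enc%d_c1", i)]] <-
      list(W = .heW(9L * cin, ch[i], 9L * cin), b = numeric(ch[i]))
    P[[sprintf("enc%d_c2", i)]] <-
      list(W = .heW(9L * ch[i], ch[i], 9L * ch[i]), b = numeric(ch[i]))
    cin <- ch[i]
  }
  for (i in rev(seq_len(d - 1L))) {
    P[[sprintf("up%d", i)]] <-
      list(W = .heW(ch[i + 1L], 4L * ch[i], 4L * ch[i + 1L]),
           b = numeric(ch[i]))
    P[[sprintf("dec%d_c1", i)]] <-
      list(W = .heW(9L * 2L * ch[i], ch[i], 9L * 2L * ch[i]),
           b = numeric(ch[i]))
    P[[sprintf("dec%d_c2", i)]] <-
      list(W = .heW(9L * ch[i], ch[i], 9L * ch[i]), b = numeric(ch[i]))
  }
  P[["final"]] <- list(W = .heW(ch[1L], cfg$classes, ch[1L]),
                       b = numeric(cfg$classes))
  opt <- lapply(P, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                    mb = p$b * 0, vb = p$b * 0))
  list(cfg = cfg, params = P, opt = opt, step = 0L)
}

.checkDivisible <- function(H, W, depth) {
  f <- 2L^(depth - 1L)
  if (H %% f != 0L || W %% f != 0L)
    stop(sprintf("input %dx%d not divisible by 2^(depth-1) = %d", H, W, f))
}

## ---- forward / backward ----

#' Forward pass; x is an (H*W x Cin) matrix
#' @noRd
.unetForward <- function(net, x, H, W, keepCache = TRUE) {
  cfg <- net$cfg; P <- net$params
  .checkDivisible(H, W, cfg$depth)
  d <- cfg$depth
  cache <- list(H = H, W = W)
  skips <- list(); dims <- list()
  cur <- x; curH <- H; curW <- W
  for (i in seq_len(d)) {
    if (i > 1L) {
      nm <- sprintf("down%d", i)
      cv <- .convF(cur, P[[nm]]$W, P[[nm]]$b, curH, curW, stride = 2L)
      if (keepCache)
        cache[[nm]] <- list(cols = cv$cols, pre = cv$y, H = curH, W = curW,
                            Cin = ncol(cur))
      cur <- pmax(cv$y, 0); curH <- cv$oH; curW <- cv$oW
    }
    for (j in 1:2) {
      nm <- sprintf("enc%d_c%d", i, j)
      cv <- .convF(cur, P[[nm]]$W, P[[nm]]$b, curH, curW, stride = 1L)
      if (keepCache)
        cache[[nm]] <- list(cols = cv$cols, pre = cv$y, H = curH, W = curW,
                            Cin = ncol(cur))
      cur <- pmax(cv$y, 0)
    }
    skips[[i]] <- cur; dims[[i]] <- c(curH, curW)
  }
  for (i in rev(seq_len(d - 1L))) {
    nm <- sprintf("up%d", i)
    up <- .tconvF(cur, P[[nm]]$W, P[[nm]]$b, curH, curW)
    if (keepCache)
      cache[[nm]] <- list(x = cur, pre = up, H = curH, W = curW)
    up <- pmax(up, 0)
    curH <- dims[[i]][1L]; curW <- dims[[i]][2L]
    cur <- cbind(skips[[i]], up)
    for (j in 1:2) {
      nm <- sprintf("dec%d_c%d", i, j)
      cv <- .convF(cur, P[[nm]]$W, P[[nm]]$b, curH, curW, stride = 1L)
      if (keepCache)
        cache[[nm]] <- list(cols = cv$cols, pre = cv$y, H = curH, W = curW,
                            Cin = ncol(cur))
      cur <- pmax(cv$y, 0)
    }
  }
  if (keepCache) cache[["finalIn"]] <- cur
  logits <- .addBias(cur %*% P[["final"]]$W, P[["final"]]$b)
  mx <- logits[cbind(seq_len(nrow(logits)), max.col(logits, "first"))]
  e <- exp(logits - mx)
  prob <- e / rowSums(e)
  list(logits = logits, prob = prob, cache = if (keepCache) cache else NULL)
}

#' Backward pass from dLogits; returns gradient list parallel to params
#' @noRd
.unetBackward <- function(net, cache, dLogits) {
  cfg <- net$cfg; P <- net$params
  d <- cfg$depth
  G <- list()
  G[["final"]] <- list(dW = crossprod(cache[["finalIn"]], dLogits),
                       db = colSums(dLogits))
  cur <- dLogits %*% t(P[["final"]]$W)
  dSkip <- vector("list", d)          # gradients flowing into encoder skips
  ch <- .unetChannels(cfg)
  for (i in seq_len(d - 1L)) {        # decoder levels, shallow to deep
    for (j in 2:1) {
      nm <- sprintf("dec%d_c%d", i, j)
      cc <- cache[[nm]]
      cur <- cur * (cc$pre > 0)
      bk <- .convB(cur, cc$cols, P[[nm]]$W, cc$H, cc$W, 1L, cc$Cin)
      G[[nm]] <- list(dW = bk$dW, db = bk$db)
      cur <- bk$dX
    }
    ## split the concat [skip_i | up_i]
    nSkip <- ch[i]
    dSkip[[i]] <- cur[, seq_len(nSkip), drop = FALSE]
    dUp <- cur[, nSkip + seq_len(nSkip), drop = FALSE]
    nm <- sprintf("up%d", i)
    cc <- cache[[nm]]
    dUp <- dUp * (cc$pre > 0)
    bk <- .tconvB(dUp, cc$x, P[[nm]]$W, cc$H, cc$W)
    G[[nm]] <- list(dW = bk$dW, db = bk$db)
    cur <- bk$dX                      # gradient w.r.t. level-(i+1) output
  }
  ## cur now holds the gradient w.r.t. the deepest encoder output; add
  ## the skip-path gradients while walking the encoder deep->shallow
  for (i in rev(seq_len(d))) {
    dOut <- cur
    if (i < d && !is.null(dSkip[[i]])) dOut <- dOut + dSkip[[i]]
    for (j in 2:1) {
      nm <- sprintf("enc%d_c%d", i, j)
      cc <- cache[[nm]]
      dOut <- dOut * (cc$pre > 0)
      bk <- .convB(dOut, cc$cols, P[[nm]]$W, cc$H, cc$W, 1L, cc$Cin)
      G[[nm]] <- list(dW = bk$dW, db = bk$db)
      dOut <- bk$dX
    }
    if (i > 1L) {
      nm <- sprintf("down%d", i)
      cc <- cache[[nm]]
      dOut <- dOut * (cc$pre > 0)
      bk <- .convB(dOut, cc$cols, P[[nm]]$W, cc$H, cc$W, 2L, cc$Cin)
      G[[nm]] <- list(dW = bk$dW, db = bk$db)
      cur <- bk$dX
    } else {
      cur <- dOut
    }
  }
  G
}

## Mean cross entropy over the included pixels; labels are 1-based
## class indices, include a logical mask (NULL = all pixels).
.softmaxCE <- function(prob, labels, include = NULL) {
  n <- nrow(prob)
  if (is.null(include)) include <- rep(TRUE, n)
  ni <- sum(include)
  if (ni == 0L) return(list(loss = NA_real_, dLogits = NULL))
  pTrue <- prob[cbind(seq_len(n), labels)]
  loss <- -mean(log(pmax(pTrue[include], 1e-12)))
  dL <- prob
  dL[cbind(seq_len(n), labels)] <- dL[cbind(seq_len(n), labels)] - 1
  dL[!include, ] <- 0
  list(loss = loss, dLogits = dL / ni)
}

#' One Adam update; disconnected per network by construction
#' @noRd
.adamStep <- function(net, grads, alpha, beta1, beta2, eps = 1e-8) {
  net$step <- net$step + 1L
  t <- net$step
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (nm in names(grads)) {
    g <- grads[[nm]]; o <- net$opt[[nm]]
    o$mW <- beta1 * o$mW + (1 - beta1) * g$dW
    o$vW <- beta2 * o$vW + (1 - beta2) * g$dW^2
    net$params[[nm]]$W <- net$params[[nm]]$W -
      alpha * (o$mW / bc1) / (sqrt(o$vW / bc2) + eps)
    o$mb <- beta1 * o$mb + (1 - beta1) * g$db
    o$vb <- beta2 * o$vb + (1 - beta2) * g$db^2
    net$params[[nm]]$b <- net$params[[nm]]$b -
      alpha * (o$mb / bc1) / (sqrt(o$vb / bc2) + eps)
    net$opt[[nm]] <- o
  }
  net
}
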