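# Minimal dense-convolutional network engine in base R.
#
# Activations are 4-D arrays (H, W, C, N), column-major. Convolutions are
# evaluated as im2col gathers followed by one BLAS matmul; the backward
# scatter (col2im) is a lazily built sparse-matrix multiply. Gather indices
# are precomputed at model-construction time, since the input spatial size
# is fixed by the layer plan. Composite layers use the pre-activation
# BN-ReLU-Conv ordering of standard DenseNets; batch-norm running statistics
# are part of the parameter state and flow through snapshot/restore.

pad_spatial <- function(x, p, fill = 0) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(fill, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  xp[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , ] <- x
  xp
}

unpad_spatial <- function(xp, p, H, W) {
  if (p == 0L) return(xp)
  xp[(p + 1L):(p + H), (p + 1L):(p + W), , , drop = FALSE]
}

# gather index matrix (k*k*C x Ho*Wo) into a padded (Hp, Wp, C) slab
im2col_idx <- function(Hp, Wp, C, k, s) {
  Ho <- (Hp - k) %/% s + 1L
  Wo <- (Wp - k) %/% s + 1L
  dr <- rep(0:(k - 1L), times = k * C)
  dc <- rep(rep(0:(k - 1L), each = k), times = C)
  ch <- rep(0:(C - 1L), each = k * k)
  off <- dr + dc * Hp + ch * (Hp * Wp)
  i0 <- rep((0:(Ho - 1L)) * s, times = Wo)
  j0 <- rep((0:(Wo - 1L)) * s, each = Ho)
  base <- (i0 + 1L) + j0 * Hp
  list(idx = outer(off, base, "+"), Ho = Ho, Wo = Wo)
}

he_uniform <- function(nr, nc, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# batch normalization over (H, W, N) per channel -----------------------------

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

new_bn <- function(channels) {
  list(gamma = rep(1, channels), beta = rep(0, channels),
       rmean = rep(0, channels), rvar = rep(1, channels))
}

bn_forward <- function(bn, x, train) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  cm <- matrix(colMeans(m), d[3], d[4])
  if (train) {
    mu <- rowMeans(cm)
    v <- rowMeans(matrix(colMeans(m^2), d[3], d[4])) - mu^2
    v <- pmax(v, 0)
  } else {
    mu <- bn$rmean
    v <- bn$rvar
  }
  inv <- 1 / sqrt(v + .BN_EPS)
  scale <- rep(bn$gamma * inv, times = d[4])
  shift <- rep(bn$beta - bn$gamma * inv * mu, times = d[4])
  y <- m * rep(scale, each = d[1] * d[2]) + rep(shift, each = d[1] * d[2])
  dim(y) <- d
  cache <- if (train) list(mu = mu, v = v, inv = inv, x = x) else NULL
  list(y = y, cache = cache)
}

bn_backward <- function(bn, dy, cache) {
  d <- dim(dy)
  npx <- d[1] * d[2]
  nred <- npx * d[4]  # elements reduced per channel
  dym <- matrix(dy, npx, d[3] * d[4])
  xm <- matrix(cache$x, npx, d[3] * d[4])
  xhat <- (xm - rep(rep(cache$mu, times = d[4]), each = npx)) *
    rep(rep(cache$inv, times = d[4]), each = npx)
  sum_dy <- rowSums(matrix(colSums(dym), d[3], d[4]))
  sum_dyx <- rowSums(matrix(colSums(dym * xhat), d[3], d[4]))
  dgamma <- sum_dyx
  dbeta <- sum_dy
  gi <- bn$gamma * cache$inv / nred
  dx <- rep(rep(gi, times = d[4]), each = npx) *
    (nred * dym - rep(rep(sum_dy, times = d[4]), each = npx) -
       xhat * rep(rep(sum_dyx, times = d[4]), each = npx))
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta, mu = cache$mu, v = cache$v)
}

bn_update <- function(bn, g, lr) {
  bn$gamma <- sgd_update(bn$gamma, g$dgamma, lr)
  bn$beta <- sgd_update(bn$beta, g$dbeta, lr)
  bn$rmean <- (1 - .BN_MOMENTUM) * bn$rmean + .BN_MOMENTUM * g$mu
  bn$rvar <- (1 - .BN_MOMENTUM) * bn$rvar + .BN_MOMENTUM * g$v
  bn
}

# convolution ----------------------------------------------------------------

# pre_norm: BN-ReLU applied to the input (pre-activation composite style);
# post_norm: BN-ReLU applied to the output (stem convolution style)
new_conv <- function(in_spatial, in_ch, out_ch, k, s, p,
                     pre_norm = FALSE, post_norm = FALSE) {
  ly <- list(type = "conv", k = k, s = s, p = p, in_ch = in_ch,
             out_ch = out_ch, pre_norm = pre_norm, post_norm = post_norm,
             in_spatial = in_spatial)
  ly$W <- he_uniform(k * k * in_ch, out_ch, fan_in = k * k * in_ch)
  ly$b <- numeric(out_ch)
  if (pre_norm) ly$bn <- new_bn(in_ch)
  if (post_norm) ly$bn <- new_bn(out_ch)
  if (!(k == 1L && s == 1L && p == 0L)) {
    Hp <- in_spatial + 2L * p
    g <- im2col_idx(Hp, Hp, in_ch, k, s)
    ly$idx <- g$idx
    ly$out_spatial <- g$Ho
    ly$env <- new.env(parent = emptyenv())  # lazy col2im scatter cache
  } else {
    ly$out_spatial <- in_spatial
  }
  ly
}

conv_scatter <- function(ly) {
  if (is.null(ly$env$scatter)) {
    Hp <- ly$in_spatial + 2L * ly$p
    ly$env$scatter <- Matrix::sparseMatrix(
      i = as.vector(ly$idx), j = seq_along(ly$idx),
      x = 1, dims = c(Hp * Hp * ly$in_ch, length(ly$idx))
    )
  }
  ly$env$scatter
}

conv_forward <- function(ly, x, train = FALSE, keep = TRUE) {
  d <- dim(x); N <- d[4]
  prem <- bn_cache <- NULL
  if (ly$pre_norm) {
    r <- bn_forward(ly$bn, x, train)
    bn_cache <- r$cache
    prem <- r$y > 0
    x <- r$y * prem
  }
  if (ly$k == 1L && ly$s == 1L && ly$p == 0L) {
    P <- d[1] * d[2]
    cols <- matrix(aperm(x, c(3, 1, 2, 4)), ly$in_ch, P * N)
    Ho <- d[1]; Wo <- d[2]
  } else {
    xp <- pad_spatial(x, ly$p)
    dp <- dim(xp)
    xpm <- matrix(xp, dp[1] * dp[2] * dp[3], N)
    cols <- xpm[as.vector(ly$idx), , drop = FALSE]
    P <- ncol(ly$idx)
    dim(cols) <- c(nrow(ly$idx), P * N)
    Ho <- ly$out_spatial; Wo <- ly$out_spatial
  }
  out <- crossprod(ly$W, cols) + ly$b
  y <- aperm(array(out, c(ly$out_ch, Ho, Wo, N)), c(2, 3, 1, 4))
  postm <- NULL
  if (ly$post_norm) {
    r <- bn_forward(ly$bn, y, train)
    bn_cache <- r$cache
    postm <- r$y > 0
    y <- r$y * postm
  }
  cache <- if (keep) list(cols = cols, prem = prem, postm = postm,
                          bn = bn_cache, in_dim = d) else NULL
  list(y = y, cache = cache)
}

conv_backward <- function(ly, dy, cache) {
  bng <- NULL
  if (ly$post_norm) {
    dy <- dy * cache$postm
    r <- bn_backward(ly$bn, dy, cache$bn)
    bng <- r[c("dgamma", "dbeta", "mu", "v")]
    dy <- r$dx
  }
  d <- cache$in_dim; N <- d[4]
  Ho <- dim(dy)[1]; Wo <- dim(dy)[2]
  P <- Ho * Wo
  dout <- matrix(aperm(dy, c(3, 1, 2, 4)), ly$out_ch, P * N)
  dW <- tcrossprod(cache$cols, dout)
  db <- rowSums(dout)
  dcols <- ly$W %*% dout
  if (ly$k == 1L && ly$s == 1L && ly$p == 0L) {
    dx <- aperm(array(dcols, c(ly$in_ch, Ho, Wo, N)), c(2, 3, 1, 4))
  } else {
    dim(dcols) <- c(length(ly$idx), N)
    dxp <- as.matrix(conv_scatter(ly) %*% dcols)
    Hp <- ly$in_spatial + 2L * ly$p
    dxp <- array(dxp, c(Hp, Hp, ly$in_ch, N))
    dx <- unpad_spatial(dxp, ly$p, d[1], d[2])
  }
  if (ly$pre_norm) {
    dx <- dx * cache$prem
    r <- bn_backward(ly$bn, dx, cache$bn)
    bng <- r[c("dgamma", "dbeta", "mu", "v")]
    dx <- r$dx
  }
  list(dx = dx, dW = dW, db = db, bng = bng)
}

conv_update <- function(ly, g, lr) {
  ly$W <- sgd_update(ly$W, g$dW, lr)
  ly$b <- sgd_update(ly$b, g$db, lr)
  if (!is.null(g$bng)) ly$bn <- bn_update(ly$bn, g$bng, lr)
  ly
}

conv_get_params <- function(ly) {
  p <- list(W = ly$W, b = ly$b)
  if (!is.null(ly$bn)) p$bn <- ly$bn
  p
}

conv_set_params <- function(ly, p) {
  ly$W <- p$W; ly$b <- p$b
  if (!is.null(p$bn)) ly$bn <- p$bn
  ly
}

# pooling --------------------------------------------------------------------

new_maxpool <- function(in_spatial, k = 3L, s = 2L, p = 1L) {
  Hp <- in_spatial + 2L * p
  g <- im2col_idx(Hp, Hp, 1L, k, s)
  list(type = "maxpool", k = k, s = s, p = p, idx = g$idx,
       in_spatial = in_spatial, out_spatial = g$Ho)
}

maxpool_forward <- function(ly, x, keep = TRUE) {
  d <- dim(x); C <- d[3]; N <- d[4]
  xp <- pad_spatial(x, ly$p, fill = -Inf)
  dp <- dim(xp)
  xpm <- matrix(xp, dp[1] * dp[2], C * N)
  M <- xpm[as.vector(ly$idx), , drop = FALSE]
  kk <- nrow(ly$idx); P <- ncol(ly$idx)
  dim(M) <- c(kk, P * C * N)
  mx <- M[1L, ]
  arg <- rep(1L, length(mx))
  for (j in 2:kk) {
    w <- M[j, ] > mx
    mx[w] <- M[j, w]
    arg[w] <- j
  }
  y <- array(mx, c(ly$out_spatial, ly$out_spatial, C, N))
  cache <- if (keep) list(arg = matrix(arg, P, C * N), in_dim = d) else NULL
  list(y = y, cache = cache)
}

maxpool_backward <- function(ly, dy, cache) {
  d <- cache$in_dim; C <- d[3]; N <- d[4]
  P <- ncol(ly$idx)
  dym <- matrix(dy, P, C * N)
  Hp <- d[1] + 2L * ly$p
  dxp <- matrix(0, Hp * Hp, C * N)
  for (j in seq_len(nrow(ly$idx))) {
    m <- cache$arg == j
    if (!any(m)) next
    rows <- ly$idx[j, ]
    dxp[rows, ] <- dxp[rows, ] + dym * m
  }
  dxp <- array(dxp, c(Hp, Hp, C, N))
  list(dx = unpad_spatial(dxp, ly$p, d[1], d[2]))
}

avgpool2_forward <- function(x) {
  d <- dim(x)
  a <- array(x, c(2L, d[1] %/% 2L, 2L, d[2] %/% 2L, d[3], d[4]))
  y <- (a[1, , 1, , , , drop = FALSE] + a[2, , 1, , , , drop = FALSE] +
        a[1, , 2, , , , drop = FALSE] + a[2, , 2, , , , drop = FALSE]) / 4
  dim(y) <- c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4])
  y
}

avgpool2_backward <- function(dy, in_dim) {
  d <- in_dim
  dxa <- array(0, c(2L, d[1] %/% 2L, 2L, d[2] %/% 2L, d[3], d[4]))
  q <- array(dy / 4, c(1L, d[1] %/% 2L, 1L, d[2] %/% 2L, d[3], d[4]))
  for (u in 1:2) for (v in 1:2) dxa[u, , v, , , ] <- q
  array(dxa, d)
}

# dense block ----------------------------------------------------------------

# each composite layer is BN-ReLU-Conv1x1 (bottleneck, optional) followed by
# BN-ReLU-Conv3x3 and dropout; its output is concatenated onto the running
# feature stack
new_dense_block <- function(in_spatial, in_ch, n_layers, growth,
                            bottleneck = TRUE, dropout = 0.2) {
  comps <- vector("list", n_layers)
  ch <- in_ch
  for (i in seq_len(n_layers)) {
    comp <- list(in_ch = ch)
    if (bottleneck) {
      comp$bn_conv <- new_conv(in_spatial, ch, 4L * growth, 1L, 1L, 0L,
                               pre_norm = TRUE)
      comp$conv3 <- new_conv(in_spatial, 4L * growth, growth, 3L, 1L, 1L,
                             pre_norm = TRUE)
    } else {
      comp$conv3 <- new_conv(in_spatial, ch, growth, 3L, 1L, 1L,
                             pre_norm = TRUE)
    }
    comps[[i]] <- comp
    ch <- ch + growth
  }
  list(type = "dense_block", comps = comps, in_ch = in_ch, out_ch = ch,
       growth = growth, dropout = dropout, bottleneck = bottleneck,
       in_spatial = in_spatial, out_spatial = in_spatial)
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  y
}

dense_block_forward <- function(ly, x, train = FALSE, keep = TRUE) {
  feats <- x
  caches <- vector("list", length(ly$comps))
  for (i in seq_along(ly$comps)) {
    comp <- ly$comps[[i]]
    cc <- list()
    h <- feats
    if (ly$bottleneck) {
      r <- conv_forward(comp$bn_conv, h, train, keep)
      cc$bn <- r$cache
      h <- r$y
    }
    r <- conv_forward(comp$conv3, h, train, keep)
    cc$c3 <- r$cache
    h <- r$y
    if (train && ly$dropout > 0) {
      mask <- (stats::runif(length(h)) > ly$dropout) / (1 - ly$dropout)
      dim(mask) <- dim(h)
      h <- h * mask
      cc$drop <- mask
    }
    cc$prev_ch <- dim(feats)[3]
    caches[[i]] <- cc
    feats <- concat_ch(feats, h)
  }
  list(y = feats, cache = if (keep) caches else NULL)
}

dense_block_backward <- function(ly, dy, caches) {
  grads <- vector("list", length(ly$comps))
  dfeats <- dy
  for (i in rev(seq_along(ly$comps))) {
    comp <- ly$comps[[i]]
    cc <- caches[[i]]
    pc <- cc$prev_ch
    d <- dim(dfeats)
    dprev <- dfeats[, , seq_len(pc), , drop = FALSE]
    dh <- dfeats[, , (pc + 1L):d[3], , drop = FALSE]
    if (!is.null(cc$drop)) dh <- dh * cc$drop
    g <- list()
    r3 <- conv_backward(comp$conv3, dh, cc$c3)
    g$c3 <- r3[c("dW", "db", "bng")]
    dh <- r3$dx
    if (ly$bottleneck) {
      rb <- conv_backward(comp$bn_conv, dh, cc$bn)
      g$bn <- rb[c("dW", "db", "bng")]
      dh <- rb$dx
    }
    grads[[i]] <- g
    dfeats <- dprev + dh
  }
  list(dx = dfeats, grads = grads)
}

softmax_cols <- function(z) {
  z <- z - matrix(apply(z, 2, max), nrow(z), ncol(z), byrow = TRUE)
  e <- exp(z)
  e / matrix(colSums(e), nrow(z), ncol(z), byrow = TRUE)
}

# model ----------------------------------------------------------------------

#' Instantiate a runnable model from a layer plan
#'
#' Builds a trainable dense-convolutional network whose stage-by-stage
#' spatial sizes match the symbolic plan exactly (verifiable with
#' [shape_probe()]). Construction is deterministic per `seed` (He-uniform
#' initialisation). `growth`, `init_channels`, `block_layers` and
#' `bottleneck` allow a reduced instantiation of the same plan for
#' CPU-budget experiments; the defaults are the standard DenseNet-169
#' configuration (growth 32, blocks 6/12/32/32, 0.5 transition compression,
#' pre-activation batch normalisation).
#'
#' @param plan a [`layer_plan`][build_layer_plan].
#' @param seed integer seed for weight initialisation.
#' @param growth channels added by each composite layer in a dense block.
#' @param init_channels channels produced by the stem convolution.
#' @param block_layers composite layers per dense block (length 4); defaults
#'   to the plan's 6/12/32/32.
#' @param bottleneck include 1x1 bottleneck convolutions in composites.
#' @param compression transition-layer channel compression factor.
#' @param dropout dropout rate inside dense blocks (0.2 per the plan).
#' @return object of class `dense_net`.
#' @export
instantiate_network <- function(plan, seed, growth = 32L,
                                init_channels = 2L * growth,
                                block_layers = plan$block_layers,
                                bottleneck = TRUE, compression = 0.5,
                                dropout = 0.2) {
  stopifnot(inherits(plan, "layer_plan"), length(block_layers) == 4L)
  H <- plan$input_size[1]
  in_ch <- plan$input_size[3]
  withr::with_seed(as.integer(seed), {
    stages <- list()
    s <- H
    stem <- new_conv(s, in_ch, init_channels, 7L, 2L, 3L, post_norm = TRUE)
    s <- stem$out_spatial
    stages[[1]] <- list(kind = "conv", ly = stem)
    pool <- new_maxpool(s)
    s <- pool$out_spatial
    stages[[2]] <- list(kind = "maxpool", ly = pool)
    ch <- init_channels
    for (b in 1:4) {
      blk <- new_dense_block(s, ch, block_layers[b], growth,
                             bottleneck = bottleneck, dropout = dropout)
      ch <- blk$out_ch
      stages[[length(stages) + 1L]] <- list(kind = "dense_block", ly = blk)
      if (b < 4L) {
        tch <- max(1L, as.integer(floor(ch * compression)))
        tconv <- new_conv(s, ch, tch, 1L, 1L, 0L, pre_norm = TRUE)
        s <- s %/% 2L
        ch <- tch
        stages[[length(stages) + 1L]] <- list(kind = "transition", ly = tconv)
      }
    }
    head <- list(
      bn = new_bn(ch),
      W = he_uniform(ch, plan$num_classes, fan_in = ch),
      b = numeric(plan$num_classes)
    )
    stages[[length(stages) + 1L]] <- list(kind = "classification", ly = head)
    structure(
      list(plan = plan, stages = stages, seed = as.integer(seed),
           cfg = list(growth = growth, init_channels = init_channels,
                      block_layers = block_layers, bottleneck = bottleneck,
                      compression = compression, dropout = dropout),
           fingerprint = paste(
             "densenet-plan", H, plan$input_size[3], plan$num_classes,
             growth, init_channels, paste(block_layers, collapse = "."),
             bottleneck, compression, sep = ":"
           )),
      class = "dense_net"
    )
  })
}

model_forward <- function(model, x, train = FALSE, keep = TRUE) {
  stopifnot(length(dim(x)) == 4L)
  caches <- vector("list", length(model$stages))
  spatial <- integer(0)
  for (i in seq_along(model$stages)) {
    st <- model$stages[[i]]
    if (st$kind == "conv") {
      r <- conv_forward(st$ly, x, train, keep)
      x <- r$y; caches[[i]] <- r$cache
    } else if (st$kind == "maxpool") {
      r <- maxpool_forward(st$ly, x, keep)
      x <- r$y; caches[[i]] <- r$cache
    } else if (st$kind == "dense_block") {
      r <- dense_block_forward(st$ly, x, train = train, keep = keep)
      x <- r$y; caches[[i]] <- r$cache
    } else if (st$kind == "transition") {
      r <- conv_forward(st$ly, x, train, keep)
      caches[[i]] <- list(conv = r$cache, pre_pool_dim = dim(r$y))
      x <- avgpool2_forward(r$y)
    } else { # classification head: BN-ReLU-global pool-FC-softmax
      rb <- bn_forward(st$ly$bn, x, train)
      relu_mask <- rb$y > 0
      xr <- rb$y * relu_mask
      d <- dim(xr)
      fm <- matrix(xr, d[1] * d[2], d[3] * d[4])
      feat <- matrix(colMeans(fm), d[3], d[4])
      logits <- crossprod(st$ly$W, feat) + st$ly$b
      probs <- softmax_cols(logits)
      caches[[i]] <- list(relu_mask = relu_mask, feat = feat, in_dim = d,
                          bn = rb$cache)
      spatial <- c(spatial, 1L)
      return(list(probs = probs, caches = caches, spatial = spatial))
    }
    spatial <- c(spatial, dim(x)[1])
  }
  stop("plan ended without classification stage")
}

# dlogits: (num_classes x N) gradient at the pre-softmax output
model_backward <- function(model, caches, dlogits) {
  n_st <- length(model$stages)
  grads <- vector("list", n_st)
  cc <- caches[[n_st]]
  st <- model$stages[[n_st]]
  ghead <- list(dW = cc$feat %*% t(dlogits), db = rowSums(dlogits))
  dfeat <- st$ly$W %*% dlogits
  d <- cc$in_dim
  dx <- array(rep(as.vector(dfeat) / (d[1] * d[2]), each = d[1] * d[2]), d)
  dx <- dx * cc$relu_mask
  rb <- bn_backward(st$ly$bn, dx, cc$bn)
  ghead$bng <- rb[c("dgamma", "dbeta", "mu", "v")]
  grads[[n_st]] <- ghead
  dx <- rb$dx
  for (i in rev(seq_len(n_st - 1L))) {
    st <- model$stages[[i]]
    if (st$kind == "conv") {
      r <- conv_backward(st$ly, dx, caches[[i]])
      grads[[i]] <- r[c("dW", "db", "bng")]
      dx <- r$dx
    } else if (st$kind == "maxpool") {
      dx <- maxpool_backward(st$ly, dx, caches[[i]])$dx
    } else if (st$kind == "dense_block") {
      r <- dense_block_backward(st$ly, dx, caches[[i]])
      grads[[i]] <- r$grads
      dx <- r$dx
    } else if (st$kind == "transition") {
      dpool <- avgpool2_backward(dx, caches[[i]]$pre_pool_dim)
      r <- conv_backward(st$ly, dpool, caches[[i]]$conv)
      grads[[i]] <- r[c("dW", "db", "bng")]
      dx <- r$dx
    }
  }
  grads
}

model_apply_grads <- function(model, grads, lr) {
  for (i in seq_along(model$stages)) {
    st <- model$stages[[i]]
    g <- grads[[i]]
    if (is.null(g)) next
    if (st$kind %in% c("conv", "transition")) {
      model$stages[[i]]$ly <- conv_update(st$ly, g, lr)
    } else if (st$kind == "classification") {
      model$stages[[i]]$ly$W <- sgd_update(st$ly$W, g$dW, lr)
      model$stages[[i]]$ly$b <- sgd_update(st$ly$b, g$db, lr)
      model$stages[[i]]$ly$bn <- bn_update(st$ly$bn, g$bng, lr)
    } else if (st$kind == "dense_block") {
      for (j in seq_along(st$ly$comps)) {
        gj <- g[[j]]
        model$stages[[i]]$ly$comps[[j]]$conv3 <-
          conv_update(st$ly$comps[[j]]$conv3, gj$c3, lr)
        if (!is.null(gj$bn)) {
          model$stages[[i]]$ly$comps[[j]]$bn_conv <-
            conv_update(st$ly$comps[[j]]$bn_conv, gj$bn, lr)
        }
      }
    }
  }
  model
}

#' Probe the per-stage spatial sizes of an instantiated model
#'
#' Runs a single forward pass on a zero image and records the spatial side
#' length after every plan row; the result must equal the plan's
#' `out_spatial` column.
#'
#' @param model a [`dense_net`][instantiate_network].
#' @return integer vector, one entry per plan row.
#' @export
shape_probe <- function(model) {
  H <- model$plan$input_size[1]
  x <- array(0, c(H, H, model$plan$input_size[3], 1L))
  model_forward(model, x, train = FALSE, keep = FALSE)$spatial
}

# one SGD step on a batch; yb are 1-based class indices
train_step <- function(model, xb, yb, lr) {
  fw <- model_forward(model, xb, train = TRUE, keep = TRUE)
  n <- dim(xb)[4]
  probs <- fw$probs
  Y <- matrix(0, nrow(probs), n)
  Y[cbind(yb, seq_len(n))] <- 1
  loss <- -mean(log(pmax(probs[cbind(yb, seq_len(n))], .CE_PROB_FLOOR)))
  dlogits <- (probs - Y) / n
  grads <- model_backward(model, fw$caches, dlogits)
  model <- model_apply_grads(model, grads, lr)
  list(model = model, loss = loss)
}

model_params <- function(model) {
  lapply(model$stages, function(st) {
    if (st$kind %in% c("conv", "transition")) {
      conv_get_params(st$ly)
    } else if (st$kind == "classification") {
      list(W = st$ly$W, b = st$ly$b, bn = st$ly$bn)
    } else if (st$kind == "dense_block") {
      lapply(st$ly$comps, function(cp) {
        out <- list(c3 = conv_get_params(cp$conv3))
        if (!is.null(cp$bn_conv)) out$bn <- conv_get_params(cp$bn_conv)
        out
      })
    } else NULL
  })
}

model_set_params <- function(model, params) {
  for (i in seq_along(model$stages)) {
    st <- model$stages[[i]]
    p <- params[[i]]
    if (is.null(p)) next
    if (st$kind %in% c("conv", "transition")) {
      model$stages[[i]]$ly <- conv_set_params(st$ly, p)
    } else if (st$kind == "classification") {
      model$stages[[i]]$ly$W <- p$W
      model$stages[[i]]$ly$b <- p$b
      model$stages[[i]]$ly$bn <- p$bn
    } else if (st$kind == "dense_block") {
      for (j in seq_along(st$ly$comps)) {
        model$stages[[i]]$ly$comps[[j]]$conv3 <-
          conv_set_params(st$ly$comps[[j]]$conv3, p[[j]]$c3)
        if (!is.null(p[[j]]$bn)) {
          model$stages[[i]]$ly$comps[[j]]$bn_conv <-
            conv_set_params(st$ly$comps[[j]]$bn_conv, p[[j]]$bn)
        }
      }
    }
  }
  model
}

#' Save / load model checkpoints
#'
#' A checkpoint stores the parameter tensors plus a plan fingerprint;
#' [load_checkpoint()] refuses to restore into a model built from a
#' different plan or configuration.
#'
#' @param model a [`dense_net`][instantiate_network].
#' @param path checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model with restored parameters.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(fingerprint = model$fingerprint,
               params = model_params(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(model, path) {
  ck <- readRDS(path)
  if (!identical(ck$fingerprint, model$fingerprint)) {
    stop("checkpoint fingerprint does not match the model's plan/config")
  }
  model_set_params(model, ck$params)
}

#' @export
print.dense_net <- function(x, ...) {
  cat(sprintf(
    "<dense_net> input %dx%dx%d, %d classes, growth %d, blocks %s%s\n",
    x$plan$input_size[1], x$plan$input_size[2], x$plan$input_size[3],
    x$plan$num_classes, x$cfg$growth,
    paste(x$cfg$block_layers, collapse = "/"),
    if (x$cfg$bottleneck) ", bottleneck" else ""
  ))
  invisible(x)
}
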