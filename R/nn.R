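# Minimal deterministic neural-net engine: 3D conv / transposed-conv / pooling /
# dense layers with hand-derived backward passes, driven by im2col/col2im C++
# primitives and BLAS matrix products. Tensors are arrays dim (D, H, W, C, N).
# All randomness goes through R's RNG so training is reproducible given a seed
# and serial execution.

conv_out_spatial <- function(sp, k, stride, pad) (sp + 2L * pad - k) %/% stride + 1L

#' @useDynLib radiogan, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Gather/scatter index maps are pure functions of (spatial dims, channels,
# kernel, stride, pad); they are memoized here so training iterations reduce
# to flat gathers plus BLAS matrix products.
.conv_cache <- new.env(parent = emptyenv())

conv_idx <- function(xdim4, k, stride, pad) {
  key <- paste(c(xdim4, k, stride, pad), collapse = ",")
  idx <- .conv_cache[[key]]
  if (is.null(idx)) {
    idx <- im2col_idx_cpp(as.integer(xdim4), as.integer(k),
                          as.integer(stride), as.integer(pad))
    .conv_cache[[key]] <- idx
  }
  idx
}

conv3d_fwd <- function(x, w, b, stride, pad) {
  xd <- dim(x)
  k <- dim(w)[1:3]
  cout <- dim(w)[5]
  kk <- as.integer(prod(k) * xd[4])
  idx <- conv_idx(xd[1:4], k, stride, pad)
  cols <- gather_cols_cpp(x, idx, as.integer(xd), kk)
  ym <- crossprod(matrix(w, ncol = cout), cols)           # Cout x (Ovox*N)
  osp <- conv_out_spatial(xd[1:3], k, stride, pad)
  ovox <- prod(osp)
  y <- aperm(array(ym, c(cout, ovox, xd[5])), c(2L, 1L, 3L))
  y <- y + rep(b, each = ovox)
  dim(y) <- c(osp, cout, xd[5])
  list(y = y, cols = cols, x_dim = xd)
}

conv3d_bwd <- function(w, cache, gy) {
  cout <- dim(w)[5]
  gyd <- dim(gy)
  ovox <- prod(gyd[1:3])
  gym <- matrix(aperm(array(gy, c(ovox, cout, gyd[5])), c(2L, 1L, 3L)), nrow = cout)
  gw <- array(tcrossprod(cache$cols, gym), dim(w))
  gb <- rowSums(gym)
  gxm <- matrix(w, ncol = cout) %*% gym
  xd <- cache$x_dim
  k <- dim(w)[1:3]
  kk <- as.integer(prod(k) * xd[4])
  idx <- conv_idx(xd[1:4], k, cache$stride, cache$pad)
  gx <- scatter_cols_cpp(gxm, idx, as.integer(xd), kk)
  list(gx = gx, gw = gw, gb = gb)
}

# Transposed conv: weight dim (kd, kh, kw, Cout, Cin); output spatial size is
# (in - 1) * stride - 2 * pad + k, the exact inverse of the conv arithmetic.
convt3d_fwd <- function(x, w, b, stride, pad) {
  xd <- dim(x)
  ivox <- prod(xd[1:3]); cin <- xd[4]; n <- xd[5]
  k <- dim(w)[1:3]; cout <- dim(w)[4]
  osp <- (xd[1:3] - 1L) * stride - 2L * pad + k
  xm <- matrix(aperm(array(x, c(ivox, cin, n)), c(2L, 1L, 3L)), nrow = cin)
  M <- matrix(w, ncol = cin) %*% xm
  bigdim <- as.integer(c(osp, cout, n))
  kk <- as.integer(prod(k) * cout)
  idx <- conv_idx(bigdim[1:4], k, stride, pad)
  y <- scatter_cols_cpp(M, idx, bigdim, kk)
  y <- y + rep(b, each = prod(osp))
  dim(y) <- c(osp, cout, n)
  list(y = y, xm = xm, x_dim = xd)
}

convt3d_bwd <- function(w, cache, gy) {
  k <- dim(w)[1:3]; cout <- dim(w)[4]; cin <- dim(w)[5]
  xd <- cache$x_dim
  ivox <- prod(xd[1:3]); n <- xd[5]
  gyd <- dim(gy)
  kk <- as.integer(prod(k) * cout)
  idx <- conv_idx(gyd[1:4], k, cache$stride, cache$pad)
  cols <- gather_cols_cpp(gy, idx, as.integer(gyd), kk)
  gxm <- crossprod(matrix(w, ncol = cin), cols)
  gx <- aperm(array(gxm, c(cin, ivox, n)), c(2L, 1L, 3L))
  dim(gx) <- xd
  gw <- array(tcrossprod(cols, cache$xm), dim(w))
  gb <- rowSums(matrix(colSums(matrix(gy, prod(gyd[1:3]))), cout))
  list(gx = gx, gw = gw, gb = gb)
}

# ---- layer constructors ----------------------------------------------------

he_sd <- function(fan_in) sqrt(2 / fan_in)

nn_dense <- function(d_in, d_out, init_sd = NULL) {
  sd <- if (is.null(init_sd)) he_sd(d_in) else init_sd
  list(type = "dense",
       par = list(w = matrix(stats::rnorm(d_out * d_in, 0, sd), d_out, d_in),
                  b = numeric(d_out)))
}

nn_conv3 <- function(c_in, c_out, k = 3L, stride = 1L, pad = 1L, init_sd = NULL) {
  sd <- if (is.null(init_sd)) he_sd(k^3 * c_in) else init_sd
  list(type = "conv3", stride = as.integer(stride), pad = as.integer(pad),
       par = list(w = array(stats::rnorm(k^3 * c_in * c_out, 0, sd), c(k, k, k, c_in, c_out)),
                  b = numeric(c_out)))
}

nn_convt3 <- function(c_in, c_out, k = 4L, stride = 2L, pad = 1L, init_sd = NULL) {
  sd <- if (is.null(init_sd)) he_sd(k^3 * c_in) else init_sd
  list(type = "convt3", stride = as.integer(stride), pad = as.integer(pad),
       par = list(w = array(stats::rnorm(k^3 * c_out * c_in, 0, sd), c(k, k, k, c_out, c_in)),
                  b = numeric(c_out)))
}

nn_pool <- function(pool = 2L) list(type = "pool", pool = as.integer(pool))
nn_lrelu <- function(slope = 0.2) list(type = "lrelu", slope = slope)
nn_relu <- function() list(type = "lrelu", slope = 0)
nn_tanh <- function() list(type = "tanh")
nn_dropout <- function(p = 0.5) list(type = "dropout", p = p)
nn_flatten <- function() list(type = "flatten")
nn_reshape <- function(dims) list(type = "reshape", dims = as.integer(dims))

nn_instnorm <- function(c_ch, eps = 1e-5) {
  list(type = "instnorm", eps = eps,
       par = list(gamma = rep(1, c_ch), beta = numeric(c_ch)))
}

# ---- forward / backward ----------------------------------------------------

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    dense = {
      y <- layer$par$w %*% x + layer$par$b
      list(y = y, cache = list(x = x))
    },
    conv3 = {
      r <- conv3d_fwd(x, layer$par$w, layer$par$b, layer$stride, layer$pad)
      list(y = r$y, cache = list(cols = r$cols, x_dim = r$x_dim,
                                 stride = layer$stride, pad = layer$pad))
    },
    convt3 = {
      r <- convt3d_fwd(x, layer$par$w, layer$par$b, layer$stride, layer$pad)
      list(y = r$y, cache = list(xm = r$xm, x_dim = r$x_dim,
                                 stride = layer$stride, pad = layer$pad))
    },
    pool = {
      r <- maxpool3d_fwd_cpp(x, as.integer(dim(x)), layer$pool)
      list(y = r$y, cache = list(idx = r$idx, x_dim = dim(x)))
    },
    lrelu = {
      neg <- x < 0
      y <- x
      y[neg] <- layer$slope * x[neg]
      list(y = y, cache = list(neg = neg))
    },
    tanh = {
      y <- tanh(x)
      list(y = y, cache = list(y = y))
    },
    dropout = {
      if (training && layer$p > 0) {
        keep <- stats::runif(length(x)) >= layer$p
        y <- x * keep / (1 - layer$p)
        dim(y) <- dim(x)
        list(y = y, cache = list(keep = keep))
      } else {
        list(y = x, cache = list(keep = NULL))
      }
    },
    flatten = {
      xd <- dim(x)
      y <- x
      dim(y) <- c(prod(xd[-length(xd)]), xd[length(xd)])
      list(y = y, cache = list(x_dim = xd))
    },
    reshape = {
      y <- x
      dim(y) <- c(layer$dims, ncol(x))
      list(y = y, cache = list(x_dim = dim(x)))
    },
    instnorm = {
      xd <- dim(x)
      s <- prod(xd[1:3]); cc <- xd[4]; n <- xd[5]
      xm <- matrix(x, s, cc * n)
      mu <- colMeans(xm)
      xc <- sweep(xm, 2L, mu)
      v <- colMeans(xc * xc)
      inv <- 1 / sqrt(v + layer$eps)
      xhat <- sweep(xc, 2L, inv, `*`)
      g <- rep(layer$par$gamma, n)
      y <- sweep(xhat, 2L, g, `*`) + rep(rep(layer$par$beta, n), each = s)
      dim(y) <- xd
      list(y = y, cache = list(xhat = xhat, inv = inv, x_dim = xd))
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, cache, gy) {
  switch(layer$type,
    dense = {
      list(gx = crossprod(layer$par$w, gy),
           grads = list(w = tcrossprod(gy, cache$x), b = rowSums(gy)))
    },
    conv3 = {
      r <- conv3d_bwd(layer$par$w, cache, gy)
      list(gx = r$gx, grads = list(w = r$gw, b = r$gb))
    },
    convt3 = {
      r <- convt3d_bwd(layer$par$w, cache, gy)
      list(gx = r$gx, grads = list(w = r$gw, b = r$gb))
    },
    pool = {
      list(gx = maxpool3d_bwd_cpp(gy, cache$idx, as.integer(cache$x_dim)),
           grads = NULL)
    },
    lrelu = {
      gx <- gy
      gx[cache$neg] <- layer$slope * gy[cache$neg]
      list(gx = gx, grads = NULL)
    },
    tanh = {
      list(gx = gy * (1 - cache$y^2), grads = NULL)
    },
    dropout = {
      if (is.null(cache$keep)) return(list(gx = gy, grads = NULL))
      gx <- gy * cache$keep / (1 - layer$p)
      dim(gx) <- dim(gy)
      list(gx = gx, grads = NULL)
    },
    flatten = {
      gx <- gy
      dim(gx) <- cache$x_dim
      list(gx = gx, grads = NULL)
    },
    reshape = {
      gx <- gy
      dim(gx) <- cache$x_dim
      list(gx = gx, grads = NULL)
    },
    instnorm = {
      xd <- cache$x_dim
      s <- prod(xd[1:3]); cc <- xd[4]; n <- xd[5]
      gym <- matrix(gy, s, cc * n)
      g <- rep(layer$par$gamma, n)
      gxhat <- sweep(gym, 2L, g, `*`)
      mh <- colMeans(gxhat)
      mhx <- colMeans(gxhat * cache$xhat)
      gx <- sweep(gxhat - rep(mh, each = s) - sweep(cache$xhat, 2L, mhx, `*`),
                  2L, cache$inv, `*`)
      dim(gx) <- xd
      ggamma <- rowSums(matrix(colSums(gym * cache$xhat), cc))
      gbeta <- rowSums(matrix(colSums(gym), cc))
      list(gx = gx, grads = list(gamma = ggamma, beta = gbeta))
    },
    stop("unknown layer type: ", layer$type)
  )
}

nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    r <- layer_forward(net$layers[[i]], x, training = training)
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(y = x, caches = caches)
}

nn_backward <- function(net, caches, gy, skip_input_grad = FALSE) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    if (skip_input_grad && i == 1L) {
      r <- layer_backward_par(net$layers[[i]], caches[[i]], gy)
      grads[i] <- list(r$grads)
      gy <- NULL
      break
    }
    r <- layer_backward(net$layers[[i]], caches[[i]], gy)
    gy <- r$gx
    grads[i] <- list(r$grads)
  }
  list(gx = gy, grads = grads)
}

# Parameter gradients only (no input gradient): used for the first layer of
# a network whose input requires no gradient, skipping the most expensive
# col2im / crossprod of the backward pass.
layer_backward_par <- function(layer, cache, gy) {
  switch(layer$type,
    dense = list(grads = list(w = tcrossprod(gy, cache$x), b = rowSums(gy))),
    conv3 = {
      cout <- dim(layer$par$w)[5]
      gyd <- dim(gy)
      ovox <- prod(gyd[1:3])
      gym <- matrix(aperm(array(gy, c(ovox, cout, gyd[5])), c(2L, 1L, 3L)),
                    nrow = cout)
      list(grads = list(w = array(tcrossprod(cache$cols, gym), dim(layer$par$w)),
                        b = rowSums(gym)))
    },
    layer_backward(layer, cache, gy)
  )
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(net) {
  st <- list(t = 0L, m = vector("list", length(net$layers)),
             v = vector("list", length(net$layers)))
  for (i in seq_along(net$layers)) {
    p <- net$layers[[i]]$par
    if (!is.null(p)) {
      st$m[[i]] <- lapply(p, function(a) array(0, dim(a) %||% length(a)))
      st$v[[i]] <- lapply(p, function(a) array(0, dim(a) %||% length(a)))
    }
  }
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(net, grads, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      st$m[[i]][[nm]] <- beta1 * st$m[[i]][[nm]] + (1 - beta1) * g[[nm]]
      st$v[[i]][[nm]] <- beta2 * st$v[[i]][[nm]] + (1 - beta2) * g[[nm]]^2
      upd <- (st$m[[i]][[nm]] / bc1) / (sqrt(st$v[[i]][[nm]] / bc2) + eps)
      p <- net$layers[[i]]$par[[nm]]
      new <- p - lr * as.vector(upd)
      if (!is.null(dim(p))) dim(new) <- dim(p) else new <- as.vector(new)
      net$layers[[i]]$par[[nm]] <- new
    }
  }
  list(net = net, state = st)
}

# Flatten all parameters into one numeric vector (used by tests and for
# finite-difference gradient checks).
nn_param_vector <- function(net) {
  unlist(lapply(net$layers, function(l) if (is.null(l$par)) NULL else unlist(l$par)),
         use.names = FALSE)
}
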