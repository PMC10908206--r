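# The neural-net engine is validated against finite differences: every
# layer's backward pass (input and parameter gradients) must match a
# central-difference numerical gradient on a small network.

ns <- asNamespace("radiogan")

num_grad <- function(fn, x, eps = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  array(g, dim(x) %||% length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_gradients <- function(net, x, tol = 1e-6) {
  loss_of <- function(net, x) sum(ns$nn_forward(net, x)$y^2)
  fw <- ns$nn_forward(net, x)
  bw <- ns$nn_backward(net, fw$caches, 2 * fw$y)
  gx_num <- num_grad(function(xx) loss_of(net, xx), x)
  expect_lt(max(abs(bw$gx - gx_num)) / max(1, max(abs(gx_num))), tol)
  for (li in seq_along(net$layers)) {
    p <- net$layers[[li]]$par
    if (is.null(p)) next
    for (nm in names(p)) {
      gn <- num_grad(function(v) {
        n2 <- net
        n2$layers[[li]]$par[[nm]] <-
          if (is.null(dim(p[[nm]]))) as.numeric(v) else array(v, dim(p[[nm]]))
        loss_of(n2, x)
      }, p[[nm]])
      ga <- bw$grads[[li]][[nm]]
      expect_lt(max(abs(ga - gn)) / max(1, max(abs(gn))), tol)
    }
  }
}

test_that("conv / pool / dense backward passes match finite differences", {
  set.seed(42)
  net <- structure(list(layers = list(
    ns$nn_conv3(2L, 3L, k = 4L, stride = 2L, pad = 1L),
    ns$nn_lrelu(0.2),
    ns$nn_conv3(3L, 2L, k = 3L, stride = 1L, pad = 1L),
    ns$nn_relu(),
    ns$nn_pool(2L),
    ns$nn_flatten(),
    ns$nn_dense(16L, 1L)
  )), class = "cgan_net")
  x <- array(rnorm(8 * 8 * 8 * 2 * 2), c(8, 8, 8, 2, 2))
  check_gradients(net, x)
})

test_that("transposed conv, instance norm and tanh gradients match finite differences", {
  set.seed(43)
  net <- structure(list(layers = list(
    ns$nn_dense(5L, 1 * 2 * 2 * 4),
    ns$nn_reshape(c(1L, 2L, 2L, 4L)),
    ns$nn_lrelu(0.2),
    ns$nn_convt3(4L, 3L),
    ns$nn_instnorm(3L),
    ns$nn_lrelu(0.2),
    ns$nn_convt3(3L, 1L, k = 2L, stride = 2L, pad = 0L),
    ns$nn_tanh()
  )), class = "cgan_net")
  x <- matrix(rnorm(5 * 3), 5, 3)
  check_gradients(net, x)
})

test_that("cached gather/scatter conv path agrees with the direct im2col kernels", {
  set.seed(44)
  x <- array(rnorm(6 * 8 * 10 * 3 * 2), c(6, 8, 10, 3, 2))
  for (cfg in list(c(k = 3, s = 1, p = 1), c(k = 4, s = 2, p = 1),
                   c(k = 2, s = 2, p = 0))) {
    cols_direct <- ns$im2col3d_cpp(x, dim(x), rep(cfg[["k"]], 3),
                                   cfg[["s"]], cfg[["p"]])
    idx <- ns$im2col_idx_cpp(dim(x)[1:4], rep(cfg[["k"]], 3L),
                             cfg[["s"]], cfg[["p"]])
    cols_cached <- ns$gather_cols_cpp(x, idx, dim(x),
                                      as.integer(cfg[["k"]]^3 * 3))
    expect_identical(dim(cols_direct), dim(cols_cached))
    expect_equal(cols_cached, cols_direct, tolerance = 0)
    # scatter is the exact adjoint of gather: <gather(x), M> == <x, scatter(M)>
    M <- matrix(rnorm(length(cols_direct)), nrow(cols_direct))
    lhs <- sum(cols_cached * M)
    rhs <- sum(x * ns$scatter_cols_cpp(M, idx, dim(x),
                                       as.integer(cfg[["k"]]^3 * 3)))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("max pooling forward picks window maxima and backward routes to argmax", {
  x <- array(0, c(4, 4, 4, 1, 1))
  x[2, 1, 1, 1, 1] <- 5
  x[3, 3, 3, 1, 1] <- -1
  r <- ns$maxpool3d_fwd_cpp(x, dim(x), 2L)
  expect_equal(dim(r$y), c(2L, 2L, 2L, 1L, 1L))
  expect_equal(r$y[1, 1, 1, 1, 1], 5)
  gx <- ns$maxpool3d_bwd_cpp(array(1, dim(r$y)), r$idx, dim(x))
  expect_equal(sum(gx), 8)           # one unit per pooled cell
  expect_equal(gx[2, 1, 1, 1, 1], 1) # routed to the argmax voxel
})

test_that("Adam updates are deterministic and reduce a quadratic loss", {
  run <- function() {
    set.seed(7)
    net <- structure(list(layers = list(ns$nn_dense(4L, 1L))),
                     class = "cgan_net")
    st <- ns$adam_init(net)
    x <- matrix(rnorm(4 * 16), 4, 16)
    target <- matrix(colSums(x * c(1, -2, 0.5, 3)), 1)
    losses <- numeric(300)
    for (it in 1:300) {
      fw <- ns$nn_forward(net, x)
      resid <- fw$y - target
      losses[it] <- mean(resid^2)
      bw <- ns$nn_backward(net, fw$caches, 2 * resid / length(resid))
      upd <- ns$adam_step(net, bw$grads, st, 0.05)
      net <- upd$net; st <- upd$state
    }
    losses
  }
  l1 <- run(); l2 <- run()
  expect_identical(l1, l2)
  expect_lt(l1[300], l1[1] / 10)
})
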