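# Finite-difference checks for every autograd primitive. Each op is probed at
# a handful of random coordinates; central differences with eps = 1e-5 should
# agree with the analytic gradient to ~1e-7 for smooth ops.

# scalar head: <node, r> so any op output can be reduced to a scalar root
ag_dot <- function(node, r) {
  msynth:::ag_node(sum(node$value * r), list(node), function(g) list(g * r))
}

grad_of <- function(build, x) {
  # build(xnode) must return the op output node; returns list(val, grad) wrt x
  xn <- msynth:::ag_param(x)
  out <- build(xn)
  msynth:::ag_backward(out)
  list(val = out$value, grad = xn$grad)
}

test_that("conv3d gradients (k = 3, 2, 1; strides 1 and 2) pass FD checks", {
  set.seed(10)
  x <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2, 1))
  r <- NULL
  for (cfg in list(list(k = 3L, s = 1L, co = 3L),
                   list(k = 2L, s = 2L, co = 2L),
                   list(k = 1L, s = 1L, co = 2L))) {
    w <- matrix(rnorm(cfg$k^3 * 2 * cfg$co, sd = 0.3), cfg$k^3 * 2, cfg$co)
    b <- rnorm(cfg$co, sd = 0.1)
    mk <- function(xx, ww, bb) {
      out <- msynth:::ag_conv3d(msynth:::ag_param(xx), msynth:::ag_param(ww),
                                msynth:::ag_param(bb), cfg$k, cfg$s)
      if (is.null(r)) r <<- array(rnorm(length(out$value)), dim(out$value))
      list(out = out, x = out$parents[[1]], w = out$parents[[2]],
           b = out$parents[[3]])
    }
    fx <- function(xx) {
      g <- mk(xx, w, b); msynth:::ag_backward(ag_dot(g$out, r))
      list(val = sum(g$out$value * r), grad = g$x$grad)
    }
    fw <- function(ww) {
      g <- mk(x, ww, b); msynth:::ag_backward(ag_dot(g$out, r))
      list(val = sum(g$out$value * r), grad = g$w$grad)
    }
    fb <- function(bb) {
      g <- mk(x, w, bb); msynth:::ag_backward(ag_dot(g$out, r))
      list(val = sum(g$out$value * r), grad = g$b$grad)
    }
    expect_lt(fd_check(fx, x), 1e-6)
    expect_lt(fd_check(fw, w), 1e-6)
    expect_lt(fd_check(fb, b), 1e-6)
    r <- NULL
  }
})

test_that("pointwise ops, pooling and upsampling pass FD checks", {
  set.seed(11)
  x <- array(rnorm(4 * 4 * 4 * 2 * 2), c(4, 4, 4, 2, 2))
  x <- x + sign(x) * 0.2 # keep values away from the ReLU kink
  for (op in list(msynth:::ag_relu, msynth:::ag_sigmoid,
                  msynth:::ag_avgpool2, msynth:::ag_upsample2)) {
    out0 <- op(msynth:::ag_param(x))
    r <- array(rnorm(length(out0$value)), dim(out0$value))
    f <- function(xx) grad_of(function(xn) ag_dot(op(xn), r), xx)
    expect_lt(fd_check(f, x), 1e-6)
  }
})

test_that("batch normalization gradients (x, gamma, beta) pass FD checks", {
  set.seed(12)
  x <- array(rnorm(4 * 4 * 4 * 3 * 2), c(4, 4, 4, 3, 2))
  gamma <- runif(3, 0.5, 1.5); beta <- rnorm(3, sd = 0.2)
  r <- array(rnorm(length(x)), dim(x))
  run <- function(xx, gg, bb) {
    st <- new.env(); st$rmean <- numeric(3); st$rvar <- rep(1, 3)
    xn <- msynth:::ag_param(xx)
    gn <- msynth:::ag_param(gg); bn <- msynth:::ag_param(bb)
    out <- msynth:::ag_bn(xn, gn, bn, st, training = TRUE)
    msynth:::ag_backward(ag_dot(out, r))
    list(val = sum(out$value * r), x = xn, g = gn, b = bn)
  }
  expect_lt(fd_check(function(v) { z <- run(v, gamma, beta)
    list(val = z$val, grad = z$x$grad) }, x), 1e-5)
  expect_lt(fd_check(function(v) { z <- run(x, v, beta)
    list(val = z$val, grad = z$g$grad) }, gamma), 1e-5)
  expect_lt(fd_check(function(v) { z <- run(x, gamma, v)
    list(val = z$val, grad = z$b$grad) }, beta), 1e-5)
  # inference mode uses the running statistics, not the batch
  st <- new.env(); st$rmean <- rep(0.3, 3); st$rvar <- rep(0.8, 3)
  out <- msynth:::ag_bn(msynth:::ag_param(x), msynth:::ag_param(gamma),
                        msynth:::ag_param(beta), st, training = FALSE)
  xhat <- (x - 0.3) / sqrt(0.8 + 1e-5)
  manual <- sweep(sweep(xhat, 4, gamma, `*`), 4, beta, `+`)
  expect_equal(out$value, manual, tolerance = 1e-12)
})

test_that("concat, GAP and linear head gradients pass FD checks", {
  set.seed(13)
  a <- array(rnorm(4^3 * 2 * 2), c(4, 4, 4, 2, 2))
  b <- array(rnorm(4^3 * 3 * 2), c(4, 4, 4, 3, 2))
  cat0 <- msynth:::ag_concat(list(msynth:::ag_param(a), msynth:::ag_param(b)))
  expect_equal(dim(cat0$value), c(4, 4, 4, 5, 2))
  expect_equal(cat0$value[, , , 1:2, ], a)
  expect_equal(cat0$value[, , , 3:5, ], b)
  r <- array(rnorm(length(cat0$value)), dim(cat0$value))
  fa <- function(v) {
    an <- msynth:::ag_param(v)
    out <- msynth:::ag_concat(list(an, msynth:::ag_const(b)))
    msynth:::ag_backward(ag_dot(out, r))
    list(val = sum(out$value * r), grad = an$grad)
  }
  expect_lt(fd_check(fa, a), 1e-6)
  # GAP -> linear -> scalar
  W <- matrix(rnorm(2 * 2, sd = 0.4), 2, 2); bb <- rnorm(2, sd = 0.1)
  rr <- matrix(rnorm(4), 2, 2)
  fg <- function(v) {
    xn <- msynth:::ag_param(v)
    out <- msynth:::ag_linear(msynth:::ag_gap(xn), W, bb)
    msynth:::ag_backward(ag_dot(out, rr))
    list(val = sum(out$value * rr), grad = xn$grad)
  }
  expect_lt(fd_check(fg, a), 1e-6)
})

test_that("loss gradients (L1, MSE, BCE, weighted softmax CE) pass FD checks", {
  set.seed(14)
  d <- c(4, 4, 4, 1, 2)
  pred <- array(rnorm(prod(d)), d)
  target <- array(rnorm(prod(d)), d)
  pred <- target + sign(pred - target) * 0.3 + (pred - target) # off the L1 kink
  mask <- array(rbinom(prod(d), 1, 0.7), d)
  f1 <- function(v) grad_of(function(xn)
    msynth:::ag_l1_masked(xn, target, mask), v)
  expect_lt(fd_check(f1, pred), 1e-6)
  f2 <- function(v) grad_of(function(xn)
    msynth:::ag_mse_masked(xn, target, mask), v)
  expect_lt(fd_check(f2, pred), 1e-6)
  z <- array(rnorm(8), c(8, 1))
  t01 <- runif(8)
  f3 <- function(v) grad_of(function(xn) msynth:::ag_bce_logits(xn, t01), v)
  expect_lt(fd_check(f3, z), 1e-6)
  zl <- array(rnorm(prod(c(4, 4, 4, 2, 2))), c(4, 4, 4, 2, 2))
  y <- array(rbinom(4^3 * 2, 1, 0.2), c(4, 4, 4, 1, 2))
  for (pw in c(1, 5)) {
    f4 <- function(v) grad_of(function(xn)
      msynth:::ag_softmax_ce2(xn, y, pos_weight = pw), v)
    expect_lt(fd_check(f4, zl), 1e-6)
  }
})

test_that("smoothness penalty: FD check and closed form for a linear field", {
  set.seed(15)
  disp <- array(rnorm(6^3 * 3, sd = 0.5), c(6, 6, 6, 3, 1))
  f <- function(v) grad_of(function(xn) msynth:::ag_smoothness(xn), v)
  expect_lt(fd_check(f, disp), 1e-6)
  # linear field d_i = alpha * coord_i scores exactly 3 * alpha^2
  alpha <- 0.3
  lin <- array(0, c(6, 6, 6, 3, 1))
  for (i in 1:6) { lin[i, , , 1, 1] <- alpha * i
                   lin[, i, , 2, 1] <- alpha * i
                   lin[, , i, 3, 1] <- alpha * i }
  v <- msynth:::ag_smoothness(msynth:::ag_const(lin))$value
  expect_equal(v, 3 * alpha^2, tolerance = 1e-12)
})

test_that("warp gradient w.r.t. the displacement passes FD checks", {
  set.seed(16)
  vol <- array(0, c(6, 6, 6, 1, 1))
  # smooth volume so trilinear interpolation is differentiable almost everywhere
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    vol[i, j, k, 1, 1] <- sin(i / 2) * cos(j / 3) + 0.2 * k
  disp <- array(runif(6^3 * 3, -0.3, 0.3) + 0.1, c(6, 6, 6, 3, 1))
  out0 <- msynth:::ag_warp_batch(vol, msynth:::ag_param(disp))
  r <- array(rnorm(length(out0$value)), dim(out0$value))
  f <- function(v) {
    dn <- msynth:::ag_param(v)
    out <- msynth:::ag_warp_batch(vol, dn)
    msynth:::ag_backward(ag_dot(out, r))
    list(val = sum(out$value * r), grad = dn$grad)
  }
  expect_lt(fd_check(f, disp, eps = 1e-6), 1e-4)
})

test_that("gradients accumulate across fan-out and sums", {
  x <- msynth:::ag_param(array(2, c(1, 1, 1, 1, 1)))
  y <- msynth:::ag_add(x, x)
  root <- msynth:::ag_node(sum(y$value), list(y), function(g) list(array(g, dim(y$value))))
  msynth:::ag_backward(root)
  expect_equal(as.vector(x$grad), 2)
  a <- msynth:::ag_node(1); b <- msynth:::ag_node(2)
  s <- msynth:::ag_sum(list(a, b, a))
  expect_equal(s$value, 4)
  msynth:::ag_backward(s)
  expect_equal(a$grad, 2)
  expect_equal(b$grad, 1)
  # constants absorb no gradient
  cns <- msynth:::ag_const(array(1, c(1, 1, 1, 1, 1)))
  z <- msynth:::ag_add(cns, x)
  msynth:::ag_backward(msynth:::ag_node(sum(z$value), list(z),
                                        function(g) list(array(g, dim(z$value)))))
  expect_null(cns$grad)
})
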