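# Minimal reverse-mode automatic differentiation over dense arrays.
#
# Feature maps are 5D arrays (D, H, W, C, N); graph nodes are environments
# holding a value, an accumulated gradient, parent links, and a backward
# closure. Only the operations the synthesis/detection networks need are
# implemented, and each has a finite-difference test.

ag_env <- new.env(parent = emptyenv())
ag_env$next_id <- 1L

ag_node <- function(value, parents = list(), bfn = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$bfn <- bfn
  e$id <- ag_env$next_id
  ag_env$next_id <- ag_env$next_id + 1L
  class(e) <- "ag_node"
  e
}

ag_param <- function(value) ag_node(value)
ag_const <- function(value) {
  n <- ag_node(value)
  n$is_const <- TRUE
  n
}

as_node <- function(x) if (inherits(x, "ag_node")) x else ag_const(x)

acc_grad <- function(node, g) {
  if (isTRUE(node$is_const)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# reverse-topological traversal from a scalar root
ag_backward <- function(root, seed_grad = 1) {
  order <- list(); mark <- new.env(parent = emptyenv())
  stack <- list(list(node = root, phase = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- top$node
    key <- as.character(nd$id)
    if (top$phase == 1L) {
      if (!is.null(mark[[key]])) next
      mark[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = nd, phase = 2L)
      for (p in nd$parents)
        if (is.null(mark[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, phase = 1L)
    } else {
      order[[length(order) + 1L]] <- nd
    }
  }
  root$grad <- seed_grad
  for (i in rev(seq_along(order))) {
    nd <- order[[i]]
    if (is.null(nd$bfn) || is.null(nd$grad)) next
    gs <- nd$bfn(nd$grad)
    for (j in seq_along(nd$parents))
      if (!is.null(gs[[j]])) acc_grad(nd$parents[[j]], gs[[j]])
  }
  invisible(root)
}

# ---- primitive operations ---------------------------------------------------

ag_conv3d <- function(x, w, b, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  x <- as_node(x); w <- as_node(w); b <- as_node(b)
  val <- cpp_conv3d(x$value, w$value, b$value, k, stride, pad)
  ag_node(val, list(x, w, b), function(g) {
    r <- cpp_conv3d_bwd(x$value, w$value, g, k, stride, pad)
    list(r$gx, r$gw, r$gb)
  })
}

ag_relu <- function(x) {
  v <- x$value
  v[v < 0] <- 0
  pos <- x$value > 0
  ag_node(v, list(x), function(g) list(g * pos))
}

ag_sigmoid <- function(x) {
  v <- 1 / (1 + exp(-x$value))
  ag_node(v, list(x), function(g) list(g * v * (1 - v)))
}

ag_add <- function(a, b) {
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_upsample2 <- function(x) {
  ag_node(cpp_upsample2(x$value), list(x), function(g) list(cpp_upsample2_bwd(g)))
}

ag_avgpool2 <- function(x) {
  xd <- dim(x$value)
  ag_node(cpp_avgpool2(x$value), list(x),
          function(g) list(cpp_avgpool2_bwd(g, as.integer(xd))))
}

# concatenate along the channel axis (4th)
ag_concat <- function(nodes) {
  vals <- lapply(nodes, function(n) n$value)
  d1 <- dim(vals[[1]])
  cs <- vapply(vals, function(v) dim(v)[4], numeric(1))
  out <- array(0, c(d1[1:3], sum(cs), d1[5]))
  at <- 0
  for (v in vals) {
    cc <- dim(v)[4]
    out[, , , at + seq_len(cc), ] <- v
    at <- at + cc
  }
  ag_node(out, nodes, function(g) {
    at <- 0
    lapply(cs, function(cc) {
      sl <- g[, , , at + seq_len(cc), , drop = FALSE]
      at <<- at + cc
      sl
    })
  })
}

# batch normalization; `state` is an env with rmean/rvar updated by side effect
ag_bn <- function(x, gamma, beta, state, training = TRUE,
                  momentum = 0.1, eps = 1e-5) {
  gamma <- as_node(gamma); beta <- as_node(beta)
  xd <- dim(x$value)
  V <- prod(xd[1:3]); C <- xd[4]; N <- xd[5]
  expand <- function(v) rep(rep(v, each = V), times = N)
  if (training) {
    cm <- .colMeans(x$value, V, C * N)
    mu <- rowMeans(matrix(cm, C, N))
    cm2 <- .colMeans(x$value^2, V, C * N)
    ex2 <- rowMeans(matrix(cm2, C, N))
    vr <- pmax(ex2 - mu^2, 0)
    state$rmean <- (1 - momentum) * state$rmean + momentum * mu
    state$rvar <- (1 - momentum) * state$rvar + momentum * vr
  } else {
    mu <- state$rmean; vr <- state$rvar
  }
  istd <- 1 / sqrt(vr + eps)
  xhat <- (x$value - expand(mu)) * expand(istd)
  val <- xhat * expand(gamma$value) + expand(beta$value)
  dim(val) <- xd
  ag_node(val, list(x, gamma, beta), function(g) {
    gg <- rowMeans(matrix(.colMeans(g * xhat, V, C * N), C, N)) * V * N
    gb <- rowMeans(matrix(.colMeans(g, V, C * N), C, N)) * V * N
    if (training) {
      mg <- gb / (V * N)
      mgx <- gg / (V * N)
      gx <- expand(gamma$value * istd) * (g - expand(mg) - xhat * expand(mgx))
    } else {
      gx <- expand(gamma$value * istd) * g
    }
    dim(gx) <- xd
    list(gx, gg, gb)
  })
}

# global average pooling over spatial dims -> (C, N) matrix
ag_gap <- function(x) {
  xd <- dim(x$value)
  V <- prod(xd[1:3]); C <- xd[4]; N <- xd[5]
  val <- matrix(.colMeans(x$value, V, C * N), C, N)
  ag_node(val, list(x), function(g) {
    gx <- array(rep(as.vector(g), each = V) / V, xd)
    list(gx)
  })
}

# dense layer on (C, N) matrices: W (Cout x Cin), b (Cout)
ag_linear <- function(x, w, b) {
  w <- as_node(w); b <- as_node(b)
  val <- w$value %*% x$value + b$value
  ag_node(val, list(x, w, b), function(g) {
    list(t(w$value) %*% g, g %*% t(x$value), rowSums(g))
  })
}

# warp each batch item of `vol` (plain array (D,H,W,1,N)) by the displacement
# node (D,H,W,3,N); gradient flows to the displacement only
ag_warp_batch <- function(vol, disp) {
  vd <- dim(vol)
  N <- vd[5]
  dd <- vd[1:3]
  val <- array(0, vd)
  for (n in seq_len(N)) {
    v3 <- array(vol[, , , 1, n], dd)
    f3 <- array(disp$value[, , , , n], c(dd, 3))
    val[, , , 1, n] <- cpp_warp(v3, f3)
  }
  ag_node(val, list(disp), function(g) {
    gd <- array(0, dim(disp$value))
    for (n in seq_len(N)) {
      v3 <- array(vol[, , , 1, n], dd)
      f3 <- array(disp$value[, , , , n], c(dd, 3))
      g3 <- array(g[, , , 1, n], dd)
      gd[, , , , n] <- cpp_warp_bwd(v3, f3, g3)
    }
    list(gd)
  })
}

# ---- scalar losses ----------------------------------------------------------

ag_l1_masked <- function(pred, target, mask) {
  m <- as.numeric(sum(mask))
  if (m == 0) stop("empty mask in L1 loss")
  diff <- (pred$value - target) * mask
  val <- sum(abs(diff)) / m
  ag_node(val, list(pred), function(g) list(g * sign(diff) * mask / m))
}

ag_mse_masked <- function(pred, target, mask) {
  m <- as.numeric(sum(mask))
  if (m == 0) stop("empty mask in MSE loss")
  diff <- (pred$value - target) * mask
  val <- sum(diff^2) / m
  ag_node(val, list(pred), function(g) list(g * 2 * diff / m))
}

# mean binary cross-entropy with logits; targets in [0,1]
ag_bce_logits <- function(logits, targets) {
  z <- logits$value
  n <- length(z)
  p <- 1 / (1 + exp(-z))
  val <- mean(ifelse(z > 0, z - z * targets + log1p(exp(-z)),
                     -z * targets + log1p(exp(z))))
  ag_node(val, list(logits), function(g) list(g * (p - targets) / n))
}

# two-class softmax cross-entropy on (D,H,W,2,N) logits vs binary target
# (D,H,W,1,N); positive class weighted by `pos_weight`
ag_softmax_ce2 <- function(logits, target, pos_weight = 1) {
  z <- logits$value
  xd <- dim(z)
  z0 <- z[, , , 1, , drop = FALSE]
  z1 <- z[, , , 2, , drop = FALSE]
  dz <- z1 - z0
  p1 <- 1 / (1 + exp(-dz))
  y <- target
  w <- 1 + (pos_weight - 1) * y
  sw <- sum(w)
  # -log p_y, numerically stable
  nlp <- ifelse(y > 0.5,
                ifelse(dz > 0, log1p(exp(-dz)), -dz + log1p(exp(dz))),
                ifelse(dz > 0, dz + log1p(exp(-dz)), log1p(exp(dz))))
  val <- sum(w * nlp) / sw
  ag_node(val, list(logits), function(g) {
    gd <- g * w * (p1 - y) / sw
    gz <- array(0, xd)
    gz[, , , 1, ] <- -gd
    gz[, , , 2, ] <- gd
    list(gz)
  })
}

# displacement smoothness: sum over channels and axes of the per-channel mean
# squared forward difference (a linear field d_i = alpha * coord_i scores
# 3 * alpha^2); input (D,H,W,3,N)
ag_smoothness <- function(disp) {
  dv <- disp$value
  xd <- dim(dv)
  slice <- function(ax, hi) {
    idx <- lapply(xd, seq_len)
    idx[[ax]] <- if (hi) 2:xd[ax] else 1:(xd[ax] - 1)
    do.call(`[`, c(list(dv), idx, list(drop = FALSE)))
  }
  difs <- vector("list", 3)
  denoms <- numeric(3)
  total <- 0
  for (ax in 1:3) {
    dif <- slice(ax, TRUE) - slice(ax, FALSE)
    denoms[ax] <- length(dif) / xd[4]   # spatial diff count x batch, per channel
    difs[[ax]] <- dif
    total <- total + sum(dif^2) / denoms[ax]
  }
  ag_node(total, list(disp), function(g) {
    gd <- array(0, xd)
    for (ax in 1:3) {
      idx_hi <- lapply(xd, seq_len); idx_hi[[ax]] <- 2:xd[ax]
      idx_lo <- lapply(xd, seq_len); idx_lo[[ax]] <- 1:(xd[ax] - 1)
      contrib <- g * 2 * difs[[ax]] / denoms[ax]
      ghi <- do.call(`[`, c(list(gd), idx_hi, list(drop = FALSE))) + contrib
      gd <- do.call(`[<-`, c(list(gd), idx_hi, list(ghi)))
      glo <- do.call(`[`, c(list(gd), idx_lo, list(drop = FALSE))) - contrib
      gd <- do.call(`[<-`, c(list(gd), idx_lo, list(glo)))
    }
    list(gd)
  })
}

ag_scale <- function(x, s) {
  ag_node(x$value * s, list(x), function(g) list(g * s))
}

ag_sum <- function(nodes) {
  val <- sum(vapply(nodes, function(n) n$value, numeric(1)))
  ag_node(val, nodes, function(g) rep(list(g), length(nodes)))
}
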