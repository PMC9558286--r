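# Network construction: parameter initialisation, residual blocks, the
# synthesis generator/discriminator and the generic 3D U-Net used by the
# detector. Parameters live in flat named lists of arrays; every forward pass
# wraps them in autograd nodes.

he_conv <- function(k, cin, cout, zero = FALSE) {
  n <- k^3 * cin
  w <- if (zero) matrix(0, n, cout)
       else matrix(rnorm(n * cout, sd = sqrt(2 / n)), n, cout)
  list(w = w, b = numeric(cout))
}

new_bn_state <- function(C) {
  e <- new.env(parent = emptyenv())
  e$rmean <- numeric(C)
  e$rvar <- rep(1, C)
  e
}

# parameter/bn-state registry built during init
net_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$params <- list()
  env$bn <- list()
  env$add_conv <- function(name, k, cin, cout, zero = FALSE) {
    p <- he_conv(k, cin, cout, zero)
    env$params[[paste0(name, ".w")]] <- p$w
    env$params[[paste0(name, ".b")]] <- p$b
  }
  env$add_bn <- function(name, C) {
    env$params[[paste0(name, ".g")]] <- rep(1, C)
    env$params[[paste0(name, ".be")]] <- numeric(C)
    env$bn[[name]] <- new_bn_state(C)
  }
  env$add_linear <- function(name, cin, cout) {
    env$params[[paste0(name, ".w")]] <- matrix(rnorm(cin * cout, sd = sqrt(1 / cin)), cout, cin)
    env$params[[paste0(name, ".b")]] <- numeric(cout)
  }
  env
}

add_resblock_params <- function(bld, pfx, cin, cout) {
  bld$add_conv(paste0(pfx, ".c1"), 3L, cin, cout)
  bld$add_bn(paste0(pfx, ".bn1"), cout)
  bld$add_conv(paste0(pfx, ".c2"), 3L, cout, cout)
  bld$add_bn(paste0(pfx, ".bn2"), cout)
  if (cin != cout) bld$add_conv(paste0(pfx, ".proj"), 1L, cin, cout)
}

# two 3x3x3 convs + batch norm each, summed identity/projection shortcut
resblock_fwd <- function(pn, bn, pfx, x, training) {
  h <- ag_conv3d(x, pn[[paste0(pfx, ".c1.w")]], pn[[paste0(pfx, ".c1.b")]], 3L)
  h <- ag_bn(h, pn[[paste0(pfx, ".bn1.g")]], pn[[paste0(pfx, ".bn1.be")]],
             bn[[paste0(pfx, ".bn1")]], training)
  h <- ag_relu(h)
  h <- ag_conv3d(h, pn[[paste0(pfx, ".c2.w")]], pn[[paste0(pfx, ".c2.b")]], 3L)
  h <- ag_bn(h, pn[[paste0(pfx, ".bn2.g")]], pn[[paste0(pfx, ".bn2.be")]],
             bn[[paste0(pfx, ".bn2")]], training)
  sc <- if (!is.null(pn[[paste0(pfx, ".proj.w")]])) {
    ag_conv3d(x, pn[[paste0(pfx, ".proj.w")]], pn[[paste0(pfx, ".proj.b")]], 1L, pad = 0L)
  } else x
  ag_relu(ag_add(h, sc))
}

# ---- generator: 4 encoder + 4 decoder residual blocks, summation skips ------

generator_init <- function(c, width, seed) {
  with_seed(seed, {
    b <- net_builder()
    w <- width
    add_resblock_params(b, "enc1", c, w)
    b$add_conv("down1", 2L, w, 2 * w)
    add_resblock_params(b, "enc2", 2 * w, 2 * w)
    b$add_conv("down2", 2L, 2 * w, 4 * w)
    add_resblock_params(b, "enc3", 4 * w, 4 * w)
    b$add_conv("down3", 2L, 4 * w, 8 * w)
    add_resblock_params(b, "enc4", 8 * w, 8 * w)
    b$add_conv("up3", 1L, 8 * w, 4 * w)
    add_resblock_params(b, "dec3", 4 * w, 4 * w)
    b$add_conv("up2", 1L, 4 * w, 2 * w)
    add_resblock_params(b, "dec2", 2 * w, 2 * w)
    b$add_conv("up1", 1L, 2 * w, w)
    add_resblock_params(b, "dec1", w, w)
    b$add_conv("out", 3L, w, 1L)
    list(params = b$params, bn = b$bn, c = c, width = width)
  })
}

generator_fwd <- function(net, pn, x, training) {
  bn <- net$bn
  cv <- function(nm, z, k, stride = 1L, pad = (k - 1L) %/% 2L)
    ag_conv3d(z, pn[[paste0(nm, ".w")]], pn[[paste0(nm, ".b")]], k, stride, pad)
  e1 <- resblock_fwd(pn, bn, "enc1", x, training)
  e2 <- resblock_fwd(pn, bn, "enc2", cv("down1", e1, 2L, 2L, 0L), training)
  e3 <- resblock_fwd(pn, bn, "enc3", cv("down2", e2, 2L, 2L, 0L), training)
  e4 <- resblock_fwd(pn, bn, "enc4", cv("down3", e3, 2L, 2L, 0L), training)
  d3 <- resblock_fwd(pn, bn, "dec3",
                     ag_add(cv("up3", ag_upsample2(e4), 1L, 1L, 0L), e3), training)
  d2 <- resblock_fwd(pn, bn, "dec2",
                     ag_add(cv("up2", ag_upsample2(d3), 1L, 1L, 0L), e2), training)
  d1 <- resblock_fwd(pn, bn, "dec1",
                     ag_add(cv("up1", ag_upsample2(d2), 1L, 1L, 0L), e1), training)
  ag_sigmoid(cv("out", d1, 3L))
}

# ---- discriminator: 4 residual blocks, each followed by pooling -------------

discriminator_init <- function(width, seed) {
  with_seed(seed, {
    b <- net_builder()
    w <- width
    add_resblock_params(b, "rb1", 1L, w)
    add_resblock_params(b, "rb2", w, 2 * w)
    add_resblock_params(b, "rb3", 2 * w, 4 * w)
    add_resblock_params(b, "rb4", 4 * w, 8 * w)
    b$add_linear("head", 8L * w, 1L)
    list(params = b$params, bn = b$bn, width = width)
  })
}

discriminator_fwd <- function(net, pn, x, training) {
  bn <- net$bn
  h <- ag_avgpool2(resblock_fwd(pn, bn, "rb1", x, training))
  h <- ag_avgpool2(resblock_fwd(pn, bn, "rb2", h, training))
  h <- ag_avgpool2(resblock_fwd(pn, bn, "rb3", h, training))
  h <- ag_avgpool2(resblock_fwd(pn, bn, "rb4", h, training))
  ag_linear(ag_gap(h), pn[["head.w"]], pn[["head.b"]])
}

# ---- generic 3D U-Net (registration / segmentation sub-networks) ------------

unet_init <- function(in_ch, out_ch, width, depth, seed, zero_final = FALSE) {
  with_seed(seed, {
    b <- net_builder()
    ws <- width * 2^(0:(depth - 1))
    add_resblock_params(b, "enc1", in_ch, ws[1])
    if (depth > 1) {
      for (l in 2:depth) {
        b$add_conv(paste0("down", l - 1), 2L, ws[l - 1], ws[l])
        add_resblock_params(b, paste0("enc", l), ws[l], ws[l])
      }
      for (l in (depth - 1):1) {
        b$add_conv(paste0("up", l), 1L, ws[l + 1], ws[l])
        add_resblock_params(b, paste0("dec", l), ws[l], ws[l])
      }
    }
    b$add_conv("out", 3L, ws[1], out_ch, zero = zero_final)
    list(params = b$params, bn = b$bn, in_ch = in_ch, out_ch = out_ch,
         width = width, depth = depth)
  })
}

unet_fwd <- function(net, pn, x, training) {
  bn <- net$bn
  cv <- function(nm, z, k, stride = 1L, pad = (k - 1L) %/% 2L)
    ag_conv3d(z, pn[[paste0(nm, ".w")]], pn[[paste0(nm, ".b")]], k, stride, pad)
  depth <- net$depth
  skips <- vector("list", depth)
  h <- resblock_fwd(pn, bn, "enc1", x, training)
  skips[[1]] <- h
  if (depth > 1) {
    for (l in 2:depth) {
      h <- cv(paste0("down", l - 1), h, 2L, 2L, 0L)
      h <- resblock_fwd(pn, bn, paste0("enc", l), h, training)
      skips[[l]] <- h
    }
    for (l in (depth - 1):1) {
      h <- ag_add(cv(paste0("up", l), ag_upsample2(h), 1L, 1L, 0L), skips[[l]])
      h <- resblock_fwd(pn, bn, paste0("dec", l), h, training)
    }
  }
  cv("out", h, 3L)
}

# ---- Adam -------------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  b1t <- 1 - beta1^st$t
  b2t <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    mh <- st$m[[nm]] / b1t
    vh <- st$v[[nm]] / b2t
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = st)
}

# run one forward+backward and return grads keyed like params
wrap_params <- function(params) lapply(params, ag_param)
collect_grads <- function(pnodes) lapply(pnodes, function(n) n$grad)
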