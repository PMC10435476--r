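# Minimal single-sample conv-net engine: forward and hand-derived backward
# passes for the handful of layer types the translation networks need.
# Tensors are (H, W, C) arrays; batch size is 1 (instance-norm training
# convention), which keeps every pass a plain array-in/array-out function.

WEIGHT_INIT_SD <- 0.02

new_conv <- function(cin, cout, k, s = 1L, p = 0L) {
  list(type = "conv", k = as.integer(k), s = as.integer(s),
       p = as.integer(p), cin = cin, cout = cout,
       W = matrix(rnorm(k * k * cin * cout, 0, WEIGHT_INIT_SD),
                  k * k * cin, cout),
       b = numeric(cout))
}

new_convt <- function(cin, cout, k, s = 2L, p = 1L, op = 1L) {
  list(type = "convt", k = as.integer(k), s = as.integer(s),
       p = as.integer(p), op = as.integer(op), cin = cin, cout = cout,
       W = matrix(rnorm(k * k * cout * cin, 0, WEIGHT_INIT_SD),
                  k * k * cout, cin),
       b = numeric(cout))
}

new_inorm <- function(c) {
  list(type = "inorm", c = c, gamma = rep(1, c), beta = rep(0, c))
}

new_relu <- function() list(type = "relu")
new_lrelu <- function(alpha = 0.2) list(type = "lrelu", alpha = alpha)
new_tanh01 <- function() list(type = "tanh01")
new_reflect <- function(p) list(type = "reflect", p = as.integer(p))
new_resblock <- function(layers) list(type = "resblock", layers = layers)

# reflect-101 index map of length n + 2p
refl_idx <- function(n, p) {
  if (p == 0) return(seq_len(n))
  c(seq(p + 1, 2), seq_len(n), seq(n - 1, n - p))
}

reflect_pad <- function(x, p) {
  x[refl_idx(dim(x)[1], p), refl_idx(dim(x)[2], p), , drop = FALSE]
}

# fold padded-row/col gradients back onto their reflection sources
# (reflect-101: padded row i <= p came from source row p + 2 - i, padded
# row p + h + i from source row h - i; columns likewise)
reflect_fold <- function(dy, p, h, w) {
  tmp <- dy[p + seq_len(h), , , drop = FALSE]
  for (i in seq_len(p)) {
    tmp[p + 2 - i, , ] <- tmp[p + 2 - i, , ] + dy[i, , ]
    tmp[h - i, , ] <- tmp[h - i, , ] + dy[p + h + i, , ]
  }
  dx <- tmp[, p + seq_len(w), , drop = FALSE]
  for (j in seq_len(p)) {
    dx[, p + 2 - j, ] <- dx[, p + 2 - j, ] + tmp[, j, ]
    dx[, w - j, ] <- dx[, w - j, ] + tmp[, p + w + j, ]
  }
  dx
}

# column-recycled scale/shift (column-major): avoids sweep()'s aperm cost
scale_cols <- function(m, v) m * rep(v, each = nrow(m))
shift_cols <- function(m, v) m + rep(v, each = nrow(m))

INORM_EPS <- 1e-5

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = {
      d <- dim(x)
      if (d[1] + 2 * layer$p < layer$k || d[2] + 2 * layer$p < layer$k)
        pam_stop("shape", sprintf(
          "input %dx%d smaller than conv kernel k=%d", d[1], d[2], layer$k))
      list(y = cpp_conv2d_fwd(x, layer$W, layer$b, layer$k, layer$s,
                              layer$p),
           cache = x)
    },
    convt = list(y = cpp_convt2d_fwd(x, layer$W, layer$b, layer$k, layer$s,
                                     layer$p, layer$op),
                 cache = x),
    inorm = {
      d <- dim(x)
      xm <- matrix(x, d[1] * d[2], d[3])
      mu <- colMeans(xm)
      xc <- shift_cols(xm, -mu)
      istd <- 1 / sqrt(colMeans(xc^2) + INORM_EPS)
      xhat <- scale_cols(xc, istd)
      y <- shift_cols(scale_cols(xhat, layer$gamma), layer$beta)
      list(y = array(y, d), cache = list(xhat = xhat, istd = istd, d = d))
    },
    relu = list(y = pmax(x, 0), cache = x > 0),
    lrelu = list(y = ifelse(x > 0, x, layer$alpha * x), cache = x > 0),
    tanh01 = {
      y <- (tanh(x) + 1) / 2
      list(y = y, cache = y)
    },
    reflect = list(y = reflect_pad(x, layer$p), cache = dim(x)[1:2]),
    resblock = {
      inner <- net_forward(layer$layers, x)
      list(y = inner$y + x, cache = inner$caches)
    },
    pam_stop("internal", paste("unknown layer type", layer$type)))
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      g <- cpp_conv2d_bwd(cache, layer$W, dy, layer$k, layer$s, layer$p)
      list(dx = g$dx, grads = list(W = g$dW, b = as.numeric(g$db)))
    },
    convt = {
      g <- cpp_convt2d_bwd(cache, layer$W, dy, layer$k, layer$s, layer$p,
                           layer$op)
      list(dx = g$dx, grads = list(W = g$dW, b = as.numeric(g$db)))
    },
    inorm = {
      d <- cache$d
      dym <- matrix(dy, d[1] * d[2], d[3])
      dgamma <- colSums(dym * cache$xhat)
      dbeta <- colSums(dym)
      dxhat <- scale_cols(dym, layer$gamma)
      m1 <- colMeans(dxhat)
      m2 <- colMeans(dxhat * cache$xhat)
      dx <- shift_cols(dxhat, -m1) - scale_cols(cache$xhat, m2)
      dx <- scale_cols(dx, cache$istd)
      list(dx = array(dx, d), grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dx = dy * cache, grads = NULL),
    lrelu = list(dx = dy * ifelse(cache, 1, layer$alpha), grads = NULL),
    tanh01 = list(dx = dy * (1 - (2 * cache - 1)^2) / 2, grads = NULL),
    reflect = list(dx = reflect_fold(dy, layer$p, cache[1], cache[2]),
                   grads = NULL),
    resblock = {
      inner <- net_backward(layer$layers, cache, dy)
      list(dx = inner$dx + dy, grads = inner$grads)
    },
    pam_stop("internal", paste("unknown layer type", layer$type)))
}

net_forward <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    st <- layer_forward(layers[[i]], x)
    x <- st$y
    caches[[i]] <- st$cache
  }
  list(y = x, caches = caches)
}

net_backward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    st <- layer_backward(layers[[i]], caches[[i]], dy)
    dy <- st$dx
    grads[i] <- list(st$grads)   # keeps NULL entries in place
  }
  list(dx = dy, grads = grads)
}

# parameter bookkeeping -------------------------------------------------------

PARAM_FIELDS <- c("W", "b", "gamma", "beta")

layer_param_count <- function(layer) {
  if (layer$type == "resblock")
    return(sum(vapply(layer$layers, layer_param_count, 1)))
  sum(vapply(PARAM_FIELDS,
             function(f) if (is.null(layer[[f]])) 0 else length(layer[[f]]),
             1))
}

# elementwise map over (layers, grads, state) applying Adam updates in place
adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (l$type == "resblock") return(adam_init(l$layers))
    st <- list()
    for (f in PARAM_FIELDS)
      if (!is.null(l[[f]]))
        st[[f]] <- list(m = l[[f]] * 0, v = l[[f]] * 0)
    st
  })
}

adam_step <- function(layers, grads, state, lr, beta1, beta2, t,
                      eps = 1e-8) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "resblock") {
      sub <- adam_step(l$layers, grads[[i]], state[[i]], lr, beta1, beta2, t,
                       eps)
      layers[[i]]$layers <- sub$layers
      state[[i]] <- sub$state
      next
    }
    g <- grads[[i]]
    if (is.null(g)) next
    for (f in names(g)) {
      st <- state[[i]][[f]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[f]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[f]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]][[f]] <- l[[f]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[f]] <- st
    }
  }
  list(layers = layers, state = state)
}

# sum two grad structures (NULL-safe), for networks used twice per step
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  out <- a
  for (i in seq_along(a)) {
    if (is.null(a[[i]])) { out[i] <- list(b[[i]]); next }
    if (is.null(b[[i]])) next
    if (is.list(a[[i]]) && is.null(a[[i]]$W) && is.null(a[[i]]$gamma) &&
        is.null(names(a[[i]]))) {
      out[[i]] <- grads_add(a[[i]], b[[i]])          # resblock nesting
    } else if (is.list(a[[i]]) && !is.null(names(a[[i]])) &&
               all(names(a[[i]]) %in% PARAM_FIELDS)) {
      for (f in names(a[[i]])) out[[i]][[f]] <- a[[i]][[f]] + b[[i]][[f]]
    } else {
      out[[i]] <- grads_add(a[[i]], b[[i]])
    }
  }
  out
}
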