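# Minimal pairwise-tensor layer library with explicit backpropagation.
# Feature maps are stored as (L*L) x C matrices; pixel p = i + (j-1)*L.
# The arithmetic-heavy primitives (im2col 3x3 convolution, 1x1 convolution,
# instance normalization) are compiled (src/layers.cpp); composition,
# dropout RNG and Adam live here.

.conv_idx_cache <- new.env(parent = emptyenv())

# shift index maps for the nine 3x3 offsets on an L x L grid (zero
# padding): a P x 9 matrix of 1-based source pixels and a validity mask
conv3_offsets <- function(L) {
  key <- as.character(L)
  if (!is.null(.conv_idx_cache[[key]])) return(.conv_idx_cache[[key]])
  grid_i <- rep(seq_len(L), times = L)
  grid_j <- rep(seq_len(L), each = L)
  offs <- expand.grid(di = -1:1, dj = -1:1)
  idx <- matrix(1L, L * L, 9L)
  valid <- matrix(FALSE, L * L, 9L)
  for (o in seq_len(9L)) {
    si <- grid_i + offs$di[o]
    sj <- grid_j + offs$dj[o]
    ok <- si >= 1L & si <= L & sj >= 1L & sj <= L
    idx[ok, o] <- si[ok] + (sj[ok] - 1L) * L
    valid[, o] <- ok
  }
  maps <- list(idx = idx, valid = valid)
  .conv_idx_cache[[key]] <- maps
  maps
}

new_param_set <- function() new.env(parent = emptyenv())

# He-normal initialized convolution layer spec; k is 1 or 3
make_conv <- function(params, name, c_in, c_out, k) {
  fan_in <- k * k * c_in
  params[[paste0(name, ".W")]] <-
    matrix(stats::rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)), fan_in, c_out)
  params[[paste0(name, ".b")]] <- numeric(c_out)
  list(type = "conv", k = k, c_in = c_in, c_out = c_out,
       W = paste0(name, ".W"), b = paste0(name, ".b"))
}

make_inorm <- function(params, name, c) {
  params[[paste0(name, ".g")]] <- rep(1, c)
  params[[paste0(name, ".b")]] <- numeric(c)
  list(type = "inorm", c = c, g = paste0(name, ".g"), b = paste0(name, ".b"))
}

make_relu <- function() list(type = "relu")
make_dropout <- function(p) list(type = "dropout", p = p)

# basic residual block: conv3-IN-ReLU-dropout-conv3-IN, identity skip,
# post-addition ReLU
make_resblock <- function(params, name, c, dropout) {
  inner <- list(
    make_conv(params, paste0(name, ".c1"), c, c, 3L),
    make_inorm(params, paste0(name, ".n1"), c),
    make_relu(),
    make_dropout(dropout),
    make_conv(params, paste0(name, ".c2"), c, c, 3L),
    make_inorm(params, paste0(name, ".n2"), c)
  )
  list(type = "res", layers = inner)
}

layer_forward <- function(params, lay, X, train, L) {
  switch(lay$type,
    conv = {
      W <- params[[lay$W]]; b <- params[[lay$b]]
      if (lay$k == 1L) {
        r <- cpp_conv1_fwd(X, W, b)
        list(y = r$y, cache = list(X = X))
      } else {
        maps <- conv3_offsets(L)
        r <- cpp_conv3_fwd(X, W, b, maps$idx, maps$valid)
        list(y = r$y, cache = list(Xcol = r$Xcol))
      }
    },
    inorm = {
      r <- cpp_inorm_fwd(X, params[[lay$g]], params[[lay$b]])
      list(y = r$y, cache = list(xhat = r$xhat, inv = r$inv))
    },
    relu = {
      mask <- X > 0
      list(y = X * mask, cache = list(mask = mask))
    },
    dropout = {
      if (train && lay$p > 0) {
        mask <- matrix((stats::runif(length(X)) >= lay$p) / (1 - lay$p),
                       nrow(X), ncol(X))
        list(y = X * mask, cache = list(mask = mask))
      } else {
        list(y = X, cache = NULL)
      }
    },
    res = {
      r <- seq_forward(params, lay$layers, X, train, L)
      s <- X + r$out
      mask <- s > 0
      list(y = s * mask, cache = list(inner = r$caches, mask = mask))
    },
    stop(sprintf("unknown layer type '%s'", lay$type))
  )
}

layer_backward <- function(params, lay, cache, dY, grads, L) {
  switch(lay$type,
    conv = {
      W <- params[[lay$W]]
      if (lay$k == 1L) {
        r <- cpp_conv1_bwd(cache$X, dY, W, !isTRUE(lay$first))
        acc_grad(grads, lay$W, r$dW)
        acc_grad(grads, lay$b, as.vector(r$db))
        if (isTRUE(lay$first)) NULL else r$dX
      } else {
        maps <- conv3_offsets(L)
        r <- cpp_conv3_bwd(cache$Xcol, dY, W, maps$idx, maps$valid)
        acc_grad(grads, lay$W, r$dW)
        acc_grad(grads, lay$b, as.vector(r$db))
        r$dX
      }
    },
    inorm = {
      r <- cpp_inorm_bwd(cache$xhat, cache$inv, params[[lay$g]], dY)
      acc_grad(grads, lay$g, as.vector(r$dg))
      acc_grad(grads, lay$b, as.vector(r$db))
      r$dx
    },
    relu = dY * cache$mask,
    dropout = if (is.null(cache)) dY else dY * cache$mask,
    res = {
      ds <- dY * cache$mask
      dx_inner <- seq_backward(params, lay$layers, cache$inner, ds, grads, L)
      ds + dx_inner
    },
    stop(sprintf("unknown layer type '%s'", lay$type))
  )
}

seq_forward <- function(params, layers, X, train, L) {
  caches <- vector("list", length(layers))
  for (s in seq_along(layers)) {
    r <- layer_forward(params, layers[[s]], X, train, L)
    X <- r$y
    caches[[s]] <- r$cache
  }
  list(out = X, caches = caches)
}

seq_backward <- function(params, layers, caches, dY, grads, L) {
  for (s in rev(seq_along(layers))) {
    dY <- layer_backward(params, layers[[s]], caches[[s]], dY, grads, L)
  }
  dY
}

acc_grad <- function(grads, name, g) {
  cur <- grads[[name]]
  grads[[name]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(as.list(params), function(p) p * 0)
  st$v <- st$m
  st
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(st$m)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  invisible(NULL)
}
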