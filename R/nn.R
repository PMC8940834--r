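# ---------------------------------------------------------------------------
# Minimal convolutional-network engine.
#
# Activations are stored as (N * H * W) x C matrices: the batch is folded
# into the rows (sample-major, column-major within each H x W plane) and
# channels are columns. Convolutions are evaluated by im2col gathers feeding
# BLAS matrix multiplies; transposed convolutions are the exact adjoint of
# the corresponding strided convolution (gather and scatter swap roles), so
# a single pair of gather/scatter kernels (src/kernels.cpp) serves both.
# Batch normalisation statistics taken over rows are therefore exactly the
# batch + spatial statistics. All layers cache what backward needs; gradients
# accumulate in the layer environments until an optimiser step consumes them.
# ---------------------------------------------------------------------------

# Conv geometry: TensorFlow-style "same" padding for a k x k kernel with the
# given stride; gather/fill index sets are cached per batch size. The weight
# layout pairs with cpp_im2col: row (kk - 1) * cin + c of W corresponds to
# kernel position kk and input channel c.
cg_new <- function(H, W, k, stride) {
  H <- as.integer(H); W <- as.integer(W)
  k <- as.integer(k); stride <- as.integer(stride)
  outH <- as.integer(ceiling(H / stride))
  outW <- as.integer(ceiling(W / stride))
  pad_h <- max((outH - 1L) * stride + k - H, 0L)
  pad_w <- max((outW - 1L) * stride + k - W, 0L)
  e <- new.env(parent = emptyenv())
  e$H <- H; e$W <- W; e$k <- k; e$stride <- stride
  e$outH <- outH; e$outW <- outW
  e$pt <- pad_h %/% 2L; e$pl <- pad_w %/% 2L
  e$Hp <- H + pad_h; e$Wp <- W + pad_w
  e$idx <- list()
  e
}

cg_idx <- function(cg, N) {
  key <- as.character(N)
  hit <- cg$idx[[key]]
  if (!is.null(hit)) return(hit)
  H <- cg$H; W <- cg$W; Hp <- cg$Hp
  r <- rep(seq_len(H), W)
  cc <- rep(seq_len(W), each = H)
  fill1 <- (cg$pt + r) + (cg$pl + cc - 1L) * Hp
  fill <- rep(fill1, N) + rep((seq_len(N) - 1L) * Hp * cg$Wp, each = H * W)

  or <- rep(seq_len(cg$outH), cg$outW)
  oc <- rep(seq_len(cg$outW), each = cg$outH)
  K <- cg$k * cg$k
  g1 <- matrix(0L, cg$outH * cg$outW, K)
  for (kk in seq_len(K)) {
    kr <- (kk - 1L) %% cg$k
    kc <- (kk - 1L) %/% cg$k
    g1[, kk] <- ((or - 1L) * cg$stride + kr + 1L) +
      ((oc - 1L) * cg$stride + kc) * Hp
  }
  npix <- cg$outH * cg$outW
  gather <- g1[rep(seq_len(npix), N), , drop = FALSE] +
    rep((seq_len(N) - 1L) * Hp * cg$Wp, each = npix)
  storage.mode(gather) <- "integer"
  out <- list(fill = as.integer(fill), gather = gather,
              npad = as.integer(N * Hp * cg$Wp))
  cg$idx[[key]] <- out
  out
}

new_layer <- function(type, pnames = character(), ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$pnames <- pnames
  args <- list(...)
  for (nm in names(args)) assign(nm, args[[nm]], envir = e)
  for (nm in pnames) assign(paste0("d", nm), NULL, envir = e)
  e
}

acc_grad <- function(ly, nm, g) {
  cur <- get(nm, envir = ly)
  assign(nm, if (is.null(cur)) g else cur + g, envir = ly)
}

zero_grads <- function(layers) {
  for (ly in layers) {
    for (nm in ly$pnames) assign(paste0("d", nm), NULL, envir = ly)
  }
  invisible(NULL)
}

# -- convolution ------------------------------------------------------------

conv_layer <- function(cin, cout, H, W, k = 4L, stride = 2L, sd = 0.02) {
  new_layer(
    "conv", pnames = c("W", "b"),
    W = matrix(stats::rnorm(k * k * cin * cout, 0, sd), k * k * cin, cout),
    b = numeric(cout),
    cin = cin, cout = cout, cg = cg_new(H, W, k, stride)
  )
}

conv_fwd <- function(ly, X, N) {
  id <- cg_idx(ly$cg, N)
  Xpad <- cpp_scatter_rows(X, id$fill, id$npad)
  Xcol <- cpp_im2col(Xpad, id$gather, ly$cin)
  ly$Xcol <- Xcol
  ly$N <- N
  Y <- Xcol %*% ly$W
  cpp_add_bias(Y, ly$b)
  Y
}

conv_bwd <- function(ly, dY) {
  id <- cg_idx(ly$cg, ly$N)
  acc_grad(ly, "dW", crossprod_fast(ly$Xcol, dY))
  acc_grad(ly, "db", colSums(dY))
  dXcol <- tcrossprod_fast(dY, ly$W)
  dXpad <- cpp_col2im(dXcol, id$gather, id$npad, ly$cin)
  cpp_gather_rows(dXpad, id$fill)
}

# -- transposed convolution (stride-2 upsampling) ---------------------------
# Geometry lives on the *output* (big) side; forward is the adjoint of the
# strided conv big -> small, i.e. scatter where the conv gathers.

convt_layer <- function(cin, cout, Hin, Win, k = 4L, stride = 2L, sd = 0.02) {
  cg <- cg_new(Hin * stride, Win * stride, k, stride)
  stopifnot(cg$outH == Hin, cg$outW == Win)
  new_layer(
    "convt", pnames = c("W", "b"),
    W = matrix(stats::rnorm(k * k * cout * cin, 0, sd), k * k * cout, cin),
    b = numeric(cout),
    cin = cin, cout = cout, cg = cg
  )
}

convt_fwd <- function(ly, X, N) {
  id <- cg_idx(ly$cg, N)
  tmp <- tcrossprod_fast(X, ly$W) # (N * smallHW) x (K * cout)
  Ypad <- cpp_col2im(tmp, id$gather, id$npad, ly$cout)
  Y <- cpp_gather_rows(Ypad, id$fill)
  cpp_add_bias(Y, ly$b)
  ly$X <- X
  ly$N <- N
  Y
}

convt_bwd <- function(ly, dY) {
  id <- cg_idx(ly$cg, ly$N)
  dYpad <- cpp_scatter_rows(dY, id$fill, id$npad)
  dYcol <- cpp_im2col(dYpad, id$gather, ly$cout)
  acc_grad(ly, "dW", crossprod_fast(dYcol, ly$X))
  acc_grad(ly, "db", colSums(dY))
  dYcol %*% ly$W
}

# GEMM dispatch: BLAS dgemm is poorly suited to the very skinny shapes that
# arise at small batch sizes deep in the network (a handful of rows against
# multi-megabyte weight matrices); hand-written streaming kernels take over
# below the threshold.
crossprod_fast <- function(A, B) {
  if (nrow(A) <= 8L) cpp_crossprod_smallk(A, B) else crossprod(A, B)
}

tcrossprod_fast <- function(X, W) {
  if (nrow(X) <= 32L) cpp_tcrossprod_smallm(X, W) else tcrossprod(X, W)
}

# -- batch normalisation ----------------------------------------------------

bn_layer <- function(c, momentum = 0.9, eps = 1e-5) {
  new_layer("bn", pnames = c("gamma", "beta"),
            gamma = rep(1, c), beta = numeric(c),
            run_mean = numeric(c), run_var = rep(1, c),
            momentum = momentum, eps = eps)
}

bn_fwd <- function(ly, X, train) {
  if (train) {
    mu <- colMeans(X)
    v <- colMeans(X^2) - mu^2
    v[v < 0] <- 0
    inv <- 1 / sqrt(v + ly$eps)
    xhat <- cpp_col_center_scale(X, mu, inv)
    ly$run_mean <- ly$momentum * ly$run_mean + (1 - ly$momentum) * mu
    ly$run_var <- ly$momentum * ly$run_var + (1 - ly$momentum) * v
    ly$xhat <- xhat
    ly$inv <- inv
    cpp_col_scale_shift(xhat, ly$gamma, ly$beta)
  } else {
    inv <- 1 / sqrt(ly$run_var + ly$eps)
    cpp_col_scale_shift(X, ly$gamma * inv,
                        ly$beta - ly$run_mean * inv * ly$gamma)
  }
}

bn_bwd <- function(ly, dY) {
  xhat <- ly$xhat
  acc_grad(ly, "dgamma", colSums(dY * xhat))
  acc_grad(ly, "dbeta", colSums(dY))
  dxhat <- cpp_col_scale_shift(dY, ly$gamma, numeric(length(ly$gamma)))
  s1 <- colMeans(dxhat)
  s2 <- colMeans(dxhat * xhat)
  cpp_bn_backward(dxhat, xhat, s1, s2, ly$inv)
}

# -- activations and dropout ------------------------------------------------

act_layer <- function(kind, slope = 0.2) {
  new_layer("act", kind = kind,
            slope = switch(kind, relu = 0, lrelu = slope, sigmoid = NA_real_))
}

act_fwd <- function(ly, X) {
  y <- if (ly$kind == "sigmoid") 1 / (1 + exp(-X)) else cpp_lrelu(X, ly$slope)
  ly$y <- y
  y
}

act_bwd <- function(ly, dY) {
  if (ly$kind == "sigmoid") dY * ly$y * (1 - ly$y)
  else cpp_lrelu_grad(dY, ly$y, ly$slope)
}

dropout_layer <- function(rate = 0.5) new_layer("dropout", rate = rate)

dropout_fwd <- function(ly, X, train) {
  if (!train || ly$rate <= 0) {
    ly$mask <- NULL
    return(X)
  }
  keep <- 1 - ly$rate
  ly$mask <- (matrix(stats::runif(length(X)), nrow(X)) < keep) / keep
  X * ly$mask
}

dropout_bwd <- function(ly, dY) {
  if (is.null(ly$mask)) dY else dY * ly$mask
}

# -- optimiser --------------------------------------------------------------

adam_step <- function(layers, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (ly in layers) {
    if (!length(ly$pnames)) next
    if (is.null(ly$opt_t)) {
      ly$opt_t <- 0L
      for (nm in ly$pnames) {
        np <- length(get(nm, envir = ly))
        # single-precision moment state, bit-cast inside cpp_adam_f
        assign(paste0("m_", nm), integer(np), envir = ly)
        assign(paste0("v_", nm), integer(np), envir = ly)
      }
    }
    ly$opt_t <- ly$opt_t + 1L
    for (nm in ly$pnames) {
      g <- get(paste0("d", nm), envir = ly)
      if (is.null(g)) next
      cpp_adam_f(get(nm, envir = ly), g,
                 get(paste0("m_", nm), envir = ly),
                 get(paste0("v_", nm), envir = ly),
                 lr, beta1, beta2, eps, ly$opt_t)
    }
  }
  invisible(NULL)
}

# Binary cross-entropy on logits: loss and d/dz, numerically stable.
bce_logits <- function(z, target) {
  sp <- ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
  list(loss = mean(sp - target * z),
       dz = (1 / (1 + exp(-z)) - target) / length(z))
}
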