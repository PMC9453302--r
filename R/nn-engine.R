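# Internal sequential-network engine.
#
# Activations travel between layers as (channels * time, batch) matrices in
# channel-major layout; 1-D convolutions are evaluated as a single BLAS
# matrix product over an im2col gather, which is what makes mini-batch
# training tractable in plain R.

layer_conv <- function(kernel, filters, stride = 1L, padding = 0L,
                       frozen = FALSE) {
  list(kind = "convolution", kernel = as.integer(kernel),
       filters = as.integer(filters), stride = as.integer(stride),
       padding = as.integer(padding), frozen = isTRUE(frozen))
}
layer_relu <- function() list(kind = "relu", frozen = FALSE)
layer_pool <- function(size, stride = size) {
  list(kind = "max_pool", size = as.integer(size),
       stride = as.integer(stride), frozen = FALSE)
}
layer_ccn <- function(window = 5L, alpha = 1e-4, beta = 0.75, bias = 2) {
  list(kind = "cross_channel_norm", window = as.integer(window),
       alpha = alpha, beta = beta, bias = bias, frozen = FALSE)
}
layer_fc <- function(units, frozen = FALSE) {
  list(kind = "fully_connected", units = as.integer(units),
       frozen = isTRUE(frozen))
}
layer_dropout <- function(rate = 0.5) {
  list(kind = "dropout", rate = rate, frozen = FALSE)
}
layer_softmax <- function() list(kind = "softmax", frozen = FALSE)

# column indices of an im2col gather over a (C, T) channel-major layout
im2col_indices <- function(C, T, k, stride) {
  Tout <- (T - k) %/% stride + 1L
  if (Tout < 1L) return(NULL)
  starts <- (seq_len(Tout) - 1L) * stride
  idx <- outer(seq_len(C),
               (rep(starts, each = k) + rep(seq_len(k) - 1L, Tout)) * C, `+`)
  dim(idx) <- c(C * k, Tout)
  list(idx = idx, Tout = Tout)
}

# resolve every layer's input/output shape and precompute gather indices
compile_net <- function(config) {
  C <- config$input_shape[1]; T <- config$input_shape[2]
  plans <- vector("list", length(config$layers))
  for (li in seq_along(config$layers)) {
    ly <- config$layers[[li]]
    pl <- ly
    pl$Cin <- C; pl$Tin <- T
    if (ly$kind == "convolution") {
      Tpad <- T + 2L * ly$padding
      ii <- im2col_indices(C, Tpad, ly$kernel, ly$stride)
      if (is.null(ii)) {
        abort_bad_arg(sprintf(
          "Layer %d: window too short for the receptive field (T=%d, kernel=%d).",
          li, T, ly$kernel))
      }
      pl$ii <- ii
      pl$Tpad <- Tpad
      if (ly$padding > 0L) {
        pl$rowmap <- as.vector(outer(seq_len(C),
                                     (ly$padding + seq_len(T) - 1L) * C, `+`))
      }
      C <- ly$filters; T <- ii$Tout
    } else if (ly$kind == "max_pool") {
      Tout <- (T - ly$size) %/% ly$stride + 1L
      if (Tout < 1L) {
        abort_bad_arg(sprintf("Layer %d: window too short for pooling.", li))
      }
      pl$idxT <- outer(seq_len(ly$size) - 1L,
                       (seq_len(Tout) - 1L) * ly$stride, `+`) + 1L
      T <- Tout
    } else if (ly$kind == "fully_connected") {
      pl$in_dim <- C * T
      C <- ly$units; T <- 1L
    } else if (!ly$kind %in% c("relu", "cross_channel_norm", "dropout",
                               "softmax")) {
      abort_bad_arg(sprintf("Unknown layer kind '%s'.", ly$kind))
    }
    pl$Cout <- C; pl$Tout_shape <- T
    plans[[li]] <- pl
  }
  plans
}

he_init <- function(rows, cols) {
  matrix(stats::rnorm(rows * cols, 0, sqrt(2 / cols)), rows, cols)
}

init_params <- function(plans, seed) {
  withr::with_seed(as.integer(seed), {
    lapply(plans, function(pl) {
      switch(pl$kind,
        convolution = list(W = he_init(pl$filters, pl$Cin * pl$kernel),
                           b = numeric(pl$filters)),
        fully_connected = list(W = he_init(pl$units, pl$in_dim),
                               b = numeric(pl$units)),
        NULL)
    })
  })
}

pad_rows <- function(X, pl, B) {
  if (pl$padding == 0L) return(X)
  Xp <- matrix(0, pl$Cin * pl$Tpad, B)
  Xp[pl$rowmap, ] <- X
  Xp
}

sliding_row_sum <- function(M, half) {
  # sum over a symmetric window of rows, truncated at the edges
  out <- M
  K <- nrow(M)
  for (o in seq_len(half)) {
    out[(1 + o):K, ] <- out[(1 + o):K, ] + M[seq_len(K - o), ]
    out[seq_len(K - o), ] <- out[seq_len(K - o), ] + M[(1 + o):K, ]
  }
  out
}

# forward pass; returns activations cache when `cache = TRUE`
nn_forward <- function(plans, params, X, train = FALSE, cache = FALSE) {
  B <- ncol(X)
  caches <- if (cache) vector("list", length(plans)) else NULL
  logits <- NULL
  for (li in seq_along(plans)) {
    pl <- plans[[li]]
    if (pl$kind == "convolution") {
      Xp <- pad_rows(X, pl, B)
      Xc <- Xp[as.vector(pl$ii$idx), , drop = FALSE]
      dim(Xc) <- c(pl$Cin * pl$kernel, pl$ii$Tout * B)
      Y <- params[[li]]$W %*% Xc + params[[li]]$b
      if (cache) caches[[li]] <- list(Xc = Xc)
      dim(Y) <- c(pl$filters * pl$ii$Tout, B)
      X <- Y
    } else if (pl$kind == "relu") {
      if (cache) caches[[li]] <- list(mask = X > 0)
      X[X < 0] <- 0
    } else if (pl$kind == "max_pool") {
      C <- pl$Cin; Tin <- pl$Tin; Tout <- ncol(pl$idxT)
      dim(X) <- c(C, Tin, B)
      cur <- X[, pl$idxT[1L, ], , drop = FALSE]
      arg <- array(1L, dim(cur))
      if (pl$size > 1L) {
        for (i in 2:pl$size) {
          cand <- X[, pl$idxT[i, ], , drop = FALSE]
          hit <- cand > cur
          cur[hit] <- cand[hit]
          arg[hit] <- i
        }
      }
      if (cache) caches[[li]] <- list(arg = arg, dims = c(C, Tin, B))
      dim(cur) <- c(C * Tout, B)
      X <- cur
    } else if (pl$kind == "cross_channel_norm") {
      C <- pl$Cin; TB <- pl$Tin * B
      dim(X) <- c(C, TB)
      s <- sliding_row_sum(X^2, pl$window %/% 2L)
      d <- pl$bias + (pl$alpha / pl$window) * s
      Y <- X * d^(-pl$beta)
      if (cache) caches[[li]] <- list(x = X, d = d)
      dim(Y) <- c(C * pl$Tin, B)
      X <- Y
    } else if (pl$kind == "fully_connected") {
      if (cache) caches[[li]] <- list(inp = X)
      X <- params[[li]]$W %*% X + params[[li]]$b
    } else if (pl$kind == "dropout") {
      if (train) {
        keep <- 1 - pl$rate
        mask <- matrix(stats::runif(length(X)) < keep, nrow(X), ncol(X)) / keep
        X <- X * mask
        if (cache) caches[[li]] <- list(mask = mask)
      }
    } else if (pl$kind == "softmax") {
      logits <- X
      mx <- apply(X, 2L, max)
      e <- exp(sweep(X, 2L, mx))
      X <- sweep(e, 2L, colSums(e), `/`)
    }
    if (cache && is.null(caches[[li]])) caches[[li]] <- list()
  }
  list(out = X, logits = logits %||% X, caches = caches)
}

# scatter-add an im2col gradient back onto the (padded) input rows
col2im <- function(dXc, pl, B) {
  ckt <- nrow(pl$ii$idx) * pl$ii$Tout
  dim(dXc) <- c(ckt, B)
  iv <- as.vector(pl$ii$idx)
  r <- rowsum(dXc, group = iv)
  dXp <- matrix(0, pl$Cin * pl$Tpad, B)
  dXp[as.integer(rownames(r)), ] <- r
  if (pl$padding > 0L) dXp[pl$rowmap, , drop = FALSE] else dXp
}

# backward pass from d(logits), using the activations cached in forward
nn_backward <- function(plans, params, caches, dX, B) {
  grads <- vector("list", length(plans))
  for (li in rev(seq_along(plans))) {
    pl <- plans[[li]]
    if (pl$kind == "softmax") {
      next  # gradient already taken w.r.t. logits
    } else if (pl$kind == "convolution") {
      Tout <- pl$ii$Tout
      dim(dX) <- c(pl$filters, Tout * B)
      Xc <- caches[[li]]$Xc
      grads[[li]] <- list(W = dX %*% t(Xc), b = rowSums(dX))
      dXc <- crossprod(params[[li]]$W, dX)
      dX <- col2im(dXc, pl, B)
    } else if (pl$kind == "relu") {
      dX <- dX * caches[[li]]$mask
    } else if (pl$kind == "max_pool") {
      dims <- caches[[li]]$dims
      arg <- caches[[li]]$arg
      Tout <- ncol(pl$idxT)
      dim(dX) <- c(dims[1], Tout, dims[3])
      back <- array(0, dims)
      for (i in seq_len(pl$size)) {
        contrib <- dX * (arg == i)
        back[, pl$idxT[i, ], ] <- back[, pl$idxT[i, ], , drop = FALSE] + contrib
      }
      dim(back) <- c(dims[1] * dims[2], dims[3])
      dX <- back
    } else if (pl$kind == "cross_channel_norm") {
      x <- caches[[li]]$x; d <- caches[[li]]$d
      dim(dX) <- dim(x)
      u <- dX * x * d^(-pl$beta - 1)
      dX <- dX * d^(-pl$beta) -
        (2 * pl$alpha * pl$beta / pl$window) * x * sliding_row_sum(u, pl$window %/% 2L)
      dim(dX) <- c(pl$Cin * pl$Tin, B)
    } else if (pl$kind == "fully_connected") {
      inp <- caches[[li]]$inp
      grads[[li]] <- list(W = dX %*% t(inp), b = rowSums(dX))
      dX <- crossprod(params[[li]]$W, dX)
    } else if (pl$kind == "dropout") {
      if (!is.null(caches[[li]]$mask)) dX <- dX * caches[[li]]$mask
    }
  }
  grads
}

# cross-entropy on softmax probabilities; y is an integer class index
softmax_ce_loss <- function(probs, y) {
  -mean(base::log(probs[cbind(y, seq_along(y))] + 1e-12))
}
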