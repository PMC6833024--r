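# Minimal layer framework backing the segmentation network.  Each layer is a
# mutable environment holding parameters, gradient accumulators and the
# forward cache its backward pass needs.  Batches are lists of H x W x C
# arrays.  Convolution forward/backward run in C++ (src/conv.cpp); everything
# here was validated against finite-difference gradients (see tests).

new_layer_env <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e
}

# "same" padding (top, left, bottom, right); even kernels pad 1 before and
# 2 after, stride-2 convolutions on even inputs pad 1 before only.
conv_padding <- function(k, stride) {
  if (stride == 1L) c(floor((k - 1) / 2), ceiling((k - 1) / 2))
  else c(1L, 0L)
}

new_conv <- function(kh, kw, cin, cout, stride = 1L, act = "relu") {
  L <- new_layer_env("conv")
  L$kh <- kh; L$kw <- kw; L$cin <- cin; L$cout <- cout
  L$stride <- stride; L$act <- act
  pv <- conv_padding(kh, stride); ph <- conv_padding(kw, stride)
  L$pad <- c(pv[1], ph[1], pv[2], ph[2])  # top, left, bottom, right
  sd <- sqrt(2 / (kh * kw * cin))         # He initialisation
  L$W <- matrix(rnorm(kh * kw * cin * cout, sd = sd), kh * kw * cin, cout)
  L$b <- numeric(cout)
  L$dW <- 0 * L$W; L$db <- numeric(cout)
  L
}

conv_forward <- function(L, xs, training) {
  p <- L$pad
  ys <- conv2d_fwd_batch(xs, L$W, L$b, L$kh, L$kw, L$stride,
                         p[1], p[2], p[3], p[4])
  if (L$act == "relu") {
    if (training) L$mask <- lapply(ys, function(y) y > 0)
    ys <- lapply(ys, function(y) { y[y < 0] <- 0; y })
  }
  if (training) L$x <- xs
  ys
}

conv_backward <- function(L, dys) {
  p <- L$pad
  if (L$act == "relu") dys <- Map(function(dy, m) dy * m, dys, L$mask)
  g <- conv2d_bwd_batch(L$x, L$W, dys, L$kh, L$kw, L$stride,
                        p[1], p[2], p[3], p[4])
  L$dW <- L$dW + g$dw
  L$db <- L$db + as.numeric(g$db)
  g$dx
}

# ---- batch normalisation ---------------------------------------------------
# Statistics over batch and spatial dimensions per channel; running averages
# (momentum 0.9) are used in inference mode so prediction is deterministic.

new_bn <- function(c, momentum = 0.9, eps = 1e-5) {
  L <- new_layer_env("bn")
  L$c <- c; L$momentum <- momentum; L$eps <- eps
  L$gamma <- rep(1, c); L$beta <- rep(0, c)
  L$dgamma <- numeric(c); L$dbeta <- numeric(c)
  L$r_mean <- rep(0, c); L$r_var <- rep(1, c)
  L
}

# reshape H x W x C -> (H*W) x C without copying data
as_pix_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

bn_forward <- function(L, xs, training) {
  cdim <- L$c
  if (training) {
    xm <- lapply(xs, as_pix_mat)
    ntot <- sum(vapply(xm, nrow, numeric(1)))
    s1 <- Reduce(`+`, lapply(xm, colSums))
    s2 <- Reduce(`+`, lapply(xm, function(m) colSums(m^2)))
    m <- s1 / ntot
    v <- pmax(s2 / ntot - m^2, 0)
    L$r_mean <- L$momentum * L$r_mean + (1 - L$momentum) * m
    L$r_var <- L$momentum * L$r_var + (1 - L$momentum) * v
    std <- sqrt(v + L$eps)
    xhat <- lapply(xm, function(mm)
      (mm - rep(m, each = nrow(mm))) / rep(std, each = nrow(mm)))
    L$xhat <- xhat; L$std <- std; L$ntot <- ntot
    Map(function(hm, x) {
      out <- hm * rep(L$gamma, each = nrow(hm)) +
        rep(L$beta, each = nrow(hm))
      dim(out) <- dim(x)
      out
    }, xhat, xs)
  } else {
    std <- sqrt(L$r_var + L$eps)
    a <- L$gamma / std
    b <- L$beta - L$r_mean * a
    lapply(xs, function(x) {
      mm <- as_pix_mat(x)
      out <- mm * rep(a, each = nrow(mm)) + rep(b, each = nrow(mm))
      dim(out) <- dim(x)
      out
    })
  }
}

bn_backward <- function(L, dys) {
  ntot <- L$ntot
  dym <- lapply(dys, as_pix_mat)
  s1 <- Reduce(`+`, lapply(dym, colSums))
  s2 <- Reduce(`+`, Map(function(dm, hm) colSums(dm * hm), dym, L$xhat))
  L$dgamma <- L$dgamma + s2
  L$dbeta <- L$dbeta + s1
  mdy <- s1 / ntot; mdyx <- s2 / ntot
  g <- L$gamma / L$std
  Map(function(dm, hm, dy) {
    n <- nrow(dm)
    out <- (dm - rep(mdy, each = n) - hm * rep(mdyx, each = n)) *
      rep(g, each = n)
    dim(out) <- dim(dy)
    out
  }, dym, L$xhat, dys)
}

# ---- linear (bilinear) x2 up-sampling --------------------------------------
# Expressed as fixed interpolation matrices so the adjoint is exact.

.up_cache <- new.env(parent = emptyenv())

upsample_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.up_cache[[key]])) return(.up_cache[[key]])
  U <- matrix(0, 2 * n, n)
  for (i in seq_len(2 * n)) {
    y <- (i - 1 + 0.5) / 2 - 0.5
    i0 <- floor(y); w <- y - i0
    i0c <- min(max(i0, 0), n - 1)
    i1c <- min(max(i0 + 1, 0), n - 1)
    U[i, i0c + 1] <- U[i, i0c + 1] + (1 - w)
    U[i, i1c + 1] <- U[i, i1c + 1] + w
  }
  .up_cache[[key]] <- U
  U
}

upsample2_fwd <- function(xs) {
  lapply(xs, function(x) {
    d <- dim(x)
    UH <- upsample_matrix(d[1]); UW <- upsample_matrix(d[2])
    out <- array(0, c(2 * d[1], 2 * d[2], d[3]))
    for (c in seq_len(d[3])) out[, , c] <- UH %*% x[, , c] %*% t(UW)
    out
  })
}

upsample2_bwd <- function(dys) {
  lapply(dys, function(dy) {
    d <- dim(dy)
    UH <- upsample_matrix(d[1] / 2); UW <- upsample_matrix(d[2] / 2)
    out <- array(0, c(d[1] / 2, d[2] / 2, d[3]))
    for (c in seq_len(d[3])) out[, , c] <- t(UH) %*% dy[, , c] %*% UW
    out
  })
}

# ---- elementwise helpers ---------------------------------------------------

batch_add <- function(as, bs) Map(function(a, b) a + b, as, bs)

concat_channels <- function(blists) {
  n <- length(blists[[1]])
  lapply(seq_len(n), function(i) {
    arrs <- lapply(blists, `[[`, i)
    d <- dim(arrs[[1]])
    total_c <- sum(vapply(arrs, function(a) dim(a)[3], numeric(1)))
    out <- array(0, c(d[1], d[2], total_c))
    at <- 0L
    for (a in arrs) {
      nc <- dim(a)[3]
      out[, , (at + 1):(at + nc)] <- a
      at <- at + nc
    }
    out
  })
}

split_channels <- function(dys, sizes) {
  lapply(seq_along(sizes), function(k) {
    from <- sum(sizes[seq_len(k - 1)]) + 1L
    to <- sum(sizes[seq_len(k)])
    lapply(dys, function(dy) dy[, , from:to, drop = FALSE])
  })
}

# ---- parameter traversal and Adam ------------------------------------------

layer_param_names <- function(L) {
  switch(L$type, conv = c("W", "b"), bn = c("gamma", "beta"), character(0))
}

# flat list of (layer, parameter-name) references in a stable order;
# ids carry the full path so nested modules never collide
collect_param_refs <- function(layers, prefix = "") {
  refs <- list()
  for (nm in names(layers)) {
    L <- layers[[nm]]
    if (is.null(L)) next
    full <- paste0(prefix, nm)
    if (is.list(L) && !is.environment(L)) {
      refs <- c(refs, collect_param_refs(L, paste0(full, ".")))
    } else {
      for (p in layer_param_names(L))
        refs[[length(refs) + 1L]] <-
          list(layer = L, name = p, id = paste(full, p))
    }
  }
  refs
}

zero_grads <- function(refs) {
  for (r in refs) {
    gname <- paste0("d", r$name)
    r$layer[[gname]] <- 0 * r$layer[[gname]]
  }
  invisible(NULL)
}

adam_step <- function(refs, state, lr, beta1, beta2, eps) {
  state$t <- state$t + 1L
  t <- state$t
  for (r in refs) {
    g <- r$layer[[paste0("d", r$name)]]
    key <- r$id
    if (is.null(state$m[[key]])) {
      state$m[[key]] <- 0 * g
      state$v[[key]] <- 0 * g
    }
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    mhat <- state$m[[key]] / (1 - beta1^t)
    vhat <- state$v[[key]] / (1 - beta2^t)
    r$layer[[r$name]] <- r$layer[[r$name]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}

new_adam_state <- function() {
  e <- new.env(parent = emptyenv())
  e$t <- 0L; e$m <- list(); e$v <- list()
  e
}

# rescale all gradients when their global Euclidean norm exceeds max_norm
clip_gradients <- function(refs, max_norm) {
  if (!is.finite(max_norm)) return(invisible(NULL))
  total <- sqrt(sum(vapply(refs, function(r)
    sum(r$layer[[paste0("d", r$name)]]^2), numeric(1))))
  if (total > max_norm) {
    sc <- max_norm / total
    for (r in refs) {
      gname <- paste0("d", r$name)
      r$layer[[gname]] <- r$layer[[gname]] * sc
    }
  }
  invisible(NULL)
}
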