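#' Training configuration for the loss-minimization strategies
#'
#' Full-scale defaults: Adam with learning rate
#' `1e-4`, `beta1 = 0.9`, `beta2 = 0.999`, `epsilon = 1e-4`; mixed-loss
#' weights `lambda1 = 1`, `lambda2 = 2`; hard-example schedules
#' `n_max = 40`, `n_min = 5`, `k_max = 15`, `k_min = 4`.  For desk-scale
#' experiments use smaller schedule ceilings (see the package vignette).
#'
#' @param lambda1,lambda2 non-negative weights of the all-sample loss term
#'   and the augmented hard-example term.
#' @param n_max,n_min schedule bounds for the number of hardest samples
#'   re-weighted each round, `N_t = min(max(n_max - t, n_min), m)`.
#' @param k_max,k_min schedule bounds for augmentation folds,
#'   `K_t = max(k_max - floor(0.25 t), k_min)`.
#' @param epochs number of training rounds `T`.
#' @param learning_rate,beta1,beta2,epsilon Adam constants.
#' @param batch_size mini-batch size.
#' @param clip_norm global gradient-norm ceiling per mini-batch; gradients
#'   are rescaled when their joint Euclidean norm exceeds it (a standard
#'   safeguard against the saturation collapse of Dice training on tiny
#'   foregrounds).  Roughly six times the norm of a healthy early-training
#'   batch; `Inf` disables clipping.
#' @param seed master seed controlling initial shuffling and augmentation.
#' @param aug_rotation_deg rotation range (degrees) of the augmentation ops.
#' @param aug_translate_frac translation range as a fraction of image side.
#' @return list of class `mmlm_config`.
#' @export
mmlm_config <- function(lambda1 = 1, lambda2 = 2,
                        n_max = 40L, n_min = 5L, k_max = 15L, k_min = 4L,
                        epochs = 30L, learning_rate = 1e-4,
                        beta1 = 0.9, beta2 = 0.999, epsilon = 1e-4,
                        batch_size = 4L, seed = 1L,
                        aug_rotation_deg = 20, aug_translate_frac = 0.05,
                        clip_norm = 2) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, n_min <= n_max, k_min <= k_max,
            n_min >= 1, k_min >= 1, epochs >= 1)
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 n_max = as.integer(n_max), n_min = as.integer(n_min),
                 k_max = as.integer(k_max), k_min = as.integer(k_min),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 aug_rotation_deg = aug_rotation_deg,
                 aug_translate_frac = aug_translate_frac,
                 clip_norm = clip_norm),
            class = "mmlm_config")
}

#' Hard-example count schedule
#'
#' `N_t = min(max(n_max - t, n_min), m)`: the number of highest-loss samples
#' re-weighted in round `t`, decreasing linearly then held at its floor and
#' never exceeding the dataset size.
#'
#' @param t round (>= 1).
#' @param n_max,n_min schedule bounds.
#' @param m dataset size.
#' @return integer.
#' @export
schedule_n <- function(t, n_max, n_min, m) {
  stopifnot(t >= 1)
  min(max(n_max - t, n_min), m)
}

#' Augmentation-fold schedule
#'
#' `K_t = max(k_max - floor(0.25 t), k_min)`: augmentation folds per hard
#' example, decreasing by one every four rounds down to its floor.
#'
#' @inheritParams schedule_n
#' @param k_max,k_min schedule bounds.
#' @return integer.
#' @export
schedule_k <- function(t, k_max, k_min) {
  stopifnot(t >= 1)
  max(k_max - floor(0.25 * t), k_min)
}

#' Rank training pairs by per-sample Dice loss
#'
#' Evaluates the frozen network on every pair and returns sample indices in
#' decreasing loss order (stable under ties).
#'
#' @param net an `msmku` network (used in inference mode).
#' @param pairs list of training pairs, each `list(image =, mask =)`.
#' @param pyramids optional precomputed image pyramids (one per pair, from
#'   [build_image_pyramid()]) to avoid rebuilding them every round.
#' @return list with `order` (indices, hardest first), `losses` and
#'   `f_scores` in original sample order.
#' @export
rank_by_loss <- function(net, pairs, pyramids = NULL) {
  if (length(pairs) == 0) stop("rank_by_loss: empty pair list")
  losses <- numeric(length(pairs))
  fs <- numeric(length(pairs))
  bs <- 8L
  idx_chunks <- split(seq_along(pairs), ceiling(seq_along(pairs) / bs))
  for (chunk in idx_chunks) {
    P <- msmku_forward(net, lapply(pairs[chunk], `[[`, "image"),
                       training = FALSE,
                       pyramids = if (!is.null(pyramids)) pyramids[chunk])
    for (i in seq_along(chunk)) {
      G <- pairs[[chunk[i]]]$mask
      losses[chunk[i]] <- dice_loss(P[[i]], G)
      fs[chunk[i]] <- mask_scores(binarize(P[[i]]), G)$f_score
    }
  }
  list(order = order(-losses), losses = losses, f_scores = fs)
}

# deterministic per-op seed derived from (seed, t, k, j); kept < 2^31
derive_seed <- function(seed, t, k, j) {
  as.integer((as.numeric(seed) * 2654435 + t * 97003 + k * 641 + j * 7919) %%
               2147483647)
}

#' Build the grid of augmentation operations for one round
#'
#' Each op is a rotation angle and (row, col) translation drawn uniformly
#' from the configured ranges, seeded by `(seed, t, k, j)` so the grid is
#' reproducible bit for bit.
#'
#' @param t round.
#' @param k_t,n_t grid dimensions (folds x hard examples).
#' @param cfg an [mmlm_config()].
#' @param side image side in pixels (scales the translation range).
#' @return list of `k_t` lists of `n_t` ops, each
#'   `list(angle =, dr =, dc =)`.
#' @export
make_augment_ops <- function(t, k_t, n_t, cfg, side) {
  lapply(seq_len(k_t), function(k)
    lapply(seq_len(n_t), function(j) {
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
      set.seed(derive_seed(cfg$seed, t, k, j))
      u <- runif(3, -1, 1)
      list(angle = u[1] * cfg$aug_rotation_deg,
           dr = u[2] * cfg$aug_translate_frac * side,
           dc = u[3] * cfg$aug_translate_frac * side)
    }))
}

identity_op <- function() list(angle = 0, dr = 0, dc = 0)

is_identity_op <- function(op) op$angle == 0 && op$dr == 0 && op$dc == 0

#' Apply one augmentation op to an image and its mask
#'
#' The identical rigid transform (rotation about the centre plus translation)
#' is applied to both; the image is resampled bilinearly, the mask by nearest
#' neighbour so it stays binary.  Out-of-frame pixels are filled by symmetric
#' reflection.
#'
#' @param op an op from [make_augment_ops()].
#' @param X image array, `Y` binary mask of the same spatial size.
#' @param Y binary mask matrix.
#' @return `list(image =, mask =)`.
#' @export
apply_augment <- function(op, X, Y) {
  if (is_identity_op(op)) return(list(image = X, mask = Y))
  list(image = warp_rigid(X, op$angle, op$dr, op$dc, "bilinear"),
       mask = warp_rigid(Y, op$angle, op$dr, op$dc, "nearest"))
}

#' Mixed maximum loss for one round
#'
#' `L_t = lambda1 * sum_i l(f(X_i), Y_i) + lambda2 * sum_{k,j}
#' l(f(R_k(Xbar_j)), R_k(Ybar_j))` where `Xbar` orders samples by decreasing
#' loss; evaluated with the network frozen.  Setting `lambda2 = 0` recovers
#' the plain loss sum (average-loss strategy); `lambda1 = 0` with identity
#' ops and one fold recovers the top-`n_t` maximal loss.
#'
#' @param net an `msmku` network.
#' @param pairs training pairs.
#' @param sorted_idx indices hardest-first (from [rank_by_loss()]).
#' @param n_t,k_t schedule values; `ops` must be a `k_t x n_t` grid.
#' @param lambda1,lambda2 term weights.
#' @param ops augmentation grid from [make_augment_ops()].
#' @return total loss (single number).
#' @export
mixed_loss <- function(net, pairs, sorted_idx, n_t, k_t, lambda1, lambda2,
                       ops) {
  m <- length(pairs)
  if (n_t > m) stop("mixed_loss: n_t exceeds the number of pairs")
  stopifnot(length(ops) == k_t, all(lengths(ops) == n_t))
  base <- rank_by_loss(net, pairs)$losses
  total <- lambda1 * sum(base)
  for (k in seq_len(k_t)) {
    for (j in seq_len(n_t)) {
      p <- pairs[[sorted_idx[j]]]
      a <- apply_augment(ops[[k]][[j]], p$image, p$mask)
      Pm <- msmku_forward(net, list(a$image), training = FALSE)[[1]]
      total <- total + lambda2 * dice_loss(Pm, a$mask)
    }
  }
  total
}

# ---- trainers --------------------------------------------------------------

# one Adam pass over a weighted multiset of (pair index, weight, op)
# entries; cached pyramids are reused for untransformed samples
run_epoch <- function(net, pairs, entries, cfg, adam, epoch_seed, pyrs) {
  set.seed(epoch_seed)
  entries <- entries[sample.int(length(entries))]
  nb <- ceiling(length(entries) / cfg$batch_size)
  for (b in seq_len(nb)) {
    take <- entries[((b - 1) * cfg$batch_size + 1):
                      min(b * cfg$batch_size, length(entries))]
    ps <- vector("list", length(take))
    gs <- vector("list", length(take))
    ws <- numeric(length(take))
    for (i in seq_along(take)) {
      e <- take[[i]]
      p <- pairs[[e$idx]]
      if (is_identity_op(e$op)) {
        ps[[i]] <- pyrs[[e$idx]]; gs[[i]] <- p$mask
      } else {
        a <- apply_augment(e$op, p$image, p$mask)
        ps[[i]] <- build_image_pyramid(a$image); gs[[i]] <- a$mask
      }
      ws[i] <- e$weight
    }
    zero_grads(net$param_refs)
    P <- msmku_forward(net, NULL, training = TRUE, pyramids = ps)
    dPs <- Map(function(p, g, w) w * dice_loss_grad(p, g), P, gs, ws)
    msmku_backward(net, dPs)
    clip_gradients(net$param_refs, cfg$clip_norm)
    adam_step(net$param_refs, adam, cfg$learning_rate,
              cfg$beta1, cfg$beta2, cfg$epsilon)
  }
  invisible(net)
}

train_core <- function(pairs, net_cfg, cfg, strategy) {
  m <- length(pairs)
  if (m < 2) stop("need at least 2 training pairs")
  side <- net_cfg$input_side
  net <- build_msmku(net_cfg)
  adam <- new_adam_state()
  pyrs <- lapply(pairs, function(p) build_image_pyramid(p$image))
  hist <- data.frame(t = integer(), n_t = integer(), k_t = integer(),
                     mean_loss = numeric(), mean_f = numeric(),
                     min_f = numeric())
  orders <- list()
  for (t in seq_len(cfg$epochs)) {
    r <- rank_by_loss(net, pairs, pyramids = pyrs)  # frozen f_{w_{t-1}}
    if (strategy == "alm") {
      # the lambda2 = 0 degeneration of the mixed loss: lambda1 * sum_i l_i
      entries <- lapply(seq_len(m), function(i)
        list(idx = i, weight = cfg$lambda1, op = identity_op()))
      n_t <- NA_integer_; k_t <- NA_integer_
    } else {
      n_t <- schedule_n(t, cfg$n_max, cfg$n_min, m)
      k_t <- if (strategy == "mlm") 1L else schedule_k(t, cfg$k_max, cfg$k_min)
      ops <- if (strategy == "mlm") {
        lapply(seq_len(k_t), function(k)
          lapply(seq_len(n_t), function(j) identity_op()))
      } else {
        make_augment_ops(t, k_t, n_t, cfg, side)
      }
      entries <- if (cfg$lambda1 > 0) {
        lapply(seq_len(m), function(i)
          list(idx = i, weight = cfg$lambda1, op = identity_op()))
      } else {
        list()
      }
      if (cfg$lambda2 > 0) {
        for (k in seq_len(k_t)) {
          for (j in seq_len(n_t)) {
            entries[[length(entries) + 1L]] <-
              list(idx = r$order[j], weight = cfg$lambda2, op = ops[[k]][[j]])
          }
        }
      }
    }
    run_epoch(net, pairs, entries, cfg, adam,
              epoch_seed = derive_seed(cfg$seed, t, 0L, 0L), pyrs = pyrs)
    hist <- rbind(hist, data.frame(
      t = t, n_t = n_t, k_t = k_t, mean_loss = mean(r$losses),
      mean_f = mean(r$f_scores), min_f = min(r$f_scores)))
    orders[[t]] <- r$order
  }
  structure(list(network = net, history = hist, orders = orders,
                 strategy = strategy, net_config = net_cfg,
                 train_config = cfg),
            class = "msmku_fit")
}

#' Fit an MSMKU segmentation network
#'
#' One entry point for the three training strategies: `"alm"` (average loss:
#' standard mini-batch Adam on the mean Dice loss), `"mlm"` (maximal loss:
#' the `N_t` highest-loss samples only, no augmentation) and `"mmlm"` (mixed
#' maximum loss: every round the `N_t` currently worst-predicted samples are
#' re-weighted by `lambda2` and replicated under `K_t` random
#' rotation/translation augmentations, on top of the `lambda1`-weighted full
#' training set).  Sample ranking always uses the parameters frozen at the
#' start of the round.
#'
#' @param pairs list of training pairs, each `list(image = side x side x 3
#'   array, mask = side x side binary matrix)`.
#' @param net_config an [msmku_config()].
#' @param train_config an [mmlm_config()].
#' @param strategy one of `"mmlm"`, `"alm"`, `"mlm"`.
#' @return An object of class `msmku_fit` with components `network`,
#'   `history` (one row per round: `t`, `n_t`, `k_t`, `mean_loss`, `mean_f`,
#'   `min_f`, measured under the frozen start-of-round parameters), `orders`
#'   (per-round hardest-first sample orderings) and the configurations.
#'   Methods: `print`, `summary`, `plot`, `predict`, `coef`.
#' @examples
#' \donttest{
#' ds <- generate_dataset(8, rare_fraction = 0, side = 32, seed = 1)
#' pairs <- lapply(ds$items, function(it) list(image = it$image, mask = it$od_mask))
#' fit <- msmku_fit(pairs, msmku_config(32, 4), mmlm_config(epochs = 2),
#'                  strategy = "alm")
#' print(fit)
#' }
#' @export
msmku_fit <- function(pairs, net_config, train_config = mmlm_config(),
                      strategy = c("mmlm", "alm", "mlm")) {
  strategy <- match.arg(strategy)
  train_core(pairs, net_config, train_config, strategy)
}

#' Train with the mixed-maximum-loss strategy
#' @inheritParams msmku_fit
#' @return an `msmku_fit` object.
#' @export
train_mmlm <- function(pairs, net_config, train_config = mmlm_config())
  train_core(pairs, net_config, train_config, "mmlm")

#' Train with the average-loss baseline
#' @inheritParams msmku_fit
#' @return an `msmku_fit` object.
#' @export
train_alm <- function(pairs, net_config, train_config = mmlm_config())
  train_core(pairs, net_config, train_config, "alm")

#' Train with the top-k maximal-loss baseline
#' @inheritParams msmku_fit
#' @return an `msmku_fit` object.
#' @export
train_mlm <- function(pairs, net_config, train_config = mmlm_config())
  train_core(pairs, net_config, train_config, "mlm")

#' @export
print.msmku_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("MSMKU fit (%s), %d rounds on side-%d inputs\n",
              toupper(x$strategy), nrow(h), x$net_config$input_side))
  cat(sprintf("final round: mean Dice loss %.4f, mean F %.4f, min F %.4f\n",
              h$mean_loss[nrow(h)], h$mean_f[nrow(h)], h$min_f[nrow(h)]))
  invisible(x)
}

#' @export
summary.msmku_fit <- function(object, ...) {
  cat(sprintf("MSMKU segmentation fit\n  strategy      : %s\n",
              toupper(object$strategy)))
  cat(sprintf("  rounds        : %d\n", nrow(object$history)))
  cat(sprintf("  input side    : %d px, base width %d (%d parameters)\n",
              object$net_config$input_side, object$net_config$base_width,
              n_params(object$network)))
  cat(sprintf("  lambda1/2     : %g / %g\n", object$train_config$lambda1,
              object$train_config$lambda2))
  cat("  history (first/last rounds):\n")
  h <- object$history
  print(h[unique(c(1, nrow(h))), ], row.names = FALSE)
  invisible(object)
}

#' @export
plot.msmku_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$t, h$mean_f, type = "l", ylim = c(0, 1), xlab = "round",
                 ylab = "training F-score", ...)
  graphics::lines(h$t, h$min_f, lty = 2)
  graphics::legend("bottomright", legend = c("mean F", "min F"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' @export
predict.msmku_fit <- function(object, image, type = c("prob", "mask"), ...)
  predict(object$network, image, type = match.arg(type))

#' @export
coef.msmku_fit <- function(object, ...) {
  refs <- object$network$param_refs
  stats::setNames(lapply(refs, function(r) r$layer[[r$name]]),
                  vapply(refs, `[[`, character(1), "id"))
}
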