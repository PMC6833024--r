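# File I/O, configuration, fold splitting and the cross-validation driver.

#' Read an RGB image from PNG/TIFF/JPEG
#'
#' @param path image file.
#' @return array `H x W x 3` in `[0, 1]`.
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  # EBImage stores (x, y[, c]) = (col, row); convert to (row, col, channel)
  if (length(dim(a)) == 2L) {
    a <- aperm(array(rep(a, 3), c(dim(a), 3)), c(2, 1, 3))
  } else {
    a <- aperm(a[, , 1:3, drop = FALSE], c(2, 1, 3))
  }
  pmin(pmax(a, 0), 1)
}

#' Read a binary mask from an 8- or 16-bit greyscale PNG
#'
#' Any value above half intensity maps to 1.
#'
#' @param path mask file.
#' @return binary matrix.
#' @export
read_mask <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3L)
    stop("read_mask: expected a greyscale mask, got a multi-channel image")
  t((a > 0.5) * 1L)
}

#' Write an image (PNG, values scaled to 8 bit)
#' @param img array `H x W x 3` in `[0, 1]`.
#' @param path output file.
#' @export
write_image <- function(img, path) {
  EBImage::writeImage(EBImage::Image(aperm(img, c(2, 1, 3)),
                                     colormode = "Color"), path)
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG with values 0/255
#' @param mask binary matrix.
#' @param path output file.
#' @export
write_mask <- function(mask, path) {
  check_binary_mask(mask)
  EBImage::writeImage(EBImage::Image(t(mask * 1.0)), path)
  invisible(path)
}

#' Ordered, label-grouped k-fold splits
#'
#' Items are grouped by label preserving their original order; each label's
#' items are dealt into `k` contiguous blocks (earlier folds get the
#' remainder, so a label with fewer items than folds concentrates in the
#' early folds), and fold `i` collects block `i` of every label.
#'
#' @param labels vector of labels in dataset order (use a constant vector
#'   for unlabelled splitting).
#' @param k number of folds.
#' @return list of `k` elements, each `list(train =, test =)` index vectors.
#' @export
kfold_splits <- function(labels, k = 5L) {
  n <- length(labels)
  if (n < k) stop("kfold_splits: fewer items than folds")
  fold_of <- integer(n)
  for (lb in unique(labels)) {
    idx <- which(labels == lb)
    nl <- length(idx)
    sizes <- rep(nl %/% k, k)
    extra <- nl %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    fold_of[idx] <- rep(seq_len(k), times = sizes)
  }
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}

#' Write / read a flat key-value (YAML) training configuration
#'
#' Field names map 1:1 to [mmlm_config()] / [msmku_config()] arguments.
#'
#' @param cfg a config object (any named list).
#' @param path file path.
#' @return `read_config` returns the named list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Evaluate a fitted network on a set of pairs
#'
#' @param net an `msmku` network or `msmku_fit`.
#' @param pairs list of `list(image =, mask =)` pairs.
#' @return data frame with one row per pair: `f_score`, `iou`,
#'   `sensitivity`, `specificity`, `dice_loss`.
#' @export
evaluate_pairs <- function(net, pairs) {
  if (inherits(net, "msmku_fit")) net <- net$network
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    P <- predict(net, p$image, type = "prob")
    sc <- mask_scores(binarize(P), p$mask)
    data.frame(item = i, f_score = sc$f_score, iou = sc$iou,
               sensitivity = sc$sensitivity, specificity = sc$specificity,
               dice_loss = dice_loss(P, p$mask))
  })
  do.call(rbind, rows)
}

#' Five-fold cross-validation of the two-stage pipeline on a dataset
#'
#' Trains a disc-stage and a cup-stage network per fold with the chosen
#' strategy and evaluates per-image segmentation scores on the held-out
#' fold.  Stage-1 trains on whole images with disc masks; stage-2 trains on
#' ROI crops (from the ground-truth disc masks) with cup masks.  Scales are
#' controlled by the two network configs; everything is seeded.
#'
#' @param dataset a dataset from [generate_dataset()] (or a compatible list
#'   with `items`).
#' @param od_config,oc_config [msmku_config()]s for the two stages.
#' @param train_config an [mmlm_config()].
#' @param strategy `"alm"`, `"mlm"` or `"mmlm"`.
#' @param k folds.
#' @return list with `od` and `oc` per-image score tables (columns include
#'   `fold`), `fold_means` and `grand_mean` F-scores for both targets.
#' @export
run_crossval <- function(dataset, od_config, oc_config,
                         train_config = mmlm_config(),
                         strategy = c("alm", "mlm", "mmlm"), k = 5L) {
  strategy <- match.arg(strategy)
  items <- dataset$items
  labels <- vapply(items, `[[`, integer(1), "label")
  splits <- kfold_splits(labels, k)
  od_side <- od_config$input_side
  oc_side <- oc_config$input_side
  prep_od <- function(it) list(
    image = resize_grid(it$image, od_side, od_side),
    mask = resize_grid(it$od_mask, od_side, od_side))
  prep_oc <- function(it) {
    roi <- detect_roi(it$od_mask)
    list(image = crop_resize(it$image, roi, oc_side),
         mask = crop_resize(it$oc_mask, roi, oc_side))
  }
  od_tab <- NULL; oc_tab <- NULL
  for (f in seq_len(k)) {
    sp <- splits[[f]]
    cfg_f <- train_config
    cfg_f$seed <- derive_seed(train_config$seed, f, 1L, 0L)
    od_fit <- msmku_fit(lapply(items[sp$train], prep_od), od_config, cfg_f,
                        strategy = strategy)
    oc_fit <- msmku_fit(lapply(items[sp$train], prep_oc), oc_config, cfg_f,
                        strategy = strategy)
    od_eval <- evaluate_pairs(od_fit, lapply(items[sp$test], prep_od))
    oc_eval <- evaluate_pairs(oc_fit, lapply(items[sp$test], prep_oc))
    od_eval$item <- sp$test; od_eval$fold <- f
    oc_eval$item <- sp$test; oc_eval$fold <- f
    od_tab <- rbind(od_tab, od_eval)
    oc_tab <- rbind(oc_tab, oc_eval)
  }
  fold_means <- data.frame(
    fold = seq_len(k),
    od_f = vapply(seq_len(k), function(f)
      mean(od_tab$f_score[od_tab$fold == f]), numeric(1)),
    oc_f = vapply(seq_len(k), function(f)
      mean(oc_tab$f_score[oc_tab$fold == f]), numeric(1)))
  list(od = od_tab, oc = oc_tab, fold_means = fold_means,
       grand_mean = c(od_f = mean(fold_means$od_f),
                      oc_f = mean(fold_means$oc_f)))
}

#' Write a training history as CSV
#'
#' Columns: `t`, `n_t`, `k_t`, `mean_loss`, `mean_f`, `min_f`.
#'
#' @param fit an `msmku_fit`.
#' @param path output CSV.
#' @export
write_history <- function(fit, path) {
  write.csv(fit$history, path, row.names = FALSE)
  invisible(path)
}
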