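#' Specification of one synthetic fundus phantom
#'
#' A phantom is a fundus-like RGB image with exact elliptical disc and cup
#' masks.  The `style` field mirrors the clinically awkward minority of
#' images: `"small_cup"` forces the cup's vertical fraction to at most 0.2,
#' `"low_contrast"` caps the cup-rim contrast at 0.15 so the cup outline is
#' barely visible; `"typical"` phantoms have a clear, moderate cup.
#'
#' @param side image side in pixels.
#' @param disc_center `(row, col)` of the disc ellipse centre.
#' @param disc_axes `(a_r, a_c)` disc semi-axes in pixels.
#' @param cup_frac `(f_r, f_c)` cup semi-axes as fractions of the disc axes,
#'   in (0, 1); `f_r` equals the analytic VCDR.
#' @param cup_offset `(dr, dc)` cup centre offset from the disc centre in
#'   pixels; the cup ellipse must stay inside the disc ellipse.
#' @param contrast cup-rim contrast in `[0, 1]` (0 = invisible cup).
#' @param n_vessels number of dark vessel strokes crossing the disc.
#' @param noise_sigma Gaussian pixel-noise standard deviation.
#' @param style one of `"typical"`, `"small_cup"`, `"low_contrast"`.
#' @param seed seed for vessels and noise.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(side = 128L,
                         disc_center = c(side / 2, side / 2),
                         disc_axes = c(0.17, 0.17) * side,
                         cup_frac = c(0.5, 0.5),
                         cup_offset = c(0, 0),
                         contrast = 0.7,
                         n_vessels = 4L,
                         noise_sigma = 0.02,
                         style = c("typical", "small_cup", "low_contrast"),
                         seed = 1L) {
  style <- match.arg(style)
  if (any(cup_frac <= 0) || any(cup_frac >= 1))
    stop("cup fractions must lie in (0, 1)")
  if (style == "small_cup" && cup_frac[1] > 0.2)
    stop("small_cup style requires cup vertical fraction <= 0.2")
  if (style == "low_contrast" && contrast > 0.15)
    stop("low_contrast style requires contrast <= 0.15")
  # sufficient condition for the cup ellipse to lie inside the disc ellipse
  if (abs(cup_offset[1]) > (1 - cup_frac[1]) * disc_axes[1] ||
      abs(cup_offset[2]) > (1 - cup_frac[2]) * disc_axes[2])
    stop("cup ellipse leaves the disc ellipse")
  structure(list(side = as.integer(side), disc_center = disc_center,
                 disc_axes = disc_axes, cup_frac = cup_frac,
                 cup_offset = cup_offset, contrast = contrast,
                 n_vessels = as.integer(n_vessels),
                 noise_sigma = noise_sigma, style = style,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Analytic vertical cup-to-disc ratio of a phantom
#'
#' `(2 * cup a_r) / (2 * disc a_r)`, i.e. the cup's vertical fraction.
#'
#' @param spec a [phantom_spec()].
#' @return VCDR in (0, 1).
#' @export
ground_truth_vcdr <- function(spec) spec$cup_frac[1]

# signed ellipse field: <= 1 inside
ellipse_field <- function(side, center, axes) {
  r <- matrix(seq_len(side), side, side)
  c <- matrix(seq_len(side), side, side, byrow = TRUE)
  ((r - center[1]) / axes[1])^2 + ((c - center[2]) / axes[2])^2
}

# smooth 1 -> 0 transition of the ellipse edge over ~1.5 px
soft_edge <- function(field, axes) {
  w <- 1.5 / mean(axes)
  pmin(pmax((1 + w - field) / (2 * w), 0), 1)
}

#' Render a phantom image and its exact disc/cup masks
#'
#' The disc and cup are filled ellipses with smooth colour gradients (cup
#' colour blended towards the disc colour by `contrast`), dark quadratic
#' Bezier vessel strokes cross the disc, and Gaussian pixel noise is added.
#' The returned masks are the exact ellipse interiors, unaffected by
#' vessels or noise.
#'
#' @param spec a [phantom_spec()].
#' @return `list(image = side x side x 3 array, od_mask =, oc_mask =)`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  s <- spec$side
  bg_col <- c(0.72, 0.32, 0.12)
  disc_col <- c(0.93, 0.76, 0.42)
  cup_col <- c(0.99, 0.93, 0.72)
  fd <- ellipse_field(s, spec$disc_center, spec$disc_axes)
  cup_center <- spec$disc_center + spec$cup_offset
  cup_axes <- spec$cup_frac * spec$disc_axes
  fc <- ellipse_field(s, cup_center, cup_axes)
  a_disc <- soft_edge(fd, spec$disc_axes)
  a_cup <- soft_edge(fc, cup_axes)
  # mild radial vignette over the background
  vign <- 1 - 0.25 * ellipse_field(s, c(s / 2, s / 2), c(s, s))
  img <- array(0, c(s, s, 3))
  cup_eff <- disc_col + spec$contrast * (cup_col - disc_col)
  for (ch in 1:3) {
    base <- bg_col[ch] * vign
    base <- base * (1 - a_disc) + disc_col[ch] * a_disc
    img[, , ch] <- base * (1 - a_cup) + cup_eff[ch] * a_cup
  }
  img <- draw_vessels(img, spec)
  if (spec$noise_sigma > 0)
    img <- img + array(rnorm(s * s * 3, sd = spec$noise_sigma), c(s, s, 3))
  img <- pmin(pmax(img, 0), 1)
  list(image = img,
       od_mask = (fd <= 1) * 1L,
       oc_mask = (fc <= 1) * 1L)
}

# dark curvilinear vessels as quadratic Bezier strokes through the disc
draw_vessels <- function(img, spec) {
  s <- spec$side
  vessel_col <- c(0.40, 0.07, 0.07)
  half_w <- max(1, round(s / 90))
  for (v in seq_len(spec$n_vessels)) {
    p0 <- spec$disc_center + runif(2, -0.3, 0.3) * spec$disc_axes
    theta <- runif(1, 0, 2 * pi)
    p2 <- c(s / 2, s / 2) + 1.2 * s * c(cos(theta), sin(theta))
    p2 <- pmin(pmax(p2, 1), s)
    p1 <- (p0 + p2) / 2 + runif(2, -0.15, 0.15) * s
    tt <- seq(0, 1, length.out = 4 * s)
    pts <- cbind((1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1],
                 (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2])
    pts <- round(pts)
    keep <- pts[, 1] >= 1 & pts[, 1] <= s & pts[, 2] >= 1 & pts[, 2] <= s
    pts <- unique(pts[keep, , drop = FALSE])
    for (dw in seq(-half_w, half_w)) {
      rr <- pmin(pmax(pts[, 1] + dw, 1), s)
      cc <- pts[, 2]
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[cbind(rr, cc)] <- 0.65 * pl[cbind(rr, cc)] + 0.35 * vessel_col[ch]
        img[, , ch] <- pl
      }
    }
  }
  img
}

#' Generate a labelled phantom dataset with an imbalanced style mix
#'
#' Draws `n` randomised phantom specs; `ceiling(rare_fraction * n)` of them
#' use a rare style (alternating `small_cup` / `low_contrast`), the rest are
#' typical.  The glaucoma label is 1 iff the VCDR of the rendered
#' ground-truth masks exceeds 0.6, so screening from perfect masks separates
#' the classes exactly.  Fully deterministic in `seed`.
#'
#' @param n number of phantoms.
#' @param rare_fraction fraction of rare-style phantoms in `[0, 1)`.
#' @param side image side in pixels.
#' @param seed master seed.
#' @return list with `items` (each `list(image, od_mask, oc_mask, style,
#'   vcdr_analytic, vcdr, label)`) and the call parameters.
#' @export
generate_dataset <- function(n, rare_fraction = 0.1, side = 64L, seed = 1L) {
  stopifnot(rare_fraction >= 0, rare_fraction < 1, n >= 1)
  set.seed(seed)
  n_rare <- ceiling(rare_fraction * n)
  styles <- rep("typical", n)
  if (n_rare > 0) {
    rare_idx <- sample.int(n, n_rare)
    styles[rare_idx] <- rep(c("small_cup", "low_contrast"),
                            length.out = n_rare)
  }
  item_seeds <- sample.int(2^30, n)
  items <- vector("list", n)
  for (i in seq_len(n)) {
    st <- styles[i]
    axes <- runif(2, 0.14, 0.20) * side
    center <- side / 2 + runif(2, -0.08, 0.08) * side
    frac_r <- switch(st,
                     typical = runif(1, 0.25, 0.80),
                     small_cup = runif(1, 0.08, 0.20),
                     low_contrast = runif(1, 0.25, 0.80))
    frac_c <- pmin(pmax(frac_r + runif(1, -0.05, 0.05), 0.05), 0.95)
    contrast <- switch(st,
                       typical = runif(1, 0.40, 0.90),
                       small_cup = runif(1, 0.40, 0.90),
                       low_contrast = runif(1, 0.05, 0.15))
    offset <- runif(2, -0.5, 0.5) * (1 - c(frac_r, frac_c)) * axes
    spec <- phantom_spec(side = side, disc_center = center, disc_axes = axes,
                         cup_frac = c(frac_r, frac_c), cup_offset = offset,
                         contrast = contrast,
                         n_vessels = sample(3:6, 1),
                         noise_sigma = runif(1, 0.01, 0.03),
                         style = st, seed = item_seeds[i])
    ph <- generate_phantom(spec)
    vcdr <- compute_vcdr(ph$od_mask, ph$oc_mask)
    items[[i]] <- list(image = ph$image, od_mask = ph$od_mask,
                       oc_mask = ph$oc_mask, style = st, spec = spec,
                       vcdr_analytic = ground_truth_vcdr(spec),
                       vcdr = vcdr, label = as.integer(vcdr > 0.6))
  }
  list(items = items, n = n, rare_fraction = rare_fraction, side = side,
       seed = seed)
}
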