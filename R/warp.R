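# Vectorised geometric resampling: resize, rotation and translation for
# images (H x W x C arrays in [0,1]) and binary masks (H x W matrices).
# Images are interpolated bilinearly; masks use nearest neighbour so they
# stay binary.  All coordinates are (row, col), 0-based internally.

# fold an integer index into [0, n-1] by symmetric reflection at the borders
reflect_index <- function(i, n) {
  n2 <- 2L * n
  j <- ((i %% n2) + n2) %% n2
  ifelse(j >= n, n2 - 1L - j, j)
}

clamp_index <- function(i, n) pmin(pmax(i, 0L), n - 1L)

# Sample one channel at fractional source coordinates (sr, sc).
# edge: "clamp" (resize) or "reflect" (augmentation fill).
sample_channel <- function(ch, sr, sc, method, edge) {
  H <- nrow(ch); W <- ncol(ch)
  fix <- if (edge == "reflect") reflect_index else clamp_index
  if (method == "nearest") {
    i <- fix(as.integer(floor(sr + 0.5)), H)
    j <- fix(as.integer(floor(sc + 0.5)), W)
    ch[cbind(i + 1L, j + 1L)]
  } else {
    i0 <- as.integer(floor(sr)); fr <- sr - i0
    j0 <- as.integer(floor(sc)); fc <- sc - j0
    i0c <- fix(i0, H); i1c <- fix(i0 + 1L, H)
    j0c <- fix(j0, W); j1c <- fix(j0 + 1L, W)
    v00 <- ch[cbind(i0c + 1L, j0c + 1L)]
    v10 <- ch[cbind(i1c + 1L, j0c + 1L)]
    v01 <- ch[cbind(i0c + 1L, j1c + 1L)]
    v11 <- ch[cbind(i1c + 1L, j1c + 1L)]
    (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
  }
}

# generic sampler: source coords given as vectors over the output grid
sample_grid <- function(x, sr, sc, out_h, out_w, method, edge) {
  if (length(dim(x)) == 3L) {
    out <- array(0, c(out_h, out_w, dim(x)[3]))
    for (c in seq_len(dim(x)[3]))
      out[, , c] <- matrix(sample_channel(x[, , c], sr, sc, method, edge),
                           out_h, out_w)
    out
  } else {
    matrix(sample_channel(x, sr, sc, method, edge), out_h, out_w)
  }
}

scale_coords <- function(n_out, n_in) ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5

#' Resize an image or mask
#'
#' Images (3-D arrays) are interpolated bilinearly, masks (matrices) by
#' nearest neighbour so the output stays binary.
#'
#' @param x image array `H x W x C` or mask matrix.
#' @param out_h,out_w output size in pixels.
#' @return resized array/matrix of the same kind.
#' @export
resize_grid <- function(x, out_h, out_w) {
  d <- dim(x)
  method <- if (length(d) == 3L) "bilinear" else "nearest"
  sr <- rep(scale_coords(out_h, d[1]), times = out_w)
  sc <- rep(scale_coords(out_w, d[2]), each = out_h)
  sample_grid(x, sr, sc, out_h, out_w, method, edge = "clamp")
}

# rotation (degrees, about the image centre) + translation (rows, cols),
# inverse-mapped so output pixel (r,c) samples the source; reflection fill.
warp_rigid <- function(x, angle_deg, dr, dc, method) {
  d <- dim(x); H <- d[1]; W <- d[2]
  th <- angle_deg * pi / 180
  ctr_r <- (H - 1) / 2; ctr_c <- (W - 1) / 2
  r <- rep(seq_len(H) - 1, times = W) - ctr_r - dr
  c <- rep(seq_len(W) - 1, each = H) - ctr_c - dc
  sr <- cos(th) * r + sin(th) * c + ctr_r
  sc <- -sin(th) * r + cos(th) * c + ctr_c
  sample_grid(x, sr, sc, H, W, method, edge = "reflect")
}
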