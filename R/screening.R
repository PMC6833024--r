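#' Vertical extent of a binary mask in pixels
#'
#' The vertical diameter is the bounding-box row extent
#' (`max occupied row - min occupied row + 1`); 0 for an empty mask.
#'
#' @param mask binary matrix.
#' @return integer pixel count.
#' @export
vertical_diameter <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  if (length(rows) == 0) return(0L)
  as.integer(max(rows) - min(rows) + 1L)
}

#' Vertical cup-to-disc ratio from a disc and a cup mask
#'
#' VCDR = vertical cup diameter / vertical disc diameter; the classic
#' glaucoma indicator (healthy eyes have small cups, advanced glaucoma
#' pushes the ratio towards 1).
#'
#' @param od,oc binary masks of equal size (disc and cup).
#' @return VCDR; 0 when the cup mask is empty.
#' @export
compute_vcdr <- function(od, oc) {
  stopifnot(all(dim(od) == dim(oc)))
  vdd <- vertical_diameter(od)
  if (vdd == 0) stop("compute_vcdr: disc mask is empty")
  vertical_diameter(oc) / vdd
}

#' Mean neuroretinal rim width per ISNT sector
#'
#' Rays are cast from the disc centroid at 1-degree steps; along each ray the
#' rim width is the distance between the cup boundary crossing and the disc
#' boundary crossing (the cup crossing degenerates to the centroid when the
#' cup is empty along that ray).  Widths are averaged over four 90-degree
#' quadrants: inferior (image-down), superior (image-up), and the two
#' horizontal quadrants assigned to nasal/temporal by eye laterality.
#'
#' @param od,oc binary masks (cup is intersected with the disc internally).
#' @param eye `"right"` (nasal = image-left, the default) or `"left"`.
#' @return named numeric vector `c(I =, S =, N =, T =)` in pixels.
#' @export
rim_widths <- function(od, oc, eye = c("right", "left")) {
  eye <- match.arg(eye)
  stopifnot(all(dim(od) == dim(oc)))
  occ <- which(od == 1, arr.ind = TRUE)
  if (nrow(occ) == 0) stop("rim_widths: disc mask is empty")
  oc <- oc * od
  ctr <- colMeans(occ)
  H <- nrow(od); W <- ncol(od)
  max_r <- sqrt(H^2 + W^2)
  angles <- (0:359) * pi / 180  # 0 = image-down, 90 deg = image-right
  steps <- seq(0, max_r, by = 0.5)
  widths <- numeric(360)
  for (a in seq_along(angles)) {
    dr <- cos(angles[a]); dc <- sin(angles[a])
    rr <- round(ctr[1] + steps * dr)
    cc <- round(ctr[2] + steps * dc)
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    rr <- rr[ok]; cc <- cc[ok]; st <- steps[ok]
    ii <- cbind(rr, cc)
    in_od <- od[ii] == 1
    in_oc <- oc[ii] == 1
    r_od <- if (any(in_od)) max(st[in_od]) else 0
    r_oc <- if (any(in_oc)) max(st[in_oc]) else 0
    widths[a] <- max(r_od - r_oc, 0)
  }
  deg <- 0:359
  sector <- function(center) {
    d <- (deg - center) %% 360
    d <- pmin(d, 360 - d)
    mean(widths[d < 45])
  }
  inferior <- sector(0)
  superior <- sector(180)
  right_w <- sector(90)   # image-right
  left_w <- sector(270)   # image-left
  if (eye == "right") c(I = inferior, S = superior, N = left_w, T = right_w)
  else c(I = inferior, S = superior, N = right_w, T = left_w)
}

#' ISNT score: how much of the healthy rim-width ordering holds
#'
#' In healthy eyes the rim is thickest inferiorly, then superiorly, then
#' nasally, thinnest temporally.  The score counts the strict inequalities
#' satisfied among `I > S`, `S > N`, `N > T` (0-3); low scores suggest
#' glaucoma.
#'
#' @param widths named vector from [rim_widths()].
#' @return integer 0-3.
#' @export
isnt_score <- function(widths) {
  stopifnot(all(widths >= 0))
  sum(widths["I"] > widths["S"], widths["S"] > widths["N"],
      widths["N"] > widths["T"])
}

#' Combined screening score from VCDR and the ISNT score
#'
#' `vcdr + gamma * (3 - isnt) / 3`; with the default `gamma = 0` the score
#' reduces to VCDR alone.
#'
#' @param vcdr vertical cup-to-disc ratio.
#' @param isnt ISNT score (0-3).
#' @param gamma weight of the ISNT deficit term.
#' @return screening score (higher = more suspicious).
#' @export
screening_score <- function(vcdr, isnt, gamma = 0) {
  vcdr + gamma * (3 - isnt) / 3
}

#' Absolute VCDR error between reference and prediction
#'
#' @param true_vcdr,pred_vcdr VCDR values.
#' @return `|true - pred|`.
#' @export
vcdr_difference <- function(true_vcdr, pred_vcdr) abs(true_vcdr - pred_vcdr)

#' Screening record for one eye from its disc and cup masks
#'
#' @inheritParams rim_widths
#' @param gamma passed to [screening_score()].
#' @return list of class `screening_record`: `vcd`, `vdd`, `vcdr`, rim
#'   `widths`, `isnt_score`, `screening_score`.
#' @export
screening_record <- function(od, oc, eye = "right", gamma = 0) {
  w <- rim_widths(od, oc, eye)
  vdd <- vertical_diameter(od)
  vcd <- vertical_diameter(oc)
  vcdr <- compute_vcdr(od, oc)
  isnt <- isnt_score(w)
  structure(list(vcd = vcd, vdd = vdd, vcdr = vcdr, widths = w,
                 isnt_score = isnt,
                 screening_score = screening_score(vcdr, isnt, gamma)),
            class = "screening_record")
}

#' @export
print.screening_record <- function(x, ...) {
  cat(sprintf("VCDR %.3f (VCD %d / VDD %d); rim I/S/N/T = %s; ISNT %d\n",
              x$vcdr, x$vcd, x$vdd,
              paste(sprintf("%.1f", x$widths), collapse = "/"),
              x$isnt_score))
  invisible(x)
}
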