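# Lobe triangularity: equal-area triangle/disc intersection-over-union
# scoring of segmented lobe masks, formalizing the visual "triangular lobe"
# assessment.

#' Segment a lobe mask from a lobe box
#'
#' Otsu threshold on a bright-lobe box, keeping the largest connected
#' component and filling holes (EBImage primitives).
#'
#' @param img numeric matrix, single-lobe box, bright-lobe polarity.
#' @return a binary (0/1) matrix of the lobe mask.
#' @export
lobe_mask <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0) stop("lobe_mask: empty foreground (flat image)")
  sc <- (img - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(sc))
  fg <- sc > th
  if (!any(fg)) stop("lobe_mask: empty foreground")
  lab <- EBImage::bwlabel(EBImage::Image(fg))
  lab <- EBImage::imageData(lab)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  mask <- (lab == keep)
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  matrix(as.numeric(EBImage::imageData(mask) > 0), nrow(img), ncol(img))
}

# equal-area equilateral triangle membership at rotation theta (rad)
triangle_membership <- function(dx, dy, area, theta) {
  side <- sqrt(4 * area / sqrt(3))
  R <- side / sqrt(3)
  ang <- theta + c(0, 2, 4) * pi / 3
  v <- cbind(R * cos(ang), R * sin(ang))
  signed_dist_triangle(dx, dy, v) <= 0
}

#' Triangularity score of a lobe mask
#'
#' `T = max_theta IoU(mask, equal-area equilateral triangle) - IoU(mask,
#' equal-area disc)`, both reference shapes centred at the mask centroid.
#' The rotation search runs at `step` degree resolution over `[0, 120)`
#' (triangle symmetry). `T > 0` reads "more triangular than round".
#'
#' @param mask binary matrix from [lobe_mask()].
#' @param pixel_size nm per pixel.
#' @param center_angle optional direction (degrees, in the lobe frame) from
#'   the lobe towards the particle centre; when given, the angular offset of
#'   the nearest best-fit triangle vertex to that direction is reported in
#'   `vertex_to_center` (degrees in `[-60, 60]`).
#' @param step rotation search step, degrees.
#' @return a one-row data frame (`T`, `iou_triangle`, `iou_disc`,
#'   `rotation`, `vertex_to_center`, `area_nm2`, `low_confidence`). The
#'   `low_confidence` flag marks masks touching the box border.
#' @export
triangularity <- function(mask, pixel_size, center_angle = NULL, step = 1) {
  m <- mask > 0
  if (!any(m)) stop("triangularity: empty mask")
  nr <- nrow(m); nc <- ncol(m)
  touches <- any(m[1, ]) || any(m[nr, ]) || any(m[, 1]) || any(m[, nc])
  idx <- which(m)
  rows <- (idx - 1) %% nr + 1
  cols <- (idx - 1) %/% nr + 1
  cy <- mean(rows); cx <- mean(cols)
  area_px <- length(idx)
  area_nm2 <- area_px * pixel_size^2

  all_r <- rep(seq_len(nr), times = nc)
  all_c <- rep(seq_len(nc), each = nr)
  dx <- (all_c - cx) * pixel_size
  dy <- (all_r - cy) * pixel_size
  mv <- as.logical(m)

  rd <- sqrt(area_nm2 / pi)
  disc <- (dx^2 + dy^2) <= rd^2
  iou_disc <- sum(mv & disc) / sum(mv | disc)

  best_iou <- -1; best_theta <- 0
  for (th_deg in seq(0, 120 - step, by = step)) {
    tri <- triangle_membership(dx, dy, area_nm2, th_deg * pi / 180)
    iou <- sum(mv & tri) / sum(mv | tri)
    if (iou > best_iou) { best_iou <- iou; best_theta <- th_deg }
  }

  v2c <- NA_real_
  if (!is.null(center_angle)) {
    verts <- (best_theta + c(0, 120, 240)) %% 360
    diffs <- ((verts - center_angle + 180) %% 360) - 180
    v2c <- diffs[which.min(abs(diffs))]
  }
  data.frame(T = best_iou - iou_disc,
             iou_triangle = best_iou, iou_disc = iou_disc,
             rotation = best_theta, vertex_to_center = v2c,
             area_nm2 = area_nm2, low_confidence = touches)
}

#' Fraction of triangular lobes versus strictness threshold
#'
#' Sweeps a triangularity threshold and reports, for each value, the
#' fraction of lobes with score strictly above it. The curve is
#' non-increasing by construction; no single "true" triangular fraction is
#' claimed, mirroring the fact that the visual criterion has no unique
#' strictness.
#'
#' @param scores numeric vector of triangularity scores (or the data frame
#'   from [triangularity()] rows, column `T`).
#' @param thresholds threshold grid; defaults to `seq(-0.5, 0.5, 0.01)`.
#' @return a data frame with `threshold` and `fraction`.
#' @export
triangular_fraction <- function(scores, thresholds = seq(-0.5, 0.5, 0.01)) {
  if (is.data.frame(scores)) scores <- scores$T
  if (!length(scores)) stop("triangular_fraction: no scores")
  data.frame(threshold = thresholds,
             fraction = vapply(thresholds,
                               function(t) mean(scores > t), 0))
}

#' Score all lobes of a stack
#'
#' Convenience wrapper: segments and scores every lobe box in a stack.
#'
#' @param stack a `csc_stack` of bright-lobe boxes.
#' @param center_angles optional vector of centre directions (degrees), one
#'   per lobe box.
#' @param step rotation search step, degrees.
#' @return a data frame of [triangularity()] rows.
#' @export
score_lobes <- function(stack, center_angles = NULL, step = 1) {
  rows <- lapply(seq_along(stack$images), function(i) {
    res <- tryCatch({
      msk <- lobe_mask(stack$images[[i]])
      triangularity(msk, stack$pixel_size,
                    center_angle = if (is.null(center_angles)) NULL
                    else center_angles[i],
                    step = step)
    }, error = function(e) NULL)
    if (!is.null(res)) res$lobe <- i
    res
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
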