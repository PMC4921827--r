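# Reference-free 2D alignment, stability-filtered classification, and class
# averaging of boxed particle and lobe images.

#' Construct a particle stack
#'
#' A stack of equal-size boxed sub-images sharing one physical scale,
#' analogous to a single-particle box file.
#'
#' @param images list of numeric matrices, all the same dimensions.
#' @param pixel_size nm per pixel.
#' @param box_size box edge length in nm (consistent with the raster shape).
#' @param coords optional data frame of source coordinates (one row per
#'   image).
#' @param polarity `"dark"` or `"bright"` particle polarity.
#' @return an object of class `csc_stack`.
#' @export
particle_stack <- function(images, pixel_size, box_size = NULL,
                           coords = NULL, polarity = "bright") {
  if (!length(images)) stop("particle_stack: empty image list")
  d <- dim(images[[1]])
  if (!all(vapply(images, function(i) identical(dim(i), d), TRUE)))
    stop("particle_stack: images differ in shape")
  if (is.null(box_size)) box_size <- d[2] * pixel_size
  if (abs(box_size / pixel_size - d[2]) > 1)
    stop("particle_stack: box_size inconsistent with raster shape")
  structure(list(images = images, pixel_size = pixel_size,
                 box_size = box_size, coords = coords,
                 polarity = polarity),
            class = "csc_stack")
}

#' @export
length.csc_stack <- function(x) length(x$images)

#' Invert image contrast
#'
#' Maps intensities by `max + min - I` per image, turning dark replica
#' lobes into the bright particles expected by the averaging stages.
#' Applying it twice returns the original image exactly.
#'
#' @param x a `csc_stack`, `csc_micrograph`, or numeric matrix.
#' @return the same type, inverted; stack/micrograph polarity flags are
#'   flipped.
#' @export
invert_contrast <- function(x) {
  flip <- function(polarity) if (polarity == "dark") "bright" else "dark"
  inv <- function(img) {
    rng <- range(img)
    rng[1] + rng[2] - img
  }
  if (inherits(x, "csc_stack")) {
    x$images <- lapply(x$images, inv)
    x$polarity <- flip(x$polarity)
    x
  } else if (inherits(x, "csc_micrograph")) {
    x$image <- inv(x$image)
    x$polarity <- flip(x$polarity)
    x
  } else inv(x)
}

#' Box particles out of a micrograph
#'
#' Extracts square boxes centred on given nm coordinates. Box sizes in nm
#' are converted to the nearest odd pixel count so every box has a centre
#' pixel. Boxes that would cross the image boundary are skipped and logged.
#'
#' @param micrograph a `csc_micrograph`.
#' @param centers two-column matrix of box centres (x, y in nm).
#' @param box_nm box edge length in nm (default 31.6, the rosette box).
#' @return a `csc_stack`; skipped centre indices are in attribute
#'   `"skipped"`.
#' @export
box_particles <- function(micrograph, centers, box_nm = 31.6) {
  px <- micrograph$pixel_size
  p <- odd_pixel_count(box_nm, px)
  half <- (p - 1L) %/% 2L
  img <- micrograph$image
  nr <- nrow(img); nc <- ncol(img)
  centers <- as.matrix(centers)
  images <- list(); kept <- integer(); skipped <- integer()
  for (i in seq_len(nrow(centers))) {
    cc <- round(centers[i, 1] / px + 0.5)
    cr <- round(centers[i, 2] / px + 0.5)
    if (cr - half < 1 || cr + half > nr || cc - half < 1 || cc + half > nc) {
      skipped <- c(skipped, i)
      next
    }
    images[[length(images) + 1]] <-
      img[(cr - half):(cr + half), (cc - half):(cc + half)]
    kept <- c(kept, i)
  }
  if (length(skipped))
    message("box_particles: skipped ", length(skipped),
            " box(es) at the image boundary")
  if (!length(images)) stop("box_particles: no boxes inside the image")
  st <- particle_stack(images, px, box_size = p * px,
                       coords = data.frame(index = kept,
                                           x = centers[kept, 1],
                                           y = centers[kept, 2]),
                       polarity = micrograph$polarity)
  attr(st, "skipped") <- skipped
  st
}

# nearest odd pixel count for a box size in nm
odd_pixel_count <- function(box_nm, pixel_size) {
  p <- round(box_nm / pixel_size)
  if (p %% 2 == 0) {
    lo <- p - 1L; hi <- p + 1L
    p <- if (abs(lo * pixel_size - box_nm) < abs(hi * pixel_size - box_nm))
      lo else hi
  }
  max(3L, as.integer(p))
}

#' Pick lobe boxes
#'
#' Extracts lobe-sized boxes (default 10.3 nm) around given lobe centres,
#' producing a stack suitable for 6- or 12-class averaging.
#'
#' @param micrograph a `csc_micrograph`.
#' @param lobe_centers two-column matrix of lobe centres (x, y in nm).
#' @param lobe_box box edge length in nm; 10.3 by default (10.6 is also in
#'   circulation for the same data; both are accepted here).
#' @return a `csc_stack` of lobe boxes.
#' @export
pick_lobes <- function(micrograph, lobe_centers, lobe_box = 10.3) {
  box_particles(micrograph, lobe_centers, box_nm = lobe_box)
}

# --- geometry helpers -------------------------------------------------------

# bilinear rotation about the image centre; out-of-frame samples take the
# image mean so rotation does not inject contrast
rotate_bilinear <- function(img, angle_deg) {
  if (angle_deg %% 360 == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  th <- angle_deg * pi / 180
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  out_r <- rep(seq_len(nr), times = nc) - cr
  out_c <- rep(seq_len(nc), each = nr) - cc
  # inverse mapping
  src_c <- cos(th) * out_c + sin(th) * out_r + cc
  src_r <- -sin(th) * out_c + cos(th) * out_r + cr
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  fill <- mean(img)
  at <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- rep(fill, length(r))
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  v <- (1 - fr) * (1 - fc) * at(r0, c0) +
    (1 - fr) * fc * at(r0, c0 + 1) +
    fr * (1 - fc) * at(r0 + 1, c0) +
    fr * fc * at(r0 + 1, c0 + 1)
  matrix(v, nr, nc)
}

# integer shift with mean fill (non-circular)
shift_image <- function(img, dr, dc) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(mean(img), nr, nc)
  sr <- seq_len(nr) - dr; sc <- seq_len(nc) - dc
  okr <- sr >= 1 & sr <= nr; okc <- sc >= 1 & sc <= nc
  out[okr, okc] <- img[sr[okr], sc[okc]]
  out
}

# cross-correlation over integer shifts (FFT, wrap-around), restricted to
# |shift| <= max_shift; returns list(dr, dc, score)
best_shift <- function(img, ref_fft, max_shift) {
  nr <- nrow(img); nc <- ncol(img)
  cc <- Re(fft(ref_fft * Conj(fft(img)), inverse = TRUE)) / (nr * nc)
  sh_r <- c(0:(nr - 1)); sh_r[sh_r > nr / 2] <- sh_r[sh_r > nr / 2] - nr
  sh_c <- c(0:(nc - 1)); sh_c[sh_c > nc / 2] <- sh_c[sh_c > nc / 2] - nc
  mask_r <- abs(sh_r) <= max_shift
  mask_c <- abs(sh_c) <= max_shift
  sub <- cc[mask_r, mask_c, drop = FALSE]
  k <- arrayInd(which.max(sub), dim(sub))
  list(dr = sh_r[mask_r][k[1]], dc = sh_c[mask_c][k[2]],
       score = max(sub))
}

normalize_image <- function(img) {
  s <- sd(img)
  if (s == 0) return(NULL)
  (img - mean(img)) / s
}

#' Reference-free iterative alignment of a particle stack
#'
#' Aligns a stack to an evolving average: the initial reference is the
#' unaligned mean; each round, every image is aligned to the reference over
#' a grid of in-plane rotations (at `angle_step`) and integer translations
#' (cross-correlation peak within `max_shift_frac` of the box), and the
#' reference is re-averaged. Iteration stops after `n_iter` rounds, when the
#' median shift falls below 0.1 pixel, or when the objective (mean
#' correlation to the reference) would decrease, which keeps the objective
#' non-decreasing. Zero-variance images are excluded with a warning.
#'
#' @param stack a `csc_stack` (bright-particle polarity recommended).
#' @param n_iter maximum number of refinement rounds.
#' @param angle_step rotation search step, degrees.
#' @param max_shift_frac translation search bound as a fraction of the box.
#' @param seed integer seed (alignment itself is deterministic; the seed
#'   fixes tie-breaking through a reproducible image order).
#' @return a list: `stack` (aligned), `transforms` (data frame with
#'   `rotation` deg, `dx`, `dy` in nm), `reference` (final average),
#'   `objective` (per-iteration mean correlation), `excluded` (indices of
#'   zero-variance images).
#' @export
align_stack <- function(stack, n_iter = 8, angle_step = 1,
                        max_shift_frac = 0.25, seed = 20160627L) {
  imgs <- stack$images
  norm <- lapply(imgs, normalize_image)
  excluded <- which(vapply(norm, is.null, TRUE))
  if (length(excluded)) {
    warning("align_stack: excluding ", length(excluded),
            " blank (zero-variance) image(s)")
    keep <- setdiff(seq_along(imgs), excluded)
  } else keep <- seq_along(imgs)
  if (length(keep) < 2) stop("align_stack: need >= 2 non-blank images")
  imgs <- imgs[keep]
  norm <- norm[keep]
  n <- length(imgs)
  nrp <- nrow(imgs[[1]])
  max_shift <- max(1L, floor(max_shift_frac * nrp))
  angles <- seq(0, 360 - angle_step, by = angle_step)

  # per-image cache of normalized rotated versions, built lazily per round
  cur <- norm                 # current aligned (normalized) images
  rot <- rep(0, n); dr <- rep(0L, n); dc <- rep(0L, n)
  objective <- numeric(0)
  prev_obj <- -Inf

  # Each sweep realigns images sequentially against the leave-one-out
  # average (the reference excludes the image being aligned, removing the
  # self-bias a plain evolving average suffers from). A sweep that lowers
  # the objective (mean correlation to the full average) is reverted, so
  # the reported objective is non-decreasing.
  for (it in seq_len(n_iter)) {
    prev_state <- list(rot = rot, dr = dr, dc = dc, cur = cur)
    shifts <- numeric(n); rot_change <- numeric(n)
    for (i in seq_len(n)) {
      others <- Reduce(`+`, cur[-i]) / (n - 1)
      refn <- normalize_image(others)
      if (is.null(refn)) next
      ref_fft <- fft(refn)
      best <- list(score = -Inf)
      for (a in angles) {
        ri <- if (a == 0) norm[[i]] else rotate_bilinear(norm[[i]], a)
        bs <- best_shift(ri, ref_fft, max_shift)
        if (bs$score > best$score)
          best <- list(score = bs$score, angle = a, dr = bs$dr, dc = bs$dc,
                       img = ri)
      }
      shifts[i] <- sqrt((best$dr - dr[i])^2 + (best$dc - dc[i])^2)
      dth <- abs(best$angle - rot[i]) %% 360
      rot_change[i] <- min(dth, 360 - dth)
      rot[i] <- best$angle; dr[i] <- best$dr; dc[i] <- best$dc
      cur[[i]] <- shift_image(best$img, best$dr, best$dc)
    }
    refn <- normalize_image(Reduce(`+`, cur) / n)
    obj <- mean(vapply(cur, function(ai) {
      sum(ai * refn) / (length(ai) - 1) / max(sd(ai), .Machine$double.eps)
    }, 0))
    if (obj < prev_obj) {  # revert; keep the objective non-decreasing
      rot <- prev_state$rot; dr <- prev_state$dr; dc <- prev_state$dc
      cur <- prev_state$cur
      break
    }
    objective <- c(objective, obj)
    prev_obj <- obj
    if (median(shifts) < 0.1 && median(rot_change) < angle_step) break
  }

  px <- stack$pixel_size
  out_imgs <- vector("list", n)
  for (i in seq_len(n))
    out_imgs[[i]] <- shift_image(
      if (rot[i] == 0) imgs[[i]] else rotate_bilinear(imgs[[i]], rot[i]),
      dr[i], dc[i])
  out <- particle_stack(out_imgs, px, box_size = stack$box_size,
                        coords = stack$coords, polarity = stack$polarity)
  list(stack = out,
       transforms = data.frame(index = keep, rotation = rot %% 360,
                               dx = dc * px, dy = dr * px),
       reference = Reduce(`+`, out_imgs) / n,
       objective = objective,
       excluded = excluded)
}

# greedy best-Jaccard matching of partition B's classes onto A's
match_classes <- function(a, b, K) {
  jac <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    ai <- a == i; bj <- b == j
    u <- sum(ai | bj)
    jac[i, j] <- if (u == 0) 0 else sum(ai & bj) / u
  }
  map <- integer(K); best <- numeric(K)
  used <- rep(FALSE, K)
  for (i in order(apply(jac, 1, max), decreasing = TRUE)) {
    j <- order(jac[i, ], decreasing = TRUE)
    j <- j[!used[j]][1]
    map[i] <- j; used[j] <- TRUE
    best[i] <- jac[i, j]
  }
  list(map = map, jaccard = best)
}

#' Stability-filtered classification and class averaging
#'
#' Runs k-means on intensity-normalized pixel vectors of an aligned stack,
#' repeated over `n_trials` seeded trials, and retains a class only when its
#' membership is reproducible: the mean Jaccard overlap between the class
#' and its best match in every other trial must reach `min_overlap`.
#' Particles of unstable classes are left unassigned. This is an explicit
#' analogue of stable-class averaging as practised in single-particle 2D
#' classification, not a reimplementation of any specific program.
#'
#' Initial centres are drawn order-invariantly (images ranked by a seeded
#' random projection), so results do not depend on stack ordering.
#'
#' @param stack an aligned `csc_stack`.
#' @param K number of classes (default 6, the rosette convention).
#' @param n_trials number of repeated classification trials.
#' @param min_overlap minimum mean Jaccard for class retention.
#' @param seed integer seed.
#' @return an object of class `csc_classes`: `averages` (list of K
#'   matrices), `assignment` (integer vector, `NA` for unassigned),
#'   `stability` (length K), `sizes`, plus the `pixel_size`.
#' @export
classify_stable <- function(stack, K = 6, n_trials = 5, min_overlap = 0.5,
                            seed = 20160627L) {
  n <- length(stack$images)
  if (K < 1) stop("classify_stable: K must be >= 1")
  if (K > n) stop("classify_stable: K exceeds number of images")
  X <- t(vapply(stack$images, function(im) {
    v <- as.numeric(im)
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }, numeric(length(stack$images[[1]]))))

  set.seed(seed)
  w <- rnorm(ncol(X))
  ord <- order(as.numeric(X %*% w))   # order-invariant canonical ranking
  init_rows <- ord[unique(round(seq(1, n, length.out = K)))]
  while (length(init_rows) < K)       # degenerate tiny stacks
    init_rows <- c(init_rows, ord[1])

  partitions <- matrix(NA_integer_, n_trials, n)
  for (t in seq_len(n_trials)) {
    set.seed(seed + t)
    centers <- X[init_rows, , drop = FALSE] +
      matrix(rnorm(K * ncol(X), 0, 0.01 * (t > 1)), K)
    km <- suppressWarnings(
      kmeans(X, centers = centers, iter.max = 100, algorithm = "Lloyd"))
    partitions[t, ] <- km$cluster
  }

  ref <- partitions[1, ]
  if (n_trials > 1) {
    jmat <- matrix(0, n_trials - 1, K)
    for (t in 2:n_trials) {
      m <- match_classes(ref, partitions[t, ], K)
      jmat[t - 1, ] <- m$jaccard
    }
    stability <- colMeans(jmat)
  } else stability <- rep(1, K)

  assignment <- ref
  assignment[stability[ref] < min_overlap] <- NA_integer_
  averages <- lapply(seq_len(K), function(k) {
    idx <- which(assignment == k)
    if (!length(idx)) return(NULL)
    Reduce(`+`, stack$images[idx]) / length(idx)
  })
  structure(list(averages = averages, assignment = assignment,
                 stability = stability,
                 sizes = vapply(seq_len(K),
                                function(k) sum(assignment == k,
                                                na.rm = TRUE), 0L),
                 pixel_size = stack$pixel_size,
                 box_size = stack$box_size),
            class = "csc_classes")
}

#' Write a stack or class averages as a multi-page TIFF
#' @param x a `csc_stack` or `csc_classes`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(x, path) {
  imgs <- if (inherits(x, "csc_classes"))
    Filter(Negate(is.null), x$averages) else x$images
  imgs <- lapply(imgs, function(im) {
    rng <- range(im)
    if (diff(rng) == 0) im * 0 else (im - rng[1]) / diff(rng)
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}
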