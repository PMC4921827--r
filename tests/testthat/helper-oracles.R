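# Independent oracles and fixture builders shared across the test files.

# Brute-force minimum enclosing circle: enumerate every circle through two
# points (as a diameter) and every circumcircle through three points, keep
# the smallest one that covers the whole set. O(n^3), used only as an
# oracle against the incremental algorithm.
brute_sec <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  eps <- 1e-9
  covers <- function(ctr, r) {
    all((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 <=
          (r * (1 + eps) + 1e-12)^2)
  }
  best <- list(center = pts[1, ], radius = Inf)
  consider <- function(ctr, r) {
    if (r < best$radius && covers(ctr, r))
      best <<- list(center = ctr, radius = r)
  }
  if (n == 1) return(list(center = as.numeric(pts[1, ]), radius = 0))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]
    consider((a + b) / 2, sqrt(sum((a - b)^2)) / 2)
  }
  if (n >= 3) {
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      a <- pts[i, ]; b <- pts[j, ]; c <- pts[k, ]
      d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
                  c[1] * (a[2] - b[2]))
      if (abs(d) < 1e-12) next
      ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
               sum(c^2) * (a[2] - b[2])) / d
      uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
               sum(c^2) * (b[1] - a[1])) / d
      consider(c(ux, uy), sqrt(sum((a - c(ux, uy))^2)))
    }
  }
  best
}

# Mann-Whitney (rank) AUC of a score separating positives from negatives.
auc_rank <- function(pos, neg) {
  r <- rank(c(pos, neg))
  n1 <- length(pos); n2 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# Render a single-lobe box with the generator's soft-edge model plus
# additive Gaussian noise; SNR here is lobe amplitude (1) over noise_sd.
render_lobe_box <- function(shape, area, noise_sd = 0, seed = 1,
                            px = 0.25, n = 41, ori_deg = 0) {
  set.seed(seed)
  # x varies along columns, y along rows (column-major fill)
  gx <- rep((seq_len(n) - (n + 1) / 2) * px, each = n)
  gy <- rep((seq_len(n) - (n + 1) / 2) * px, times = n)
  sdist <- cscmorph:::lobe_signed_dist(gx, gy, c(0, 0), area, shape,
                                       ori_deg * pi / 180)
  cov <- matrix(pmin(1, pmax(0, 0.5 - sdist / px)), n, n)
  cov + matrix(rnorm(n * n, 0, noise_sd), n, n)
}

# Render a whole noiseless six-lobed particle (bright lobes on zero
# background) for alignment / overlay tests.
render_particle <- function(areas = rep(39.9, 6), ring_radius = 8.5,
                            rot0 = 0, shape = "round",
                            px = 0.25, n = 127) {
  gx <- rep((seq_len(n) - (n + 1) / 2) * px, each = n)
  gy <- rep((seq_len(n) - (n + 1) / 2) * px, times = n)
  img <- matrix(0, n, n)
  for (l in seq_along(areas)) {
    th <- (rot0 + (l - 1) * 60) * pi / 180
    ctr <- ring_radius * c(cos(th), sin(th))
    ori <- atan2(-ctr[2], -ctr[1])
    sdist <- cscmorph:::lobe_signed_dist(gx, gy, ctr, areas[l], shape, ori)
    img <- img + matrix(pmin(1, pmax(0, 0.5 - sdist / px)), n, n)
  }
  img
}

# Regular hexagon vertices (one vertex at angle phase, degrees).
regular_hexagon <- function(radius = 1, center = c(0, 0), phase = 0) {
  th <- (phase + seq(0, 300, by = 60)) * pi / 180
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

# Disk-set constructor reachable from tests (internal in the package).
mk_disks <- function(x, y, r, monomer = 1L) {
  cscmorph:::disk_set(x, y, r, monomer)
}

# Circular difference of two angles in degrees, in [0, 180].
ang_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}
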