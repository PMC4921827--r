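# Particle metrology: smallest enclosing circle, two-geometry perimeter and
# diameter estimates, lobe polygon areas, opposite-lobe spacings, and
# summary tables in the cohort layout.

#' Smallest enclosing circle of a point set
#'
#' Welzl's randomized algorithm (move-to-front variant) for the minimum
#' enclosing circle. All points lie inside or on the returned circle, which
#' is supported by at most three of them.
#'
#' @param points a two-column matrix (x, y), one row per point.
#' @return a list with `center` (length-2 numeric) and `radius`.
#' @export
smallest_enclosing_circle <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("smallest_enclosing_circle: empty input")
  if (nrow(points) == 1)
    return(list(center = as.numeric(points[1, ]), radius = 0))
  pts <- points  # incremental algorithm is order-independent in its result
  eps <- 1e-10
  inside <- function(circ, p) {
    sqrt(sum((p - circ$center)^2)) <= circ$radius * (1 + eps) + eps
  }
  circ2 <- function(a, b) {
    list(center = (a + b) / 2, radius = sqrt(sum((a - b)^2)) / 2)
  }
  circ3 <- function(a, b, c) {
    # circumcircle; falls back to the best 2-point circle when collinear
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
                c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-14) {
      cands <- list(circ2(a, b), circ2(a, c), circ2(b, c))
      ok <- vapply(cands, function(cc) inside(cc, a) && inside(cc, b) &&
                     inside(cc, c), TRUE)
      cands <- cands[ok]
      return(cands[[which.min(vapply(cands, `[[`, 0, "radius"))]])
    }
    ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
             sum(c^2) * (a[2] - b[2])) / d
    uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
             sum(c^2) * (b[1] - a[1])) / d
    ctr <- c(ux, uy)
    list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
  }
  circ <- circ2(pts[1, ], pts[2, ])
  n <- nrow(pts)
  for (i in seq_len(n)) {
    p <- pts[i, ]
    if (inside(circ, p)) next
    circ <- list(center = p, radius = 0)
    for (j in seq_len(i - 1)) {
      q <- pts[j, ]
      if (inside(circ, q)) next
      circ <- circ2(p, q)
      for (k in seq_len(j - 1)) {
        r <- pts[k, ]
        if (inside(circ, r)) next
        circ <- circ3(p, q, r)
      }
    }
  }
  circ
}

#' Circular perimeter and diameter estimate
#'
#' Diameter estimation from the smallest circle that contains all six lobes:
#' the circle is fitted over every lobe outer-edge point, and
#' `P_circ = 2 * pi * radius`, `d_circ = P_circ / pi`.
#'
#' @param lobe_outer_points a list of six two-column matrices of outer-edge
#'   points (nm), one per lobe, or a single matrix of pooled points from six
#'   identified lobes.
#' @return a list with `P_circ`, `d_circ` (nm) and the fitted `circle`.
#' @export
circular_estimate <- function(lobe_outer_points) {
  if (is.list(lobe_outer_points) && !is.matrix(lobe_outer_points)) {
    if (length(lobe_outer_points) != 6)
      stop("exclusion: particle does not present six identified lobes")
    pts <- do.call(rbind, lobe_outer_points)
  } else {
    pts <- as.matrix(lobe_outer_points)
  }
  circ <- smallest_enclosing_circle(pts)
  P <- 2 * pi * circ$radius
  list(P_circ = P, d_circ = P / pi, circle = circ)
}

#' Hexagonal perimeter and diameter estimate
#'
#' The irregular hexagon through the six outer-centre-edge points of the
#' lobes gives the perimeter; the diameter follows from regular-hexagon
#' geometry under the across-flats convention `d_hex = (sqrt(3) / 6) *
#' P_hex`. Points are re-ordered by polar angle about their centroid before
#' the perimeter is accumulated.
#'
#' @param lobe_edge_midpoints a 6 x 2 matrix of points (nm).
#' @return a list with `P_hex`, `d_hex` (nm) and the ordered `vertices`.
#' @export
hexagonal_estimate <- function(lobe_edge_midpoints) {
  pts <- as.matrix(lobe_edge_midpoints)
  if (nrow(pts) != 6) stop("hexagonal_estimate: exactly 6 points required")
  ctr <- colMeans(pts)
  ord <- order(atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1]))
  pts <- pts[ord, ]
  seg <- sqrt(rowSums((pts - pts[c(2:6, 1), ])^2))
  if (any(seg < 1e-12) || abs(polygon_area_signed(pts)) < 1e-12)
    stop("hexagonal_estimate: degenerate hexagon")
  P <- sum(seg)
  list(P_hex = P, d_hex = sqrt(3) / 6 * P, vertices = pts)
}

# signed shoelace area (positive for counter-clockwise order)
polygon_area_signed <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# first properly-crossing pair of non-adjacent edges, or NULL (vectorized)
polygon_crossing_pair <- function(v) {
  n <- nrow(v)
  nxt <- c(2:n, 1)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  keep <- (nxt[i] != j) & (nxt[j] != i) & !(i == 1 & nxt[j] == 1)
  i <- i[keep]; j <- j[keep]
  if (!length(i)) return(NULL)
  ax <- v[i, 1]; ay <- v[i, 2]; bx <- v[nxt[i], 1]; by <- v[nxt[i], 2]
  cx <- v[j, 1]; cy <- v[j, 2]; dx <- v[nxt[j], 1]; dy <- v[nxt[j], 2]
  d1 <- (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx)
  d2 <- (dx - cx) * (by - cy) - (dy - cy) * (bx - cx)
  d3 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d4 <- (bx - ax) * (dy - ay) - (by - ay) * (dx - ax)
  cross <- (d1 * d2 < 0) & (d3 * d4 < 0)
  if (!any(cross)) return(NULL)
  k <- which(cross)[1]
  c(i[k], nxt[i[k]], j[k], nxt[j[k]])
}

#' Area of a traced lobe polygon
#'
#' Absolute shoelace area of a simple closed polygon, scaled by the square of
#' an optional pixel-to-nm factor; independent of vertex orientation.
#' Self-intersecting polygons are rejected with the offending segment pair
#' named.
#'
#' @param polygon a two-column matrix of vertices (closed implicitly).
#' @param scale linear scale factor applied to coordinates (e.g. nm/pixel
#'   when vertices are in pixels); default 1.
#' @return the area, in squared coordinate units times `scale^2`.
#' @export
lobe_area <- function(polygon, scale = 1) {
  v <- as.matrix(polygon)
  # drop an explicitly repeated closing vertex
  if (nrow(v) > 1 && all(abs(v[1, ] - v[nrow(v), ]) < 1e-12))
    v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3) stop("lobe_area: polygon needs >= 3 vertices")
  bad <- polygon_crossing_pair(v)
  if (!is.null(bad))
    stop(sprintf(
      "lobe_area: polygon self-intersects (segments %d-%d and %d-%d)",
      bad[1], bad[2], bad[3], bad[4]))
  abs(polygon_area_signed(v)) * scale^2
}

#' Centre-to-centre spacings of opposite lobes
#'
#' For six lobe centroids ordered around the ring, returns the three
#' distances between opposite pairs (1-4, 2-5, 3-6) and their mean.
#'
#' @param lobe_centroids a 6 x 2 matrix of centroids ordered by polar angle.
#' @return a list with `spacings` (length 3, nm) and `mean`.
#' @export
opposite_lobe_spacings <- function(lobe_centroids) {
  pts <- as.matrix(lobe_centroids)
  if (nrow(pts) != 6) stop("opposite_lobe_spacings: exactly 6 centroids")
  sp <- vapply(1:3, function(i) sqrt(sum((pts[i, ] - pts[i + 3, ])^2)), 0)
  list(spacings = sp, mean = mean(sp))
}

# polygon centroid (area-weighted)
polygon_centroid <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-14) return(colMeans(v))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

#' Measure one rosette particle from lobe polygons
#'
#' Runs the full per-particle metrology on traced (or ground-truth) lobe
#' polygons: smallest-enclosing-circle perimeter/diameter over all polygon
#' vertices, hexagonal perimeter/diameter from the outer-centre-edge point
#' of each lobe (the boundary point farthest along the centre-to-centroid
#' direction), shoelace lobe areas, and opposite-lobe spacings. Particles
#' without exactly six lobes are excluded (error of class
#' `csc_exclusion`), mirroring the exclusion of five-lobed or indistinct
#' particles from six-lobe metrology.
#'
#' @param polygons a list of lobe polygons (two-column matrices, nm); the
#'   particle centre may be supplied via `center` or attribute `"center"`.
#' @param center optional particle centre (length-2, nm); defaults to the
#'   mean of lobe centroids.
#' @param particle_id identifier copied into the result.
#' @return a one-row data frame with `particle_id`, `P_circ`, `d_circ`,
#'   `P_hex`, `d_hex`, `mean_lobe_area`, `mean_opposite_spacing`, plus the
#'   per-lobe areas and spacings as attributes `"lobe_areas"` and
#'   `"spacings"`.
#' @export
measure_rosette <- function(polygons, center = NULL, particle_id = NA) {
  if (length(polygons) != 6) {
    cond <- structure(class = c("csc_exclusion", "error", "condition"),
                      list(message = sprintf(
                        "particle %s excluded: %d lobes (6 required)",
                        particle_id, length(polygons)), call = NULL))
    stop(cond)
  }
  cents <- t(vapply(polygons, polygon_centroid, numeric(2)))
  if (is.null(center)) center <- attr(polygons, "center")
  if (is.null(center)) center <- colMeans(cents)
  ord <- order(atan2(cents[, 2] - center[2], cents[, 1] - center[1]))
  polygons <- polygons[ord]
  cents <- cents[ord, ]
  areas <- vapply(polygons, lobe_area, 0)
  ce <- circular_estimate(polygons)
  mids <- t(vapply(seq_len(6), function(i) {
    u <- cents[i, ] - center
    u <- u / sqrt(sum(u^2))
    v <- polygons[[i]]
    proj <- (v[, 1] - center[1]) * u[1] + (v[, 2] - center[2]) * u[2]
    v[which.max(proj), ]
  }, numeric(2)))
  he <- hexagonal_estimate(mids)
  sp <- opposite_lobe_spacings(cents)
  out <- data.frame(particle_id = particle_id,
                    P_circ = ce$P_circ, d_circ = ce$d_circ,
                    P_hex = he$P_hex, d_hex = he$d_hex,
                    mean_lobe_area = mean(areas),
                    mean_opposite_spacing = sp$mean)
  attr(out, "lobe_areas") <- areas
  attr(out, "spacings") <- sp$spacings
  out
}

#' Measure a cohort of particles
#'
#' Applies [measure_rosette()] to every particle in a set of annotations
#' (e.g. from [ground_truth_polygons()]); non-six-lobed particles are
#' excluded and counted, not measured.
#'
#' @param annotation list of per-particle polygon lists.
#' @return a list with `measurements` (data frame, one row per measured
#'   particle), `lobe_areas` (vector over all measured lobes), `n_excluded`
#'   and `excluded_ids`.
#' @export
measure_cohort <- function(annotation) {
  rows <- list(); areas <- numeric(); excl <- c()
  for (nm in names(annotation)) {
    polys <- annotation[[nm]]
    pid <- attr(polys, "particle_id") %||% nm
    res <- tryCatch(measure_rosette(polys, particle_id = pid),
                    csc_exclusion = function(e) NULL)
    if (is.null(res)) {
      excl <- c(excl, pid)
    } else {
      rows[[length(rows) + 1]] <- res
      areas <- c(areas, attr(res, "lobe_areas"))
    }
  }
  if (length(excl))
    message(length(excl), " particle(s) excluded from six-lobe metrology")
  list(measurements = if (length(rows)) do.call(rbind, rows) else NULL,
       lobe_areas = areas, n_excluded = length(excl), excluded_ids = excl)
}

#' Summary table of cohort measurements
#'
#' Builds the reporting table: per-group mean and sample SD (n - 1
#' denominator) for each measured column, group-level means, and an overall
#' row that is the unweighted mean of the group means (not the pooled mean),
#' matching the convention of the published cohort table.
#'
#' @param values a named list of groups; each group is a named list of
#'   numeric vectors (one per measured quantity, e.g. `perimeter`,
#'   `diameter`, `lobe_area`).
#' @return a data frame with one row per group plus an `Overall` row;
#'   columns `<quantity>_mean` and `<quantity>_sd` (SD is `NA` for
#'   single-value groups).
#' @export
summarize_measurements <- function(values) {
  if (length(values) == 0) stop("summarize_measurements: no groups")
  keep <- vapply(values, function(g) any(lengths(g) > 0), TRUE)
  if (any(!keep)) {
    warning("empty group(s) omitted: ",
            paste(names(values)[!keep], collapse = ", "))
    values <- values[keep]
  }
  quantities <- unique(unlist(lapply(values, names)))
  rows <- lapply(names(values), function(g) {
    r <- list(group = g)
    for (q in quantities) {
      v <- values[[g]][[q]]
      r[[paste0(q, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      r[[paste0(q, "_sd")]] <- if (length(v) > 1) sd(v) else NA_real_
    }
    as.data.frame(r, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  overall <- list(group = "Overall")
  for (q in quantities) {
    gm <- tab[[paste0(q, "_mean")]]
    overall[[paste0(q, "_mean")]] <- mean(gm, na.rm = TRUE)
    overall[[paste0(q, "_sd")]] <- NA_real_
  }
  rbind(tab, as.data.frame(overall, stringsAsFactors = FALSE))
}

#' Write measurements or summaries as TSV
#' @param x a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurements_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
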