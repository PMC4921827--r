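# Smallest enclosing circle, two-geometry estimates, polygon metrology.

test_that("smallest_enclosing_circle handles canonical cases", {
  # two points: diameter circle
  r <- smallest_enclosing_circle(rbind(c(0, 0), c(2, 0)))
  expect_equal(r$center, c(1, 0))
  expect_equal(r$radius, 1)
  # interior point does not change the circle
  r2 <- smallest_enclosing_circle(rbind(c(0, 0), c(2, 0), c(1, 0.5)))
  expect_equal(r2$radius, 1)
  # equilateral triangle: circumcircle
  tri <- rbind(c(1, 0), c(cos(2 * pi / 3), sin(2 * pi / 3)),
               c(cos(4 * pi / 3), sin(4 * pi / 3)))
  r3 <- smallest_enclosing_circle(tri)
  expect_equal(r3$radius, 1, tolerance = 1e-9)
  expect_equal(r3$center, c(0, 0), tolerance = 1e-9)
  # collinear points
  r4 <- smallest_enclosing_circle(rbind(c(0, 0), c(1, 0), c(3, 0)))
  expect_equal(r4$radius, 1.5)
  # single point and empty input
  expect_equal(smallest_enclosing_circle(rbind(c(2, 3)))$radius, 0)
  expect_error(smallest_enclosing_circle(matrix(0, 0, 2)), "empty")
})

test_that("smallest_enclosing_circle is order-independent and RNG-silent", {
  set.seed(42)
  pts <- matrix(rnorm(20), ncol = 2)
  a <- smallest_enclosing_circle(pts)
  b <- smallest_enclosing_circle(pts[sample(10), ])
  expect_equal(a$radius, b$radius, tolerance = 1e-9)
  expect_equal(a$center, b$center, tolerance = 1e-9)
  # calling it must not advance the RNG state of the caller
  set.seed(1); before <- .Random.seed
  invisible(smallest_enclosing_circle(pts))
  expect_identical(.Random.seed, before)
})

test_that("smallest_enclosing_circle matches the brute-force oracle (spot check)", {
  set.seed(100)
  for (i in 1:100) {
    n <- sample(3:8, 1)
    pts <- matrix(runif(2 * n, -10, 10), ncol = 2)
    got <- smallest_enclosing_circle(pts)
    want <- brute_sec(pts)
    expect_equal(got$radius, want$radius, tolerance = 1e-7)
    d <- sqrt((pts[, 1] - got$center[1])^2 + (pts[, 2] - got$center[2])^2)
    expect_true(all(d <= got$radius * (1 + 1e-9) + 1e-9))
  }
})

test_that("circular_estimate follows the P = 2 pi r convention", {
  hexpts <- regular_hexagon(5)
  ce <- circular_estimate(hexpts)
  expect_equal(ce$P_circ, 2 * pi * 5, tolerance = 1e-9)
  expect_equal(ce$d_circ, 10, tolerance = 1e-9)
  expect_error(circular_estimate(list(hexpts, hexpts)), "exclusion")
})

test_that("hexagonal_estimate uses the across-flats diameter convention", {
  v <- regular_hexagon(1)          # side 1, perimeter 6
  he <- hexagonal_estimate(v)
  expect_equal(he$P_hex, 6, tolerance = 1e-12)
  expect_equal(he$d_hex, sqrt(3), tolerance = 1e-12)  # across flats
  # vertex order must not matter
  he2 <- hexagonal_estimate(v[c(4, 1, 6, 3, 2, 5), ])
  expect_equal(he2$P_hex, he$P_hex)
  expect_error(hexagonal_estimate(v[1:5, ]), "exactly 6")
  expect_error(hexagonal_estimate(matrix(1, 6, 2)), "degenerate")
})

test_that("lobe_area computes scaled shoelace areas and rejects bad polygons", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(lobe_area(sq), 1)
  expect_equal(lobe_area(sq[4:1, ]), 1)              # orientation-free
  expect_equal(lobe_area(sq, scale = 0.5), 0.25)     # nm/pixel scaling
  expect_equal(lobe_area(rbind(sq, sq[1, ])), 1)     # closing vertex
  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(lobe_area(bow), "self-intersects \\(segments")
  expect_error(lobe_area(sq[1:2, ]), ">= 3 vertices")
})

test_that("opposite_lobe_spacings pairs lobes across the ring", {
  v <- regular_hexagon(8.5)
  sp <- opposite_lobe_spacings(v)
  expect_equal(sp$spacings, rep(17, 3), tolerance = 1e-12)
  expect_equal(sp$mean, 17)
  expect_error(opposite_lobe_spacings(v[1:5, ]), "exactly 6")
})

test_that("measure_rosette reproduces an analytic particle", {
  ring <- 8.5; area <- 36
  r_lobe <- sqrt(area / pi)
  ctrs <- regular_hexagon(ring)
  polys <- lapply(seq_len(6), function(i)
    cscmorph:::lobe_outline(ctrs[i, ], area, "round", NA))
  m <- measure_rosette(polys, center = c(0, 0), particle_id = "p1")
  expect_equal(m$d_circ, 2 * (ring + r_lobe), tolerance = 1e-3)
  expect_equal(m$mean_opposite_spacing, 17, tolerance = 1e-9)
  expect_equal(attr(m, "lobe_areas"), rep(area, 6), tolerance = 1e-3)
  # outer-centre-edge points sit at ring + r_lobe, so
  # P_hex equals the perimeter of the hexagon through those points
  expect_equal(m$P_hex, 6 * (ring + r_lobe), tolerance = 1e-3)
  expect_s3_class(tryCatch(measure_rosette(polys[1:5]), error = identity),
                  "csc_exclusion")
})

test_that("measure_cohort excludes non-six-lobed particles", {
  cfg <- simulation_config(n_particles = 4, seed = 21L,
                           five_lobe_fraction = 0)
  gt <- simulate_micrograph(cfg)$ground_truth
  gt5 <- gt[!(gt$particle_id == 2 & gt$lobe == 6), ]   # drop one lobe
  gt5$n_lobes[gt5$particle_id == 2] <- 5L
  ann <- ground_truth_polygons(gt5)
  expect_message(coh <- measure_cohort(ann), "excluded")
  expect_equal(coh$n_excluded, 1)
  expect_equal(nrow(coh$measurements), 3)
  expect_equal(length(coh$lobe_areas), 18)
})

test_that("summarize_measurements builds the cohort table layout", {
  vals <- list(g1 = list(q = c(1, 2, 3)),
               g2 = list(q = c(10, 20, 30, 40, 50)))
  tab <- summarize_measurements(vals)
  expect_equal(tab$group, c("g1", "g2", "Overall"))
  expect_equal(tab$q_mean, c(2, 30, 16))   # unweighted mean of group means
  expect_false(tab$q_mean[3] == mean(c(1, 2, 3, 10, 20, 30, 40, 50)))
  expect_equal(tab$q_sd[1], sd(1:3))       # n - 1 denominator
  expect_true(is.na(tab$q_sd[3]))
  one <- summarize_measurements(list(g = list(q = 5)))
  expect_true(is.na(one$q_sd[1]))
  expect_warning(summarize_measurements(list(a = list(q = 1:3),
                                             b = list(q = numeric()))),
                 "empty group")
  expect_error(summarize_measurements(list()), "no groups")
})

test_that("measurements write as TSV", {
  tab <- summarize_measurements(list(g = list(q = c(1, 2))))
  path <- tempfile(fileext = ".tsv")
  write_measurements_tsv(tab, path)
  back <- read.delim(path)
  expect_equal(back$q_mean, tab$q_mean)
  unlink(path)
})
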