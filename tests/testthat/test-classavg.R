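# Contrast inversion, particle boxing, reference-free alignment and
# stability-filtered classification.

test_that("invert_contrast is an involution and flips polarity", {
  m <- matrix(runif(16), 4, 4)
  expect_equal(invert_contrast(invert_contrast(m)), m)
  expect_equal(max(invert_contrast(m)) + min(m), max(m) + min(m))
  cfg <- simulation_config(n_particles = 1, seed = 1L)
  mic <- simulate_micrograph(cfg)$micrograph
  expect_identical(mic$polarity, "dark")
  inv <- invert_contrast(mic)
  expect_identical(inv$polarity, "bright")
  expect_equal(invert_contrast(inv)$image, mic$image)
})

test_that("box sizes round to the nearest odd pixel count", {
  expect_equal(cscmorph:::odd_pixel_count(31.6, 0.25), 127L)  # 126.4 -> odd
  expect_equal(cscmorph:::odd_pixel_count(10.3, 0.25), 41L)
  expect_equal(cscmorph:::odd_pixel_count(0.25, 0.25), 3L)    # floor at 3
})

test_that("box_particles extracts centred boxes and skips the boundary", {
  cfg <- simulation_config(n_particles = 4, seed = 9L,
                           five_lobe_fraction = 0)
  sim <- simulate_micrograph(cfg)
  centers <- unique(sim$ground_truth[, c("center_x", "center_y")])
  st <- box_particles(sim$micrograph, as.matrix(centers))
  expect_s3_class(st, "csc_stack")
  expect_length(st, 4)
  expect_equal(dim(st$images[[1]]), c(127, 127))
  # centre pixel of each box is a background-or-darker lobe region, and the
  # particle (6 dark lobes) lies fully inside: box mean below background
  expect_true(all(vapply(st$images, mean, 0) < 0.55))
  # a centre at the very image edge is skipped with a message
  expect_message(
    st2 <- box_particles(sim$micrograph,
                         rbind(as.matrix(centers), c(1, 1))),
    "skipped 1")
  expect_equal(attr(st2, "skipped"), 5L)
  expect_length(st2, 4)
})

test_that("rotation helper is exact at 360 and invertible in the interior", {
  img <- render_particle(n = 61)
  expect_identical(cscmorph:::rotate_bilinear(img, 360), img)
  back <- cscmorph:::rotate_bilinear(cscmorph:::rotate_bilinear(img, 30), -30)
  core <- 16:46
  # double bilinear interpolation smears the 1-pixel soft edge; the bulk
  # of the image must still round-trip
  expect_lt(max(abs(back[core, core] - img[core, core])), 0.25)
  expect_lt(mean(abs(back[core, core] - img[core, core])), 0.01)
})

test_that("align_stack recovers known rotations and shifts (noiseless)", {
  base <- render_particle(areas = c(30, 35, 40, 45, 50, 38),
                          shape = "triangular")
  true_rot <- c(0, 40, 125, 230)
  true_sh <- rbind(c(0, 0), c(3, -2), c(-4, 1), c(2, 5))
  imgs <- lapply(seq_along(true_rot), function(i) {
    cscmorph:::shift_image(cscmorph:::rotate_bilinear(base, true_rot[i]),
                           true_sh[i, 1], true_sh[i, 2])
  })
  st <- particle_stack(imgs, pixel_size = 0.25)
  ali <- align_stack(st, n_iter = 6, angle_step = 5)
  # objective is non-decreasing by construction
  expect_true(all(diff(ali$objective) >= -1e-12))
  # relative recovered rotations match the applied ones within the step
  rec <- ali$transforms$rotation
  rel_err <- ang_diff(rec - rec[1], -(true_rot - true_rot[1]))
  expect_true(all(rel_err <= 5 + 1e-9))
  # aligned images agree with each other (bilinear resampling at a coarse
  # 5 degree step bounds how close the copies can get)
  a <- ali$stack$images
  cors <- vapply(2:4, function(i) cor(as.numeric(a[[1]]),
                                      as.numeric(a[[i]])), 0)
  expect_true(all(cors > 0.9))
})

test_that("align_stack excludes blank images with a warning", {
  base <- render_particle(n = 61)
  st <- particle_stack(list(base, matrix(0.5, 61, 61), base + 0),
                       pixel_size = 0.25)
  expect_warning(ali <- align_stack(st, n_iter = 1, angle_step = 90),
                 "blank")
  expect_equal(ali$excluded, 2L)
  expect_length(ali$stack, 2)
  expect_error(suppressWarnings(
    align_stack(particle_stack(list(base, matrix(1, 61, 61)), 0.25),
                n_iter = 1)), ">= 2")
})

test_that("classify_stable separates distinct shape classes", {
  tri <- lapply(1:6, function(i)
    render_lobe_box("triangular", 40, noise_sd = 0.05, seed = i))
  rnd <- lapply(1:6, function(i)
    render_lobe_box("round", 40, noise_sd = 0.05, seed = 100 + i))
  st <- particle_stack(c(tri, rnd), pixel_size = 0.25)
  cl <- classify_stable(st, K = 2, n_trials = 3, seed = 42L)
  expect_s3_class(cl, "csc_classes")
  expect_equal(cl$stability, c(1, 1))
  expect_length(unique(cl$assignment[1:6]), 1)
  expect_length(unique(cl$assignment[7:12]), 1)
  expect_false(cl$assignment[1] == cl$assignment[7])
  expect_equal(sort(cl$sizes), c(6L, 6L))
  expect_equal(dim(cl$averages[[1]]), c(41, 41))
})

test_that("classification does not depend on stack order at fixed seed", {
  tri <- lapply(1:4, function(i)
    render_lobe_box("triangular", 40, noise_sd = 0.05, seed = i))
  rnd <- lapply(1:4, function(i)
    render_lobe_box("round", 40, noise_sd = 0.05, seed = 50 + i))
  imgs <- c(tri, rnd)
  perm <- c(5, 2, 8, 1, 4, 7, 3, 6)
  a <- classify_stable(particle_stack(imgs, 0.25), K = 2, n_trials = 2,
                       seed = 7L)
  b <- classify_stable(particle_stack(imgs[perm], 0.25), K = 2,
                       n_trials = 2, seed = 7L)
  # the partitions must be identical up to label names
  expect_equal(length(unique(paste(a$assignment,
                                   b$assignment[order(perm)]))), 2)
})

test_that("classification recovers truth with high ARI at SNR 1", {
  skip_if_not_installed("mclust")
  # two particle classes differing in lobe size (as rosette class averages
  # do), additive noise sd equal to the lobe amplitude (SNR 1)
  mk <- function(area, seed) {
    set.seed(seed)
    render_particle(areas = rep(area, 6), n = 111) +
      matrix(rnorm(111 * 111, 0, 1), 111, 111)
  }
  small <- lapply(1:6, function(i) mk(25, i))
  large <- lapply(1:6, function(i) mk(55, 300 + i))
  st <- particle_stack(c(small, large), pixel_size = 0.25)
  cl <- classify_stable(st, K = 2, n_trials = 3, seed = 5L)
  truth <- rep(1:2, each = 6)
  got <- cl$assignment
  keep <- !is.na(got)
  ari <- mclust::adjustedRandIndex(truth[keep], got[keep])
  expect_gte(ari, 0.8)
})

test_that("class averages and stacks write as multi-page TIFF", {
  imgs <- lapply(1:3, function(i) render_lobe_box("round", 30, seed = i))
  st <- particle_stack(imgs, 0.25)
  path <- tempfile(fileext = ".tif")
  write_stack_tiff(st, path)
  pages <- tiff::readTIFF(path, all = TRUE)
  expect_length(pages, 3)
  unlink(path)
})
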