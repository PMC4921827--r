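# Slab projection, disk-union areas, blurring, Cn packing and assemblies.

test_that("project_slab collapses a helix column to one vdW disk", {
  m <- make_toy_bundle(1, helix_radius = 0.4)
  d <- project_slab(m)
  expect_equal(nrow(d), 1)
  expect_equal(d$radius, 0.4)
  expect_equal(union_area(d, grid_resolution = 0.005), pi * 0.4^2,
               tolerance = 2e-3)
})

test_that("the slab interval selects atoms and is closed", {
  m <- make_toy_bundle(2, helix_radius = 0.5)
  # narrow slab still catches the z = 0 atoms
  d <- project_slab(m, midplane = 0, half_thickness = 0)
  expect_equal(nrow(d), 2)
  expect_error(project_slab(m, midplane = 100, half_thickness = 1),
               "no atoms within the slab")
})

test_that("unknown elements fall back to the default radius with a warning", {
  m <- make_toy_bundle(2, helix_radius = 0.17)
  path <- tempfile(fileext = ".pdb")
  write_toy_pdb(m, path)
  txt <- readLines(path)
  txt <- gsub(" C  ", " X  ", txt, fixed = TRUE)   # mangle the element
  writeLines(txt, path)
  expect_warning(d <- project_slab(path), "default radius")
  expect_true(all(d$radius == 0.17))
  unlink(path)
})

test_that("prune_disks removes duplicates and contained disks", {
  d <- mk_disks(c(0, 0, 0, 5), c(0, 0, 0.1, 0), c(1, 1, 0.2, 1))
  p <- cscmorph:::prune_disks(d)
  expect_equal(nrow(p), 2)                 # dup dropped, contained dropped
  expect_equal(union_area(p), union_area(d), tolerance = 1e-6)
})

test_that("union_area matches closed forms", {
  one <- mk_disks(0, 0, 1.5)
  expect_lt(abs(union_area(one) - pi * 1.5^2) / (pi * 1.5^2), 2e-3)
  # disjoint disks add
  two <- mk_disks(c(0, 10), c(0, 0), c(1, 2))
  expect_equal(union_area(two), pi * (1 + 4), tolerance = 0.01 * pi * 5)
  # coincident disks count once
  same <- mk_disks(c(0, 0), c(0, 0), c(1, 1))
  expect_equal(union_area(same), pi, tolerance = 0.01 * pi)
  # overlapping pair: 2 * pi r^2 - lens
  ov <- mk_disks(c(0, 1), c(0, 0), c(1, 1))
  want <- 2 * pi - cscmorph:::lens_area(1, 1, 1)
  expect_lt(abs(union_area(ov) - want) / want, 2e-3)
  expect_error(union_area(one[0, ]), "no disks")
  expect_error(union_area(one, grid_resolution = 0), "positive")
})

test_that("lens_area is the exact two-disk intersection", {
  expect_equal(cscmorph:::lens_area(3, 1, 1), 0)          # disjoint
  expect_equal(cscmorph:::lens_area(2, 1, 1), 0)          # tangent
  expect_equal(cscmorph:::lens_area(0.2, 0.5, 2), pi * 0.25)  # contained
  # r1 = r2 = 1, d = 1: 2 * acos(1/2) - (1/2) * sqrt(3)
  expect_equal(cscmorph:::lens_area(1, 1, 1),
               2 * acos(0.5) - sqrt(3) / 2, tolerance = 1e-12)
})

test_that("grid and Monte-Carlo union areas agree", {
  set.seed(8)
  d <- mk_disks(runif(4, 0, 3), runif(4, 0, 3), runif(4, 0.4, 1.2))
  g <- union_area(d)
  mc <- union_area_mc(d, n_samples = 4e5, seed = 3L)
  expect_lt(abs(g - mc) / mc, 0.01)
})

test_that("blur_and_threshold auto-calibrates to the hard union area", {
  d <- project_slab(make_toy_bundle(8, helix_radius = 0.5))
  bt <- blur_and_threshold(d, R = 2.5)
  expect_s3_class(bt, "csc_density")
  expect_lt(abs(bt$iso_area - bt$hard_area) / bt$hard_area, 0.01)
  # a fixed lower threshold encloses more area than a higher one
  lo <- blur_and_threshold(d, R = 2.5, tau = 0.3)
  hi <- blur_and_threshold(d, R = 2.5, tau = 0.7)
  expect_gt(lo$iso_area, hi$iso_area)
  # small blur: isosurface stays close to the hard footprint
  tight <- blur_and_threshold(d, R = 0.2, tau = 0.5)
  expect_lt(abs(tight$iso_area - tight$hard_area) / tight$hard_area, 0.1)
  expect_error(blur_and_threshold(d, R = -1), "positive")
  expect_error(blur_and_threshold(d, R = 1, tau = 2), "tau")
})

test_that("gaussian_blur conserves mass away from the boundary", {
  img <- matrix(0, 51, 51); img[24:28, 24:28] <- 1
  b <- cscmorph:::gaussian_blur(img, 2)
  expect_equal(sum(b), sum(img), tolerance = 1e-6)
  expect_identical(cscmorph:::gaussian_blur(img, 0), img)
})

test_that("build_cn_oligomer packs tangent single-disk monomers exactly", {
  mono <- mk_disks(0, 0, 1)
  dim2 <- build_cn_oligomer(mono, 2, contact_tolerance = 0, phase_step = 90)
  # two unit disks become tangent: centre radius 1, centres 2 apart
  expect_equal(dim2$layout$r_mono, 1, tolerance = 0.02)
  expect_equal(dim2$area, 2 * pi, tolerance = 0.05)
  expect_equal(dim2$monomer_area, pi, tolerance = 0.01)
  expect_equal(sort(unique(dim2$disks$monomer)), 1:2)
  hex6 <- build_cn_oligomer(mono, 6, contact_tolerance = 0, phase_step = 90)
  # tangent ring of six unit disks: centre radius 1 / sin(pi/6) = 2
  expect_equal(hex6$layout$r_mono, 2, tolerance = 0.02)
  expect_error(build_cn_oligomer(mono, 1), "2..6")
  expect_error(build_cn_oligomer(mono, 7), "2..6")
})

test_that("a contact tolerance allows proportionally deeper overlap", {
  mono <- mk_disks(0, 0, 1)
  tight <- build_cn_oligomer(mono, 2, contact_tolerance = 0.2,
                             phase_step = 90)
  loose <- build_cn_oligomer(mono, 2, contact_tolerance = 0,
                             phase_step = 90)
  expect_lt(tight$layout$r_mono, loose$layout$r_mono)
  expect_lt(tight$area, loose$area)
})

test_that("build_sixfold_assembly honours the ring geometry", {
  lobe <- mk_disks(0, 0, 1)
  asm <- build_sixfold_assembly(lobe, r_ring = 8.5)
  expect_equal(nrow(asm$disks), 6)
  expect_equal(sort(unique(asm$disks$monomer)), 1:6)
  # opposite lobes 2 * r_ring apart
  d14 <- sqrt((asm$disks$x[1] - asm$disks$x[4])^2 +
                (asm$disks$y[1] - asm$disks$y[4])^2)
  expect_equal(d14, 17, tolerance = 1e-9)
  expect_equal(asm$clash_area, 0, tolerance = 0.05)
  expect_equal(asm$area, 6 * pi, tolerance = 0.1)
  # a too-tight ring clashes; clash is reported, not forbidden
  tight <- build_sixfold_assembly(lobe, r_ring = 0.9)
  expect_gt(tight$clash_area, 0.5)
  expect_error(build_sixfold_assembly(lobe, r_ring = 0), "positive")
})

test_that("auto lobe rotation does not worsen the clash", {
  tri <- build_cn_oligomer(project_slab(make_toy_bundle(4, 0.5)), 3,
                           phase_step = 45)
  fixed <- build_sixfold_assembly(tri, r_ring = 4, lobe_rotation = "fixed")
  auto <- build_sixfold_assembly(tri, r_ring = 4, lobe_rotation = "auto",
                                 rotation_step = 15)
  expect_lte(auto$clash_area, fixed$clash_area + 1e-6)
})
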