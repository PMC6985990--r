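# A small scene builder: a slab-shaped ventricle plus point lesions at
# controlled distances from its surface.
scene <- function(lesion_at, dims = c(24, 11, 11)) {
  vent <- array(FALSE, dims); vent[1:4, , ] <- TRUE
  wmh <- array(FALSE, dims)
  for (v in lesion_at) wmh[v, 6, 6] <- TRUE
  list(wmh = wmh, vent = vent)
}

test_that("the 3 mm rule is boundary-inclusive on the anisotropic grid", {
  sp <- c(1, 1, 1)
  # ventricle surface column at x = 4; lesion centre distances 2, 3, 4 mm
  for (case in list(c(6, "CPWMH"), c(7, "CPWMH"), c(8, "DWMH"))) {
    sc <- scene(as.integer(case[1]))
    cl <- classify_wmh(sc$wmh, sc$vent, sp)
    expect_equal(cl$lesions$class, case[2])
    expect_equal(cl$lesions$min_dist, as.integer(case[1]) - 4)
  }
})

test_that("a connected lesion takes one class; any-voxel rule reaches the margin", {
  sp <- c(1, 1, 1)
  sc <- scene(integer(0), dims = c(30, 11, 11))
  sc$wmh[6:20, 6, 6] <- TRUE   # one lesion spanning 2 mm to 16 mm
  cl <- classify_wmh(sc$wmh, sc$vent, sp)
  expect_equal(nrow(cl$lesions), 1)
  expect_equal(cl$lesions$class, "CPWMH")
  maj <- classify_wmh(sc$wmh, sc$vent, sp, rule = "majority")
  expect_equal(maj$lesions$class, "DWMH")  # most voxels beyond 3 mm
})

test_that("classification is monotone in the ventricle mask", {
  sp <- c(0.9, 0.9, 4)
  set.seed(21)
  sc <- scene(integer(0), dims = c(20, 12, 8))
  sc$wmh[sample(length(sc$wmh), 60)] <- TRUE
  sc$wmh[sc$vent] <- FALSE
  small_cl <- classify_wmh(sc$wmh, sc$vent, sp)
  grown <- sc$vent
  grown[5, , ] <- TRUE
  big_cl <- classify_wmh(sc$wmh, grown & !sc$wmh, sp)
  was_cp <- small_cl$class_map == 1L
  expect_true(all(big_cl$class_map[was_cp] == 1L))
})

test_that("connected components match the flood-fill oracle and 26-connectivity", {
  two <- array(FALSE, c(12, 12, 12))
  two[2:4, 2:4, 2:4] <- TRUE
  two[8:10, 8:10, 8:10] <- TRUE
  expect_equal(extract_lesions(two)$n, 2)

  corner <- array(FALSE, c(6, 6, 6))
  corner[2, 2, 2] <- TRUE
  corner[3, 3, 3] <- TRUE      # touch at one corner only
  expect_equal(extract_lesions(corner)$n, 1)

  set.seed(14)
  for (i in 1:5) {
    m <- array(runif(10 * 10 * 10) < 0.12, c(10, 10, 10))
    expect_equal(extract_lesions(m)$n, flood_fill_count(m))
  }
})

test_that("lesion ordering is deterministic by first voxel index", {
  m <- array(FALSE, c(12, 12, 12))
  m[10, 10, 10] <- TRUE
  m[2, 2, 2] <- TRUE
  les <- extract_lesions(m)
  expect_equal(les$labels[2, 2, 2], 1L)
  expect_equal(les$labels[10, 10, 10], 2L)
})

test_that("ball mesh area is within 5% of the closed form and hull agrees", {
  ph <- make_lesion_phantom("ball", list(r = 10))
  mm <- mesh_metrics(ph$mask, ph$spacing)
  expect_lt(abs(mm$surface_area - 4 * pi * 100) / (4 * pi * 100), 0.05)
  # convex body: hull volume equals volume, hull area below surface area
  expect_equal(mm$hull_volume, mm$volume, tolerance = 1e-9)
  expect_lte(mm$hull_area, mm$surface_area * 1.01)
})

test_that("voxelized hull volume matches the facet-enumeration oracle", {
  set.seed(5)
  m <- array(FALSE, c(7, 7, 7))
  m[sample(length(m), 22)] <- TRUE
  if (extract_lesions(m)$n >= 1) {
    sp <- c(1, 1, 1)
    hv <- hull_voxel_volume(m, sp)
    P <- voxel_coords(m, sp)
    cand <- as.matrix(expand.grid(0:6, 0:6, 0:6))
    inside <- apply(cand, 1, function(q) brute_hull_contains(P, q))
    expect_equal(hv, sum(inside))
  }
})

test_that("dented ball is measurably concave; hull exceeds the lesion volume", {
  pd <- make_lesion_phantom("dented_ball", list(r = 8, dent_r = 5))
  mm <- mesh_metrics(pd$mask, pd$spacing)
  expect_gt(mm$hull_volume, mm$volume)
  sf <- shape_features(mm, voxel_coords(pd$mask, pd$spacing))
  expect_lt(sf$solidity, 1)
  expect_lt(sf$convexity, 1)
  expect_gt(sf$concavity_index, 0)
})

test_that("shape features of canonical bodies match analytic expectations", {
  ph <- make_lesion_phantom("ball", list(r = 10))
  sf <- shape_features(mesh_metrics(ph$mask, ph$spacing),
                       voxel_coords(ph$mask, ph$spacing))
  expect_lt(abs(sf$solidity - 1), 0.05)
  expect_lt(abs(sf$convexity - 1), 0.05)
  expect_lt(abs(sf$concavity_index), 0.1)
  expect_lt(sf$eccentricity, 0.1)

  pe <- make_lesion_phantom("ellipsoid", list(semiaxes = c(20, 5, 5)))
  se <- shape_features(mesh_metrics(pe$mask, pe$spacing),
                       voxel_coords(pe$mask, pe$spacing))
  expect_equal(se$eccentricity, sqrt(1 - 25 / 400), tolerance = 0.02)
})

test_that("shape features are invariant under 90-degree rotation and translation", {
  pd <- make_lesion_phantom("dented_ball", list(r = 6, dent_r = 4))
  sp <- pd$spacing
  base <- shape_features(mesh_metrics(pd$mask, sp), voxel_coords(pd$mask, sp))
  rot <- aperm(pd$mask, c(2, 3, 1))                 # axis permutation
  rsf <- shape_features(mesh_metrics(rot, sp), voxel_coords(rot, sp))
  shifted <- array(FALSE, dim(pd$mask) + 3)
  shifted[3 + seq_len(dim(pd$mask)[1]) - 1, 3 + seq_len(dim(pd$mask)[2]) - 1,
          3 + seq_len(dim(pd$mask)[3]) - 1] <- pd$mask
  ssf <- shape_features(mesh_metrics(shifted, sp), voxel_coords(shifted, sp))
  for (f in c("solidity", "convexity", "concavity_index", "eccentricity")) {
    expect_equal(rsf[[f]], base[[f]], tolerance = 1e-6)
    expect_equal(ssf[[f]], base[[f]], tolerance = 1e-6)
  }
})

test_that("finer resolution moves ball solidity and convexity closer to 1", {
  errs <- sapply(c(0.9, 0.45), function(sp) {
    ph <- make_lesion_phantom("ball", list(r = 8), spacing = rep(sp, 3))
    mm <- mesh_metrics(ph$mask, ph$spacing)
    sf <- shape_features(mm, voxel_coords(ph$mask, ph$spacing))
    abs(sf$convexity - 1) + abs(sf$solidity - 1)
  })
  expect_lte(errs[2], errs[1] + 0.005)
})

test_that("box-counting dimension is right for line, plane-boundary and fractal sets", {
  seg <- make_lesion_phantom("segment", list(length = 40))
  expect_equal(fractal_dimension(seg$mask)$fd, 1, tolerance = 0.15)

  cube <- array(TRUE, c(64, 64, 64))
  expect_equal(fractal_dimension(boundary_voxels(cube))$fd, 2, tolerance = 0.15)

  men <- make_lesion_phantom("menger_like", list(level = 2))
  fd <- fractal_dimension(men$mask, sizes = c(1, 3, 9))
  expect_equal(fd$fd, log(20) / log(3), tolerance = 0.2)
  expect_equal(fd$counts, c(400L, 20L, 1L))

  tiny <- array(FALSE, c(4, 4, 4)); tiny[2, 2, 2] <- TRUE
  out <- fractal_dimension(tiny)
  expect_true(is.na(out$fd))
  expect_equal(out$flag, "insufficient_scales")
})

test_that("patient aggregation averages per class and flags a missing class", {
  sc <- scene(integer(0), dims = c(30, 13, 13))
  sc$wmh[5:7, 5:7, 5:7] <- TRUE      # periventricular blob
  sc$wmh[20:23, 6:9, 6:9] <- TRUE    # deep blob
  ps <- patient_shape_summary(sc$wmh, sc$vent, c(1, 1, 1))
  expect_equal(sort(ps$lesions$class), c("CPWMH", "DWMH"))
  expect_equal(ps$summary$n_lesions, c(1L, 1L))
  one <- ps$lesions[ps$lesions$class == "CPWMH", ]
  expect_equal(ps$summary$solidity[ps$summary$class == "CPWMH"], one$solidity)

  # two lesions of one class average; the other class is flagged missing
  tab <- data.frame(class = c("CPWMH", "CPWMH"), volume = c(1, 3),
                    surface_area = c(5, 7), solidity = c(0.8, 0.6),
                    convexity = c(1, 1), concavity_index = c(0, 0),
                    eccentricity = c(0.2, 0.4), fd = c(1.9, 2.1))
  agg <- aggregate_patient(tab)
  expect_equal(agg$solidity[agg$class == "CPWMH"], 0.7)
  expect_true(agg$missing[agg$class == "DWMH"])
  expect_true(is.na(agg$solidity[agg$class == "DWMH"]))
})
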