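test_that("depth surfaces interpolate the white-pial segment", {
  white <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        matrix(c(1, 2, 3), 1))
  pial <- surface_mesh(rbind(c(0, 0, 2), c(1, 0, 2), c(0, 1, 2)),
                       matrix(c(1, 2, 3), 1))
  expect_equal(depth_surface(white, pial, 0)$vertices, white$vertices)
  expect_equal(depth_surface(white, pial, 1)$vertices, pial$vertices)
  expect_equal(depth_surface(white, pial, 0.4)$vertices[1, ], c(0, 0, 0.8))
  expect_error(depth_surface(white, icosphere(0), 0.5), "vertex counts")
  expect_error(depth_surface(white, pial, 1.2), "\\[0, 1\\]")
})

test_that("wm surfaces displace along the inward normal", {
  m <- icosphere(3, 40)
  w1 <- wm_surface(m, 1.0)
  expect_equal(sqrt(rowSums(w1$vertices^2)), rep(39, 642), tolerance = 1e-3)
  w2 <- wm_surface(wm_surface(m, 0.5), 0.5)
  expect_equal(w2$vertices, w1$vertices, tolerance = 1e-4)
  expect_identical(wm_surface(m, 0), m)
})

test_that("trilinear sampling interpolates exactly on simple grids", {
  d <- array(0, c(8, 8, 8))
  d[4, 5, 6] <- 42
  vol <- volume_image(d + 100, diag(4))
  at <- function(xyz) surface_mesh(matrix(xyz, 1), matrix(c(1, 1, 1), 1),
                                   validate = FALSE)
  # voxel centre: exact stored value (0-based index (3,4,5))
  expect_equal(as.numeric(sample_volume(at(c(3, 4, 5)), vol)), 142)
  # midway between two voxels along one axis
  expect_equal(as.numeric(sample_volume(at(c(3.5, 4, 5)), vol)), 121)
  # uniform volume: any position inside gives the constant
  uni <- volume_image(array(100, c(8, 8, 8)), diag(4))
  expect_equal(as.numeric(sample_volume(at(c(2.3, 4.7, 5.1)), uni)), 100)
  # outside the grid: flagged undefined, not zero
  out <- sample_volume(at(c(20, 2, 2)), vol)
  expect_true(is.na(out[1]))
  expect_equal(attr(out, "n_undefined"), 1L)
})

test_that("nearest-neighbour sampling picks the containing voxel", {
  d <- array(seq_len(27), c(3, 3, 3))
  vol <- volume_image(d, diag(4))
  m <- surface_mesh(matrix(c(1.2, 0.8, 1.4), 1), matrix(c(1, 1, 1), 1),
                    validate = FALSE)
  expect_equal(as.numeric(sample_volume(m, vol, interpolation = "nearest")),
               d[2, 2, 2])
})

test_that("the feature stack has thickness plus 4 x 2 ratio columns", {
  s <- make_phantom_subject(recovery_phantom())
  f <- contrast_features(s$white, s$pial, s$volume)
  expect_s3_class(f, "feature_stack")
  expect_identical(colnames(f),
                   c("thickness", "G20.W0.5", "G40.W0.5", "G60.W0.5",
                     "G80.W0.5", "G20.W1", "G40.W1", "G60.W1", "G80.W1"))
  expect_equal(ncol(f) - 1L, 8L)
  expect_true(all(f[, -1] > 0))
})

test_that("a uniform volume gives ratio 1 everywhere for any geometry", {
  s <- make_phantom_subject(recovery_phantom(), rng_seed = 3L)
  uni <- volume_image(array(77, dim(s$volume$data)), s$volume$affine)
  f <- contrast_features(s$white, s$pial, uni)
  expect_equal(unname(f[, -1]), matrix(1, 162, 8), tolerance = 1e-9)
})

test_that("ratios are invariant to global intensity rescaling; thickness to intensity entirely", {
  s <- make_phantom_subject(recovery_phantom(subdivisions = 2L), rng_seed = 8L)
  f1 <- contrast_features(s$white, s$pial, s$volume)
  scaled <- volume_image(s$volume$data * 3.7, s$volume$affine)
  f2 <- contrast_features(s$white, s$pial, scaled)
  expect_equal(unname(f2[, -1]), unname(f1[, -1]), tolerance = 1e-12)
  expect_identical(f2[, "thickness"], f1[, "thickness"])
})

test_that("the wm-over-gm ratio direction is the reciprocal", {
  s <- make_phantom_subject(recovery_phantom())
  f <- contrast_features(s$white, s$pial, s$volume)
  g <- contrast_features(s$white, s$pial, s$volume,
                         ratio_direction = "wm_over_gm")
  expect_equal(unname(g[, -1]), unname(1 / f[, -1]), tolerance = 1e-9)
})
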