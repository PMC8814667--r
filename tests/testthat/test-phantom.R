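test_that("noise-free phantom recovers configured intensities and thickness", {
  pc <- recovery_phantom()
  s <- make_phantom_subject(pc)
  expect_equal(cortical_thickness(s$white, s$pial), rep(3, 162),
               tolerance = 1e-6)
  mid <- depth_surface(s$white, s$pial, 0.5)
  gm <- sample_volume(mid, s$volume)
  expect_equal(as.numeric(gm), rep(pc$gm, 162), tolerance = 1e-9)
  wm <- sample_volume(wm_surface(s$white, 1.0), s$volume)
  expect_equal(as.numeric(wm), rep(pc$wm, 162), tolerance = 1e-9)
})

test_that("contrast effect shifts in-mask GM/WM ratio by the constructed amount", {
  pc <- recovery_phantom()
  mesh <- mssm:::phantom_mesh(pc)
  mask <- cap_mask(mesh, 45)
  eff <- effect_spec(contrast_mask = mask, contrast_delta = 0.3)
  s <- make_phantom_subject(pc, eff)
  f <- contrast_features(s$white, s$pial, s$volume)
  # clear of the mask boundary: restrict to a tighter cap / its complement
  core <- cap_mask(mesh, 30)
  rim <- !cap_mask(mesh, 60)
  expect_equal(mean(f[core, "G40.W1"]), (75 + 0.3 * 35) / 110, tolerance = 0.01)
  expect_equal(mean(f[rim, "G40.W1"]), 75 / 110, tolerance = 0.01)
})

test_that("in-mask ratio increases monotonically with contrast_delta", {
  pc <- recovery_phantom()
  mesh <- mssm:::phantom_mesh(pc)
  mask <- cap_mask(mesh, 45)
  core <- cap_mask(mesh, 30)
  means <- sapply(c(0, 0.1, 0.2, 0.4), function(delta) {
    eff <- effect_spec(contrast_mask = mask, contrast_delta = delta)
    s <- make_phantom_subject(pc, eff)
    mean(contrast_features(s$white, s$pial, s$volume)[core, "G40.W1"])
  })
  expect_true(all(diff(means) > 0))
})

test_that("thinning reduces measured thickness only inside the mask", {
  pc <- recovery_phantom()
  mesh <- mssm:::phantom_mesh(pc)
  mask <- cap_mask(mesh, 40)
  eff <- effect_spec(thickness_mask = mask, thickness_delta_mm = 0.8)
  s <- make_phantom_subject(pc, eff)
  th <- cortical_thickness(s$white, s$pial)
  expect_equal(th[mask], rep(2.2, sum(mask)), tolerance = 1e-6)
  expect_equal(th[!mask], rep(3.0, sum(!mask)), tolerance = 1e-6)
})

test_that("a thickness delta at least as large as the cortex is rejected", {
  pc <- recovery_phantom()
  mesh <- mssm:::phantom_mesh(pc)
  eff <- effect_spec(thickness_mask = cap_mask(mesh, 30),
                     thickness_delta_mm = 3)
  expect_error(make_phantom_subject(pc, eff), "degenerate ribbon")
})

test_that("pial surface lies strictly outside the white surface", {
  s <- make_phantom_subject(tiny_phantom(), rng_seed = 4L)
  rw <- sqrt(rowSums(s$white$vertices^2))
  rp <- sqrt(rowSums(s$pial$vertices^2))
  expect_true(all(rp > rw))
})

test_that("cohorts are reproducible from the seed, byte for byte on disk", {
  pc <- tiny_phantom()
  mesh <- mssm:::phantom_mesh(pc)
  eff <- ad_effect(mesh, thickness_delta_mm = 0.3, contrast_delta = 0.1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_cohort(pc, eff, 2, 2, seed = 5L, out_dir = d1)
  make_cohort(pc, eff, 2, 2, seed = 5L, out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(all(c("cohort.csv", "truth.json") %in% f1))
  expect_identical(f1, list.files(d2, recursive = TRUE))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_true(all(unname(h1) == unname(h2)))
})

test_that("affected and control subjects differ only as specified", {
  pc <- tiny_phantom()
  mesh <- mssm:::phantom_mesh(pc)
  eff <- ad_effect(mesh)
  co <- make_cohort(pc, eff, 3, 3, seed = 2L)
  expect_equal(as.vector(table(co$cohort$label)[c("AD", "CN")]), c(3L, 3L))
  expect_true(all(co$severity[co$cohort$label == "CN", ] == 0))
  expect_true(any(co$severity[co$cohort$label == "AD", ] > 0))
})

test_that("phantom config invariants are enforced", {
  expect_error(phantom_config(gm = 120), "WM > GM > CSF")
  expect_error(phantom_config(thickness_mm = -1), "positive")
  expect_error(phantom_config(noise_sd = -0.1), "noise_sd")
  expect_error(effect_spec(thickness_delta_mm = -0.2), ">= 0")
})
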