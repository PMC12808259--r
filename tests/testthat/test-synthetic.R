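test_that("scene generation is byte-identical under a fixed seed", {
  p <- scene_params("WHITE_COTTON", height = 128, width = 128,
                    n_particles = 20, seed = 3)
  a <- simulate_scene(p)
  b <- simulate_scene(p)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$particles, b$truth$particles)
  expect_identical(a$truth$mask, b$truth$mask)

  tp <- scene_params("TAPE", height = 64, width = 64, n_particles = 5,
                     seed = 3)
  expect_identical(simulate_tape_scan(tp)$image$pixels,
                   simulate_tape_scan(tp)$image$pixels)
})

test_that("denim texture concentrates its energy at the twill frequency", {
  p <- scene_params("DENIM", height = 256, width = 256, seed = 4)
  bg <- generate_fabric_texture(p)
  f <- p$constants$denim_twill_freq
  spec <- Mod(stats::fft(bg$pixels))^2
  spec[1, 1] <- 0 # drop DC
  peak <- which(spec == max(spec), arr.ind = TRUE)[1, ]
  # unshifted DFT coordinates of the diagonal twill: (f, f) or its conjugate
  u <- peak[1] - 1; v <- peak[2] - 1
  if (u > 128) u <- 256 - u
  if (v > 128) v <- 256 - v
  expect_lte(abs(u - f), 1)
  expect_lte(abs(v - f), 1)
})

test_that("noiseless gradient-free weave is exactly periodic", {
  k <- scene_defaults()
  k$white_gradient_amp <- 0
  k$white_weave_freq <- 64 # period 4 px on a 256-wide frame
  p <- scene_params("WHITE_COTTON", height = 256, width = 256, noise_sd = 0,
                    seed = 1, constants = k)
  bg <- generate_fabric_texture(p)
  expect_equal(bg$pixels[, 1:252], bg$pixels[, 5:256], tolerance = 1e-12)
  expect_equal(bg$pixels[1:252, ], bg$pixels[5:256, ], tolerance = 1e-12)
})

test_that("planting zero particles changes nothing", {
  p <- scene_params("DENIM", height = 64, width = 64, n_particles = 0,
                    seed = 6)
  bg <- generate_fabric_texture(p)
  sc <- plant_particles(bg, p)
  expect_identical(sc$image$pixels, bg$pixels)
  expect_equal(nrow(sc$truth$particles), 0)
  expect_false(any(sc$truth$mask))
})

test_that("non-overlapping planted particles form exactly n components", {
  p <- scene_params("WHITE_COTTON", n_particles = 50, seed = 11)
  sc <- plant_particles(generate_fabric_texture(p), p)
  # independent labelling of the truth mask (EBImage, 4-connectivity, which
  # agrees with 8 for disjoint guard-banded discs)
  n_comp <- max(EBImage::bwlabel(sc$truth$mask * 1))
  expect_equal(n_comp, 50)
  expect_true(all(sc$image$pixels[sc$truth$mask] <= 0.15))
})

test_that("doubling dispersion spreads particles farther from the defect", {
  mean_dist <- function(disp, seed) {
    p <- scene_params("WHITE_COTTON", height = 128, width = 128,
                      n_particles = 20, dispersion = disp, seed = seed)
    tab <- plant_particles(generate_fabric_texture(p), p)$truth$particles
    mean(sqrt((tab$row - 64)^2 + (tab$col - 64)^2))
  }
  d1 <- vapply(1:20, function(s) mean_dist(15, s), numeric(1))
  d2 <- vapply(1:20, function(s) mean_dist(30, s), numeric(1))
  expect_gt(mean(d2), mean(d1))
})

test_that("impossible packing requests fail with guidance", {
  p <- scene_params("WHITE_COTTON", height = 32, width = 32,
                    n_particles = 500, seed = 1)
  expect_error(plant_particles(generate_fabric_texture(p), p),
               "could only place")
})

test_that("defects exclude particles and are carved out of the truth mask", {
  p <- scene_params("WHITE_COTTON", height = 128, width = 128,
                    n_particles = 20, defect_radius = 10, seed = 9)
  sc <- plant_particles(generate_fabric_texture(p), p)
  expect_false(any(sc$truth$mask & sc$truth$defect_mask))
  d <- sqrt((sc$truth$particles$row - 64)^2 + (sc$truth$particles$col - 64)^2)
  expect_true(all(d > 10))
  expect_true(all(sc$image$pixels[sc$truth$defect_mask] <= 0.05))
})

test_that("blood rendering follows the modality and state contrasts", {
  mk <- function(modality, state) {
    p <- scene_params("DENIM", height = 128, width = 128, n_particles = 10,
                      blood = list(state = state, coverage = 0.15,
                                   droplets = 6),
                      seed = 17)
    sc <- simulate_scene(p, modality = modality)
    list(img = sc$image, truth = sc$truth)
  }
  wet_ir <- mk("IR", "wet")
  dry_ir <- mk("IR", "dry")
  pure_blood <- function(x) x$truth$blood_mask & !x$truth$mask
  # dried blood is lighter than wet blood in IR
  expect_gt(mean(dry_ir$img$pixels[pure_blood(dry_ir)]),
            mean(wet_ir$img$pixels[pure_blood(wet_ir)]))

  # wet blood under visible light carries specular highlights
  wet_vl <- mk("VL", "wet")
  expect_gt(max(wet_vl$img$pixels[pure_blood(wet_vl)]), 0.9)
  # while the bulk of the stain is near-black
  expect_lt(median(wet_vl$img$pixels[pure_blood(wet_vl)]), 0.2)

  # coverage 0 leaves the scene untouched
  p0 <- scene_params("DENIM", height = 64, width = 64, n_particles = 5,
                     blood = list(state = "wet", coverage = 0, droplets = 0),
                     seed = 1)
  bg <- generate_fabric_texture(p0)
  sc <- plant_particles(bg, p0)
  after <- add_blood(sc$image, sc$truth, p0)
  expect_identical(after$image$pixels, sc$image$pixels)

  expect_error(scene_params("DENIM", blood = list(state = "wet",
                                                  coverage = 0.95)),
               "coverage")
})

test_that("paired renders keep geometry and flip only material intensities", {
  p <- scene_params("DENIM", height = 128, width = 128, n_particles = 15,
                    seed = 23)
  pair <- render_pair(p)
  expect_identical(pair$vl$truth$particles, pair$ir$truth$particles)
  bg_px <- !pair$vl$truth$mask
  expect_gt(mean(pair$ir$image$pixels[bg_px]),
            mean(pair$vl$image$pixels[bg_px]))
  expect_true(all(pair$vl$image$pixels[pair$vl$truth$mask] < 0.2))
  expect_true(all(pair$ir$image$pixels[pair$ir$truth$mask] < 0.2))

  pw <- scene_params("WHITE_COTTON", height = 128, width = 128,
                     n_particles = 15, seed = 23)
  wpair <- render_pair(pw)
  expect_lt(abs(mean(wpair$ir$image$pixels[!wpair$ir$truth$mask]) -
                  mean(wpair$vl$image$pixels[!wpair$vl$truth$mask])), 0.05)
})

test_that("stage seeding leaves the caller's RNG stream untouched", {
  set.seed(314)
  before <- .Random.seed
  p <- scene_params("WHITE_COTTON", height = 64, width = 64,
                    n_particles = 5, seed = 2)
  invisible(simulate_scene(p))
  expect_identical(.Random.seed, before)
})
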