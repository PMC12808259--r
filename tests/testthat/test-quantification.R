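test_that("physical area is exactly the calibrated pixel area", {
  expect_identical(particle_area(0, 0.1), 0)
  expect_equal(particle_area(25, 0.1), 0.25)
  for (l in c(0.01, 0.05, 0.1, 1, 2.5)) {
    for (n in c(0, 1, 7, 144, 100000)) {
      expect_identical(particle_area(n, l), l^2 * n)
    }
  }
  expect_error(particle_area(-1, 0.1), "n_pixel")
  expect_error(particle_area(5, 0), "l_pixel")
})

test_that("per-particle areas are additive over a particle set", {
  m <- random_mask(32, 32, 0.2, seed = 8)
  ps <- label_components(m, l_pixel = 0.07)
  expect_equal(sum(ps$area_mm2), 0.07^2 * sum(ps$n_pixel))
  q <- summarize_particles(ps)
  expect_equal(q$total_area_mm2, sum(ps$area_mm2))
})

test_that("summaries report count and totals consistent with the mask", {
  empty <- label_components(gsr_mask(matrix(FALSE, 4, 4)))
  q0 <- summarize_particles(empty)
  expect_equal(q0$count, 0)
  expect_equal(q0$total_pixels, 0)
  expect_true(is.na(q0$total_area_mm2))

  pix <- matrix(FALSE, 8, 8); pix[2:3, 2:3] <- TRUE; pix[6:7, 6:7] <- TRUE
  q <- summarize_particles(label_components(gsr_mask(pix)))
  expect_equal(q$count, 2)
  expect_equal(q$total_pixels, 8)
  expect_equal(q$total_area_pixels, 8)

  for (seed in 1:5) {
    m <- random_mask(24, 24, 0.3, seed = seed)
    q <- summarize_particles(label_components(m))
    expect_equal(q$total_pixels, sum(m$pixels)) # mask-sum oracle
    expect_equal(q$count, flood_fill_oracle(m$pixels)$count)
  }
})

test_that("blank fabric yields zero particles end to end", {
  p <- scene_params("WHITE_COTTON", height = 256, width = 256,
                    n_particles = 0, seed = 7)
  sc <- simulate_scene(p)
  q <- run_fabric_pipeline(sc$image)
  expect_equal(q$count, 0)
  expect_equal(q$provenance$threshold, 0)
})

test_that("planted particles on white cotton are recovered exactly", {
  p <- scene_params("WHITE_COTTON", height = 256, width = 256,
                    n_particles = 50, seed = 11)
  sc <- simulate_scene(p)
  q <- run_fabric_pipeline(sc$image)
  expect_equal(q$count, 50)
  expect_gte(detection_score(q, sc$truth)$f1, 0.99)
})

test_that("denim band-pass pipeline recovers planted particles", {
  p <- scene_params("DENIM", n_particles = 200, seed = 13)
  sc <- simulate_scene(p)
  q <- run_fabric_pipeline(sc$image)
  expect_gte(q$count, 190)
  expect_lte(q$count, 210)
  expect_gte(detection_score(q, sc$truth)$f1, 0.9)
  expect_equal(q$provenance$filter$kind, "band_pass")
})

test_that("tape pipeline counts planted spots through the value channel", {
  blank <- gsr_rgb(array(0.95, dim = c(64, 64, 3)))
  expect_equal(run_tape_pipeline(blank)$count, 0)          # constant scan
  expect_equal(run_tape_pipeline(blank, list(threshold = 0.5))$count, 0)

  p <- scene_params("TAPE", height = 256, width = 256, n_particles = 30,
                    seed = 5)
  sc <- simulate_tape_scan(p)
  q <- run_tape_pipeline(sc$image)
  expect_equal(q$count, 30)
  expect_equal(q$provenance$route, "hsv_value_channel")
})

test_that("tape counts are invariant under a global hue rotation", {
  p <- scene_params("TAPE", height = 128, width = 128, n_particles = 15,
                    seed = 5)
  sc <- simulate_tape_scan(p)
  q1 <- run_tape_pipeline(sc$image)
  rotated <- gsr_rgb(hue_rotate_exact(sc$image$pixels, 0.35))
  q2 <- run_tape_pipeline(rotated)
  expect_identical(q1$count, q2$count)
  expect_identical(q1$total_pixels, q2$total_pixels)
})

test_that("pipelines are deterministic for identical input and config", {
  p <- scene_params("DENIM", height = 128, width = 128, n_particles = 30,
                    seed = 21)
  sc <- simulate_scene(p)
  q1 <- run_fabric_pipeline(sc$image)
  q2 <- run_fabric_pipeline(sc$image)
  expect_identical(q1, q2)
})

test_that("count is non-increasing in min_pixels and threshold tightening", {
  p <- scene_params("WHITE_COTTON", height = 128, width = 128,
                    n_particles = 25, seed = 2)
  sc <- simulate_scene(p)
  counts_mp <- vapply(c(1, 2, 4, 8, 16), function(k) {
    run_fabric_pipeline(sc$image, config = list(min_pixels = k))$count
  }, numeric(1))
  expect_true(all(diff(counts_mp) <= 0))

  # lowering the threshold leaves fewer foreground pixels
  px <- vapply(c(0.6, 0.4, 0.2, 0.1), function(t) {
    run_fabric_pipeline(sc$image, config = list(threshold = t))$total_pixels
  }, numeric(1))
  expect_true(all(diff(px) <= 0))
})

test_that("pipeline routing validates its input types", {
  rgb <- gsr_rgb(array(0.5, dim = c(8, 8, 3)))
  expect_error(run_fabric_pipeline(rgb), "run_tape_pipeline")
  grey <- gsr_image(matrix(0.5, 8, 8))
  expect_error(run_tape_pipeline(grey), "run_fabric_pipeline")
  unk <- gsr_image(matrix(0.5, 16, 16), fabric = "UNKNOWN")
  expect_error(run_fabric_pipeline(unk), "preset|filter")
  # but an explicit filter config unlocks unknown fabrics
  q <- run_fabric_pipeline(
    unk, config = list(filter = filter_spec("high_pass", 2),
                       threshold = 0.5))
  expect_s3_class(q, "gsr_quant")
})

test_that("region of interest restricts the analysis frame", {
  p <- scene_params("WHITE_COTTON", height = 256, width = 256,
                    n_particles = 40, seed = 31)
  sc <- simulate_scene(p)
  full <- run_fabric_pipeline(sc$image)
  # a tiny corner ROI holds none of the centrally dispersed particles
  corner <- run_fabric_pipeline(
    sc$image, config = list(roi = c(1, 1, 20, 20)))
  expect_equal(corner$count, 0)
  expect_gt(full$count, 0)
})

test_that("tidy and glance expose the particle table and one-row summary", {
  p <- scene_params("WHITE_COTTON", height = 128, width = 128,
                    n_particles = 10, seed = 3)
  sc <- simulate_scene(p)
  q <- run_fabric_pipeline(sc$image)
  td <- tidy(q)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), q$count)
  gl <- glance(q)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$count, q$count)
  expect_equal(gl$filter, "high_pass")
})
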