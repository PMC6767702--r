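test_that("identical configuration and seed reproduce the scene exactly", {
  a <- small_scene(seed = 5)
  b <- small_scene(seed = 5)
  expect_identical(a$ribbons$coords, b$ribbons$coords)
  expect_identical(a$ribbons$volumes, b$ribbons$volumes)
  expect_identical(a$efferents$coords, b$efferents$coords)
  expect_identical(a$ribbons$annotations$true_side,
                   b$ribbons$annotations$true_side)
  c_ <- small_scene(seed = 6)
  expect_false(identical(a$ribbons$coords, c_$ribbons$coords))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- rnorm(3)
  set.seed(123)
  invisible(small_scene(seed = 99))
  expect_identical(rnorm(3), before)
})

test_that("side labels partition the ribbons and match the requested fraction", {
  sc <- generate_scene(scene_config(n_ihc = 40, pillar_fraction = 0.5,
                                    seed = 2))
  side <- sc$ribbons$annotations$true_side
  expect_true(all(side %in% c("pillar", "modiolar")))
  n <- n_puncta(sc$ribbons)
  expect_equal(sum(side == "pillar") + sum(side == "modiolar"), n)
  # exact allocation: realized fraction equals 0.5 up to integer rounding,
  # well inside the binomial 99% interval
  expect_lt(abs(mean(side == "pillar") - 0.5), 2.58 * sqrt(0.25 / n))
})

test_that("a unit volume ratio gives indistinguishable pillar and modiolar volumes", {
  sc <- generate_scene(scene_config(n_ihc = 60, seed = 3,
                                    modiolar_pillar_volume_ratio = 1,
                                    pillar_fraction = 0.5))
  side <- sc$ribbons$annotations$true_side
  expect_gte(n_puncta(sc$ribbons), 500)
  tt <- t.test(sc$ribbons$volumes[side == "pillar"],
               sc$ribbons$volumes[side == "modiolar"])
  expect_gt(tt$p.value, 0.01)
})

test_that("per-cell ribbon counts recover the Poisson mean", {
  sc <- generate_scene(scene_config(n_ihc = 200, cells_per_ohc_row = 3,
                                    ribbons_per_ihc_mean = 17, seed = 8))
  rate <- n_puncta(sc$ribbons) / 200
  expect_lt(abs(rate - 17), 3 * sqrt(17 / 200))
})

test_that("efferent placement honors the developmental stage", {
  mat <- generate_scene(scene_config(n_ihc = 30, efferent_stage = "mature",
                                     seed = 4))
  # mature terminals all sub-nuclear (nuclei near z = 0; jitter is small)
  expect_true(all(mat$efferents$coords[, 3] < 0))
  imm <- generate_scene(scene_config(n_ihc = 60, efferent_stage = "immature",
                                     axosomatic_fraction_immature = 0.3,
                                     seed = 4))
  frac_above <- mean(imm$efferents$coords[, 3] > 0)
  n <- n_puncta(imm$efferents)
  expect_gt(frac_above, 0)
  expect_lt(abs(frac_above - 0.3), 2.58 * sqrt(0.3 * 0.7 / n))
})

test_that("the landmark lies strictly off the IHC row axis, on the pillar side", {
  sc <- small_scene()
  ax <- fit_axis(sc$ihc_nuclei)
  rel <- sc$landmark_point - ax$centroid
  perp <- rel - sum(rel * ax$direction) * ax$direction
  expect_gt(sqrt(sum(perp^2)), 5)
})

test_that("degenerate and invalid configurations are rejected", {
  expect_error(scene_config(n_ihc = 2), "n_ihc")
  expect_error(scene_config(pillar_fraction = 1.2))
  expect_error(scene_config(ihc_spacing_um = 0))
  expect_error(scene_config(n_ohc_rows = 5), "n_ohc_rows")
  expect_error(scene_config(modiolar_pillar_volume_ratio = 0.8))
})

test_that("row curvature bends the nuclei row onto an arc", {
  sc <- generate_scene(scene_config(n_ihc = 30, row_curvature = 1 / 200,
                                    placement_jitter_um = 0, seed = 1))
  pos <- sc$ihc_nuclei$centroids
  # all nuclei at distance ~200 from the arc centre (0, 200, 0)
  r <- sqrt(pos[, 1]^2 + (pos[, 2] - 200)^2)
  expect_true(all(abs(r - 200) < 1e-6))
})
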