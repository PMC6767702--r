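test_that("the principal axis of collinear points is the line itself", {
  pts <- cbind(c(0, 1, 2, 5), 0, 0)
  ax <- fit_axis(pts)
  expect_equal(abs(ax$direction), c(1, 0, 0))
  expect_equal(ax$extent_min_point, c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(ax$extent_max_point, c(5, 0, 0), ignore_attr = TRUE)
})

test_that("axis fitting is permutation invariant and recovers the row direction", {
  sc <- generate_scene(scene_config(n_ihc = 15, seed = 21))
  ax1 <- fit_axis(sc$ribbons)
  perm <- sample(n_puncta(sc$ribbons))
  ax2 <- fit_axis(sc$ribbons$coords[perm, ])
  expect_equal(ax1$direction, ax2$direction)
  expect_equal(ax1$centroid, ax2$centroid)
  # row direction of the generated scene is +x; within 2 degrees
  angle <- acos(min(1, abs(sum(ax1$direction * c(1, 0, 0))))) * 180 / pi
  expect_lt(angle, 2)
})

test_that("degenerate point clouds are rejected", {
  expect_error(fit_axis(cbind(c(0, 1), 0, 0)), "at least 3")
  expect_error(fit_axis(matrix(1, 5, 3)), "coincident")
})

test_that("the plane from constructed geometry separates as expected", {
  # ribbons along x in the z = 0 plane; nuclei centroid lifted in +z
  rib <- fit_axis(cbind(c(-4, -2, 0, 2, 4), 0, 0))
  nuc <- fit_axis(cbind(c(-1, 0, 1), 0, 3 + c(-0.01, 0, 0.01)))
  plane <- build_plane(rib, nuc, landmark = c(0, 5, 0))
  # plane contains the x-axis and the centroid; +y side is pillar
  expect_equal(abs(sum(plane$normal * c(0, 1, 0))), 1, tolerance = 1e-4)
  d <- signed_distance(rbind(c(0, 2, 0), c(0, -2, 0)), plane)
  expect_gt(d[1], 0)
  expect_lt(d[2], 0)
  # swapping the landmark to the opposite side flips every label
  plane2 <- build_plane(rib, nuc, landmark = c(0, -5, 0))
  expect_equal(signed_distance(rbind(c(0, 2, 0), c(0, -2, 0)), plane2), -d)
})

test_that("collinear defining points and on-plane landmarks are rejected", {
  rib <- fit_axis(cbind(c(-4, -2, 0, 2, 4), 0, 0))
  nuc_on_axis <- fit_axis(cbind(c(-1, 0.001, 1), 0, 0))
  expect_error(build_plane(rib, nuc_on_axis, c(0, 5, 0)), "degenerate")
  nuc <- fit_axis(cbind(c(-1, 0, 1), 0, 3 + c(-0.01, 0, 0.01)))
  expect_error(build_plane(rib, nuc, c(2, 0, 0)), "landmark")
})

test_that("classification recovers ground-truth sides and fractions", {
  for (pf in c(0.44, 0.5)) {
    sc <- generate_scene(scene_config(n_ihc = 30, pillar_fraction = pf,
                                      seed = 7))
    part <- scene_partition(sc)
    expect_identical(unname(part$side), sc$ribbons$annotations$true_side)
    expect_equal(sum(part$counts), n_puncta(sc$ribbons))
    expect_equal(sum(part$fractions), 1)
    expect_lt(abs(part$fractions[["pillar"]] - pf), 0.01)
  }
})

test_that("mirror-symmetric ribbon pairs split exactly 50/50", {
  rib_axis <- fit_axis(cbind(seq(-10, 10, by = 2), 0, -4 + 1e-9 * seq(-10, 10, by = 2)))
  nuc <- fit_axis(cbind(c(-1, 0, 1), 0, c(-0.01, 0, 0.01)))
  plane <- build_plane(rib_axis, nuc, landmark = c(0, 20, 0))
  x <- seq(-9, 9, by = 2)
  pairs <- rbind(cbind(x, 2, -4), cbind(x, -2, -4))
  part <- classify_ribbons(puncta_set(pairs), plane)
  expect_equal(unname(part$counts), c(10, 10), ignore_attr = TRUE)
})

test_that("classification accuracy degrades gracefully with jitter", {
  acc <- vapply(c(0.5, 2, 4), function(j) {
    sc <- generate_scene(scene_config(n_ihc = 30, placement_jitter_um = j,
                                      pillar_fraction = 0.5, seed = 13))
    part <- scene_partition(sc)
    mean(part$side == sc$ribbons$annotations$true_side)
  }, numeric(1))
  expect_equal(acc[1], 1)          # offset/jitter = 6
  expect_true(all(diff(acc) <= 0)) # monotone degradation
  expect_gt(acc[3], 0.5)           # still better than chance
})

test_that("volume normalization divides by the stack median", {
  ps <- puncta_set(cbind(1:3, 0, 0), volumes = c(1, 2, 3))
  expect_equal(normalize_volumes(ps)$volumes, c(0.5, 1, 1.5))
  same <- puncta_set(cbind(1:4, 0, 0), volumes = rep(7, 4))
  expect_equal(normalize_volumes(same)$volumes, rep(1, 4))
})

test_that("normalization is idempotent and per stack, pooled across sets", {
  s1a <- puncta_set(cbind(1:3, 0, 0), "s1", "CTBP2", volumes = c(1, 2, 3))
  s1b <- puncta_set(cbind(1:2, 0, 0), "s1", "CTBP2-OHC", volumes = c(4, 5))
  s2 <- puncta_set(cbind(1:3, 0, 0), "s2", "CTBP2", volumes = c(10, 20, 30))
  out <- normalize_volumes(list(s1a, s1b, s2))
  # stack s1 median over pooled volumes {1,2,3,4,5} = 3
  expect_equal(out[[1]]$volumes, c(1, 2, 3) / 3)
  expect_equal(out[[2]]$volumes, c(4, 5) / 3)
  expect_equal(out[[3]]$volumes, c(0.5, 1, 1.5))
  twice <- normalize_volumes(out)
  expect_equal(lapply(twice, `[[`, "volumes"), lapply(out, `[[`, "volumes"))
  expect_error(normalize_volumes(puncta_set(cbind(1, 0, 0))), "volumes")
})

test_that("partition summary reports the modiolar/pillar volume gradient", {
  sc <- generate_scene(scene_config(n_ihc = 30, seed = 31,
                                    modiolar_pillar_volume_ratio = 1,
                                    pillar_fraction = 0.5))
  res <- classify_stack(sc$ribbons, sc$ihc_nuclei, sc$landmark_point)
  sm <- res$summary
  expect_equal(sum(sm$by_side$fraction), 1)
  # ratio-1 scene: recovered ratio near 1 (Damaraland-like, no gradient)
  expect_lt(abs(sm$volume_ratio_modiolar_pillar - 1), 0.15)
  tt <- t.test(res$partition$ribbons$volumes[res$partition$side == "pillar"],
               res$partition$ribbons$volumes[res$partition$side == "modiolar"])
  expect_gt(tt$p.value, 0.05)
})

test_that("an empty side leaves the ratio undefined and flagged", {
  rib_axis <- fit_axis(cbind(c(-4, 0, 4), 0, -4 + c(-1e-9, 0, 1e-9)))
  nuc <- fit_axis(cbind(c(-1, 0, 1), 0, c(-0.01, 0, 0.01)))
  plane <- build_plane(rib_axis, nuc, landmark = c(0, 20, 0))
  only_pillar <- puncta_set(cbind(c(-1, 0, 1), 3, -4), volumes = c(1, 2, 3))
  sm <- summarize_partition(classify_ribbons(only_pillar, plane))
  expect_false(sm$ratio_defined)
  expect_true(is.na(sm$volume_ratio_modiolar_pillar))
})
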