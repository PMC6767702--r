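test_that("a single centred punctum renders with its peak at that voxel", {
  # with the declared box, (2.1, 2.1, 1.65) is the centre of a voxel
  ps <- puncta_set(rbind(c(2.1, 2.1, 1.65)))
  st <- render_stack(ps, voxel_size_um = c(0.2, 0.2, 0.3),
                     psf_sigma_um = c(0.3, 0.3, 0.45),
                     bbox = rbind(c(0, 0, 0), c(4.2, 4.2, 3.3)))
  idx <- arrayInd(which.max(st$image), dim(st$image))
  ctr <- st$origin_um + (idx - 0.5) * st$voxel_size_um
  expect_equal(as.numeric(ctr), c(2.1, 2.1, 1.65), tolerance = 1e-9)
})

test_that("integrated blob intensity equals the punctum volume within 1%", {
  ps <- puncta_set(rbind(c(0, 0, 0)), volumes = 0.5)
  st <- render_stack(ps, voxel_size_um = c(0.15, 0.15, 0.25),
                     psf_sigma_um = c(0.3, 0.3, 0.45), margin_um = 4)
  expect_equal(sum(st$image), 0.5, tolerance = 0.01)
})

test_that("the noiseless render is deterministic across noise seeds", {
  ps <- blob_field(c(2, 2, 1))
  a <- render_stack(ps, noise_model = "none", noise_seed = 1)
  b <- render_stack(ps, noise_model = "none", noise_seed = 2)
  expect_identical(a$image, b$image)
  n1 <- render_stack(ps, noise_model = "gaussian", snr = 5, noise_seed = 1)
  n2 <- render_stack(ps, noise_model = "gaussian", snr = 5, noise_seed = 2)
  expect_false(identical(n1$image, n2$image))
})

test_that("puncta outside a declared bounding box are rejected", {
  ps <- puncta_set(rbind(c(0, 0, 0), c(30, 0, 0)))
  expect_error(render_stack(ps, bbox = rbind(c(-5, -5, -5), c(10, 5, 5))),
               "outside")
})

test_that("stacks round-trip through multi-page TIFF with metadata", {
  ps <- blob_field(c(2, 2, 2))
  st <- render_stack(ps)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(st, path)
  back <- read_stack_tiff(path)
  expect_equal(dim(back$image), dim(st$image))
  expect_equal(back$voxel_size_um, st$voxel_size_um)
  expect_equal(back$image, st$image, tolerance = 1e-6)
})

test_that("detection finds every well-separated punctum within a voxel", {
  ps <- blob_field(c(3, 3, 2), seed = 11)
  st <- render_stack(ps, voxel_size_um = c(0.2, 0.2, 0.3),
                     psf_sigma_um = c(0.25, 0.25, 0.4))
  det <- detect_spots(st)
  expect_equal(n_puncta(det), n_puncta(ps))
  d <- nn_distances(det$coords, ps$coords)$distances
  expect_lt(max(d), sqrt(sum(c(0.2, 0.2, 0.3)^2)))  # within one voxel
})

test_that("an all-zero stack yields an empty set, not an error", {
  det <- detect_spots(array(0, c(10, 10, 5)), voxel_size_um = c(0.2, 0.2, 0.3))
  expect_equal(n_puncta(det), 0)
})

test_that("detection count is monotone non-increasing in the peak threshold", {
  ps <- blob_field(c(3, 3, 1), seed = 12, vol_sdlog = 0.9)
  st <- render_stack(ps)
  counts <- vapply(c(0.02, 0.1, 0.3, 0.6, 0.9), function(th) {
    n_puncta(detect_spots(st, config = detection_config(peak_threshold = th)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detections shift with whole-voxel translations of the stack", {
  ps <- blob_field(c(2, 2, 1), seed = 13)
  st <- render_stack(ps)
  shifted <- st
  shift_vox <- c(3L, 2L, 1L)
  d <- dim(st$image)
  shifted$image <- array(0, d)
  shifted$image[(1 + shift_vox[1]):d[1], (1 + shift_vox[2]):d[2],
                (1 + shift_vox[3]):d[3]] <-
    st$image[1:(d[1] - shift_vox[1]), 1:(d[2] - shift_vox[2]),
             1:(d[3] - shift_vox[3])]
  a <- detect_spots(st)
  b <- detect_spots(shifted)
  expect_equal(n_puncta(a), n_puncta(b))
  ord_a <- order(a$coords[, 1], a$coords[, 2], a$coords[, 3])
  ord_b <- order(b$coords[, 1], b$coords[, 2], b$coords[, 3])
  expect_equal(b$coords[ord_b, ] -
                 matrix(shift_vox * st$voxel_size_um, n_puncta(a), 3,
                        byrow = TRUE),
               a$coords[ord_a, ], tolerance = 1e-9)
})

test_that("measured volumes match the analytic half-maximum ellipsoid", {
  vol <- 0.6
  ps <- puncta_set(rbind(c(0, 0, 0)), volumes = vol)
  psf <- c(0.25, 0.25, 0.4)
  st <- render_stack(ps, voxel_size_um = c(0.1, 0.1, 0.15),
                     psf_sigma_um = psf, margin_um = 4)
  det <- detect_spots(st)
  mv <- measure_volumes(st, det)
  obj_sigma <- (vol / (4 / 3 * pi))^(1 / 3) / sqrt(2 * log(2))
  sig <- sqrt(psf^2 + obj_sigma^2)
  analytic <- 4 / 3 * pi * prod(sig * sqrt(2 * log(2)))
  expect_equal(mv$volumes[1], analytic, tolerance = 0.15)
})

test_that("identical blobs measure identical volumes; ranks track truth", {
  # grid-aligned twin blobs (identical sub-voxel phase)
  two <- puncta_set(rbind(c(0, 0, 0), c(10, 0, 0)), volumes = c(0.5, 0.5))
  st <- render_stack(two, voxel_size_um = c(0.2, 0.2, 0.25),
                     bbox = rbind(c(-3, -3, -3), c(13, 3, 3)))
  mv <- measure_volumes(st, detect_spots(st))
  expect_lt(abs(diff(mv$volumes)), prod(st$voxel_size_um) + 1e-12)

  ps <- blob_field(c(4, 4, 2), seed = 14)
  stack <- render_stack(ps, voxel_size_um = c(0.2, 0.2, 0.3))
  det <- detect_spots(stack)
  mv2 <- measure_volumes(stack, det)
  truth_idx <- apply(det$coords, 1, function(p)
    which.min(colSums((t(ps$coords) - p)^2)))
  rho <- cor(mv2$volumes, ps$volumes[truth_idx], method = "spearman")
  expect_gt(rho, 0.95)
})
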