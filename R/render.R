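#' Render puncta as a 3D image stack
#'
#' Stand-in for confocal acquisition: each punctum becomes a 3D Gaussian
#' blob. The blob's per-axis sigma combines the point-spread function with an
#' object size derived from the punctum's volume (a sphere of equal volume,
#' scaled so that the half-maximum ellipsoid of the object Gaussian has that
#' volume), and its integrated intensity equals the punctum volume (or 1 for
#' volume-less sets), so both size and brightness carry the ground truth.
#'
#' @param puncta a [puncta_set()].
#' @param voxel_size_um length-3 voxel size (x, y, z), um.
#' @param psf_sigma_um length-3 Gaussian PSF sigma, um.
#' @param noise_model "none", "gaussian" (additive, sd = peak/snr) or
#'   "poisson" (counts scaled so the peak SNR is \code{snr}).
#' @param snr peak signal-to-noise ratio for the noise models.
#' @param bbox optional 2 x 3 matrix (rows = min, max corners, um) declaring
#'   the rendered volume; puncta outside it are an error. Defaults to the
#'   puncta extent plus \code{margin_um}.
#' @param margin_um margin added around the puncta when \code{bbox} is NULL.
#' @param noise_seed RNG seed for the noise draw only; the noiseless render
#'   is deterministic and independent of it.
#' @return An object of class \code{rendered_stack}: list with \code{image}
#'   (3D array, x-y-z order), \code{voxel_size_um}, \code{origin_um} (um
#'   coordinates of the corner of voxel \code{[1,1,1]}), \code{channel}.
#' @export
render_stack <- function(puncta, voxel_size_um = c(0.2, 0.2, 0.3),
                         psf_sigma_um = c(0.3, 0.3, 0.45),
                         noise_model = c("none", "gaussian", "poisson"),
                         snr = 10, bbox = NULL, margin_um = 2,
                         noise_seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(puncta, "puncta_set"), length(voxel_size_um) == 3,
            all(voxel_size_um > 0), length(psf_sigma_um) == 3,
            all(psf_sigma_um >= 0))
  pts <- puncta$coords
  if (nrow(pts) == 0L) stop("cannot render an empty puncta set")
  if (is.null(bbox)) {
    bbox <- rbind(apply(pts, 2, min) - margin_um,
                  apply(pts, 2, max) + margin_um)
  } else {
    bbox <- as.matrix(bbox)
    out <- sweep(pts, 2, bbox[1, ], `<`) | sweep(pts, 2, bbox[2, ], `>`)
    if (any(out))
      stop(sum(rowSums(out) > 0), " puncta lie outside the declared bounding box")
  }
  dims <- unname(pmax(ceiling((bbox[2, ] - bbox[1, ]) / voxel_size_um), 3))
  origin <- unname(bbox[1, ])
  img <- array(0, dim = dims)
  vols <- if (is.null(puncta$volumes)) rep(1, nrow(pts)) else puncta$volumes
  # half-maximum ellipsoid of a Gaussian with sigma s has volume
  # (4/3) pi prod(s * sqrt(2 log 2)); invert for an isotropic object sigma
  obj_sigma <- if (is.null(puncta$volumes)) rep(0, nrow(pts)) else
    (vols / (4 / 3 * pi))^(1 / 3) / sqrt(2 * log(2))
  for (i in seq_len(nrow(pts))) {
    sig <- sqrt(psf_sigma_um^2 + obj_sigma[i]^2)
    sig <- pmax(sig, 1e-6)
    ctr_vox <- (pts[i, ] - origin) / voxel_size_um + 0.5  # voxel-center coords
    rad <- ceiling(4.5 * sig / voxel_size_um)
    lo <- pmax(floor(ctr_vox - rad), 1)
    hi <- pmin(ceiling(ctr_vox + rad), dims)
    gax <- lapply(1:3, function(k) {
      x_um <- ((lo[k]:hi[k]) - ctr_vox[k]) * voxel_size_um[k]
      stats::dnorm(x_um, sd = sig[k])
    })
    blob <- vols[i] * outer(outer(gax[[1]], gax[[2]]), gax[[3]]) *
      prod(voxel_size_um)
    img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + blob
  }
  if (noise_model != "none" && max(img) > 0) {
    peak <- max(img)
    img <- with_local_seed(noise_seed, {
      if (noise_model == "gaussian") {
        img + array(stats::rnorm(length(img), sd = peak / snr), dim = dims)
      } else {
        scale <- snr^2 / peak
        array(stats::rpois(length(img), img * scale) / scale, dim = dims)
      }
    })
  }
  structure(list(image = img, voxel_size_um = as.numeric(voxel_size_um),
                 origin_um = as.numeric(origin), channel = puncta$channel),
            class = "rendered_stack")
}

#' @export
print.rendered_stack <- function(x, ...) {
  cat(sprintf("<rendered_stack> channel '%s', %d x %d x %d voxels @ (%g, %g, %g) um\n",
              x$channel, dim(x$image)[1], dim(x$image)[2], dim(x$image)[3],
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3]))
  invisible(x)
}

#' Render all channels of a synthetic scene
#'
#' Renders the IHC ribbon, OHC ribbon and efferent channels of a scene into
#' separate stacks over a common bounding box.
#'
#' @param scene a [generate_scene()] result.
#' @param ... passed to [render_stack()].
#' @return named list of \code{rendered_stack}s
#'   (\code{ribbons}, \code{ohc_ribbons}, \code{efferents}).
#' @export
render_scene <- function(scene, ...) {
  stopifnot(inherits(scene, "synthetic_scene"))
  all_pts <- rbind(scene$ribbons$coords, scene$ohc_ribbons$coords,
                   scene$efferents$coords)
  bbox <- rbind(apply(all_pts, 2, min) - 2, apply(all_pts, 2, max) + 2)
  list(ribbons = render_stack(scene$ribbons, bbox = bbox, ...),
       ohc_ribbons = render_stack(scene$ohc_ribbons, bbox = bbox, ...),
       efferents = render_stack(scene$efferents, bbox = bbox, ...))
}

#' Write a rendered stack as multi-page TIFF
#'
#' One page per optical section (z-slice), 32-bit float, intensities scaled
#' to a unit peak. Voxel size, origin and the intensity scale are written to
#' a JSON sidecar (\code{<path>.json}) read back by [read_stack_tiff()].
#'
#' @param stack a [render_stack()] result.
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "rendered_stack"))
  peak <- max(stack$image, 1e-12)
  pages <- lapply(seq_len(dim(stack$image)[3]), function(k) {
    # TIFF pages are row-major images: rows = y, columns = x
    t(pmax(stack$image[, , k], 0) / peak)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(voxel_size_um = stack$voxel_size_um, origin_um = stack$origin_um,
         channel = stack$channel, intensity_scale = peak),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' @param path TIFF path written by [write_stack_tiff()] (or any multi-page
#'   grayscale TIFF; without a JSON sidecar, voxel size must be supplied).
#' @param voxel_size_um fallback voxel size when no sidecar exists.
#' @return a \code{rendered_stack}.
#' @export
read_stack_tiff <- function(path, voxel_size_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  img <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) img[, , k] <- t(pages[[k]])
  meta_path <- paste0(path, ".json")
  origin <- c(0, 0, 0); channel <- "unknown"; scale <- 1
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    voxel_size_um <- meta$voxel_size_um
    origin <- meta$origin_um
    channel <- meta$channel
    scale <- meta$intensity_scale
  }
  if (is.null(voxel_size_um))
    stop("no JSON sidecar found; voxel_size_um must be supplied")
  structure(list(image = img * scale, voxel_size_um = voxel_size_um,
                 origin_um = origin, channel = channel),
            class = "rendered_stack")
}
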