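#' Spot-detection configuration
#'
#' Parameters of the scale-space Laplacian-of-Gaussian detector and the
#' seeded volume measurement that stand in for commercial spots/surfaces
#' tools.
#'
#' @param sigma_min_um,sigma_max_um blob-scale search range (Gaussian sigma,
#'   um); \code{sigma_min_um < sigma_max_um}.
#' @param n_scales number of scales, geometrically spaced over the range.
#' @param peak_threshold fraction of the global maximum LoG response below
#'   which candidate peaks are discarded, in (0, 1).
#' @param volume_threshold fraction of a seed's peak intensity defining its
#'   supra-threshold region for volume measurement, in (0, 1).
#' @return An object of class \code{detection_config}.
#' @export
detection_config <- function(sigma_min_um = 0.25, sigma_max_um = 0.9,
                             n_scales = 5, peak_threshold = 0.1,
                             volume_threshold = 0.5) {
  stopifnot(sigma_min_um > 0, sigma_min_um < sigma_max_um,
            n_scales >= 1,
            peak_threshold > 0, peak_threshold < 1,
            volume_threshold > 0, volume_threshold < 1)
  structure(list(sigma_min_um = sigma_min_um, sigma_max_um = sigma_max_um,
                 n_scales = as.integer(n_scales),
                 peak_threshold = peak_threshold,
                 volume_threshold = volume_threshold),
            class = "detection_config")
}

# Separable Gaussian blur along one axis (zero-padded boundary); sigma in
# voxels. Dense banded-matrix multiply after permuting the axis first.
blur_axis <- function(arr, sigma_vox, axis) {
  if (sigma_vox <= 0) return(arr)
  d <- dim(arr)
  n <- d[axis]
  r <- max(1L, ceiling(4 * sigma_vox))
  kern <- stats::dnorm(-r:r, sd = sigma_vox)
  kern <- kern / sum(kern)
  k_mat <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- (j - r):(j + r)
    ok <- idx >= 1 & idx <= n
    k_mat[idx[ok], j] <- kern[ok]
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- t(k_mat) %*% matrix(a, nrow = n)
  aperm(array(m, dim = da), order(perm))
}

gauss_blur3 <- function(arr, sigma_vox) {
  for (ax in 1:3) arr <- blur_axis(arr, sigma_vox[ax], ax)
  arr
}

# Second difference along an axis divided by the squared voxel size
# (um^-2); replicated boundary keeps edge curvature near zero.
second_diff_axis <- function(arr, axis, h_um) {
  d <- dim(arr)
  n <- d[axis]
  idx_p <- pmin(seq_len(n) + 1L, n)
  idx_m <- pmax(seq_len(n) - 1L, 1L)
  slice_idx <- function(i) {
    args <- list(arr, quote(expr =), quote(expr =), quote(expr =))
    args[[axis + 1L]] <- i
    args$drop <- FALSE
    do.call(`[`, args)
  }
  (slice_idx(idx_p) + slice_idx(idx_m) - 2 * arr) / h_um^2
}

# Scale-normalized LoG response (positive at bright blobs) at one scale.
log_response <- function(img, voxel_size_um, sigma_um) {
  sm <- gauss_blur3(img, sigma_um / voxel_size_um)
  lap <- second_diff_axis(sm, 1, voxel_size_um[1]) +
    second_diff_axis(sm, 2, voxel_size_um[2]) +
    second_diff_axis(sm, 3, voxel_size_um[3])
  -mean(sigma_um^2) * lap
}

# 3 x 3 x 3 grey dilation via sequential per-axis rolling max.
dilate3 <- function(arr) {
  d <- dim(arr)
  for (axis in 1:3) {
    n <- d[axis]
    idx_p <- pmin(seq_len(n) + 1L, n)
    idx_m <- pmax(seq_len(n) - 1L, 1L)
    sl <- function(i) {
      args <- list(arr, quote(expr =), quote(expr =), quote(expr =))
      args[[axis + 1L]] <- i
      args$drop <- FALSE
      do.call(`[`, args)
    }
    arr <- pmax(arr, sl(idx_p), sl(idx_m))
  }
  arr
}

#' Detect puncta in a 3D stack
#'
#' Scale-space blob detection: the stack is smoothed at geometrically spaced
#' Gaussian scales (per-axis sigmas scaled by the voxel size, so anisotropic
#' sampling is handled), the scale-normalized Laplacian response is computed,
#' and local response maxima that are also the best response across scales
#' are kept. Peaks below \code{peak_threshold} times the global maximum
#' response are discarded; nearby candidates are merged, strongest first,
#' with a minimum separation of the detected scale.
#'
#' @param stack a [render_stack()] / [read_stack_tiff()] result, or a bare
#'   3D array.
#' @param voxel_size_um length-3 voxel size; taken from the stack when
#'   available.
#' @param config a [detection_config()].
#' @param channel channel label for the returned set.
#' @return a [puncta_set()] of detected centers (um), with per-detection
#'   \code{response}, \code{scale_um} and voxel indices as annotations. An
#'   all-zero stack yields an empty set.
#' @export
detect_spots <- function(stack, voxel_size_um = NULL,
                         config = detection_config(), channel = NULL) {
  if (inherits(stack, "rendered_stack")) {
    img <- stack$image
    if (is.null(voxel_size_um)) voxel_size_um <- stack$voxel_size_um
    origin <- stack$origin_um
    if (is.null(channel)) channel <- stack$channel
  } else {
    img <- stack
    origin <- c(0, 0, 0)
    if (is.null(channel)) channel <- "detected"
  }
  stopifnot(length(dim(img)) == 3L, !is.null(voxel_size_um),
            length(voxel_size_um) == 3L, all(voxel_size_um > 0),
            inherits(config, "detection_config"))
  empty <- puncta_set(matrix(numeric(0), 0, 3), "stack1", channel)
  if (all(img == 0)) return(empty)
  sigmas <- if (config$n_scales == 1L) config$sigma_min_um else
    exp(seq(log(config$sigma_min_um), log(config$sigma_max_um),
            length.out = config$n_scales))
  resp <- lapply(sigmas, function(s) log_response(img, voxel_size_um, s))
  # per-voxel best scale and response
  best <- resp[[1]]
  best_scale <- array(1L, dim = dim(img))
  for (k in seq_along(resp)[-1]) {
    better <- resp[[k]] > best
    best[better] <- resp[[k]][better]
    best_scale[better] <- k
  }
  gmax <- max(best)
  if (gmax <= 0) return(empty)
  thr <- config$peak_threshold * gmax
  cand <- which(best >= dilate3(best) & best >= thr)
  if (!length(cand)) return(empty)
  ord <- order(best[cand], decreasing = TRUE)
  cand <- cand[ord]
  ijk <- arrayInd(cand, dim(img))
  pos <- sweep(sweep(ijk - 0.5, 2, voxel_size_um, `*`), 2, origin, `+`)
  # greedy non-maximum suppression at the detected scale
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    sep <- sigmas[best_scale[cand[i]]]
    if (!any(keep)) {
      keep[i] <- TRUE
    } else {
      prev <- pos[keep, , drop = FALSE]
      d2 <- (prev[, 1] - pos[i, 1])^2 + (prev[, 2] - pos[i, 2])^2 +
        (prev[, 3] - pos[i, 3])^2
      keep[i] <- min(d2) > sep^2
    }
  }
  ijk <- ijk[keep, , drop = FALSE]
  pos <- pos[keep, , drop = FALSE]
  puncta_set(pos, "stack1", channel,
             annotations = data.frame(
               response = best[cand[keep]],
               scale_um = sigmas[best_scale[cand[keep]]],
               vox_i = ijk[, 1], vox_j = ijk[, 2], vox_k = ijk[, 3]))
}

#' Measure punctum volumes around detected seeds
#'
#' For each seed, the connected region (6-connectivity) of voxels with
#' intensity at or above \code{volume_threshold} times the seed's peak
#' intensity; voxels reached by several seeds are claimed by the nearest
#' seed. Volume = claimed voxel count x voxel volume. A seed whose region is
#' empty gets one voxel volume and a flag.
#'
#' @param stack the same stack the seeds were detected in.
#' @param seeds a [detect_spots()] result (voxel-index annotations required).
#' @param voxel_size_um length-3 voxel size; taken from the stack when
#'   available.
#' @param config a [detection_config()] (only \code{volume_threshold} used).
#' @return the seeds [puncta_set()] with measured \code{volumes} (um^3) and
#'   a logical \code{flagged_empty} annotation.
#' @export
measure_volumes <- function(stack, seeds, voxel_size_um = NULL,
                            config = detection_config()) {
  if (inherits(stack, "rendered_stack")) {
    img <- stack$image
    if (is.null(voxel_size_um)) voxel_size_um <- stack$voxel_size_um
  } else img <- stack
  stopifnot(inherits(seeds, "puncta_set"),
            !is.null(seeds$annotations),
            all(c("vox_i", "vox_j", "vox_k") %in% names(seeds$annotations)),
            length(voxel_size_um) == 3L)
  d <- dim(img)
  ns <- n_puncta(seeds)
  if (ns == 0L) return(seeds)
  ijk <- as.matrix(seeds$annotations[, c("vox_i", "vox_j", "vox_k")])
  lin <- function(m) (m[, 3] - 1L) * d[1] * d[2] + (m[, 2] - 1L) * d[1] + m[, 1]
  owner <- integer(length(img))           # 0 = unclaimed
  claimed <- vector("list", ns)
  strides <- c(1L, d[1], d[1] * d[2])
  for (s in seq_len(ns)) {
    peak <- img[ijk[s, 1], ijk[s, 2], ijk[s, 3]]
    thr <- config$volume_threshold * peak
    if (peak <= 0) { claimed[[s]] <- integer(0); next }
    visited <- new.env(hash = TRUE, size = 256L)
    start <- lin(ijk[s, , drop = FALSE])
    frontier <- start
    assign(as.character(start), TRUE, envir = visited)
    region <- integer(0)
    while (length(frontier)) {
      region <- c(region, frontier)
      coords <- arrayInd(frontier, d)
      nbrs <- integer(0)
      for (ax in 1:3) for (dsign in c(-1L, 1L)) {
        ok <- coords[, ax] + dsign >= 1L & coords[, ax] + dsign <= d[ax]
        if (any(ok)) nbrs <- c(nbrs, frontier[ok] + dsign * strides[ax])
      }
      nbrs <- unique(nbrs)
      nbrs <- nbrs[img[nbrs] >= thr]
      fresh <- vapply(nbrs, function(v) {
        k <- as.character(v)
        if (exists(k, envir = visited, inherits = FALSE)) FALSE else {
          assign(k, TRUE, envir = visited); TRUE
        }
      }, logical(1))
      frontier <- nbrs[fresh]
    }
    claimed[[s]] <- region
  }
  # resolve voxels claimed by several seeds: nearest seed wins
  all_vox <- unlist(claimed)
  dup_vox <- unique(all_vox[duplicated(all_vox)])
  if (length(dup_vox)) {
    seed_um <- seeds$coords
    for (v in dup_vox) {
      claimants <- which(vapply(claimed, function(r) v %in% r, logical(1)))
      vc <- (arrayInd(v, d) - 0.5) * voxel_size_um
      if (inherits(stack, "rendered_stack")) vc <- vc + stack$origin_um
      d2 <- rowSums(sweep(seed_um[claimants, , drop = FALSE], 2,
                          as.numeric(vc))^2)
      lose <- claimants[-which.min(d2)]
      for (l in lose) claimed[[l]] <- setdiff(claimed[[l]], v)
    }
  }
  counts <- lengths(claimed)
  flagged <- counts == 0L
  counts[flagged] <- 1L
  seeds$volumes <- counts * prod(voxel_size_um)
  seeds$annotations$flagged_empty <- flagged
  seeds
}
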