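#' Fit a principal axis to a 3D point cloud
#'
#' Fits the first principal component of the centered covariance of a point
#' cloud: the line through the centroid along the dominant eigenvector. Used
#' on the ribbon cloud and on the nuclei cloud to construct the
#' pillar-modiolar separating plane.
#'
#' The eigenvector sign is fixed by forcing a positive dot product with +x
#' (falling back to +y, then +z, when orthogonal) so results do not depend on
#' the linear-algebra backend. The extent points are the projections, onto
#' the fitted line, of the data points with minimal and maximal scalar
#' projection.
#'
#' @param points n x 3 matrix of coordinates (um), a data.frame with x/y/z
#'   columns, or a [puncta_set()] / [hair_cell_set()].
#' @return An object of class \code{fitted_axis}: list with \code{centroid},
#'   unit \code{direction}, \code{extent_min_point}, \code{extent_max_point}.
#' @examples
#' ax <- fit_axis(cbind(x = c(0, 1, 2, 3), y = 0, z = 0))
#' ax$direction   # (1, 0, 0)
#' @export
fit_axis <- function(points) {
  pts <- coords_of(points)
  if (nrow(pts) < 3L)
    stop("degenerate geometry: need at least 3 points to fit an axis")
  ctr <- colMeans(pts)
  centered <- sweep(pts, 2, ctr)
  cv <- crossprod(centered) / (nrow(pts) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[1] <= sqrt(.Machine$double.eps) * max(1, sum(diag(cv))))
    stop("degenerate geometry: points are (numerically) coincident")
  dir <- eg$vectors[, 1]
  # deterministic sign: positive component along the first non-orthogonal axis
  for (k in 1:3) {
    if (abs(dir[k]) > 1e-12) {
      if (dir[k] < 0) dir <- -dir
      break
    }
  }
  dir <- unit(dir)
  proj <- drop(centered %*% dir)
  structure(
    list(centroid = ctr, direction = dir,
         extent_min_point = ctr + min(proj) * dir,
         extent_max_point = ctr + max(proj) * dir),
    class = "fitted_axis")
}

#' @export
print.fitted_axis <- function(x, ...) {
  cat(sprintf("<fitted_axis> centroid (%.2f, %.2f, %.2f), direction (%.3f, %.3f, %.3f)\n",
              x$centroid[1], x$centroid[2], x$centroid[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

# Accept matrices, data.frames, puncta/hair-cell sets.
coords_of <- function(x) {
  if (inherits(x, "puncta_set")) return(x$coords)
  if (inherits(x, "hair_cell_set")) {
    if (is.null(x$centroids)) stop("hair_cell_set has no centroids")
    return(x$centroids)
  }
  as_coord_matrix(x)
}

#' Construct the pillar-modiolar separating plane
#'
#' The plane is defined by three points: the two extent points of the axis
#' fitted to the ribbon cloud and the centroid of the axis fitted to the
#' nuclei cloud. Its unit normal is oriented so that the supplied landmark
#' point (an anatomical structure known to lie on the pillar side, e.g. the
#' OHC-region centroid) has positive signed distance.
#'
#' @param ribbon_axis [fit_axis()] result for the ribbon cloud.
#' @param nuclei_axis [fit_axis()] result for the nuclei cloud.
#' @param landmark length-3 point on the pillar side; must not lie on the
#'   plane.
#' @return An object of class \code{separating_plane}: list with
#'   \code{points} (3 x 3 matrix of defining points), unit \code{normal},
#'   and \code{offset} such that signed distance = \code{x . normal - offset}.
#' @export
build_plane <- function(ribbon_axis, nuclei_axis, landmark) {
  stopifnot(inherits(ribbon_axis, "fitted_axis"),
            inherits(nuclei_axis, "fitted_axis"))
  landmark <- as.numeric(landmark)
  stopifnot(length(landmark) == 3L)
  a <- ribbon_axis$extent_min_point
  b <- ribbon_axis$extent_max_point
  c_ <- nuclei_axis$centroid
  u <- b - a
  v <- c_ - a
  n <- cross3(u, v)
  scale <- max(vnorm(u), vnorm(v))
  if (vnorm(n) <= 1e-10 * scale^2)
    stop("degenerate geometry: the nuclei centroid lies on the ribbon axis; ",
         "a wider field of view is needed to define the pillar-modiolar plane")
  n <- unit(n)
  if (sum(n * (landmark - a)) < 0) n <- -n
  if (abs(sum(n * (landmark - a))) <= 1e-10 * max(1, scale))
    stop("landmark lies on the separating plane; orientation undecidable")
  structure(
    list(points = rbind(ribbon_min = a, ribbon_max = b, nuclei_centroid = c_),
         normal = n, offset = sum(n * a)),
    class = "separating_plane")
}

#' @export
print.separating_plane <- function(x, ...) {
  cat(sprintf("<separating_plane> normal (%.3f, %.3f, %.3f), offset %.3f\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  invisible(x)
}

#' Signed distance of points to a separating plane
#'
#' Positive distances are on the pillar side by construction of the plane.
#'
#' @param points coordinates (matrix, data.frame or [puncta_set()]).
#' @param plane a [build_plane()] result.
#' @return numeric vector of signed distances (um).
#' @export
signed_distance <- function(points, plane) {
  stopifnot(inherits(plane, "separating_plane"))
  drop(coords_of(points) %*% plane$normal) - plane$offset
}

#' Classify ribbons as pillar or modiolar
#'
#' Labels every ribbon by the side of the separating plane it falls on:
#' pillar for positive signed distance, modiolar for negative. A signed
#' distance of exactly zero is labelled pillar and flagged as a tie (a
#' measure-zero event kept deterministic).
#'
#' @param ribbons a [puncta_set()] of afferent ribbons.
#' @param plane a [build_plane()] result.
#' @return An object of class \code{pm_partition}: list with \code{side}
#'   (character vector), \code{signed_distance} (um), \code{plane},
#'   \code{counts} and \code{fractions} per side, \code{ties} (indices of
#'   zero-distance ribbons), and the input \code{ribbons}.
#' @examples
#' sc <- generate_scene(scene_config(n_ihc = 8, seed = 3))
#' part <- classify_ribbons(sc$ribbons,
#'   build_plane(fit_axis(sc$ribbons), fit_axis(sc$ihc_nuclei),
#'               sc$landmark_point))
#' part$fractions
#' @export
classify_ribbons <- function(ribbons, plane) {
  stopifnot(inherits(ribbons, "puncta_set"))
  d <- signed_distance(ribbons, plane)
  side <- ifelse(d >= 0, "pillar", "modiolar")
  counts <- c(pillar = sum(side == "pillar"),
              modiolar = sum(side == "modiolar"))
  total <- sum(counts)
  structure(
    list(side = side, signed_distance = d, plane = plane,
         counts = counts,
         fractions = if (total > 0) counts / total else counts * NA_real_,
         ties = which(d == 0), ribbons = ribbons),
    class = "pm_partition")
}

#' @export
print.pm_partition <- function(x, ...) {
  cat(sprintf("<pm_partition> %d ribbons: %d pillar (%.1f%%), %d modiolar (%.1f%%)%s\n",
              sum(x$counts), x$counts["pillar"], 100 * x$fractions["pillar"],
              x$counts["modiolar"], 100 * x$fractions["modiolar"],
              if (length(x$ties)) sprintf(" [%d ties -> pillar]", length(x$ties))
              else ""))
  invisible(x)
}

#' Normalize punctum volumes to the stack median
#'
#' Divides every volume by the median volume of its own stack so that volume
#' gradients can be compared across stacks acquired with different settings.
#' The median is taken over all ribbons of the stack, not per side.
#'
#' @param sets a [puncta_set()] with volumes, or a list of them (one per
#'   stack; sets sharing a \code{stack_id} are normalized by their pooled
#'   median).
#' @return the same structure with volumes replaced by normalized volumes.
#'   Normalization is idempotent up to the median of already-normalized
#'   values being 1.
#' @examples
#' ps <- puncta_set(cbind(1:3, 0, 0), volumes = c(1, 2, 3))
#' normalize_volumes(ps)$volumes   # 0.5 1.0 1.5
#' @export
normalize_volumes <- function(sets) {
  single <- inherits(sets, "puncta_set")
  if (single) sets <- list(sets)
  stopifnot(all(vapply(sets, inherits, logical(1), "puncta_set")))
  if (any(vapply(sets, function(s) is.null(s$volumes), logical(1))))
    stop("all sets must carry volumes to normalize")
  stack_ids <- vapply(sets, `[[`, character(1), "stack_id")
  med <- tapply(unlist(lapply(sets, `[[`, "volumes")),
                rep(stack_ids, vapply(sets, n_puncta, integer(1))),
                stats::median)
  if (any(!is.finite(med)) || any(med <= 0))
    stop("stack median volume must be > 0")
  out <- lapply(sets, function(s) {
    s$volumes <- s$volumes / med[[s$stack_id]]
    s
  })
  if (single) out[[1]] else out
}

#' Summarize a pillar-modiolar partition
#'
#' Per-side counts, count fractions, and mean +/- SEM of (normalized) ribbon
#' volumes, plus the steepness of the volume gradient as the ratio of the
#' modiolar to the pillar mean volume.
#'
#' @param partition a [classify_ribbons()] result.
#' @param volumes optional numeric vector of (normalized) volumes aligned
#'   with the partitioned ribbons; defaults to the volumes stored in the
#'   partition's ribbon set.
#' @return An object of class \code{pm_summary}: data.frame \code{by_side}
#'   (side, n, fraction, mean_volume, sem_volume) plus
#'   \code{volume_ratio_modiolar_pillar} (NA, with a flag, when a side is
#'   empty).
#' @export
summarize_partition <- function(partition, volumes = NULL) {
  stopifnot(inherits(partition, "pm_partition"))
  if (is.null(volumes)) volumes <- partition$ribbons$volumes
  if (sum(partition$counts) == 0L) stop("partition is empty")
  sides <- c("pillar", "modiolar")
  rows <- lapply(sides, function(s) {
    sel <- partition$side == s
    ms <- if (!is.null(volumes)) mean_sem(volumes[sel]) else
      list(mean = NA_real_, sem = NA_real_, n = sum(sel))
    data.frame(side = s, n = sum(sel),
               fraction = unname(partition$fractions[s]),
               mean_volume = ms$mean, sem_volume = ms$sem)
  })
  by_side <- do.call(rbind, rows)
  ratio <- NA_real_
  ratio_defined <- all(by_side$n > 0) && !is.null(volumes)
  if (ratio_defined)
    ratio <- by_side$mean_volume[by_side$side == "modiolar"] /
      by_side$mean_volume[by_side$side == "pillar"]
  structure(list(by_side = by_side,
                 volume_ratio_modiolar_pillar = ratio,
                 ratio_defined = ratio_defined),
            class = "pm_summary")
}

#' @export
print.pm_summary <- function(x, ...) {
  print(x$by_side, row.names = FALSE)
  if (x$ratio_defined)
    cat(sprintf("modiolar/pillar mean volume ratio: %.3f\n",
                x$volume_ratio_modiolar_pillar))
  else cat("volume ratio undefined (empty side or no volumes)\n")
  invisible(x)
}

#' Full pillar-modiolar classification for one stack
#'
#' Convenience wrapper running the whole chain: axis fits to ribbons and
#' nuclei, plane construction oriented by the landmark, per-ribbon
#' classification, per-stack median volume normalization (when volumes are
#' present), and the per-side summary.
#'
#' @param ribbons a [puncta_set()] of IHC afferent ribbons.
#' @param nuclei a [hair_cell_set()] (or point matrix) of IHC nuclei.
#' @param landmark length-3 point on the pillar side.
#' @return list with \code{partition} ([classify_ribbons()] result, on
#'   normalized volumes when available) and \code{summary}
#'   ([summarize_partition()] result).
#' @export
classify_stack <- function(ribbons, nuclei, landmark) {
  plane <- build_plane(fit_axis(ribbons), fit_axis(nuclei), landmark)
  if (!is.null(ribbons$volumes)) ribbons <- normalize_volumes(ribbons)
  partition <- classify_ribbons(ribbons, plane)
  list(partition = partition, summary = summarize_partition(partition))
}
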