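#' Nearest-neighbor distances between two puncta channels
#'
#' For every source punctum (e.g. a CTBP2 afferent ribbon), the Euclidean
#' distance to its nearest target punctum (e.g. a synapsin efferent
#' terminal). Both point sets must come from the same stack and coordinate
#' frame; the relation is directional (source to target is not target to
#' source).
#'
#' The default implementation bins targets into a uniform grid and expands
#' the search ring until the running minimum provably cannot be beaten, which
#' is exact: candidate distances are computed with the same arithmetic as the
#' all-pairs scan, and the true nearest target is always among the
#' candidates, so results equal brute force bit for bit.
#'
#' @param source,target [puncta_set()]s (or coordinate matrices).
#' @param method "auto" picks the grid for large problems and the all-pairs
#'   scan for small ones; "grid" and "brute" force one path.
#' @return An object of class \code{distance_distribution}: list with
#'   \code{distances} (um, one per source punctum), \code{ecdf}, \code{mean},
#'   \code{sem}, \code{n}, and the channel labels.
#' @examples
#' d <- nn_distances(puncta_set(rbind(c(0, 0, 0))),
#'                   puncta_set(rbind(c(3, 4, 0), c(10, 0, 0))))
#' d$distances   # 5
#' @export
nn_distances <- function(source, target, method = c("auto", "grid", "brute")) {
  method <- match.arg(method)
  s <- coords_of(source)
  t_ <- coords_of(target)
  if (nrow(t_) == 0L) stop("target set is empty")
  src_ch <- if (inherits(source, "puncta_set")) source$channel else "source"
  tgt_ch <- if (inherits(target, "puncta_set")) target$channel else "target"
  if (inherits(source, "puncta_set") && inherits(target, "puncta_set") &&
      source$stack_id != target$stack_id)
    warning("source and target come from different stacks ('",
            source$stack_id, "' vs '", target$stack_id,
            "'); distances assume a shared coordinate frame")
  if (nrow(s) == 0L) {
    d <- numeric(0)
  } else if (method == "brute" ||
             (method == "auto" && as.double(nrow(s)) * nrow(t_) <= 250000)) {
    d <- nn_brute(s, t_)
  } else {
    d <- nn_grid(s, t_)
  }
  ms <- mean_sem(d)
  structure(
    list(distances = d, source_channel = src_ch, target_channel = tgt_ch,
         n = length(d), mean = ms$mean, sem = ms$sem,
         ecdf = if (length(d)) stats::ecdf(d) else NULL),
    class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("<distance_distribution> %s -> %s: n = %d, mean %.3f um (SEM %.3f)\n",
              x$source_channel, x$target_channel, x$n,
              x$mean, x$sem))
  invisible(x)
}

# All-pairs scan; per-pair arithmetic is the contract shared with nn_grid.
nn_brute <- function(s, t_) {
  vapply(seq_len(nrow(s)), function(i) {
    d2 <- (t_[, 1] - s[i, 1])^2 + (t_[, 2] - s[i, 2])^2 +
      (t_[, 3] - s[i, 3])^2
    sqrt(min(d2))
  }, numeric(1))
}

# Exact grid-accelerated nearest neighbor. Targets are hashed into cubic
# cells of side h; for a source in cell c0, every cell at Chebyshev ring r
# is at Euclidean distance >= (r - 1) * h, so once the best distance found
# is <= r * h no farther ring can improve it.
nn_grid <- function(s, t_) {
  n <- nrow(t_)
  lo <- pmin(apply(t_, 2, min), apply(s, 2, min))
  span <- pmax(apply(t_, 2, max), apply(s, 2, max)) - lo
  h <- max((prod(pmax(span, 1e-6)) / n * 2)^(1 / 3), max(span) / 64, 1e-6)
  key <- function(m) {
    ix <- floor(sweep(m, 2, lo) / h)
    list(ix = ix, k = paste(ix[, 1], ix[, 2], ix[, 3]))
  }
  tk <- key(t_)
  buckets <- split(seq_len(n), tk$k)
  sk <- key(s)
  max_ring <- max(ceiling(span / h)) + 1
  vapply(seq_len(nrow(s)), function(i) {
    c0 <- sk$ix[i, ]
    best <- Inf
    r <- 0L
    repeat {
      # cells on the Chebyshev ring of radius r around c0
      if (r == 0L) {
        cells <- matrix(c0, 1, 3)
      } else {
        g <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
        g <- g[pmax(abs(g[, 1]), abs(g[, 2]), abs(g[, 3])) == r, , drop = FALSE]
        cells <- sweep(g, 2, c0, `+`)
      }
      ks <- paste(cells[, 1], cells[, 2], cells[, 3])
      idx <- unlist(buckets[ks], use.names = FALSE)
      if (length(idx)) {
        d2 <- (t_[idx, 1] - s[i, 1])^2 + (t_[idx, 2] - s[i, 2])^2 +
          (t_[idx, 3] - s[i, 3])^2
        m <- min(d2)
        if (m < best) best <- m
      }
      if ((is.finite(best) && sqrt(best) <= r * h) || r > max_ring) break
      r <- r + 1L
    }
    sqrt(best)
  }, numeric(1))
}

#' Compare two nearest-neighbor distance distributions
#'
#' Quantifies the developmental shift between an immature and a mature
#' afferent-to-efferent distance distribution: the difference of means with
#' its standard error, and a dominance flag marking a pointwise rightward
#' ECDF shift (the mature cumulative curve at or below the immature one
#' everywhere, within a tolerance).
#'
#' @param immature,mature [nn_distances()] results.
#' @param tol pointwise ECDF tolerance for the dominance flag.
#' @return An object of class \code{distance_shift}: list with
#'   \code{mean_difference} (mature minus immature, um), \code{se_difference},
#'   \code{rightward_shift} (logical), \code{max_ecdf_excess} (largest amount
#'   by which the mature ECDF exceeds the immature one), and the two inputs'
#'   means.
#' @export
compare_distributions <- function(immature, mature, tol = 0.02) {
  stopifnot(inherits(immature, "distance_distribution"),
            inherits(mature, "distance_distribution"),
            immature$n > 0, mature$n > 0)
  grid <- sort(unique(c(immature$distances, mature$distances)))
  excess <- mature$ecdf(grid) - immature$ecdf(grid)
  structure(
    list(mean_immature = immature$mean, mean_mature = mature$mean,
         mean_difference = mature$mean - immature$mean,
         se_difference = sqrt(immature$sem^2 + mature$sem^2),
         max_ecdf_excess = max(excess),
         rightward_shift = max(excess) <= tol, tol = tol),
    class = "distance_shift")
}

#' @export
print.distance_shift <- function(x, ...) {
  cat(sprintf(paste0("<distance_shift> mean %.3f -> %.3f um ",
                     "(difference %+.3f +/- %.3f); rightward ECDF shift: %s\n"),
              x$mean_immature, x$mean_mature, x$mean_difference,
              x$se_difference, if (x$rightward_shift) "yes" else "no"))
  invisible(x)
}
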