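#' Immunopuncta point set
#'
#' A labeled set of 3D immunofluorescent puncta from one confocal stack and
#' one channel (e.g. CTBP2 ribbons, synapsin efferent terminals, BK channel
#' puncta). Coordinates are in micrometres; volumes, when present, in
#' cubic micrometres.
#'
#' @param coords numeric matrix with 3 columns (x, y, z in um), one row per
#'   punctum. A data.frame with columns x/y/z (or x_um/y_um/z_um) is accepted.
#' @param stack_id character scalar identifying the image stack.
#' @param channel character scalar naming the label channel.
#' @param volumes optional numeric vector of per-punctum volumes (um^3),
#'   strictly positive and the same length as the number of puncta.
#' @param annotations optional data.frame of extra per-punctum columns
#'   (e.g. the generator's \code{true_side}); carried through unmodified.
#' @return An object of class \code{puncta_set}.
#' @examples
#' ps <- puncta_set(cbind(x = 0:2, y = 0, z = 0), "stack1", "CTBP2")
#' n_puncta(ps)
#' @export
puncta_set <- function(coords, stack_id = "stack1", channel = "CTBP2",
                       volumes = NULL, annotations = NULL) {
  coords <- as_coord_matrix(coords)
  if (!all(is.finite(coords)))
    stop("puncta coordinates must be finite")
  if (!is.null(volumes)) {
    volumes <- as.numeric(volumes)
    if (length(volumes) != nrow(coords))
      stop("volumes must align with points: ", length(volumes),
           " volumes for ", nrow(coords), " points")
    if (any(!is.finite(volumes)) || any(volumes <= 0))
      stop("volumes must be finite and > 0")
  }
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
    if (nrow(annotations) != nrow(coords))
      stop("annotations must have one row per punctum")
  }
  structure(
    list(stack_id = as.character(stack_id)[1],
         channel = as.character(channel)[1],
         coords = coords, volumes = volumes, annotations = annotations),
    class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set> stack '%s', channel '%s': %d puncta%s\n",
              x$stack_id, x$channel, nrow(x$coords),
              if (is.null(x$volumes)) "" else " (with volumes)"))
  invisible(x)
}

#' Number of puncta in a set
#' @param x a \code{puncta_set}.
#' @return integer count.
#' @export
n_puncta <- function(x) {
  stopifnot(inherits(x, "puncta_set"))
  nrow(x$coords)
}

#' @export
as.data.frame.puncta_set <- function(x, ...) {
  df <- data.frame(stack_id = rep(x$stack_id, nrow(x$coords)),
                   channel = rep(x$channel, nrow(x$coords)),
                   x_um = x$coords[, 1], y_um = x$coords[, 2],
                   z_um = x$coords[, 3],
                   stringsAsFactors = FALSE)
  df$volume_um3 <- if (is.null(x$volumes)) rep(NA_real_, nrow(df)) else x$volumes
  if (!is.null(x$annotations)) df <- cbind(df, x$annotations)
  df
}

#' Hair-cell nuclei set
#'
#' Centroids of immunodetected hair-cell nuclei for one stack and one cell
#' type. The cell count is the denominator of all per-cell densities and the
#' nuclei cloud anchors the pillar-modiolar separating plane.
#'
#' @param centroids numeric matrix with 3 columns (x, y, z in um), or a
#'   data.frame with x/y/z columns; may be omitted when only a count is known.
#' @param cell_type "IHC" or "OHC".
#' @param stack_id character scalar identifying the image stack.
#' @param count integer number of cells; defaults to \code{nrow(centroids)}.
#' @return An object of class \code{hair_cell_set}.
#' @export
hair_cell_set <- function(centroids = NULL, cell_type = c("IHC", "OHC"),
                          stack_id = "stack1", count = NULL) {
  cell_type <- match.arg(cell_type)
  if (!is.null(centroids)) {
    centroids <- as_coord_matrix(centroids)
    if (!all(is.finite(centroids))) stop("centroids must be finite")
    if (is.null(count)) count <- nrow(centroids)
    if (count != nrow(centroids))
      stop("count (", count, ") disagrees with number of centroids (",
           nrow(centroids), ")")
  }
  if (is.null(count)) stop("either centroids or count must be given")
  count <- as.integer(count)
  if (count < 1L) stop("count must be >= 1")
  structure(
    list(stack_id = as.character(stack_id)[1], cell_type = cell_type,
         centroids = centroids, count = count),
    class = "hair_cell_set")
}

#' @export
print.hair_cell_set <- function(x, ...) {
  cat(sprintf("<hair_cell_set> stack '%s': %d %s nuclei%s\n",
              x$stack_id, x$count, x$cell_type,
              if (is.null(x$centroids)) " (count only)" else ""))
  invisible(x)
}

# Coerce coordinate input (matrix or data.frame) to an n x 3 numeric matrix
# with canonical column names.
as_coord_matrix <- function(coords) {
  if (is.data.frame(coords)) {
    nm <- names(coords)
    pick <- function(a, b) if (a %in% nm) a else if (b %in% nm) b else
      stop("coordinate data.frame needs columns x/y/z or x_um/y_um/z_um")
    coords <- cbind(coords[[pick("x_um", "x")]],
                    coords[[pick("y_um", "y")]],
                    coords[[pick("z_um", "z")]])
  }
  coords <- as.matrix(coords)
  if (length(coords) == 3L && nrow(coords) == 3L && ncol(coords) == 1L)
    coords <- t(coords)
  if (ncol(coords) != 3L)
    stop("coordinates must have 3 columns (x, y, z)")
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x_um", "y_um", "z_um")
  rownames(coords) <- NULL
  coords
}
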