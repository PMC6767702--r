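#' Puncta density per hair cell
#'
#' The number of synaptic elements per hair cell within one field of view:
#' puncta count divided by the number of hair cells, kept as an exact ratio
#' (rounding is presentation only).
#'
#' @param puncta a [puncta_set()] or a bare puncta count.
#' @param cells a [hair_cell_set()] or a bare cell count (>= 1).
#' @param group optional label (species / age / region) carried into
#'   summaries.
#' @return An object of class \code{density_summary}: list with
#'   \code{puncta_count}, \code{cell_count}, \code{density}, \code{channel},
#'   \code{cell_type}, \code{group}.
#' @examples
#' density_per_cell(255, 205)$density   # 1.2439... -> prints as 1.2
#' @export
density_per_cell <- function(puncta, cells, group = NA_character_) {
  pc <- if (inherits(puncta, "puncta_set")) n_puncta(puncta) else
    as.integer(puncta)
  channel <- if (inherits(puncta, "puncta_set")) puncta$channel else
    NA_character_
  cc <- if (inherits(cells, "hair_cell_set")) cells$count else
    as.integer(cells)
  cell_type <- if (inherits(cells, "hair_cell_set")) cells$cell_type else
    NA_character_
  if (is.na(cc) || cc < 1L) stop("cell count must be >= 1")
  if (is.na(pc) || pc < 0L) stop("puncta count must be >= 0")
  if (inherits(puncta, "puncta_set") && inherits(cells, "hair_cell_set") &&
      puncta$stack_id != cells$stack_id)
    warning("puncta and cells come from different stacks")
  structure(
    list(puncta_count = pc, cell_count = cc, density = pc / cc,
         channel = channel, cell_type = cell_type, group = group),
    class = "density_summary")
}

#' @export
print.density_summary <- function(x, ...) {
  cat(sprintf("<density_summary>%s %d puncta / %d %s = %.1f per cell\n",
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              x$puncta_count, x$cell_count,
              if (is.na(x$cell_type)) "cells" else x$cell_type, x$density))
  invisible(x)
}

#' Developmental fold change of a density
#'
#' Ratio of an immature (young) to a mature (old) per-cell density, e.g. the
#' reduction of afferent ribbons per hair cell across postnatal pruning. Also
#' reported rounded to the nearest integer fold ("approximately two-fold").
#'
#' @param density_young,density_old [density_per_cell()] results or bare
#'   densities. When both are \code{density_summary} objects their channel
#'   and cell type must agree.
#' @return list with \code{ratio} (young / old), \code{fold} (nearest
#'   integer), and \code{defined} (FALSE, with NA ratio, when the old density
#'   is zero).
#' @examples
#' fold_change(41.5, 17.7)   # ratio 2.34, fold 2
#' @export
fold_change <- function(density_young, density_old) {
  get_d <- function(x) if (inherits(x, "density_summary")) x$density else
    as.numeric(x)
  if (inherits(density_young, "density_summary") &&
      inherits(density_old, "density_summary")) {
    same <- function(f) {
      a <- density_young[[f]]; b <- density_old[[f]]
      is.na(a) || is.na(b) || a == b
    }
    if (!same("channel") || !same("cell_type"))
      stop("fold change requires the same channel and cell type")
  }
  young <- get_d(density_young)
  old <- get_d(density_old)
  if (old == 0)
    return(list(ratio = NA_real_, fold = NA_integer_, defined = FALSE))
  r <- young / old
  list(ratio = r, fold = as.integer(round(r)), defined = TRUE)
}
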