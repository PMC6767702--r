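# Point-table dialect: comma-separated, UTF-8, dot decimal, header required.
# Required columns: stack_id, channel, x_um, y_um, z_um. Optional: volume_um3
# (per-punctum volumes) and any number of extra columns, which are preserved
# as per-punctum annotations. Coordinates are always micrometres, never
# voxels (voxel-to-um conversion is the detector's job).

PUNCTA_REQUIRED_COLS <- c("stack_id", "channel", "x_um", "y_um", "z_um")

#' Read a puncta point table
#'
#' Reads the CSV point-table dialect exported by the scene generator (and by
#' 3D reconstruction software after column mapping) and partitions the rows
#' into one [puncta_set()] per (stack_id, channel). Unknown columns are kept
#' as per-punctum annotations. No row is ever dropped silently: malformed
#' coordinates either raise a row-level error naming the line, or, with
#' \code{on_bad_row = "drop"}, are removed with a warning reporting the count.
#'
#' @param path CSV file path.
#' @param channel_filter optional channel label; only matching rows are
#'   returned.
#' @param on_bad_row "error" (default) or "drop".
#' @return list of \code{puncta_set}s, ordered by first appearance.
#' @export
read_puncta_table <- function(path, channel_filter = NULL,
                              on_bad_row = c("error", "drop")) {
  on_bad_row <- match.arg(on_bad_row)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing <- setdiff(PUNCTA_REQUIRED_COLS, names(df))
  if (length(missing))
    stop("format error: missing required column(s) ",
         paste(missing, collapse = ", "), " in ", path)
  coord_cols <- c("x_um", "y_um", "z_um")
  num <- lapply(coord_cols, function(cc) suppressWarnings(as.numeric(df[[cc]])))
  names(num) <- coord_cols
  bad <- which(Reduce(`|`, lapply(num, function(v) !is.finite(v))))
  if (length(bad)) {
    # +1 for the header: report physical line numbers
    msg <- paste0("non-numeric or non-finite coordinate on line(s) ",
                  paste(utils::head(bad + 1L, 10), collapse = ", "),
                  if (length(bad) > 10) ", ..." else "")
    if (on_bad_row == "error") stop("row-level error in ", path, ": ", msg)
    warning("dropped ", length(bad), " row(s) from ", path, ": ", msg)
    keep <- setdiff(seq_len(nrow(df)), bad)
    df <- df[keep, , drop = FALSE]
    num <- lapply(num, `[`, keep)
  }
  for (cc in coord_cols) df[[cc]] <- num[[cc]]
  if ("volume_um3" %in% names(df))
    df$volume_um3 <- suppressWarnings(as.numeric(df$volume_um3))
  if (!is.null(channel_filter)) df <- df[df$channel %in% channel_filter, ,
                                         drop = FALSE]
  key <- paste(df$stack_id, df$channel, sep = "\r")
  extra_cols <- setdiff(names(df), c(PUNCTA_REQUIRED_COLS, "volume_um3"))
  lapply(unique(key), function(k) {
    rows <- df[key == k, , drop = FALSE]
    vols <- NULL
    if ("volume_um3" %in% names(rows) && !all(is.na(rows$volume_um3)))
      vols <- rows$volume_um3
    puncta_set(as.matrix(rows[, coord_cols]),
               stack_id = rows$stack_id[1], channel = rows$channel[1],
               volumes = vols,
               annotations = if (length(extra_cols))
                 rows[, extra_cols, drop = FALSE] else NULL)
  })
}

#' Write puncta sets as a point table
#'
#' Inverse of [read_puncta_table()] on the declared columns (coordinates
#' round-trip at full double precision).
#'
#' @param sets a [puncta_set()] or list of them.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_puncta_table <- function(sets, path) {
  if (inherits(sets, "puncta_set")) sets <- list(sets)
  df <- do.call(rbind, lapply(sets, function(s) {
    d <- as.data.frame(s)
    # align annotation columns across sets
    d
  }))
  # rbind of heterogeneous annotation columns: refuse rather than guess
  ncols <- vapply(sets, function(s) ncol(as.data.frame(s)), integer(1))
  if (length(unique(ncols)) > 1L)
    stop("sets have differing annotation columns; write them separately")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a hair-cell nuclei table
#'
#' Same CSV dialect as [read_puncta_table()], with the channel column holding
#' the cell type ("IHC" or "OHC"). Returns one [hair_cell_set()] per
#' (stack_id, cell type).
#'
#' @param path CSV file path.
#' @return list of \code{hair_cell_set}s.
#' @export
read_hair_cell_table <- function(path) {
  sets <- read_puncta_table(path)
  lapply(sets, function(s) {
    if (!s$channel %in% c("IHC", "OHC"))
      stop("hair-cell table channel must be IHC or OHC, got '", s$channel, "'")
    hair_cell_set(s$coords, s$channel, s$stack_id)
  })
}

#' Write hair-cell nuclei as a point table
#' @param cells a [hair_cell_set()] or list of them (centroids required).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_hair_cell_table <- function(cells, path) {
  if (inherits(cells, "hair_cell_set")) cells <- list(cells)
  sets <- lapply(cells, function(hc) {
    if (is.null(hc$centroids)) stop("hair_cell_set has no centroids to write")
    puncta_set(hc$centroids, hc$stack_id, hc$cell_type)
  })
  write_puncta_table(sets, path)
}

#' Write a synthetic scene to a directory
#'
#' Emits the generator's ground truth as point tables (ribbons with
#' \code{true_side}, OHC ribbons, efferent terminals, nuclei) plus a JSON
#' file holding the configuration and the landmark point.
#'
#' @param scene a [generate_scene()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_puncta_table(scene$ribbons, file.path(dir, "ribbons.csv"))
  write_puncta_table(scene$ohc_ribbons, file.path(dir, "ohc_ribbons.csv"))
  write_puncta_table(scene$efferents, file.path(dir, "efferents.csv"))
  write_hair_cell_table(list(scene$ihc_nuclei, scene$ohc_nuclei),
                        file.path(dir, "nuclei.csv"))
  meta <- c(unclass(scene$config),
            list(landmark_point = as.numeric(scene$landmark_point)))
  jsonlite::write_json(meta, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a scene configuration from JSON
#'
#' @param path JSON file with \code{scene_config} fields (extra fields such
#'   as a stored landmark are ignored).
#' @return a [scene_config()].
#' @export
read_scene_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- cfg[intersect(names(cfg), names(formals(scene_config)))]
  do.call(scene_config, cfg)
}

#' Group summary (mean +/- SEM with N)
#'
#' Per-group mean, SEM and N for a measured quantity, with groups kept in
#' declared factor order. The backbone of the package's summary tables.
#'
#' @param values numeric vector.
#' @param group group label per value; a factor's level order is respected,
#'   otherwise order of first appearance is used. Empty factor levels yield a
#'   row with N = 0 and blank statistics.
#' @param digits digits used in the formatted \code{mean +/- SEM} string.
#' @return data.frame with columns \code{group}, \code{n}, \code{mean},
#'   \code{sem}, \code{formatted}.
#' @examples
#' group_summary(c(1, 2, 3), rep("a", 3))   # mean 2, SEM 0.577
#' @export
group_summary <- function(values, group, digits = 1) {
  if (!is.factor(group)) group <- factor(group, levels = unique(group))
  rows <- lapply(levels(group), function(lv) {
    v <- values[group == lv]
    ms <- mean_sem(v)
    fmt <- if (ms$n == 0) "" else if (ms$n == 1)
      sprintf("%.*f (N = 1)", digits, ms$mean) else
        sprintf("%.*f ± %.*f (N = %d)", digits, ms$mean, digits, ms$sem,
                ms$n)
    data.frame(group = lv, n = ms$n, mean = ms$mean, sem = ms$sem,
               formatted = fmt, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write summary tables as TSV
#'
#' Writes one TSV per named element of \code{results}, each a data.frame in
#' the mean-plus-minus-SEM layout produced by [group_summary()] (or any
#' data.frame). Column order is preserved deterministically.
#'
#' @param results named list of data.frames.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_summary_tables <- function(results, dir) {
  stopifnot(is.list(results), length(results) > 0,
            !is.null(names(results)), all(names(results) != ""))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(results), function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(results[[nm]], p, sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "")
    p
  }, character(1))
  invisible(paths)
}
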