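#' Electrode layout of a planar MEA
#'
#' Builds the electrode map of a planar micro-electrode array laid out on a
#' regular grid. The default reproduces the standard 120-electrode array:
#' a 12 x 12 grid at 200 um pitch with a triangle of 6 positions missing at
#' each corner (144 - 24 = 120 electrodes).
#'
#' Electrode identifiers are `"R<row>C<col>"` with zero-padded indices;
#' positions are planar coordinates in micrometres with the origin at the
#' first row/column position.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param pitch_um centre-to-centre electrode spacing in micrometres.
#' @param drop_corners drop the 6-electrode triangle at each corner
#'   (the standard 120-electrode arrangement). Set `FALSE` for a full grid.
#' @return An object of class `mea_layout`: a list with `electrode_ids`,
#'   `positions` (data frame with `electrode_id`, `x`, `y`, `row`, `col`),
#'   `pitch_um`, `n_rows`, `n_cols`.
#' @examples
#' lay <- mea_layout()
#' length(lay$electrode_ids) # 120
#' @export
mea_layout <- function(n_rows = 12L, n_cols = 12L, pitch_um = 200,
                       drop_corners = TRUE) {
  stopifnot(n_rows >= 1, n_cols >= 1, pitch_um > 0)
  grid <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  if (drop_corners) {
    dr <- pmin(grid$row - 1L, n_rows - grid$row)
    dc <- pmin(grid$col - 1L, n_cols - grid$col)
    grid <- grid[dr + dc > 2L, , drop = FALSE]
  }
  grid <- grid[order(grid$row, grid$col), , drop = FALSE]
  ids <- sprintf("R%02dC%02d", grid$row, grid$col)
  pos <- data.frame(
    electrode_id = ids,
    x = (grid$col - 1L) * pitch_um,
    y = (grid$row - 1L) * pitch_um,
    row = grid$row, col = grid$col,
    stringsAsFactors = FALSE
  )
  rownames(pos) <- NULL
  out <- structure(
    list(electrode_ids = ids, positions = pos, pitch_um = pitch_um,
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
    class = "mea_layout"
  )
  validate_layout(out)
  out
}

#' Build a layout from explicit electrode positions
#'
#' @param positions data frame with columns `electrode_id`, `x`, `y`
#'   (micrometres). `row`/`col` columns are optional.
#' @param pitch_um nominal pitch in micrometres.
#' @param n_rows,n_cols nominal grid dimensions (metadata).
#' @return An `mea_layout` object.
#' @export
mea_layout_from_positions <- function(positions, pitch_um = 200,
                                      n_rows = NA_integer_, n_cols = NA_integer_) {
  stopifnot(is.data.frame(positions),
            all(c("electrode_id", "x", "y") %in% names(positions)))
  positions$electrode_id <- as.character(positions$electrode_id)
  if (!all(c("row", "col") %in% names(positions))) {
    r <- positions$y / pitch_um + 1
    c_ <- positions$x / pitch_um + 1
    if (all(abs(r - round(r)) < 1e-9) && all(abs(c_ - round(c_)) < 1e-9)) {
      positions$row <- as.integer(round(r))
      positions$col <- as.integer(round(c_))
    }
  }
  out <- structure(
    list(electrode_ids = positions$electrode_id, positions = positions,
         pitch_um = pitch_um, n_rows = as.integer(n_rows),
         n_cols = as.integer(n_cols)),
    class = "mea_layout"
  )
  validate_layout(out)
  out
}

validate_layout <- function(layout) {
  if (anyDuplicated(layout$electrode_ids)) {
    stop("layout: duplicated electrode identifiers", call. = FALSE)
  }
  pos <- layout$positions
  if (anyDuplicated(pos[, c("x", "y")])) {
    stop("layout: electrode positions are not pairwise distinct", call. = FALSE)
  }
  if (!all(is.finite(pos$x)) || !all(is.finite(pos$y))) {
    stop("layout: non-finite electrode positions", call. = FALSE)
  }
  invisible(layout)
}

#' @export
print.mea_layout <- function(x, ...) {
  cat(sprintf("<mea_layout> %d electrodes, %s x %s grid, pitch %g um\n",
              length(x$electrode_ids),
              ifelse(is.na(x$n_rows), "?", x$n_rows),
              ifelse(is.na(x$n_cols), "?", x$n_cols),
              x$pitch_um))
  invisible(x)
}

#' Euclidean electrode distances in units of the array pitch
#'
#' @param layout an `mea_layout`.
#' @param from electrode identifier to measure from.
#' @return Named numeric vector of distances (in pitches) to every electrode.
#' @export
electrode_distances <- function(layout, from) {
  pos <- layout$positions
  i <- match(from, pos$electrode_id)
  if (is.na(i)) stop("unknown electrode: ", from, call. = FALSE)
  d <- sqrt((pos$x - pos$x[i])^2 + (pos$y - pos$y[i])^2) / layout$pitch_um
  stats::setNames(d, pos$electrode_id)
}

# ---- compartment geometry ----------------------------------------------

#' Compartment regions
#'
#' Planar regions used to assign electrodes to culture compartments. The
#' three-compartment device consists of one large chamber and two smaller
#' round chambers connected by microchannels; electrodes under the channel
#' region (or outside every chamber) stay unassigned.
#'
#' @param label compartment label.
#' @param xlim,ylim rectangle bounds in micrometres (closed intervals).
#' @return A region specification for [assign_compartments()].
#' @export
rect_region <- function(label, xlim, ylim) {
  stopifnot(length(xlim) == 2, length(ylim) == 2,
            xlim[1] <= xlim[2], ylim[1] <= ylim[2])
  structure(list(label = label, shape = "rect", xlim = xlim, ylim = ylim),
            class = "mea_region")
}

#' @rdname rect_region
#' @param center circle centre `c(x, y)` in micrometres.
#' @param radius circle radius in micrometres.
#' @export
circle_region <- function(label, center, radius) {
  stopifnot(length(center) == 2, radius > 0)
  structure(list(label = label, shape = "circle", center = center,
                 radius = radius),
            class = "mea_region")
}

region_contains <- function(region, x, y) {
  switch(region$shape,
    rect = x >= region$xlim[1] & x <= region$xlim[2] &
           y >= region$ylim[1] & y <= region$ylim[2],
    circle = (x - region$center[1])^2 + (y - region$center[2])^2 <=
             region$radius^2,
    stop("unknown region shape: ", region$shape, call. = FALSE)
  )
}

#' Default three-compartment geometry for a 12 x 12 layout
#'
#' Splits the array into a large chamber (columns 1-6), two small chambers
#' (columns 8-12, rows split at row 6), and leaves the microchannel strips
#' (column 7 and the row between the small chambers) unassigned. The real
#' device geometry varies between preparations, so the regions are a
#' per-dataset input; this default matches the synthetic generator.
#'
#' @param layout an `mea_layout` built by [mea_layout()].
#' @return List of three regions: `big`, `small_left`, `small_right`.
#' @export
default_compartment_geometry <- function(layout = mea_layout()) {
  p <- layout$pitch_um
  half <- p / 2
  list(
    rect_region("big",         xlim = c(-half, 5 * p + half),
                               ylim = c(-half, (layout$n_rows - 1) * p + half)),
    rect_region("small_left",  xlim = c(7 * p - half, (layout$n_cols - 1) * p + half),
                               ylim = c(-half, 4 * p + half)),
    rect_region("small_right", xlim = c(7 * p - half, (layout$n_cols - 1) * p + half),
                               ylim = c(6 * p - half, (layout$n_rows - 1) * p + half))
  )
}

#' Assign electrodes to compartments
#'
#' Each electrode is assigned to the region containing its position;
#' electrodes contained in no region (e.g. under microchannels) are left
#' unassigned (`NA`). Overlapping regions are a configuration error: the
#' compartments partition the culture area.
#'
#' @param layout an `mea_layout`.
#' @param geometry list of regions from [rect_region()]/[circle_region()].
#' @return Named character vector mapping `electrode_id` to a compartment
#'   label (`NA` when unassigned), of class `mea_compartments`.
#' @export
assign_compartments <- function(layout, geometry = default_compartment_geometry(layout)) {
  stopifnot(length(geometry) >= 1)
  pos <- layout$positions
  labels <- rep(NA_character_, nrow(pos))
  hits <- integer(nrow(pos))
  for (region in geometry) {
    inside <- region_contains(region, pos$x, pos$y)
    hits <- hits + inside
    labels[inside] <- region$label
  }
  if (any(hits > 1)) {
    bad <- pos$electrode_id[hits > 1][1]
    stop("assign_compartments: overlapping regions (electrode ", bad,
         " falls in more than one compartment)", call. = FALSE)
  }
  structure(stats::setNames(labels, pos$electrode_id),
            class = "mea_compartments")
}
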