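#' Build the cubical dissection grid
#'
#' Converts a physical cube edge length to per-axis voxel spans
#' (`round(edge_um / pitch)`, minimum 1) and cube counts
#' (`ceiling(voxels / span)`). Edge cubes may be truncated by the image
#' border; they are kept and flagged. 2D inputs (single z slice) get a
#' z span of 1, so the volume is dissected into squares.
#'
#' Cube regions are the half-open voxel index ranges
#' `[i*span, min((i+1)*span, n))` per axis (0-based `i`, `j`, `k` along
#' x, y, z); `cube_id = i + nx*j + nx*ny*k`.
#'
#' @param mask a [binary_biovolume()] (supplies shape and geometry).
#' @param edge_um cube edge length in um; must be at least the largest
#'   voxel pitch.
#' @return A `cube_grid` object: list with `edge_um`, `span` (sx, sy, sz),
#'   `counts` (nx, ny, nz), `dim` (mask shape, z/y/x), `geometry`.
#' @export
build_cube_grid <- function(mask, edge_um) {
  stopifnot(inherits(mask, "binary_biovolume"))
  g <- mask$geometry
  d <- dim(mask$mask)
  two_d <- d[1] == 1L
  max_pitch <- if (two_d) max(g$dx, g$dy) else max(g$dx, g$dy, g$dz)
  if (edge_um < max_pitch) {
    stop("edge_um (", edge_um, ") must be at least one voxel pitch (",
         max_pitch, " um)", call. = FALSE)
  }
  span <- c(sx = max(1L, as.integer(round(edge_um / g$dx))),
            sy = max(1L, as.integer(round(edge_um / g$dy))),
            sz = if (two_d) 1L else max(1L, as.integer(round(edge_um / g$dz))))
  counts <- c(nx = as.integer(ceiling(d[3] / span[["sx"]])),
              ny = as.integer(ceiling(d[2] / span[["sy"]])),
              nz = as.integer(ceiling(d[1] / span[["sz"]])))
  structure(list(edge_um = edge_um, span = span, counts = counts,
                 dim = d, geometry = g),
            class = "cube_grid")
}

#' @export
print.cube_grid <- function(x, ...) {
  cat(sprintf("<cube_grid edge %g um: span (%d,%d,%d) voxels, counts (%d,%d,%d)>\n",
              x$edge_um, x$span[["sx"]], x$span[["sy"]], x$span[["sz"]],
              x$counts[["nx"]], x$counts[["ny"]], x$counts[["nz"]]))
  invisible(x)
}

# 0-based cube grid index per voxel along one axis
axis_cube_index <- function(n_vox, span) (seq_len(n_vox) - 1L) %/% span

# array of 0-based cube_id per voxel
cube_id_array <- function(grid) {
  d <- grid$dim
  ix <- axis_cube_index(d[3], grid$span[["sx"]])
  iy <- axis_cube_index(d[2], grid$span[["sy"]])
  iz <- axis_cube_index(d[1], grid$span[["sz"]])
  nx <- grid$counts[["nx"]]; ny <- grid$counts[["ny"]]
  id_z <- iz * nx * ny
  id_y <- iy * nx
  array(rep(id_z, times = d[2] * d[3]), d) +
    array(rep(rep(id_y, each = d[1]), times = d[3]), d) +
    array(rep(ix, each = d[1] * d[2]), d)
}

# per-cube region sizes (voxels), truncation flags and grid indices for a
# set of 0-based cube ids
cube_region_info <- function(grid, ids) {
  nx <- grid$counts[["nx"]]; ny <- grid$counts[["ny"]]
  i <- ids %% nx
  j <- (ids %/% nx) %% ny
  k <- ids %/% (nx * ny)
  d <- grid$dim
  lx <- pmin((i + 1L) * grid$span[["sx"]], d[3]) - i * grid$span[["sx"]]
  ly <- pmin((j + 1L) * grid$span[["sy"]], d[2]) - j * grid$span[["sy"]]
  lz <- pmin((k + 1L) * grid$span[["sz"]], d[1]) - k * grid$span[["sz"]]
  list(i = i, j = j, k = k,
       region_voxels = as.integer(lx * ly * lz),
       truncated = lx < grid$span[["sx"]] | ly < grid$span[["sy"]] |
                   lz < grid$span[["sz"]])
}

#' Assign foreground voxels to cubes
#'
#' Builds the skeleton cube table: one record per cube that contains at
#' least one foreground voxel, with its grid indices, region size,
#' foreground voxel count and truncation flag. Every foreground voxel is
#' counted in exactly one cube, so the foreground total is conserved.
#'
#' @param mask a [binary_biovolume()].
#' @param grid a [build_cube_grid()] result for the same-shaped mask.
#' @param frame 0-based frame index recorded in the table.
#' @return A `cube_table`: data.frame with columns `frame`, `cube_id`,
#'   `i`, `j`, `k`, `region_voxels`, `fg_voxels`, `truncated`; the grid is
#'   attached as attribute `"grid"`.
#' @export
assign_voxels <- function(mask, grid, frame = 0L) {
  stopifnot(inherits(mask, "binary_biovolume"), inherits(grid, "cube_grid"))
  if (!identical(dim(mask$mask), grid$dim)) {
    stop("grid was built for a different mask shape", call. = FALSE)
  }
  ids <- cube_id_array(grid)
  fg <- which(mask$mask)
  if (length(fg) == 0L) {
    warning("empty mask: cube table has no records", call. = FALSE)
    tab <- data.frame(frame = integer(0), cube_id = integer(0),
                      i = integer(0), j = integer(0), k = integer(0),
                      region_voxels = integer(0), fg_voxels = integer(0),
                      truncated = logical(0))
    return(as_cube_table(tab, grid))
  }
  occ <- ids[fg]
  cnt <- table(occ)
  occ_ids <- as.integer(names(cnt))
  info <- cube_region_info(grid, occ_ids)
  tab <- data.frame(frame = as.integer(frame), cube_id = occ_ids,
                    i = info$i, j = info$j, k = info$k,
                    region_voxels = info$region_voxels,
                    fg_voxels = as.integer(cnt),
                    truncated = info$truncated)
  as_cube_table(tab, grid)
}

as_cube_table <- function(df, grid) {
  attr(df, "grid") <- grid
  class(df) <- c("cube_table", "data.frame")
  df
}

#' Import labeled objects as cytometry records
#'
#' For an imported labeled mask (e.g. an external single-cell
#' segmentation), each positive label becomes one record whose region is
#' the label's own voxel set, bypassing the cubical grid. Object-level
#' cytometry then runs through the same table machinery as cube cytometry.
#'
#' @param mask a [binary_biovolume()] carrying a `labels` array.
#' @param frame 0-based frame index.
#' @return A `cube_table` with one record per label; `cube_id` is the label.
#' @export
assign_labels <- function(mask, frame = 0L) {
  stopifnot(inherits(mask, "binary_biovolume"))
  if (is.null(mask$labels)) stop("mask carries no label array", call. = FALSE)
  lab <- mask$labels
  fg <- lab > 0L
  cnt <- table(lab[fg])
  tab <- data.frame(frame = as.integer(frame),
                    cube_id = as.integer(names(cnt)),
                    i = NA_integer_, j = NA_integer_, k = NA_integer_,
                    region_voxels = as.integer(cnt),
                    fg_voxels = as.integer(cnt),
                    truncated = FALSE)
  as_cube_table(tab, NULL)
}
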