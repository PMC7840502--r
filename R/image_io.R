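# TIFF stack/mask I/O with explicit voxel geometry, cube-table CSV export
# and legacy VTK export for ParaView rendering.
#
# Multi-page TIFF layout convention: pages are ordered frame-major, then
# channel, then z (z fastest), i.e. page = ((frame * n_channels) +
# channel) * nz + z. Voxel geometry always comes from the caller (sidecar
# configuration), never from TIFF resolution tags, for reproducibility.

#' Read one channel/frame of a TIFF stack
#'
#' @param path TIFF file (single- or multi-page).
#' @param geometry a [voxel_geometry()]; TIFF tags are not consulted.
#' @param channel channel index (1-based) or name in `channel_names`.
#' @param frame 0-based frame index.
#' @param n_channels,n_frames page-layout of the file.
#' @param channel_names optional names, one per channel.
#' @return An [intensity_stack()] with axis order (z, y, x); a 2D image
#'   yields shape `(1, ny, nx)`.
#' @export
read_stack <- function(path, geometry, channel = 1L, frame = 0L,
                       n_channels = 1L, n_frames = 1L, channel_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(inherits(geometry, "voxel_geometry"))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  npages <- length(pages)
  if (npages %% (n_channels * n_frames) != 0L) {
    stop("configuration error: ", npages, " pages are not divisible by ",
         "n_channels * n_frames = ", n_channels * n_frames, call. = FALSE)
  }
  nz <- npages %/% (n_channels * n_frames)
  if (is.character(channel)) {
    if (is.null(channel_names)) {
      stop("configuration error: channel requested by name but channel_names not given",
           call. = FALSE)
    }
    ci <- match(channel, channel_names)
    if (is.na(ci)) stop("configuration error: unknown channel '", channel, "'",
                        call. = FALSE)
  } else {
    ci <- as.integer(channel)
  }
  if (ci < 1L || ci > n_channels) {
    stop("configuration error: channel ", ci, " requested but file has ",
         n_channels, " channels", call. = FALSE)
  }
  if (frame < 0L || frame >= n_frames) {
    stop("configuration error: frame ", frame, " requested but file has ",
         n_frames, " frames", call. = FALSE)
  }
  first <- (as.integer(frame) * n_channels + (ci - 1L)) * nz
  sl <- pages[first + seq_len(nz)]
  ny <- nrow(sl[[1]]); nx <- ncol(sl[[1]])
  a <- array(0, c(nz, ny, nx))
  for (z in seq_len(nz)) a[z, , ] <- sl[[z]]
  nm <- if (!is.null(channel_names)) channel_names[ci] else paste0("ch", ci)
  intensity_stack(a, geometry, channel = nm, frame = frame)
}

#' Write an intensity stack (or raw array) as a multi-page TIFF
#'
#' Values are stored as unsigned integers of the given bit depth; the
#' written file reads back to identical integer values via [read_stack()].
#'
#' @param x an [intensity_stack()] or a numeric (z, y, x) array of
#'   non-negative integers.
#' @param path output file.
#' @param bits 8 or 16 bits per sample.
#' @return The path, invisibly.
#' @export
write_stack <- function(x, path, bits = 16L) {
  a <- if (inherits(x, "intensity_stack")) x$values else as_zyx_array(x)
  maxval <- 2^bits - 1
  if (any(a < 0) || any(a > maxval)) {
    stop("values outside [0, ", maxval, "] cannot be stored at ", bits, " bits",
         call. = FALSE)
  }
  pages <- lapply(seq_len(dim(a)[1]), function(z) {
    matrix(a[z, , ], dim(a)[2], dim(a)[3]) / maxval
  })
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                  compression = "none")
  invisible(path)
}

#' Read a presegmented mask TIFF
#'
#' Nonzero voxels become foreground. When the file contains more than one
#' distinct positive integer, the values are retained as object labels for
#' imported-object cytometry (see [assign_labels()]).
#'
#' @param path TIFF file of integer (or boolean 0/1) voxels.
#' @param geometry a [voxel_geometry()].
#' @param expect_dim optional (nz, ny, nx) shape of the dataset's
#'   intensity stacks; a mismatch is an error.
#' @return A [binary_biovolume()] (with `labels` when the mask is labeled).
#' @export
read_mask <- function(path, geometry, expect_dim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  a <- array(0, c(nz, ny, nx))
  for (z in seq_len(nz)) a[z, , ] <- pages[[z]]
  if (any(a != round(a))) {
    stop("mask TIFF contains non-integer values; binarize it before import",
         call. = FALSE)
  }
  if (!is.null(expect_dim) && !identical(dim(a), as.integer(expect_dim))) {
    stop("mask shape (", paste(dim(a), collapse = "x"),
         ") does not match the dataset (", paste(expect_dim, collapse = "x"), ")",
         call. = FALSE)
  }
  if (!any(a > 0)) warning("mask has no foreground voxels", call. = FALSE)
  labels <- NULL
  pos <- unique(a[a > 0])
  if (length(pos) > 1L) {
    labels <- a
    storage.mode(labels) <- "integer"
  }
  binary_biovolume(a > 0, geometry, labels = labels)
}

#' Write a mask (or label array) as TIFF
#' @param mask a [binary_biovolume()]; its label array is written when
#'   present, otherwise 0/1.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_biovolume"))
  a <- if (!is.null(mask$labels)) mask$labels else mask$mask * 1L
  write_stack(array(as.numeric(a), dim(a)), path,
              bits = if (max(a) > 255) 16L else 8L)
}

#' Write a cube table as CSV
#'
#' Header: `frame, cube_id, i, j, k`, then one column per parameter in
#' sorted order. Missing values are written as the literal `NaN`; numbers
#' carry 15 significant digits so a round-trip read reproduces them.
#'
#' @param table a nonempty cube table.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_cube_table <- function(table, path) {
  if (nrow(table) == 0L) stop("refusing to write an empty cube table", call. = FALSE)
  params <- cube_parameters(table)
  cols <- c("frame", "cube_id", "i", "j", "k", params)
  out <- table[cols]
  fmt <- function(v) {
    if (is.numeric(v) && !is.integer(v)) {
      s <- formatC(v, digits = 15, format = "g")
      s[!is.finite(v) & is.nan(v)] <- "NaN"
      s[is.na(v) & !is.nan(v)] <- "NaN"
      trimws(s)
    } else as.character(v)
  }
  body <- vapply(out, fmt, character(nrow(out)))
  if (nrow(out) == 1L) body <- matrix(body, nrow = 1L)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path, call. = FALSE))
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  writeLines(apply(body, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read a cube-table CSV written by [write_cube_table()]
#' @param path CSV file.
#' @return data.frame with `NaN` for missing cells.
#' @export
read_cube_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Write global metrics as long-format CSV
#' @param metrics a `global_metrics` data.frame.
#' @param path output file.
#' @param frame frame index recorded in the first column.
#' @return The path, invisibly.
#' @export
write_global_metrics <- function(metrics, path, frame = 0L) {
  df <- data.frame(frame = frame, metric = metrics$metric,
                   value = trimws(formatC(metrics$value, digits = 15, format = "g")),
                   units = metrics$units)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export cube parameters as a legacy VTK file for ParaView
#'
#' Writes an ASCII `STRUCTURED_POINTS` dataset whose cells are the cubes:
#' point dimensions are the per-axis cube counts plus one, `SPACING` is
#' the physical cube edge per axis, and each requested parameter becomes a
#' `CELL_DATA` scalar array (`nan` in unoccupied cubes) alongside a 0/1
#' `occupied` array.
#'
#' @param table a cube table for one frame.
#' @param grid the [build_cube_grid()] the table was built on.
#' @param params character vector of parameter names to export.
#' @param path output `.vtk` file.
#' @return The path, invisibly.
#' @export
export_vtk <- function(table, grid, params, path) {
  stopifnot(inherits(grid, "cube_grid"))
  avail <- cube_parameters(table)
  bad <- setdiff(params, avail)
  if (length(bad)) {
    stop("unknown parameter(s) ", paste(bad, collapse = ", "),
         "; available: ", paste(avail, collapse = ", "), call. = FALSE)
  }
  g <- grid$geometry
  nx <- grid$counts[["nx"]]; ny <- grid$counts[["ny"]]; nz <- grid$counts[["nz"]]
  ncell <- nx * ny * nz
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "cubecyte cube parameters",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", nx + 1L, ny + 1L, nz + 1L),
               "ORIGIN 0 0 0",
               sprintf("SPACING %.17g %.17g %.17g",
                       grid$span[["sx"]] * g$dx, grid$span[["sy"]] * g$dy,
                       grid$span[["sz"]] * g$dz),
               sprintf("CELL_DATA %d", ncell)), con)
  # cube_id = i + nx*j + nx*ny*k is exactly the VTK cell order (x fastest)
  write_scalar <- function(name, vec) {
    writeLines(c(sprintf("SCALARS %s double 1", name), "LOOKUP_TABLE default"), con)
    s <- sprintf("%.17g", vec)
    s[is.nan(vec)] <- "nan"
    writeLines(s, con)
  }
  occ <- numeric(ncell)
  occ[table$cube_id + 1L] <- 1
  write_scalar("occupied", occ)
  for (p in params) {
    v <- rep(NaN, ncell)
    v[table$cube_id + 1L] <- table[[p]]
    write_scalar(gsub("[^A-Za-z0-9_]", "_", p), v)
  }
  invisible(path)
}
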