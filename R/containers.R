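#' Voxel geometry
#'
#' Physical voxel pitch in micrometres along each axis. Confocal stacks are
#' typically anisotropic (z pitch coarser than xy), so all three pitches are
#' carried explicitly and every physical quantity in the package is computed
#' from them.
#'
#' @param dx,dy,dz voxel pitch in um along x, y and z; all strictly positive.
#' @return A `voxel_geometry` object (list with elements `dx`, `dy`, `dz`).
#' @export
voxel_geometry <- function(dx, dy, dz) {
  for (v in c(dx, dy, dz)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("voxel pitches must be single finite positive numbers", call. = FALSE)
    }
  }
  structure(list(dx = dx, dy = dy, dz = dz), class = "voxel_geometry")
}

#' @export
format.voxel_geometry <- function(x, ...) {
  sprintf("<voxel_geometry dx=%g dy=%g dz=%g um>", x$dx, x$dy, x$dz)
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Intensity stack
#'
#' One channel/frame of voxel intensities on a regular grid. Values are
#' stored as a 3D array indexed `[z, y, x]` with `z = 1` the
#' substratum-adjacent plane; 2D images are carried as a single z slice.
#'
#' @param values numeric 3D array `(nz, ny, nx)` (a matrix is promoted to a
#'   single z slice); all values finite and non-negative.
#' @param geometry a [voxel_geometry()].
#' @param channel channel name (character scalar).
#' @param frame 0-based frame index.
#' @return An `intensity_stack` object.
#' @export
intensity_stack <- function(values, geometry, channel = "ch1", frame = 0L) {
  values <- as_zyx_array(values)
  if (!all(is.finite(values))) stop("intensity values must be finite", call. = FALSE)
  if (any(values < 0)) stop("intensity values must be non-negative", call. = FALSE)
  stopifnot(inherits(geometry, "voxel_geometry"))
  structure(
    list(values = values, geometry = geometry,
         channel = as.character(channel), frame = as.integer(frame)),
    class = "intensity_stack")
}

#' @export
print.intensity_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<intensity_stack '%s' frame %d: %d x %d x %d (z,y,x), %s>\n",
              x$channel, x$frame, d[1], d[2], d[3], format(x$geometry)))
  invisible(x)
}

#' Binary biovolume
#'
#' The segmented biomass mask on the same voxel grid as its source stack.
#' An optional integer label array carries imported object identities
#' (e.g. an external single-cell segmentation).
#'
#' @param mask logical 3D array `(nz, ny, nx)`; a matrix is promoted to a
#'   single z slice.
#' @param geometry a [voxel_geometry()].
#' @param labels optional integer array of the same shape; 0 = background.
#' @return A `binary_biovolume` object.
#' @export
binary_biovolume <- function(mask, geometry, labels = NULL) {
  mask <- as_zyx_array(mask)
  storage.mode(mask) <- "logical"
  stopifnot(inherits(geometry, "voxel_geometry"))
  if (!is.null(labels)) {
    labels <- as_zyx_array(labels)
    if (!identical(dim(labels), dim(mask))) {
      stop("label array shape must match mask shape", call. = FALSE)
    }
    storage.mode(labels) <- "integer"
  }
  structure(list(mask = mask, geometry = geometry, labels = labels),
            class = "binary_biovolume")
}

#' @export
print.binary_biovolume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<binary_biovolume %d x %d x %d (z,y,x), %d foreground voxels, %s>\n",
              d[1], d[2], d[3], sum(x$mask), format(x$geometry)))
  invisible(x)
}

# Promote a matrix to a (1, ny, nx) array; validate a 3D array.
as_zyx_array <- function(x) {
  if (is.matrix(x)) {
    dim(x) <- c(1L, nrow(x), ncol(x))
  } else if (is.array(x) && length(dim(x)) == 3L) {
    # already (z, y, x)
  } else {
    stop("expected a matrix or a 3D array indexed (z, y, x)", call. = FALSE)
  }
  x
}

# Integer range that is empty (not descending) when from > to.
seq_range <- function(from, to) {
  if (from > to) integer(0) else seq.int(from, to)
}

# Evaluate expr with a temporarily fixed RNG state (no leakage of global state).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Pearson correlation that returns NaN (not NA + warning) on degenerate input.
safe_pearson <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L) return(NaN)
  da <- a - mean(a); db <- b - mean(b)
  den <- sqrt(sum(da^2) * sum(db^2))
  if (den == 0) return(NaN)
  sum(da * db) / den
}

safe_spearman <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  safe_pearson(rank(a[ok]), rank(b[ok]))
}

# Manders overlap coefficient over paired non-negative vectors.
manders_overlap <- function(a, b) {
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(NaN)
  sum(a * b) / den
}
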