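#' Distance fields and biofilm reference points
#'
#' Computes, for every foreground voxel, the Euclidean distance (um) to the
#' biofilm outer surface, together with the biovolume centre of mass, its
#' projection onto the substratum plane and the maximum thickness. These are
#' the spatial coordinates in which biofilm-internal properties are expressed
#' (distance to surface, to substratum, to the centre of mass, or to the
#' centre of mass projected onto the substratum).
#'
#' The outer surface is the interface between foreground and background. The
#' volume is treated as surrounded by background on all faces except,
#' in `substrate_mode = "attached"`, the substratum face (z = 1 plane): a
#' surface-attached biofilm is not "exposed" at its base, so voxels touching
#' the substratum are not surface voxels. Use `substrate_mode = "floating"`
#' for free-floating aggregates, where all faces count as exposed. The
#' distance transform is anisotropy-aware: physical pitches enter per axis.
#'
#' For 2D inputs (a single z slice) the distance is computed in-plane and
#' `substrate_mode` has no effect.
#'
#' @param mask a [binary_biovolume()] with at least one foreground voxel.
#' @param substrate_mode `"attached"` (default) or `"floating"`.
#' @return A `distance_fields` object: list with
#'   \item{d_surface}{array (um), `NA` at background voxels;}
#'   \item{com}{centre of mass of the biovolume, um, named (x, y, z);}
#'   \item{com_projected}{`com` with z set to 0;}
#'   \item{max_thickness}{maximum column thickness, um;}
#'   \item{column_height}{`(ny, nx)` matrix of column thicknesses, um.}
#' @export
compute_distance_fields <- function(mask, substrate_mode = c("attached", "floating")) {
  substrate_mode <- match.arg(substrate_mode)
  stopifnot(inherits(mask, "binary_biovolume"))
  m <- mask$mask
  g <- mask$geometry
  if (!any(m)) stop("mask has no foreground voxels", call. = FALSE)
  d <- dim(m)

  dsq <- edt_surface_squared(m, g, substrate_mode)
  d_surface <- sqrt(dsq)
  d_surface[!m] <- NA_real_

  # centre of mass over foreground voxel centers (unweighted)
  idx <- which(m, arr.ind = TRUE) # columns: z (dim1), y, x
  com <- c(x = (mean(idx[, 3]) - 0.5) * g$dx,
           y = (mean(idx[, 2]) - 0.5) * g$dy,
           z = (mean(idx[, 1]) - 0.5) * g$dz)
  ch <- column_heights(m, g)
  structure(list(d_surface = d_surface,
                 com = com,
                 com_projected = c(com[["x"]], com[["y"]], 0),
                 max_thickness = max(ch),
                 column_height = ch),
            class = "distance_fields")
}

# Squared EDT from foreground voxel centers to the nearest background voxel
# center, with a one-voxel background pad on exposed faces (sufficient for an
# exact result, as the nearest point of an infinite background half-space is
# always in its first layer).
edt_surface_squared <- function(m, g, substrate_mode) {
  d <- dim(m)
  two_d <- d[1] == 1L
  if (two_d) {
    pad <- array(FALSE, d + c(0L, 2L, 2L))
    pad[, 2:(d[2] + 1L), 2:(d[3] + 1L)] <- m
    src <- !pad
    dsq <- edt_squared_cpp(src, dim(pad), c(g$dz, g$dy, g$dx))
    return(array(dsq, dim(pad))[, 2:(d[2] + 1L), 2:(d[3] + 1L), drop = FALSE])
  }
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- m
  if (substrate_mode == "attached") {
    # substratum pad plane mirrors the biofilm base: contact is not surface
    pad[1L, 2:(d[2] + 1L), 2:(d[3] + 1L)] <- m[1L, , ]
  }
  src <- !pad
  dsq <- edt_squared_cpp(src, dim(pad), c(g$dz, g$dy, g$dx))
  array(dsq, dim(pad))[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), drop = FALSE]
}

# Column thickness map: (1 + highest foreground z index, 0-based) * dz per
# (y, x) column, ignoring interior gaps (COMSTAT thickness-map convention);
# 0 for empty columns.
column_heights <- function(m, g) {
  d <- dim(m)
  m2 <- matrix(m, nrow = d[1])
  h <- numeric(ncol(m2))
  for (z in seq_len(d[1])) h <- pmax(h, z * m2[z, ])
  matrix(h * g$dz, nrow = d[2], ncol = d[3])
}
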