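# Connected-component labeling of voxel masks via igraph on the
# foreground adjacency graph. 26-connectivity in 3D, 8-connectivity for
# single-slice (2D) inputs.

half_neighborhood_offsets <- function(two_d) {
  off <- expand.grid(oz = -1:1, oy = -1:1, ox = -1:1)
  off <- off[!(off$oz == 0 & off$oy == 0 & off$ox == 0), ]
  if (two_d) off <- off[off$oz == 0, ]
  # keep one offset per +/- pair (lexicographically positive)
  keep <- off$oz > 0 | (off$oz == 0 & (off$oy > 0 | (off$oy == 0 & off$ox > 0)))
  off[keep, , drop = FALSE]
}

# Integer label array (0 = background); labels are 1..n_components in
# order of each component's smallest linear voxel index (deterministic).
label_components <- function(m) {
  d <- dim(m)
  lab <- array(0L, d)
  fg <- which(m)
  if (length(fg) == 0L) return(lab)
  lin <- array(seq_along(m), d)
  offs <- half_neighborhood_offsets(two_d = d[1] == 1L)
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    oz <- offs$oz[r]; oy <- offs$oy[r]; ox <- offs$ox[r]
    zr <- seq_range(max(1L, 1L - oz), min(d[1], d[1] - oz))
    yr <- seq_range(max(1L, 1L - oy), min(d[2], d[2] - oy))
    xr <- seq_range(max(1L, 1L - ox), min(d[3], d[3] - ox))
    if (!length(zr) || !length(yr) || !length(xr)) next
    a <- lin[zr, yr, xr, drop = FALSE]
    b <- lin[zr + oz, yr + oy, xr + ox, drop = FALSE]
    ok <- m[a] & m[b]
    edges[[r]] <- cbind(a[ok], b[ok])
  }
  e <- do.call(rbind, edges)
  vid <- match(seq_along(m), fg) # linear index -> vertex id
  gr <- igraph::make_graph(edges = if (is.null(e) || nrow(e) == 0L) integer(0)
                           else rbind(vid[e[, 1]], vid[e[, 2]]),
                           n = length(fg), directed = FALSE)
  memb <- igraph::components(gr)$membership
  # fg is ascending, so renumbering by first occurrence makes labels
  # deterministic in linear voxel order
  lab[fg] <- match(memb, unique(memb))
  lab
}

# Drop connected components smaller than min_voxels.
remove_small_components <- function(m, min_voxels) {
  if (min_voxels <= 1L || !any(m)) return(m)
  lab <- label_components(m)
  sizes <- tabulate(lab[lab > 0L])
  small <- which(sizes < min_voxels)
  if (length(small)) m[lab %in% small] <- FALSE
  m
}

# Per-z-slice hole filling: background regions (4-connectivity) of a slice
# that do not touch the slice border are converted to foreground. 2D by
# design, so real vertical channels through a biofilm are not sealed.
fill_holes_slices <- function(m) {
  d <- dim(m)
  for (z in seq_len(d[1])) {
    sl <- matrix(m[z, , ], d[2], d[3])
    m[z, , ] <- fill_holes_2d(sl)
  }
  m
}

fill_holes_2d <- function(sl) {
  ny <- nrow(sl); nx <- ncol(sl)
  bg <- !sl
  if (!any(bg)) return(sl)
  # flood the border-connected background with a BFS over 4-neighbors
  reach <- matrix(FALSE, ny, nx)
  border <- bg
  border[2:(ny - 1), 2:(nx - 1)] <- FALSE
  frontier <- which(border)
  reach[frontier] <- TRUE
  while (length(frontier)) {
    r <- ((frontier - 1L) %% ny) + 1L
    c <- ((frontier - 1L) %/% ny) + 1L
    nb <- c(frontier[r > 1L] - 1L, frontier[r < ny] + 1L,
            frontier[c > 1L] - ny, frontier[c < nx] + ny)
    nb <- unique(nb[bg[nb] & !reach[nb]])
    reach[nb] <- TRUE
    frontier <- nb
  }
  sl | (bg & !reach)
}
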