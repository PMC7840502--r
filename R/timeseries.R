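# Time series: frame registration, cube-lineage tracking, clonal cluster
# sizes and spatiotemporal kymographs.

#' Register frames by rigid xy drift
#'
#' Estimates the integer-voxel xy drift of each frame relative to the
#' previous one as the argmax of the 2D cross-correlation of the
#' z-projected masks, and accumulates it. Ties are broken toward the
#' smallest shift (then lexicographically), so pure symmetric growth
#' registers as zero drift. No z registration is performed
#' (surface-attached growth assumption).
#'
#' @param masks list of [binary_biovolume()]s, one per frame, same shape.
#' @param max_shift_vox maximum allowed per-step shift magnitude (voxels).
#' @return Integer matrix `n_frames x 2` (columns `x`, `y`): accumulated
#'   drift of each frame relative to frame 1.
#' @export
register_frames <- function(masks, max_shift_vox = Inf) {
  if (length(masks) < 2L) stop("need at least two frames", call. = FALSE)
  d <- dim(masks[[1]]$mask)
  proj <- lapply(masks, function(m) {
    if (!identical(dim(m$mask), d)) stop("frames must share one shape", call. = FALSE)
    p <- matrix(0, d[2], d[3])
    p[] <- as.numeric(apply(m$mask, c(2, 3), any))
    p
  })
  n <- length(masks)
  drift <- matrix(0L, n, 2, dimnames = list(NULL, c("x", "y")))
  for (t in 2:n) {
    if (!any(proj[[t]] > 0) || !any(proj[[t - 1]] > 0)) {
      warning("empty frame at position ", t, ": zero drift assumed", call. = FALSE)
      step <- c(0L, 0L)
    } else {
      step <- xcorr_argmax_2d(proj[[t - 1]], proj[[t]], max_shift_vox)
    }
    drift[t, ] <- drift[t - 1, ] + step
  }
  drift
}

# argmax over integer shifts u of sum_v P1(v) * P2(v + u); returns c(x, y)
xcorr_argmax_2d <- function(p1, p2, max_shift) {
  ny <- nrow(p1); nx <- ncol(p1)
  My <- as.integer(stats::nextn(2L * ny, c(2, 3, 5)))
  Mx <- as.integer(stats::nextn(2L * nx, c(2, 3, 5)))
  a <- matrix(0, My, Mx); a[1:ny, 1:nx] <- p1
  b <- matrix(0, My, Mx); b[1:ny, 1:nx] <- p2
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) / (My * Mx)
  ly <- max(-(ny - 1L), -floor(max_shift)):min(ny - 1L, floor(max_shift))
  lx <- max(-(nx - 1L), -floor(max_shift)):min(nx - 1L, floor(max_shift))
  grid <- expand.grid(uy = ly, ux = lx)
  iy <- ifelse(grid$uy >= 0, grid$uy, My + grid$uy) + 1L
  ix <- ifelse(grid$ux >= 0, grid$ux, Mx + grid$ux) + 1L
  val <- cc[cbind(iy, ix)]
  ord <- order(-val, grid$uy^2 + grid$ux^2, grid$uy, grid$ux)
  best <- grid[ord[1], ]
  c(as.integer(best$ux), as.integer(best$uy))
}

#' Track cube lineages across frames
#'
#' Connects cube `c_t` to cube `c_(t+1)` when, after drift correction,
#' their regions share at least one voxel that is foreground in both
#' frames. Each child keeps only its largest-overlap parent (ties go to
#' the lowest parent `cube_id`), so the lineage graph is a forest; roots
#' are cubes without a parent.
#'
#' Cubes colonized for the first time (no voxel overlap with the previous
#' frame) would otherwise start spurious new lineages at the expanding
#' front; with `attach_new = TRUE` (default) such a child is attached to
#' the occupied 26-neighbor cube of the previous frame with the most
#' biomass (ties to the lowest `cube_id`), recorded with
#' `overlap_voxels = 0` and `direct = FALSE`.
#'
#' @param tables list of cube tables (one per frame, one shared grid).
#' @param masks list of [binary_biovolume()]s matching the tables.
#' @param drifts accumulated drift matrix from [register_frames()], or
#'   `NULL` for no drift.
#' @param attach_new link newly colonized cubes to a neighboring lineage.
#' @return A `track_graph`: list with `edges` (data.frame `frame`,
#'   `parent_id`, `child_id`, `overlap_voxels`, `direct`) and `nodes`
#'   (data.frame `frame`, `cube_id`, `is_root`).
#' @export
track_cubes <- function(tables, masks, drifts = NULL, attach_new = TRUE) {
  n <- length(tables)
  stopifnot(n == length(masks), n >= 2L)
  grid <- attr(tables[[1]], "grid")
  for (t in seq_len(n)) {
    gt <- attr(tables[[t]], "grid")
    if (!identical(gt$span, grid$span) || !identical(gt$counts, grid$counts)) {
      stop("all frames must share one cube grid", call. = FALSE)
    }
  }
  if (is.null(drifts)) drifts <- matrix(0L, n, 2, dimnames = list(NULL, c("x", "y")))
  d <- grid$dim
  ids <- cube_id_array(grid)
  edges <- list()
  for (t in seq_len(n - 1L)) {
    step <- drifts[t + 1L, ] - drifts[t, ] # child coords = parent coords + step
    sx <- step[["x"]]; sy <- step[["y"]]
    yr <- seq_range(max(1L, 1L - sy), min(d[2], d[2] - sy))
    xr <- seq_range(max(1L, 1L - sx), min(d[3], d[3] - sx))
    if (!length(yr) || !length(xr)) next
    zr <- seq_len(d[1])
    m_par <- masks[[t]]$mask[zr, yr, xr, drop = FALSE]
    m_chi <- masks[[t + 1L]]$mask[zr, yr + sy, xr + sx, drop = FALSE]
    both <- which(m_par & m_chi)
    if (!length(both)) next
    id_par <- ids[zr, yr, xr, drop = FALSE][both]
    id_chi <- ids[zr, yr + sy, xr + sx, drop = FALSE][both]
    ov <- stats::aggregate(list(overlap_voxels = rep(1L, length(both))),
                           by = list(parent_id = id_par, child_id = id_chi), FUN = sum)
    # single largest-overlap parent per child, lowest parent id on ties
    ov <- ov[order(ov$child_id, -ov$overlap_voxels, ov$parent_id), ]
    ov <- ov[!duplicated(ov$child_id), ]
    e_t <- data.frame(frame = t - 1L, parent_id = ov$parent_id,
                      child_id = ov$child_id,
                      overlap_voxels = ov$overlap_voxels, direct = TRUE)
    if (attach_new) {
      miss <- tables[[t + 1L]][!(tables[[t + 1L]]$cube_id %in% e_t$child_id), ]
      if (nrow(miss)) {
        par_tab <- tables[[t]]
        att <- attach_to_neighbor(miss, par_tab, grid)
        if (nrow(att)) {
          e_t <- rbind(e_t, data.frame(frame = t - 1L, parent_id = att$parent_id,
                                       child_id = att$child_id,
                                       overlap_voxels = 0L, direct = FALSE))
        }
      }
    }
    edges[[t]] <- e_t
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(frame = integer(0), parent_id = integer(0),
               child_id = integer(0), overlap_voxels = integer(0),
               direct = logical(0))
  nodes <- do.call(rbind, lapply(seq_len(n), function(t) {
    data.frame(frame = t - 1L, cube_id = tables[[t]]$cube_id)
  }))
  child_key <- paste(edges$frame + 1L, edges$child_id)
  nodes$is_root <- !(paste(nodes$frame, nodes$cube_id) %in% child_key)
  structure(list(edges = edges, nodes = nodes, n_frames = n), class = "track_graph")
}

#' Drift-correct a series of masks
#'
#' Translates each frame's mask back by its accumulated xy drift so that
#' all frames live in the coordinate system of frame 1. Dissecting the
#' aligned masks on one shared grid gives cubes a stable positional
#' identity across frames; content shifted beyond the border is cropped.
#'
#' @param masks list of [binary_biovolume()]s.
#' @param drifts accumulated drift matrix from [register_frames()].
#' @return List of aligned [binary_biovolume()]s.
#' @export
align_masks <- function(masks, drifts) {
  stopifnot(length(masks) == nrow(drifts))
  lapply(seq_along(masks), function(t) {
    m <- masks[[t]]
    if (drifts[t, "x"] == 0L && drifts[t, "y"] == 0L) return(m)
    m$mask <- shift_mask_xy(m$mask, -drifts[t, "x"], -drifts[t, "y"])
    m
  })
}

# attach parentless children to their best occupied 26-neighbor at the
# previous frame: most parent biomass, then lowest cube_id
attach_to_neighbor <- function(children, parents, grid) {
  nx <- grid$counts[["nx"]]; ny <- grid$counts[["ny"]]; nz <- grid$counts[["nz"]]
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0 & offs$dk == 0), ]
  out <- data.frame(parent_id = integer(0), child_id = integer(0))
  for (r in seq_len(nrow(children))) {
    ii <- children$i[r] + offs$di; jj <- children$j[r] + offs$dj
    kk <- children$k[r] + offs$dk
    ok <- ii >= 0 & ii < nx & jj >= 0 & jj < ny & kk >= 0 & kk < nz
    nid <- (ii + nx * jj + nx * ny * kk)[ok]
    m <- match(nid, parents$cube_id)
    cand <- parents[m[!is.na(m)], ]
    if (!nrow(cand)) next
    cand <- cand[order(-cand$fg_voxels, cand$cube_id), ]
    out <- rbind(out, data.frame(parent_id = cand$cube_id[1],
                                 child_id = children$cube_id[r]))
  }
  out
}

#' Write a track graph edge list as CSV
#' @param graph a [track_cubes()] result.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_track_edges <- function(graph, path) {
  stopifnot(inherits(graph, "track_graph"))
  utils::write.csv(graph$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Clonal cluster sizes from channel dominance
#'
#' Labels each cube by its dominant channel — channel A when
#' `mean_A / (mean_A + mean_B) >= min_fraction`, channel B symmetrically,
#' otherwise mixed — and measures the connected components
#' (26-connectivity on the cube grid) of same-label, non-mixed cubes.
#'
#' @param table a cube table with `<ch>_mean` and `biovolume_um3` columns.
#' @param channel_a,channel_b channel names.
#' @param min_fraction dominance threshold in `(0.5, 1]`.
#' @return data.frame with one row per clonal cluster: `label`,
#'   `n_cubes`, `size_um3`.
#' @export
clonal_cluster_sizes <- function(table, channel_a, channel_b, min_fraction = 0.9) {
  ca <- paste0(channel_a, "_mean"); cb <- paste0(channel_b, "_mean")
  for (col in c(ca, cb, "biovolume_um3")) {
    if (is.null(table[[col]])) stop("column '", col, "' missing from table", call. = FALSE)
  }
  tot <- table[[ca]] + table[[cb]]
  frac_a <- ifelse(tot > 0, table[[ca]] / tot, NaN)
  lab <- ifelse(is.nan(frac_a), "mixed",
                ifelse(frac_a >= min_fraction, channel_a,
                       ifelse(1 - frac_a >= min_fraction, channel_b, "mixed")))
  out <- list()
  nb <- neighbor_rows(table, include_self = FALSE)
  for (ch in c(channel_a, channel_b)) {
    sel <- which(lab == ch)
    if (!length(sel)) next
    sub <- match(seq_len(nrow(table)), sel) # row -> vertex within label
    e <- cbind(rep(sel, ncol(nb)), as.vector(nb[sel, ]))
    e <- e[!is.na(e[, 2]) & lab[pmax(e[, 2], 1)] == ch & !is.na(sub[pmax(e[, 2], 1)]), ,
           drop = FALSE]
    gr <- igraph::make_graph(edges = rbind(sub[e[, 1]], sub[e[, 2]]),
                             n = length(sel), directed = FALSE)
    memb <- igraph::components(gr)$membership
    sz <- rowsum(cbind(1, table$biovolume_um3[sel]), memb)
    out[[ch]] <- data.frame(label = ch, n_cubes = as.integer(sz[, 1]),
                            size_um3 = sz[, 2])
  }
  if (!length(out)) {
    return(data.frame(label = character(0), n_cubes = integer(0),
                      size_um3 = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Spatiotemporal kymograph
#'
#' Aggregates a cube parameter into a (distance bin) x (time or
#' biofilm-volume bin) matrix: per frame, cubes are binned by `axis_param`
#' with width `bin_um`, and each cell holds the foreground-voxel-weighted
#' mean of `param` (weighting prevents sparse edge cubes from dominating).
#' With `x_axis = "biovolume"`, frames are placed into equal-width bins of
#' their total biovolume instead of time.
#'
#' @param tables list of cube tables, one per frame.
#' @param param parameter to aggregate.
#' @param axis_param spatial coordinate for the y bins (e.g.
#'   `"dist_surface_um"`).
#' @param bin_um y bin width, um.
#' @param x_axis `"time"` or `"biovolume"`.
#' @param n_volume_bins number of x bins when `x_axis = "biovolume"`.
#' @return A `kymograph`: list with `x`, `y` (bin centers), `y_edges`,
#'   `values` (matrix, rows = y bins), `weights`, `param`, `axis_param`.
#' @export
kymograph <- function(tables, param, axis_param, bin_um,
                      x_axis = c("time", "biovolume"),
                      n_volume_bins = length(tables)) {
  x_axis <- match.arg(x_axis)
  if (bin_um <= 0) stop("bin_um must be positive", call. = FALSE)
  for (tab in tables) {
    for (col in c(param, axis_param)) {
      if (is.null(tab[[col]])) stop("parameter '", col, "' missing from a frame table",
                                    call. = FALSE)
    }
  }
  av <- unlist(lapply(tables, function(t) t[[axis_param]]))
  av <- av[is.finite(av)]
  if (!length(av)) stop("axis parameter has no finite values", call. = FALSE)
  lo <- floor(min(av) / bin_um) * bin_um
  nbin <- max(1L, ceiling((max(av) - lo) / bin_um + 1e-9))
  y_edges <- lo + (0:nbin) * bin_um
  y_centers <- y_edges[-1] - bin_um / 2

  frame_cells <- lapply(tables, function(tab) {
    v <- tab[[param]]; a <- tab[[axis_param]]; w <- tab$fg_voxels
    ok <- is.finite(v) & is.finite(a)
    b <- pmin(pmax(findInterval(a[ok], y_edges, rightmost.closed = TRUE), 1L), nbin)
    num <- rep(0, nbin); den <- rep(0, nbin)
    if (any(ok)) {
      s <- rowsum(cbind(v[ok] * w[ok], w[ok]), b)
      rows <- as.integer(rownames(s))
      num[rows] <- s[, 1]; den[rows] <- s[, 2]
    }
    list(num = num, den = den)
  })

  if (x_axis == "time") {
    groups <- as.list(seq_along(tables))
    x <- vapply(tables, function(t) as.numeric(t$frame[1]), numeric(1))
  } else {
    vol <- vapply(tables, function(t) sum(t$biovolume_um3), numeric(1))
    rng <- range(vol)
    if (rng[1] == rng[2]) {
      groups <- list(seq_along(tables)); x <- rng[1]
    } else {
      eb <- seq(rng[1], rng[2], length.out = n_volume_bins + 1L)
      gi <- pmin(pmax(findInterval(vol, eb, rightmost.closed = TRUE), 1L),
                 n_volume_bins)
      groups <- split(seq_along(tables), gi)
      x <- (eb[-1] - diff(eb) / 2)[as.integer(names(groups))]
    }
  }
  values <- matrix(NaN, nbin, length(groups))
  weights <- matrix(0, nbin, length(groups))
  for (ci in seq_along(groups)) {
    num <- Reduce(`+`, lapply(frame_cells[groups[[ci]]], `[[`, "num"))
    den <- Reduce(`+`, lapply(frame_cells[groups[[ci]]], `[[`, "den"))
    values[, ci] <- ifelse(den > 0, num / den, NaN)
    weights[, ci] <- den
  }
  structure(list(x = x, y = y_centers, y_edges = y_edges, values = values,
                 weights = weights, param = param, axis_param = axis_param,
                 x_axis = x_axis),
            class = "kymograph")
}

#' Normalize one kymograph by another
#'
#' Cell-wise ratio of two identically binned kymographs (e.g. a reporter
#' normalized to a constitutively expressed channel). Denominator cells
#' that are missing or not positive give `NaN`; weights are the cell-wise
#' minimum of the two weight matrices.
#'
#' @param k_num,k_den [kymograph()]s with identical binning.
#' @return A `kymograph` of ratios.
#' @export
normalize_kymograph <- function(k_num, k_den) {
  stopifnot(inherits(k_num, "kymograph"), inherits(k_den, "kymograph"))
  if (!isTRUE(all.equal(k_num$y_edges, k_den$y_edges)) ||
      !isTRUE(all.equal(k_num$x, k_den$x))) {
    stop("kymographs are binned differently", call. = FALSE)
  }
  vals <- ifelse(is.finite(k_den$values) & k_den$values > 0,
                 k_num$values / k_den$values, NaN)
  out <- k_num
  out$values <- vals
  out$weights <- pmin(k_num$weights, k_den$weights)
  out$param <- paste0(k_num$param, "/", k_den$param)
  out
}

#' Write a kymograph as a CSV matrix
#'
#' Comment lines carry the x values and y bin edges; the matrix body has
#' one row per y bin with the bin center in the first column.
#'
#' @param k a [kymograph()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_kymograph_csv <- function(k, path) {
  stopifnot(inherits(k, "kymograph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# kymograph param=", k$param, " axis=", k$axis_param,
           " x_axis=", k$x_axis),
    paste0("# x: ", paste(format(k$x, digits = 15), collapse = ",")),
    paste0("# y_edges: ", paste(format(k$y_edges, digits = 15), collapse = ","))),
    con)
  body <- cbind(y_center = k$y, as.data.frame(k$values))
  names(body) <- c("y_center", paste0("x", seq_along(k$x)))
  utils::write.table(format(body, digits = 15, trim = TRUE), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
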