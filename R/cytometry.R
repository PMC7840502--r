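# Per-cube cytometry: geometry/distance, intensity, texture, correlation
# and neighborhood parameters, plus custom parameters and gating.
#
# Bookkeeping columns (frame, cube_id, i, j, k, region_voxels, fg_voxels,
# truncated) are not parameters; everything else in the table is. All cube
# statistics are computed over the cube's foreground voxels only —
# parameters describe biomass, not background — except fill_fraction,
# whose denominator is the (possibly truncated) cube region.

BOOKKEEPING_COLS <- c("frame", "cube_id", "i", "j", "k",
                      "region_voxels", "fg_voxels", "truncated")

#' List the per-cube parameter names of a table
#'
#' @param table a cube table.
#' @return Sorted character vector of parameter column names (bookkeeping
#'   columns excluded).
#' @export
cube_parameters <- function(table) {
  sort(setdiff(names(table), BOOKKEEPING_COLS))
}

# fg voxel indices, their table-row group and zyx/physical coordinates
cube_voxel_groups <- function(table, mask) {
  grid <- attr(table, "grid")
  if (is.null(grid)) stop("cube table carries no grid", call. = FALSE)
  if (!identical(dim(mask$mask), grid$dim)) {
    stop("mask shape does not match the table's grid", call. = FALSE)
  }
  d <- grid$dim
  fg <- which(mask$mask)
  ids <- cube_id_array(grid)
  grp <- match(ids[fg], table$cube_id)
  if (anyNA(grp)) stop("mask does not match the table (foreground voxel in an unlisted cube)",
                       call. = FALSE)
  z <- ((fg - 1L) %% d[1]) + 1L
  y <- (((fg - 1L) %/% d[1]) %% d[2]) + 1L
  x <- ((fg - 1L) %/% (d[1] * d[2])) + 1L
  list(fg = fg, grp = grp, z = z, y = y, x = x, grid = grid, n = nrow(table))
}

group_mean <- function(v, grp, n) {
  s <- rep(NaN, n)
  agg <- rowsum(cbind(v, 1), grp)
  s[as.integer(rownames(agg))] <- agg[, 1] / agg[, 2]
  s
}

# per-voxel exposed face area (um^2): foreground voxel faces adjacent to
# background. The image border counts as background on every face except,
# in attached mode, the substratum (z = 1) face. 2D inputs count only
# in-plane faces.
exposed_area_per_voxel <- function(mask, substrate_mode = "attached") {
  m <- mask$mask
  g <- mask$geometry
  d <- dim(m)
  two_d <- d[1] == 1L
  areas <- c(z = g$dx * g$dy, y = g$dx * g$dz, x = g$dy * g$dz)
  out <- array(0, d)
  shift_fg <- function(oz, oy, ox, fill) {
    s <- array(fill, d)
    zr <- seq_range(max(1L, 1L + oz), min(d[1], d[1] + oz))
    yr <- seq_range(max(1L, 1L + oy), min(d[2], d[2] + oy))
    xr <- seq_range(max(1L, 1L + ox), min(d[3], d[3] + ox))
    s[zr, yr, xr] <- m[zr - oz, yr - oy, xr - ox, drop = FALSE]
    s
  }
  dirs <- list(c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  if (!two_d) dirs <- c(dirs, list(c(1, 0, 0), c(-1, 0, 0)))
  for (dd in dirs) {
    ax <- if (dd[1] != 0) "z" else if (dd[2] != 0) "y" else "x"
    # neighbor in direction -dd of the shifted array == neighbor in +dd of m
    fill <- FALSE
    if (dd[1] == -1 && substrate_mode == "attached") fill <- NA # handled below
    nb <- shift_fg(dd[1], dd[2], dd[3], FALSE)
    exposed <- m & !nb
    if (dd[1] == -1 && substrate_mode == "attached") {
      exposed[1, , ] <- FALSE # substratum contact is not exposed surface
    }
    out <- out + exposed * areas[[ax]]
  }
  out
}

#' Geometric and distance parameters per cube
#'
#' Adds the structural parameter family: local density (fill fraction),
#' voxel count, biovolume, centroid, the four spatial distance coordinates
#' (outer surface, substratum, centre of mass, projected centre of mass),
#' local thickness, exposed surface area and local surface-to-volume ratio.
#'
#' @param table a cube table from [assign_voxels()].
#' @param mask the [binary_biovolume()] the table was built from.
#' @param fields [compute_distance_fields()] result for the same mask.
#' @param substrate_mode `"attached"` or `"floating"`; controls whether the
#'   substratum face counts as exposed surface.
#' @return The table with 13 added parameter columns.
#' @export
quantify_geometry <- function(table, mask, fields,
                              substrate_mode = c("attached", "floating")) {
  substrate_mode <- match.arg(substrate_mode)
  cv <- cube_voxel_groups(table, mask)
  g <- mask$geometry
  vox_um3 <- g$dx * g$dy * g$dz

  table$fill_fraction <- table$fg_voxels / table$region_voxels
  table$foreground_voxel_count <- table$fg_voxels
  table$biovolume_um3 <- table$fg_voxels * vox_um3
  table$centroid_x_um <- group_mean((cv$x - 0.5) * g$dx, cv$grp, cv$n)
  table$centroid_y_um <- group_mean((cv$y - 0.5) * g$dy, cv$grp, cv$n)
  table$centroid_z_um <- group_mean((cv$z - 0.5) * g$dz, cv$grp, cv$n)
  table$dist_surface_um <- group_mean(fields$d_surface[cv$fg], cv$grp, cv$n)
  table$dist_substrate_um <- table$centroid_z_um
  com <- fields$com
  table$dist_com_um <- sqrt((table$centroid_x_um - com[["x"]])^2 +
                            (table$centroid_y_um - com[["y"]])^2 +
                            (table$centroid_z_um - com[["z"]])^2)
  table$dist_com_projected_um <- sqrt((table$centroid_x_um - com[["x"]])^2 +
                                      (table$centroid_y_um - com[["y"]])^2)

  # local thickness: mean whole-biofilm column height over the cube's
  # distinct occupied xy-columns
  col_id <- (cv$x - 1L) * dim(mask$mask)[2] + cv$y
  u <- !duplicated(cbind(cv$grp, col_id))
  table$local_thickness_um <- group_mean(fields$column_height[cbind(cv$y[u], cv$x[u])],
                                         cv$grp[u], cv$n)

  area <- exposed_area_per_voxel(mask, substrate_mode)
  sa <- rep(0, cv$n)
  agg <- rowsum(area[cv$fg], cv$grp)
  sa[as.integer(rownames(agg))] <- agg[, 1]
  table$exposed_surface_area_um2 <- sa
  table$local_surface_to_volume_um <- ifelse(table$biovolume_um3 > 0,
                                             sa / table$biovolume_um3, NaN)
  table
}

#' Intensity parameters per cube
#'
#' For each channel, adds the foreground-voxel summary statistics
#' `<ch>_mean`, `_sd` (population), `_cv` (sd/mean, `NaN` when the mean is
#' 0), `_median`, `_min`, `_max`, `_sum`, `_range`.
#'
#' @param table a cube table.
#' @param mask the source [binary_biovolume()].
#' @param stacks named list of [intensity_stack()]s sharing the mask shape.
#' @return The table with 8 added columns per channel.
#' @export
quantify_intensity <- function(table, mask, stacks) {
  cv <- cube_voxel_groups(table, mask)
  for (ch in names(stacks)) {
    st <- stacks[[ch]]
    if (!identical(dim(st$values), dim(mask$mask))) {
      stop("channel '", ch, "' shape does not match the mask", call. = FALSE)
    }
    v <- st$values[cv$fg]
    agg <- rowsum(cbind(v, v^2, 1), cv$grp)
    rows <- as.integer(rownames(agg))
    n <- agg[, 3]
    mu <- agg[, 1] / n
    sdv <- sqrt(pmax(agg[, 2] / n - mu^2, 0))
    put <- function(x) { out <- rep(NaN, cv$n); out[rows] <- x; out }
    table[[paste0(ch, "_mean")]] <- put(mu)
    table[[paste0(ch, "_sd")]] <- put(sdv)
    table[[paste0(ch, "_cv")]] <- put(ifelse(mu != 0, sdv / mu, NaN))
    med <- vapply(split(v, cv$grp), stats::median, numeric(1))
    mn <- vapply(split(v, cv$grp), min, numeric(1))
    mx <- vapply(split(v, cv$grp), max, numeric(1))
    table[[paste0(ch, "_median")]] <- put(med)
    table[[paste0(ch, "_min")]] <- put(mn)
    table[[paste0(ch, "_max")]] <- put(mx)
    table[[paste0(ch, "_sum")]] <- put(agg[, 1])
    table[[paste0(ch, "_range")]] <- put(mx - mn)
  }
  table
}

# GLCM statistics for one cube given quantized levels on a region box
glcm_stats <- function(q, levels) {
  # q: integer array (region box) with NA outside the cube's foreground
  d <- dim(q)
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (ax in 1:3) {
    if (d[ax] < 2L) next
    idx_a <- lapply(d, seq_len)
    idx_b <- idx_a
    idx_a[[ax]] <- seq_len(d[ax] - 1L)
    idx_b[[ax]] <- seq.int(2L, d[ax])
    a <- q[idx_a[[1]], idx_a[[2]], idx_a[[3]], drop = FALSE]
    b <- q[idx_b[[1]], idx_b[[2]], idx_b[[3]], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    pairs_i <- c(pairs_i, a[ok]); pairs_j <- c(pairs_j, b[ok])
  }
  if (!length(pairs_i)) {
    return(c(contrast = NaN, correlation = NaN, energy = NaN,
             homogeneity = NaN, entropy = NaN))
  }
  # symmetric pooled GLCM
  P <- matrix(0, levels, levels)
  tab <- table(factor(pairs_i, levels = 1:levels),
               factor(pairs_j, levels = 1:levels))
  P <- unclass(tab) + t(unclass(tab))
  P <- P / sum(P)
  i <- row(P); j <- col(P)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
  ent <- -sum(ifelse(P > 0, P * log(P), 0))
  c(contrast = sum(P * (i - j)^2),
    correlation = if (sd_i > 0 && sd_j > 0)
      sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j) else NaN,
    energy = sum(P^2),
    homogeneity = sum(P / (1 + abs(i - j))),
    entropy = ent)
}

#' Texture parameters per cube
#'
#' For each channel, computes a gray-level co-occurrence matrix over the
#' cube's foreground voxels — intensities quantized to `levels` equal bins
#' between the cube's min and max, voxel-pair offsets of one voxel along
#' each axis pooled and symmetrized — and adds `<ch>_glcm_contrast`,
#' `_glcm_correlation`, `_glcm_energy`, `_glcm_homogeneity`,
#' `_glcm_entropy` (natural log). Cubes with fewer than 8 foreground
#' voxels get `NaN` in every texture parameter.
#'
#' @inheritParams quantify_intensity
#' @param levels number of gray levels for quantization.
#' @return The table with 5 added columns per channel.
#' @export
quantify_texture <- function(table, mask, stacks, levels = 8L) {
  cv <- cube_voxel_groups(table, mask)
  grid <- cv$grid
  d <- grid$dim
  stat_names <- c("contrast", "correlation", "energy", "homogeneity", "entropy")
  by_cube <- split(seq_along(cv$fg), cv$grp)
  for (ch in names(stacks)) {
    vals <- stacks[[ch]]$values
    out <- matrix(NaN, nrow(table), 5)
    for (gname in names(by_cube)) {
      r <- as.integer(gname)
      vi <- by_cube[[gname]]
      if (length(vi) < 8L) next
      v <- vals[cv$fg[vi]]
      lo <- min(v); hi <- max(v)
      q <- if (hi > lo) pmin(floor((v - lo) / (hi - lo) * levels) + 1L, levels)
           else rep(1L, length(v))
      # place quantized values into the cube's region box
      z0 <- min(cv$z[vi]); y0 <- min(cv$y[vi]); x0 <- min(cv$x[vi])
      box <- array(NA_integer_,
                   c(max(cv$z[vi]) - z0 + 1L, max(cv$y[vi]) - y0 + 1L,
                     max(cv$x[vi]) - x0 + 1L))
      box[cbind(cv$z[vi] - z0 + 1L, cv$y[vi] - y0 + 1L, cv$x[vi] - x0 + 1L)] <- q
      out[r, ] <- glcm_stats(box, levels)
    }
    for (s in seq_along(stat_names)) {
      table[[paste0(ch, "_glcm_", stat_names[s])]] <- out[, s]
    }
  }
  table
}

# neighbor-row matrix: for each table row, the table rows of its 26
# grid neighbors plus (optionally) itself; NA where absent/unoccupied
neighbor_rows <- function(table, include_self = TRUE) {
  grid <- attr(table, "grid")
  nx <- grid$counts[["nx"]]; ny <- grid$counts[["ny"]]; nz <- grid$counts[["nz"]]
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  if (!include_self) offs <- offs[!(offs$di == 0 & offs$dj == 0 & offs$dk == 0), ]
  out <- matrix(NA_integer_, nrow(table), nrow(offs))
  for (r in seq_len(nrow(offs))) {
    ii <- table$i + offs$di[r]; jj <- table$j + offs$dj[r]; kk <- table$k + offs$dk[r]
    ok <- ii >= 0 & ii < nx & jj >= 0 & jj < ny & kk >= 0 & kk < nz
    nid <- ii + nx * jj + nx * ny * kk
    m <- rep(NA_integer_, nrow(table))
    m[ok] <- match(nid[ok], table$cube_id)
    out[, r] <- m
  }
  out
}

rowwise_pearson <- function(X, Y) {
  ok <- !is.na(X) & !is.na(Y) & is.finite(X) & is.finite(Y)
  X0 <- ifelse(ok, X, 0); Y0 <- ifelse(ok, Y, 0)
  n <- rowSums(ok)
  sx <- rowSums(X0); sy <- rowSums(Y0)
  sxx <- rowSums(X0^2); syy <- rowSums(Y0^2); sxy <- rowSums(X0 * Y0)
  num <- n * sxy - sx * sy
  den <- sqrt(pmax(n * sxx - sx^2, 0) * pmax(n * syy - sy^2, 0))
  ifelse(n >= 3 & den > 0, num / den, NaN)
}

#' Channel correlation parameters per cube
#'
#' For every unordered channel pair, adds the per-cube Pearson and Spearman
#' correlations and the Manders overlap coefficient
#' \eqn{\mathrm{MOC} = \sum A_i B_i / \sqrt{\sum A_i^2 \sum B_i^2}}
#' over the cube's foreground voxels. For every channel, adds
#' `<ch>_density_corr`: the Pearson correlation, across the cube's occupied
#' 26-neighborhood (including itself), between the neighbors' mean channel
#' intensity and their fill fraction (`NaN` with fewer than 3 occupied
#' cubes in the neighborhood). Requires `fill_fraction` (run
#' [quantify_geometry()] first).
#'
#' @inheritParams quantify_intensity
#' @return The table with `3 * choose(n_channels, 2) + n_channels` added
#'   columns.
#' @export
quantify_correlations <- function(table, mask, stacks) {
  if (is.null(table$fill_fraction)) {
    stop("fill_fraction missing: run quantify_geometry() first", call. = FALSE)
  }
  cv <- cube_voxel_groups(table, mask)
  chn <- names(stacks)
  volt <- lapply(stacks, function(s) s$values[cv$fg])
  by_cube <- split(seq_along(cv$fg), cv$grp)
  rows <- as.integer(names(by_cube))
  if (length(chn) >= 2L) {
    for (ai in seq_len(length(chn) - 1L)) {
      for (bi in seq.int(ai + 1L, length(chn))) {
        a <- chn[ai]; b <- chn[bi]
        pe <- rep(NaN, nrow(table)); sp <- pe; mo <- pe
        for (gi in seq_along(by_cube)) {
          vi <- by_cube[[gi]]
          va <- volt[[a]][vi]; vb <- volt[[b]][vi]
          pe[rows[gi]] <- safe_pearson(va, vb)
          sp[rows[gi]] <- safe_spearman(va, vb)
          mo[rows[gi]] <- manders_overlap(va, vb)
        }
        table[[paste0(a, b, "_pearson")]] <- pe
        table[[paste0(a, b, "_spearman")]] <- sp
        table[[paste0(a, b, "_moc")]] <- mo
      }
    }
  }
  nb <- neighbor_rows(table, include_self = TRUE)
  fill_nb <- matrix(table$fill_fraction[nb], nrow(table))
  for (ch in chn) {
    mu <- group_mean(volt[[ch]], cv$grp, cv$n)
    table[[paste0(ch, "_density_corr")]] <-
      rowwise_pearson(matrix(mu[nb], nrow(table)), fill_nb)
  }
  table
}

#' Neighborhood-context parameters per cube
#'
#' Adds `occupied_neighbor_count` (0-26), `neighborhood_mean_fill` (mean
#' fill fraction over occupied 26-neighbors, `NaN` if isolated),
#' `fill_gradient_magnitude` (central-difference gradient of fill fraction
#' across the +/-1 cube neighbors per axis, unoccupied in-grid neighbors
#' count as fill 0, one-sided at the grid border; 1/um),
#' `relative_height` (centroid z over local thickness) and
#' `dist_surface_normalized` (distance to surface over max thickness).
#' Requires the geometry parameters (run [quantify_geometry()] first).
#'
#' @param table a cube table with geometry parameters.
#' @param fields the [compute_distance_fields()] result.
#' @return The table with 5 added columns.
#' @export
quantify_neighborhood <- function(table, fields) {
  if (is.null(table$fill_fraction)) {
    stop("fill_fraction missing: run quantify_geometry() first", call. = FALSE)
  }
  grid <- attr(table, "grid")
  nb <- neighbor_rows(table, include_self = FALSE)
  fill_nb <- matrix(table$fill_fraction[nb], nrow(table))
  occ <- rowSums(!is.na(fill_nb))
  table$occupied_neighbor_count <- occ
  table$neighborhood_mean_fill <- ifelse(occ > 0, rowMeans(fill_nb, na.rm = TRUE), NaN)

  g <- grid$geometry
  h <- c(x = grid$span[["sx"]] * g$dx,
         y = grid$span[["sy"]] * g$dy,
         z = grid$span[["sz"]] * g$dz)
  nxyz <- c(x = grid$counts[["nx"]], y = grid$counts[["ny"]], z = grid$counts[["nz"]])
  ijk <- list(x = table$i, y = table$j, z = table$k)
  grad2 <- 0
  for (ax in c("x", "y", "z")) {
    gaxis <- axis_fill_gradient(table, grid, ax, h[[ax]], nxyz[[ax]], ijk[[ax]])
    grad2 <- grad2 + gaxis^2
  }
  table$fill_gradient_magnitude <- sqrt(grad2)

  table$relative_height <- ifelse(table$local_thickness_um > 0,
                                  table$centroid_z_um / table$local_thickness_um, NaN)
  table$dist_surface_normalized <- if (fields$max_thickness > 0)
    table$dist_surface_um / fields$max_thickness else NaN
  table
}

# fill fraction of the +/-1 neighbor along one axis (0 when the in-grid
# neighbor is unoccupied), central difference where both sides exist
axis_fill_gradient <- function(table, grid, ax, h, n_ax, idx_ax) {
  nx <- grid$counts[["nx"]]; ny <- grid$counts[["ny"]]
  step <- switch(ax, x = 1L, y = nx, z = nx * ny)
  fill_at <- function(ids, inside) {
    f <- numeric(length(ids))
    f[inside] <- 0
    m <- match(ids[inside], table$cube_id)
    f[inside][!is.na(m)] <- table$fill_fraction[m[!is.na(m)]]
    f[!inside] <- NA_real_
    f
  }
  up_in <- idx_ax + 1L < n_ax
  dn_in <- idx_ax - 1L >= 0L
  f_up <- fill_at(table$cube_id + step, up_in)
  f_dn <- fill_at(table$cube_id - step, dn_in)
  f0 <- table$fill_fraction
  ifelse(up_in & dn_in, (f_up - f_dn) / (2 * h),
         ifelse(up_in, (f_up - f0) / h,
                ifelse(dn_in, (f0 - f_dn) / h, 0)))
}

#' Run the full per-cube parameter set
#'
#' Convenience wrapper running [quantify_geometry()],
#' [quantify_intensity()], [quantify_texture()],
#' [quantify_correlations()] and [quantify_neighborhood()] in order. With
#' two channels this yields the full 49-parameter cube cytometry set.
#'
#' @inheritParams quantify_intensity
#' @param fields optional precomputed [compute_distance_fields()]; computed
#'   here when `NULL`.
#' @param substrate_mode `"attached"` or `"floating"`.
#' @param texture_levels gray levels for the texture family.
#' @return The fully parameterized cube table.
#' @export
quantify_cubes <- function(table, mask, stacks, fields = NULL,
                           substrate_mode = c("attached", "floating"),
                           texture_levels = 8L) {
  substrate_mode <- match.arg(substrate_mode)
  if (is.null(fields)) fields <- compute_distance_fields(mask, substrate_mode)
  table <- quantify_geometry(table, mask, fields, substrate_mode)
  table <- quantify_intensity(table, mask, stacks)
  table <- quantify_texture(table, mask, stacks, texture_levels)
  table <- quantify_correlations(table, mask, stacks)
  quantify_neighborhood(table, fields)
}

#' Add a custom derived parameter
#'
#' Evaluates an arithmetic expression over existing parameter names, per
#' record, and appends it as a new column. Allowed: `+ - * / ^`, unary
#' minus, parentheses, numeric literals and the functions `log`, `log10`,
#' `exp`, `sqrt`, `abs`. Division by zero and logarithms or roots of
#' out-of-domain values yield `NaN` for that record.
#'
#' @param table a cube table.
#' @param name new parameter name (must be unused).
#' @param expr expression text, e.g. `"ch1_mean / ch2_mean"`.
#' @return The table with the new column.
#' @export
add_custom_parameter <- function(table, name, expr) {
  if (name %in% names(table)) {
    stop("parameter '", name, "' already exists", call. = FALSE)
  }
  parsed <- tryCatch(parse(text = expr, keep.source = FALSE)[[1]],
                     error = function(e) {
                       stop("parse error in expression '", expr, "': ",
                            conditionMessage(e), call. = FALSE)
                     })
  allowed_funs <- c("+", "-", "*", "/", "^", "(", "log", "log10", "exp",
                    "sqrt", "abs")
  param_names <- setdiff(names(table), c("frame", "cube_id", "truncated"))
  check_node <- function(node) {
    if (is.call(node)) {
      fn <- as.character(node[[1]])
      if (!fn %in% allowed_funs) {
        stop("function '", fn, "' is not allowed in custom parameters",
             call. = FALSE)
      }
      for (k in seq_along(node)[-1]) check_node(node[[k]])
    } else if (is.name(node)) {
      nm <- as.character(node)
      if (!nm %in% param_names) {
        near <- agrep(nm, param_names, max.distance = 0.3, value = TRUE)
        stop("unknown parameter '", nm, "'",
             if (length(near)) paste0("; did you mean: ",
                                      paste(utils::head(near, 3), collapse = ", "))
             else "", call. = FALSE)
      }
    } else if (!is.numeric(node)) {
      stop("literal of type ", typeof(node), " is not allowed", call. = FALSE)
    }
  }
  check_node(parsed)
  env <- list2env(as.list(table[param_names]), parent = baseenv())
  assign("/", function(a, b) ifelse(b == 0, NaN, base::"/"(a, b)), envir = env)
  assign("log", function(x) ifelse(x > 0, base::log(x), NaN), envir = env)
  assign("log10", function(x) ifelse(x > 0, base::log10(x), NaN), envir = env)
  assign("sqrt", function(x) ifelse(x >= 0, base::sqrt(x), NaN), envir = env)
  table[[name]] <- as.numeric(eval(parsed, env))
  table
}

#' Gate cube subpopulations
#'
#' Selects the records satisfying every range predicate, by analogy with
#' flow-cytometry gating. Records with `NaN`/`NA` in any gated parameter
#' are excluded from both the gate and its complement.
#'
#' @param table a cube table.
#' @param predicates list of predicates, each a list with `parameter`,
#'   `lower`, `upper` and optional `include_lower`/`include_upper`
#'   (default `TRUE`).
#' @param complement return the records failing the gate instead.
#' @return The gated cube table (grid attribute preserved).
#' @export
gate <- function(table, predicates, complement = FALSE) {
  if (!length(predicates)) return(table)
  keep <- rep(TRUE, nrow(table))
  defined <- rep(TRUE, nrow(table))
  for (p in predicates) {
    if (is.null(p$parameter) || !p$parameter %in% names(table)) {
      stop("gate parameter '", p$parameter, "' not found", call. = FALSE)
    }
    lo <- if (is.null(p$lower)) -Inf else p$lower
    hi <- if (is.null(p$upper)) Inf else p$upper
    if (lo > hi) stop("gate on '", p$parameter, "': lower bound exceeds upper bound",
                      call. = FALSE)
    il <- if (is.null(p$include_lower)) TRUE else isTRUE(p$include_lower)
    iu <- if (is.null(p$include_upper)) TRUE else isTRUE(p$include_upper)
    v <- table[[p$parameter]]
    defined <- defined & is.finite(v)
    ok <- (if (il) v >= lo else v > lo) & (if (iu) v <= hi else v < hi)
    keep <- keep & !is.na(ok) & ok
  }
  sel <- if (complement) defined & !keep else defined & keep
  out <- table[sel, , drop = FALSE]
  if (nrow(out) == 0L) warning("gate selected no records", call. = FALSE)
  as_cube_table(out, attr(table, "grid"))
}
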