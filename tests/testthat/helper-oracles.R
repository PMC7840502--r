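# Shared fixtures and independent brute-force oracles. All fixtures are
# generated in code under fixed seeds; oracles deliberately avoid the code
# paths they check.

iso_geom <- function(p = 1) voxel_geometry(p, p, p)

# stack two (z, y, x) arrays along z (channel pages of one TIFF)
abind_zyx <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  nz <- sum(vapply(parts, function(p) dim(p)[1], numeric(1)))
  out <- array(0, c(nz, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

random_mask <- function(dim_zyx, p = 0.5, geometry = iso_geom()) {
  binary_biovolume(array(stats::runif(prod(dim_zyx)) < p, dim_zyx), geometry)
}

# O(n^2) nearest-background distance for every foreground voxel, including
# the out-of-volume background half-spaces (and the substratum face rule)
brute_surface_distance <- function(mask, substrate_mode) {
  m <- mask$mask
  g <- mask$geometry
  d <- dim(m)
  bg <- which(!m, arr.ind = TRUE)
  fg <- which(m, arr.ind = TRUE)
  pitch <- c(g$dz, g$dy, g$dx)
  res <- numeric(nrow(fg))
  for (i in seq_len(nrow(fg))) {
    p <- fg[i, ]
    best <- Inf
    if (nrow(bg)) {
      best <- min(sqrt(colSums(((t(bg) - p) * pitch)^2)))
    }
    # perpendicular distances to the surrounding background half-spaces
    cand <- c(p[1] * pitch[1], (d[1] - p[1] + 1) * pitch[1],
              p[2] * pitch[2], (d[2] - p[2] + 1) * pitch[2],
              p[3] * pitch[3], (d[3] - p[3] + 1) * pitch[3])
    if (substrate_mode == "attached") cand <- cand[-1]
    min(best, cand)
    res[i] <- min(best, cand)
  }
  res
}

# exhaustive Otsu scan over interior histogram edges with binned moments
brute_otsu <- function(h) {
  nb <- length(h$counts)
  n <- sum(h$counts)
  best <- -Inf
  level <- NA_real_
  for (k in seq_len(nb - 1L)) {
    c0 <- h$counts[1:k]
    c1 <- h$counts[(k + 1L):nb]
    w0 <- sum(c0) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(c0 * h$mids[1:k]) / sum(c0)
    m1 <- sum(c1 * h$mids[(k + 1L):nb]) / sum(c1)
    sb <- w0 * w1 * (m0 - m1)^2
    if (sb > best + 1e-15) {
      best <- sb
      level <- h$edges[k + 1L]
    }
  }
  level
}

# exhaustive maximum-correlation scan over interior histogram edges
brute_mct <- function(v, bins = 256L) {
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  cand <- edges[2:bins]
  r <- vapply(cand, function(t) {
    b <- as.numeric(v > t)
    if (stats::sd(b) == 0) return(-Inf)
    stats::cor(v, b)
  }, numeric(1))
  cand[which.max(r)]
}

# direct-sum spatial correlation oracle (triple loop over lags)
brute_correlation <- function(mask_a, mask_b, dr, rmax) {
  A <- mask_a$mask * 1
  B <- mask_b$mask * 1
  g <- mask_a$geometry
  da <- A - mean(A)
  db <- B - mean(B)
  d <- dim(A)
  pitch <- c(g$dz, g$dy, g$dx)
  lmax <- pmin(d - 1L, floor(rmax / pitch))
  rows <- list()
  for (lz in -lmax[1]:lmax[1]) for (ly in -lmax[2]:lmax[2]) for (lx in -lmax[3]:lmax[3]) {
    r <- sqrt((lz * pitch[1])^2 + (ly * pitch[2])^2 + (lx * pitch[3])^2)
    if (r > rmax) next
    z1 <- max(1, 1 - lz):min(d[1], d[1] - lz)
    y1 <- max(1, 1 - ly):min(d[2], d[2] - ly)
    x1 <- max(1, 1 - lx):min(d[3], d[3] - lx)
    s <- sum(da[z1, y1, x1] * db[z1 + lz, y1 + ly, x1 + lx])
    rows[[length(rows) + 1L]] <- c(r = r, cov = s / (length(z1) * length(y1) * length(x1)))
  }
  m <- do.call(rbind, rows)
  val <- m[, "cov"] / sqrt(mean(da^2) * mean(db^2))
  bin <- ifelse(m[, "r"] == 0, 0, ceiling(m[, "r"] / dr))
  v <- tapply(val, bin, mean)
  data.frame(bin = as.numeric(names(v)), value = as.numeric(v))
}

# minimal independent reader for legacy VTK STRUCTURED_POINTS cell data
parse_vtk_cell_data <- function(path) {
  lines <- readLines(path)
  ncell_line <- grep("^CELL_DATA", lines, value = TRUE)
  ncell <- as.integer(sub("CELL_DATA ", "", ncell_line))
  dims <- as.integer(strsplit(sub("DIMENSIONS ", "", grep("^DIMENSIONS", lines,
                                                          value = TRUE)), " ")[[1]])
  out <- list()
  for (s in grep("^SCALARS", lines)) {
    nm <- strsplit(lines[s], " ")[[1]][2]
    out[[nm]] <- as.numeric(lines[(s + 2L):(s + 1L + ncell)])
  }
  list(ncell = ncell, dims = dims, arrays = out)
}

# standard two-channel synthetic colony used by several suites
demo_colony <- function(radius = 3, dim_zyx = c(16, 32, 32), pitch = 0.25,
                        seed = 3) {
  g <- voxel_geometry(pitch, pitch, pitch)
  mask <- make_colony(synth_spec("hemisphere", list(radius = radius),
                                 dim_zyx, g, seed = seed))
  chs <- mix_strains(mask, c(0.5, 0.5), cluster_edge_um = 4 * pitch,
                     seed = seed + 1)
  list(mask = mask, channels = chs, geometry = g)
}
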