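#' Segmentation configuration
#'
#' Bundles the choices that turn an intensity stack into a binary biovolume:
#' an optional smoothing filter, one of four automatic threshold algorithms
#' (or a manual level), a minimum object size (despeckling) and optional
#' per-slice hole filling.
#'
#' @param method one of `"otsu"`, `"ridler_calvard"`, `"robust_background"`,
#'   `"mct"` (maximum correlation thresholding) or `"manual"`.
#' @param manual_level intensity level, required iff `method = "manual"`.
#'   Foreground is strictly greater than the level.
#' @param filter filter spec: `list(type = "none")`,
#'   `list(type = "median", radius_um = r)` or
#'   `list(type = "gaussian", sigma_um = s)`.
#' @param min_object_voxels connected components (26-connectivity; 8 in 2D)
#'   smaller than this many voxels are removed after thresholding.
#' @param fill_holes fill background holes per z slice (2D fill, so real
#'   vertical channels are not sealed).
#' @param histogram_bins bins for the otsu/mct candidate-level scan.
#' @param trim_fraction,k_sd robust-background parameters: the dimmest and
#'   brightest `trim_fraction` of voxels are discarded and the level is
#'   `mean + k_sd * sd` of the remainder.
#' @param rc_tol convergence tolerance (intensity units) for the
#'   Ridler-Calvard iteration.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(method = c("otsu", "ridler_calvard",
                                           "robust_background", "mct", "manual"),
                                manual_level = NULL,
                                filter = list(type = "none"),
                                min_object_voxels = 0L,
                                fill_holes = FALSE,
                                histogram_bins = 256L,
                                trim_fraction = 0.05,
                                k_sd = 2,
                                rc_tol = 1e-6) {
  method <- match.arg(method)
  if (method == "manual" && is.null(manual_level)) {
    stop("method = 'manual' requires manual_level", call. = FALSE)
  }
  if (!is.list(filter) || is.null(filter$type) ||
      !filter$type %in% c("none", "median", "gaussian")) {
    stop("filter$type must be one of 'none', 'median', 'gaussian'", call. = FALSE)
  }
  if (identical(filter$type, "median") &&
      (is.null(filter$radius_um) || filter$radius_um < 0)) {
    stop("median filter requires radius_um >= 0", call. = FALSE)
  }
  if (identical(filter$type, "gaussian") &&
      (is.null(filter$sigma_um) || filter$sigma_um < 0)) {
    stop("gaussian filter requires sigma_um >= 0", call. = FALSE)
  }
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    stop("trim_fraction must be in [0, 0.5)", call. = FALSE)
  }
  if (k_sd <= 0) stop("k_sd must be positive", call. = FALSE)
  if (min_object_voxels < 0) stop("min_object_voxels must be >= 0", call. = FALSE)
  structure(list(method = method, manual_level = manual_level, filter = filter,
                 min_object_voxels = as.integer(min_object_voxels),
                 fill_holes = isTRUE(fill_holes),
                 histogram_bins = as.integer(histogram_bins),
                 trim_fraction = trim_fraction, k_sd = k_sd, rc_tol = rc_tol),
            class = "segmentation_config")
}

#' Intensity histogram
#'
#' Equal-width histogram spanning the observed intensity range; the interior
#' bin edges are the candidate threshold levels for the otsu and mct scans.
#'
#' @param values numeric vector or array of intensities.
#' @param bins number of equal-width bins.
#' @return List with `edges` (length `bins + 1`), `counts`, `mids`.
#' @export
intensity_histogram <- function(values, bins = 256L) {
  v <- as.numeric(values)
  if (!all(is.finite(v))) stop("intensities must be finite", call. = FALSE)
  rng <- range(v)
  if (rng[1] == rng[2]) {
    # a single degenerate bin; thresholders reject this explicitly
    return(list(edges = c(rng[1], rng[1]), counts = length(v), mids = rng[1]))
  }
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  counts <- tabulate(bin_index(v, rng, bins), nbins = bins)
  list(edges = edges, counts = counts, mids = (edges[-1] + edges[-(bins + 1L)]) / 2)
}

bin_index <- function(v, rng, bins) {
  k <- floor((v - rng[1]) / (rng[2] - rng[1]) * bins) + 1L
  pmin(as.integer(k), bins)
}

#' Otsu threshold
#'
#' Scans every interior bin edge of the histogram and returns the level
#' maximizing the between-class variance
#' \eqn{\sigma_b^2(t) = \omega_0 \omega_1 (\mu_0 - \mu_1)^2}, where class 0
#' holds intensities at or below the level and class 1 above it (class
#' moments from bin midpoints). Ties are broken by the lowest level.
#'
#' @param hist an [intensity_histogram()].
#' @return Threshold level (intensity units); foreground is `intensity > level`.
#' @export
threshold_otsu <- function(hist) {
  nb <- length(hist$counts)
  if (sum(hist$counts > 0) < 2L) {
    stop("degenerate input: fewer than two distinct intensity levels; ",
         "use a manual threshold", call. = FALSE)
  }
  n <- sum(hist$counts)
  w <- hist$counts / n
  cw <- cumsum(w)                        # omega0 at each interior edge
  cm <- cumsum(w * hist$mids)            # partial first moment
  mu <- cm[nb]
  k <- seq_len(nb - 1L)                  # candidate = edge after bin k
  w0 <- cw[k]; w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- cm[k] / w0
  mu1 <- (mu - cm[k]) / w1
  sb2 <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  hist$edges[which.max(sb2) + 1L]
}

#' Ridler-Calvard (iterative intermeans) threshold
#'
#' Starting from the global mean, iterates
#' \eqn{T_{k+1} = (\mathrm{mean}(v \le T_k) + \mathrm{mean}(v > T_k)) / 2}
#' until the update is smaller than `tol` (hard cap 1000 iterations).
#'
#' @param values numeric vector/array with at least two distinct values.
#' @param tol convergence tolerance in intensity units.
#' @return The fixed-point threshold level.
#' @export
threshold_ridler_calvard <- function(values, tol = 1e-6) {
  v <- as.numeric(values)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  if (length(unique(v)) < 2L) {
    stop("degenerate input: constant image; use a manual threshold", call. = FALSE)
  }
  t_cur <- mean(v)
  for (it in seq_len(1000L)) {
    lo <- v[v <= t_cur]; hi <- v[v > t_cur]
    if (!length(lo) || !length(hi)) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_cur) < tol) return(t_new)
    t_cur <- t_new
  }
  t_cur
}

#' Robust-background threshold
#'
#' Discards the dimmest and brightest `trim_fraction` of voxels and places
#' the level at `mean + k_sd * sd` of the remainder, so that a dominant
#' background distribution sets the level robustly to bright outliers.
#'
#' @param values numeric vector/array.
#' @param trim_fraction fraction trimmed from each tail, in `[0, 0.5)`.
#' @param k_sd number of standard deviations above the trimmed mean.
#' @return Threshold level.
#' @export
threshold_robust_background <- function(values, trim_fraction = 0.05, k_sd = 2) {
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    stop("trim_fraction must be in [0, 0.5)", call. = FALSE)
  }
  if (k_sd <= 0) stop("k_sd must be positive", call. = FALSE)
  v <- sort(as.numeric(values))
  drop <- floor(length(v) * trim_fraction)
  keep <- v[seq.int(drop + 1L, length(v) - drop)]
  if (!length(keep)) stop("degenerate input: trimming removed all voxels", call. = FALSE)
  s <- if (length(keep) > 1L) stats::sd(keep) else 0
  mean(keep) + k_sd * s
}

#' Maximum correlation threshold
#'
#' Returns the level maximizing the Pearson correlation between the voxel
#' intensities and their binarization (`intensity > level`), scanned
#' exhaustively over the interior edges of an equal-width histogram. Ties
#' are broken by the lowest level.
#'
#' @param values numeric vector/array with at least two distinct values.
#' @param bins number of candidate-level bins.
#' @return Threshold level.
#' @export
threshold_mct <- function(values, bins = 256L) {
  v <- as.numeric(values)
  if (length(unique(v)) < 2L) {
    stop("degenerate input: constant image; use a manual threshold", call. = FALSE)
  }
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  cand <- edges[2:bins]
  sv <- sort(v)
  n <- length(sv)
  csum <- cumsum(sv)
  mean_v <- csum[n] / n
  var_v <- mean(sv^2) - mean_v^2
  # for each candidate t: n1 = #{v > t}, s1 = sum of those values
  n_le <- findInterval(cand, sv) # counts v <= t
  n1 <- n - n_le
  s1 <- csum[n] - ifelse(n_le > 0, csum[pmax(n_le, 1L)], 0)
  p <- n1 / n
  cov <- s1 / n - mean_v * p
  denom <- sqrt(var_v * p * (1 - p))
  r <- ifelse(denom > 0, cov / denom, -Inf)
  cand[which.max(r)]
}

#' Pre-threshold filtering
#'
#' Applies the configured smoothing filter to an intensity stack. The median
#' filter uses an anisotropy-aware ellipsoidal footprint (the physical
#' radius is converted to voxel offsets per axis); the Gaussian filter is a
#' separable zero-padded convolution with per-axis sigma in voxels.
#'
#' @param stack an [intensity_stack()].
#' @param filter filter spec as in [segmentation_config()].
#' @return A filtered [intensity_stack()].
#' @export
preprocess <- function(stack, filter = list(type = "none")) {
  stopifnot(inherits(stack, "intensity_stack"))
  type <- if (is.null(filter$type)) "none" else filter$type
  out <- switch(type,
    none = stack$values,
    median = {
      r <- filter$radius_um
      if (is.null(r) || r < 0) stop("median filter requires radius_um >= 0", call. = FALSE)
      median_filter_3d(stack$values, stack$geometry, r)
    },
    gaussian = {
      s <- filter$sigma_um
      if (is.null(s) || s < 0) stop("gaussian filter requires sigma_um >= 0", call. = FALSE)
      gaussian_filter_3d(stack$values, stack$geometry, s)
    },
    stop("unknown filter type: ", type, call. = FALSE))
  intensity_stack(out, stack$geometry, stack$channel, stack$frame)
}

median_filter_3d <- function(a, g, radius_um) {
  if (radius_um == 0) return(a)
  d <- dim(a)
  pitches <- c(g$dz, g$dy, g$dx)
  hw <- pmax(floor(radius_um / pitches), 0)
  off <- expand.grid(oz = -hw[1]:hw[1], oy = -hw[2]:hw[2], ox = -hw[3]:hw[3])
  phys <- sqrt((off$oz * g$dz)^2 + (off$oy * g$dy)^2 + (off$ox * g$dx)^2)
  off <- off[phys <= radius_um + 1e-12, ]
  zi <- slice.index(a, 1); yi <- slice.index(a, 2); xi <- slice.index(a, 3)
  vals <- matrix(0, length(a), nrow(off))
  for (r in seq_len(nrow(off))) {
    z <- pmin(pmax(zi + off$oz[r], 1L), d[1])
    y <- pmin(pmax(yi + off$oy[r], 1L), d[2])
    x <- pmin(pmax(xi + off$ox[r], 1L), d[3])
    vals[, r] <- a[cbind(as.vector(z), as.vector(y), as.vector(x))]
  }
  array(apply(vals, 1, stats::median), d)
}

gaussian_filter_3d <- function(a, g, sigma_um) {
  if (sigma_um == 0) return(a)
  pitches <- c(g$dz, g$dy, g$dx)
  for (ax in 1:3) {
    sig <- sigma_um / pitches[ax]
    if (dim(a)[ax] == 1L || sig == 0) next
    h <- max(1L, ceiling(3 * sig))
    k <- exp(-(seq(-h, h))^2 / (2 * sig^2))
    k <- k / sum(k)
    a <- conv_axis(a, k, ax)
  }
  a
}

# zero-padded separable convolution along one axis via a banded matrix
conv_axis <- function(a, kernel, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  n <- d[axis]
  h <- (length(kernel) - 1L) / 2L
  idx <- outer(seq_len(n), seq_len(n), function(i, j) i - j + h + 1L)
  K <- matrix(0, n, n)
  inb <- idx >= 1L & idx <= length(kernel)
  K[inb] <- kernel[idx[inb]]
  m <- K %*% matrix(ap, nrow = n)
  aperm(array(m, dim(ap)), order(perm))
}

#' Segment an intensity stack into a binary biovolume
#'
#' Runs the configured pipeline: filter, threshold (foreground strictly
#' above the level), remove small objects, optionally fill per-slice holes.
#' The chosen threshold level is recorded in the result's `provenance`
#' attribute.
#'
#' @param stack an [intensity_stack()].
#' @param cfg a [segmentation_config()].
#' @return A [binary_biovolume()]; `attr(, "provenance")` holds the method
#'   and the chosen level.
#' @export
segment <- function(stack, cfg) {
  stopifnot(inherits(stack, "intensity_stack"), inherits(cfg, "segmentation_config"))
  filtered <- preprocess(stack, cfg$filter)
  v <- filtered$values
  level <- switch(cfg$method,
    otsu = threshold_otsu(intensity_histogram(v, cfg$histogram_bins)),
    ridler_calvard = threshold_ridler_calvard(v, cfg$rc_tol),
    robust_background = threshold_robust_background(v, cfg$trim_fraction, cfg$k_sd),
    mct = threshold_mct(v, cfg$histogram_bins),
    manual = cfg$manual_level)
  m <- v > level
  if (!any(m)) {
    warning("segmentation produced an empty mask (level ", format(level),
            " at or above the maximum intensity)", call. = FALSE)
  }
  if (cfg$min_object_voxels > 0L) m <- remove_small_components(m, cfg$min_object_voxels)
  if (cfg$fill_holes) m <- fill_holes_slices(m)
  out <- binary_biovolume(m, stack$geometry)
  attr(out, "provenance") <- list(method = cfg$method, level = level,
                                  channel = stack$channel, frame = stack$frame)
  out
}
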