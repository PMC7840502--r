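# Whole-biofilm (global) parameters: COMSTAT-compatible structure metrics,
# channel colocalization, 3D spatial correlation functions and global
# summaries of the cube parameters.

new_global_metrics <- function(metric, value, units, provenance = NULL) {
  df <- data.frame(metric = metric, value = as.numeric(value),
                   units = units, stringsAsFactors = FALSE)
  attr(df, "provenance") <- provenance
  class(df) <- c("global_metrics", "data.frame")
  df
}

#' Look up a global metric value by name
#' @param metrics a `global_metrics` data.frame.
#' @param name metric name.
#' @return The scalar value.
#' @export
metric_value <- function(metrics, name) {
  i <- match(name, metrics$metric)
  if (is.na(i)) stop("unknown metric '", name, "'", call. = FALSE)
  metrics$value[i]
}

#' Global biofilm structure metrics
#'
#' COMSTAT-compatible whole-biofilm parameters computed from the binary
#' biovolume: biovolume, maximum thickness, the two mean-thickness variants
#' (averaged over all columns of the field, and over biomass-occupied
#' columns only), substratum coverage, exposed surface area (voxel-face
#' counting; the substratum face is excluded in attached mode), the
#' roughness coefficient
#' \eqn{R_a^* = \frac{1}{N} \sum_i |L_i - \bar L| / \bar L} over occupied
#' column thicknesses \eqn{L_i}, and the surface-to-biovolume ratio.
#' Column thickness is `(1 + highest foreground z index) * dz`, ignoring
#' interior gaps (the COMSTAT thickness-map convention).
#'
#' @param mask a nonempty [binary_biovolume()].
#' @param substrate_mode `"attached"` (default) or `"floating"`.
#' @return A `global_metrics` data.frame (metric, value, units).
#' @export
global_structure <- function(mask, substrate_mode = c("attached", "floating")) {
  substrate_mode <- match.arg(substrate_mode)
  stopifnot(inherits(mask, "binary_biovolume"))
  m <- mask$mask
  if (!any(m)) stop("mask has no foreground voxels", call. = FALSE)
  g <- mask$geometry
  ch <- column_heights(m, g)
  occ <- ch[ch > 0]
  lbar <- mean(occ)
  area <- sum(exposed_area_per_voxel(mask, substrate_mode))
  biovol <- sum(m) * g$dx * g$dy * g$dz
  new_global_metrics(
    metric = c("biovolume_um3", "max_thickness_um", "mean_thickness_all_um",
               "mean_thickness_biomass_um", "substratum_coverage",
               "exposed_surface_area_um2", "roughness_coefficient",
               "surface_to_biovolume_um_inv"),
    value = c(biovol, max(ch), mean(ch), lbar, mean(m[1, , ]),
              area, mean(abs(occ - lbar)) / lbar, area / biovol),
    units = c("um^3", "um", "um", "um", "", "um^2", "", "1/um"),
    provenance = list(substrate_mode = substrate_mode, dim = dim(m)))
}

#' Voxel-level colocalization of two channels
#'
#' Over the mask's foreground voxels, computes Pearson's correlation
#' coefficient, the Manders overlap coefficient
#' \eqn{\sum A_i B_i / \sqrt{\sum A_i^2 \sum B_i^2}}, the Manders split
#' coefficients (`manders_m1` = fraction of channel-A intensity located
#' where B is above its level, and symmetrically `manders_m2`), and — from
#' per-channel binarizations at `level_a`/`level_b` — the volume overlap
#' fractions and relative biovolume abundances of the two channels.
#'
#' @param stack_a,stack_b [intensity_stack()]s of the two channels.
#' @param mask the [binary_biovolume()] defining the analysis region.
#' @param level_a,level_b per-channel binarization levels; when `NULL`,
#'   an Otsu threshold over the mask voxels of that channel is used.
#' @return A `global_metrics` data.frame.
#' @export
colocalization <- function(stack_a, stack_b, mask,
                           level_a = NULL, level_b = NULL) {
  stopifnot(inherits(stack_a, "intensity_stack"),
            inherits(stack_b, "intensity_stack"),
            inherits(mask, "binary_biovolume"))
  if (!identical(dim(stack_a$values), dim(stack_b$values)) ||
      !identical(dim(stack_a$values), dim(mask$mask))) {
    stop("channel stacks and mask must share one shape", call. = FALSE)
  }
  if (!any(mask$mask)) stop("mask has no foreground voxels", call. = FALSE)
  a <- stack_a$values[mask$mask]
  b <- stack_b$values[mask$mask]
  auto_level <- function(v, chname) {
    tryCatch(threshold_otsu(intensity_histogram(v)),
             error = function(e) {
               warning("channel '", chname, "' is constant within the mask; ",
                       "binarization level set to its value", call. = FALSE)
               v[1]
             })
  }
  if (is.null(level_a)) level_a <- auto_level(a, stack_a$channel)
  if (is.null(level_b)) level_b <- auto_level(b, stack_b$channel)

  if (sum(a) == 0 || sum(b) == 0) {
    warning("zero-intensity channel: Manders coefficients are NaN", call. = FALSE)
  }
  moc <- manders_overlap(a, b)
  m1 <- if (sum(a) > 0) sum(a[b > level_b]) / sum(a) else NaN
  m2 <- if (sum(b) > 0) sum(b[a > level_a]) / sum(b) else NaN
  bin_a <- a > level_a
  bin_b <- b > level_b
  na <- sum(bin_a); nb <- sum(bin_b); nab <- sum(bin_a & bin_b)
  new_global_metrics(
    metric = c("pearson", "moc", "manders_m1", "manders_m2",
               "overlap_fraction_A", "overlap_fraction_B",
               "relative_abundance_A", "relative_abundance_B"),
    value = c(safe_pearson(a, b), moc, m1, m2,
              if (na > 0) nab / na else NaN,
              if (nb > 0) nab / nb else NaN,
              if (na + nb > 0) na / (na + nb) else NaN,
              if (na + nb > 0) nb / (na + nb) else NaN),
    units = rep("", 8),
    provenance = list(level_a = level_a, level_b = level_b,
                      channels = c(stack_a$channel, stack_b$channel)))
}

#' 3D spatial correlation function of one or two masks
#'
#' Computes the normalized spatial cross-covariance of two indicator
#' fields (or the autocorrelation of one): the fields are centered over
#' the analysis window, the cross-covariance is evaluated for every
#' integer voxel lag within `rmax_um` by zero-padded frequency-domain
#' convolution, divided per lag by the number of valid in-window voxel
#' pairs (no periodic wraparound), normalized by the zero-lag standard
#' deviations, and shell-averaged into bins of width `dr_um` using
#' physical (anisotropy-aware) lag lengths. The zero lag is reported as
#' its own bin, so an autocorrelation profile starts at exactly 1.
#'
#' @param mask_a a [binary_biovolume()].
#' @param mask_b optional second [binary_biovolume()] of the same shape;
#'   `NULL` gives the autocorrelation of `mask_a`.
#' @param dr_um radial bin width, um.
#' @param rmax_um maximum lag length, um; truncated with a warning when it
#'   exceeds the window.
#' @return A `correlation_profile`: data.frame with columns `r` (bin
#'   center, um), `value`, `pairs`.
#' @export
spatial_correlation <- function(mask_a, mask_b = NULL, dr_um, rmax_um) {
  stopifnot(inherits(mask_a, "binary_biovolume"))
  if (dr_um <= 0) stop("dr_um must be positive", call. = FALSE)
  if (rmax_um < dr_um) stop("rmax_um must be at least dr_um", call. = FALSE)
  auto <- is.null(mask_b)
  if (auto) mask_b <- mask_a
  if (!identical(dim(mask_a$mask), dim(mask_b$mask))) {
    stop("masks must share one shape", call. = FALSE)
  }
  g <- mask_a$geometry
  d <- dim(mask_a$mask)
  pitch <- c(g$dz, g$dy, g$dx)
  lmax <- pmin(d - 1L, floor(rmax_um / pitch))
  span_um <- sqrt(sum(((d - 1L) * pitch)^2))
  if (rmax_um > span_um) {
    warning("rmax_um exceeds the window extent; profile truncated at ",
            format(span_um), " um", call. = FALSE)
  }
  da <- as.numeric(mask_a$mask) - mean(mask_a$mask)
  db <- as.numeric(mask_b$mask) - mean(mask_b$mask)
  M <- vapply(seq_len(3), function(ax)
    as.integer(stats::nextn(d[ax] + lmax[ax], c(2, 3, 5))), integer(1))
  pad_a <- array(0, M); pad_a[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- da
  pad_b <- array(0, M); pad_b[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- db
  cc <- Re(stats::fft(Conj(stats::fft(pad_a)) * stats::fft(pad_b),
                      inverse = TRUE)) / prod(M)
  # enumerate lags and their per-lag pair counts
  lag <- expand.grid(lz = -lmax[1]:lmax[1], ly = -lmax[2]:lmax[2],
                     lx = -lmax[3]:lmax[3])
  r_um <- sqrt((lag$lz * pitch[1])^2 + (lag$ly * pitch[2])^2 +
               (lag$lx * pitch[3])^2)
  keep <- r_um <= rmax_um
  lag <- lag[keep, ]; r_um <- r_um[keep]
  wrap <- function(l, m) ifelse(l >= 0, l, m + l) + 1L
  idx <- cbind(wrap(lag$lz, M[1]), wrap(lag$ly, M[2]), wrap(lag$lx, M[3]))
  npairs <- (d[1] - abs(lag$lz)) * (d[2] - abs(lag$ly)) * (d[3] - abs(lag$lx))
  cov_lag <- cc[idx] / npairs
  # normalize by zero-lag standard deviations (Pearson-type)
  var_a <- mean(da^2)
  var_b <- mean(db^2)
  norm <- sqrt(var_a * var_b)
  value_lag <- if (norm > 0) cov_lag / norm else rep(NaN, length(cov_lag))
  # shell-average: the zero lag is its own bin, then (0, dr], (dr, 2*dr], ...
  bin <- ifelse(r_um == 0, 0L, ceiling(r_um / dr_um))
  agg_v <- rowsum(cbind(value_lag, 1), bin)
  agg_p <- rowsum(npairs, bin)
  bins <- as.integer(rownames(agg_v))
  out <- data.frame(r = ifelse(bins == 0L, 0, (bins - 0.5) * dr_um),
                    value = agg_v[, 1] / agg_v[, 2],
                    pairs = agg_p[, 1])
  out <- out[order(out$r), ]
  rownames(out) <- NULL
  attr(out, "auto") <- auto
  class(out) <- c("correlation_profile", "data.frame")
  out
}

#' Cluster-size and separation summaries of a correlation profile
#'
#' For an autocorrelation profile, the characteristic cluster size is the
#' smallest `r` at which the profile first drops below `1/e` (linear
#' interpolation between bin centers). For a cross-correlation profile,
#' the characteristic species separation is the `r` of the first interior
#' local maximum at `r > 0`. Either summary is `NaN` (with a warning) when
#' the profile never crosses/peaks within its range.
#'
#' @param profile a [spatial_correlation()] result.
#' @return A `global_metrics` data.frame with `cluster_size_um` (auto) or
#'   `separation_um` (cross).
#' @export
correlation_summaries <- function(profile) {
  stopifnot(inherits(profile, "correlation_profile"))
  auto <- isTRUE(attr(profile, "auto"))
  r <- profile$r; v <- profile$value
  if (auto) {
    thr <- exp(-1)
    below <- which(v < thr)
    if (!length(below)) {
      warning("autocorrelation never drops below 1/e within rmax", call. = FALSE)
      return(new_global_metrics("cluster_size_um", NaN, "um"))
    }
    k <- below[1]
    val <- if (k == 1L) r[1] else {
      r[k - 1] + (thr - v[k - 1]) * (r[k] - r[k - 1]) / (v[k] - v[k - 1])
    }
    return(new_global_metrics("cluster_size_um", val, "um"))
  }
  # first interior local maximum at r > 0
  n <- length(v)
  sep <- NaN
  for (k in seq_len(n)) {
    if (r[k] <= 0 || k == 1L || k == n) next
    if (v[k] > v[k - 1] && v[k] >= v[k + 1]) { sep <- r[k]; break }
  }
  if (is.nan(sep)) warning("no interior cross-correlation maximum within rmax",
                           call. = FALSE)
  new_global_metrics("separation_um", sep, "um")
}

#' Global summaries of every cube parameter
#'
#' For each cube parameter, emits its mean, standard deviation, median and
#' quartiles over the table's records (`NaN` records excluded; quartiles
#' use linear interpolation). Together with the structure and
#' colocalization registries this is the route to hundreds of global
#' parameters per biofilm.
#'
#' @param table a nonempty cube table.
#' @return A `global_metrics` data.frame with five metrics per parameter,
#'   named `<parameter>_{mean,sd,median,q1,q3}`.
#' @export
summarize_cube_parameters <- function(table) {
  if (nrow(table) == 0L) stop("cube table is empty", call. = FALSE)
  params <- cube_parameters(table)
  out <- lapply(params, function(p) {
    v <- table[[p]]
    v <- v[is.finite(v)]
    if (!length(v)) return(rep(NaN, 5))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    c(mean(v), if (length(v) > 1L) stats::sd(v) else 0, q[2], q[1], q[3])
  })
  new_global_metrics(
    metric = as.vector(t(outer(params, c("_mean", "_sd", "_median", "_q1", "_q3"),
                               paste0))),
    value = unlist(out),
    units = rep("", 5 * length(params)))
}
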