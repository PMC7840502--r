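# Seeded generator of synthetic biofilm volumes: colony-shaped binary
# ground truth, reporter intensity fields and nested growth series. All
# outputs are pure functions of (spec, seed); no global RNG state leaks.

#' Synthetic colony specification
#'
#' @param shape one of `"hemisphere"`, `"slab"`, `"slab_with_wrinkle"`,
#'   `"sphere"` (free-floating), `"two_strain_blocks"`, `"random_mixture"`.
#' @param size_um named list of physical sizes: `radius` (hemisphere,
#'   sphere), `thickness` (slab), `base_thickness`/`ridge_thickness`/
#'   `ridge_x` (slab_with_wrinkle, `ridge_x` = c(from, to) in um),
#'   `fill` (random_mixture foreground probability).
#' @param dim_zyx volume shape in voxels, `(nz, ny, nx)`.
#' @param geometry a [voxel_geometry()].
#' @param seed integer seed (mandatory; all randomness derives from it).
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(shape = c("hemisphere", "slab", "slab_with_wrinkle",
                                 "sphere", "two_strain_blocks", "random_mixture"),
                       size_um = list(), dim_zyx, geometry, seed) {
  shape <- match.arg(shape)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(inherits(geometry, "voxel_geometry"), length(dim_zyx) == 3L)
  structure(list(shape = shape, size_um = size_um,
                 dim_zyx = as.integer(dim_zyx), geometry = geometry,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# physical voxel-center coordinate arrays (um) for a volume
voxel_center_coords <- function(d, g) {
  z <- (seq_len(d[1]) - 0.5) * g$dz
  y <- (seq_len(d[2]) - 0.5) * g$dy
  x <- (seq_len(d[3]) - 0.5) * g$dx
  list(z = array(rep(z, times = d[2] * d[3]), d),
       y = array(rep(rep(y, each = d[1]), times = d[3]), d),
       x = array(rep(x, each = d[1] * d[2]), d))
}

#' Generate a synthetic colony mask
#'
#' Deterministic ground-truth biovolume for a given spec and seed. A
#' hemisphere of radius R sits on the substratum at the xy centre of the
#' field (voxels whose centers satisfy the ball inequality with z >= 0); a
#' slab is a uniform layer of the given thickness; `slab_with_wrinkle`
#' adds a thicker ridge over a stated x interval (a two-thickness
#' construction with a bimodal local-thickness signature); a sphere floats
#' at the field centre; `two_strain_blocks` places two disjoint cuboids;
#' `random_mixture` draws i.i.d. foreground voxels.
#'
#' @param spec a [synth_spec()].
#' @return A [binary_biovolume()].
#' @export
make_colony <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  d <- spec$dim_zyx
  g <- spec$geometry
  s <- spec$size_um
  ext <- c(z = d[1] * g$dz, y = d[2] * g$dy, x = d[3] * g$dx)
  co <- voxel_center_coords(d, g)
  m <- switch(spec$shape,
    hemisphere = {
      r <- s$radius
      if (is.null(r) || r > min(ext["y"], ext["x"]) / 2 || r > ext["z"]) {
        stop("hemisphere radius missing or larger than the volume", call. = FALSE)
      }
      (co$x - ext[["x"]] / 2)^2 + (co$y - ext[["y"]] / 2)^2 + co$z^2 <= r^2
    },
    slab = {
      h <- s$thickness
      if (is.null(h) || h > ext["z"]) stop("slab thickness missing or too large",
                                           call. = FALSE)
      co$z <= h
    },
    slab_with_wrinkle = {
      h1 <- s$base_thickness; h2 <- s$ridge_thickness; rx <- s$ridge_x
      if (is.null(h1) || is.null(h2) || is.null(rx) || h2 <= h1 ||
          max(h1, h2) > ext["z"]) {
        stop("slab_with_wrinkle needs base_thickness < ridge_thickness <= volume height",
             call. = FALSE)
      }
      ridge <- co$x >= rx[1] & co$x <= rx[2]
      co$z <= ifelse(ridge, h2, h1)
    },
    sphere = {
      r <- s$radius
      if (is.null(r) || 2 * r > min(ext)) {
        stop("sphere radius missing or larger than the volume", call. = FALSE)
      }
      (co$x - ext[["x"]] / 2)^2 + (co$y - ext[["y"]] / 2)^2 +
        (co$z - ext[["z"]] / 2)^2 <= r^2
    },
    two_strain_blocks = {
      # two disjoint cuboids occupying the lower half of z, split along x
      gap <- if (is.null(s$gap)) 2 * g$dx else s$gap
      h <- if (is.null(s$thickness)) ext[["z"]] / 2 else s$thickness
      b1 <- co$x < ext[["x"]] / 2 - gap / 2 & co$z <= h
      b2 <- co$x > ext[["x"]] / 2 + gap / 2 & co$z <= h
      b1 | b2
    },
    random_mixture = {
      p <- if (is.null(s$fill)) 0.5 else s$fill
      with_seed(spec$seed, array(stats::runif(prod(d)) < p, d))
    })
  binary_biovolume(array(m, d), g)
}

#' Superimpose a reporter intensity field on a mask
#'
#' Foreground voxels take the field value plus background plus seeded
#' noise; background voxels take the background level plus noise. Values
#' are clipped at zero. `exp_decay_from_surface` uses the same distance
#' transform as the cube cytometry, emulating e.g. an oxygen-proxy
#' reporter that decays with depth below the biofilm surface.
#'
#' @param mask a [binary_biovolume()].
#' @param field list: `type` one of `"constant"`,
#'   `"exp_decay_from_surface"`, `"exp_decay_from_substrate"`,
#'   `"linear_gradient"`; `amplitude` (default 100); `lambda_um` (decay
#'   length, decays); `axis` and `slope` (per um, linear_gradient);
#'   `substrate_mode` for the surface distance (default attached).
#' @param noise list: `gaussian_sd` (default 0), `poisson` (logical).
#' @param background background intensity level.
#' @param seed integer seed for the noise.
#' @param channel,frame metadata for the resulting stack.
#' @return An [intensity_stack()].
#' @export
add_intensity_field <- function(mask, field, noise = list(gaussian_sd = 0),
                                background = 0, seed = 1L,
                                channel = "ch1", frame = 0L) {
  stopifnot(inherits(mask, "binary_biovolume"))
  d <- dim(mask$mask)
  g <- mask$geometry
  amp <- if (is.null(field$amplitude)) 100 else field$amplitude
  vals <- array(0, d)
  fgv <- switch(field$type,
    constant = amp,
    exp_decay_from_surface = {
      if (is.null(field$lambda_um) || field$lambda_um <= 0) {
        stop("exp_decay_from_surface needs lambda_um > 0", call. = FALSE)
      }
      sm <- if (is.null(field$substrate_mode)) "attached" else field$substrate_mode
      fl <- compute_distance_fields(mask, sm)
      amp * exp(-fl$d_surface[mask$mask] / field$lambda_um)
    },
    exp_decay_from_substrate = {
      if (is.null(field$lambda_um) || field$lambda_um <= 0) {
        stop("exp_decay_from_substrate needs lambda_um > 0", call. = FALSE)
      }
      co <- voxel_center_coords(d, g)
      amp * exp(-co$z[mask$mask] / field$lambda_um)
    },
    linear_gradient = {
      if (is.null(field$axis) || is.null(field$slope)) {
        stop("linear_gradient needs axis and slope", call. = FALSE)
      }
      co <- voxel_center_coords(d, g)
      amp + field$slope * co[[field$axis]][mask$mask]
    },
    stop("unknown field type: ", field$type, call. = FALSE))
  vals[mask$mask] <- fgv
  vals <- vals + background
  gsd <- if (is.null(noise$gaussian_sd)) 0 else noise$gaussian_sd
  use_pois <- isTRUE(noise$poisson)
  if (gsd > 0 || use_pois) {
    vals <- with_seed(seed, {
      v <- vals
      if (use_pois) v <- array(stats::rpois(length(v), lambda = pmax(v, 0)), d)
      if (gsd > 0) v <- v + array(stats::rnorm(length(v), sd = gsd), d)
      v
    })
  }
  intensity_stack(pmax(vals, 0), g, channel = channel, frame = frame)
}

#' Partition a mask into clonal strain patches
#'
#' Dissects the foreground into cubic patches of edge `cluster_edge_um`
#' and assigns each patch to one of two strains with the given
#' probabilities (seeded). Each strain's channel is bright (200) on its
#' own voxels and dim (10) on the other strain's voxels; background is 0.
#'
#' @param mask a [binary_biovolume()].
#' @param fractions length-2 non-negative vector summing to 1.
#' @param cluster_edge_um patch edge length, um (at least one voxel pitch).
#' @param seed integer seed for the patch assignment.
#' @param bright,dim_level intensities inside/outside the strain's voxels.
#' @return List of two [intensity_stack()]s named `ch1`, `ch2`, plus the
#'   per-voxel strain label array as attribute `"strain"` (1/2, 0 outside).
#' @export
mix_strains <- function(mask, fractions = c(0.5, 0.5), cluster_edge_um,
                        seed = 1L, bright = 200, dim_level = 10) {
  stopifnot(inherits(mask, "binary_biovolume"), length(fractions) == 2L)
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions < 0)) {
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  }
  grid <- build_cube_grid(mask, cluster_edge_um)
  ids <- cube_id_array(grid)
  n_patches <- prod(grid$counts)
  strain_of_patch <- with_seed(seed,
    sample.int(2L, n_patches, replace = TRUE, prob = fractions))
  strain <- array(0L, dim(mask$mask))
  strain[mask$mask] <- strain_of_patch[ids[mask$mask] + 1L]
  ch <- lapply(1:2, function(s) {
    v <- array(0, dim(mask$mask))
    v[mask$mask] <- ifelse(strain[mask$mask] == s, bright, dim_level)
    intensity_stack(v, mask$geometry, channel = paste0("ch", s))
  })
  names(ch) <- c("ch1", "ch2")
  attr(ch, "strain") <- strain
  ch
}

#' Grow a nested time series of colonies
#'
#' Builds `n_frames` masks from a monotone growth rule (a function of the
#' 0-based frame index returning the size parameter, e.g. the hemisphere
#' radius in um). Masks are nested when no drift is requested; an optional
#' per-frame integer xy drift translates each successive frame.
#'
#' @param spec a [synth_spec()] (`hemisphere`, `sphere` or `slab`).
#' @param n_frames number of frames (at least 2).
#' @param growth_rule function(frame_index) -> radius/thickness in um;
#'   must be non-decreasing over the frames.
#' @param drift_per_frame integer xy drift applied per frame step,
#'   `c(x, y)` voxels.
#' @return List of [binary_biovolume()]s, one per frame.
#' @export
grow_series <- function(spec, n_frames, growth_rule,
                        drift_per_frame = c(0L, 0L)) {
  stopifnot(inherits(spec, "synth_spec"), n_frames >= 2L)
  sizes <- vapply(seq_len(n_frames) - 1L, growth_rule, numeric(1))
  if (any(diff(sizes) < 0)) stop("growth_rule must be non-decreasing", call. = FALSE)
  key <- switch(spec$shape, hemisphere = "radius", sphere = "radius",
                slab = "thickness",
                stop("grow_series supports hemisphere, sphere and slab", call. = FALSE))
  masks <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    sp <- spec
    sp$size_um[[key]] <- sizes[t]
    m <- make_colony(sp)
    shift <- (t - 1L) * as.integer(drift_per_frame)
    if (any(shift != 0L)) m$mask <- shift_mask_xy(m$mask, shift[1], shift[2])
    masks[[t]] <- m
  }
  masks
}

# translate a mask by integer voxels in x and y (background fill)
shift_mask_xy <- function(m, sx, sy) {
  d <- dim(m)
  out <- array(FALSE, d)
  yr <- seq_range(max(1L, 1L + sy), min(d[2], d[2] + sy))
  xr <- seq_range(max(1L, 1L + sx), min(d[3], d[3] + sx))
  if (length(yr) && length(xr)) {
    out[, yr, xr] <- m[, yr - sy, xr - sx, drop = FALSE]
  }
  out
}
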