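test_that("surface distances match hand geometry and the brute-force oracle", {
  g <- iso_geom()
  # 1-voxel slab at the substratum, attached: nearest background is above
  sl <- array(FALSE, c(4, 5, 5)); sl[1, , ] <- TRUE
  f <- compute_distance_fields(binary_biovolume(sl, g), "attached")
  expect_true(all(f$d_surface[sl] == 1))

  # isolated voxel, floating: one voxel pitch in every direction
  sv <- array(FALSE, c(5, 5, 5)); sv[3, 3, 3] <- TRUE
  f2 <- compute_distance_fields(binary_biovolume(sv, g), "floating")
  expect_equal(f2$d_surface[3, 3, 3], 1)

  set.seed(31)
  for (i in 1:6) {
    m <- random_mask(c(6, 12, 12), p = stats::runif(1, 0.3, 0.7))
    if (!any(m$mask)) next
    for (mode in c("attached", "floating")) {
      f <- compute_distance_fields(m, mode)
      expect_equal(f$d_surface[m$mask], brute_surface_distance(m, mode),
                   tolerance = 1e-12)
    }
  }
  # anisotropic geometry
  ga <- voxel_geometry(0.5, 0.5, 2)
  ma <- random_mask(c(4, 8, 8), p = 0.5, geometry = ga)
  fa <- compute_distance_fields(ma, "floating")
  expect_equal(fa$d_surface[ma$mask], brute_surface_distance(ma, "floating"),
               tolerance = 1e-12)

  expect_error(compute_distance_fields(
    binary_biovolume(array(FALSE, c(2, 2, 2)), g)), "foreground")
})

test_that("erosion never increases the surface distance at surviving voxels", {
  set.seed(32)
  m <- make_colony(synth_spec("hemisphere", list(radius = 4), c(12, 24, 24),
                              voxel_geometry(0.5, 0.5, 0.5), seed = 2))
  f0 <- compute_distance_fields(m, "attached")
  eroded <- m
  eroded$mask <- m$mask & f0$d_surface > 1 & !is.na(f0$d_surface)
  f1 <- compute_distance_fields(eroded, "attached")
  keep <- eroded$mask
  expect_true(all(f1$d_surface[keep] <= f0$d_surface[keep] + 1e-12))
})

test_that("geometric cube parameters follow their constructions", {
  g <- iso_geom()
  m <- binary_biovolume(array(TRUE, c(8, 8, 8)), g)  # slab 8 um thick
  grid <- build_cube_grid(m, 4)
  f <- compute_distance_fields(m, "attached")
  tab <- quantify_geometry(assign_voxels(m, grid), m, f)
  expect_true(all(tab$fill_fraction == 1))
  expect_true(all(tab$local_thickness_um == 8))
  expect_equal(sum(tab$biovolume_um3),
               metric_value(global_structure(m), "biovolume_um3"))
  # interior cube of a large solid block has no exposed surface
  big <- binary_biovolume(array(TRUE, c(12, 12, 12)), g)
  bgrid <- build_cube_grid(big, 4)
  btab <- quantify_geometry(assign_voxels(big, bgrid), big,
                            compute_distance_fields(big, "floating"), "floating")
  interior <- btab[btab$i == 1 & btab$j == 1 & btab$k == 1, ]
  expect_equal(interior$exposed_surface_area_um2, 0)

  # half-filled cubes: 2 of 4 z-layers of each span-4 cube
  h <- array(FALSE, c(8, 8, 8)); h[1:2, , ] <- TRUE
  htab <- quantify_geometry(assign_voxels(binary_biovolume(h, g), grid),
                            binary_biovolume(h, g),
                            compute_distance_fields(binary_biovolume(h, g)))
  expect_true(all(htab$fill_fraction == 0.5))
})

test_that("intensity statistics match direct arithmetic", {
  g <- iso_geom()
  m <- array(FALSE, c(4, 4, 4)); m[1, 1, 1:4] <- TRUE
  bb <- binary_biovolume(m, g)
  grid <- build_cube_grid(bb, 4)
  v <- array(0, c(4, 4, 4)); v[1, 1, 1:4] <- c(1, 2, 3, 4)
  tab <- quantify_intensity(assign_voxels(bb, grid), bb,
                            list(ch1 = intensity_stack(v, g)))
  expect_equal(tab$ch1_mean, 2.5)
  expect_equal(tab$ch1_median, 2.5)
  expect_equal(tab$ch1_sum, 10)
  expect_equal(tab$ch1_range, 3)
  expect_equal(tab$ch1_sd, sqrt(mean((c(1, 2, 3, 4) - 2.5)^2)))

  vc <- array(0, c(4, 4, 4)); vc[1, 1, 1:4] <- 100
  tc <- quantify_intensity(assign_voxels(bb, grid), bb,
                           list(ch1 = intensity_stack(vc, g)))
  expect_equal(tc$ch1_sd, 0)
  expect_equal(tc$ch1_cv, 0)
  expect_equal(tc$ch1_range, 0)

  # single-voxel cube: sd 0, cv 0 for positive mean
  one <- array(FALSE, c(4, 4, 4)); one[1, 1, 1] <- TRUE
  to <- quantify_intensity(assign_voxels(binary_biovolume(one, g), grid),
                           binary_biovolume(one, g),
                           list(ch1 = intensity_stack(vc, g)))
  expect_equal(to$ch1_sd, 0)
  expect_equal(to$ch1_cv, 0)
})

test_that("GLCM texture matches hand-enumerated pairs and conventions", {
  g <- iso_geom()
  m <- array(FALSE, c(4, 4, 4)); m[1:2, 1:2, 1:2] <- TRUE
  bb <- binary_biovolume(m, g)
  grid <- build_cube_grid(bb, 2)
  v <- array(0, c(4, 4, 4))
  v[2, 1:2, 1:2] <- 10  # top z-plane bright, bottom dark
  tab <- quantify_texture(assign_voxels(bb, grid), bb,
                          list(ch1 = intensity_stack(v, g)), levels = 8)
  # hand tabulation: z-pairs 4x(1,8); y- and x-pairs 2x(1,1) + 2x(8,8) each
  P <- matrix(0, 8, 8)
  P[1, 1] <- 8; P[8, 8] <- 8; P[1, 8] <- 4; P[8, 1] <- 4
  P <- P / 24
  i <- row(P); j <- col(P)
  expect_equal(tab$ch1_glcm_contrast, sum(P * (i - j)^2))
  expect_equal(tab$ch1_glcm_energy, sum(P^2))
  expect_equal(tab$ch1_glcm_homogeneity, sum(P / (1 + abs(i - j))))
  expect_equal(tab$ch1_glcm_entropy, -sum(ifelse(P > 0, P * log(P), 0)))
  mi <- sum(i * P); sdi <- sqrt(sum((i - mi)^2 * P))
  expect_equal(tab$ch1_glcm_correlation, sum((i - mi) * (j - mi) * P) / sdi^2)

  # constant cube: degenerate single-cell GLCM
  vc <- array(0, c(4, 4, 4)); vc[m] <- 7
  tc <- quantify_texture(assign_voxels(bb, grid), bb,
                         list(ch1 = intensity_stack(vc, g)), levels = 8)
  expect_equal(tc$ch1_glcm_energy, 1)
  expect_equal(tc$ch1_glcm_contrast, 0)
  expect_equal(tc$ch1_glcm_homogeneity, 1)
  expect_equal(tc$ch1_glcm_entropy, 0)
  expect_true(is.nan(tc$ch1_glcm_correlation))

  # fewer than 8 foreground voxels: all texture NaN
  small <- array(FALSE, c(4, 4, 4)); small[1, 1, 1:4] <- TRUE
  ts <- quantify_texture(assign_voxels(binary_biovolume(small, g), grid),
                         binary_biovolume(small, g),
                         list(ch1 = intensity_stack(v, g)))
  expect_true(all(is.nan(unlist(ts[grep("glcm", names(ts))]))))
})

test_that("channel correlations hit their analytic limits", {
  g <- iso_geom()
  m <- binary_biovolume(array(TRUE, c(4, 4, 4)), g)
  grid <- build_cube_grid(m, 4)
  set.seed(41)
  v <- array(stats::runif(64) * 50 + 1, c(4, 4, 4))
  same <- list(ch1 = intensity_stack(v, g), ch2 = intensity_stack(v, g))
  tab <- assign_voxels(m, grid)
  tab <- quantify_geometry(tab, m, compute_distance_fields(m))
  t1 <- quantify_correlations(tab, m, same)
  expect_equal(t1$ch1ch2_pearson, 1)
  expect_equal(t1$ch1ch2_spearman, 1)
  expect_equal(t1$ch1ch2_moc, 1)

  # anti-correlated positive channels: pearson -1, moc < 1
  w <- 60 - v
  t2 <- quantify_correlations(tab, m, list(ch1 = intensity_stack(v, g),
                                           ch2 = intensity_stack(w, g)))
  expect_equal(t2$ch1ch2_pearson, -1)
  expect_lt(t2$ch1ch2_moc, 1)
  expect_equal(t2$ch1ch2_moc,
               sum(v * w) / sqrt(sum(v^2) * sum(w^2)))

  # constant channel: pearson NaN, moc defined
  cst <- array(5, c(4, 4, 4))
  t3 <- quantify_correlations(tab, m, list(ch1 = intensity_stack(cst, g),
                                           ch2 = intensity_stack(v, g)))
  expect_true(is.nan(t3$ch1ch2_pearson))
  expect_false(is.nan(t3$ch1ch2_moc))
})

test_that("neighborhood parameters resolve context and gradients", {
  g <- iso_geom()
  big <- binary_biovolume(array(TRUE, c(12, 12, 12)), g)
  grid <- build_cube_grid(big, 4)
  f <- compute_distance_fields(big, "attached")
  tab <- quantify_geometry(assign_voxels(big, grid), big, f)
  tab <- quantify_neighborhood(tab, f)
  interior <- tab[tab$i == 1 & tab$j == 1 & tab$k == 1, ]
  expect_equal(interior$occupied_neighbor_count, 26)
  expect_equal(interior$neighborhood_mean_fill, 1)
  expect_equal(interior$fill_gradient_magnitude, 0)

  # isolated cube
  one <- array(FALSE, c(12, 12, 12)); one[1:4, 1:4, 1:4] <- TRUE
  bb1 <- binary_biovolume(one, g)
  f1 <- compute_distance_fields(bb1)
  tb1 <- quantify_neighborhood(quantify_geometry(assign_voxels(bb1, grid), bb1, f1), f1)
  expect_equal(tb1$occupied_neighbor_count, 0)
  expect_true(is.nan(tb1$neighborhood_mean_fill))

  # linear fill ramp along x: gradient magnitude equals the slope
  ramp <- array(FALSE, c(4, 4, 16))
  # cube x-index i gets fill (i+1)/4 by filling z-layers
  for (i in 0:3) ramp[seq_len(i + 1), , i * 4 + 1:4] <- TRUE
  bbr <- binary_biovolume(ramp, g)
  rgrid <- build_cube_grid(bbr, 4)
  fr <- compute_distance_fields(bbr)
  tr <- quantify_neighborhood(quantify_geometry(assign_voxels(bbr, rgrid), bbr, fr), fr)
  slope <- 0.25 / 4 # fill step per cube / cube edge (um)
  expect_equal(tr$fill_gradient_magnitude[tr$i %in% 1:2 & tr$k == 0],
               rep(slope, 2), tolerance = 1e-12)
})

test_that("the two-channel parameter set totals exactly 49", {
  demo <- demo_colony()
  grid <- build_cube_grid(demo$mask, 1)
  tab <- quantify_cubes(assign_voxels(demo$mask, grid), demo$mask, demo$channels)
  pars <- cube_parameters(tab)
  expect_length(pars, 49L)
  expect_length(unique(pars), 49L)
  # ranges
  expect_true(all(tab$fill_fraction >= 0 & tab$fill_fraction <= 1))
  corr <- tab$ch1ch2_pearson[is.finite(tab$ch1ch2_pearson)]
  expect_true(all(corr >= -1 - 1e-12 & corr <= 1 + 1e-12))
  moc <- tab$ch1ch2_moc[is.finite(tab$ch1ch2_moc)]
  expect_true(all(moc >= 0 & moc <= 1 + 1e-12))
})

test_that("custom parameters evaluate with NaN conventions and good errors", {
  demo <- demo_colony()
  grid <- build_cube_grid(demo$mask, 1)
  tab <- quantify_cubes(assign_voxels(demo$mask, grid), demo$mask, demo$channels)
  tab <- add_custom_parameter(tab, "ratio", "ch1_mean / ch2_mean")
  expect_equal(tab$ratio, ifelse(tab$ch2_mean == 0, NaN,
                                 tab$ch1_mean / tab$ch2_mean))
  tab <- add_custom_parameter(tab, "f2", "fill_fraction^2 + 1")
  expect_equal(tab$f2, tab$fill_fraction^2 + 1) # fill 0.5 -> 1.25
  # log of non-positive -> NaN
  tab$zerovol <- 0
  tab2 <- add_custom_parameter(tab, "lz", "log10(zerovol)")
  expect_true(all(is.nan(tab2$lz)))
  expect_error(add_custom_parameter(tab, "bad", "fill_fraktion * 2"),
               "fill_fraction")
  expect_error(add_custom_parameter(tab, "evil", "system('ls')"), "not allowed")
})

test_that("gating selects subpopulations and partitions non-NaN records", {
  g <- iso_geom()
  df <- data.frame(frame = 0L, cube_id = 0:3, i = 0:3, j = 0L, k = 0L,
                   region_voxels = 8L, fg_voxels = 4L, truncated = FALSE,
                   fill_fraction = c(0.2, 0.5, 0.9, NaN))
  tab <- cubecyte:::as_cube_table(df, NULL)
  inside <- gate(tab, list(list(parameter = "fill_fraction",
                                lower = 0.5, upper = 1.0)))
  expect_equal(nrow(inside), 2L)
  outside <- gate(tab, list(list(parameter = "fill_fraction",
                                 lower = 0.5, upper = 1.0)), complement = TRUE)
  expect_equal(nrow(outside), 1L)
  expect_equal(sort(c(inside$cube_id, outside$cube_id)), 0:2) # NaN excluded
  expect_error(gate(tab, list(list(parameter = "fill_fraction",
                                   lower = 1, upper = 0))), "lower bound")
  expect_warning(gate(tab, list(list(parameter = "fill_fraction",
                                     lower = 0.95, upper = 0.99))), "no records")
})

test_that("two-thickness slab gating reassigns cubes to their regions", {
  g <- voxel_geometry(0.5, 0.5, 0.5)
  sp <- synth_spec("slab_with_wrinkle",
                   list(base_thickness = 4, ridge_thickness = 10,
                        ridge_x = c(10, 20)),
                   c(24, 32, 64), g, seed = 1)
  mask <- make_colony(sp)
  grid <- build_cube_grid(mask, 2)
  f <- compute_distance_fields(mask)
  tab <- quantify_geometry(assign_voxels(mask, grid), mask, f)
  ridge <- gate(tab, list(list(parameter = "local_thickness_um", lower = 7)))
  base <- gate(tab, list(list(parameter = "local_thickness_um", lower = 7)),
               complement = TRUE)
  correct <- sum(ridge$centroid_x_um > 10 & ridge$centroid_x_um < 20) +
    sum(base$centroid_x_um <= 10 | base$centroid_x_um >= 20)
  expect_gte(correct / nrow(tab), 0.99)
})
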