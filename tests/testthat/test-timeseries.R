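ts_series <- function(drift = c(0L, 0L), rule = function(t) 2 + 0.5 * t,
                      n = 3, seed = 7) {
  g <- voxel_geometry(0.25, 0.25, 0.25)
  grow_series(synth_spec("hemisphere", list(radius = rule(0)), c(24, 64, 64),
                         g, seed = seed), n, rule, drift_per_frame = drift)
}

test_that("frame registration recovers constructed drifts", {
  # identical frames -> zero drift
  m <- ts_series()[1]
  expect_true(all(register_frames(rep(m, 3)) == 0L))

  # pure translation (+3, -2) per frame -> recovered exactly
  ms <- ts_series(drift = c(3L, -2L), rule = function(t) 3)
  dr <- register_frames(ms)
  expect_equal(dr[, "x"], c(0L, 3L, 6L))
  expect_equal(dr[, "y"], c(0L, -2L, -4L))

  # pure symmetric growth -> zero drift
  mg <- ts_series()
  expect_true(all(register_frames(mg) == 0L))

  # empty frame -> zero drift with warning
  g <- voxel_geometry(0.25, 0.25, 0.25)
  empty <- binary_biovolume(array(FALSE, dim(ms[[1]]$mask)), g)
  expect_warning(dre <- register_frames(list(ms[[1]], empty)), "empty")
  expect_true(all(dre == 0L))
})

test_that("static series track as identity chains forming a forest", {
  ms <- rep(ts_series()[1], 3)
  grid <- build_cube_grid(ms[[1]], 1)
  tabs <- lapply(1:3, function(t) assign_voxels(ms[[t]], grid, frame = t - 1))
  tg <- track_cubes(tabs, ms, NULL)
  expect_true(all(tg$edges$parent_id == tg$edges$child_id))
  expect_false(any(duplicated(paste(tg$edges$frame, tg$edges$child_id))))
  expect_equal(sum(tg$nodes$is_root), nrow(tabs[[1]]))
  # every cube persists across all three frames
  expect_equal(nrow(tg$edges), 2L * nrow(tabs[[1]]))
})

test_that("radial growth keeps lineages rooted at frame one", {
  ms <- ts_series()
  grid <- build_cube_grid(ms[[1]], 1)
  tabs <- lapply(1:3, function(t) assign_voxels(ms[[t]], grid, frame = t - 1))
  tg <- track_cubes(tabs, ms, NULL)
  # every frame-2 cube has a parent; roots equal frame-1 cube count
  f2 <- tabs[[2]]$cube_id
  expect_true(all(f2 %in% tg$edges$child_id[tg$edges$frame == 0]))
  expect_equal(sum(tg$nodes$is_root), nrow(tabs[[1]]))
  expect_false(any(duplicated(paste(tg$edges$frame, tg$edges$child_id))))
  expect_true(all(tg$edges$overlap_voxels[tg$edges$direct] > 0))
})

test_that("a vanishing cube ends its lineage", {
  g <- iso_geom()
  m1 <- array(FALSE, c(4, 8, 8)); m1[1:2, 1:4, 1:4] <- TRUE; m1[1:2, 5:8, 5:8] <- TRUE
  m2 <- array(FALSE, c(4, 8, 8)); m2[1:2, 1:4, 1:4] <- TRUE
  masks <- list(binary_biovolume(m1, g), binary_biovolume(m2, g))
  grid <- build_cube_grid(masks[[1]], 4)
  tabs <- lapply(1:2, function(t) assign_voxels(masks[[t]], grid, frame = t - 1))
  tg <- track_cubes(tabs, masks, NULL, attach_new = FALSE)
  dead <- setdiff(tabs[[1]]$cube_id, tg$edges$parent_id)
  expect_gt(length(dead), 0)
})

test_that("registration plus alignment makes tracking drift-invariant", {
  rule <- function(t) 3
  m0 <- ts_series(rule = rule)
  ms <- ts_series(drift = c(3L, -2L), rule = rule)
  dr <- register_frames(ms)
  al <- align_masks(ms, dr)
  expect_true(all(mapply(function(a, b) identical(a$mask, b$mask), al, m0)))
  grid <- build_cube_grid(m0[[1]], 1)
  t0 <- lapply(1:3, function(t) assign_voxels(m0[[t]], grid, frame = t - 1))
  ta <- lapply(1:3, function(t) assign_voxels(al[[t]], grid, frame = t - 1))
  expect_identical(track_cubes(t0, m0, NULL)$edges,
                   track_cubes(ta, al, NULL)$edges)
})

test_that("clonal cluster sizes follow the constructed strain layout", {
  g <- iso_geom()
  # two disjoint blocks, one per strain
  m <- array(FALSE, c(4, 4, 16))
  m[, , 1:6] <- TRUE; m[, , 11:16] <- TRUE
  bb <- binary_biovolume(m, g)
  grid <- build_cube_grid(bb, 2)
  tab <- assign_voxels(bb, grid)
  ch1 <- array(0, dim(m)); ch1[, , 1:6] <- 200; ch1[, , 11:16] <- 10
  ch2 <- array(0, dim(m)); ch2[, , 1:6] <- 10; ch2[, , 11:16] <- 200
  stacks <- list(ch1 = intensity_stack(ch1, g), ch2 = intensity_stack(ch2, g))
  tab <- quantify_geometry(tab, bb, compute_distance_fields(bb))
  tab <- quantify_intensity(tab, bb, stacks)
  cl <- clonal_cluster_sizes(tab, "ch1", "ch2", min_fraction = 0.9)
  expect_equal(nrow(cl), 2L)
  expect_setequal(cl$label, c("ch1", "ch2"))
  expect_equal(sort(cl$size_um3), sort(c(sum(m[, , 1:6]), sum(m[, , 11:16]))))

  # single dominant strain: one component spanning the biovolume
  solo <- quantify_intensity(
    quantify_geometry(assign_voxels(bb, grid), bb, compute_distance_fields(bb)),
    bb, list(ch1 = intensity_stack(array(200 * m, dim(m)), g),
             ch2 = intensity_stack(array(1 * m, dim(m)), g)))
  cls <- clonal_cluster_sizes(solo, "ch1", "ch2")
  expect_true(all(cls$label == "ch1"))
  expect_equal(sum(cls$size_um3), sum(m))

  # fine random mixture at a strict threshold: everything mixed
  demo <- demo_colony()
  gr <- build_cube_grid(demo$mask, 2)
  tmix <- quantify_intensity(
    quantify_geometry(assign_voxels(demo$mask, gr), demo$mask,
                      compute_distance_fields(demo$mask)),
    demo$mask, demo$channels)
  cm <- clonal_cluster_sizes(tmix, "ch1", "ch2", min_fraction = 0.995)
  expect_equal(nrow(cm), 0L)
})

test_that("kymographs aggregate with voxel weights and recover gradients", {
  g <- voxel_geometry(0.25, 0.25, 0.25)
  mask <- make_colony(synth_spec("slab", list(thickness = 8), c(40, 32, 32), g,
                                 seed = 5))
  st <- add_intensity_field(mask, list(type = "exp_decay_from_surface",
                                       lambda_um = 2), seed = 6)
  grid <- build_cube_grid(mask, 1)
  f <- compute_distance_fields(mask)
  tab <- quantify_geometry(assign_voxels(mask, grid), mask, f)
  tab <- quantify_intensity(tab, mask, list(ch1 = st))

  k <- kymograph(list(tab), "ch1_mean", "dist_surface_um", 0.5)
  ok <- is.finite(k$values[, 1]) & k$values[, 1] > 0
  fit <- stats::lm(log(k$values[ok, 1]) ~ k$y[ok])
  lambda <- -1 / stats::coef(fit)[[2]]
  expect_lt(abs(lambda - 2) / 2, 0.1)

  # column weight conservation over cubes with finite param and axis
  good <- is.finite(tab$ch1_mean) & is.finite(tab$dist_surface_um)
  expect_equal(sum(k$weights[, 1]), sum(tab$fg_voxels[good]))
  # weighted cell mean consistency with the table-wide weighted mean
  wm_cells <- sum(k$values[ok, 1] * k$weights[ok, 1]) / sum(k$weights[ok, 1])
  wm_table <- sum(tab$ch1_mean[good] * tab$fg_voxels[good]) / sum(tab$fg_voxels[good])
  expect_equal(wm_cells, wm_table)

  # constant parameter -> all defined cells equal it
  tab$const5 <- 5
  k5 <- kymograph(list(tab), "const5", "dist_surface_um", 0.5)
  expect_true(all(k5$values[is.finite(k5$values)] == 5))
  # empty bins carry NaN and zero weight
  expect_true(all(k5$weights[is.nan(k5$values)] == 0))
})

test_that("kymograph normalization is cell-wise with NaN guards", {
  g <- voxel_geometry(0.25, 0.25, 0.25)
  demo <- demo_colony()
  grid <- build_cube_grid(demo$mask, 1)
  f <- compute_distance_fields(demo$mask)
  tab <- quantify_geometry(assign_voxels(demo$mask, grid), demo$mask, f)
  tab <- quantify_intensity(tab, demo$mask, demo$channels)
  kn <- kymograph(list(tab), "ch1_mean", "dist_surface_um", 0.5)
  kd <- kymograph(list(tab), "ch1_mean", "dist_surface_um", 0.5)
  r <- normalize_kymograph(kn, kd)
  expect_true(all(r$values[is.finite(r$values)] == 1))

  kd2 <- kd
  kd2$values[] <- 0
  r0 <- normalize_kymograph(kn, kd2)
  expect_true(all(is.nan(r0$values)))

  kd3 <- kd
  kd3$values <- kd$values / 2
  r2 <- normalize_kymograph(kn, kd3)
  expect_true(all(abs(r2$values[is.finite(r2$values)] - 2) < 1e-12))

  kb <- kymograph(list(tab), "ch1_mean", "dist_surface_um", 1.0)
  expect_error(normalize_kymograph(kn, kb), "binned")
})

test_that("biovolume can replace time on the kymograph x axis", {
  ms <- ts_series()
  grid <- build_cube_grid(ms[[1]], 1)
  tabs <- lapply(1:3, function(t) {
    f <- compute_distance_fields(ms[[t]])
    quantify_geometry(assign_voxels(ms[[t]], grid, frame = t - 1), ms[[t]], f)
  })
  k <- kymograph(tabs, "fill_fraction", "dist_substrate_um", 0.5,
                 x_axis = "biovolume")
  expect_true(all(diff(k$x) > 0))
  expect_equal(ncol(k$values), length(k$x))
})
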