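test_that("point groups have the right orders and are closed", {
  expect_equal(build_group("C1")$order, 1L)
  expect_equal(build_group("C2")$order, 2L)
  expect_equal(build_group("D7")$order, 14L)
  expect_equal(build_group("T")$order, 12L)
  g <- build_group("O")
  expect_equal(g$order, 24L)
  # brute-force closure: every pairwise product is in the set
  keys <- vapply(g$rotations, cryolayer:::.mat_key, character(1L))
  for (a in g$rotations) for (b in g$rotations) {
    expect_true(cryolayer:::.mat_key(a %*% b) %in% keys)
  }
  # all operators proper rotations
  dets <- vapply(g$rotations, det, numeric(1L))
  expect_equal(dets, rep(1, 24L), tolerance = 1e-9)
  expect_equal(build_group("I")$order, 60L)
  expect_error(build_group("Q3"), "unknown")
})

test_that("Euler matrix round-trip preserves angles", {
  set.seed(10)
  for (i in 1:50) {
    ang <- c(runif(1, -180, 180), runif(1, 1, 179), runif(1, -180, 180))
    back <- matrix_to_euler(euler_to_matrix(ang[1], ang[2], ang[3]))
    expect_equal(unname(back), ang, tolerance = 1e-9)
  }
})

test_that("C1 reduction is the identity on (rot, tilt)", {
  set.seed(11)
  g <- build_group("C1")
  ang <- cbind(runif(100, -180, 180), runif(100, 1, 179), runif(100, -180, 180))
  red <- reduce_to_asymmetric_unit(ang, g)
  expect_equal(red$rot, ang[, 1], tolerance = 1e-9)
  expect_equal(red$tilt, ang[, 2], tolerance = 1e-9)
})

test_that("reduction is invariant under group operators and idempotent", {
  set.seed(12)
  for (nm in c("C2", "C4", "D2", "D7", "O")) {
    g <- build_group(nm)
    n <- 200L
    ang <- cbind(runif(n, -180, 180), acos(runif(n, -1, 1)) * 180 / pi,
                 runif(n, -180, 180))
    red0 <- reduce_to_asymmetric_unit(ang, g)
    # compose each orientation with a random group operator first
    ang2 <- t(vapply(seq_len(n), function(i) {
      A <- euler_to_matrix(ang[i, 1], ang[i, 2], ang[i, 3])
      S <- g$rotations[[sample(g$order, 1L)]]
      matrix_to_euler(A %*% S)
    }, numeric(3L)))
    red1 <- reduce_to_asymmetric_unit(ang2, g)
    expect_equal(red1$rot, red0$rot, tolerance = 1e-6)
    expect_equal(red1$tilt, red0$tilt, tolerance = 1e-6)
    # idempotence: reducing a reduced orientation changes nothing
    red2 <- reduce_to_asymmetric_unit(cbind(red0$rot, red0$tilt, 0), g)
    expect_equal(red2$rot, red0$rot, tolerance = 1e-6)
    expect_equal(red2$tilt, red0$tilt, tolerance = 1e-6)
  }
})

test_that("dihedral reduction folds tilt to at most 90 degrees", {
  set.seed(13)
  g <- build_group("D2")
  ang <- cbind(runif(500, -180, 180), acos(runif(500, -1, 1)) * 180 / pi,
               runif(500, -180, 180))
  red <- reduce_to_asymmetric_unit(ang, g)
  expect_lte(max(red$tilt), 90 + 1e-9)
})

test_that("heatmaps conserve counts and localise point masses", {
  set.seed(14)
  ds <- generate_spa_dataset(spa_manifest(seed = 14L, n_micrographs = 2L,
                                          n_particles_per_micrograph = 300L))
  map <- orientation_heatmap(ds$table, "C1")
  expect_equal(sum(map$bins), 600)
  expect_true(all(map$bins >= 0))

  one <- ds$table[rep(1L, 50L), ]
  tab1 <- particle_table(as.data.frame(one), pixel_size = 0.97)
  map1 <- orientation_heatmap(tab1, "C1")
  expect_equal(sum(map1$bins > 0), 1L)
  expect_equal(max(map1$bins), 50)
  expect_equal(coverage_fraction(map1), 1 / (36 * 18))
})

test_that("symmetry-equivalent datasets produce bin-identical heatmaps", {
  set.seed(15)
  g <- build_group("D7")
  n <- 400L
  rec <- data.frame(micrograph_id = "m", coord_x = runif(n), coord_y = runif(n),
                    defocus_u = 10000, defocus_v = 10000,
                    angle_rot = runif(n, -180, 180),
                    angle_tilt = acos(runif(n, -1, 1)) * 180 / pi,
                    angle_psi = runif(n, -180, 180))
  tab <- particle_table(rec, pixel_size = 1)
  rec2 <- rec
  for (i in seq_len(n)) {
    A <- euler_to_matrix(rec$angle_rot[i], rec$angle_tilt[i], rec$angle_psi[i])
    S <- g$rotations[[1L + i %% g$order]]
    e <- matrix_to_euler(A %*% S)
    rec2$angle_rot[i] <- e[["rot"]]; rec2$angle_tilt[i] <- e[["tilt"]]
    rec2$angle_psi[i] <- e[["psi"]]
  }
  tab2 <- particle_table(rec2, pixel_size = 1)
  expect_equal(orientation_heatmap(tab2, g)$bins, orientation_heatmap(tab, g)$bins)
})

test_that("preferred orientations give lower coverage than uniform", {
  for (seed in 1:10) {
    du <- generate_spa_dataset(spa_manifest(seed = seed, n_micrographs = 1L,
                                            n_particles_per_micrograph = 2000L))
    dp <- generate_spa_dataset(spa_manifest(
      seed = seed, n_micrographs = 1L, n_particles_per_micrograph = 2000L,
      orientation = list(kind = "preferred", axis = c(0, 0, 1),
                         concentration = 50)))
    cu <- coverage_fraction(orientation_heatmap(du$table, "C1"))
    cp <- coverage_fraction(orientation_heatmap(dp$table, "C1"))
    expect_lt(cp, cu)
  }
})

test_that("tables without Euler angles are refused with a clear error", {
  tab <- read_particle_star(write_legacy_star_fixture(),
                            default_pixel_size = 0.97)
  expect_error(orientation_heatmap(tab, "C1"), "Euler angles")
})
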