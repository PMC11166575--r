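test_that("defocus-to-z mean-centres per micrograph with the right sign", {
  rec <- data.frame(
    micrograph_id = c("a", "a", "b", "b", "b"),
    coord_x = c(0, 100, 0, 50, 100), coord_y = c(0, 0, 0, 0, 0),
    defocus_u = c(10000, 10200, 12000, 12000, 12000),
    defocus_v = c(10000, 10200, 12000, 12000, 12000))
  tab <- particle_table(rec, pixel_size = 2)
  clouds <- defocus_to_z(tab)
  # default convention: smaller underfocus is higher in the ice
  expect_equal(clouds[["a"]]$z, c(100, -100))
  expect_equal(clouds[["b"]]$z, c(0, 0, 0))   # constant defocus -> all zero
  expect_equal(clouds[["a"]]$x, c(0, 200))    # pixels -> Angstrom
  flipped <- defocus_to_z(tab, convention = "defocus_increasing_up")
  expect_equal(flipped[["a"]]$z, c(-100, 100))
})

test_that("defocus averages the astigmatic pair", {
  rec <- data.frame(micrograph_id = c("a", "a"), coord_x = 0:1, coord_y = 0:1,
                    defocus_u = c(10000, 10300), defocus_v = c(10100, 10200))
  clouds <- defocus_to_z(particle_table(rec, pixel_size = 1))
  expect_equal(clouds[["a"]]$z, c(100, -100))
})

test_that("noiseless generated z is recovered exactly up to mean-centring", {
  m <- spa_manifest(seed = 5L, n_micrographs = 2L,
                    n_particles_per_micrograph = 50L,
                    defocus_noise_sd = 0, tilt_sd = 0.02)
  ds <- generate_spa_dataset(m)
  clouds <- defocus_to_z(ds$table, convention = m$z_convention)
  for (k in 1:2) {
    zt <- ds$truth$micrographs[[k]]$z_true
    expect_equal(clouds[[k]]$z, zt - mean(zt), tolerance = 1e-6)
  }
})

test_that("plane fit interpolates three points exactly", {
  cl <- z_cloud(x = c(0, 1, 0), y = c(0, 0, 1), z = c(0, 1, 2))
  fit <- fit_plane(cl)
  expect_equal(fit$a, 1, tolerance = 1e-12)
  expect_equal(fit$b, 2, tolerance = 1e-12)
  expect_equal(fit$c, 0, tolerance = 1e-12)
  expect_equal(fit$rms_residual, 0, tolerance = 1e-9)
  expect_equal(sqrt(sum(fit$unit_normal^2)), 1, tolerance = 1e-12)
  expect_gt(fit$unit_normal[3L], 0)
})

test_that("noiseless coplanar clouds are recovered to 1e-9", {
  set.seed(42)
  x <- runif(500, 0, 4000); y <- runif(500, 0, 4000)
  cl <- z_cloud(x, y, 0.01 * x + 0.02 * y + 500)
  fit <- fit_plane(cl)
  expect_equal(fit$a, 0.01, tolerance = 1e-9)
  expect_equal(fit$b, 0.02, tolerance = 1e-9)
  expect_equal(fit$c, 500, tolerance = 1e-9)
  expect_lt(fit$rms_residual, 1e-9 * 500)
  expect_lt(max(abs(distances_to_plane(cl, fit))), 1e-6)
})

test_that("noisy tilt recovery agrees with the normal-equations oracle", {
  set.seed(7)
  x <- runif(2000, 0, 4000); y <- runif(2000, 0, 4000)
  z <- 0.01 * x + 0.02 * y + 500 + rnorm(2000, 0, 20)
  fit <- fit_plane(z_cloud(x, y, z))
  oracle <- ls_plane_oracle(x, y, z)
  expect_equal(fit$a, oracle$beta[1L], tolerance = 1e-9)
  expect_equal(fit$b, oracle$beta[2L], tolerance = 1e-9)
  expect_lt(abs(fit$a - 0.01), 3 * oracle$se[1L])
  expect_lt(abs(fit$b - 0.02), 3 * oracle$se[2L])
})

test_that("degenerate and undersized clouds are refused", {
  expect_error(fit_plane(z_cloud(0:5, 0:5, 0:5)), "collinear|degenerate")
  expect_error(fit_plane(z_cloud(c(0, 1), c(0, 1), c(0, 1))), "insufficient")
  expect_error(fit_plane(z_cloud(runif(5), runif(5), runif(5)),
                         min_points = 10L), "insufficient")
})

test_that("signed distances are true orthogonal distances", {
  # horizontal plane: distances reduce to z - c
  cl <- z_cloud(runif(50), runif(50), rnorm(50, 5))
  fith <- structure(list(a = 0, b = 0, c = 5, unit_normal = c(0, 0, 1),
                         rms_residual = 0, n_points = 50L,
                         micrograph_id = NULL), class = "plane_fit")
  expect_equal(distances_to_plane(cl, fith), cl$z - 5)

  # tilted plane: a point 100 A vertically above maps to 100/sqrt(1+a^2)
  a <- 0.05
  plane <- z_cloud(c(0, 100, 0, 100), c(0, 0, 100, 100),
                   a * c(0, 100, 0, 100))
  fit <- fit_plane(plane)
  pt <- z_cloud(50, 50, a * 50 + 100)
  d <- distances_to_plane(pt, fit)
  expect_equal(d, 100 / sqrt(1 + a^2), tolerance = 1e-9)
  # brute-force point-to-plane oracle: minimise distance over the plane
  obj <- function(p) sqrt((p[1] - 50)^2 + (p[2] - 50)^2 +
                            (a * p[1] - (a * 50 + 100))^2)
  brute <- optim(c(50, 50), obj, method = "BFGS")$value
  expect_equal(abs(d), brute, tolerance = 1e-5)
})

test_that("fitting is equivariant under z-shift and xy-translation", {
  set.seed(8)
  x <- runif(200, 0, 1000); y <- runif(200, 0, 1000)
  z <- 0.03 * x - 0.01 * y + rnorm(200, 0, 10)
  f0 <- fit_plane(z_cloud(x, y, z))
  d0 <- distances_to_plane(z_cloud(x, y, z), f0)
  fz <- fit_plane(z_cloud(x, y, z + 250))
  expect_equal(fz$a, f0$a, tolerance = 1e-12)
  expect_equal(fz$b, f0$b, tolerance = 1e-12)
  expect_equal(fz$c, f0$c + 250, tolerance = 1e-9)
  expect_equal(distances_to_plane(z_cloud(x, y, z + 250), fz), d0,
               tolerance = 1e-9)
  fxy <- fit_plane(z_cloud(x + 500, y - 300, z))
  expect_equal(distances_to_plane(z_cloud(x + 500, y - 300, z), fxy), d0,
               tolerance = 1e-9)
  expect_equal(mean(d0), 0, tolerance = 1e-6)
})

test_that("distances refuse a fit from a different micrograph", {
  cla <- z_cloud(runif(10), runif(10), runif(10), micrograph_id = "a")
  clb <- z_cloud(runif(10), runif(10), runif(10), micrograph_id = "b")
  expect_error(distances_to_plane(clb, fit_plane(cla)), "frame mismatch")
})
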