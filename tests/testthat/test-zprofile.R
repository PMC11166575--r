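test_that("KDE summary: mode, normalization and bimodal construction", {
  set.seed(1)
  x <- rnorm(1e5, 0, 40)
  k <- kde_summary(x)
  expect_lt(abs(k$mode - k$median), 0.05 * 40)
  # density integrates to 1 within 1e-3 on its grid
  dx <- diff(k$grid[1:2])
  expect_equal(sum(k$density) * dx, 1, tolerance = 1e-3)
  expect_equal(k$mean, mean(x))
  expect_equal(k$median, median(x))

  mix <- c(rnorm(5e3, -100, 15), rnorm(5e3, 100, 15))
  km <- kde_summary(mix)
  peaks <- km$grid[cryolayer:::.peak_prominences(km$density)$peaks]
  major <- peaks[abs(peaks) > 50]
  expect_length(major, 2L)
  expect_equal(sort(sign(major)), c(-1, 1))
  expect_lt(max(abs(abs(major) - 100)), 15)

  expect_error(kde_summary(rep(3, 100)), "zero variance|degenerate")
})

test_that("skewness is the raw moment coefficient g1", {
  set.seed(2)
  x <- rexp(500)
  expect_equal(skewness(c(x, -x)), 0, tolerance = 1e-12)
  expect_equal(skewness(-x), -skewness(x), tolerance = 1e-12)
  # agrees with a direct central-moment computation
  xc <- x - mean(x)
  expect_equal(skewness(x), mean(xc^3) / mean(xc^2)^1.5, tolerance = 1e-12)
  expect_error(skewness(rep(1, 10)), "zero-variance")
})

test_that("skewness tiers follow the printed thresholds with boundary ties up", {
  expect_equal(classify_skewness(0.3), "symmetric")
  expect_equal(classify_skewness(-0.7), "moderate_left")
  expect_equal(classify_skewness(1.2), "high_right")
  expect_equal(classify_skewness(c(0.5, -0.5)), c("moderate_right", "moderate_left"))
  expect_equal(classify_skewness(c(1, -1)), c("high_right", "high_left"))
  expect_equal(classify_skewness(c(-0.49, 0.99, -1.01)),
               c("symmetric", "moderate_right", "high_left"))
})

test_that("mirrored samples always classify symmetric", {
  set.seed(3)
  for (i in 1:25) {
    x <- switch(1 + i %% 3, rexp(200), rnorm(200, 5, 2), runif(200)^3)
    expect_equal(classify_skewness(skewness(c(x, -x))), "symmetric")
  }
})

test_that("layering detection separates layers from heavy tails", {
  set.seed(4)
  expect_equal(detect_layering(rnorm(3000, 0, 30)), "unimodal")
  two <- c(rnorm(1500, -90, 15), rnorm(1500, 90, 15))  # 6 sigma apart
  expect_equal(detect_layering(two), "bimodal")
  laplace <- rexp(3000, 1 / 30) * sample(c(-1, 1), 3000, replace = TRUE)
  expect_equal(detect_layering(laplace), "unimodal")
  expect_equal(detect_layering(rep(1, 100)), "indeterminate")
})

test_that("ice thickness implements the central-fraction extent", {
  set.seed(5)
  u <- runif(2e5, -50, 50)
  expect_equal(ice_thickness(u), 80, tolerance = 0.01)
  expect_equal(ice_thickness(u, fraction = 1), max(u) - min(u))
  # monotone in fraction, invariant under shift
  fr <- c(0.2, 0.5, 0.8, 0.95)
  th <- vapply(fr, function(f) ice_thickness(u, f), numeric(1L))
  expect_true(all(diff(th) > 0))
  expect_equal(ice_thickness(u + 123.4), ice_thickness(u), tolerance = 1e-9)
  expect_error(ice_thickness(u, fraction = 0), "fraction")
  expect_error(ice_thickness(u, fraction = 1.2), "fraction")
})

test_that("per-micrograph profiles respect the inclusion threshold", {
  set.seed(6)
  expect_message(p <- z_profile(rnorm(5), min_particles = 10L), "excluded")
  expect_null(p)
  p <- z_profile(rnorm(500, 0, 40), micrograph_id = "m1")
  expect_s3_class(p, "z_profile")
  expect_equal(p$n, 500L)
  expect_equal(p$tier, classify_skewness(p$skewness))
  expect_equal(p$modality, "unimodal")
})

test_that("dataset summary: boxplot rule, tiers, permutation invariance", {
  mk <- function(s, id) {
    # profile stub with controlled skewness, real distances
    p <- z_profile(rnorm(200, 0, 30), micrograph_id = id)
    p$skewness <- s
    p$tier <- classify_skewness(s)
    p
  }
  profs <- Map(mk, c(-0.1, 0, 0.1), c("a", "b", "c"))
  s <- summarize_dataset(profs)
  expect_equal(s$boxplot$median, 0)
  expect_length(s$boxplot$outliers, 0L)
  expect_equal(sum(unlist(s$tier_fractions)), 1, tolerance = 1e-9)
  expect_lte(s$boxplot$q1, s$boxplot$median)
  expect_lte(s$boxplot$median, s$boxplot$q3)

  set.seed(7)
  many <- Map(mk, c(rnorm(50, 0, 0.05), 5.0), paste0("m", 1:51))
  s2 <- summarize_dataset(many)
  expect_equal(s2$boxplot$outliers, 5.0)
  expect_lt(s2$boxplot$whisker_high, 5.0)

  s3 <- summarize_dataset(rev(many))
  expect_equal(s3$boxplot, s2$boxplot)
  expect_equal(s3$thickness_mean, s2$thickness_mean)
  expect_equal(sort(s3$skewness_values), sort(s2$skewness_values))
  expect_error(summarize_dataset(list(NULL)), "no valid")
})

test_that("thickness CI narrows with micrograph count and brackets the mean", {
  set.seed(8)
  profs <- lapply(1:30, function(i)
    z_profile(rnorm(400, 0, 40), micrograph_id = paste0("m", i)))
  s <- summarize_dataset(profs)
  expect_lt(s$thickness_ci95[1L], s$thickness_mean)
  expect_gt(s$thickness_ci95[2L], s$thickness_mean)
  th <- vapply(profs, `[[`, numeric(1L), "thickness")
  expect_equal(s$thickness_ci95[2L] - s$thickness_mean,
               1.96 * sd(th) / sqrt(30), tolerance = 1e-9)
})
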