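test_that("generation is deterministic under a fixed seed", {
  a <- generate_inventory(stand_params(), seed = 42)
  b <- generate_inventory(stand_params(), seed = 42)
  expect_identical(a$trees, b$trees)
  expect_identical(a$plots, b$plots)

  set.seed(7); p1 <- generate_plot_covariates(stand_params(), n = 3)
  set.seed(7); p2 <- generate_plot_covariates(stand_params(), n = 3)
  expect_identical(p1, p2)
})

test_that("covariates stay in their documented ranges and landform follows altitude", {
  params <- stand_params()
  set.seed(1)
  cov <- generate_plot_covariates(params, n = 10000)
  expect_true(all(cov$altitude_m >= 105 & cov$altitude_m <= 1250))
  expect_true(all(cov$stand_density >= 80 & cov$stand_density <= 150))
  expect_true(all(cov$slope_direction %in% c("N","NE","E","SE","S","SW","W","NW")))
  expect_identical(cov$landform, landform_from_altitude(cov$altitude_m))
  expect_equal(landform_from_altitude(750), "low-mountain")
  expect_equal(landform_from_altitude(c(150, 350, 1100)),
               c("hill", "hill", "mid-mountain"))
})

test_that("zero-noise stands sit exactly on the allometric curves", {
  params <- stand_params(
    height_allometry = list(a = 0.95, b = 0.80, sd_log = 0),
    crown_width = list(c0 = 0.5, c_dbh = 0.15, c_height = 0.05, sd = 0),
    crown_length = list(c0 = -0.5, c_dbh = 0.08, c_height = 0.45, sd = 0))
  set.seed(3)
  tr <- generate_stand(minimal_plot(), params)
  expect_equal(tr$height_m, 1.3 + 0.95 * tr$dbh_cm^0.80, tolerance = 1e-12)
  expect_equal(tr$crown_width_m,
               0.5 + 0.15 * tr$dbh_cm + 0.05 * tr$height_m, tolerance = 1e-12)
  expect_equal(tr$crown_length_m,
               -0.5 + 0.08 * tr$dbh_cm + 0.45 * tr$height_m, tolerance = 1e-12)
})

test_that("large Weibull shape collapses the DBH spread", {
  params <- stand_params(dbh_shape = 200, driver_effects = null_driver_effects())
  set.seed(4)
  tr <- generate_stand(minimal_plot(stand_density = 150), params)
  expect_lt(stats::sd(tr$dbh_cm), 0.2)
})

test_that("empirical mean DBH matches the closed-form Weibull mean within 1%", {
  # shape/scale regime where (1, 40] truncation is negligible
  params <- stand_params(driver_effects = null_driver_effects())
  shape <- params$dbh_shape
  scale <- 12.19 / gamma(1 + 1 / shape)   # middle-stage scale
  set.seed(5)
  plot <- minimal_plot(stand_age = 25L, n_trees = 100000L)
  tr <- generate_stand(plot, params)
  expect_equal(mean(tr$dbh_cm), scale * gamma(1 + 1 / shape), tolerance = 0.01)
})

test_that("generated records satisfy every tree and plot invariant", {
  inv <- table1_inventory(seed = 6)
  expect_silent(validate_trees <- standstruct:::validate_trees(inv$trees))
  expect_true(all(inv$trees$dbh_cm > 0 & inv$trees$dbh_cm <= 40))
  expect_true(all(inv$trees$height_m > 1.3))
  expect_true(all(inv$trees$crown_length_m >= 0 &
                    inv$trees$crown_length_m <= inv$trees$height_m))
  expect_true(all(inv$trees$live_crown_ratio >= 0 &
                    inv$trees$live_crown_ratio <= 1))
  # clamping is rare at default parameters
  expect_lt(inv$ground_truth$clamp_rate, 0.01)
})

test_that("the default inventory is shaped like the nine-city study region", {
  inv <- table1_inventory(seed = 7)
  expect_equal(nrow(inv$plots), 31L)
  expect_equal(nrow(inv$trees), 3633L)
  expect_setequal(unique(inv$plots$city), default_city_table()$city)
  expect_named(inv$ground_truth$dbh_shape, c("plot_id", "shape", "scale"))
})

test_that("with all driver effects zero, plot diversity varies only by sampling noise", {
  params <- stand_params(
    cities = data.frame(city = "Null", plots = 40L, trees = NA_integer_),
    age_range = c(25L, 25L),
    driver_effects = null_driver_effects())
  inv <- generate_inventory(params, seed = 8)
  pd <- plot_diversity(inv$trees, inv$plots)
  # every plot shares the same true shape/scale, so the spread of H is the
  # sampling noise of ~100-tree stands: small, and uncorrelated with slope
  expect_lt(stats::sd(pd$shannon), 0.12)
  expect_equal(length(unique(inv$ground_truth$dbh_shape$shape)), 1L)
})

test_that("closed-form path truth matches a brute-force simulated population", {
  params <- stand_params(driver_effects = null_driver_effects())
  shape <- params$dbh_shape
  scale <- 12.19 / gamma(1 + 1 / shape)
  set.seed(9)
  tr <- generate_stand(minimal_plot(n_trees = 200000L), params)
  truth <- true_path_coefficients(params, shape, scale, "crown_width",
                                  site = attr(tr, "site_mult"))
  d <- stats::sd(tr$dbh_cm); h <- stats::sd(tr$height_m)
  y <- stats::sd(tr$crown_width_m)
  expect_equal(truth$sd_dbh, d, tolerance = 0.01)
  expect_equal(truth$sd_height, h, tolerance = 0.01)
  expect_equal(truth$sd_y, y, tolerance = 0.01)
  expect_equal(truth$r_dbh_height, stats::cor(tr$dbh_cm, tr$height_m),
               tolerance = 0.01)
})

test_that("simulate_path_data embeds its stated standardized truth", {
  d <- simulate_path_data(200000, p_direct = c(0.47, 0.27), r = 0.68, seed = 10)
  expect_equal(stats::cor(d$dbh, d$height), 0.68, tolerance = 0.01)
  fit <- stats::lm(y ~ dbh + height, data = d)
  expect_equal(unname(stats::coef(fit)["dbh"] * stats::sd(d$dbh) / stats::sd(d$y)),
               0.47, tolerance = 0.01)
})
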