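test_that("age stages map ages to the four labelled ranges", {
  expect_equal(as.character(assign_age_stage(c(8, 20, 21, 30, 31, 40, 41, 51))),
               c("young", "young", "middle", "middle", "near-mature",
                 "near-mature", "mature", "mature"))
  expect_error(assign_age_stage(61), "range")
  expect_error(assign_age_stage(0), "range")
})

test_that("binning uses lower-open/upper-closed classes and conserves trees", {
  d <- bin_dbh(c(5.0, 5.1))
  expect_equal(d$counts[1:2], c(1L, 1L))   # 5.0 -> "<=5", 5.1 -> "5-8"
  expect_equal(bin_dbh(8.0)$counts[2], 1L) # boundary joins the lower class

  expect_equal(bin_dbh(1:10 * 3.7)$n_classes, 10L)

  # brute-force per-value binning oracle
  set.seed(1)
  vals <- stats::qweibull(stats::runif(1000, 0, stats::pweibull(40, 2, 12)), 2, 12)
  vals <- vals[vals > 0]
  d <- bin_dbh(vals)
  edges <- dbh_class_edges()
  brute <- integer(10)
  for (v in vals) {
    for (j in 1:10) if (v > edges[j] && v <= edges[j + 1]) brute[j] <- brute[j] + 1L
  }
  expect_equal(d$counts, brute)
  expect_equal(sum(d$counts), length(vals))
  expect_equal(sum(d$proportions), 1, tolerance = 1e-12)
})

test_that("DBH above 40 cm errors by default and folds only on request", {
  expect_error(bin_dbh(c(10, 45)), "40 cm")
  expect_warning(d <- bin_dbh(c(10, 45), allow_overflow = TRUE), "folded")
  expect_equal(d$counts[10], 1L)
  expect_error(bin_dbh(c(-1, 10)), "> 0")
})

test_that("Shannon index matches hand values and its bounds", {
  expect_equal(shannon_index(c(50, rep(0, 9))), 0)
  expect_equal(shannon_index(rep(7, 10)), log(10), tolerance = 1e-12)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25, rep(0, 7))), 1.039721,
               tolerance = 1e-6)
  expect_error(shannon_index(rep(0, 10)), "empty")
  # invariant under class relabeling
  set.seed(2)
  cnt <- rpois(10, 20)
  expect_equal(shannon_index(cnt), shannon_index(sample(cnt)))
  # moving a tree from the fullest class to an empty one raises H
  cnt <- c(40, 10, 8, 5, 3, 2, 1, 1, 0, 0)
  cnt2 <- cnt; cnt2[1] <- cnt2[1] - 1L; cnt2[9] <- 1L
  expect_gt(shannon_index(cnt2), shannon_index(cnt))
})

test_that("Shannon agrees with an independent implementation on random stands", {
  skip_if_not_installed("vegan")
  set.seed(3)
  for (i in 1:25) {
    cnt <- rpois(10, runif(1, 1, 30))
    if (sum(cnt) == 0) next
    expect_equal(shannon_index(cnt),
                 unname(vegan::diversity(cnt, index = "shannon")),
                 tolerance = 1e-12)
  }
})

test_that("moments are the population estimators with excess kurtosis", {
  expect_equal(distribution_moments(c(-1, 0, 1))$skewness, 0)
  expect_equal(distribution_moments(c(0, 0, 0, 1))$skewness, 1.1547,
               tolerance = 1e-4)
  expect_error(distribution_moments(rep(2, 5)), "constant")
  expect_error(distribution_moments(c(1, 2)), "3")

  # textbook brute-force loop to 1e-12
  set.seed(4)
  x <- rlnorm(500)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  got <- distribution_moments(x)
  expect_equal(got$skewness, m3 / m2^1.5, tolerance = 1e-12)
  expect_equal(got$kurtosis, m4 / m2^2 - 3, tolerance = 1e-12)

  # Monte-Carlo limit: standard normal draws give ~0 skewness/excess kurtosis
  set.seed(5)
  z <- rnorm(1e6)
  mz <- distribution_moments(z)
  expect_lt(abs(mz$skewness), 0.02)
  expect_lt(abs(mz$kurtosis), 0.02)
})

test_that("pairwise stage tests behave under null, shift, and count the pairs", {
  set.seed(6)
  plots <- do.call(rbind, lapply(1:4, function(i) {
    minimal_plot(plot_id = paste0("P", i), stand_age = c(15L, 25L, 35L, 45L)[i])
  }))
  plots$n_trees <- NULL
  same <- do.call(rbind, lapply(plots$plot_id, function(p) minimal_trees(50, p)))
  res <- pairwise_stage_tests(same, plots, "dbh")
  expect_equal(nrow(res), 6L)                 # 4 stages -> 6 pairs
  expect_true(all(res$p_value > 0.9))         # identical groups

  shifted <- same
  mature <- plots$plot_id[plots$stand_age == 45L]
  idx <- shifted$plot_id == mature
  set.seed(7)
  shifted$dbh_cm <- rnorm(nrow(shifted), 10, 1)
  shifted$dbh_cm[idx] <- rnorm(sum(idx), 13, 1)
  res2 <- pairwise_stage_tests(shifted, plots, "dbh")
  expect_lt(min(res2$p_value[res2$stage_a == "mature" | res2$stage_b == "mature"]),
            1e-6)

  # stage with no trees is skipped with a warning
  sub <- same[same$plot_id != mature, ]
  expect_warning(res3 <- pairwise_stage_tests(sub, plots, "dbh"), "mature")
  expect_equal(nrow(res3), 3L)
})

test_that("the quadratic class-proportion fit matches the normal equations", {
  # proportions exactly quadratic in midpoint -> zero residuals
  edges <- dbh_class_edges()
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  q <- 0.3 - 0.02 * mid + 0.0004 * mid^2
  q <- q / sum(q)
  counts <- round(q * 1e6)
  d <- bin_dbh(rep(mid, counts))
  fc <- fit_class_proportion_curve(d)
  expect_lt(max(abs(fc$curve$fit - fc$curve$proportion)), 1e-6)

  # closed-form normal equations oracle on a random distribution
  set.seed(8)
  vals <- stats::qweibull(stats::runif(2000, 0, stats::pweibull(39, 1.8, 13)), 1.8, 13)
  d <- bin_dbh(vals)
  fc <- fit_class_proportion_curve(d)
  X <- cbind(1, mid, mid^2)
  beta <- solve(t(X) %*% X, t(X) %*% d$proportions)
  expect_equal(unname(fc$coefficients), as.numeric(beta), tolerance = 1e-10)
  expect_true(all(fc$curve$lwr <= fc$curve$fit & fc$curve$fit <= fc$curve$upr))

  # steeply decreasing proportions give a decreasing fitted curve
  dd <- bin_dbh(rep(mid, c(500, 280, 150, 80, 40, 20, 10, 5, 2, 1)))
  fcd <- fit_class_proportion_curve(dd)
  expect_true(all(diff(fcd$curve$fit[1:6]) < 0))

  expect_error(fit_class_proportion_curve(bin_dbh(c(1, 2, 3))), "3 non-empty")
})

test_that("per-group distribution summaries carry the documented columns", {
  inv <- table1_inventory(seed = 9)
  summ <- distribution_summary(inv$trees, inv$plots, "city")
  expect_named(summ, c("city", "n_trees", "skewness", "kurtosis", "shannon"))
  expect_equal(nrow(summ), 9L)
  expect_equal(sum(summ$n_trees), 3633L)
  expect_true(all(summ$shannon > 0 & summ$shannon < log(10)))
  by_stage <- distribution_summary(inv$trees, inv$plots, "stage")
  expect_true(all(by_stage$stage %in%
                    c("young", "middle", "near-mature", "mature")))
})
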