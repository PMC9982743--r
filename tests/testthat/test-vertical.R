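test_that("cut-off height follows CPS = 0.4 CL + HBLC", {
  expect_equal(cutoff_height(10, 5), 7)          # hand evaluation
  expect_equal(cutoff_height(12, 0), 12)         # no crown
  expect_equal(cutoff_height(10, 10), 4)         # full crown: 0.4 * height
  expect_equal(cutoff_height(10, 5), 10 - 0.6 * 5)
})

test_that("live crown ratio is crown length over height", {
  expect_equal(live_crown_ratio(10, 10), 1)
  expect_equal(live_crown_ratio(10, 0), 0)
  expect_equal(live_crown_ratio(10, 4.73), 0.473)
})

test_that("the hand-traced three-tree stand stratifies into 2/1", {
  tr <- data.frame(height_m = c(10, 8, 6), crown_length_m = c(5, 4, 3))
  st <- tstrat_assign(tr)
  expect_equal(st$n_strata, 2L)
  expect_equal(st$stratum, c(1L, 1L, 2L))        # founder cut-off 7 m
  expect_equal(st$cps_m, c(7, 4.2))
  expect_equal(st$summary$share_pct, c(2, 1) / 3 * 100, tolerance = 1e-12)
})

test_that("degenerate stands stratify sensibly", {
  one <- tstrat_assign(data.frame(height_m = 9, crown_length_m = 4))
  expect_equal(one$n_strata, 1L)
  expect_equal(one$summary$share_pct, 100)

  same <- tstrat_assign(data.frame(height_m = rep(7, 5), crown_length_m = rep(3, 5)))
  expect_equal(same$n_strata, 1L)
  expect_error(tstrat_assign(data.frame(height_m = numeric(0),
                                        crown_length_m = numeric(0))), "empty")
})

test_that("stratification is invariant to input order and to scaling", {
  set.seed(1)
  for (i in 1:200) {
    n <- sample(3:25, 1)
    h <- runif(n, 4, 20)
    tr <- data.frame(height_m = h, crown_length_m = runif(n, 0.2, 0.9) * h,
                     dbh_cm = runif(n, 5, 30))
    st <- tstrat_assign(tr)
    # shares sum to 100, strata contiguous from 1
    expect_equal(sum(st$summary$share_pct), 100, tolerance = 1e-9)
    expect_equal(sort(unique(st$stratum)), seq_len(st$n_strata))
    # stratum 1 holds the tallest tree
    expect_equal(st$stratum[which.max(tr$height_m)], 1L)
    # n_strata bounded by distinct heights
    expect_lte(st$n_strata, length(unique(tr$height_m)))

    perm <- sample(n)
    st_p <- tstrat_assign(tr[perm, ])
    expect_equal(st_p$stratum, st$stratum[perm])
    expect_equal(st_p$n_strata, st$n_strata)

    cs <- runif(1, 0.5, 3)
    tr_s <- tr
    tr_s$height_m <- cs * tr$height_m
    tr_s$crown_length_m <- cs * tr$crown_length_m
    st_s <- tstrat_assign(tr_s)
    expect_equal(st_s$stratum, st$stratum)
    expect_equal(st_s$cps_m, cs * st$cps_m, tolerance = 1e-12)
  }
})

test_that("adding a tree below every cut-off leaves existing assignments alone", {
  set.seed(2)
  for (i in 1:50) {
    n <- sample(4:15, 1)
    h <- runif(n, 8, 20)
    tr <- data.frame(height_m = h, crown_length_m = runif(n, 0.2, 0.8) * h)
    st <- tstrat_assign(tr)
    short <- data.frame(height_m = min(st$cps_m) * 0.5,
                        crown_length_m = min(st$cps_m) * 0.2)
    st2 <- tstrat_assign(rbind(tr, short))
    expect_equal(st2$stratum[seq_len(n)], st$stratum)
  }
})

test_that("two-cohort stands report two strata and pooled means match brute force", {
  make_two_cohort <- function(seed) {
    set.seed(seed)
    # tall cohort compact relative to its founder's cut-off
    # (cut-off <= 20 - 0.6*4 = 17.6 < 18, so the whole cohort joins)
    tall <- data.frame(height_m = runif(15, 18, 20),
                       crown_length_m = runif(15, 4, 5),
                       dbh_cm = runif(15, 18, 25))
    # understory strictly below every tall cut-off (>= 20 - 0.6*5 = 17) but
    # compact enough that its own founder's cut-off (<= 8 - 0.6*2.5 = 6.5)
    # keeps it in a single second stratum
    under <- data.frame(height_m = runif(5, 7.5, 8),
                        crown_length_m = runif(5, 2.5, 3),
                        dbh_cm = runif(5, 5, 8))
    rbind(tall, under)
  }
  stands <- lapply(1:6, make_two_cohort)
  results <- lapply(stands, tstrat_assign)
  expect_true(all(vapply(results, function(r) r$n_strata, integer(1)) == 2L))

  summ <- population_layer_summary(results, stands)
  expect_equal(unname(summ$plots_by_n_strata["2"]), 6L)
  # brute-force pooled dominant-layer means
  dom <- do.call(rbind, Map(function(r, s) s[r$stratum == 1, ], results, stands))
  expect_equal(summ$dominant_share_pct, 100 * nrow(dom) / sum(sapply(stands, nrow)))
  expect_equal(summ$dominant_mean_height_m, mean(dom$height_m), tolerance = 1e-12)
  expect_equal(summ$dominant_mean_dbh_cm, mean(dom$dbh_cm), tolerance = 1e-12)
  expect_equal(summ$dominant_mean_crown_length_m, mean(dom$crown_length_m),
               tolerance = 1e-12)
})

test_that("single-stratum plots give a 100% dominant layer", {
  stands <- lapply(1:4, function(i) {
    set.seed(i)
    data.frame(height_m = runif(10, 18, 19), crown_length_m = runif(10, 8, 9))
  })
  results <- lapply(stands, tstrat_assign)
  summ <- population_layer_summary(results, stands)
  expect_equal(summ$dominant_share_pct, 100)
  expect_true(is.na(summ$multilayer_mean_dominant_share_pct))
})

test_that("stratify_inventory annotates every tree with its stratum", {
  inv <- table1_inventory(seed = 10)
  strat <- stratify_inventory(inv$trees, inv$plots)
  expect_equal(nrow(strat$per_tree), nrow(inv$trees))
  expect_true(all(strat$per_tree$stratum >= 1))
  expect_equal(length(strat$results), 31L)
  expect_gt(strat$layer_summary$dominant_share_pct, 50)
})
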