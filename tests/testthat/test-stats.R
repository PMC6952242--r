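phantom_task <- function(size, axis) {
  sprintf("low scatter cyst %g mm %s diameter", size, axis)
}

rec <- function(user, tool, dataset, measurement, value, valid = TRUE) {
  tibble::tibble(user = user, tool = tool, dataset = dataset,
                 measurement = measurement, value_mm = value, valid = valid)
}

test_that("phantom summaries report mean, sample SD and error against truth", {
  recs <- dplyr::bind_rows(
    rec(c("u1", "u2"), "A", "phantom", phantom_task(10, "H"), c(10.3, 10.3)),
    rec(c("u1", "u2"), "B", "phantom", phantom_task(10, "H"), c(9.0, 10.0)),
    rec(c("u1", "u2"), "A", "phantom", phantom_task(4, "V"), c(2.8, 3.6)),
    rec("u1", "B", "phantom", phantom_task(4, "V"), 3.9)
  )
  s <- summarize_phantom(recs)
  cell <- function(size, axis, tool) {
    dplyr::filter(s, size_mm == size, axis == !!axis, tool == !!tool)
  }
  # identical values: SD exactly zero (representable, not NA)
  expect_equal(cell(10, "H", "A")$mean_mm, 10.3)
  expect_identical(cell(10, "H", "A")$sd_mm, 0)
  # hand-computed cell: mean 3.2, SD sqrt(0.32), error 0.8
  expect_equal(cell(4, "V", "A")$mean_mm, 3.2)
  expect_equal(cell(4, "V", "A")$sd_mm, sqrt(0.32), tolerance = 1e-12)
  expect_equal(cell(4, "V", "A")$error_mm, 0.8, tolerance = 1e-12)
  # single record: SD undefined
  expect_true(is.na(cell(4, "V", "B")$sd_mm))
  # best-accuracy / best-precision flags per row
  expect_true(cell(4, "V", "B")$best_accuracy)   # |3.9 - 4| < |3.2 - 4|
  expect_false(cell(4, "V", "A")$best_accuracy)
  expect_true(cell(10, "H", "A")$best_precision) # SD 0 beats SD 0.707
  # invalid records are excluded
  recs2 <- dplyr::bind_rows(recs, rec("u3", "A", "phantom",
                                      phantom_task(10, "H"), 99, valid = FALSE))
  expect_equal(summarize_phantom(recs2), s)
})

test_that("agreement summarises paired differences against the reference", {
  recs <- dplyr::bind_rows(
    rec(c("u1", "u2"), "T", "d1", "m1", c(10, 12)),
    rec(c("u1", "u2"), "R", "d1", "m1", c(11, 11))
  )
  ag <- agreement(recs, "T", "R")
  expect_identical(ag$n_pairs, 2L)
  expect_equal(ag$mean_diff_mm, 0)
  expect_equal(ag$sd_diff_mm, sqrt(2), tolerance = 1e-12)
  expect_identical(ag$n_within_threshold, 2L)
  # constant reference: regression flagged degenerate
  expect_true(ag$degenerate)
  expect_true(is.na(ag$slope))

  # the threshold count uses strict inequality
  recs2 <- dplyr::bind_rows(
    rec(c("u1", "u2"), "T", "d1", "m1", c(12, 13)),
    rec(c("u1", "u2"), "R", "d1", "m1", c(10, 10))
  )
  expect_identical(agreement(recs2, "T", "R")$n_within_threshold, 0L)
})

test_that("agreement matches brute-force recomputation on random pairs", {
  set.seed(71)
  n <- 40L
  ref_vals <- runif(n, 10, 50)
  tool_vals <- ref_vals + rnorm(n)
  recs <- dplyr::bind_rows(
    rec(sprintf("u%d", 1:n), "T", "d", "m", tool_vals),
    rec(sprintf("u%d", 1:n), "R", "d", "m", ref_vals)
  )
  ag <- agreement(recs, "T", "R")
  d <- tool_vals - ref_vals
  expect_equal(ag$mean_diff_mm, brute_mean(d), tolerance = 1e-12)
  expect_equal(ag$sd_diff_mm, brute_sd(d), tolerance = 1e-12)
  expect_identical(ag$n_within_threshold, sum(abs(d) < 2))
  # OLS slope/intercept from the closed-form normal equations
  sl <- sum((ref_vals - mean(ref_vals)) * (tool_vals - mean(tool_vals))) /
    sum((ref_vals - mean(ref_vals))^2)
  expect_equal(ag$slope, sl, tolerance = 1e-9)
  expect_equal(ag$intercept, mean(tool_vals) - sl * mean(ref_vals), tolerance = 1e-9)

  # unpaired and invalid records are dropped and counted
  extra <- dplyr::bind_rows(recs, rec("u99", "T", "d", "m", 30),
                            rec("u1", "T", "d", "m2", 5, valid = FALSE))
  ag2 <- agreement(extra, "T", "R")
  expect_identical(ag2$n_pairs, n)
  expect_identical(ag2$n_dropped, 1L)
})

test_that("paired t-test matches the closed form and stats::t.test", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 2, 4, 4, 6)
  res <- paired_ttest(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_identical(res$df, 4L)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  expect_equal(res$mean_a, 3); expect_equal(res$sd_a, sd(a))

  set.seed(72)
  x <- rnorm(95, 28, 14); y <- x + rnorm(95, -0.5, 2)
  res2 <- paired_ttest(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_identical(res2$df, 94L)
  expect_equal(res2$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res2$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("degenerate paired t-tests are reported, not crashed", {
  res <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_true(res$no_variation)
  expect_true(is.na(res$t))
  expect_true(is.na(res$p_value))

  res2 <- paired_ttest(c(2, 3, 4), c(1, 2, 3))
  expect_true(res2$no_variation)
  expect_identical(res2$t, Inf)
  expect_identical(res2$p_value, 0)

  expect_error(paired_ttest(1, 2), class = "caliper3d_empty_error")
})

test_that("intra-user variability follows the cross-tool mean definition", {
  # one instance, tools 10/12/14: diffs -2/0/+2, single diff per tool -> NA
  one <- dplyr::bind_rows(
    rec("u1", "A", "d1", "m1", 10),
    rec("u1", "B", "d1", "m1", 12),
    rec("u1", "C", "d1", "m1", 14)
  )
  v <- intra_user_variability(one)
  expect_true(all(is.na(v$sd_mm)))
  expect_identical(v$n, rep(1L, 3))

  # two instances engineered so tool A's diffs are -2 and 0 -> SD sqrt(2)
  two <- dplyr::bind_rows(
    rec("u1", "A", "d1", "m1", 10), rec("u1", "B", "d1", "m1", 14),
    rec("u1", "A", "d1", "m2", 20), rec("u1", "B", "d1", "m2", 20)
  )
  v2 <- intra_user_variability(two)
  expect_equal(v2$sd_mm[v2$tool == "A"], sqrt(2), tolerance = 1e-12)

  # all tools identical everywhere -> all SDs zero
  same <- dplyr::bind_rows(
    rec("u1", c("A", "B"), "d1", "m1", 10),
    rec("u1", c("A", "B"), "d1", "m2", 25)
  )
  expect_true(all(intra_user_variability(same)$sd_mm == 0))

  # single-tool instances are excluded and counted
  lonely <- dplyr::bind_rows(two, rec("u1", "A", "d9", "m9", 50))
  v3 <- intra_user_variability(lonely)
  expect_identical(attr(v3, "n_excluded"), 1L)
  expect_identical(v3$n[v3$tool == "A"], 2L)
})

test_that("coarser display precision does not reduce difference SDs in expectation", {
  plan <- default_truth(build_session_plan())
  sds <- vapply(1:30, function(seed) {
    fine <- tool_models(c("T", "R"), sigma_mm = 0.5, precision_mm = 0.1)
    coarse <- tool_models(c("T", "R"), sigma_mm = 0.5, precision_mm = c(1, 0.1))
    c(agreement(simulate_observer(plan, tools = fine, seed = seed), "T", "R")$sd_diff_mm,
      agreement(simulate_observer(plan, tools = coarse, seed = seed), "T", "R")$sd_diff_mm)
  }, numeric(2))
  expect_gte(mean(sds[2, ]), mean(sds[1, ]))
})

test_that("tidiers and evaluation wrapper expose the study results", {
  plan <- default_truth(build_session_plan())
  recs <- simulate_observer(plan, seed = 8, omit_n = 5, omit_tool = "QLAB")
  ev <- evaluate_study(recs)
  expect_named(ev$ttests, c("Tomtec", "VR"))
  td <- tidy(ev)
  expect_identical(nrow(td), 2L)
  expect_true(all(c("mean.diff", "sd.diff", "statistic", "p.value", "df") %in% names(td)))
  expect_identical(td$df, c(124L, 124L))

  g <- glance(ev$ttests$VR)
  expect_identical(g$parameter, 124L)
  expect_s3_class(tidy(ev$agreement$VR), "tbl_df")
  # plots build without error
  expect_s3_class(autoplot(ev$agreement$VR), "ggplot")
  expect_s3_class(autoplot(ev$phantom_summary), "ggplot")
  expect_s3_class(autoplot(ev$intra_user), "ggplot")
})
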