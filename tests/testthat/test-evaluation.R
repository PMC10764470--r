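make_toy_masks <- function() {
  truth <- matrix(FALSE, 4, 4)
  truth[1:2, 1:2] <- TRUE                    # 4 true pixels
  pred <- matrix(FALSE, 4, 4)
  pred[1, 1] <- pred[1, 2] <- pred[2, 1] <- TRUE  # 3 of the 4
  pred[4, 4] <- pred[4, 3] <- TRUE                # 2 outside
  list(pred = pred, truth = truth)
}

test_that("FP/FN percentages match hand counts on the 4x4 fixture", {
  tm <- make_toy_masks()
  e <- fp_fn_percent(tm$pred, tm$truth)
  expect_equal(unname(e), c(50, 25))
  expect_equal(mean_error(e[["fp_pct"]], e[["fn_pct"]]), 37.5)

  # perfect prediction and total miss
  expect_equal(unname(fp_fn_percent(tm$truth, tm$truth)), c(0, 0))
  empty <- tm$truth & FALSE
  expect_equal(unname(fp_fn_percent(empty, tm$truth)), c(0, 100))

  # FP can exceed 100% of the true area
  big <- matrix(TRUE, 4, 4)
  expect_gt(fp_fn_percent(big, tm$truth)[["fp_pct"]], 100)

  expect_error(fp_fn_percent(tm$pred, empty), "denominator")
  expect_error(fp_fn_percent(matrix(TRUE, 2, 2), tm$truth), "shapes")
})

test_that("metrics are invariant under simultaneous mirroring of both masks", {
  set.seed(2)
  pred <- matrix(runif(30 * 20) < 0.3, 30, 20)
  truth <- matrix(runif(30 * 20) < 0.3, 30, 20)
  truth[1, 1] <- TRUE
  e1 <- fp_fn_percent(pred, truth)
  e2 <- fp_fn_percent(pred[, 20:1], truth[, 20:1])
  expect_equal(e1, e2)
  # but asymmetric in its arguments
  expect_false(isTRUE(all.equal(unname(fp_fn_percent(pred, truth)),
                                unname(fp_fn_percent(truth, pred)))))
})

test_that("per-image mean reproduces the published worked arithmetic", {
  expect_equal(round(mean_error(7.92, 16.97), 2), 12.45)
  expect_equal(mean_error(0, 0), 0)
})

test_that("aggregation produces the Left/Right/Both x FP/FN/Mean table", {
  recs <- rbind(eval_record("a", "L", 10, 20),
                eval_record("b", "R", 30, 40))
  tab <- aggregate_eval(recs)
  expect_equal(tab$side, rep(c("Left", "Right", "Both"), each = 3))
  expect_equal(tab$metric, rep(c("FP", "FN", "Mean"), 3))
  both <- tab[tab$side == "Both", ]
  expect_equal(both$value[both$metric == "FP"], 20)
  expect_equal(both$value[both$metric == "FN"], 30)
  expect_equal(both$value[both$metric == "Mean"], 25)
  expect_equal(unique(both$n), 2)

  # singleton group equals the record
  tab1 <- aggregate_eval(recs[1, ])
  expect_equal(tab1$value[tab1$side == "Both"], c(10, 20, 15))

  # two methods: one block per method per side, and linearity of "Both"
  recs2 <- rbind(eval_record("a", "L", 10, 20, method = "m1"),
                 eval_record("a2", "R", 14, 22, method = "m1"),
                 eval_record("b", "L", 30, 40, method = "m2"))
  tab2 <- aggregate_eval(recs2, group_by = "method")
  expect_setequal(unique(tab2$method), c("m1", "m2"))
  m1 <- tab2[tab2$method == "m1", ]
  left_fp <- m1$value[m1$side == "Left" & m1$metric == "FP"]
  right_fp <- m1$value[m1$side == "Right" & m1$metric == "FP"]
  both_fp <- m1$value[m1$side == "Both" & m1$metric == "FP"]
  nl <- m1$n[m1$side == "Left"][1]; nr <- m1$n[m1$side == "Right"][1]
  expect_equal(both_fp, (left_fp * nl + right_fp * nr) / (nl + nr))

  expect_error(aggregate_eval(recs, group_by = "bmi"), "unknown group key")
})

test_that("the record constructor enforces the mean identity", {
  r <- eval_record("x", "L", 7.92, 16.97)
  expect_equal(r$mean_pct, (7.92 + 16.97) / 2)
  expect_error(eval_record("x", "L", -1, 10))
  expect_error(eval_record("x", "L", 10, 120))
})

test_that("two-sample Z matches the closed-form oracle and its symmetries", {
  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  # closed form: means 2.5/4.5, unbiased variances 5/3 each
  z_expected <- (2.5 - 4.5) / sqrt((5 / 3) / 4 + (5 / 3) / 4)
  zt <- two_sample_z(a, b)
  expect_equal(zt$z, z_expected, tolerance = 1e-5)
  expect_equal(zt$z, -2.19089, tolerance = 1e-4)
  expect_equal(zt$p_two_sided, 2 * pnorm(z_expected), tolerance = 1e-10)
  expect_lt(abs(zt$p_two_sided - 0.0285), 1e-3)

  # identical samples: z = 0, p = 1
  z0 <- two_sample_z(a, a)
  expect_equal(z0$z, 0)
  expect_equal(z0$p_two_sided, 1)

  # swapped samples negate z, preserve p
  zs <- two_sample_z(b, a)
  expect_equal(zs$z, -zt$z)
  expect_equal(zs$p_two_sided, zt$p_two_sided)

  # zero-variance sentinels
  expect_identical(two_sample_z(c(1, 1), c(2, 2))$z, -Inf)
  expect_equal(two_sample_z(c(1, 1), c(2, 2))$p_two_sided, 0)
  expect_equal(two_sample_z(c(1, 1), c(1, 1))$z, 0)
})

test_that("Welch t matches hand computation and stats::t.test", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  tt <- two_sample_t(a, b)
  expect_equal(tt$t, -1.22474, tolerance = 1e-4)
  expect_equal(tt$df, 4, tolerance = 1e-10)
  expect_equal(tt$p_two_sided, 0.2879, tolerance = 1e-3)

  # dual route: agree with stats::t.test on random data
  set.seed(77)
  for (i in 1:5) {
    x <- rnorm(sample(5:20, 1)); y <- rnorm(sample(5:20, 1), 0.5)
    ref <- t.test(x, y)
    mine <- two_sample_t(x, y)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-8)
    expect_equal(mine$p_two_sided, ref$p.value, tolerance = 1e-10)
  }

  expect_equal(two_sample_t(a, a)$t, 0)
  expect_equal(two_sample_t(a, a)$p_two_sided, 1)
})

test_that("left/right phantom areas separate under a 10% inflation", {
  # mirrors the cohort design: right wedges ~10% larger in area
  specs <- generate_cohort(200, seed = 31, render = FALSE)
  areas <- vapply(specs, analytic_wedge_area, numeric(1))
  sides <- vapply(specs, function(s) s$side, character(1))
  tt <- two_sample_t(areas[sides == "L"], areas[sides == "R"])
  expect_lt(tt$p_two_sided, 0.001)
  expect_lt(tt$t, 0)
})
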