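test_that("confusion counts match a brute-force tally", {
  withr::with_seed(1, {
    true <- sample(0:2, 300, replace = TRUE)
    pred <- sample(0:2, 300, replace = TRUE)
  })
  cm <- confusion(true, pred)
  for (i in 0:2) for (j in 0:2) {
    expect_equal(cm$table[as.character(i), as.character(j)],
                 sum(true == i & pred == j))
  }
  # perfect predictions: no off-diagonal mass
  cmp <- confusion(true, true)
  expect_equal(sum(cmp$table) - sum(diag(cmp$table)), 0)
  b <- binary_counts <- nirspain:::binary_counts(cmp)
  expect_equal(b$fp + b$fn, 0)
  expect_error(confusion(c(0, 5), c(0, 1)), "codes")
  expect_error(confusion(0:1, 0:2), "equal length")
})

test_that("metric panel implements the standard definitions", {
  # all-majority predictor at low prevalence: sens 0, spec 1, PLR flagged
  true <- rep(c(1L, 0L), c(132, 868))
  pred <- rep(0L, 1000)
  rep1 <- metrics(confusion(true, pred))
  expect_equal(rep1$sensitivity, 0)
  expect_equal(rep1$specificity, 1)
  expect_true(is.infinite(rep1$plr) || is.nan(rep1$plr))
  expect_true("plr_infinite" %in% rep1$flags)
  # perfect classifier
  rep2 <- metrics(confusion(true, true))
  expect_equal(rep2$accuracy, 1)
  expect_equal(rep2$kappa, 1)
  # published operating points reproduce the printed PLRs
  expect_equal(round(0.326 / (1 - 0.861), 2), 2.35)
  r3 <- metrics(reconstruct_from_summary(0.326, 0.861, 0.2))
  expect_equal(round(r3$plr, 2), 2.35)
  r4 <- metrics(reconstruct_from_summary(0.409, 0.801, 0.2))
  expect_equal(round(r4$plr, 2), 2.06)
})

test_that("summary reconstruction recovers the published derived cells", {
  prev <- 23900 / 180580
  rep <- metrics(reconstruct_from_summary(0.326, 0.861, prev, n = 180580))
  expect_equal(round(rep$kappa, 2), 0.17)
  expect_equal(round(rep$npv, 3), 0.893)
  # chance agreement: sens = spec = prev = 0.5 gives kappa 0
  rep0 <- metrics(reconstruct_from_summary(0.5, 0.5, 0.5))
  expect_equal(rep0$kappa, 0, tolerance = 1e-12)
  expect_error(reconstruct_from_summary(1.2, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("metric identities hold for random reconstructions", {
  withr::with_seed(8, {
    for (i in 1:25) {
      sens <- runif(1, 0.05, 0.95)
      spec <- runif(1, 0.05, 0.95)
      prev <- runif(1, 0.05, 0.95)
      rep <- metrics(reconstruct_from_summary(sens, spec, prev))
      expect_equal(rep$plr * (1 - rep$specificity), rep$sensitivity,
                   tolerance = 1e-12)
      expect_equal(rep$accuracy, prev * sens + (1 - prev) * spec,
                   tolerance = 1e-12)
    }
  })
})

test_that("kappa stays near zero under random labels", {
  withr::with_seed(13, {
    kaps <- replicate(20, {
      true <- sample(0:1, 4000, replace = TRUE)
      pred <- sample(0:1, 4000, replace = TRUE)
      metrics(confusion(true, pred))$kappa
    })
  })
  # binomial-scale bound: sd(kappa) ~ 1/sqrt(n)
  expect_lt(max(abs(kaps)), 3 / sqrt(4000) + 3 * sd(kaps))
  expect_lt(abs(mean(kaps)), 0.02)
})

test_that("fold assignment partitions cubes under every mode", {
  hb <- hb_timeseries("s1", array(1, c(140, 40, 2)))
  truth <- list(state = integer(140), trial_index = rep(1:10, each = 14))
  set <- make_type1_cubes(hb, truth)  # 101 cubes
  set$anchors <- set$anchors[1:100, ]
  plan <- cv_plan(10, "sample-shuffled", seed = 2)
  folds <- nirspain:::assign_folds(set, plan)
  expect_equal(unname(table(folds)), rep(10L, 10), ignore_attr = TRUE)
  tb <- nirspain:::assign_folds(set, cv_plan(5, "trial-blocked", seed = 2))
  split_tab <- table(set$anchors$trial, tb)
  expect_true(all(rowSums(split_tab > 0) == 1L))  # no trial spans folds
  expect_error(nirspain:::assign_folds(set, cv_plan(11, "trial-blocked")),
               ">= 11 groups")
})

test_that("published operating-point table is self-consistent where stated", {
  checked <- check_operating_points()
  # recomputed PLR within printing precision for self-consistent rows
  ok <- checked[checked$self_consistent, ]
  expect_gte(nrow(ok), 7L)
  expect_true(all(abs(ok$plr_recomputed - ok$plr) <= 0.01))
  # rows whose printed PLR disagrees with recomputation by one printing
  # unit are flagged, not silently accepted
  flagged <- checked[!checked$self_consistent, ]
  expect_true(all(round(flagged$plr_recomputed, 2) != flagged$plr))
})
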