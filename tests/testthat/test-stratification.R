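test_that("threshold_table matches hand-counted confusion tables", {
  tt <- threshold_table(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(tt$threshold, c(1, 2, 3, 4, 5))
  r3 <- tt[tt$threshold == 3, ]
  expect_equal(unlist(r3[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))
  r2 <- tt[tt$threshold == 2, ]  # TP=2 FP=1 TN=1 FN=0
  expect_equal(unlist(r2[c("tp", "fp", "tn", "fn")]),
               c(tp = 2, fp = 1, tn = 1, fn = 0))
  expect_equal(r2$sensitivity, 1)
  expect_equal(r2$specificity, 0.5)
  expect_equal(r2$ppv, 2 / 3)
  expect_equal(r2$npv, 1)
  # sentinel row: empty high-risk group
  rs <- tt[nrow(tt), ]
  expect_equal(rs$sensitivity, 0)
  expect_equal(rs$specificity, 1)
  expect_true(is.na(rs$ppv))
  expect_equal(rs$highrisk_frequency, 0)
})

test_that("threshold_table agrees with exhaustive enumeration for n <= 12", {
  set.seed(71)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    sc <- sample(0:5, n, replace = TRUE)
    st <- c(0, 1, sample(0:1, n - 2, replace = TRUE))  # both classes present
    tt <- threshold_table(sc, st)
    for (i in seq_len(nrow(tt))) {
      o <- oracle_confusion(sc, st, tt$threshold[i])
      expect_equal(unlist(tt[i, c("tp", "fp", "tn", "fn")]),
                   c(tp = o$tp, fp = o$fp, tn = o$tn, fn = o$fn))
      expect_equal(tt$sensitivity[i], o$sens)
      expect_equal(tt$specificity[i], o$spec)
      expect_equal(tt$ppv[i], o$ppv)
      expect_equal(tt$npv[i], o$npv)
      expect_equal(tt$highrisk_frequency[i], o$q)
    }
    # monotone structure down the table
    expect_true(all(diff(tt$sensitivity) <= 0))
    expect_true(all(diff(tt$specificity) >= 0))
  }
})

test_that("bookkeeping and ratio-law identities hold on every row", {
  set.seed(72)
  for (rep in 1:10) {
    n <- 500
    sc <- rpois(n, 8)
    st <- rbinom(n, 1, 0.3)
    tt <- threshold_table(sc, st)
    n1 <- sum(st); n0 <- n - n1
    expect_true(all(tt$tp + tt$fn == n1))
    expect_true(all(tt$fp + tt$tn == n0))
    # sens * (#affected) = ppv * (#flagged) = TP, exactly
    flagged <- tt$tp + tt$fp
    has <- flagged > 0
    expect_equal(tt$sensitivity[has] * n1, tt$ppv[has] * flagged[has])
    # NPV analogue
    unflagged <- tt$tn + tt$fn
    hasu <- unflagged > 0
    expect_equal(tt$specificity[hasu] * n0, tt$npv[hasu] * unflagged[hasu])
    # ratio law sens/ppv = q-hat/p-hat, in cross-multiplied form so the
    # TP = 0 rows (0/0) are covered too
    expect_equal(tt$sensitivity[has] * (n1 / n),
                 tt$ppv[has] * tt$highrisk_frequency[has])
  }
})

test_that("threshold_table validates inputs", {
  expect_error(threshold_table(1:4, c(1, 1, 1, 1)), "both affected")
  expect_error(threshold_table(1:4, c(0, 1, 2, 0)), "binary")
  expect_error(threshold_table(1:4, c(0, 1)), "equal length")
})

test_that("auc matches enumeration, the trapezoid oracle, and is tie- and transform-invariant", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(auc(c(1, 2, 1, 2), c(0, 1, 1, 0))$auc, 0.5)
  expect_equal(auc(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc, 0.75)

  set.seed(73)
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    sc <- sample(0:6, n, replace = TRUE)  # heavy ties
    st <- c(0, 1, rbinom(n - 2, 1, 0.4))
    a <- auc(sc, st)$auc
    expect_equal(a, oracle_trapezoid_auc(sc, st), tolerance = 1e-12)
    # invariance under a strictly monotone transform
    expect_equal(auc(exp(sc / 2) + 1, st)$auc, a, tolerance = 1e-12)
  }
})

test_that("confidence intervals are well-formed and DeLong shrinks with n", {
  set.seed(74)
  sc <- rnorm(400) + rep(c(0, 1), each = 200)
  st <- rep(c(0, 1), each = 200)
  for (method in c("delong", "hanley")) {
    r <- auc(sc, st, ci_method = method)
    expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
    expect_true(r$ci_low >= 0 && r$ci_high <= 1)
  }
  small <- auc(sc[c(1:40, 201:240)], st[c(1:40, 201:240)])
  expect_gt(small$se, auc(sc, st)$se)
  expect_error(auc(1:4, c(1, 1, 1, 1)), "both affected")
})

test_that("threshold_for_group_frequency picks the nearest achievable group", {
  # exact quantile achievable with distinct scores
  r <- threshold_for_group_frequency(1:10, 0.10)
  expect_equal(r$threshold, 10)
  expect_equal(r$achieved_q, 0.10)
  # candidates give q in {1, 0.25, 0}; nearest to 0.5 is 0.25
  r2 <- threshold_for_group_frequency(c(1, 1, 1, 2), 0.5)
  expect_equal(r2$threshold, 2)
  expect_equal(r2$achieved_q, 0.25)
  # exactly achievable step returns it
  r3 <- threshold_for_group_frequency(c(1, 2, 3, 4), 0.75)
  expect_equal(r3$achieved_q, 0.75)
  expect_equal(r3$threshold, 2)
  expect_error(threshold_for_group_frequency(1:4, 0), "target_q")
})

test_that("metrics_vs_group_frequency re-indexes by q with the expected endpoints", {
  set.seed(75)
  sc <- rbinom(600, 20, 0.4)
  st <- rbinom(600, 1, plogis(sc - 8))
  tt <- threshold_table(sc, st)
  mv <- metrics_vs_group_frequency(tt)
  expect_true(all(diff(mv$highrisk_frequency) >= 0))
  # flag everyone: sensitivity 1, PPV = empirical disease frequency
  full <- mv[mv$highrisk_frequency == 1, ]
  expect_equal(full$sensitivity, 1)
  expect_equal(full$ppv, mean(st))
  # empty group: sensitivity 0
  expect_equal(mv$sensitivity[mv$highrisk_frequency == 0], 0)
  # |sens - ppv| is minimal where q is nearest the empirical disease frequency
  has <- !is.na(mv$ppv)
  i_min <- which.min(abs(mv$sensitivity[has] - mv$ppv[has]))
  i_q <- which.min(abs(mv$highrisk_frequency[has] - mean(st)))
  expect_equal(i_min, i_q)
})
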