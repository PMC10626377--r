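mk_bli <- function(ids, arm, weeks, radiance_fn) {
  do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(mouse_id = ids[i], arm = arm, week = weeks,
               radiance = radiance_fn(i, weeks), stringsAsFactors = FALSE)
  }))
}

test_that("fold_change is 1 at baseline and ratios elsewhere", {
  bli <- mk_bli("m1", "NT", 3:7, function(i, w) 1e6 * 2^(w - 3))
  fc <- fold_change(bli, baseline_week = 3)
  expect_equal(fc$fold_change, c(1, 2, 4, 8, 16))

  const <- mk_bli("m2", "NT", 3:6, function(i, w) rep(5e5, length(w)))
  expect_equal(fold_change(const, 3)$fold_change, rep(1, 4))

  # invariant under global rescaling of the radiance unit
  bli2 <- bli; bli2$radiance <- bli2$radiance * 1e3
  expect_equal(fold_change(bli2, 3)$fold_change, fc$fold_change)

  expect_error(fold_change(bli[bli$week != 3, ], 3), "baseline")
})

test_that("group_radiance_summary masks weeks with too few survivors", {
  set.seed(2)
  bli <- rbind(mk_bli(paste0("a", 1:10), "Ac", 3:8, function(i, w) exp(w + i / 10)),
               mk_bli(paste0("n", 1:4), "NT", 3:8, function(i, w) exp(w)))
  g <- group_radiance_summary(bli, min_alive = 5)
  expect_false(any(g$masked[g$arm == "Ac"]))
  expect_true(all(g$masked[g$arm == "NT"]))
  expect_true(all(is.na(g$mean[g$masked])))
  # never a mean computed from fewer than min_alive values
  expect_true(all(g$n[!g$masked] >= 5))
  # unmasked weeks are nonincreasing in min_alive
  n_unmasked <- vapply(1:6, function(m) {
    sum(!group_radiance_summary(bli, min_alive = m)$masked)
  }, numeric(1))
  expect_true(all(diff(n_unmasked) <= 0))
})

test_that("anova_bonferroni matches hand/oneway.test computation", {
  res <- anova_bonferroni(list(A = c(1, 2, 3), B = c(4, 5, 6)))
  # hand: SSB = 13.5, SSW = 4, F = 13.5 / 1 = 13.5 on (1, 4) df
  expect_equal(res$f_statistic, 13.5, tolerance = 1e-12)
  ow <- oneway.test(v ~ g, data = data.frame(v = 1:6, g = rep(c("A", "B"), each = 3)),
                    var.equal = TRUE)
  expect_equal(res$p_overall, ow$p.value, tolerance = 1e-12)
  # single contrast: no multiplicity penalty
  expect_equal(res$contrasts$p_adjusted, min(1, 1 * res$contrasts$p_raw))

  # Bonferroni multiplies by the number of contrasts, clipped at 1
  set.seed(9)
  vals <- list(A = rnorm(6), B = rnorm(6), C = rnorm(6))
  r3 <- anova_bonferroni(vals)
  expect_identical(nrow(r3$contrasts), 3L)
  expect_equal(r3$contrasts$p_adjusted, pmin(1, 3 * r3$contrasts$p_raw))

  # three identical arms: degenerate convention p = 1
  same <- anova_bonferroni(list(A = c(2, 2), B = c(2, 2), C = c(2, 2)))
  expect_identical(same$p_overall, 1)
  expect_true(all(same$contrasts$p_adjusted == 1))
})

test_that("km_estimate: step curve, medians and not-reached", {
  rec <- data.frame(mouse_id = paste0("m", 1:10), arm = "NT",
                    time = rep(8.3, 10), event = 1)
  km <- km_estimate(rec)
  expect_equal(km$medians$median, 8.3)

  # KM curve is a nonincreasing step function starting at 1
  rec2 <- data.frame(mouse_id = paste0("x", 1:8), arm = "A",
                     time = c(2, 3, 3, 5, 6, 8, 9, 12),
                     event = c(1, 1, 0, 1, 1, 0, 1, 1))
  km2 <- km_estimate(rec2)
  s <- summary(km2$fit, censored = TRUE)$surv
  expect_lte(max(s), 1)
  expect_true(all(diff(s) <= 1e-12))

  # all-censored arm alongside an arm with events: median not reached
  rec3 <- rbind(rec2,
                data.frame(mouse_id = paste0("c", 1:5), arm = "B",
                           time = rep(20, 5), event = 0))
  km3 <- km_estimate(rec3)
  expect_true(is.na(km3$medians$median[km3$medians$arm == "B"]))
  expect_error(km_estimate(rec3[rec3$event == 0, ]), "at least one event")
})

test_that("km median matches the exponential closed form at large n", {
  set.seed(123)
  lam <- log(2) / 14.6
  rec <- data.frame(mouse_id = seq_len(1e4), arm = "A",
                    time = stats::rexp(1e4, lam), event = 1)
  med <- km_estimate(rec)$medians$median
  expect_lt(abs(med / 14.6 - 1), 0.02)
})

test_that("logrank matches the hand-computed O-E/V table", {
  # arm A events {1, 2}; arm B events {3, 4}:
  # t=1: E_A = 1/2, V = 1/4; t=2: E_A = 1/3, V = 2/9; t=3: n_A = 0.
  # chi^2 = (2 - 5/6)^2 / (1/4 + 2/9) = 2.88235...
  rec <- data.frame(mouse_id = paste0("m", 1:4), arm = rep(c("A", "B"), each = 2),
                    time = 1:4, event = 1)
  lr <- logrank(rec, c("A", "B"))
  expect_equal(lr$statistic, (2 - 5 / 6)^2 / (1 / 4 + 2 / 9), tolerance = 1e-9)
  expect_equal(lr$p, pchisq(lr$statistic, 1, lower.tail = FALSE))

  # identical event times in both arms -> statistic 0, p 1
  rec2 <- data.frame(mouse_id = paste0("m", 1:6), arm = rep(c("A", "B"), 3),
                     time = rep(c(2, 5, 9), each = 2), event = 1)
  lr2 <- logrank(rec2, c("A", "B"))
  expect_equal(lr2$statistic, 0, tolerance = 1e-12)
  expect_equal(lr2$p, 1, tolerance = 1e-12)

  # invariant under label exchange
  lr_ab <- logrank(rec, c("A", "B")); lr_ba <- logrank(rec, c("B", "A"))
  expect_equal(lr_ab$p, lr_ba$p)

  expect_error(logrank(rec, c("A", "Z")), "empty arm")
})
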