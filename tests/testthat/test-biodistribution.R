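test_that("decay_correct applies the half-life factor exactly", {
  expect_identical(decay_correct(10, 160.8, 0), 10)
  expect_equal(decay_correct(10, 42, 42), 20)
  expect_equal(decay_correct(10, 42, -42), 5)
  # the 24-h delayed Ac-225 counting correction
  expect_equal(decay_correct(1, 237.6, 24), 2^(24 / 237.6), tolerance = 1e-12)
  expect_equal(2^(24 / 237.6), 1.0725, tolerance = 1e-4)
  expect_error(decay_correct(10, -1, 0), "half_life")
})

test_that("quantify_samples recovers %IA and %IA/g", {
  # activity equal to injected, 1 g, no delay -> 100 %IA and 100 %IA/g
  s <- biodist_row(measured_activity = 1000, sample_mass = 1,
                   injected_activity = 1000, time_pi = 0, count_time = 0)
  q <- quantify_samples(s, "177Lu")
  expect_equal(q$pct_ia, 100)
  expect_equal(q$pct_ia_per_g, 100)

  # synthetic kidney sample constructed to read 13.3 %IA/g at 1 h
  hl <- half_life_hours("177Lu")
  s2 <- biodist_row(organ = "kidneys", time_pi = 1, count_time = 1,
                    sample_mass = 0.4, injected_activity = 30000,
                    measured_activity = 13.3 * 0.4 / 100 * 30000 * 2^(-1 / hl))
  expect_equal(quantify_samples(s2, "177Lu")$pct_ia_per_g, 13.3, tolerance = 1e-9)

  # scale invariance: doubling measured and injected leaves %IA unchanged
  s3 <- s2; s3$measured_activity <- s3$measured_activity * 2
  s3$injected_activity <- s3$injected_activity * 2
  expect_equal(quantify_samples(s3, "177Lu")$pct_ia,
               quantify_samples(s2, "177Lu")$pct_ia)
})

test_that("the Ac-225 secular-equilibrium counting rule flags early counts", {
  s <- biodist_row(time_pi = 4, count_time = 6, injected_activity = 40,
                   measured_activity = 0.02)
  expect_warning(q <- quantify_samples(s, "225Ac"), "equilibrium")
  expect_identical(q$flag, "counted_before_equilibrium")
  s_ok <- biodist_row(time_pi = 4, count_time = 28, injected_activity = 40,
                      measured_activity = 0.02)
  expect_silent(q2 <- quantify_samples(s_ok, "225Ac"))
  expect_identical(q2$flag, "")
})

test_that("summarize_uptake computes per-cell mean/SD/n", {
  mk <- function(vals, organ = "tumor", tp = 4) {
    do.call(rbind, lapply(seq_along(vals), function(i) {
      biodist_row(animal_id = paste0("m", i), organ = organ, time_pi = tp,
                  count_time = tp, sample_mass = 1, injected_activity = 100,
                  measured_activity = vals[i] / 100 * 100 * 2^(-tp / half_life_hours("177Lu")))
    }))
  }
  q <- quantify_samples(mk(c(12, 13, 14)), "177Lu")
  u <- summarize_uptake(q)
  expect_equal(u$mean_pct_ia_per_g, 13, tolerance = 1e-9)
  expect_equal(u$sd_pct_ia_per_g, 1, tolerance = 1e-9)
  expect_identical(u$n, 3L)

  q5 <- quantify_samples(mk(rep(7, 5)), "177Lu")
  expect_equal(summarize_uptake(q5)$sd_pct_ia, 0, tolerance = 1e-10)

  expect_identical(nrow(summarize_uptake(quantify_samples(
    biodist_row()[0, ], "177Lu"))), 0L)
})

test_that("summarize_uptake is invariant to input order (brute-force check)", {
  cfg <- sim_config(seed = 42)
  s <- simulate_biodistribution(cfg, "177Lu")
  q <- quantify_samples(s, "177Lu")
  u1 <- summarize_uptake(q)
  set.seed(1)
  u2 <- summarize_uptake(q[sample(nrow(q)), ])
  expect_equal(u1, u2)
  # brute-force recomputation of one cell
  cell <- q$pct_ia_per_g[q$organ == "tumor" & q$time_pi == 24]
  expect_equal(u1$mean_pct_ia_per_g[u1$organ == "tumor" & u1$time_pi == 24],
               sum(cell) / length(cell))
  expect_equal(u1$sd_pct_ia_per_g[u1$organ == "tumor" & u1$time_pi == 24],
               sqrt(sum((cell - mean(cell))^2) / (length(cell) - 1)))
})

test_that("welch_compare matches t.test on reconstructed raw data", {
  cases <- list(c(25.9, 3.5, 5, 13.3, 1.6, 5),
                c(9.3, 1.3, 5, 6.3, 0.9, 5),
                c(14.4, 4.1, 5, 14.1, 4.9, 5),
                c(2.0, 0.4, 7, 2.5, 1.1, 4))
  for (cc in cases) {
    w <- welch_compare(cc[1], cc[2], cc[3], cc[4], cc[5], cc[6])
    x <- raw_with_moments(cc[1], cc[2], cc[3])
    y <- raw_with_moments(cc[4], cc[5], cc[6])
    tt <- t.test(x, y)   # Welch by default
    expect_equal(w$statistic, unname(tt$statistic), tolerance = 1e-9)
    expect_equal(w$df, unname(tt$parameter), tolerance = 1e-9)
    expect_equal(w$p_two_sided, tt$p.value, tolerance = 1e-9)
  }
})

test_that("welch_compare symmetry, identity and degenerate conventions", {
  w1 <- welch_compare(10, 2, 5, 8, 3, 6)
  w2 <- welch_compare(8, 3, 6, 10, 2, 5)
  expect_equal(w1$statistic, -w2$statistic)
  expect_equal(w1$p_two_sided, w2$p_two_sided)

  wid <- welch_compare(5, 1, 5, 5, 1, 5)
  expect_identical(wid$statistic, 0)
  expect_identical(wid$p_two_sided, 1)

  expect_identical(welch_compare(3, 0, 5, 3, 0, 5)$p_two_sided, 1)
  expect_identical(welch_compare(3, 0, 5, 4, 0, 5)$p_two_sided, 0)

  # equal variance & n: Welch df -> n1+n2-2 and t equals pooled t
  x <- raw_with_moments(10, 2, 6); y <- raw_with_moments(12, 2, 6)
  w <- welch_compare(10, 2, 6, 12, 2, 6)
  pooled <- t.test(x, y, var.equal = TRUE)
  expect_equal(w$df, 10)
  expect_equal(w$statistic, unname(pooled$statistic), tolerance = 1e-9)
})

test_that("compare_uptake pairs shared cells and supports Holm", {
  u1 <- data.frame(organ = c("tumor", "kidneys"), time_pi = c(4, 4), n = 5,
                   mean_pct_ia_per_g = c(14.4, 10), sd_pct_ia_per_g = c(4.1, 2),
                   mean_pct_ia = NA, sd_pct_ia = NA)
  u2 <- data.frame(organ = c("tumor", "liver"), time_pi = c(4, 4), n = 5,
                   mean_pct_ia_per_g = c(14.1, 3), sd_pct_ia_per_g = c(4.9, 1),
                   mean_pct_ia = NA, sd_pct_ia = NA)
  cmp <- compare_uptake(u1, u2)
  expect_identical(nrow(cmp), 1L)
  expect_identical(cmp$organ, "tumor")
  expect_equal(cmp$p_adjusted, cmp$p)
})
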