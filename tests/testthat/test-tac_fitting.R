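PAPER_GRID <- c(1, 4, 24, 48, 168)

test_that("make_tac validates and normalises input order", {
  expect_error(make_tac(c(1, 1, 2), c(1, 2, 3)), "distinct")
  expect_error(make_tac(c(1, 2), c(-1, 2)))
  tac <- make_tac(c(4, 1, 24), c(2, 1, 3))
  expect_identical(tac$times, c(1, 4, 24))
  expect_identical(tac$values, c(1, 2, 3))
})

test_that("noiseless bi-exponential data are recovered to 1e-6 relative", {
  truth <- c(10, 0.1, 5, 0.005)
  y <- truth[1] * exp(-truth[2] * PAPER_GRID) + truth[3] * exp(-truth[4] * PAPER_GRID)
  f <- fit_model(make_tac(PAPER_GRID, y), "bi_exp")
  expect_true(f$converged)
  est <- c(f$A1, f$lambda1, f$A2, f$lambda2)
  expect_lt(max(abs(est / truth - 1)), 1e-6)
  expect_gte(f$lambda1, f$lambda2)  # ordering convention
})

test_that("bi_exp nests mono_exp on mono-exponential data", {
  y <- 8 * exp(-0.02 * PAPER_GRID)
  fm <- fit_model(make_tac(PAPER_GRID, y), "mono_exp")
  fb <- fit_model(make_tac(PAPER_GRID, y), "bi_exp")
  expect_lt(fm$rss, 1e-8)
  expect_lt(fb$rss, fm$rss + 1e-8)    # nesting, up to numerical zero
})

test_that("fit is invariant to data-point order and needs k+1 points", {
  set.seed(3)
  y <- 10 * exp(-0.1 * PAPER_GRID) + 5 * exp(-0.005 * PAPER_GRID)
  y <- y * (1 + rnorm(5, 0, 0.05))
  f1 <- fit_model(make_tac(PAPER_GRID, y), "bi_exp")
  perm <- c(3, 1, 5, 2, 4)
  f2 <- fit_model(make_tac(PAPER_GRID[perm], y[perm]), "bi_exp")
  expect_equal(c(f1$A1, f1$lambda1, f1$A2, f1$lambda2),
               c(f2$A1, f2$lambda1, f2$A2, f2$lambda2), tolerance = 1e-12)
  expect_error(fit_model(make_tac(c(1, 4, 24), c(3, 2, 1)), "bi_exp"),
               "at least 5 points")
})

test_that("AICc arithmetic and select_model follow the stated rules", {
  # frozen hand value: n=5, rss=100, k=2 -> 5 ln 20 + 4 + 12/2 = 24.97866
  expect_equal(aicc(5, 100, 2), 5 * log(20) + 4 + 6, tolerance = 1e-12)
  expect_message(expect_true(is.na(aicc(5, 99.9, 4))), "excluded")

  fake <- function(form, rss, k, a) {
    structure(list(model_form = form, rss = rss, k = k, aicc = a,
                   n_points = 5L, converged = TRUE), class = "fit_result")
  }
  mono <- fake("mono_exp", 100, 2L, aicc(5, 100, 2))
  bi <- fake("bi_exp", 99.9, 4L, suppressMessages(aicc(5, 99.9, 4)))
  expect_message(sel <- select_model(list(mono, bi)), "excluded")
  expect_identical(sel$model_form, "mono_exp")

  # ties broken toward fewer parameters
  a <- fake("mono_exp", 50, 2L, 10); b <- fake("bi_exp", 40, 4L, 10)
  expect_identical(select_model(list(b, a))$model_form, "mono_exp")
  # single candidate returned unchanged
  expect_identical(select_model(list(mono)), mono)
  expect_identical(select_model(mono), mono)
})

test_that("bi-exponential truth is selected at larger n under low noise", {
  # n = 9 so both candidates have a defined AICc
  tt <- c(1, 2, 4, 8, 24, 48, 96, 168, 336)
  truth <- c(10, 0.3, 5, 0.004)
  base <- truth[1] * exp(-truth[2] * tt) + truth[3] * exp(-truth[4] * tt)
  set.seed(7)
  wins <- 0L
  for (i in 1:20) {
    y <- pmax(base * (1 + rnorm(length(tt), 0, 0.02)), 1e-6)
    fits <- list(fit_model(make_tac(tt, y), "mono_exp"),
                 fit_model(make_tac(tt, y), "bi_exp"))
    sel <- select_model(fits)
    wins <- wins + (sel$model_form == "bi_exp")
  }
  expect_gte(wins, 18)   # >= 90% of seeded replicates
})

test_that("cumulated activity: closed form, flags and monotonicity", {
  f <- structure(list(A1 = 1, lambda1 = 0.1, A2 = 0, lambda2 = 1,
                      converged = TRUE), class = "fit_result")
  expect_equal(cumulated_activity(f, physical_lambda = 0)$value, 10)

  f2 <- structure(list(A1 = 3, lambda1 = 0.2, A2 = 4, lambda2 = 0.004,
                       converged = TRUE), class = "fit_result")
  lam <- 0.00434
  on <- cumulated_activity(f2, lam, data_is_decay_corrected = TRUE)$value
  off <- cumulated_activity(f2, lam, data_is_decay_corrected = FALSE)$value
  expect_lt(on, off)                       # re-applied physical decay shrinks
  expect_equal(off, 3 / 0.2 + 4 / 0.004)

  # finite horizon < infinite horizon; divergence guarded
  fh <- cumulated_activity(f2, lam, horizon = 100)$value
  expect_lt(fh, on + 1e-12)
  f3 <- structure(list(A1 = 1, lambda1 = 0, A2 = 0, lambda2 = 1,
                       converged = TRUE), class = "fit_result")
  expect_error(cumulated_activity(f3, 0), "divergent")
  expect_error(cumulated_activity(structure(list(converged = FALSE),
                                            class = "fit_result"), 0),
               "non-converged")
})

test_that("closed-form integral agrees with adaptive quadrature", {
  set.seed(5)
  for (i in 1:25) {
    A1 <- runif(1, 0.5, 20); l1 <- 10^runif(1, -1.5, 0)
    A2 <- runif(1, 0.5, 20); l2 <- 10^runif(1, -3, -1.7)
    lam <- 0.004
    f <- structure(list(A1 = A1, lambda1 = l1, A2 = A2, lambda2 = l2,
                        converged = TRUE), class = "fit_result")
    closed <- cumulated_activity(f, lam)$value
    quad <- quadrature_cumulated(A1, l1 + lam, A2, l2 + lam, 20 / (l2 + lam))
    expect_equal(closed, quad, tolerance = 1e-3)
  }
})

test_that("cumulated activity is monotone in amplitudes and rates", {
  mk <- function(A1, l1, A2, l2) structure(
    list(A1 = A1, lambda1 = l1, A2 = A2, lambda2 = l2, converged = TRUE),
    class = "fit_result")
  base <- cumulated_activity(mk(3, 0.2, 4, 0.004), 0.003)$value
  expect_gt(cumulated_activity(mk(3.5, 0.2, 4, 0.004), 0.003)$value, base)
  expect_gt(cumulated_activity(mk(3, 0.2, 4.5, 0.004), 0.003)$value, base)
  expect_lt(cumulated_activity(mk(3, 0.25, 4, 0.004), 0.003)$value, base)
  expect_lt(cumulated_activity(mk(3, 0.2, 4, 0.005), 0.003)$value, base)
})

test_that("AICc converges to AIC for large n", {
  n <- 1e4
  expect_lt(abs(aicc(n, 123.4, 4) - (n * log(123.4 / n) + 8)), 0.005)
})

test_that("fixed-physical-rate variant pins the slow rate", {
  lam <- decay_lambda("177Lu")
  y <- 2 * exp(-0.3 * PAPER_GRID) + 5 * exp(-lam * PAPER_GRID)
  f <- fit_model(make_tac(PAPER_GRID, y), "bi_exp_fixed_phys", fixed_lambda = lam)
  expect_equal(f$lambda2, lam)
  expect_equal(c(f$A1, f$lambda1, f$A2), c(2, 0.3, 5), tolerance = 1e-4)
})
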