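test_that("ROC points cumulate from the high-confidence end", {
  r1 <- build_roc(c(0, 0, 0, 0, 0, 10), c(10, 0, 0, 0, 0, 0))
  expect_equal(r1$hit_cum, rep(1, 5))
  expect_equal(r1$fa_cum, rep(0, 5))

  r2 <- build_roc(rep(2, 6), rep(2, 6))
  expect_equal(r2$hit_cum, (1:5) / 6)
  expect_equal(r2$fa_cum, (1:5) / 6)

  r3 <- build_roc(c(1, 2, 3, 4, 5, 9), c(9, 5, 4, 3, 2, 1))
  expect_equal(r3$hit_cum, c(9, 14, 18, 21, 23) / 24)
  expect_equal(r3$fa_cum, c(1, 3, 6, 10, 15) / 24)

  expect_error(build_roc(rep(0, 6), rep(1, 6)), "positive total")
  expect_true(all(diff(r3$hit_cum) >= 0) && all(diff(r3$fa_cum) >= 0))
})

test_that("model category probabilities behave at the corners and sum to one", {
  crit <- c(-1, -0.5, 0, 0.5, 1)
  pure_rec <- dpsd_probs(1, 0.3, crit)
  expect_equal(pure_rec$old, c(0, 0, 0, 0, 0, 1))

  collapse <- dpsd_probs(0, 0, crit)
  expect_equal(collapse$old, collapse$new)

  mid <- dpsd_probs(0.5, 1, crit)
  expect_equal(mid$old[6], 0.75)

  set.seed(42)
  for (i in 1:25) {
    R <- runif(1)
    d <- runif(1, -0.5, 3)
    cr <- sort(rnorm(5, 0, 1.2))
    if (any(diff(cr) == 0)) next
    p <- dpsd_probs(R, d, cr)
    expect_equal(sum(p$old), 1, tolerance = 1e-12)
    expect_equal(sum(p$new), 1, tolerance = 1e-12)
    expect_gte(p$old[6], R)
  }

  expect_error(dpsd_probs(0.5, 1, c(0, -1, 1, 2, 3)), "increasing")
})

test_that("maximum likelihood recovers generating parameters", {
  # pure familiarity: fitted R near 0, d_f near truth
  tab0 <- expected_dpsd_table(0, 1, n_old = 1e5, n_new = 1e5)
  f0 <- fit_dpsd(tab0$old, tab0$new)
  expect_lt(f0$R, 0.02)
  expect_equal(f0$d_f, 1, tolerance = 0.05)

  # mixed process on the model-expected table
  tabm <- expected_dpsd_table(0.4, 1.0)
  fm <- fit_dpsd(tabm$old, tabm$new)
  expect_lt(abs(fm$R - 0.4), 0.05)
  expect_lt(abs(fm$d_f - 1.0), 0.05)

  # multinomial sampling noise at 10,000 trials per row (3-SD bands)
  set.seed(11)
  tab <- sampled_dpsd_table(0.4, 1.0)
  f <- fit_dpsd(tab$old, tab$new)
  expect_true(f$converged)
  expect_lt(abs(f$R - 0.4), 0.06)
  expect_lt(abs(f$d_f - 1.0), 0.12)
  expect_true(all(diff(f$criteria) > 0))
  expect_lte(f$log_lik, 0)

  # likelihood at the optimum is no worse than at the truth
  nll_true <- recmem:::dpsd_nll(
    c(qlogis(0.4), 1.0, -0.8, log(diff(c(-0.8, -0.3, 0.1, 0.6, 1.1)))),
    tab$old, tab$new)
  expect_lte(-f$log_lik, nll_true + 1e-6)

  # perfect-separation boundary
  fb <- fit_dpsd(c(0, 0, 0, 0, 0, 10), c(10, 0, 0, 0, 0, 0))
  expect_gte(fb$R, 0.95)
})

test_that("fit is invariant to count scaling and flags degenerate tables", {
  tab <- expected_dpsd_table(0.3, 0.8, n_old = 500, n_new = 500)
  f1 <- fit_dpsd(tab$old, tab$new)
  f3 <- fit_dpsd(3 * tab$old, 3 * tab$new)
  expect_equal(f3$R, f1$R, tolerance = 1e-3)
  expect_equal(f3$d_f, f1$d_f, tolerance = 1e-3)
  expect_equal(f3$criteria, f1$criteria, tolerance = 1e-2)

  dg <- fit_dpsd(c(0, 0, 10, 0, 0, 0), c(0, 0, 10, 0, 0, 0))
  expect_false(dg$identifiable)
  expect_false(dg$converged)
})

test_that("with no recollection the fit reduces to equal-variance SDT", {
  tab <- expected_dpsd_table(0, 1.2, n_old = 1e5, n_new = 1e5)
  f <- fit_dpsd(tab$old, tab$new)
  yes_no <- dprime_c(sum(tab$old[4:6]), sum(tab$old),
                     sum(tab$new[4:6]), sum(tab$new))
  expect_equal(f$d_f, yes_no$d_prime, tolerance = 0.02)
})

test_that("least-squares fitting agrees with maximum likelihood on clean tables", {
  tab <- expected_dpsd_table(0.4, 1.0)
  ml <- fit_dpsd(tab$old, tab$new, method = "ml")
  ss <- fit_dpsd(tab$old, tab$new, method = "sse")
  expect_equal(ss$R, ml$R, tolerance = 0.02)
  expect_equal(ss$d_f, ml$d_f, tolerance = 0.02)
  expect_true(is.na(ss$log_lik) && !is.na(ss$sse))
})
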