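test_that("Mann-Whitney statistic and exact p match enumeration", {
  m <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(m$statistic, 0)
  expect_equal(m$p_value, 1 / 3, tolerance = 1e-12)

  # identical samples: U at its midpoint, p = 1
  v <- c(0.2, 0.5, 0.9)
  same <- mann_whitney(v, v)
  expect_equal(same$statistic, 9 / 2)
  expect_equal(same$p_value, 1)

  # all values tied across both groups
  tied <- mann_whitney(rep(1, 4), rep(1, 6))
  expect_equal(tied$statistic, 12)
  expect_equal(tied$p_value, 1)

  # statistic is brute-force pair counting
  a <- c(1, 3, 5)
  b <- c(2, 4, 6)
  expect_equal(mann_whitney(a, b)$statistic,
               sum(outer(a, b, ">")))  # 3 pairs with a_i > b_j
})

test_that("effect size A equals brute-force pair counting and is complementary", {
  expect_equal(effect_size_A(c(4, 5, 6), c(1, 2, 3)), 1)
  expect_equal(effect_size_A(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(effect_size_A(c(1, 3), c(2, 4)), 0.25)

  set.seed(21)
  for (i in 1:20) {
    a <- sample(1:6, sample(2:8, 1), replace = TRUE)
    b <- sample(1:6, sample(2:8, 1), replace = TRUE)
    expect_equal(effect_size_A(a, b), brute_force_A(a, b))
    expect_equal(effect_size_A(a, b) + effect_size_A(b, a), 1)
  }
})

test_that("permutation test enumerates exhaustively when feasible", {
  expect_equal(permutation_test(1, 2)$p_value, 1)
  expect_equal(permutation_test(c(10, 11, 12), c(1, 2, 3))$p_value, 0.1)

  # exhaustive p agrees with an independent enumeration oracle
  a <- c(0.3, 1.2, 2.2, 0.9)
  b <- c(2.5, 3.1, 1.9)
  idx <- utils::combn(7, 4)
  pool <- c(a, b)
  t_obs <- mean(a) - mean(b)
  t_all <- apply(idx, 2, function(i) mean(pool[i]) - mean(pool[-i]))
  expect_equal(permutation_test(a, b)$p_value,
               mean(abs(t_all) >= abs(t_obs) - 1e-12))

  # Monte Carlo branch is seed-reproducible
  set.seed(99)
  x <- rnorm(12)
  y <- rnorm(25)
  p1 <- permutation_test(x, y, n_perm = 500, seed = 3)$p_value
  p2 <- permutation_test(x, y, n_perm = 500, seed = 3)$p_value
  expect_identical(p1, p2)

  expect_error(permutation_test(numeric(0), c(1, 2)), "length")
})

test_that("Spearman correlation handles exact and approximate branches", {
  expect_equal(spearman_rho(1:5, (1:5)^3)$rho, 1)
  expect_equal(spearman_rho(1:5, rev(1:5))$rho, -1)

  s <- spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(s$rho, 0.6)
  # exact permutation p frozen from full enumeration of the 24 orderings
  expect_equal(s$p_value, 10 / 24, tolerance = 1e-12)

  # t approximation branch against cor.test
  set.seed(5)
  x <- rnorm(20)
  y <- x + rnorm(20)
  s2 <- spearman_rho(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(s2$rho, unname(ct$estimate))
  expect_equal(s2$p_value, ct$p.value, tolerance = 1e-6)

  expect_false(spearman_rho(rep(1, 5), 1:5)$defined)
})

test_that("Holm adjustment matches the hand step-down and its bounds", {
  # hand step-down: sorted (0.01*3, 0.03*2, 0.04*1) = (0.03, 0.06, 0.04),
  # running max -> (0.03, 0.06, 0.06), mapped back to input order
  expect_equal(holm_correct(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_correct(0.5), 0.5)
  expect_equal(holm_correct(c(1, 1)), c(1, 1))

  set.seed(8)
  for (i in 1:10) {
    p <- runif(sample(2:6, 1))
    h <- holm_correct(p)
    expect_true(all(h >= p))
    expect_true(all(h <= pmin(1, length(p) * p)))  # never above Bonferroni
  }
  expect_error(holm_correct(c(0.5, 1.2)), "0, 1")
})

test_that("chi-square matches the Pearson formula", {
  even <- chi_square(matrix(10, 2, 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)

  diag <- chi_square(matrix(c(20, 0, 0, 20), 2))
  expect_equal(diag$statistic, 40)
  expect_equal(diag$df, 1)

  tab <- matrix(c(3, 15, 9, 10), 2)
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chi_square(tab)$statistic,
               sum((tab - exp_counts)^2 / exp_counts))

  expect_error(chi_square(matrix(c(0, 0, 5, 7), 2)), "marginal")
})

test_that("z summaries standardize against controls and average across tasks", {
  mk <- function(id, task, d, r, f) {
    data.frame(subject_id = id, task = task, d_prime = d, R_index = r,
               F_index = f)
  }
  idx <- rbind(
    mk("c1", "ROC", 1, 0.2, 1), mk("c1", "PDP", 1, 0.2, 1),
    mk("c1", "RKG", 1, 0.2, 1),
    mk("c2", "ROC", 3, 0.6, 2), mk("c2", "PDP", 3, 0.6, 2),
    mk("c2", "RKG", 3, 0.6, 2),
    mk("p1", "ROC", 2, 0.4, 1.5), mk("p1", "PDP", 2, 0.4, 1.5),
    mk("p1", "RKG", 2, 0.4, 1.5),
    mk("p2", "ROC", 1, 0.2, 1), mk("p2", "PDP", 1, 0.2, 1),
    mk("p2", "RKG", 1, 0.2, 1)
  )
  z <- z_summary(idx, c("c1", "c2"))
  # p1 sits exactly at the control mean on every task
  expect_equal(unlist(z[z$subject_id == "p1", c("z_dprime", "z_R", "z_F")]),
               c(z_dprime = 0, z_R = 0, z_F = 0))
  # p2 sits one control SD below the mean everywhere
  expect_equal(unname(z$z_dprime[z$subject_id == "p2"]),
               (1 - 2) / sd(c(1, 3)))

  # averaging: make p1's three task z-scores -1, -2, -3 on d'
  idx2 <- idx
  sds <- sd(c(1, 3))
  idx2$d_prime[idx2$subject_id == "p1"] <- 2 - sds * c(1, 2, 3)
  z2 <- z_summary(idx2, c("c1", "c2"))
  expect_equal(z2$z_dprime[z2$subject_id == "p1"], -2)

  # missing a task excludes the subject and reports it
  idx3 <- idx[!(idx$subject_id == "p2" & idx$task == "RKG"), ]
  z3 <- z_summary(idx3, c("c1", "c2"))
  expect_false("p2" %in% z3$subject_id)
  expect_equal(attr(z3, "excluded"), "p2")

  # zero control SD is an error naming the index
  idx4 <- idx
  idx4$F_index[idx4$subject_id %in% c("c1", "c2")] <- 1
  expect_error(z_summary(idx4, c("c1", "c2")), "F_index")
})
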