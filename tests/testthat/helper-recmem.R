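# Shared fixtures, built in code.

# Deterministic "large-n" confidence table: expected counts under the
# dual-process model, rounded. Useful for recovery checks without
# multinomial noise.
expected_dpsd_table <- function(R, d_f, criteria = c(-0.8, -0.3, 0.1, 0.6, 1.1),
                                n_old = 10000, n_new = 10000) {
  p <- dpsd_probs(R, d_f, criteria)
  list(old = round(n_old * p$old), new = round(n_new * p$new))
}

# Multinomial draw from the model (independent of the simulator code path).
sampled_dpsd_table <- function(R, d_f, criteria = c(-0.8, -0.3, 0.1, 0.6, 1.1),
                               n_old = 10000, n_new = 10000) {
  p <- dpsd_probs(R, d_f, criteria)
  list(old = as.vector(stats::rmultinom(1, n_old, p$old)),
       new = as.vector(stats::rmultinom(1, n_new, p$new)))
}

# Brute-force stochastic superiority, written independently of
# effect_size_A (double loop, no outer()).
brute_force_A <- function(a, b) {
  wins <- 0
  for (x in a) for (y in b) {
    if (x > y) wins <- wins + 1
    else if (x == y) wins <- wins + 0.5
  }
  wins / (length(a) * length(b))
}

# Exhaustive two-sided permutation p-value for the rank-sum statistic,
# enumerating every label assignment (independent Mann-Whitney oracle).
exhaustive_ranksum_p <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  r <- rank(pool)
  idx <- utils::combn(length(pool), n1)
  sums <- apply(idx, 2L, function(i) sum(r[i]))
  obs <- sum(r[seq_len(n1)])
  mu <- n1 * (length(pool) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# Aggregate one subject's simulated RKG trials into count rows.
rkg_rows_from_trials <- function(tr) {
  row_for <- function(cls) {
    d <- tr[tr$item_class == cls, ]
    yes <- d$response == "yes"
    c(R = sum(yes & d$attribution %in% "R"),
      K = sum(yes & d$attribution %in% "K"),
      G = sum(yes & d$attribution %in% "G"),
      no = sum(!yes))
  }
  list(old = row_for("target"), new = row_for("distractor"))
}

# Fixed latents without randomness (zero-spread draw).
fixed_latents <- function(rho, delta, yes_criterion = 0.55,
                          guess_rate = 0.15,
                          criteria = c(-0.8, -0.35, 0.1, 0.55, 1.1)) {
  structure(list(rho = rho, delta = delta, criteria_roc = criteria,
                 yes_criterion = yes_criterion, guess_rate = guess_rate,
                 group = "control"),
            class = "subject_latents")
}
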