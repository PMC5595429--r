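#' Mann-Whitney U test for two independent samples
#'
#' Two-sided Mann-Whitney test with midrank tie handling. The statistic is
#' \eqn{U = \#\{a_i > b_j\} + 0.5\,\#\{a_i = b_j\}} (the Wilcoxon W of
#' `wilcox.test(a, b)`). The p-value is exact (enumeration) when
#' `n1 * n2 <= exact_limit` and there are no ties, otherwise a normal
#' approximation with tie correction (no continuity correction) is used.
#' The Vargha-Delaney A effect size ([effect_size_A()]) is attached.
#'
#' @param a,b Numeric vectors (no missing values).
#' @param exact_limit Largest `n1 * n2` for which the exact distribution is
#'   used (default 400).
#' @return An object of class `"group_comparison"`: list with
#'   `statistic_name` (`"U"`), `statistic`, `p_value`, `effect_A`, `n1`,
#'   `n2`, `method` (`"mann_whitney"`).
#' @examples
#' mann_whitney(c(1.2, 0.8, 1.5), c(0.3, 0.6, 0.9, 0.2))
#' @export
mann_whitney <- function(a, b, exact_limit = 400L) {
  check_sample(a, "a")
  check_sample(b, "b")
  n1 <- length(a)
  n2 <- length(b)
  u <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  if (length(unique(c(a, b))) == 1L) {
    p <- 1
  } else {
    ties <- anyDuplicated(c(a, b)) > 0L
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = (n1 * n2 <= exact_limit) && !ties,
                         correct = FALSE)
    )
    p <- min(1, wt$p.value)
  }
  new_group_comparison("U", u, p, effect_size_A(a, b), n1, n2, "mann_whitney")
}

#' Vargha-Delaney A: stochastic superiority of one sample over another
#'
#' \eqn{A = [\#\{a_i > b_j\} + 0.5\,\#\{a_i = b_j\}] / (n_1 n_2)}: the
#' probability that a random member of `a` exceeds a random member of `b`,
#' ties counting half. A = 0.5 means no effect; conventional bands read
#' roughly 0.56-0.64 as small, 0.65-0.71 as medium and above 0.71 as large.
#' Computed by exhaustive pair comparison.
#'
#' @param a,b Numeric vectors.
#' @return A number in \[0, 1\].
#' @examples
#' effect_size_A(c(4, 5, 6), c(1, 2, 3))  # 1: complete separation
#' @export
effect_size_A <- function(a, b) {
  check_sample(a, "a")
  check_sample(b, "b")
  (sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))) /
    (length(a) * length(b))
}

#' Two-sample permutation test
#'
#' Two-sided permutation test of group-label exchangeability, suited to
#' small samples. When the number of distinct label assignments
#' `choose(n1 + n2, n1)` does not exceed `exact_limit`, all assignments are
#' enumerated and \eqn{p = \#\{|T_{perm}| \ge |T_{obs}|\} / N_{comb}} (the
#' observed split is one of the enumerated ones, so p > 0). Otherwise
#' `n_perm` seeded random shuffles give
#' \eqn{p = (1 + \#\{|T_{perm}| \ge |T_{obs}|\}) / (1 + n_{perm})}.
#'
#' @param a,b Numeric vectors.
#' @param statistic `"mean_diff"` (default) or `"median_diff"`.
#' @param n_perm Number of Monte Carlo shuffles when enumeration is
#'   infeasible.
#' @param seed Integer seed for the Monte Carlo branch; the global RNG
#'   state is left untouched.
#' @param exact_limit Enumeration cutoff on `choose(n1 + n2, n1)`
#'   (default 50000).
#' @return A `"group_comparison"` with `method = "permutation"`; the
#'   statistic is the observed group difference.
#' @examples
#' permutation_test(c(10, 11, 12), c(1, 2, 3))  # exhaustive: p = 0.1
#' @export
permutation_test <- function(a, b, statistic = c("mean_diff", "median_diff"),
                             n_perm = 10000L, seed = 1L,
                             exact_limit = 50000L) {
  statistic <- match.arg(statistic)
  check_sample(a, "a")
  check_sample(b, "b")
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  n1 <- length(a)
  n2 <- length(b)
  pool <- c(a, b)
  n <- n1 + n2
  stat_fun <- if (statistic == "mean_diff") {
    function(x, y) mean(x) - mean(y)
  } else {
    function(x, y) stats::median(x) - stats::median(y)
  }
  t_obs <- stat_fun(a, b)
  tol <- 1e-12 + 1e-8 * abs(t_obs)

  if (choose(n, n1) <= exact_limit) {
    idx <- utils::combn(n, n1)
    t_perm <- apply(idx, 2L, function(i) stat_fun(pool[i], pool[-i]))
    p <- mean(abs(t_perm) >= abs(t_obs) - tol)
  } else {
    t_perm <- with_local_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        take <- sample.int(n, n1)
        stat_fun(pool[take], pool[-take])
      }, numeric(1))
    })
    p <- (1 + sum(abs(t_perm) >= abs(t_obs) - tol)) / (1 + n_perm)
  }
  new_group_comparison(statistic, t_obs, p, effect_size_A(a, b),
                       n1, n2, "permutation")
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks. For `n <= 8` the p-value is exact, by
#' enumeration of all permutations of one ranking; for larger n the usual
#' t approximation on `rho` is used. Two-sided throughout.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value`, `n`, and `defined` (`FALSE`, with
#'   `rho = NA`, when either ranking has zero variance).
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3))  # rho = 0.6
#' @export
spearman_rho <- function(x, y) {
  check_sample(x, "x")
  check_sample(y, "y")
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have equal length")
  if (n < 3) stop("need at least 3 paired observations")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, defined = FALSE))
  }
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    perms <- permutations_of(n)
    rho_perm <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    t_stat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-300))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, defined = TRUE)
}

#' Bonferroni-Holm step-down adjustment
#'
#' Wraps [stats::p.adjust()] with input validation; adjusted p-values are
#' returned in the input order, capped at 1, with the step-down
#' monotonicity enforced.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @examples
#' holm_correct(c(0.01, 0.04, 0.03))
#' @export
holm_correct <- function(p) {
  if (length(p) == 0L) stop("'p' must be non-empty")
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("all p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Pearson chi-square test of independence
#'
#' Pearson chi-square on an r x c count table, no continuity correction,
#' df = (r - 1)(c - 1). Used for nominal group comparisons (sex,
#' handedness).
#'
#' @param tab Matrix of non-negative counts, at least 2 x 2.
#' @return List with `statistic`, `p_value`, `df`.
#' @examples
#' chi_square(matrix(c(3, 15, 9, 10), 2))
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(!is.finite(tab)) || any(tab < 0))
    stop("counts must be non-negative and finite")
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("table must be at least 2 x 2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has a zero marginal; drop the empty row/column first")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       df = unname(ct$parameter))
}

#' Cross-task z-score summaries against the control group
#'
#' Standardizes each per-subject index (d', R, F) within each task against
#' the control subjects' mean and standard deviation, then averages the
#' three task z-scores into a summary score per index. Subjects missing any
#' task are excluded from the summary (reported in the `"excluded"`
#' attribute).
#'
#' @param indices Data frame as produced by [score_subjects()]: columns
#'   `subject_id`, `task`, `d_prime`, `R_index`, `F_index`.
#' @param control_ids Character vector of control subject ids (at least 2
#'   per task must be present in `indices`).
#' @return Data frame with one row per subject: `subject_id`, `z_dprime`,
#'   `z_R`, `z_F`. Attribute `"excluded"` lists subjects dropped for
#'   missing tasks.
#' @export
z_summary <- function(indices, control_ids) {
  req <- c("subject_id", "task", "d_prime", "R_index", "F_index")
  if (!all(req %in% names(indices)))
    stop("'indices' must have columns ", paste(req, collapse = ", "))
  tasks <- sort(unique(indices$task))
  cols <- c(z_dprime = "d_prime", z_R = "R_index", z_F = "F_index")

  z <- indices[c("subject_id", "task")]
  for (out in names(cols)) {
    src <- cols[[out]]
    z[[out]] <- NA_real_
    for (tk in tasks) {
      in_task <- indices$task == tk
      ctrl <- indices[[src]][in_task & indices$subject_id %in% control_ids]
      if (length(ctrl) < 2)
        stop("need >= 2 control subjects for task ", tk)
      s <- stats::sd(ctrl)
      if (s == 0)
        stop("zero control standard deviation for ", src, " in task ", tk)
      z[[out]][in_task] <- (indices[[src]][in_task] - mean(ctrl)) / s
    }
  }

  n_tasks <- length(tasks)
  counts <- table(z$subject_id)
  complete <- names(counts)[counts == n_tasks]
  excluded <- setdiff(unique(z$subject_id), complete)
  zc <- z[z$subject_id %in% complete, ]
  out <- aggregate(zc[names(cols)], by = list(subject_id = zc$subject_id),
                   FUN = mean)
  out <- out[match(unique(zc$subject_id), out$subject_id), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

# ---- internals -------------------------------------------------------------

check_sample <- function(x, what) {
  if (length(x) < 1L) stop("'", what, "' must have length >= 1")
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'", what, "' must be finite numeric (handle missing values upstream)")
  invisible(TRUE)
}

new_group_comparison <- function(statistic_name, statistic, p_value,
                                 effect_A, n1, n2, method) {
  structure(
    list(statistic_name = statistic_name, statistic = unname(statistic),
         p_value = unname(p_value), effect_A = effect_A,
         n1 = n1, n2 = n2, method = method),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("%s test (n1 = %d, n2 = %d)\n", x$method, x$n1, x$n2))
  cat(sprintf("  %s = %.*g, p = %.*g, A = %.*g\n", x$statistic_name,
              digits, x$statistic, digits, x$p_value, digits, x$effect_A))
  invisible(x)
}

# All n! permutations of 1..n as an n! x n matrix (n <= 8 in practice).
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    out[rows, -1L] <- ifelse(sub >= k, sub + 1L, sub)
  }
  out
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
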