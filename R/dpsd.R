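#' Cumulative confidence-rating ROC points
#'
#' Builds the five ROC points of a 6-point confidence design by cumulating
#' response counts from the high-confidence ("sure old") end. Point k gives
#' the proportion of responses at confidence >= 7 - k, i.e. the operating
#' points obtained by progressively relaxing the "old" threshold from
#' confidence 6 down to 2. Raw proportions are used (no rate correction):
#' the ROC points are descriptive; smoothing decisions belong to the
#' likelihood in [fit_dpsd()].
#'
#' @param old_counts Integer vector of length 6: confidence 1..6 counts for
#'   studied (target) items.
#' @param new_counts Integer vector of length 6: confidence 1..6 counts for
#'   unstudied (distractor) items.
#' @return A list with components `hit_cum` and `fa_cum`, each a
#'   non-decreasing numeric vector of 5 cumulative proportions.
#' @examples
#' build_roc(c(5, 5, 10, 10, 10, 20), c(20, 15, 10, 10, 3, 2))
#' @export
build_roc <- function(old_counts, new_counts) {
  check_confusion(old_counts, new_counts)
  list(
    hit_cum = cumsum(rev(old_counts))[1:5] / sum(old_counts),
    fa_cum  = cumsum(rev(new_counts))[1:5] / sum(new_counts)
  )
}

check_confusion <- function(old_counts, new_counts) {
  for (v in list(old_counts, new_counts)) {
    if (length(v) != 6L || any(!is.finite(v)) || any(v < 0))
      stop("confidence counts must be 6 non-negative finite numbers")
  }
  if (sum(old_counts) <= 0 || sum(new_counts) <= 0)
    stop("each item class needs a positive total count")
  invisible(TRUE)
}

#' Predicted confidence-category probabilities under the dual-process model
#'
#' The dual-process signal-detection (high-threshold) model: unstudied items
#' produce a standard-normal familiarity strength partitioned into six
#' confidence categories by five ordered criteria. Studied items are
#' recollected with probability `R`, which forces the top confidence
#' category; otherwise their strength is Normal(`d_f`, 1) partitioned at the
#' same criteria.
#'
#' @param R Recollection probability in \[0, 1\].
#' @param d_f Familiarity strength (mean old-item strength, z-units).
#' @param criteria Strictly increasing numeric vector of 5 confidence
#'   criteria.
#' @return A list with components `old` and `new`, each a 6-vector of
#'   category probabilities (confidence 1..6) summing to 1.
#' @examples
#' dpsd_probs(0.3, 1, c(-1, -0.5, 0, 0.5, 1))
#' @export
dpsd_probs <- function(R, d_f, criteria) {
  if (length(R) != 1L || !is.finite(R) || R < 0 || R > 1)
    stop("'R' must be a probability in [0, 1]")
  if (length(d_f) != 1L || !is.finite(d_f))
    stop("'d_f' must be a finite number")
  if (length(criteria) != 5L || any(!is.finite(criteria)) ||
      any(diff(criteria) <= 0))
    stop("'criteria' must be 5 strictly increasing finite numbers")
  cuts_new <- stats::pnorm(c(criteria, Inf))
  cuts_old <- stats::pnorm(c(criteria, Inf), mean = d_f)
  p_new <- diff(c(0, cuts_new))
  p_fam <- diff(c(0, cuts_old))
  p_old <- (1 - R) * p_fam
  p_old[6] <- p_old[6] + R
  list(old = p_old, new = p_new)
}

# Negative multinomial log-likelihood of a 2x6 confidence table.
# Probabilities floored at 1e-12 so the likelihood stays finite with zero
# predicted mass in an observed cell.
dpsd_nll <- function(theta, old_counts, new_counts) {
  R <- stats::plogis(theta[1])
  d_f <- theta[2]
  criteria <- theta[3] + c(0, cumsum(exp(theta[4:7])))
  cuts_new <- stats::pnorm(c(criteria, Inf))
  cuts_old <- stats::pnorm(c(criteria, Inf), mean = d_f)
  p_new <- diff(c(0, cuts_new))
  p_old <- (1 - R) * diff(c(0, cuts_old))
  p_old[6] <- p_old[6] + R
  -(sum(old_counts * log(pmax(p_old, 1e-12))) +
      sum(new_counts * log(pmax(p_new, 1e-12))))
}

# Sum of squared errors between observed and model-implied ROC points
# (both hit and false-alarm coordinates, 5 thresholds).
dpsd_sse <- function(theta, roc) {
  R <- stats::plogis(theta[1])
  d_f <- theta[2]
  criteria <- theta[3] + c(0, cumsum(exp(theta[4:7])))
  thr <- rev(criteria)   # thresholds for P(conf >= 6), ..., P(conf >= 2)
  hit_pred <- R + (1 - R) * stats::pnorm(d_f - thr)
  fa_pred <- stats::pnorm(-thr)
  sum((roc$hit_cum - hit_pred)^2) + sum((roc$fa_cum - fa_pred)^2)
}

# Moment-based starting value: criteria from the corrected distractor
# cumulative rates, d_f from the corrected yes/no collapse, R from the
# excess of top-category hits over what familiarity alone would predict.
dpsd_start <- function(old_counts, new_counts) {
  n_old <- sum(old_counts)
  n_new <- sum(new_counts)
  fa_cum <- (cumsum(rev(new_counts))[1:5] + 0.5) / (n_new + 1)
  crit <- rev(stats::qnorm(1 - fa_cum))
  crit <- cummax(crit + seq(0, 2e-3, length.out = 5)) +
    seq(0, 2e-3, length.out = 5)  # enforce strict order at start
  h <- corrected_rate(sum(old_counts[4:6]), n_old)
  f <- corrected_rate(sum(new_counts[4:6]), n_new)
  d0 <- max(0.1, stats::qnorm(h) - stats::qnorm(f))
  h6 <- corrected_rate(old_counts[6], n_old)
  r0 <- min(0.9, max(0.02, h6 - stats::pnorm(d0 - crit[5])))
  c(stats::qlogis(r0), d0, crit[1], log(pmax(diff(crit), 1e-3)))
}

# Fixed multistart perturbations (in the unconstrained parameterization);
# deterministic so that fits are bit-reproducible.
dpsd_perturbations <- matrix(c(
   0.0,  0.0,  0.0,  0.0,  0.0,  0.0,  0.0,
  -2.0,  0.5,  0.0,  0.0,  0.0,  0.0,  0.0,
   1.0, -0.5, -0.3,  0.2,  0.2,  0.2,  0.2,
  -1.0,  1.0,  0.3, -0.2, -0.2, -0.2, -0.2,
   2.0,  0.8, -0.5,  0.4, -0.3,  0.3, -0.3,
  -3.0, -0.5,  0.5, -0.4,  0.3, -0.3,  0.3
), ncol = 7, byrow = TRUE)

#' Fit the dual-process signal-detection model to a confidence table
#'
#' Estimates recollection `R`, familiarity strength `d_f` and five
#' confidence criteria from a 2 x 6 table of confidence counts by maximum
#' likelihood (default) or by least squares on the ROC points. The fitted
#' `R` is the ROC task's recollection index and `d_f` its familiarity
#' index.
#'
#' Optimization runs over an unconstrained parameterization (logit `R`,
#' free `d_f`, first criterion plus log-increments) with a deterministic
#' multistart: a moment-based start plus fixed perturbations. Predicted
#' category probabilities are floored at 1e-12 inside the likelihood so
#' zero cells never produce an infinite objective.
#'
#' @inheritParams build_roc
#' @param method `"ml"` for multinomial maximum likelihood (default) or
#'   `"sse"` for least squares on the 5 ROC points.
#' @param n_starts Number of multistart optimizations (1..6); the first is
#'   the moment-based start.
#' @param reltol Relative convergence tolerance on the objective.
#' @return An object of class `"dpsd_fit"`: list with `R`, `d_f`,
#'   `criteria` (sorted, length 5), `log_lik` (ML objective at the optimum;
#'   `NA` for SSE fits, which carry `sse` instead), `converged`,
#'   `identifiable`, `n_restarts_used`, `method`.
#' @examples
#' probs <- dpsd_probs(0.4, 1, c(-0.8, -0.3, 0.1, 0.6, 1.1))
#' old <- round(1000 * probs$old); new <- round(1000 * probs$new)
#' fit_dpsd(old, new)
#' @export
fit_dpsd <- function(old_counts, new_counts, method = c("ml", "sse"),
                     n_starts = 5L, reltol = 1e-8) {
  method <- match.arg(method)
  check_confusion(old_counts, new_counts)
  n_starts <- max(1L, min(nrow(dpsd_perturbations), as.integer(n_starts)))

  # Degenerate: all mass in the same single category for both rows gives no
  # information about any parameter; flag rather than raise.
  occ_old <- which(old_counts > 0)
  occ_new <- which(new_counts > 0)
  if (length(occ_old) == 1L && length(occ_new) == 1L && occ_old == occ_new) {
    return(structure(
      list(R = 0, d_f = 0, criteria = c(-1, -0.5, 0, 0.5, 1),
           log_lik = 0, sse = NA_real_, converged = FALSE,
           identifiable = FALSE, n_restarts_used = 0L, method = method),
      class = "dpsd_fit"
    ))
  }

  if (method == "ml") {
    obj <- function(theta) dpsd_nll(theta, old_counts, new_counts)
  } else {
    roc <- build_roc(old_counts, new_counts)
    obj <- function(theta) dpsd_sse(theta, roc)
  }

  start0 <- dpsd_start(old_counts, new_counts)
  best <- NULL
  for (k in seq_len(n_starts)) {
    th0 <- start0 + dpsd_perturbations[k, ]
    # box bounds regularize likelihood ridges (e.g. perfect separation,
    # where unbounded d_f and R -> 1 fit equally well): familiarity
    # strength and criteria are kept in a plausible z-range
    opt <- stats::nlminb(th0, obj,
                         lower = c(-15, -8, -8, rep(-8, 4)),
                         upper = c(15, 8, 8, rep(3, 4)),
                         control = list(rel.tol = reltol, iter.max = 500))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }

  theta <- best$par
  criteria <- theta[3] + c(0, cumsum(exp(theta[4:7])))
  structure(
    list(R = stats::plogis(theta[1]),
         d_f = theta[2],
         criteria = criteria,
         log_lik = if (method == "ml") -best$objective else NA_real_,
         sse = if (method == "sse") best$objective else NA_real_,
         converged = best$convergence == 0L,
         identifiable = TRUE,
         n_restarts_used = n_starts,
         method = method),
    class = "dpsd_fit"
  )
}

#' @export
print.dpsd_fit <- function(x, digits = 3, ...) {
  cat("Dual-process signal-detection fit (", x$method, ")\n", sep = "")
  if (!x$identifiable) {
    cat("  degenerate table: parameters not identifiable\n")
    return(invisible(x))
  }
  cat(sprintf("  R (recollection)  = %.*f\n", digits, x$R))
  cat(sprintf("  d_f (familiarity) = %.*f\n", digits, x$d_f))
  cat("  criteria:", paste(formatC(x$criteria, digits = digits, format = "f"),
                           collapse = " "), "\n")
  if (x$method == "ml")
    cat(sprintf("  log-likelihood = %.*f\n", digits, x$log_lik))
  else
    cat(sprintf("  SSE = %.*g\n", digits, x$sse))
  if (!x$converged) cat("  warning: optimizer did not report convergence\n")
  invisible(x)
}
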