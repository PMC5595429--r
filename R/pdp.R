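#' Process-dissociation estimates of recollection and familiarity
#'
#' Scores the associative-pairs recognition task by the process dissociation
#' logic. "Yes" responses to intact (target) pairs are *included* items —
#' recollection and familiarity both support them. "Yes" responses to
#' recombined pairs are *excluded* items — recollection of the original
#' pairing would have vetoed them, so they are attributed to familiarity
#' alone. The indices are
#' \deqn{R = p(\mathrm{included}) - p(\mathrm{excluded}), \qquad
#'       F = p(\mathrm{excluded}) / (1 - R).}
#' Overall discrimination d' and criterion c are computed from intact-pair
#' hits against the chosen false-alarm class via [dprime_c()].
#'
#' @param intact_yes "Yes" count to intact (target) pairs.
#' @param recombined_yes "Yes" count to recombined pairs.
#' @param new_yes "Yes" count to new pairs.
#' @param n_intact,n_recombined,n_new Pair totals per class (default 40
#'   each, the task design).
#' @param correct_rates If `TRUE` (default) every rate passes through
#'   [corrected_rate()] first, which keeps \eqn{R < 1} and hence `F`
#'   defined. With the correction off, raw proportions are used and `F` is
#'   returned as `NA` (flagged) when \eqn{R = 1}.
#' @param fa_class Which distractor class defines d' and c: `"new"`
#'   (default; pure old/new discrimination — recombined pairs are already
#'   consumed by the PDP equations) or `"pooled"` (new + recombined).
#' @return An object of class `"pdp_indices"`: list with `p_included`,
#'   `p_excluded`, `R_pdp`, `F_pdp` (probability scale), `f_defined`,
#'   `d_prime`, `criterion_c`, `hit_rate`, `fa_rate`.
#' @examples
#' pdp_indices(36, 12, 5)
#' @export
pdp_indices <- function(intact_yes, recombined_yes, new_yes,
                        n_intact = 40L, n_recombined = 40L, n_new = 40L,
                        correct_rates = TRUE,
                        fa_class = c("new", "pooled")) {
  fa_class <- match.arg(fa_class)
  for (cnt in list(c(intact_yes, n_intact), c(recombined_yes, n_recombined),
                   c(new_yes, n_new))) {
    if (cnt[2] <= 0 || cnt[1] < 0 || cnt[1] > cnt[2])
      stop("each 'yes' count must lie in [0, class total], totals positive")
  }
  rate <- if (correct_rates) corrected_rate else function(x, n) x / n
  p_inc <- rate(intact_yes, n_intact)
  p_exc <- rate(recombined_yes, n_recombined)
  r <- p_inc - p_exc
  if (r < 1) {
    f <- p_exc / (1 - r)
    f_defined <- TRUE
  } else {
    f <- NA_real_
    f_defined <- FALSE
  }
  sdt <- if (fa_class == "new") {
    dprime_c(intact_yes, n_intact, new_yes, n_new)
  } else {
    dprime_c(intact_yes, n_intact, new_yes + recombined_yes,
             n_new + n_recombined)
  }
  structure(
    list(p_included = p_inc, p_excluded = p_exc,
         R_pdp = r, F_pdp = f, f_defined = f_defined,
         d_prime = sdt$d_prime, criterion_c = sdt$criterion_c,
         hit_rate = sdt$hit_rate, fa_rate = sdt$fa_rate,
         fa_class = fa_class),
    class = "pdp_indices"
  )
}

#' @export
print.pdp_indices <- function(x, digits = 3, ...) {
  cat("Process-dissociation indices\n")
  cat(sprintf("  p(included) = %.*f   p(excluded) = %.*f\n",
              digits, x$p_included, digits, x$p_excluded))
  cat(sprintf("  R = %.*f   F = %s\n", digits, x$R_pdp,
              if (x$f_defined) formatC(x$F_pdp, digits = digits, format = "f")
              else "undefined (R = 1)"))
  cat(sprintf("  d' = %.*f   c = %.*f   (false alarms: %s pairs)\n",
              digits, x$d_prime, digits, x$criterion_c, x$fa_class))
  invisible(x)
}
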