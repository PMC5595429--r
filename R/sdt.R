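#' Snodgrass-Corwin corrected response rate
#'
#' Converts a success count out of a trial total into a proportion strictly
#' inside (0, 1) using the correction \eqn{(x + 0.5) / (n + 1)}. Rates of 0
#' and 1 are thereby avoided, so the standard-normal quantile transform used
#' by [dprime_c()] is always finite. The same correction is applied to every
#' hit and false-alarm rate in the package before any quantile transform.
#'
#' @param successes Non-negative integer count of successes (e.g. hits).
#' @param trials Positive integer number of trials. May be a vector recycled
#'   against `successes`.
#' @return Numeric vector of corrected proportions in the open interval
#'   (0, 1).
#' @examples
#' corrected_rate(0, 60)   # 0.5/61, not 0
#' corrected_rate(60, 60)  # 60.5/61, not 1
#' corrected_rate(30, 60)  # exactly 0.5
#' @export
corrected_rate <- function(successes, trials) {
  if (length(successes) == 0L || length(trials) == 0L)
    stop("'successes' and 'trials' must be non-empty")
  if (any(!is.finite(successes)) || any(!is.finite(trials)))
    stop("counts must be finite")
  if (any(trials <= 0))
    stop("'trials' must be positive")
  if (any(successes < 0) || any(successes > trials))
    stop("'successes' must lie in [0, trials]")
  (successes + 0.5) / (trials + 1)
}

#' Equal-variance signal-detection indices d' and criterion c
#'
#' Computes discrimination d' and response criterion c from hit and
#' false-alarm counts. Both rates are first passed through
#' [corrected_rate()], then transformed with the standard-normal inverse CDF:
#' \deqn{d' = z(H) - z(F), \quad c = -\tfrac{1}{2}(z(H) + z(F)).}
#' Negative c indicates a liberal bias (many "yes" responses), positive c a
#' conservative one.
#'
#' @param hits Hit count (studied items called "old").
#' @param hit_trials Number of studied items.
#' @param fas False-alarm count (unstudied items called "old").
#' @param fa_trials Number of unstudied items.
#' @return An object of class `"sdt_indices"`: a list with elements
#'   `hit_rate`, `fa_rate` (corrected rates), `d_prime` and `criterion_c`.
#' @examples
#' dprime_c(50, 60, 10, 60)
#' dprime_c(30, 60, 30, 60)  # equal rates: d' = 0, c = 0
#' @seealso [corrected_rate()]
#' @export
dprime_c <- function(hits, hit_trials, fas, fa_trials) {
  h <- corrected_rate(hits, hit_trials)
  f <- corrected_rate(fas, fa_trials)
  sdt_from_rates(h, f)
}

# d'/c from rates already in (0,1); shared by dprime_c and the RKG
# familiarity index (whose component rates are themselves derived).
sdt_from_rates <- function(hit_rate, fa_rate) {
  if (any(hit_rate <= 0 | hit_rate >= 1 | fa_rate <= 0 | fa_rate >= 1))
    stop("rates must lie strictly inside (0, 1); apply corrected_rate() first")
  zh <- stats::qnorm(hit_rate)
  zf <- stats::qnorm(fa_rate)
  structure(
    list(hit_rate = hit_rate, fa_rate = fa_rate,
         d_prime = zh - zf, criterion_c = -0.5 * (zh + zf)),
    class = "sdt_indices"
  )
}

#' @export
print.sdt_indices <- function(x, digits = 3, ...) {
  cat("Signal-detection indices\n")
  cat(sprintf("  hit rate (corrected): %.*f   fa rate (corrected): %.*f\n",
              digits, x$hit_rate, digits, x$fa_rate))
  cat(sprintf("  d' = %.*f   c = %.*f\n",
              digits, x$d_prime, digits, x$criterion_c))
  invisible(x)
}
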