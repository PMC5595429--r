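#' Remember/Know/Guess estimates of recollection and familiarity
#'
#' Scores the Remember/Know/Guess task. Each "yes" response carries an
#' attribution: R (remembered with encoding context), K (recognized without
#' context) or G (guessed). The default estimator follows the independence
#' Remember/Know logic: recollection is the corrected Remember rate for
#' targets minus that for distractors,
#' \deqn{R_{rkg} = P^*(R \mid old) - P^*(R \mid new),}
#' and familiarity is a d'-type contrast of the familiarity-driven "yes"
#' rates, each conditioned on the item not being recollected:
#' \deqn{F_{old} = \frac{P^*(K \cup G, yes \mid old)}{1 - P^*(R \mid old)},
#'       \quad
#'       F_{new} = \frac{P^*(K \cup G, yes \mid new)}{1 - P^*(R \mid new)},
#'       \quad F_{rkg} = z(F_{old}) - z(F_{new}).}
#' \eqn{P^*} denotes the Snodgrass-Corwin [corrected_rate()] with the item
#' class total as denominator. The conditional rates are clamped into the
#' corrected open interval before the quantile transform (a row with no "no"
#' responses would otherwise give a rate of exactly 1). Overall d' and c use
#' all "yes" responses against all "no" responses.
#'
#' @param old Named integer vector `c(R=, K=, G=, no=)` of response counts
#'   for studied items (row sum = number of targets, default design 60).
#' @param new Same for unstudied items (default design 60 distractors).
#' @param variant `"irk"` (default, independence estimator above) or
#'   `"literal"`: recollection as the corrected yes-rate difference scaled
#'   by the proportion of target "yes" responses attributed R,
#'   \eqn{(H^* - FA^*) \cdot P(R \mid yes, old)}; familiarity unchanged.
#' @param drop_guesses If `TRUE`, G trials are removed from both rows (and
#'   from the class totals) before any rate is formed. Default `FALSE`:
#'   guesses count as familiarity-driven "yes" responses.
#' @return An object of class `"rkg_indices"`: list with `R_rkg`, `F_rkg`
#'   (z-units), `d_prime`, `criterion_c`, `yes_rate_old`, `yes_rate_new`,
#'   `r_rate_old`, `r_rate_new`, `f_rate_old`, `f_rate_new`, `f_defined`.
#' @examples
#' rkg_indices(c(R = 30, K = 12, G = 3, no = 15),
#'             c(R = 1, K = 6, G = 5, no = 48))
#' @export
rkg_indices <- function(old, new, variant = c("irk", "literal"),
                        drop_guesses = FALSE) {
  variant <- match.arg(variant)
  old <- check_rkg_row(old, "old")
  new <- check_rkg_row(new, "new")
  if (drop_guesses) {
    old["G"] <- 0L
    new["G"] <- 0L
  }
  n_old <- sum(old)
  n_new <- sum(new)

  r_old <- corrected_rate(old[["R"]], n_old)
  r_new <- corrected_rate(new[["R"]], n_new)
  yes_old <- old[["R"]] + old[["K"]] + old[["G"]]
  yes_new <- new[["R"]] + new[["K"]] + new[["G"]]

  # familiarity-driven "yes" rates under the independence correction
  f_old <- corrected_rate(old[["K"]] + old[["G"]], n_old) / (1 - r_old)
  f_new <- corrected_rate(new[["K"]] + new[["G"]], n_new) / (1 - r_new)
  f_defined <- (1 - r_old) > 1e-9 && (1 - r_new) > 1e-9
  lo <- 0.5 / (max(n_old, n_new) + 1)
  f_old <- min(max(f_old, lo), 1 - lo)
  f_new <- min(max(f_new, lo), 1 - lo)
  f_rkg <- if (f_defined) stats::qnorm(f_old) - stats::qnorm(f_new)
           else NA_real_

  sdt <- dprime_c(yes_old, n_old, yes_new, n_new)

  r_rkg <- if (variant == "irk") {
    r_old - r_new
  } else {
    p_r_given_yes <- if (yes_old > 0) old[["R"]] / yes_old else 0
    (sdt$hit_rate - sdt$fa_rate) * p_r_given_yes
  }

  structure(
    list(R_rkg = r_rkg, F_rkg = f_rkg, f_defined = f_defined,
         d_prime = sdt$d_prime, criterion_c = sdt$criterion_c,
         yes_rate_old = sdt$hit_rate, yes_rate_new = sdt$fa_rate,
         r_rate_old = r_old, r_rate_new = r_new,
         f_rate_old = f_old, f_rate_new = f_new,
         variant = variant),
    class = "rkg_indices"
  )
}

check_rkg_row <- function(x, what) {
  need <- c("R", "K", "G", "no")
  if (is.null(names(x)) || !all(need %in% names(x)))
    stop("'", what, "' must be a named count vector with entries R, K, G, no")
  x <- x[need]
  if (any(!is.finite(x)) || any(x < 0))
    stop("'", what, "' counts must be non-negative and finite")
  if (sum(x) <= 0)
    stop("'", what, "' row must have a positive total")
  x
}

#' @export
print.rkg_indices <- function(x, digits = 3, ...) {
  cat("Remember/Know/Guess indices (", x$variant, ")\n", sep = "")
  cat(sprintf("  R = %.*f   F = %s (z-units)\n", digits, x$R_rkg,
              if (x$f_defined) formatC(x$F_rkg, digits = digits, format = "f")
              else "undefined"))
  cat(sprintf("  d' = %.*f   c = %.*f\n", digits, x$d_prime,
              digits, x$criterion_c))
  invisible(x)
}
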