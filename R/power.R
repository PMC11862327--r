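#' Power of a repeated-measures within-factors F test
#'
#' Noncentral-F power in the G*Power within-factors convention: with effect
#' size f, N subjects, m repeated measurements, correlation rho among them
#' and nonsphericity epsilon, the noncentrality is
#' `lambda = f^2 * N * m * epsilon / (1 - rho)` with numerator df
#' `(m - 1) * epsilon` and denominator df
#' `(N - groups) * (m - 1) * epsilon`.
#'
#' @param n total sample size (must exceed `groups`).
#' @param f Cohen's f effect size.
#' @param alpha significance level.
#' @param groups number of groups (default 2).
#' @param m number of repeated measurements (default 4).
#' @param rho correlation among repeated measures (default 0.8).
#' @param epsilon nonsphericity correction in (0, 1\] (default 1).
#' @return achieved power (1 - beta).
#' @examples
#' achievedPower(34, f = 0.15)
#' @export
achievedPower <- function(n, f, alpha = 0.05, groups = 2, m = 4, rho = 0.8,
                          epsilon = 1) {
  stopIfNot(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  stopIfNot(f >= 0, "f must be non-negative")
  stopIfNot(rho >= 0 && rho < 1, "rho must lie in [0, 1)")
  stopIfNot(m >= 2, "need at least two repeated measurements")
  stopIfNot(epsilon > 0 && epsilon <= 1, "epsilon must lie in (0, 1]")
  stopIfNot(n > groups, "n must exceed the number of groups")
  lambda <- f^2 * n * m * epsilon / (1 - rho)
  df1 <- (m - 1) * epsilon
  df2 <- (n - groups) * (m - 1) * epsilon
  pf(qf(1 - alpha, df1, df2), df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Smallest sample size reaching a target power
#'
#' Iterates the total sample size upward and returns the first value whose
#' [achievedPower()] meets `targetPower`. By default the search steps in
#' multiples of `groups` (balanced groups, as G*Power reports total sample
#' sizes); set `balanced = FALSE` to step by 1.
#'
#' @inheritParams achievedPower
#' @param targetPower required power (default 0.90).
#' @param balanced step in multiples of `groups` (default TRUE).
#' @param nMax search bound (default 1e5).
#' @return the required total sample size.
#' @examples
#' requiredSampleSize(f = 0.15, targetPower = 0.90)
#' @export
requiredSampleSize <- function(f, alpha = 0.05, targetPower = 0.90,
                               groups = 2, m = 4, rho = 0.8, epsilon = 1,
                               balanced = TRUE, nMax = 1e5) {
  stopIfNot(targetPower > 0 && targetPower < 1,
            "targetPower must lie in (0, 1)")
  stopIfNot(f > 0, "f must be positive for a finite sample size")
  step <- if (balanced) groups else 1L
  n <- if (balanced) {
    step * ceiling((groups + 1) / step)
  } else {
    groups + 1L
  }
  while (n <= nMax) {
    if (achievedPower(n, f, alpha, groups, m, rho, epsilon) >= targetPower) {
      return(n)
    }
    n <- n + step
  }
  stop("target power unreachable within nMax", call. = FALSE)
}

#' Blinding accuracy with an exact binomial test
#'
#' @param correct number of correct condition guesses.
#' @param total total number of guesses.
#' @return a list: `accuracy` (percent, one decimal), `correct`, `total`,
#'   `p` (two-sided exact binomial test against chance 0.5).
#' @examples
#' blindingAccuracy(66, 145)
#' @export
blindingAccuracy <- function(correct, total) {
  stopIfNot(total > 0, "total must be positive")
  stopIfNot(correct >= 0 && correct <= total,
            "correct must lie in [0, total]")
  list(accuracy = round(100 * correct / total, 1),
       correct = correct, total = total,
       p = binom.test(correct, total, p = 0.5)$p.value)
}
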