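#' Baseline-correct per-phase indices within each session
#'
#' Subtracts each session's baseline value of every index from the same
#' session's later phases, separately for the stimulation and caloric-load
#' phases. Sessions without a baseline row are dropped with a message.
#'
#' @param summary a data frame with columns `subject`, `session`,
#'   `condition`, `side`, `phase` and one column per index.
#' @param indices character vector of index columns; defaults to every
#'   numeric column that is not a label.
#' @return a data frame of per-session deltas (`phase` keeps the later-phase
#'   label; values are phase minus baseline).
#' @export
baselineCorrect <- function(summary,
                            indices = NULL) {
  labels <- c("subject", "session", "condition", "side", "phase")
  stopIfNot(all(labels %in% names(summary)),
            "summary must carry subject/session/condition/side/phase")
  if (is.null(indices)) {
    indices <- setdiff(names(summary)[vapply(summary, is.numeric, TRUE)],
                       c(labels, "n_windows_used", "retained_fraction",
                         "session", "subject"))
  }
  out <- list()
  for (key in split(seq_len(nrow(summary)),
                    paste(summary$subject, summary$session))) {
    block <- summary[key, , drop = FALSE]
    base <- block[block$phase == "baseline", , drop = FALSE]
    if (nrow(base) != 1L) {
      message("session without unique baseline dropped: subject ",
              block$subject[1], " session ", block$session[1])
      next
    }
    later <- block[block$phase != "baseline", , drop = FALSE]
    for (i in seq_len(nrow(later))) {
      row <- later[i, c(labels, indices), drop = FALSE]
      row[indices] <- later[i, indices] - base[1, indices]
      out[[length(out) + 1L]] <- row
    }
  }
  stopIfNot(length(out) > 0L, "no session with baseline and a later phase")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Net stimulation effect: taVNS minus sham pairwise differences
#'
#' Pairs baseline-corrected deltas by subject, side and phase and returns
#' the taVNS minus sham difference per pair. Unmatched rows are dropped with
#' a message.
#'
#' @param deltas output of [baselineCorrect()].
#' @param indices index columns; default: all numeric non-label columns.
#' @return a data frame with columns `subject`, `side`, `phase` and one
#'   difference column per index.
#' @export
netEffect <- function(deltas, indices = NULL) {
  labels <- c("subject", "session", "condition", "side", "phase")
  if (is.null(indices)) {
    indices <- setdiff(names(deltas)[vapply(deltas, is.numeric, TRUE)],
                       labels)
  }
  tav <- deltas[deltas$condition == "taVNS", , drop = FALSE]
  sha <- deltas[deltas$condition == "sham", , drop = FALSE]
  m <- merge(tav, sha, by = c("subject", "side", "phase"),
             suffixes = c(".tavns", ".sham"))
  dropped <- nrow(tav) + nrow(sha) - 2L * nrow(m)
  if (dropped > 0L) message(dropped, " unmatched delta rows dropped")
  stopIfNot(nrow(m) > 0L, "no matched taVNS/sham pairs")
  out <- m[, c("subject", "side", "phase"), drop = FALSE]
  for (idx in indices) {
    out[[idx]] <- m[[paste0(idx, ".tavns")]] - m[[paste0(idx, ".sham")]]
  }
  out[order(out$subject, out$side, out$phase), , drop = FALSE]
}

#' Percentile bootstrap of a mean difference
#'
#' Resamples the paired differences with replacement `nResamples` times.
#' The estimate is the sample mean; the confidence interval is the
#' percentile interval at `1 - alpha`; the two-tailed p-value is twice the
#' smaller tail proportion of resampled means on either side of zero,
#' floored at `1/nResamples` and capped at 1.
#'
#' @param diffs numeric vector of paired differences (n >= 5).
#' @param nResamples number of bootstrap resamples (default 50000).
#' @param alpha two-sided significance level (default 0.05).
#' @param seed optional integer seed for the resampling stream.
#' @return a one-row data frame: `b`, `ci_lo`, `ci_hi`, `p_boot`, `n`.
#' @examples
#' bootstrapEffect(c(-1, -2, -3, -4, -5), nResamples = 2000, seed = 1)
#' @export
bootstrapEffect <- function(diffs, nResamples = 50000, alpha = 0.05,
                            seed = NULL) {
  stopIfNot(is.numeric(diffs) && length(diffs) >= 5L,
            "need at least 5 paired differences")
  stopIfNot(all(is.finite(diffs)), "differences must be finite")
  stopIfNot(nResamples >= 1000, "use at least 1000 resamples")
  stopIfNot(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  n <- length(diffs)
  b <- mean(diffs)
  means <- withSeed(seed, {
    colMeans(matrix(sample(diffs, n * nResamples, replace = TRUE), nrow = n))
  })
  ci <- unname(quantile(means, c(alpha / 2, 1 - alpha / 2)))
  p <- 2 * min(mean(means <= 0), mean(means >= 0))
  p <- min(max(p, 1 / nResamples), 1)
  data.frame(b = b, ci_lo = ci[1], ci_hi = ci[2], p_boot = p, n = n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  stopIfNot(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Cohen's dz for paired differences
#'
#' @param diffs numeric vector of paired differences (n >= 2, non-zero
#'   spread).
#' @return `mean(diffs) / sd(diffs)` (sample SD).
#' @export
cohensDz <- function(diffs) {
  stopIfNot(is.numeric(diffs) && length(diffs) >= 2L, "need n >= 2")
  s <- sd(diffs)
  stopIfNot(s > 0, "zero variance: dz undefined")
  mean(diffs) / s
}

# integrand of the JZS alternative marginal likelihood: noncentral-t
# density of the observed t at ncp delta*sqrt(n), weighted by the Cauchy
# effect-size prior
jzsIntegrand <- function(delta, t, n, rscale) {
  # dt(ncp) can warn about its final-digit precision; that accuracy is far
  # inside the quadrature tolerance
  suppressWarnings(dt(t, df = n - 1, ncp = delta * sqrt(n))) *
    dcauchy(delta, 0, rscale)
}

#' JZS Bayes factor for a one-sample (paired) t-test
#'
#' Default Bayesian t-test: the alternative places a Cauchy prior with
#' scale `rscale` on the standardized effect size, the null fixes it at
#' zero. `BF10` is the ratio of marginal likelihoods of the observed t
#' statistic, the numerator integrated numerically over the prior.
#'
#' @param diffs numeric vector of paired differences; alternatively pass
#'   `t` and `n` directly.
#' @param t,n t statistic and sample size (used when `diffs` is missing).
#' @param rscale Cauchy prior scale (default 0.5, reflecting
#'   small-to-moderate expected effects).
#' @return `BF10` (> 1 favours the alternative).
#' @examples
#' jzsBayesFactor(t = 0, n = 36)   # < 1: maximal support for the null
#' @export
jzsBayesFactor <- function(diffs = NULL, t = NULL, n = NULL, rscale = 0.5) {
  if (!is.null(diffs)) {
    stopIfNot(length(diffs) >= 2L, "need n >= 2")
    n <- length(diffs)
    s <- sd(diffs)
    stopIfNot(s > 0, "zero variance: t statistic undefined")
    t <- mean(diffs) / (s / sqrt(n))
  }
  stopIfNot(!is.null(t) && !is.null(n) && n >= 2,
            "provide diffs, or t and n")
  stopIfNot(rscale > 0, "rscale must be positive")
  alt <- integrate(jzsIntegrand, -Inf, Inf, t = t, n = n, rscale = rscale,
                   rel.tol = 1e-10, abs.tol = 0, subdivisions = 400L)
  if (alt$message != "OK") {
    stop("numerical integration failed: ", alt$message, call. = FALSE)
  }
  alt$value / dt(t, df = n - 1)
}

#' MANOVA with Pillai's trace
#'
#' Fits the multivariate linear model `Y ~ X`, forms the hypothesis (H) and
#' error (E) cross-product matrices for the non-intercept terms, and
#' computes Pillai's trace `V = sum eigenvalues of H (H + E)^-1` with its
#' standard F approximation. With a single response column this reduces
#' exactly to the univariate ANOVA F test.
#'
#' @param y numeric matrix of dependent variables (one column per index).
#' @param x design: a factor, a numeric vector/matrix of regressors, or a
#'   data frame of them (an intercept is always added).
#' @return a list of class `ManovaResult`: `pillai`, `F`, `df1`, `df2`, `p`.
#' @examples
#' y <- cbind(a = rnorm(30), b = rnorm(30))
#' manovaPillai(y, gl(3, 10))
#' @export
manovaPillai <- function(y, x) {
  y <- as.matrix(y)
  stopIfNot(is.numeric(y), "y must be numeric")
  stopIfNot(nrow(y) >= 3L, "too few observations")
  xdf <- if (is.data.frame(x)) x else data.frame(x = x)
  stopIfNot(nrow(xdf) == nrow(y), "x and y sizes differ")
  X <- model.matrix(~ ., data = xdf)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$qraux == 0 | seq_len(ncol(X)) > qx$rank]
    stop("rank-deficient design; aliased: ",
         paste(tail(colnames(X), ncol(X) - qx$rank), collapse = ", "),
         call. = FALSE)
  }
  q <- qx$rank - 1L                       # hypothesis df (non-intercept)
  stopIfNot(q >= 1L, "design has no effect term")
  v <- nrow(y) - qx$rank                  # error df
  stopIfNot(v >= 1L, "no error degrees of freedom")
  fit <- stats::lm.fit(X, y)
  res <- as.matrix(fit$residuals)
  E <- crossprod(res)
  fitted0 <- matrix(colMeans(y), nrow(y), ncol(y), byrow = TRUE)
  H <- crossprod(as.matrix(y - res) - fitted0)
  p <- ncol(y)
  HE <- H + E
  if (rcond(HE) < 1e-12) {
    stop("H + E is (near-)singular; check for duplicated or constant ",
         "response columns", call. = FALSE)
  }
  V <- sum(Re(eigen(solve(HE, H), only.values = TRUE)$values))
  s <- min(p, q)
  mm <- (abs(p - q) - 1) / 2
  nn <- (v - p - 1) / 2
  df1 <- s * (2 * mm + s + 1)
  df2 <- s * (2 * nn + s + 1)
  Fstat <- (df2 / df1) * V / (s - V)
  structure(list(pillai = V, F = Fstat, df1 = df1, df2 = df2,
                 p = pf(Fstat, df1, df2, lower.tail = FALSE)),
            class = "ManovaResult")
}

#' @export
print.ManovaResult <- function(x, ...) {
  cat(sprintf("Pillai's trace V = %.4f, F(%g, %g) = %.3f, p = %.4g\n",
              x$pillai, x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Compare cross-side correlations between conditions (Fisher z)
#'
#' Tests whether taVNS-induced changes correlate more strongly across
#' stimulation sides than sham-induced changes: the paired correlation
#' coefficients (one pair per cardiovascular index) are Fisher
#' z-transformed and their differences submitted to a one-sample t-test
#' against zero.
#'
#' @param rTavns,rSham numeric vectors of correlation coefficients (equal
#'   length, strictly inside (-1, 1)).
#' @return a list: `t`, `df`, `p`, `meanZDiff`.
#' @examples
#' sideCorrelationTest(c(.6, .5, .7), c(.2, .1, .3))
#' @export
sideCorrelationTest <- function(rTavns, rSham) {
  stopIfNot(length(rTavns) == length(rSham) && length(rTavns) >= 2L,
            "need matched correlation vectors of length >= 2")
  stopIfNot(all(abs(c(rTavns, rSham)) < 1),
            "correlations must lie strictly inside (-1, 1)")
  d <- atanh(rTavns) - atanh(rSham)
  n <- length(d)
  s <- sd(d)
  if (s == 0) {
    if (all(d == 0)) return(list(t = 0, df = n - 1L, p = 1, meanZDiff = 0))
    stop("degenerate input: identical nonzero differences", call. = FALSE)
  }
  tstat <- mean(d) / (s / sqrt(n))
  list(t = tstat, df = n - 1L, p = 2 * pt(-abs(tstat), n - 1L),
       meanZDiff = mean(d))
}

#' Bootstrap effect table for all indices and phases
#'
#' Runs the full per-index inference on a net-effect table: main effects
#' average each subject's left- and right-side differences first, then the
#' averaged differences are bootstrapped; Cohen's dz and the JZS Bayes
#' factor are computed on the same differences, and Benjamini-Hochberg
#' adjustment is applied across all tests in the table.
#'
#' @param net output of [netEffect()].
#' @param indices index columns to test (default: all numeric non-label).
#' @param bySide additionally report per-side effects (default FALSE).
#' @param nResamples,alpha bootstrap settings (defaults 50000, 0.05).
#' @param rscale Cauchy prior scale for the Bayes factor (default 0.5).
#' @param seed root seed; each test gets a derived, recorded seed.
#' @param minN refuse inference below this many subjects (default 5).
#' @return a data frame with one row per index x phase (x side), columns
#'   `index`, `phase`, `side`, `b`, `ci_lo`, `ci_hi`, `p_boot`, `p_adj`,
#'   `dz`, `bf10`, `n`, `seed`.
#' @export
analyzeEffects <- function(net, indices = NULL, bySide = FALSE,
                           nResamples = 50000, alpha = 0.05, rscale = 0.5,
                           seed = NULL, minN = 5) {
  labels <- c("subject", "side", "phase")
  stopIfNot(all(labels %in% names(net)), "net must come from netEffect()")
  if (is.null(indices)) {
    indices <- setdiff(names(net)[vapply(net, is.numeric, TRUE)], labels)
  }
  cells <- expand.grid(index = indices, phase = unique(net$phase),
                       side = if (bySide) c("both", "left", "right")
                              else "both",
                       stringsAsFactors = FALSE)
  seeds <- deriveSeeds(seed, sprintf("%s_%s_%s", cells$index, cells$phase,
                                     cells$side))
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sub <- net[net$phase == cells$phase[i], , drop = FALSE]
    if (cells$side[i] == "both") {
      agg <- tapply(sub[[cells$index[i]]], sub$subject, mean, na.rm = TRUE)
      diffs <- as.numeric(agg)
    } else {
      diffs <- sub[[cells$index[i]]][sub$side == cells$side[i]]
    }
    diffs <- diffs[is.finite(diffs)]
    stopIfNot(length(diffs) >= minN,
              sprintf("fewer than %d subjects for %s/%s; inference refused",
                      minN, cells$index[i], cells$phase[i]))
    bt <- bootstrapEffect(diffs, nResamples = nResamples, alpha = alpha,
                          seed = seeds[i])
    rows[[i]] <- data.frame(
      index = cells$index[i], phase = cells$phase[i], side = cells$side[i],
      bt[, c("b", "ci_lo", "ci_hi", "p_boot")],
      dz = if (sd(diffs) > 0) cohensDz(diffs) else NA_real_,
      bf10 = if (sd(diffs) > 0) jzsBayesFactor(diffs, rscale = rscale)
             else NA_real_,
      n = length(diffs), seed = unname(seeds[i]))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bhAdjust(out$p_boot)
  rownames(out) <- NULL
  out[, c("index", "phase", "side", "b", "ci_lo", "ci_hi", "p_boot",
          "p_adj", "dz", "bf10", "n", "seed")]
}
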