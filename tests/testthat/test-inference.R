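mkSummary <- function() {
  grid <- expand.grid(subject = 1:6, session = 1:4,
                      phase = c("baseline", "stimulation", "caloric_load"),
                      stringsAsFactors = FALSE)
  grid$condition <- ifelse(grid$session %in% c(1, 3), "taVNS", "sham")
  grid$side <- ifelse(grid$session <= 2, "left", "right")
  grid$rmssd <- 40
  grid$rmssd[grid$phase == "stimulation" & grid$condition == "taVNS"] <- 36
  grid$rmssd[grid$phase == "caloric_load"] <- 39
  grid
}

test_that("baseline correction subtracts the session baseline", {
  d <- baselineCorrect(mkSummary(), indices = "rmssd")
  expect_true(all(d$phase != "baseline"))
  expect_equal(unique(d$rmssd[d$phase == "stimulation" &
                                d$condition == "taVNS"]), -4)
  expect_equal(unique(d$rmssd[d$phase == "stimulation" &
                                d$condition == "sham"]), 0)
  expect_equal(unique(d$rmssd[d$phase == "caloric_load"]), -1)
})

test_that("sessions without a baseline are excluded with a message", {
  s <- mkSummary()
  s <- s[!(s$subject == 1 & s$session == 1 & s$phase == "baseline"), ]
  expect_message(d <- baselineCorrect(s, indices = "rmssd"), "dropped")
  expect_false(any(d$subject == 1 & d$session == 1))
})

test_that("net effects are taVNS minus sham pairwise differences", {
  d <- baselineCorrect(mkSummary(), indices = "rmssd")
  net <- netEffect(d, indices = "rmssd")
  expect_equal(unique(net$rmssd[net$phase == "stimulation"]), -4)
  expect_equal(unique(net$rmssd[net$phase == "caloric_load"]), 0)
  expect_equal(nrow(net), 6 * 2 * 2)
})

test_that("bootstrap handles degenerate and signed inputs correctly", {
  z <- bootstrapEffect(rep(0, 10), nResamples = 2000, seed = 1)
  expect_equal(z$b, 0)
  expect_equal(c(z$ci_lo, z$ci_hi), c(0, 0))
  expect_equal(z$p_boot, 1)
  neg <- bootstrapEffect(c(-1, -2, -3, -4, -5), nResamples = 5000, seed = 2)
  expect_lt(neg$ci_hi, 0)
  expect_equal(neg$b, -3)
  expect_lte(neg$p_boot, 0.05)
  const <- bootstrapEffect(rep(2, 8), nResamples = 2000, seed = 3)
  expect_equal(c(const$ci_lo, const$ci_hi), c(2, 2))
  expect_equal(const$p_boot, 1 / 2000)
  expect_error(bootstrapEffect(1:3), "at least 5")
})

test_that("bootstrap p-value and CI agree about excluding zero", {
  set.seed(4)
  for (shift in c(0, 0.3, 0.6, 1)) {
    x <- rnorm(36) + shift
    r <- bootstrapEffect(x, nResamples = 50000, seed = 5)
    expect_equal(r$p_boot <= 0.05, r$ci_lo > 0 | r$ci_hi < 0)
  }
})

test_that("BH adjustment equals the hand step-up rule", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(6)
  for (i in 1:5) {
    p <- runif(sample(3:12, 1))
    expect_equal(bhAdjust(p), bhStepUpOracle(p))
    expect_true(all(bhAdjust(p) >= p))
    expect_true(all(diff(bhAdjust(sort(p))) >= -1e-12))
  }
})

test_that("Cohen's dz follows its definition and is antisymmetric", {
  x <- c(-15, -5, 5)  # mean -5, sd 10
  expect_equal(cohensDz(x), -0.5)
  expect_equal(cohensDz(-x), 0.5)
  expect_error(cohensDz(rep(0, 5)), "variance")
})

test_that("JZS Bayes factor matches fine-grid quadrature to 1e-6", {
  for (tc in list(c(0, 36), c(2.1, 36), c(-3.5, 20), c(1.2, 10))) {
    bf <- jzsBayesFactor(t = tc[1], n = tc[2])
    oracle <- jzsSimpsonOracle(tc[1], tc[2])
    expect_lt(abs(bf - oracle) / oracle, 1e-6)
  }
})

test_that("JZS Bayes factor favours the null at t = 0 and grows in |t|", {
  expect_lt(jzsBayesFactor(t = 0, n = 36), 1)
  ts <- c(0, 0.5, 1, 2, 3, 5)
  bfs <- vapply(ts, function(t) jzsBayesFactor(t = t, n = 36), numeric(1))
  expect_true(all(diff(bfs) > 0))
  set.seed(7)
  d <- rnorm(20, -0.6)
  expect_equal(jzsBayesFactor(d),
               jzsBayesFactor(t = mean(d) / (sd(d) / sqrt(20)), n = 20))
})

test_that("Pillai's trace reduces to the univariate F for one response", {
  set.seed(8)
  y <- rnorm(30)
  g <- gl(3, 10)
  m <- manovaPillai(cbind(y), g)
  a <- anova(lm(y ~ g))
  expect_equal(m$F, a$`F value`[1])
  expect_equal(m$p, a$`Pr(>F)`[1])
  expect_equal(m$pillai / (1 - m$pillai) * (m$df2 / m$df1), m$F)
})

test_that("Pillai's trace agrees with the reference MANOVA fit", {
  set.seed(9)
  y <- matrix(rnorm(40 * 4), 40)
  y[, 1] <- y[, 1] + rep(c(0, 0.8), each = 20)
  g <- gl(2, 20)
  m <- manovaPillai(y, g)
  ref <- summary(stats::manova(y ~ g), test = "Pillai")$stats
  expect_equal(m$pillai, unname(ref[1, "Pillai"]))
  expect_equal(m$F, unname(ref[1, "approx F"]))
  expect_equal(m$df1, unname(ref[1, "num Df"]))
  expect_equal(m$df2, unname(ref[1, "den Df"]))
})

test_that("null MANOVA p-values are uniform at the 5% level", {
  set.seed(10)
  hits <- mean(replicate(500, {
    manovaPillai(matrix(rnorm(30 * 4), 30), gl(2, 15))$p < 0.05
  }))
  expect_gt(hits, 0.03)
  expect_lt(hits, 0.07)
})

test_that("degenerate designs and responses are refused", {
  set.seed(11)
  y <- matrix(rnorm(20 * 2), 20)
  ydup <- cbind(y, y[, 1])
  expect_error(manovaPillai(ydup, gl(2, 10)), "singular|duplicated")
  x <- data.frame(a = gl(2, 10), b = gl(2, 10))
  expect_error(manovaPillai(y, x), "rank|aliased")
})

test_that("Fisher-z side-correlation comparison behaves as specified", {
  expect_equal(atanh(0), 0)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  r <- c(0.6, 0.4, 0.7, 0.5)
  eq <- sideCorrelationTest(r, r)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  expect_error(sideCorrelationTest(c(1, 0.5), c(0.2, 0.3)), "inside")
  res <- sideCorrelationTest(c(0.6, 0.7, 0.5, 0.65), c(0.2, 0.3, 0.1, 0.25))
  ref <- t.test(atanh(c(0.6, 0.7, 0.5, 0.65)) -
                  atanh(c(0.2, 0.3, 0.1, 0.25)))
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
})

test_that("the effect table averages sides first and adjusts p-values", {
  set.seed(12)
  d <- baselineCorrect(mkSummary(), indices = "rmssd")
  net <- netEffect(d, indices = "rmssd")
  net$rmssd <- net$rmssd + rnorm(nrow(net), 0, 0.5)
  eff <- analyzeEffects(net, indices = "rmssd", nResamples = 2000, seed = 13)
  expect_equal(nrow(eff), 2L)
  expect_setequal(eff$phase, c("stimulation", "caloric_load"))
  expect_equal(eff$n, c(6L, 6L))
  expect_equal(eff$p_adj, bhAdjust(eff$p_boot))
  stim <- eff[eff$phase == "stimulation", ]
  agg <- tapply(net$rmssd[net$phase == "stimulation"],
                net$subject[net$phase == "stimulation"], mean)
  expect_equal(stim$b, mean(agg))
})
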