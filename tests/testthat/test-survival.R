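# Cox partial likelihood, linear fits, C-index, Kaplan-Meier, stratification.
# survival::coxph / survfit / concordance serve as independent cross-checks.

test_that("partial likelihood matches hand-evaluated examples", {
  # two events, equal scores: -(1/2)[(0 - log 2) + (0 - log 1)] = log(2)/2
  expect_equal(negLogPartialLikelihood(c(0, 0), survivalCohort(c(1, 2), c(1, 1))),
               log(2) / 2, tolerance = 1e-12)
  # censored subject contributes only through the risk set
  expect_equal(negLogPartialLikelihood(c(1, 0), survivalCohort(c(1, 2), c(1, 0))),
               log(1 + exp(1)) - 1, tolerance = 1e-12)
  # a lone event whose risk set is itself
  expect_equal(negLogPartialLikelihood(3.2, survivalCohort(5, 1)), 0)
  expect_error(negLogPartialLikelihood(c(1, 2), survivalCohort(c(1, 2), c(0, 0))),
               "no events")
})

test_that("the loss depends only on score differences and never overflows", {
  rc <- randomCohort(40, seed = 51)
  l0 <- negLogPartialLikelihood(rc$h, rc$cohort)
  expect_lt(abs(negLogPartialLikelihood(rc$h + 17.3, rc$cohort) - l0), 1e-10)
  big <- rc$h * 50 / max(abs(rc$h))
  expect_true(is.finite(negLogPartialLikelihood(big, rc$cohort)))
  expect_true(all(is.finite(sphsurv:::coxLossGradient(big, rc$time, rc$event))))
})

test_that("the Breslow loss gradient matches finite differences", {
  rc <- randomCohort(25, seed = 52, tieProb = 0.5)
  g <- sphsurv:::coxLossGradient(rc$h, rc$time, rc$event)
  eps <- 1e-6
  for (k in c(1, 7, 20)) {
    hp <- rc$h; hp[k] <- hp[k] + eps
    hm <- rc$h; hm[k] <- hm[k] - eps
    fd <- (negLogPartialLikelihood(hp, rc$cohort) -
             negLogPartialLikelihood(hm, rc$cohort)) / (2 * eps)
    expect_lt(abs(fd - g[k]) / max(abs(fd), 1e-8), 1e-4)
  }
})

test_that("Efron tie handling agrees with Breslow when no times are tied", {
  rc <- randomCohort(20, seed = 53)
  expect_equal(negLogPartialLikelihood(rc$h, rc$cohort, ties = "efron"),
               negLogPartialLikelihood(rc$h, rc$cohort, ties = "breslow"),
               tolerance = 1e-12)
})

test_that("C-index matches hand examples and the documented tie rules", {
  expect_equal(concordanceIndex(c(3, 2, 1), survivalCohort(c(1, 2, 3), c(1, 1, 1))), 1)
  expect_equal(concordanceIndex(c(2, 1, 4), survivalCohort(c(2, 4, 3), c(1, 1, 0))), 0.5)
  expect_equal(concordanceIndex(c(1, 1, 1), survivalCohort(c(1, 2, 3), c(1, 1, 1))), 0.5)
  expect_error(concordanceIndex(c(1, 2), survivalCohort(c(3, 3), c(0, 0))),
               "comparable")
})

test_that("C-index equals brute-force pair enumeration on random cohorts", {
  for (s in 1:100) {
    rc <- randomCohort(30, seed = 600 + s, censorFraction = 0.3,
                       tieProb = if (s %% 3 == 0) 0.5 else 0)
    expect_equal(concordanceIndex(rc$h, rc$cohort),
                 bruteForceCIndex(rc$h, rc$time, rc$event))
  }
})

test_that("C-index is antisymmetric under score negation without ties", {
  for (s in 1:10) {
    rc <- randomCohort(25, seed = 700 + s)
    expect_equal(concordanceIndex(rc$h, rc$cohort) +
                   concordanceIndex(-rc$h, rc$cohort), 1, tolerance = 1e-12)
  }
})

test_that("C-index agrees with the survival package on tie-free cohorts", {
  skip_if_not_installed("survival")
  for (s in 1:5) {
    rc <- randomCohort(60, seed = 800 + s)
    ours <- concordanceIndex(rc$h, rc$cohort)
    ref <- survival::concordance(
      survival::Surv(rc$time, rc$event) ~ rc$h, reverse = TRUE)$concordance
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("Kaplan-Meier matches hand-computed survival probabilities", {
  km <- kaplanMeier(survivalCohort(c(1, 2, 3), c(1, 0, 1)))
  expect_equal(kmSurvival(km, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(kmSurvival(km, 3), 0)
  expect_equal(kmSurvival(km, 0.5), 1)

  # all censored: survival stays at 1
  kmAll <- kaplanMeier(survivalCohort(c(1, 2), c(0, 0)))
  expect_equal(kmSurvival(kmAll, 10), 1)

  # all events at distinct times telescope to (n-k)/n
  n <- 7
  kmTel <- kaplanMeier(survivalCohort(1:n, rep(1, n)))
  expect_equal(kmTel@surv, (n - 1:n) / n, tolerance = 1e-12)
})

test_that("Kaplan-Meier without censoring equals the empirical survivor function", {
  set.seed(61)
  tms <- rexp(50) + 0.1
  km <- kaplanMeier(survivalCohort(tms, rep(1, 50)))
  at <- sort(tms)
  expect_equal(kmSurvival(km, at), 1 - rank(at) / 50, tolerance = 1e-12)
})

test_that("Kaplan-Meier agrees with survival::survfit under censoring", {
  skip_if_not_installed("survival")
  rc <- randomCohort(40, seed = 62)
  km <- kaplanMeier(rc$cohort)
  sf <- survival::survfit(survival::Surv(rc$time, rc$event) ~ 1)
  ref <- summary(sf, times = km@time)
  expect_equal(km@surv, ref$surv, tolerance = 1e-10)
})

test_that("median stratification follows the documented tie rule", {
  g <- stratifyByMedian(c(1, 2, 3, 4))
  expect_identical(as.character(g), c("low", "low", "high", "high"))
  expect_identical(as.character(stratifyByMedian(rep(2, 5))), rep("low", 5))
  g5 <- stratifyByMedian(c(5, 1, 3, 2, 4))
  expect_equal(sum(g5 == "low"), 3)   # ceiling(n/2) with the <=-median rule
  expect_error(stratifyByMedian(1), "at least 2")
})

test_that("Newton fit recovers simulated coefficients and minimizes the loss", {
  spec <- phantomCohortSpec(nSubjects = 500, betaTrue = c(1), lambda0 = 0.05,
                            cMax = 60, seed = 63)
  x <- matrix(rnorm(500), 500, 1)
  coh <- simulateSurvival(spec, x)
  fit <- fitLinearCoxph(coh)
  expect_gte(fit$beta, 0.8)
  expect_lte(fit$beta, 1.2)
  expect_lt(fit$gradientNorm, 1e-8)

  # stationarity via finite differences of the loss itself
  eps <- 1e-5
  lossAt <- function(b) negLogPartialLikelihood(as.vector(x * b), coh)
  fd <- (lossAt(fit$beta + eps) - lossAt(fit$beta - eps)) / (2 * eps)
  expect_lt(abs(fd), 1e-6)

  # local minimality under random perturbations
  set.seed(64)
  for (e in c(1e-4, 1e-3, 1e-2)) {
    expect_lte(lossAt(fit$beta), lossAt(fit$beta + sample(c(-1, 1), 1) * e) + 1e-12)
  }
})

test_that("Newton fit matches survival::coxph with Breslow ties", {
  skip_if_not_installed("survival")
  spec <- phantomCohortSpec(nSubjects = 200, betaTrue = c(0.8, -0.5),
                            seed = 65)
  x <- matrix(rnorm(400), 200, 2)
  coh <- simulateSurvival(spec, x)
  fit <- fitLinearCoxph(coh)
  ref <- survival::coxph(
    survival::Surv(survivalTimes(coh), eventIndicators(coh)) ~ x,
    ties = "breslow")
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
})

test_that("null simulations yield near-zero coefficients", {
  spec <- phantomCohortSpec(nSubjects = 500, betaTrue = c(0), seed = 66)
  x <- matrix(rnorm(500), 500, 1)
  coh <- simulateSurvival(spec, x)
  expect_lt(abs(fitLinearCoxph(coh)$beta), 0.2)
})

test_that("degenerate fits fail loudly", {
  # perfect separation: monotone likelihood
  coh <- survivalCohort(c(1, 2, 3, 4), c(1, 1, 1, 1),
                        covariates = matrix(c(4, 3, 2, 1), 4, 1))
  expect_error(fitLinearCoxph(coh))
  expect_error(fitLinearCoxph(survivalCohort(c(1, 2), c(1, 1))), "covariates")
})
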