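# Survival statistics for right-censored data.
#
# The hazard model is lambda(t|x) = lambda0(t) exp(h(x)); with a linear
# log-risk h(x) = beta'x this is the Cox proportional hazards model, and with
# the spherical network as h it is the DeepSurv generalization. The training
# criterion is the average negative log partial likelihood with Breslow
# handling of tied event times; the risk set at an event time T_i is
# {j : T_j >= T_i} and includes subject i itself.

#' Construct a survival cohort
#'
#' @param time observation times (months), > 0
#' @param event 0/1 event indicators (1 = death observed at \code{time})
#' @param covariates optional numeric matrix of per-subject covariates
#' @param risk optional per-subject risk scores (log-risk scale)
#' @param subjectId optional identifiers
#' @return a \linkS4class{SurvivalCohort}
#' @export
survivalCohort <- function(time, event, covariates = NULL, risk = numeric(0),
                           subjectId = NULL) {
  n <- length(time)
  if (is.null(subjectId)) subjectId <- sprintf("S%04d", seq_len(n))
  if (is.null(covariates)) covariates <- matrix(numeric(0), 0, 0)
  new("SurvivalCohort", subjectId = as.character(subjectId),
      time = as.numeric(time), event = as.integer(event),
      covariates = as.matrix(covariates), risk = as.numeric(risk))
}

#' Average negative log partial likelihood
#'
#' \deqn{L = -\frac{1}{N_E}\sum_{i: E_i=1}\Big[h_i - \log\sum_{j: T_j \ge T_i}
#' e^{h_j}\Big]}
#' with Breslow handling of ties (all events at a tied time share the same
#' risk set, which includes the subjects failing at that time). Optional Efron
#' correction refines the tied-time risk sets. The log-sum-exp is shifted by
#' the maximum, so scores up to +-50 are handled without overflow.
#'
#' @param h risk scores (log-risk), one per subject
#' @param cohort a \linkS4class{SurvivalCohort}
#' @param ties \code{"breslow"} (default) or \code{"efron"}
#' @return scalar loss
#' @export
negLogPartialLikelihood <- function(h, cohort, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  time <- survivalTimes(cohort); event <- eventIndicators(cohort)
  if (length(h) != length(time)) stop("score/cohort length mismatch")
  if (any(!is.finite(h))) stop("scores must be finite")
  nev <- sum(event)
  if (nev == 0L) stop("loss undefined: cohort contains no events")
  loss <- 0
  for (t0 in unique(time[event == 1L])) {
    atRisk <- time >= t0
    dying <- event == 1L & time == t0
    d <- sum(dying)
    hmax <- max(h[atRisk])     # per-risk-set shift: stable for any score spread
    eh <- exp(h[atRisk] - hmax)
    denom <- sum(eh)
    if (ties == "breslow" || d == 1L) {
      loss <- loss - sum(h[dying] - hmax - log(denom)) / nev
    } else {
      tieSum <- sum(exp(h[dying] - hmax))
      r <- 0:(d - 1)
      loss <- loss - (sum(h[dying] - hmax) -
                        sum(log(denom - r / d * tieSum))) / nev
    }
  }
  loss
}

# gradient of the Breslow loss wrt the scores; used by the trainer.
# The softmax over each risk set is shifted by its own maximum so the
# gradient stays finite for arbitrarily spread scores.
coxLossGradient <- function(h, time, event) {
  nev <- sum(event)
  grad <- -as.numeric(event)
  for (t0 in unique(time[event == 1L])) {
    atRisk <- time >= t0
    d <- sum(event == 1L & time == t0)
    eh <- exp(h[atRisk] - max(h[atRisk]))
    grad[atRisk] <- grad[atRisk] + d * eh / sum(eh)
  }
  grad / nev
}

#' Fit the linear Cox proportional hazards model
#'
#' Newton iterations on the Breslow partial likelihood until the gradient
#' infinity-norm drops below \code{tol}. This is the classical linear special
#' case h(x) = beta'x of the hazard model and doubles as the package's
#' independent reference connecting the loss to recoverable parameters.
#'
#' @param cohort a \linkS4class{SurvivalCohort} with covariates
#' @param tol gradient infinity-norm convergence threshold
#' @param maxIter maximum Newton steps
#' @return list with \code{beta}, final \code{loss}, \code{iterations},
#'   \code{gradientNorm}
#' @export
fitLinearCoxph <- function(cohort, tol = 1e-8, maxIter = 100L) {
  X <- covariateMatrix(cohort)
  if (nrow(X) == 0L) stop("cohort has no covariates")
  time <- survivalTimes(cohort); event <- eventIndicators(cohort)
  if (sum(event) == 0L) stop("no events: partial likelihood undefined")
  p <- ncol(X)
  beta <- rep(0, p)
  nev <- sum(event)
  for (iter in seq_len(maxIter)) {
    eta <- as.vector(X %*% beta)
    grad <- as.vector(t(X) %*% coxLossGradient(eta, time, event))
    hess <- matrix(0, p, p)
    eh <- exp(eta - max(eta))
    for (t0 in unique(time[event == 1L])) {
      atRisk <- which(time >= t0)
      d <- sum(event == 1L & time == t0)
      wr <- eh[atRisk] / sum(eh[atRisk])
      xbar <- colSums(X[atRisk, , drop = FALSE] * wr)
      xc <- sweep(X[atRisk, , drop = FALSE], 2, xbar, "-")
      hess <- hess + d * t(xc) %*% (xc * wr) / nev
    }
    if (max(abs(grad)) < tol) {
      if (max(abs(beta)) > 15)
        stop("monotone partial likelihood (perfect separation): |beta| ",
             "diverges; no finite maximizer exists")
      return(list(beta = beta,
                  loss = negLogPartialLikelihood(eta, cohort),
                  iterations = iter - 1L, gradientNorm = max(abs(grad))))
    }
    step <- tryCatch(solve(hess, grad), error = function(e)
      stop("Cox Newton step failed (singular information matrix): ",
           conditionMessage(e)))
    if (any(!is.finite(step)) || max(abs(beta - step)) > 50)
      stop("Cox fit diverging (monotone likelihood / perfect separation?)")
    beta <- beta - step
  }
  stop("Cox Newton did not converge in ", maxIter,
       " iterations; last gradient norm ", format(max(abs(grad))))
}

#' Harrell's concordance index
#'
#' Fraction of comparable subject pairs whose risk ordering matches the
#' observed survival ordering. Pair (i, j) is comparable with i the earlier
#' subject iff \code{E_i = 1} and \code{T_i < T_j}, or \code{T_i = T_j} with
#' \code{E_i = 1, E_j = 0}. Concordant pairs (higher risk for the earlier
#' subject) count 1, tied scores 0.5. Higher score = higher risk = shorter
#' expected survival.
#'
#' @param h risk scores
#' @param cohort a \linkS4class{SurvivalCohort}
#' @return concordance in [0, 1]
#' @export
concordanceIndex <- function(h, cohort) {
  time <- survivalTimes(cohort); event <- eventIndicators(cohort)
  n <- length(time)
  if (length(h) != n) stop("score/cohort length mismatch")
  num <- 0; den <- 0
  for (i in which(event == 1L)) {
    later <- time > time[i] | (time == time[i] & event == 0L)
    later[i] <- FALSE
    den <- den + sum(later)
    num <- num + sum(h[i] > h[later]) + 0.5 * sum(h[i] == h[later])
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

#' Kaplan-Meier estimate of the survivor function
#'
#' \deqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over distinct event times,
#' with censored subjects leaving the risk set just after their censoring
#' time.
#'
#' @param cohort a \linkS4class{SurvivalCohort}
#' @return a \linkS4class{KMEstimate}
#' @export
kaplanMeier <- function(cohort) {
  time <- survivalTimes(cohort); event <- eventIndicators(cohort)
  if (length(time) == 0L) stop("empty cohort")
  evt <- sort(unique(time[event == 1L]))
  surv <- numeric(length(evt)); nRisk <- numeric(length(evt))
  nEvent <- numeric(length(evt))
  s <- 1
  for (k in seq_along(evt)) {
    nRisk[k] <- sum(time >= evt[k])
    nEvent[k] <- sum(time == evt[k] & event == 1L)
    s <- s * (1 - nEvent[k] / nRisk[k])
    surv[k] <- s
  }
  new("KMEstimate", time = evt, surv = surv, nRisk = nRisk, nEvent = nEvent)
}

#' Evaluate a Kaplan-Meier estimate at arbitrary times
#' @param km a \linkS4class{KMEstimate}
#' @param t times
#' @return S(t)
#' @export
kmSurvival <- function(km, t) {
  vapply(t, function(tt) {
    k <- sum(km@time <= tt)
    if (k == 0L) 1 else km@surv[k]
  }, numeric(1))
}

#' Median survival time of a Kaplan-Meier estimate
#'
#' Smallest event time with S(t) <= 0.5, or NA if the curve never reaches 0.5.
#' @param km a \linkS4class{KMEstimate}
#' @return time or NA
#' @export
kmMedian <- function(km) {
  i <- which(km@surv <= 0.5)
  if (length(i) == 0L) NA_real_ else km@time[min(i)]
}

#' Median-risk stratification into low/high groups
#'
#' Subjects with score above the median go to \code{"high"}; scores at or
#' below the median go to \code{"low"} (deterministic tie rule). With distinct
#' scores and even n the split is exactly half/half.
#'
#' @param h risk scores, length >= 2
#' @return factor with levels \code{low}, \code{high}
#' @export
stratifyByMedian <- function(h) {
  if (length(h) < 2L) stop("need at least 2 subjects to stratify")
  med <- stats::median(h)
  factor(ifelse(h > med, "high", "low"), levels = c("low", "high"))
}
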