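# DeepSurv-style training of the spherical risk network.
#
# The network's scalar outputs h are plugged into the average negative log
# partial likelihood; mini-batches form their own risk sets (the standard
# stochastic compromise for Cox training; set batchSize >= n for exact
# full-cohort risk sets). Optimization is Adam with decoupled weight decay on
# the filter and dense weights. Model selection uses the validation loss;
# the validation C-index is logged for transparency. Channel normalization
# statistics are computed on the training split only and stored in the model,
# so no information leaks from validation or test subjects.

# per-channel mean/sd over a set of maps
computeNormStats <- function(maps, idx = seq_along(maps)) {
  chans <- channelNames(maps[[1]])
  stats <- lapply(chans, function(ch) {
    v <- unlist(lapply(maps[idx], function(m) mapChannel(m, ch)))
    list(mean = mean(v), sd = max(stats::sd(v), 1e-8))
  })
  names(stats) <- chans
  stats
}

# stack standardized maps into the (S, Cin, 2B, 2B) batch array
stackInputs <- function(maps, model) {
  B2 <- 2 * model@config$bandwidth
  S <- length(maps)
  X <- array(0, c(S, model@config$channelsIn, B2, B2))
  for (s in seq_len(S)) X[s, , , ] <- standardizeInput(model, maps[[s]])
  X
}

# event-stratified index split: returns list(train, val)
stratifiedHoldout <- function(event, valFraction) {
  val <- integer(0)
  for (e in unique(event)) {
    idx <- which(event == e)
    k <- round(length(idx) * valFraction)
    if (k > 0) val <- c(val, sample(idx, k))
  }
  list(train = setdiff(seq_along(event), val), val = sort(val))
}

#' Train the spherical risk network
#'
#' Minimizes the average negative log partial likelihood of the network
#' outputs by Adam, with mini-batch risk sets (batches are reshuffled until
#' every batch contains an event). An event-stratified validation split is
#' held out for model selection on validation loss; the returned model is the
#' best-validation-loss checkpoint.
#'
#' @param maps list of \linkS4class{SphericalMap}, one per subject
#' @param cohort matching \linkS4class{SurvivalCohort}
#' @param config network architecture from \code{\link{networkConfig}}
#' @param seed RNG seed; fixed seed makes the run bit-reproducible
#' @param epochs training epochs
#' @param learningRate Adam step size
#' @param weightDecay decoupled weight decay on filter/dense weights
#' @param batchSize mini-batch size; use >= n for full-batch (exact) risk sets
#' @param valFraction held-out fraction for model selection (0 disables)
#' @param verbose print per-epoch progress
#' @return list: \code{model} (\linkS4class{RiskModel}), \code{history}
#'   (data.frame: epoch, trainLoss, valLoss, valCIndex), \code{split}
#'   (train/val indices, so the provenance of the normalization statistics
#'   can be audited)
#' @export
trainRiskModel <- function(maps, cohort, config = networkConfig(), seed = 1L,
                           epochs = 60L, learningRate = 1e-3,
                           weightDecay = 1e-4, batchSize = 64L,
                           valFraction = 0.2, verbose = FALSE) {
  n <- length(maps)
  if (n != nSubjects(cohort)) stop("maps/cohort length mismatch")
  time <- survivalTimes(cohort); event <- eventIndicators(cohort)
  if (sum(event) == 0L) stop("training set contains no events")
  set.seed(seed)
  sp <- stratifiedHoldout(event, valFraction)
  tr <- sp$train; va <- sp$val
  if (sum(event[tr]) == 0L) stop("training split contains no events")

  model <- newRiskModel(config, seed = seed)
  model@normStats <- computeNormStats(maps, tr)
  X <- stackInputs(maps, model)

  pv <- paramsToVec(model@params)
  skeleton <- model@params
  # decoupled weight decay applies to filter/dense weights, not biases
  decayMask <- rep(1, length(pv))
  biasNames <- c("bias1", "bias2", "bd1", "bd2")
  off <- 0L
  for (nm in names(skeleton)) {
    len <- length(paramsToVec(skeleton[nm]))
    if (nm %in% biasNames) decayMask[off + seq_len(len)] <- 0
    off <- off + len
  }
  stopifnot(off == length(pv))

  mAd <- numeric(length(pv)); vAd <- numeric(length(pv))
  beta1 <- 0.9; beta2 <- 0.999; epsAd <- 1e-8
  step <- 0L
  bestVal <- Inf; bestVec <- pv
  hist <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                     valLoss = numeric(0), valCIndex = numeric(0))

  evalLoss <- function(pvec, idx) {
    p <- vecToParams(pvec, skeleton)
    fw <- riskForwardBatch(p, config, X[idx, , , , drop = FALSE])
    h <- fw$h
    list(loss = negLogPartialLikelihood(h, survivalCohort(time[idx], event[idx])),
         h = h)
  }

  for (ep in seq_len(epochs)) {
    # batches resampled until every batch's risk structure has an event
    for (try in 1:100) {
      ord <- sample(tr)
      batches <- split(ord, ceiling(seq_along(ord) / batchSize))
      if (all(vapply(batches, function(b) sum(event[b]) > 0, logical(1)))) break
      if (try == 100) stop("could not form batches with events; reduce batchSize")
    }
    epLoss <- 0
    for (b in batches) {
      p <- vecToParams(pv, skeleton)
      fw <- riskForwardBatch(p, config, X[b, , , , drop = FALSE],
                             keepCache = TRUE)
      epLoss <- epLoss + negLogPartialLikelihood(
        fw$h, survivalCohort(time[b], event[b])) * length(b)
      gh <- coxLossGradient(fw$h, time[b], event[b])
      gv <- paramsToVec(riskBackwardBatch(p, config, fw, gh)[names(skeleton)])
      step <- step + 1L
      mAd <- beta1 * mAd + (1 - beta1) * gv
      vAd <- beta2 * vAd + (1 - beta2) * gv^2
      mh <- mAd / (1 - beta1^step)
      vh <- vAd / (1 - beta2^step)
      pv <- pv - learningRate * (mh / (sqrt(vh) + epsAd) +
                                   weightDecay * decayMask * pv)
    }
    epLoss <- epLoss / length(tr)
    if (length(va) > 0 && sum(event[va]) > 0) {
      ev <- evalLoss(pv, va)
      vci <- tryCatch(concordanceIndex(ev$h,
                                       survivalCohort(time[va], event[va])),
                      error = function(e) NA_real_)
      if (ev$loss < bestVal) { bestVal <- ev$loss; bestVec <- pv }
      hist <- rbind(hist, data.frame(epoch = ep, trainLoss = epLoss,
                                     valLoss = ev$loss, valCIndex = vci))
      if (verbose) message(sprintf("epoch %3d train %.4f val %.4f C %.3f",
                                   ep, epLoss, ev$loss, vci))
    } else {
      bestVec <- pv
      hist <- rbind(hist, data.frame(epoch = ep, trainLoss = epLoss,
                                     valLoss = NA_real_, valCIndex = NA_real_))
      if (verbose) message(sprintf("epoch %3d train %.4f", ep, epLoss))
    }
  }
  model@params <- vecToParams(bestVec, skeleton)
  list(model = model, history = hist, split = sp)
}

#' Predict risk scores for a list of maps
#' @param model a trained \linkS4class{RiskModel}
#' @param maps list of \linkS4class{SphericalMap}
#' @return numeric vector of log-risk scores
#' @export
predictRiskAll <- function(model, maps) {
  X <- stackInputs(maps, model)
  riskForwardBatch(model@params, model@config, X)$h
}
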